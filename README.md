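# MeshOverlap

Mesh-based regional comparison of 3D segmentations of small structures.

## What problem this solves

Segmentations of small anatomical structures (the motivating case is the
hippocampus on T1-weighted MRI, outlined manually or by FSL-FIRST /
FreeSurfer) need to be compared across repeated scans and across methods:
how reproducible is each method between back-to-back acquisitions, and
where along the structure do methods systematically disagree? Resampling
one label map into another scan's voxel lattice introduces interpolation
error comparable to the effects of interest. MeshOverlap avoids that by
converting each label map once, in its native space, into a closed
triangulated surface, moving the surfaces with the rigid registration
matrices, and measuring everything on the surfaces.

The toolkit computes, for surface pairs \(A, B\) on a fine regular point
grid (with \(N(V)\) the number of grid points inside surface \(V\)):

- global overlap `Jacc(A,B) = N(A∩B) / N(A∪B)`;
- regional overlap `Jacc_ROI = N((A∩B)∩ROI) / N((A∩ROI)∪(B∩ROI))` for
  anterior/middle/posterior regions obtained by splitting a template mask
  35/45/20% along its long (first principal) axis;
- grid-counted and divergence-theorem volumes, globally and per region;
- full-circle registration QC: for a closed cycle of transforms,
  `RM = ∏ T_ij` should be the identity; the residual is summarized as
  `TranslationTotal = ‖t(RM)‖`,
  `RotationTotal = acos((trace R(RM) − 1)/2)` and
  `Consistency = Jacc(S, RM(S))`, with `1 − Consistency` the registration
  error;
- linear mixed models for volumes and ninth-power-transformed Jaccard
  indices (`J = Jacc⁹`), with factorial fixed effects (group, method,
  hemisphere, timepoint, region and interactions), a per-subject random
  intercept, ML estimation, Satterthwaite per-term tests, and backward AIC
  elimination of the fixed structure.

Synthetic phantoms with analytic ground truth (spheres, ellipsoids, a
bent tube with a computable long axis; back-to-back pairs under a known
rigid perturbation with boundary noise; factorial tables drawn from a
known mixed model) make the whole pipeline testable without scan data.
See `vignettes/meshoverlap-methods.Rmd` for the methods account.

## Worked example

```r
library(MeshOverlap)

# a back-to-back phantom pair: 8 mm sphere at 1 mm voxels, the second
# acquisition shifted by (1, 0.5, 0) mm and rotated 2 deg, with 5% of
# boundary voxels flipped to mimic outline variability
pair <- makePair(shapeSpec("sphere", radii = 8), dims = c(25, 25, 25),
                 perturbation = rigidFromAxisAngle(c(0, 0, 1), 2, c(1, 0.5, 0)),
                 flipRate = 0.05, seed = 42)
a <- extractSurface(pair$a)
b <- extractSurface(pair$b)
a
#> TriSurface: 2006 vertices, 4008 triangles, 1 component(s)
#>   bbox (mm): [ -7.5, -7.5, -7.5 ] - [ 7.5, 7.5, 7.5 ]

comparePair(a, b, spacing = 0.5)
#> ComparisonRecord (grid spacing 0.5 mm)
#>   global Jaccard: 0.796627
#>   volumes (mm^3): A = 2103.62 , B = 2091.5
```

The two segmentations of the same 2145 mm³ sphere overlap with Jaccard
0.797 — the misregistration-plus-noise level typical of automated
hippocampus outlines — and the grid-counted volumes (2104 and 2092 mm³)
carry the ~2% discretization deficit of binarized 1 mm data, identical
for both members so differences remain meaningful. For Gaussian
modelling the index is transformed: `transformResponse(0.796627)` gives
`0.1292` (= 0.797⁹).

Registration QC on a consistent cycle is exactly clean:

```r
rm <- composeCircle(list(pair$truth, invertRigid(pair$truth)))
c(translationTotal(rm), rotationTotal(rm))
#> [1] 0 0
```

Mixed-model machinery on a simulated design (20 subjects per diagnostic
group, volume-like response in cm³):

```r
tab <- simulateObservations(designSpec(
  effects = list(intercept = 1.2, group = c(AD = -0.2),
                 region = c(Middle = 0.1, Posterior = -0.45)),
  subjectSD = 0.1, residualSD = 0.05, seed = 1))
fit <- fitModel(tab, modelSpec(fixed = c("group", "region")))
fit
#> FitResult: response ~ group + region + (1 | subject)
#>   ML logLik: 4246.19  AIC: -8476.38  k: 8
#>   sd(subject): 0.089948  sd(residual): 0.051897

head(predictionTable(fit, at = list(hemisphere = "Left", timepoint = "BL",
                                    method = "Manual"))[
  c("group", "region", "predicted")], 4)
#>   group   region predicted
#> 1    AD Anterior  1.011956
#> 2  CTRL Anterior  1.219586
#> 3  MCIN Anterior  1.194973
#> 4  MCIP Anterior  1.210847
```

The fitted cell means recover the injected structure (AD anterior
1.0 = 1.2 − 0.2, the others ≈ 1.2 up to subject sampling), and
`backwardSelect(tab, volumeModelFull())` would prune the factorial model
down to the supported terms, returning the full drop-by-drop trace.

A command-line surface over the same functions (subcommands `phantom`,
`extract`, `regions`, `compare`, `circleqc`, `fitmodel`) is installed at
`inst/cli/meshoverlap.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","meshoverlap.R",package="MeshOverlap"))')" \
    phantom --kind sphere --radii 8,8,8 --dims 25,25,25 --seed 7 --out work/
```

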