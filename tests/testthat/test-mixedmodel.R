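test_that("the Jaccard power transform is exact and guarded", {
  expect_identical(transformResponse(1), 1)
  expect_identical(transformResponse(0), 0)
  expect_equal(transformResponse(0.829), 0.829^9, tolerance = 1e-15)
  expect_equal(transformResponse(0.829), 0.1849, tolerance = 1e-3)
  expect_true(is.na(transformResponse(NA)))
  expect_error(transformResponse(1.2), "0, 1")
  # strictly monotone: method rankings survive the transform
  j <- sort(runif(50))
  expect_identical(order(transformResponse(j)), order(j))
})

test_that("modelSpec canonicalizes terms and enforces marginality", {
  sp <- modelSpec(fixed = c("region:group", "group", "region"))
  expect_true("group:region" %in% sp@fixed)
  expect_error(modelSpec(fixed = c("group:region")), "marginality")
  expect_error(modelSpec(fixed = c("dose")), "unknown factor")
  expect_match(deparse(specFormula(sp)), "1 | subject")
})

test_that("noiseless tables are recovered coefficient-exactly", {
  tab <- simulateObservations(designSpec(nPerGroup = 4,
                                         effects = trueVolumeEffects()))
  fit <- fitModel(tab, modelSpec(fixed = trueVolumeTerms()))
  cf <- coef(fit)
  eff <- trueVolumeEffects()
  expect_equal(cf[["(Intercept)"]], eff$intercept, tolerance = 1e-8)
  expect_equal(cf[["groupCTRL"]], eff$group[["CTRL"]], tolerance = 1e-8)
  expect_equal(cf[["methodManual"]], eff$method[["Manual"]], tolerance = 1e-8)
  expect_equal(cf[["hemisphereRight"]], eff$hemisphere[["Right"]], tolerance = 1e-8)
  expect_equal(cf[["timepointM12"]], eff$timepoint[["M12"]], tolerance = 1e-8)
  expect_equal(cf[["groupCTRL:regionMiddle"]],
               eff[["group:region"]][["CTRL.Middle"]], tolerance = 1e-8)
  expect_equal(cf[["methodManual:regionPosterior"]],
               eff[["method:region"]][["Manual.Posterior"]], tolerance = 1e-8)
  expect_lt(fit@varcomp[["residual.sd"]], 1e-6)
})

test_that("the AIC identity holds and nesting never loses likelihood", {
  tab <- simulateObservations(designSpec(nPerGroup = 3,
                                         effects = trueVolumeEffects(),
                                         subjectSD = 0.1, residualSD = 0.05,
                                         seed = 21))
  small <- fitModel(tab, modelSpec(fixed = c("group", "region")))
  big <- fitModel(tab, modelSpec(fixed = c("group", "region", "group:region",
                                           "method")))
  for (f in list(small, big))
    expect_equal(f@AIC, 2 * f@nparam - 2 * f@logLik, tolerance = 1e-8)
  expect_gte(big@logLik, small@logLik)
})

test_that("variance components are estimated sanely", {
  tab <- simulateObservations(designSpec(nPerGroup = 20,
                                         effects = list(intercept = 5),
                                         subjectSD = 0, residualSD = 1,
                                         seed = 9))
  fit <- fitModel(tab, modelSpec(fixed = character()))
  expect_lt(abs(fit@varcomp[["residual.sd"]] - 1), 0.2)
  expect_lt(fit@varcomp[["subject.sd"]], 0.15)
})

test_that("inestimable designs fail naming the term", {
  tab <- simulateObservations(designSpec(nPerGroup = 3,
                                         effects = list(intercept = 1),
                                         residualSD = 0.1, seed = 2))
  tab <- tab[!(tab$group == "AD" & tab$region == "Middle"), ]
  expect_error(fitModel(tab, modelSpec(fixed = c("group", "region",
                                                 "group:region"))),
               "group:region")
})

test_that("term p-values separate huge effects from noise and sharpen with data", {
  tab <- simulateObservations(designSpec(nPerGroup = 5,
                                         effects = list(intercept = 1,
                                                        region = c(Middle = 2)),
                                         subjectSD = 0.1, residualSD = 0.3,
                                         seed = 31))
  fit <- fitModel(tab, modelSpec(fixed = c("region", "method")))
  p <- termPvalues(fit, tab)
  expect_identical(attr(p, "method"), "satterthwaite")
  expect_lt(p[["region"]], 1e-6)
  expect_gt(p[["method"]], 0.001)

  doubled <- rbind(tab, tab)
  doubled$subject <- c(as.character(tab$subject),
                       paste0(as.character(tab$subject), "b"))
  p2 <- termPvalues(fitModel(doubled, modelSpec(fixed = c("region", "method"))),
                    doubled)
  expect_lt(p2[["region"]], p[["region"]] + 1e-12)
  # the likelihood-ratio fallback agrees on what matters
  p3 <- termPvalues(fit, tab, method = "lrt")
  expect_identical(attr(p3, "method"), "lrt")
  expect_lt(p3[["region"]], 1e-6)
})

test_that("null p-values are approximately uniform", {
  lv <- list(group = "CTRL", method = c("FIRST", "FreeSurfer", "Manual"),
             hemisphere = "Left", timepoint = "BL", region = "Anterior")
  sp <- modelSpec(fixed = "method")
  pv <- vapply(1:200, function(s) {
    tab <- simulateObservations(designSpec(nPerGroup = 24, levels = lv,
                                           effects = list(intercept = 1),
                                           subjectSD = 0.5, residualSD = 1,
                                           seed = 5000 + s))
    termPvalues(fitModel(tab, sp), tab)[["method"]]
  }, 0)
  expect_gt(suppressWarnings(stats::ks.test(pv, "punif"))$p.value, 0.01)
})

test_that("backward elimination keeps a strongly supported true model intact", {
  tab <- simulateObservations(designSpec(nPerGroup = 10,
                                         effects = trueVolumeEffects(),
                                         subjectSD = 0.1, residualSD = 0.01,
                                         seed = 77))
  sel <- backwardSelect(tab, modelSpec(fixed = trueVolumeTerms()))
  expect_setequal(sel$spec@fixed, trueVolumeTerms())
  expect_true(all(!sel$trace$accepted))
})

test_that("selection is invariant to row order and records a full trace", {
  tab <- simulateObservations(designSpec(nPerGroup = 8,
                                         effects = trueVolumeEffects(),
                                         subjectSD = 0.1, residualSD = 0.05,
                                         seed = 13))
  sel1 <- backwardSelect(tab, volumeModelFull())
  set.seed(1)
  sel2 <- backwardSelect(tab[sample(nrow(tab)), ], volumeModelFull())
  expect_setequal(sel1$spec@fixed, sel2$spec@fixed)
  expect_identical(sel1$trace$term, sel2$trace$term)
  expect_true(all(c("step", "term", "p_value", "p_method", "aic_before",
                    "aic_after", "accepted") %in% names(sel1$trace)))
  # a main effect is never dropped while a retained interaction contains it
  kept <- volumeModelFull()@fixed
  for (i in seq_len(nrow(sel1$trace))) {
    if (!sel1$trace$accepted[i]) break
    tm <- sel1$trace$term[i]
    fs <- strsplit(tm, ":")[[1]]
    others <- setdiff(kept, tm)
    expect_false(any(vapply(others, function(o)
      all(fs %in% strsplit(o, ":")[[1]]), TRUE)))
    kept <- others
  }
})

test_that("cell predictions mirror the model structure", {
  tab <- simulateObservations(designSpec(nPerGroup = 4,
                                         effects = trueVolumeEffects()))
  fit <- fitModel(tab, modelSpec(fixed = trueVolumeTerms()))
  # noiseless: predictions equal observed cell means exactly
  cells <- unique(tab[c("group", "method", "hemisphere", "timepoint", "region")])
  pr <- predictCells(fit, cells)
  key <- do.call(paste, c(tab[names(cells)], sep = "."))
  obs <- tapply(tab$response, key, mean)
  expect_equal(unname(pr$predicted),
               as.vector(obs[do.call(paste, c(cells, sep = "."))]),
               tolerance = 1e-8)

  # additive hemisphere effect: right-table minus left-table is constant
  tabL <- predictionTable(fit, at = list(hemisphere = "Left"))
  tabR <- predictionTable(fit, at = list(hemisphere = "Right"))
  d <- tabR$predicted - tabL$predicted
  expect_lt(diff(range(d)), 1e-10)
  expect_equal(d[1], coef(fit)[["hemisphereRight"]], tolerance = 1e-8)

  # group:region interaction: group differences vary by region
  g <- predictionTable(fit, at = list(hemisphere = "Left", timepoint = "BL",
                                      method = "Manual"))
  dCtrl <- with(g, predicted[group == "CTRL"] - predicted[group == "AD"])
  expect_gt(diff(range(dCtrl)), 0.01)

  expect_error(predictCells(fit, data.frame(group = "XX", method = "Manual",
                                            hemisphere = "Left",
                                            timepoint = "BL",
                                            region = "Anterior")),
               "unknown level")
})
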