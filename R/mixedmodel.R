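## Linear-mixed-model analysis of volumes and (transformed) Jaccard indices:
## Gaussian models with fixed factorial effects and a per-subject random
## intercept, fitted by maximum likelihood (ML, not REML: AIC comparisons
## across different fixed-effect structures are only valid under ML),
## per-term ANOVA p-values with Satterthwaite denominator degrees of
## freedom, and backward elimination driven by AIC: the currently least
## significant droppable term is removed while the AIC does not increase.

.MM_FACTORS <- c("group", "method", "hemisphere", "timepoint", "region")

#' Power transform of Jaccard indices for Gaussian modelling
#'
#' Jaccard reproducibility indices are bounded and left-skewed; raising
#' them to the 9th power symmetrizes their error distribution well enough
#' for a Gaussian linear mixed model. Strictly monotone on \[0, 1\], so
#' method rankings on the transformed scale carry back to the Jaccard
#' scale.
#'
#' @param j Jaccard fraction(s) in \[0, 1\] (`NA` passed through).
#' @param power exponent (default 9).
#' @return `j ^ power`.
#' @examples
#' transformResponse(0.829)  # ~0.186
#' @export
transformResponse <- function(j, power = 9) {
  bad <- !is.na(j) & (j < 0 | j > 1)
  if (any(bad))
    stop("Jaccard values must lie in [0, 1]; offending value: ", j[bad][1])
  j^power
}

## canonical term: factors ordered as in .MM_FACTORS, joined by ":"
.canonTerm <- function(term) {
  parts <- strsplit(term, ":", fixed = TRUE)[[1]]
  bad <- setdiff(parts, .MM_FACTORS)
  if (length(bad))
    stop("unknown factor '", bad[1], "' in term '", term, "'; valid factors: ",
         paste(.MM_FACTORS, collapse = ", "))
  paste(parts[order(match(parts, .MM_FACTORS))], collapse = ":")
}

.termFactors <- function(term) strsplit(term, ":", fixed = TRUE)[[1]]

## ---------------------------------------------------------------------------
## ModelSpec
## ---------------------------------------------------------------------------

#' Fixed/random structure of a candidate mixed model
#'
#' Fixed terms are main effects and interactions over the factors `group`,
#' `method`, `hemisphere`, `timepoint`, `region`; the per-subject random
#' intercept is always present. Marginality is enforced: every
#' interaction's constituent main effects must be included.
#'
#' @slot response response column name.
#' @slot fixed character vector of canonical fixed terms.
#' @slot droppable subset of `fixed` eligible for backward elimination.
#' @export
setClass("ModelSpec",
  representation(response = "character", fixed = "character",
                 droppable = "character"))

setValidity("ModelSpec", function(object) {
  msg <- character()
  for (tm in object@fixed) {
    f <- .termFactors(tm)
    if (length(f) > 1) {
      need <- setdiff(f, object@fixed)
      if (length(need))
        msg <- c(msg, paste0("interaction ", tm, " requires main effect(s) ",
                             paste(need, collapse = ", "), " (marginality)"))
    }
  }
  if (!all(object@droppable %in% object@fixed))
    msg <- c(msg, "droppable terms must be a subset of the fixed terms")
  if (length(msg)) msg else TRUE
})

#' Construct a ModelSpec
#'
#' @param response response column name (default `"response"`).
#' @param fixed character vector of fixed terms, e.g.
#'   `c("group", "method", "group:method")`.
#' @param droppable terms eligible for elimination (default: all fixed
#'   terms).
#' @return A [ModelSpec-class].
#' @examples
#' modelSpec(fixed = c("group", "region", "group:region"))
#' @export
modelSpec <- function(response = "response", fixed = character(),
                      droppable = fixed) {
  fixed <- vapply(fixed, .canonTerm, "", USE.NAMES = FALSE)
  droppable <- vapply(droppable, .canonTerm, "", USE.NAMES = FALSE)
  new("ModelSpec", response = response, fixed = unique(fixed),
      droppable = unique(droppable))
}

setMethod("show", "ModelSpec", function(object) {
  cat("ModelSpec:", object@response, "~",
      paste(object@fixed, collapse = " + "),
      if (length(object@fixed)) "+" else "", "(1 | subject)\n")
})

#' @describeIn ModelSpec-class the model as an R formula (with the random
#'   intercept).
#' @param spec a `ModelSpec`.
#' @export
specFormula <- function(spec) {
  rhs <- paste(c(spec@fixed, "(1 | subject)"), collapse = " + ")
  as.formula(paste(spec@response, "~", rhs))
}

#' Full starting models of the standard analyses
#'
#' `volumeModelFull()` is the full model for regional volumes
#' (all five main effects plus the physiologically motivated interactions,
#' including the two three-way terms); `jaccardModelWhole()` the full model
#' for whole-structure reproducibility; `jaccardModelRegional()` the full
#' model for regional reproducibility.
#'
#' @param response response column name.
#' @return A [ModelSpec-class].
#' @export
volumeModelFull <- function(response = "response") {
  modelSpec(response, c("method", "group", "hemisphere", "region",
                        "timepoint",
                        "group:method", "group:region", "method:region",
                        "method:hemisphere", "timepoint:group",
                        "timepoint:region", "timepoint:group:region",
                        "group:region:method"))
}

#' @rdname volumeModelFull
#' @export
jaccardModelWhole <- function(response = "response") {
  modelSpec(response, c("group", "method", "hemisphere", "timepoint",
                        "group:method", "method:hemisphere"))
}

#' @rdname volumeModelFull
#' @export
jaccardModelRegional <- function(response = "response") {
  modelSpec(response, c("group", "method", "hemisphere", "timepoint",
                        "region", "group:method", "method:hemisphere",
                        "region:method", "region:group"))
}

## ---------------------------------------------------------------------------
## FitResult
## ---------------------------------------------------------------------------

#' Fitted mixed model with bookkeeping for selection
#'
#' @slot model the underlying `lmerModLmerTest` fit (ML).
#' @slot spec the [ModelSpec-class] that was fitted.
#' @slot coefficients named fixed-effect estimates (treatment coding,
#'   alphabetically first level as reference).
#' @slot logLik maximized log-likelihood.
#' @slot AIC Akaike information criterion (`2k - 2 logLik`).
#' @slot nparam number of free parameters `k`.
#' @slot varcomp named variance components (`subject.sd`, `residual.sd`).
#' @export
setClass("FitResult",
  representation(model = "ANY", spec = "ModelSpec", coefficients = "numeric",
                 logLik = "numeric", AIC = "numeric", nparam = "integer",
                 varcomp = "numeric"))

setMethod("show", "FitResult", function(object) {
  cat("FitResult:", object@spec@response, "~",
      paste(object@spec@fixed, collapse = " + "), "+ (1 | subject)\n")
  cat("  ML logLik:", signif(object@logLik, 8), " AIC:",
      signif(object@AIC, 8), " k:", object@nparam, "\n")
  cat("  sd(subject):", signif(object@varcomp[["subject.sd"]], 5),
      " sd(residual):", signif(object@varcomp[["residual.sd"]], 5), "\n")
})

#' @describeIn FitResult-class fixed-effect estimates.
#' @param object a `FitResult`.
#' @export
setMethod("coef", "FitResult", function(object) object@coefficients)

## factors get alphabetical levels so treatment coding has a fixed,
## reproducible reference level
.prepareTable <- function(table, spec) {
  need <- unique(c("subject", unlist(lapply(spec@fixed, .termFactors)),
                   spec@response))
  missing <- setdiff(need, names(table))
  if (length(missing))
    stop("observation table lacks column(s): ", paste(missing, collapse = ", "))
  table <- table[!is.na(table[[spec@response]]), , drop = FALSE]
  table$subject <- factor(as.character(table$subject))
  for (f in intersect(.MM_FACTORS, names(table)))
    table[[f]] <- factor(as.character(table[[f]]))
  table
}

#' Fit a Gaussian linear mixed model by maximum likelihood
#'
#' Treatment coding with the alphabetically first level of every factor as
#' reference; subject random intercept; ML estimation. Records with missing
#' response are dropped listwise. A rank-deficient fixed-effect design
#' (empty cells making a term inestimable) is an error naming the term.
#'
#' @param table observation `data.frame` (columns `subject`, the factors
#'   used by `spec`, and the response).
#' @param spec a [ModelSpec-class].
#' @return A [FitResult-class].
#' @export
fitModel <- function(table, spec) {
  stopifnot(is(spec, "ModelSpec"))
  table <- .prepareTable(table, spec)
  if (nlevels(table$subject) < 2L) stop("at least 2 subjects are required")
  ## estimability pre-check on the fixed design
  fixedForm <- if (length(spec@fixed))
    as.formula(paste("~", paste(spec@fixed, collapse = " + "))) else ~1
  X <- model.matrix(fixedForm, table)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    culprit <- attr(X, "assign")[match(aliased[1], colnames(X))]
    lab <- attr(terms(fixedForm), "term.labels")[culprit]
    stop("singular fixed-effect design: term '", lab,
         "' is not estimable (empty cells); offending column: ", aliased[1])
  }
  fit <- withCallingHandlers(
    suppressMessages(lmerTest::lmer(specFormula(spec), data = table,
                                    REML = FALSE)),
    warning = function(w) {
      if (grepl("failed to converge|unidentifiable|nearly|gradient|Hessian|singular",
                conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  vc <- as.data.frame(lme4::VarCorr(fit))
  subjSD <- vc$sdcor[vc$grp == "subject"][1]
  resSD <- vc$sdcor[vc$grp == "Residual"][1]
  ll <- logLik(fit)
  new("FitResult", model = fit, spec = spec,
      coefficients = lme4::fixef(fit),
      logLik = as.numeric(ll), AIC = AIC(fit),
      nparam = as.integer(attr(ll, "df")),
      varcomp = c(subject.sd = subjSD, residual.sd = resSD))
}

#' Per-term ANOVA p-values of a fitted model
#'
#' Type-III F tests with Satterthwaite's approximation for the denominator
#' degrees of freedom (the default); when the Satterthwaite computation
#' fails, likelihood-ratio p-values against the term-deleted model are
#' substituted. The method actually used is recorded in the
#' `"method"` attribute.
#'
#' @param fit a [FitResult-class].
#' @param table the observation table (needed only for the
#'   likelihood-ratio fallback).
#' @param method `"satterthwaite"` (default) or `"lrt"`.
#' @return named numeric vector of p-values per fixed term, with attribute
#'   `"method"`.
#' @export
termPvalues <- function(fit, table = NULL, method = c("satterthwaite", "lrt")) {
  method <- match.arg(method)
  if (method == "satterthwaite") {
    p <- tryCatch({
      a <- suppressMessages(anova(fit@model, type = 3, ddf = "Satterthwaite"))
      setNames(a[["Pr(>F)"]], vapply(rownames(a), .canonTerm, ""))
    }, error = function(e) NULL)
    if (!is.null(p) && !anyNA(p))
      return(structure(p, method = "satterthwaite"))
    method <- "lrt"
  }
  if (is.null(table))
    stop("likelihood-ratio p-values need the observation table")
  p <- vapply(fit@spec@fixed, function(tm) {
    reduced <- .dropTerm(fit@spec, tm, force = TRUE)
    rfit <- fitModel(table, reduced)
    stat <- max(0, 2 * (fit@logLik - rfit@logLik))
    df <- fit@nparam - rfit@nparam
    pchisq(stat, df, lower.tail = FALSE)
  }, 0)
  structure(setNames(p, fit@spec@fixed), method = "lrt")
}

## remove a term from a spec; force = TRUE skips the marginality validity
## (used for LRT p-values of main effects still covered by interactions)
.dropTerm <- function(spec, term, force = FALSE) {
  fixed <- setdiff(spec@fixed, term)
  droppable <- setdiff(spec@droppable, term)
  if (force) {
    sp <- new("ModelSpec", response = spec@response, fixed = spec@fixed,
              droppable = spec@droppable)
    sp@fixed <- fixed; sp@droppable <- droppable
    return(sp)
  }
  modelSpec(spec@response, fixed, droppable)
}

## terms currently eligible for dropping: droppable and not contained in any
## retained higher-order term
.candidateTerms <- function(spec) {
  Filter(function(tm) {
    f <- .termFactors(tm)
    !any(vapply(setdiff(spec@fixed, tm), function(other) {
      all(f %in% .termFactors(other))
    }, TRUE))
  }, spec@droppable)
}

#' Backward AIC elimination of fixed model terms
#'
#' Starting from the full model, the currently least significant droppable
#' term (highest per-term p-value; a main effect only becomes droppable
#' once no retained interaction contains it) is removed and the model
#' refitted; the drop is kept if the AIC does not increase. Elimination
#' stops when the best candidate drop increases the AIC. P-value ties are
#' broken by dropping the higher-order term first, then alphabetically.
#'
#' @param table observation `data.frame`.
#' @param full the full [ModelSpec-class] to start from.
#' @param pvalueMethod passed to [termPvalues()].
#' @return list with `spec` (selected [ModelSpec-class]), `fit` (its
#'   [FitResult-class]) and `trace` (`data.frame`: one row per attempted
#'   drop with the p-value, AICs before/after, acceptance and p-value
#'   method).
#' @export
backwardSelect <- function(table, full, pvalueMethod = "satterthwaite") {
  current <- full
  fit <- fitModel(table, current)
  trace <- list()
  repeat {
    cand <- .candidateTerms(current)
    if (!length(cand)) break
    p <- termPvalues(fit, table, method = pvalueMethod)
    pc <- p[cand]
    ## least significant first; ties: higher order first, then alphabetical
    ord <- order(-pc, -vapply(cand, function(tm) length(.termFactors(tm)), 0L),
                 cand)
    victim <- cand[ord[1]]
    reduced <- .dropTerm(current, victim)
    newFit <- fitModel(table, reduced)
    accepted <- newFit@AIC <= fit@AIC
    trace[[length(trace) + 1L]] <- data.frame(
      step = length(trace) + 1L, term = victim,
      p_value = unname(pc[ord[1]]), p_method = attr(p, "method"),
      aic_before = fit@AIC, aic_after = newFit@AIC,
      accepted = accepted, stringsAsFactors = FALSE)
    if (!accepted) break
    current <- reduced
    fit <- newFit
  }
  trace <- if (length(trace)) do.call(rbind, trace)
    else data.frame(step = integer(), term = character(),
                    p_value = numeric(), p_method = character(),
                    aic_before = numeric(), aic_after = numeric(),
                    accepted = logical(), stringsAsFactors = FALSE)
  list(spec = current, fit = fit, trace = trace)
}

#' Model-implied cell means
#'
#' Fixed-effects-only predictions for factor-level combinations. For a
#' model with additive main effects (say hemisphere and timepoint), the
#' predicted table of any other hemisphere/timepoint differs from a base
#' table by the single fitted offset, so all cells can be reconstructed
#' from one table plus the offsets.
#'
#' @param fit a [FitResult-class].
#' @param cells `data.frame` of factor-level combinations (one column per
#'   factor used by the model). Unknown levels are an error.
#' @return `cells` with a `predicted` column appended.
#' @export
predictCells <- function(fit, cells) {
  stopifnot(is(fit, "FitResult"))
  used <- unique(unlist(lapply(fit@spec@fixed, .termFactors)))
  missing <- setdiff(used, names(cells))
  if (length(missing))
    stop("cells lack factor column(s): ", paste(missing, collapse = ", "))
  mf <- fit@model@frame
  for (f in used) {
    lv <- levels(mf[[f]])
    badlev <- setdiff(unique(as.character(cells[[f]])), lv)
    if (length(badlev))
      stop("unknown level '", badlev[1], "' for factor ", f)
    cells[[f]] <- factor(as.character(cells[[f]]), levels = lv)
  }
  cells$predicted <- predict(fit@model, newdata = cells, re.form = NA)
  cells
}

#' Predicted-mean table over a full factor cross
#'
#' Convenience wrapper building the cross of the requested factor levels
#' (taken from the fit) with optional fixed conditioning values, and
#' predicting every cell.
#'
#' @param fit a [FitResult-class].
#' @param rows,cols factor names spanning the table.
#' @param at named list pinning the remaining factors to single levels.
#' @return `data.frame` in long format with a `predicted` column.
#' @export
predictionTable <- function(fit, rows = "region", cols = "group",
                            at = list()) {
  mf <- fit@model@frame
  used <- unique(unlist(lapply(fit@spec@fixed, .termFactors)))
  lv <- lapply(setNames(used, used), function(f) levels(mf[[f]]))
  for (f in names(at)) lv[[f]] <- at[[f]]
  cells <- expand.grid(lv, stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  predictCells(fit, cells)
}
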