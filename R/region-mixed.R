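#' Percent methylation from pyrosequencing counts
#'
#' `100 * C / (C + T)` per CpG; zero-depth entries become `NA` with a
#' warning rather than dividing by zero.
#'
#' @param C,Tc cytosine (methylated) and thymine (unmethylated) read
#'   counts, same shape.
#' @return percent methylation in [0, 100].
#' @export
#' @examples
#' percentMethylation(9, 1)  # 90
percentMethylation <- function(C, Tc) {
  stopifnot(all(C >= 0, na.rm = TRUE), all(Tc >= 0, na.rm = TRUE))
  depth <- C + Tc
  if (any(depth == 0, na.rm = TRUE)) {
    warning("zero-depth entries set to NA")
  }
  out <- ifelse(depth > 0, 100 * C / depth, NA_real_)
  out
}

#' Assemble a long-format pyrosequencing region table
#'
#' @param pct CpG x sample matrix of percent methylation.
#' @param design cohort covariate table; columns are joined by sample.
#' @return data.frame: `sample_id`, `cpg_index`, `percent` plus the
#'   covariates.
#' @export
pyroRegionData <- function(pct, design) {
  stopifnot(ncol(pct) == nrow(design))
  long <- data.frame(
    sample_id = rep(design$sample_id, each = nrow(pct)),
    cpg_index = rep(seq_len(nrow(pct)), times = ncol(pct)),
    percent = as.vector(pct))
  merge(long, design, by = "sample_id", sort = FALSE)
}

#' Regional mixed-model association for a pyrosequenced region
#'
#' Percent methylation across the CpGs of one region is modeled with a
#' linear mixed model: fixed effects for the GDM indicator and the
#' covariates, and a random intercept per sample to absorb within-sample
#' correlation across CpGs (REML). The exposure coefficient is reported on
#' the percent scale with a Wald 95% CI (normal reference). If the random
#' intercept variance is estimated as zero (singular fit), the model is
#' refit as fixed-effects OLS with a cluster-robust (by-sample) sandwich
#' SE and flagged.
#'
#' @param data long-format table from [pyroRegionData()] (needs
#'   `percent`, `sample_id`, `cpg_index` and the covariates).
#' @param covariates character vector of fixed-effect covariate names
#'   (besides the exposure).
#' @param exposure exposure column, default "gdm".
#' @param level CI level.
#' @return one-row data.frame: `coef`, `se`, `ci_lo`, `ci_hi`, `p`,
#'   `n_samples`, `n_cpgs`, `singular`.
#' @export
fitRegionModel <- function(data,
                           covariates = c("age", "bmi", "sex", "smoking",
                                          "ethnicity"),
                           exposure = "gdm", level = 0.95) {
  nCpg <- length(unique(data$cpg_index))
  nSam <- length(unique(data$sample_id))
  if (nCpg < 2) stop("regional model needs >= 2 CpGs")
  if (nSam < 10) stop("regional model needs >= 10 samples")
  covariates <- covariates[vapply(covariates, function(v)
    length(unique(data[[v]])) > 1, logical(1))]
  fml <- stats::reformulate(c(exposure, covariates, "(1 | sample_id)"),
                            response = "percent")
  fit <- suppressMessages(lme4::lmer(fml, data = data, REML = TRUE))
  singular <- lme4::isSingular(fit, tol = 1e-5)
  if (singular) {
    fmlF <- stats::reformulate(c(exposure, covariates),
                               response = "percent")
    ols <- lm(fmlF, data = data)
    V <- sandwich::vcovCL(ols, cluster = data$sample_id)
    cf <- coef(ols)[exposure]
    se <- sqrt(V[exposure, exposure])
  } else {
    cf <- lme4::fixef(fit)[exposure]
    se <- sqrt(diag(as.matrix(stats::vcov(fit))))[exposure]
  }
  z <- qnorm(1 - (1 - level) / 2)
  data.frame(coef = unname(cf), se = unname(se),
             ci_lo = unname(cf - z * se), ci_hi = unname(cf + z * se),
             p = unname(2 * stats::pnorm(-abs(cf / se))),
             n_samples = nSam, n_cpgs = nCpg, singular = singular)
}

#' Effect modification in the regional mixed model
#'
#' Adds a dichotomous modifier and its interaction with the exposure to
#' the regional model and reports the Wald p of the interaction term plus
#' stratum-specific exposure effects (each stratum refit separately with
#' the same covariates).
#'
#' @param data long-format region table.
#' @param modifier name of the dichotomous modifier column (e.g. age or
#'   BMI dichotomized at the discovery-cohort median, see
#'   [dichotomizeAtMedian()]); both strata must contain at least
#'   `minPerCell` cases and controls.
#' @param covariates fixed-effect covariates (the modifier, if present
#'   here, is removed to avoid duplication).
#' @param exposure exposure column.
#' @param minPerCell minimum cases and controls per stratum.
#' @return list with `interaction_p` and `strata`, a data.frame of
#'   per-stratum exposure effects with CIs.
#' @export
testEffectModification <- function(data, modifier,
                                   covariates = c("age", "bmi", "sex",
                                                  "smoking", "ethnicity"),
                                   exposure = "gdm", minPerCell = 3) {
  m <- data[[modifier]]
  if (length(unique(m)) < 2) stop("modifier is constant")
  if (length(unique(m)) > 2) stop("modifier must be dichotomous")
  covariates <- setdiff(covariates, modifier)
  covariates <- covariates[vapply(covariates, function(v)
    length(unique(data[[v]])) > 1, logical(1))]
  bySample <- unique(data[, c("sample_id", exposure, modifier)])
  tabs <- table(bySample[[modifier]], bySample[[exposure]])
  if (any(tabs < minPerCell)) {
    stop("each stratum needs at least ", minPerCell,
         " cases and controls")
  }
  ix <- sprintf("%s:%s", exposure, modifier)
  fml <- stats::reformulate(
    c(exposure, modifier, covariates,
      sprintf("%s:%s", exposure, modifier), "(1 | sample_id)"),
    response = "percent")
  fit <- suppressMessages(lme4::lmer(fml, data = data, REML = TRUE))
  cf <- lme4::fixef(fit)
  V <- as.matrix(stats::vcov(fit))
  ixName <- grep(paste0("^", exposure, ":"), names(cf), value = TRUE)
  if (!length(ixName)) ixName <- grep(":", names(cf), value = TRUE)
  z <- cf[ixName] / sqrt(V[ixName, ixName])
  interP <- unname(2 * stats::pnorm(-abs(z)))

  strata <- do.call(rbind, lapply(sort(unique(m)), function(lev) {
    sub <- data[data[[modifier]] == lev, , drop = FALSE]
    est <- fitRegionModel(sub, covariates = covariates,
                          exposure = exposure)
    cbind(stratum = as.character(lev), est)
  }))
  list(interaction_p = interP, strata = strata)
}

#' Dichotomize a covariate at the discovery-cohort median
#'
#' Returns a two-level factor `"low"`/`"high"` split at the median of the
#' covariate in a reference (discovery) cohort, applied to any cohort's
#' values — the convention used when probing effect modification in a
#' validation cohort with thresholds fixed by the discovery data.
#'
#' @param x values to dichotomize.
#' @param reference values whose median defines the threshold (default
#'   `x` itself).
#' @return factor with levels `low` (<= median) and `high`.
#' @export
dichotomizeAtMedian <- function(x, reference = x) {
  thr <- median(reference, na.rm = TRUE)
  factor(ifelse(x <= thr, "low", "high"), levels = c("low", "high"))
}
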