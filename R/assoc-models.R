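#' Build the adjusted model design
#'
#' Standard covariate set of the site/gene association models: GDM
#' indicator, maternal age (years), pre-pregnancy BMI (kg/m2), infant sex,
#' maternal smoking, plus any selected surrogate components.
#'
#' @param design cohort covariate table (needs `gdm`, `age`, `bmi`,
#'   `sex`, `smoking`).
#' @param surrogateSet optional \linkS4class{SurrogateSet}; selected
#'   components are appended.
#' @param extra optional data.frame of extra covariates (e.g. ethnicity
#'   for the pyrosequencing models).
#' @return data.frame with the exposure in column `gdm`.
#' @export
modelFrame <- function(design, surrogateSet = NULL, extra = NULL) {
  mf <- design[, c("gdm", "age", "bmi", "sex", "smoking")]
  if (!is.null(extra)) mf <- cbind(mf, extra)
  # a covariate constant across the sample (e.g. no smokers recruited)
  # cannot confound and would make the design singular
  keep <- vapply(mf, function(v) length(unique(v)) > 1, logical(1))
  keep["gdm"] <- TRUE
  mf <- mf[, keep, drop = FALSE]
  if (!is.null(surrogateSet)) {
    sv <- surrogates(surrogateSet, selectedOnly = TRUE)
    if (ncol(sv)) mf <- cbind(mf, as.data.frame(sv))
  }
  mf
}

#' Robust Wald association model for one feature
#'
#' Ordinary least squares of the feature on the exposure and covariates,
#' with a heteroscedasticity-consistent (sandwich) covariance for the
#' exposure coefficient and a two-sided Wald test. Methylation beta values
#' have variances that depend on the methylation level itself, which
#' motivates the robust standard errors. HC1 (the degrees-of-freedom-
#' corrected sandwich) is the default: paired with the residual-df t
#' reference it is calibrated at the cohort sizes this package targets
#' (n near 80), whereas HC3 plus a t reference applies two small-sample
#' corrections at once and becomes conservative. HC3 and HC0 remain
#' available. The covariance is delegated to [sandwich::vcovHC()].
#'
#' @param y numeric feature vector (beta values or log2 expression).
#' @param modelData data.frame of covariates including the exposure.
#' @param exposure name of the exposure column (default "gdm").
#' @param hcType sandwich flavor: "HC1" (default), "HC3" or "HC0".
#' @param dfMethod "residual" (t reference with n - rank df) or "normal".
#' @return one-row data.frame: `effect` (cases minus controls),
#'   `robust_se`, `t_stat`, `p_value`, `n`.
#' @export
fitFeatureModel <- function(y, modelData, exposure = "gdm",
                            hcType = c("HC1", "HC3", "HC0"),
                            dfMethod = c("residual", "normal")) {
  hcType <- match.arg(hcType)
  dfMethod <- match.arg(dfMethod)
  stopifnot(exposure %in% names(modelData))
  dat <- cbind(.y = y, modelData)
  fit <- lm(.y ~ ., data = dat)
  if (any(is.na(coef(fit)))) {
    stop("rank-deficient design; collinear column(s): ",
         paste(names(coef(fit))[is.na(coef(fit))], collapse = ", "))
  }
  n <- length(y)
  rk <- fit$rank
  if (n <= rk + 2) stop("too few samples for the design")
  cf <- coef(fit)[exposure]
  if (sd(y) == 0) {
    return(data.frame(effect = 0, robust_se = 0, t_stat = 0, p_value = 1,
                      n = n, degenerate = TRUE))
  }
  V <- sandwich::vcovHC(fit, type = hcType)
  se <- sqrt(V[exposure, exposure])
  t <- cf / se
  p <- if (dfMethod == "residual") 2 * pt(-abs(t), df = n - rk)
       else 2 * stats::pnorm(-abs(t))
  data.frame(effect = unname(cf), robust_se = unname(se),
             t_stat = unname(t), p_value = unname(p), n = n,
             degenerate = FALSE)
}

# Vectorized OLS + HC sandwich for a whole feature matrix against one
# fixed design. Identical to looping fitFeatureModel over rows (tested),
# but a single pass of matrix algebra: with A = (X'X)^{-1} X', the robust
# variance of the exposure coefficient is sum_j A[k,j]^2 w_j where w_j are
# the HC meat weights of feature-specific residuals.
.ewasMatrix <- function(Y, modelData, exposure, hcType, dfMethod) {
  X <- model.matrix(~ ., data = modelData)
  n <- nrow(X)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop <- qrX$pivot[(qrX$rank + 1L):ncol(X)]
    stop("rank-deficient design; collinear column(s): ",
         paste(colnames(X)[drop], collapse = ", "))
  }
  if (!exposure %in% colnames(X)) stop("exposure column not in design")
  A <- solve(crossprod(X), t(X))                 # p x n
  Bhat <- A %*% t(Y)                             # p x F coefficients
  H <- X %*% A                                   # hat matrix
  h <- diag(H)
  Efit <- t(Y) - X %*% Bhat                      # n x F residuals
  k <- match(exposure, colnames(X))
  w <- switch(hcType,
              HC0 = Efit^2,
              HC1 = Efit^2 * n / (n - qrX$rank),
              HC3 = Efit^2 / (1 - h)^2)
  se <- sqrt(as.vector(A[k, ]^2 %*% w))
  eff <- Bhat[k, ]
  t <- ifelse(se > 0, eff / se, 0)
  df <- n - qrX$rank
  p <- if (dfMethod == "residual") 2 * pt(-abs(t), df = df)
       else 2 * stats::pnorm(-abs(t))
  p[se == 0] <- 1
  data.frame(feature_id = rownames(Y), effect = eff, robust_se = se,
             t_stat = t, p_value = p, n = n, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Epigenome-wide association study
#'
#' Fits the robust-Wald model of [fitFeatureModel()] to every probe of a
#' (filtered, normalized) \linkS4class{BetaSet} and returns the
#' association table sorted as input, with the count of probes below the
#' significance threshold attached as an attribute.
#'
#' @param beta a \linkS4class{BetaSet} or probe x sample matrix.
#' @param modelData covariate data.frame from [modelFrame()]; rows must
#'   align with the samples.
#' @param alpha site-level significance threshold (default 0.001, the
#'   methylation cutoff of the study design).
#' @inheritParams fitFeatureModel
#' @return data.frame (`feature_id`, `effect`, `robust_se`, `t_stat`,
#'   `p_value`, `n`) with attribute `n_significant`.
#' @export
runEWAS <- function(beta, modelData, exposure = "gdm", alpha = 0.001,
                    hcType = c("HC1", "HC3", "HC0"),
                    dfMethod = c("residual", "normal")) {
  hcType <- match.arg(hcType)
  dfMethod <- match.arg(dfMethod)
  Y <- if (is(beta, "BetaSet")) getBeta(beta) else as.matrix(beta)
  if (ncol(Y) != nrow(modelData)) {
    stop("sample mismatch between data (", ncol(Y), ") and design (",
         nrow(modelData), ")")
  }
  out <- .ewasMatrix(Y, modelData, exposure, hcType, dfMethod)
  attr(out, "alpha") <- alpha
  attr(out, "n_significant") <- sum(out$p_value < alpha)
  out
}

#' Transcriptome-wide association study
#'
#' Same model as [runEWAS()] applied to gene-level log2 expression, with
#' the study's expression significance default (alpha = 0.01) and an
#' optional restriction to coding genes before fitting.
#'
#' @param expr gene x sample log2 expression matrix.
#' @param modelData covariate data.frame.
#' @param geneAnnot optional gene annotation with a `coding` column used
#'   when `codingOnly = TRUE`.
#' @param codingOnly restrict to coding genes (reporting convention).
#' @param alpha significance threshold (default 0.01).
#' @inheritParams fitFeatureModel
#' @return association table as in [runEWAS()].
#' @export
runTWAS <- function(expr, modelData, geneAnnot = NULL, codingOnly = FALSE,
                    exposure = "gdm", alpha = 0.01,
                    hcType = c("HC1", "HC3", "HC0"),
                    dfMethod = c("residual", "normal")) {
  hcType <- match.arg(hcType)
  dfMethod <- match.arg(dfMethod)
  Y <- as.matrix(expr)
  if (codingOnly) {
    if (is.null(geneAnnot)) stop("geneAnnot required when codingOnly=TRUE")
    keep <- rownames(Y) %in% geneAnnot$gene_id[geneAnnot$coding]
    if (!any(keep)) stop("no coding genes left after the restriction")
    Y <- Y[keep, , drop = FALSE]
  }
  if (ncol(Y) != nrow(modelData)) {
    stop("sample mismatch between data and design")
  }
  out <- .ewasMatrix(Y, modelData, exposure, hcType, dfMethod)
  attr(out, "alpha") <- alpha
  attr(out, "n_significant") <- sum(out$p_value < alpha)
  out
}
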