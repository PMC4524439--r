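#' Estimate surrogate variables for batch and ethnicity confounding
#'
#' A data-driven stand-in for independent surrogate variable analysis:
#' (1) the feature x sample data matrix is residualized on the full
#' primary design (exposure plus measured covariates), so exposure signal
#' cannot be absorbed into the surrogates; (2) the residual matrix is
#' decomposed by singular value decomposition, with the number of retained
#' components chosen by permutation-based parallel analysis (a component
#' is kept only when its singular value exceeds the upper envelope of
#' singular values obtained after permuting each feature's residuals
#' independently), capped at `kMax`; the retained probe-space loadings
#' are then scored against the original centered data, since a surrogate
#' must be allowed to track the exposure-aligned portion of a batch
#' effect, which a residual-space score (orthogonal to the exposure by
#' construction) never could; (3) each component's sample
#' scores are tested against every measured confounder surrogate (chip,
#' row, column, ethnicity) by one-way ANOVA F tests (component scores are
#' near-Gaussian linear combinations, where the parametric test has the
#' better power; a Kruskal-Wallis option is kept); (4) components with a
#' Benjamini-Hochberg q-value below `qCut` against any confounder are
#' flagged as selected for inclusion in downstream models.
#'
#' On pure-noise data parallel analysis retains (almost always) nothing,
#' so the selection is empty and downstream models proceed unadjusted,
#' with a warning.
#'
#' @param dataMat numeric matrix, features x samples (betas or log2
#'   expression).
#' @param design data.frame of primary model covariates (exposure
#'   included) used for residualization; expanded via [stats::model.matrix()].
#' @param confounders data.frame of categorical confounder surrogates
#'   (one row per sample), e.g. chip, row, column, ethnicity.
#' @param kMax maximum number of components; default
#'   `min(10, floor(nSamples / 5))`.
#' @param qCut selection threshold on the BH q-value.
#' @param nPerm permutations for parallel analysis.
#' @param seed RNG seed for the permutations.
#' @param screen association test for step (3): "anova" (default) or
#'   "kruskal".
#' @return a \linkS4class{SurrogateSet}.
#' @export
estimateSurrogates <- function(dataMat, design, confounders, kMax = NULL,
                               qCut = 0.05, nPerm = 20, seed = 1,
                               screen = c("anova", "kruskal")) {
  screen <- match.arg(screen)
  dataMat <- as.matrix(dataMat)
  n <- ncol(dataMat)
  stopifnot(nrow(design) == n, nrow(confounders) == n)
  X <- model.matrix(~ ., data = design)
  r <- qr(X)$rank
  if (is.null(kMax)) kMax <- min(10L, floor(n / 5))
  if (kMax >= n) stop("kMax must be smaller than the number of samples")
  if (kMax >= n - r) kMax <- n - r - 1L

  # residualize on the primary design (sample-space projection)
  Q <- qr.Q(qr(X))
  E <- dataMat - (dataMat %*% Q) %*% t(Q)

  withSeed(seed, {
    sv <- svd(E, nu = kMax, nv = kMax)
    # parallel analysis: null envelope of leading singular values under
    # independent within-feature permutation of residuals
    nullMax <- matrix(NA_real_, nPerm, kMax)
    for (b in seq_len(nPerm)) {
      Eb <- t(apply(E, 1, sample))
      Eb <- Eb - (Eb %*% Q) %*% t(Q)    # re-residualize the permuted matrix
      nullMax[b, ] <- svd(Eb, nu = 0, nv = 0)$d[seq_len(kMax)]
    }
    thresh <- apply(nullMax, 2, quantile, probs = 0.95, names = FALSE)
    k <- sum(sv$d[seq_len(kMax)] > thresh)

    if (k == 0L) {
      warning("no residual component exceeds the parallel-analysis ",
              "envelope: no surrogates selected")
      return(new("SurrogateSet",
                 components = matrix(numeric(0), nrow = n, ncol = 0),
                 report = data.frame(component = integer(0),
                                     confounder = character(0),
                                     p = numeric(0), q = numeric(0)),
                 selected = logical(0), method = "svd+parallel-analysis"))
    }

    # Loadings are estimated on the exposure-protected residuals, but the
    # sample scores must come from the original data: a residual-space
    # score is orthogonal to the exposure by construction and so could
    # never correct the exposure-aligned part of a batch effect — it
    # would only shrink residuals and inflate the Wald statistics.
    U <- sv$u[, seq_len(k), drop = FALSE]
    Yc <- dataMat - rowMeans(dataMat)
    V <- qr.Q(qr(crossprod(Yc, U)))[, seq_len(k), drop = FALSE]
    rownames(V) <- colnames(dataMat)
    colnames(V) <- paste0("SV", seq_len(k))

    rep <- do.call(rbind, lapply(seq_len(k), function(j) {
      do.call(rbind, lapply(names(confounders), function(cf) {
        f <- factor(confounders[[cf]])
        p <- if (nlevels(f) < 2) 1
        else if (screen == "anova") {
          fit <- stats::anova(lm(V[, j] ~ f))
          fit[["Pr(>F)"]][1]
        } else suppressWarnings(kruskal.test(V[, j], f)$p.value)
        data.frame(component = j, confounder = cf, p = p)
      }))
    }))
    rep$q <- fdrCorrect(rep$p)
    selected <- vapply(seq_len(k), function(j) {
      any(rep$q[rep$component == j] < qCut)
    }, logical(1))
    if (!any(selected)) {
      warning("no component associated with a confounder at q < ", qCut,
              ": models proceed unadjusted")
    }
    new("SurrogateSet", components = V, report = rep, selected = selected,
        method = "svd+parallel-analysis")
  })
}

#' Variance attributable to a batch factor
#'
#' Mean proportion of per-feature variance explained by a categorical
#' batch label, optionally after regressing out a set of surrogate
#' components. Used to quantify how much injected batch structure the
#' selected surrogates remove.
#'
#' @param dataMat features x samples matrix.
#' @param batch categorical batch label per sample.
#' @param surrogates optional sample x k matrix to regress out first.
#' @param excess subtract the chance level of the R-squared (the expected
#'   value under no batch structure, `(L-1)/df`), flooring at 0, so that
#'   "attributable" variance means variance above what a random factor
#'   would explain.
#' @return mean R-squared of the batch factor across features.
#' @export
batchVarianceExplained <- function(dataMat, batch, surrogates = NULL,
                                   excess = FALSE) {
  dataMat <- as.matrix(dataMat)
  f <- factor(batch)
  Y <- t(dataMat)
  if (!is.null(surrogates) && ncol(surrogates) > 0) {
    Qs <- qr.Q(qr(cbind(1, surrogates)))
    Y <- Y - Qs %*% crossprod(Qs, Y)
  }
  Xb <- model.matrix(~ f)
  Qb <- qr.Q(qr(Xb))
  Yc <- sweep(Y, 2, colMeans(Y))
  fitted <- Qb %*% crossprod(Qb, Y)
  fittedC <- sweep(fitted, 2, colMeans(fitted))
  ssb <- colSums(fittedC^2)
  sst <- colSums(Yc^2)
  r2 <- mean(ifelse(sst > 0, ssb / sst, 0))
  if (excess) {
    k <- if (is.null(surrogates)) 0L else ncol(surrogates)
    chance <- (nlevels(f) - 1) / (nrow(Y) - 1 - k)
    r2 <- max(0, r2 - chance)
  }
  r2
}
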