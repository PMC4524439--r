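#' Background-correct expression intensities
#'
#' Per sample, subtracts a low-quantile baseline (default the 2.5th
#' percentile) from the linear-scale intensities and floors the result at
#' a small positive constant, then (optionally) log2-transforms. A simple
#' monotone baseline-removal step: within a sample the transformation is
#' a common shift, so probe ordering is preserved.
#'
#' @param x positive numeric matrix, probes x samples, linear scale.
#' @param baselineQuantile quantile used as the per-sample background.
#' @param floor lower bound applied after subtraction (must be > 0).
#' @param log2Transform return log2 intensities (default TRUE).
#' @return corrected matrix, same dimensions.
#' @export
backgroundCorrect <- function(x, baselineQuantile = 0.025, floor = 1,
                              log2Transform = TRUE) {
  x <- as.matrix(x)
  if (any(x <= 0)) stop("intensities must be positive")
  stopifnot(floor > 0)
  bl <- apply(x, 2, quantile, probs = baselineQuantile, names = FALSE)
  out <- pmax(sweep(x, 2, bl, `-`), floor)
  if (log2Transform) out <- log2(out)
  out
}

#' Median-polish summarization of one gene's probes
#'
#' Decomposes a probes x samples log2 block into overall + row (probe) +
#' column (sample) effects by iterative median sweeps (rows first, then
#' columns; tolerance 1e-6, at most `maxIter` full sweeps) and returns the
#' per-sample gene value `overall + column effect`. For an exactly
#' additive block this recovers the column effects exactly; with an
#' outlying cell the medians make the fit robust.
#'
#' @param block numeric matrix (probes x samples) on the log2 scale; a
#'   vector is treated as a single-probe gene.
#' @param maxIter maximum sweep iterations.
#' @param eps convergence tolerance on the residual L1 norm.
#' @return numeric vector of per-sample gene values.
#' @export
medianPolishGene <- function(block, maxIter = 20, eps = 1e-6) {
  if (is.null(dim(block))) block <- matrix(block, nrow = 1)
  if (all(is.na(block))) stop("all-missing probe block")
  if (nrow(block) == 1L) return(drop(block))
  # the sweep cap is part of the contract; the estimate at the cap is used
  fit <- suppressWarnings(
    stats::medpolish(block, eps = eps, maxiter = maxIter,
                     trace.iter = FALSE, na.rm = TRUE))
  fit$overall + fit$col
}

#' Summarize probe-level expression to gene level
#'
#' Applies [medianPolishGene()] to each gene's probe block.
#'
#' @param probeMat probe x sample matrix (log2 scale).
#' @param probeMap data.frame with columns `probe_id`, `gene_id`; probes
#'   are matched to `rownames(probeMat)`.
#' @return gene x sample matrix of summarized log2 expression.
#' @export
summarizeGenes <- function(probeMat, probeMap) {
  stopifnot(all(c("probe_id", "gene_id") %in% names(probeMap)))
  idx <- match(probeMap$probe_id, rownames(probeMat))
  if (anyNA(idx)) stop("probeMap refers to probes absent from the matrix")
  groups <- split(idx, probeMap$gene_id)
  out <- t(vapply(groups, function(ix) {
    medianPolishGene(probeMat[ix, , drop = FALSE])
  }, numeric(ncol(probeMat))))
  colnames(out) <- colnames(probeMat)
  out
}

#' Full expression preprocessing chain
#'
#' Background correction, quantile normalization of the log2 probe matrix,
#' and median-polish summarization into one value per gene.
#'
#' @param probes linear-scale probe x sample intensity matrix.
#' @param probeMap probe-to-gene map (`probe_id`, `gene_id`).
#' @param normalize apply quantile normalization between samples.
#' @inheritParams backgroundCorrect
#' @return gene x sample log2 expression matrix.
#' @export
preprocessExpression <- function(probes, probeMap, normalize = TRUE,
                                 baselineQuantile = 0.025, floor = 1) {
  x <- backgroundCorrect(probes, baselineQuantile, floor)
  if (normalize) x <- quantileNormalize(x)
  summarizeGenes(x, probeMap)
}

#' Delta-Ct from qRT-PCR cycle thresholds
#'
#' `deltaCt = Ct(gene of interest) - Ct(reference gene)`; replicate Ct
#' values are averaged before subtraction. Missing replicates are dropped
#' with a warning; if all replicates of either side are missing the result
#' is `NA`.
#'
#' @param ctGene numeric vector of target-gene replicate Ct values.
#' @param ctRef numeric vector of reference-gene (e.g. GAPDH) replicate
#'   Ct values.
#' @return length-1 numeric delta-Ct.
#' @export
#' @examples
#' deltaCt(c(24, 25, 26), c(20, 20, 20))  # 5
deltaCt <- function(ctGene, ctRef) {
  checkSide <- function(x, label) {
    if (any(is.na(x))) {
      if (all(is.na(x))) return(NA_real_)
      warning("missing ", label, " replicate(s) dropped")
    }
    if (any(x <= 0, na.rm = TRUE)) stop("Ct values must be positive")
    mean(x, na.rm = TRUE)
  }
  g <- checkSide(ctGene, "target")
  r <- checkSide(ctRef, "reference")
  g - r
}

#' Delta-Ct for a long-format qRT-PCR table
#'
#' @param tbl data.frame with columns `sample`, `gene`, `replicate`, `ct`.
#' @param refGene reference gene name (default "GAPDH").
#' @return data.frame `sample`, `gene`, `delta_ct` for all non-reference
#'   genes.
#' @export
deltaCtTable <- function(tbl, refGene = "GAPDH") {
  stopifnot(all(c("sample", "gene", "ct") %in% names(tbl)))
  if (!refGene %in% tbl$gene) stop("reference gene not present: ", refGene)
  out <- list()
  for (s in unique(tbl$sample)) {
    sub <- tbl[tbl$sample == s, ]
    ref <- sub$ct[sub$gene == refGene]
    for (g in setdiff(unique(sub$gene), refGene)) {
      out[[length(out) + 1L]] <- data.frame(
        sample = s, gene = g,
        delta_ct = deltaCt(sub$ct[sub$gene == g], ref))
    }
  }
  do.call(rbind, out)
}
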