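#' Select the features of a genomic window
#'
#' CpGs within a closed `flank` (default 10 kb) of the window boundaries,
#' and genes whose transcription start site lies inside the window
#' proper — mirroring a region definition that takes nearby CpGs but only
#' resident genes.
#'
#' @param probeAnnot probe annotation (`probe_id`, `chrom`, `pos`).
#' @param geneAnnot gene annotation (`gene_id`, `chrom`, `tss`).
#' @param window list(chrom, start, end), 1-based inclusive.
#' @param flank CpG flank in bp.
#' @return list with character vectors `cpgs` and `genes`.
#' @export
selectWindowFeatures <- function(probeAnnot, geneAnnot, window,
                                 flank = 10000) {
  stopifnot(all(c("chrom", "start", "end") %in% names(window)))
  if (window$end < window$start) stop("empty window")
  cpgs <- probeAnnot$probe_id[
    probeAnnot$chrom == window$chrom &
      probeAnnot$pos >= window$start - flank &
      probeAnnot$pos <= window$end + flank]
  genes <- geneAnnot$gene_id[
    geneAnnot$chrom == window$chrom &
      geneAnnot$tss >= window$start & geneAnnot$tss <= window$end]
  list(cpgs = cpgs, genes = genes)
}

# Shared permutation index stream: one n x nPerm matrix of permutations
# drawn under `seed`, reused across every pair so edge p-values do not
# depend on the order in which pairs are visited.
makePermIndex <- function(n, nPerm, seed) {
  withSeed(seed, {
    matrix(vapply(seq_len(nPerm), function(i) sample.int(n),
                  integer(n)), nrow = n)
  })
}

# centered average-rank transform of a matrix's rows; rows with zero
# variance come back as NA rows
.centeredRanks <- function(M) {
  R <- t(apply(M, 1, rank, ties.method = "average"))
  R <- R - rowMeans(R)
  nrm <- sqrt(rowSums(R^2))
  R[nrm == 0, ] <- NA_real_
  list(R = R, norm = nrm)
}

#' Spearman correlation with permutation significance
#'
#' Spearman's rho (Pearson correlation of average ranks) with a two-sided
#' permutation p-value: the fraction of permutations of `y` whose |rho|
#' meets or exceeds the observed |rho|. When no permutation does, the
#' p-value is imputed as 1e-6 (the convention for p = 0 under 10,000
#' permutations).
#'
#' @param x,y paired numeric vectors, length >= 10.
#' @param nPerm number of permutations.
#' @param seed RNG seed (ignored when `permIndex` is given).
#' @param permIndex optional precomputed permutation matrix from
#'   [makePermIndex()] for a shared stream across many pairs.
#' @param floorP value imputed when the permutation count is zero.
#' @return list(rho, p).
#' @export
permutationSpearman <- function(x, y, nPerm = 10000, seed = 1,
                                permIndex = NULL, floorP = 1e-6) {
  n <- length(x)
  stopifnot(length(y) == n)
  if (n < 10) stop("need at least 10 paired observations")
  if (sd(x) == 0 || sd(y) == 0) {
    warning("constant vector: Spearman correlation undefined")
    return(list(rho = NA_real_, p = NA_real_))
  }
  if (is.null(permIndex)) permIndex <- makePermIndex(n, nPerm, seed)
  rx <- rank(x, ties.method = "average"); rx <- rx - mean(rx)
  ry <- rank(y, ties.method = "average"); ry <- ry - mean(ry)
  denom <- sqrt(sum(rx^2) * sum(ry^2))
  rho <- sum(rx * ry) / denom
  Yp <- matrix(ry[permIndex], n, ncol(permIndex))
  rhoPerm <- as.vector(crossprod(rx, Yp)) / denom
  hits <- sum(abs(rhoPerm) >= abs(rho) - 1e-12)
  p <- hits / ncol(permIndex)
  if (p == 0) p <- floorP
  list(rho = rho, p = p)
}

#' Methylation-expression and co-expression permutation networks
#'
#' Tests every CpG x gene pair (methylation vs expression) and every gene
#' pair (co-expression) within a window by permutation Spearman
#' correlation, using one shared permutation stream. P-values are
#' Benjamini-Hochberg corrected within each edge family separately (the
#' "regional" FDR); the methylation-expression family returns all q <
#' `qCut` edges, the co-expression family returns the q < `qCut` edges
#' truncated to the `maxExprEdges` largest |rho|.
#'
#' @param betaW CpG x sample beta matrix of the window.
#' @param exprW gene x sample log2 expression matrix of the window.
#' @param nPerm permutations per pair.
#' @param seed RNG seed for the shared permutation stream.
#' @param qCut regional FDR threshold.
#' @param maxExprEdges cap on reported co-expression edges.
#' @param floorP imputation for zero permutation counts.
#' @return list of data.frames `methExpr` (cpg, gene, rho, p, q) and
#'   `exprExpr` (gene_a, gene_b, rho, p, q); attributes `"all_methExpr"`
#'   and `"all_exprExpr"` keep the unfiltered tables.
#' @export
buildNetworks <- function(betaW, exprW, nPerm = 10000, seed = 1,
                          qCut = 0.05, maxExprEdges = 100,
                          floorP = 1e-6) {
  betaW <- as.matrix(betaW); exprW <- as.matrix(exprW)
  n <- ncol(betaW)
  stopifnot(ncol(exprW) == n, n >= 10)
  P <- makePermIndex(n, nPerm, seed)
  rb <- .centeredRanks(betaW)
  re <- .centeredRanks(exprW)
  dropB <- rb$norm == 0; dropE <- re$norm == 0
  if (any(dropB) || any(dropE)) {
    warning(sum(dropB) + sum(dropE),
            " constant feature(s) dropped from the network")
  }

  pairP <- function(Xc, xNorm, yc, yNorm) {
    # obs and permuted rho of every row of Xc against one y
    denom <- xNorm * yNorm
    obs <- as.vector(Xc %*% yc) / denom
    Yp <- matrix(yc[P], n, ncol(P))
    prm <- (Xc %*% Yp) / denom
    pv <- rowMeans(abs(prm) >= abs(obs) - 1e-12)
    list(rho = obs, p = pv)
  }

  methExpr <- NULL
  keepB <- which(!dropB)
  if (length(keepB)) {
    res <- lapply(which(!dropE), function(g) {
      r <- pairP(rb$R[keepB, , drop = FALSE], rb$norm[keepB],
                 re$R[g, ], re$norm[g])
      data.frame(cpg = rownames(betaW)[keepB],
                 gene = rownames(exprW)[g], rho = r$rho, p = r$p)
    })
    methExpr <- do.call(rbind, res)
  }

  exprExpr <- NULL
  keepE <- which(!dropE)
  if (length(keepE) >= 2) {
    res <- list()
    for (jj in 2:length(keepE)) {
      g <- keepE[jj]
      prev <- keepE[seq_len(jj - 1)]
      r <- pairP(re$R[prev, , drop = FALSE], re$norm[prev],
                 re$R[g, ], re$norm[g])
      res[[jj - 1]] <- data.frame(gene_a = rownames(exprW)[prev],
                                  gene_b = rownames(exprW)[g],
                                  rho = r$rho, p = r$p)
    }
    exprExpr <- do.call(rbind, res)
  }

  finish <- function(df) {
    if (is.null(df) || !nrow(df)) return(df)
    df$p[df$p == 0] <- floorP
    df$q <- fdrCorrect(df$p)
    rownames(df) <- NULL
    df
  }
  methExpr <- finish(methExpr)
  exprExpr <- finish(exprExpr)

  sigME <- if (!is.null(methExpr)) methExpr[methExpr$q < qCut, ] else NULL
  sigEE <- NULL
  if (!is.null(exprExpr)) {
    sigEE <- exprExpr[exprExpr$q < qCut, ]
    if (nrow(sigEE) > maxExprEdges) {
      sigEE <- sigEE[order(-abs(sigEE$rho))[seq_len(maxExprEdges)], ]
    }
  }
  out <- list(methExpr = sigME, exprExpr = sigEE)
  attr(out, "all_methExpr") <- methExpr
  attr(out, "all_exprExpr") <- exprExpr
  out
}

#' Collapse CpG methylation into positional clusters
#'
#' Greedy left-to-right chaining: a cluster is extended while the next
#' CpG lies within `within` bp (default 5 kb) of the last member and the
#' total cluster span stays within `maxWidth` bp (default 10 kb). Every
#' CpG belongs to exactly one cluster; the cluster value per sample is
#' the mean beta of its members.
#'
#' @param betaW CpG x sample beta matrix (rows ordered by position).
#' @param positions bp positions of the CpGs (sorted ascending).
#' @param within maximum gap to extend a cluster.
#' @param maxWidth maximum cluster span.
#' @return list: `values` (cluster x sample means), `clusters`
#'   (data.frame `start`, `end`, `n`, `members`).
#' @export
collapseClusters <- function(betaW, positions, within = 5000,
                             maxWidth = 10000) {
  betaW <- as.matrix(betaW)
  stopifnot(length(positions) == nrow(betaW))
  if (is.unsorted(positions)) stop("positions must be sorted")
  n <- length(positions)
  clusterId <- integer(n)
  cid <- 1L
  clusterId[1] <- cid
  anchor <- positions[1]
  for (i in seq_len(n)[-1]) {
    if (positions[i] - positions[i - 1] <= within &&
        positions[i] - anchor <= maxWidth) {
      clusterId[i] <- cid
    } else {
      cid <- cid + 1L
      clusterId[i] <- cid
      anchor <- positions[i]
    }
  }
  groups <- split(seq_len(n), clusterId)
  vals <- t(vapply(groups, function(ix) {
    colMeans(betaW[ix, , drop = FALSE])
  }, numeric(ncol(betaW))))
  info <- data.frame(
    start = vapply(groups, function(ix) min(positions[ix]), 0),
    end = vapply(groups, function(ix) max(positions[ix]), 0),
    n = lengths(groups),
    members = vapply(groups, function(ix)
      paste(rownames(betaW)[ix], collapse = ","), ""))
  rownames(vals) <- rownames(info) <- paste0("cluster", names(groups))
  colnames(vals) <- colnames(betaW)
  list(values = vals, clusters = info)
}

#' Case-minus-control mean difference profile
#'
#' Unadjusted group mean differences per feature (collapsed methylation
#' cluster or gene), the quantity plotted along a window to appraise
#' coordinated regulation; apply to random control windows to build a
#' comparison envelope.
#'
#' @param values feature x sample matrix.
#' @param group binary exposure per sample (1 = case).
#' @return data.frame `feature`, `difference`.
#' @export
groupDifferenceProfile <- function(values, group) {
  values <- as.matrix(values)
  stopifnot(ncol(values) == length(group), all(group %in% c(0, 1)))
  if (!any(group == 1) || !any(group == 0)) stop("both groups required")
  d <- rowMeans(values[, group == 1, drop = FALSE]) -
    rowMeans(values[, group == 0, drop = FALSE])
  data.frame(feature = rownames(values) %||% seq_along(d), difference = d)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
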