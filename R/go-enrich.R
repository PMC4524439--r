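#' Construct a term universe from a DAG and direct annotations
#'
#' Propagates gene annotations from each term to all of its ancestors
#' (the true-path rule) and computes the information content
#' `IC(t) = -log(annotated(t) / annotated(root))`. The parent structure
#' must be a rooted DAG; a cycle raises an error.
#'
#' @param parents named list: for each term id, character vector of its
#'   direct parent term ids (empty for the root). Exactly one root is
#'   required.
#' @param annotation named list of character vectors: the genes directly
#'   annotated to each term (terms absent from the list get none).
#' @return a \linkS4class{TermUniverse}.
#' @export
termUniverse <- function(parents, annotation) {
  ids <- names(parents)
  if (is.null(ids) || anyDuplicated(ids)) {
    stop("parents must be a uniquely named list")
  }
  unknown <- setdiff(unlist(parents, use.names = FALSE), ids)
  if (length(unknown)) stop("unknown parent term(s): ",
                            paste(unknown, collapse = ", "))
  roots <- ids[lengths(parents) == 0]
  if (length(roots) != 1) stop("exactly one root term is required, found ",
                               length(roots))

  # Kahn topological order; leftover nodes indicate a cycle
  indeg <- setNames(integer(length(ids)), ids)   # edges child -> parent
  for (ch in ids) indeg[parents[[ch]]] <- indeg[parents[[ch]]] + 1L
  queue <- ids[indeg == 0]                       # leaves first
  topo <- character(0)
  while (length(queue)) {
    t <- queue[1]; queue <- queue[-1]
    topo <- c(topo, t)
    for (p in parents[[t]]) {
      indeg[p] <- indeg[p] - 1L
      if (indeg[p] == 0L) queue <- c(queue, p)
    }
  }
  if (length(topo) != length(ids)) stop("term DAG contains a cycle")

  tg <- setNames(vector("list", length(ids)), ids)
  for (t in ids) tg[[t]] <- unique(annotation[[t]])
  for (t in topo) {                              # leaves before ancestors
    for (p in parents[[t]]) tg[[p]] <- union(tg[[p]], tg[[t]])
  }
  nRoot <- length(tg[[roots]])
  if (nRoot == 0) stop("root term annotates no genes")
  ic <- vapply(tg, function(g) {
    if (length(g) == 0) Inf else -log(length(g) / nRoot)
  }, numeric(1))
  new("TermUniverse", parents = parents, termGenes = tg, ic = ic,
      root = roots)
}

# all ancestors of a term (including itself)
.ancestorsOf <- function(universe, term) {
  seen <- character(0)
  stack <- term
  while (length(stack)) {
    t <- stack[1]; stack <- stack[-1]
    if (t %in% seen) next
    seen <- c(seen, t)
    stack <- c(stack, universe@parents[[t]])
  }
  seen
}

#' Jiang-Conrath semantic similarity between two terms
#'
#' Distance `d = IC(a) + IC(b) - 2 IC(MICA)` where MICA is the most
#' informative common ancestor, rescaled to (0, 1] similarity. The default
#' scaling is `1 / (1 + d)`; `"linear"` uses `1 - min(1, d)`.
#'
#' @param universe a \linkS4class{TermUniverse}.
#' @param a,b term ids.
#' @param scaling "inverse" (default) or "linear".
#' @return similarity in [0, 1]; 1 iff the terms have identical IC equal
#'   to their MICA's (in particular when `a == b`).
#' @export
jiangConrath <- function(universe, a, b,
                         scaling = c("inverse", "linear")) {
  scaling <- match.arg(scaling)
  ic <- informationContent(universe, c(a, b))
  common <- intersect(.ancestorsOf(universe, a), .ancestorsOf(universe, b))
  mica <- max(universe@ic[common][is.finite(universe@ic[common])])
  d <- ic[[1]] + ic[[2]] - 2 * mica
  if (!is.finite(d)) return(0)
  if (scaling == "inverse") 1 / (1 + d) else 1 - min(1, d)
}

# pairwise JC similarity matrix over a term set
.jcMatrix <- function(universe, terms, scaling = "inverse") {
  anc <- lapply(terms, .ancestorsOf, universe = universe)
  ic <- universe@ic
  k <- length(terms)
  S <- diag(1, k)
  if (k < 2) { dimnames(S) <- list(terms, terms); return(S) }
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      common <- intersect(anc[[i]], anc[[j]])
      mica <- max(ic[common][is.finite(ic[common])])
      d <- ic[[terms[i]]] + ic[[terms[j]]] - 2 * mica
      s <- if (!is.finite(d)) 0
           else if (scaling == "inverse") 1 / (1 + d) else 1 - min(1, d)
      S[i, j] <- S[j, i] <- s
    }
  }
  dimnames(S) <- list(terms, terms)
  S
}

#' Reduce a term set to non-redundant representatives
#'
#' Terms are first restricted to those annotating between `minGenes` and
#' `maxGenes` genes (propagated counts). Pairwise Jiang-Conrath
#' similarities at or above `simCutoff` define a graph whose connected
#' components ("clusters of highly similar terms", single linkage) are
#' each represented by the member annotating the most genes, ties broken
#' by the lexicographically smallest id.
#'
#' @param universe a \linkS4class{TermUniverse}.
#' @param minGenes,maxGenes propagated-size window (defaults 20 and 1500).
#' @param simCutoff similarity threshold defining "highly similar".
#' @param scaling JC scaling passed to the similarity (see
#'   [jiangConrath()]).
#' @return character vector of representative term ids (sorted), with the
#'   cluster membership attached as attribute `"clusters"`.
#' @export
reduceTerms <- function(universe, minGenes = 20, maxGenes = 1500,
                        simCutoff = 0.7,
                        scaling = c("inverse", "linear")) {
  scaling <- match.arg(scaling)
  sizes <- lengths(universe@termGenes)
  keep <- names(sizes)[sizes >= minGenes & sizes <= maxGenes]
  if (!length(keep)) stop("no terms within the size window [",
                          minGenes, ", ", maxGenes, "]")
  keep <- sort(keep)
  S <- .jcMatrix(universe, keep, scaling)
  adj <- S >= simCutoff
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)$membership
  reps <- vapply(split(keep, comp), function(members) {
    sz <- sizes[members]
    best <- members[sz == max(sz)]
    sort(best)[1]
  }, character(1))
  out <- sort(unname(reps))
  attr(out, "clusters") <- split(keep, comp)
  out
}

#' Closest-gene assignment for CpG probes
#'
#' Each probe is assigned to the gene minimizing the distance from the
#' probe position to the gene's nearest boundary (0 when the probe falls
#' inside the gene body); exact ties go to the lexicographically smaller
#' gene id. Probes on a chromosome without genes stay unassigned (`NA`).
#' (Computed directly rather than through a nearest-range query: exact
#' equidistant ties on opposite sides must resolve deterministically.)
#'
#' @param probeAnnot data.frame with `probe_id`, `chrom`, `pos`.
#' @param geneAnnot data.frame with `gene_id`, `chrom`, `start`, `end`.
#' @return data.frame `probe_id`, `gene_id`, `distance`, aligned to
#'   `probeAnnot`.
#' @export
assignClosestGene <- function(probeAnnot, geneAnnot) {
  gene <- rep(NA_character_, nrow(probeAnnot))
  dist <- rep(NA_real_, nrow(probeAnnot))
  for (ch in unique(probeAnnot$chrom)) {
    pIdx <- which(probeAnnot$chrom == ch)
    g <- geneAnnot[geneAnnot$chrom == ch, , drop = FALSE]
    if (!nrow(g)) next
    g <- g[order(g$gene_id), , drop = FALSE]   # tie -> smaller id wins
    pos <- probeAnnot$pos[pIdx]
    # distance to the nearer boundary, 0 inside the gene body
    D <- pmax(outer(g$start, pos, `-`), outer(-g$end, pos, `+`), 0)
    best <- apply(D, 2, which.min)             # first minimum = smaller id
    gene[pIdx] <- g$gene_id[best]
    dist[pIdx] <- D[cbind(best, seq_along(pos))]
  }
  data.frame(probe_id = probeAnnot$probe_id, gene_id = gene,
             distance = dist, stringsAsFactors = FALSE)
}

# Haldane-Anscombe odds ratios for many terms at once.
# counts: sig genes in term; K: term sizes; nSig, G: margins.
.termOddsRatio <- function(counts, K, nSig, G) {
  a <- counts
  b <- nSig - a
  c <- K - a
  d <- G - nSig - c
  ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5))
}

#' Resampling GO enrichment for methylation hits
#'
#' Methylation arrays interrogate some genes with many more probes than
#' others, so the genes reachable from a random set of significant CpGs
#' are not a uniform draw from the gene universe — a naive hypergeometric
#' test is biased for probe-dense terms. This test builds the null
#' directly on the array design: the observed odds ratio of each term
#' (genes mapped from the significant CpGs vs term membership, with
#' Haldane-Anscombe 0.5 corrections) is compared against odds ratios from
#' `nResamples` random draws of the same number of CpGs from all retained
#' probes (without replacement), each mapped to closest genes the same
#' way. `p = (1 + #(OR_null >= OR_obs)) / (nResamples + 1)` (upper tail =
#' enrichment, never exactly zero), with Benjamini-Hochberg q-values.
#'
#' @param sigCpgs character vector of significant probe ids (subset of
#'   `probeAnnot$probe_id`).
#' @param probeAnnot annotation of all retained probes (the resampling
#'   frame).
#' @param geneAnnot gene coordinates for closest-gene assignment; its
#'   `gene_id` set is the gene universe.
#' @param universe a \linkS4class{TermUniverse}.
#' @param terms term ids to test (e.g. the [reduceTerms()] output);
#'   default all terms except the root.
#' @param nResamples number of random CpG draws.
#' @param seed RNG seed.
#' @return data.frame: `term_id`, `n_sig_genes_in_term`, `odds_ratio`,
#'   `p`, `q`, `method`.
#' @export
methylationEnrichment <- function(sigCpgs, probeAnnot, geneAnnot, universe,
                                  terms = NULL, nResamples = 10000,
                                  seed = 1) {
  if (!length(sigCpgs)) stop("empty significant CpG set")
  if (!all(sigCpgs %in% probeAnnot$probe_id)) {
    stop("sigCpgs must be drawn from the retained probes")
  }
  if (is.null(terms)) terms <- setdiff(names(universe@parents),
                                       universe@root)
  genes <- geneAnnot$gene_id
  G <- length(genes)
  map <- assignClosestGene(probeAnnot, geneAnnot)
  geneOfProbe <- setNames(match(map$gene_id, genes), map$probe_id)

  tg <- termGenes(universe, terms)
  Mt <- vapply(tg, function(g) genes %in% g, logical(G))  # G x T
  K <- colSums(Mt)
  usable <- K > 0
  Mt <- Mt[, usable, drop = FALSE]
  terms <- terms[usable]
  K <- K[usable]
  storage.mode(Mt) <- "double"

  sigGeneIdx <- unique(geneOfProbe[sigCpgs])
  sigGeneIdx <- sigGeneIdx[!is.na(sigGeneIdx)]
  sVec <- numeric(G); sVec[sigGeneIdx] <- 1
  nSig <- sum(sVec)
  obsCounts <- as.vector(crossprod(Mt, sVec))
  obsOR <- .termOddsRatio(obsCounts, K, nSig, G)

  nProbes <- nrow(probeAnnot)
  k <- length(sigCpgs)
  exceed <- numeric(length(terms))
  withSeed(seed, {
    for (r in seq_len(nResamples)) {
      draw <- geneOfProbe[sample.int(nProbes, k)]
      gi <- unique(draw[!is.na(draw)])
      sv <- numeric(G); sv[gi] <- 1
      cnt <- as.vector(crossprod(Mt, sv))
      orNull <- .termOddsRatio(cnt, K, sum(sv), G)
      exceed <- exceed + (orNull >= obsOR)
    }
  })
  p <- (1 + exceed) / (nResamples + 1)
  data.frame(term_id = terms, n_sig_genes_in_term = obsCounts,
             odds_ratio = obsOR, p = p, q = fdrCorrect(p),
             method = "resampling", row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Hypergeometric GO enrichment for expression hits
#'
#' One-sided (upper tail) hypergeometric over-representation test of the
#' significant gene set within each term, over a stated gene universe;
#' odds ratios carry the same Haldane-Anscombe correction as the
#' resampling test so the two are directly comparable.
#'
#' @param sigGenes character vector of significant gene ids.
#' @param geneUniverse character vector of all eligible genes; `sigGenes`
#'   must be a subset.
#' @param universe a \linkS4class{TermUniverse}.
#' @param terms term ids to test; default all but the root.
#' @return data.frame: `term_id`, `n_sig_genes_in_term`, `odds_ratio`,
#'   `p`, `q`, `method`.
#' @export
expressionEnrichment <- function(sigGenes, geneUniverse, universe,
                                 terms = NULL) {
  if (!all(sigGenes %in% geneUniverse)) {
    stop("sigGenes must be contained in the gene universe")
  }
  if (is.null(terms)) terms <- setdiff(names(universe@parents),
                                       universe@root)
  G <- length(geneUniverse)
  nSig <- length(unique(sigGenes))
  tg <- termGenes(universe, terms)
  K <- vapply(tg, function(g) sum(geneUniverse %in% g), integer(1))
  a <- vapply(tg, function(g) sum(unique(sigGenes) %in% g), integer(1))
  usable <- K > 0
  terms <- terms[usable]; K <- K[usable]; a <- a[usable]
  p <- phyper(a - 1, K, G - K, nSig, lower.tail = FALSE)
  if (nSig == 0) p[] <- 1
  or <- .termOddsRatio(a, K, nSig, G)
  data.frame(term_id = terms, n_sig_genes_in_term = a,
             odds_ratio = or, p = p, q = fdrCorrect(p),
             method = "hypergeometric", row.names = NULL,
             stringsAsFactors = FALSE)
}
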