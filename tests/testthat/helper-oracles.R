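# Independent oracles used across the suite. These deliberately use naive
# formulations (explicit enumeration, textbook definitions) so they share
# no code path with the package implementations they check.

# Benjamini-Hochberg by the textbook definition: q_i is the smallest
# estimated FDR over all rejection thresholds that include p_i.
bhBruteForce <- function(p) {
  n <- length(p)
  q <- numeric(n)
  for (i in seq_len(n)) {
    cand <- p[p >= p[i]]
    q[i] <- min(vapply(cand, function(t) {
      min(1, n * t / sum(p <= t))
    }, numeric(1)))
  }
  q
}

# Hypergeometric upper-tail P(X >= a) by explicit summation of the pmf.
hyperTailBruteForce <- function(a, K, nSig, G) {
  ks <- a:min(K, nSig)
  if (a > min(K, nSig)) return(0)
  sum(exp(lchoose(K, ks) + lchoose(G - K, nSig - ks) - lchoose(G, nSig)))
}

# Maximal qualifying runs of candidate probes, by explicit per-start
# extension plus a maximality check (single chromosome; positions
# sorted). Strict contiguity: a run is a set of *consecutive* probes, all
# candidates, same effect sign, consecutive gaps <= maxGap.
bruteForceBumps <- function(pos, tstat, effect, thr, maxGap, minProbes) {
  n <- length(pos)
  cand <- abs(tstat) >= thr
  # can probe j extend a run ending at j-1 with reference sign s?
  extends <- function(j, s) {
    cand[j] && sign(effect[j]) == s &&
      (pos[j] - pos[j - 1L]) <= maxGap
  }
  out <- list()
  for (i in seq_len(n)) {
    if (!cand[i]) next
    s <- sign(effect[i])
    # left-maximality: probe i-1 must not prepend to this run
    if (i > 1L && extends(i, sign(effect[i - 1L])) && cand[i - 1L]) next
    j <- i
    while (j < n && extends(j + 1L, s)) j <- j + 1L
    if ((j - i + 1L) >= minProbes) {
      out[[length(out) + 1L]] <- c(start = pos[i], end = pos[j],
                                   n = j - i + 1L)
    }
  }
  if (!length(out)) {
    return(data.frame(start = numeric(0), end = numeric(0),
                      n = integer(0)))
  }
  as.data.frame(do.call(rbind, out))
}

# nearest gene by exhaustive search over every gene on the probe's
# chromosome, distance to the closer boundary (0 inside), ties -> smaller id
bruteForceClosestGene <- function(chrom, pos, geneAnnot) {
  g <- geneAnnot[geneAnnot$chrom == chrom, , drop = FALSE]
  if (!nrow(g)) return(NA_character_)
  d <- ifelse(pos >= g$start & pos <= g$end, 0,
              pmin(abs(pos - g$start), abs(pos - g$end)))
  best <- g$gene_id[d == min(d)]
  sort(best)[1]
}
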