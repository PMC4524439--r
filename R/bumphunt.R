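#' Bump-hunting detection of differentially methylated regions
#'
#' Flags probes whose adjusted-model |T| statistic exceeds the genome-wide
#' `quantileCut` quantile (default the 99th percentile over all retained
#' probes), then chains flagged probes into regions: consecutive candidate
#' probes at most `maxGap` bp apart (default 500 bp) and with the same
#' effect sign form a run. In strict mode (default) a retained
#' sub-threshold probe lying between two candidates breaks the run —
#' "contiguous" is read literally; `strict = FALSE` chains candidates over
#' intervening probes. Runs shorter than `minProbes` are reported
#' separately as site-level hits. Regions are summarized by the mean
#' member effect (`summary = "mean"`) or the sum (`"area"`), and ranked by
#' the absolute summary effect.
#'
#' @param assoc association table from [runEWAS()] (one row per probe).
#' @param annot probe annotation aligned to `assoc` by `probe_id`; must be
#'   sorted by (chrom, pos), otherwise an error is raised.
#' @param maxGap maximum gap between consecutive candidate probes (bp).
#' @param quantileCut quantile of |t| defining candidate probes.
#' @param minProbes minimum probes per reported region.
#' @param strict sub-threshold probes split runs (see above).
#' @param summary "mean" or "area" region effect summary.
#' @return a [GenomicRanges::GRanges] of regions sorted by position, with
#'   metadata columns `n_probes`, `summary_effect`, `max_abs_t` and
#'   `probe_ids` (comma-separated); singleton candidates are attached as
#'   attribute `"singletons"` (a data.frame). Returns an empty GRanges
#'   when no probe passes the threshold.
#' @export
findBumps <- function(assoc, annot, maxGap = 500, quantileCut = 0.99,
                      minProbes = 2, strict = TRUE,
                      summary = c("mean", "area")) {
  summary <- match.arg(summary)
  idx <- match(assoc$feature_id, annot$probe_id)
  if (anyNA(idx)) stop("association table and annotation are not aligned")
  ann <- annot[idx, , drop = FALSE]
  byChrom <- split(seq_len(nrow(ann)),
                   factor(ann$chrom, levels = unique(ann$chrom)))
  sortedOk <- all(vapply(byChrom, function(ix) {
    all(diff(ix) == 1L) && !is.unsorted(ann$pos[ix])
  }, logical(1)))
  if (!sortedOk) stop("probes must be sorted by (chromosome, position)")
  absT <- abs(assoc$t_stat)
  thr <- quantile(absT, quantileCut, names = FALSE)
  cand <- absT >= thr

  regions <- list()
  singles <- list()
  for (ch in unique(ann$chrom)) {
    onCh <- which(ann$chrom == ch)
    scan <- if (strict) onCh else onCh[cand[onCh]]
    if (!length(scan)) next
    runStart <- NULL
    flush <- function(run) {
      if (is.null(run) || !length(run)) return()
      eff <- assoc$effect[run]
      rec <- list(chrom = ch, start = min(ann$pos[run]),
                  end = max(ann$pos[run]), n = length(run),
                  effect = if (summary == "mean") mean(eff) else sum(eff),
                  maxT = max(absT[run]),
                  ids = paste(assoc$feature_id[run], collapse = ","))
      if (length(run) >= minProbes) {
        regions[[length(regions) + 1L]] <<- rec
      } else {
        singles[[length(singles) + 1L]] <<- rec
      }
    }
    run <- integer(0)
    for (i in scan) {
      if (!cand[i]) { flush(run); run <- integer(0); next }
      if (length(run)) {
        gap <- ann$pos[i] - ann$pos[run[length(run)]]
        sameSign <- sign(assoc$effect[i]) ==
          sign(assoc$effect[run[length(run)]])
        if (gap > maxGap || !sameSign) { flush(run); run <- integer(0) }
      }
      run <- c(run, i)
    }
    flush(run)
  }

  toGR <- function(recs) {
    if (!length(recs)) {
      return(GenomicRanges::GRanges(
        seqnames = character(0), ranges = IRanges::IRanges(),
        n_probes = integer(0), summary_effect = numeric(0),
        max_abs_t = numeric(0), probe_ids = character(0)))
    }
    GenomicRanges::GRanges(
      seqnames = vapply(recs, `[[`, "", "chrom"),
      ranges = IRanges::IRanges(
        start = vapply(recs, `[[`, 0, "start"),
        end = vapply(recs, `[[`, 0, "end")),
      n_probes = vapply(recs, `[[`, 0L, "n"),
      summary_effect = vapply(recs, `[[`, 0, "effect"),
      max_abs_t = vapply(recs, `[[`, 0, "maxT"),
      probe_ids = vapply(recs, `[[`, "", "ids"))
  }
  gr <- sort(toGR(regions))
  attr(gr, "threshold") <- thr
  attr(gr, "singletons") <- if (length(singles)) {
    do.call(rbind, lapply(singles, as.data.frame))
  } else data.frame()
  gr
}

#' Rank region candidates for pyrosequencing validation
#'
#' Regions whose peak probe (largest |t|) carries a SNP-at-target or
#' cross-hybridization flag are excluded (such probes complicate primer
#' design and may reflect polymorphism rather than methylation); the
#' remainder must have peak-probe p below `alphaPeak` and are ranked by
#' absolute summary effect, largest first.
#'
#' @param regions GRanges from [findBumps()].
#' @param assoc association table (per probe).
#' @param annot probe annotation with the exclusion flags.
#' @param alphaPeak required peak-probe significance (default 0.001).
#' @return data.frame of ranked candidates: `chrom`, `start`, `end`,
#'   `n_probes`, `summary_effect`, `peak_probe`, `peak_p`, `rank`;
#'   excluded regions are attached as attribute `"excluded"`.
#' @export
rankCandidatesForValidation <- function(regions, assoc, annot,
                                        alphaPeak = 0.001) {
  if (!length(regions)) {
    out <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), n_probes = integer(0),
                      summary_effect = numeric(0),
                      peak_probe = character(0), peak_p = numeric(0),
                      rank = integer(0))
    attr(out, "excluded") <- character(0)
    return(out)
  }
  tIdx <- setNames(seq_len(nrow(assoc)), assoc$feature_id)
  flagIdx <- setNames(seq_len(nrow(annot)), annot$probe_id)
  rows <- lapply(seq_along(regions), function(i) {
    ids <- strsplit(S4Vectors::mcols(regions)$probe_ids[i], ",")[[1]]
    ts <- abs(assoc$t_stat[tIdx[ids]])
    peak <- ids[which.max(ts)]
    fl <- annot[flagIdx[peak], ]
    data.frame(
      chrom = as.character(GenomicRanges::seqnames(regions))[i],
      start = GenomicRanges::start(regions)[i],
      end = GenomicRanges::end(regions)[i],
      n_probes = S4Vectors::mcols(regions)$n_probes[i],
      summary_effect = S4Vectors::mcols(regions)$summary_effect[i],
      peak_probe = peak,
      peak_p = assoc$p_value[tIdx[peak]],
      peak_flagged = isTRUE(fl$snp_at_target) || isTRUE(fl$cross_hyb_x))
  })
  tab <- do.call(rbind, rows)
  excluded <- tab$peak_probe[tab$peak_flagged]
  keep <- tab[!tab$peak_flagged & tab$peak_p < alphaPeak, , drop = FALSE]
  keep <- keep[order(-abs(keep$summary_effect)), , drop = FALSE]
  keep$rank <- seq_len(nrow(keep))
  keep$peak_flagged <- NULL
  rownames(keep) <- NULL
  attr(keep, "excluded") <- excluded
  keep
}
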