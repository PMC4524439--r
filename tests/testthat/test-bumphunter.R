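# build a minimal association table + annotation on one chromosome
toyAssoc <- function(pos, t, effect = t, chrom = "chr1") {
  ids <- sprintf("cg%03d", seq_along(pos))
  list(assoc = data.frame(feature_id = ids, effect = effect,
                          robust_se = 1, t_stat = t,
                          p_value = 2 * pnorm(-abs(t)), n = 20),
       annot = data.frame(probe_id = ids, chrom = chrom, pos = pos,
                          probe_type = "II", snp_at_target = FALSE,
                          cross_hyb_x = FALSE))
}

test_that("candidate probes chain into regions by the 500 bp gap rule", {
  # 3 candidates at 100/400/800 (gaps 300, 400), same sign -> one region
  tt <- c(5, 5.2, 4.8, seq(0.05, 0.95, length.out = 97))
  pos <- c(100, 400, 800, seq(10000, 106000, by = 1000))
  x <- toyAssoc(pos, tt)
  gr <- findBumps(x$assoc, x$annot, quantileCut = 0.96)
  expect_length(gr, 1)
  expect_equal(GenomicRanges::start(gr), 100)
  expect_equal(GenomicRanges::end(gr), 800)
  expect_equal(S4Vectors::mcols(gr)$n_probes, 3L)
  expect_equal(S4Vectors::mcols(gr)$summary_effect, mean(c(5, 5.2, 4.8)))
  # candidates 600 bp apart stay apart; minProbes=2 drops singletons
  tt2 <- c(5, 5.2, seq(0.05, 0.95, length.out = 98))
  pos2 <- c(100, 700, seq(10000, 107000, by = 1000))
  x2 <- toyAssoc(pos2, tt2)
  gr2 <- findBumps(x2$assoc, x2$annot, quantileCut = 0.98)
  expect_length(gr2, 0)
  expect_equal(nrow(attr(gr2, "singletons")), 2)
})

test_that("strict mode splits runs at intervening sub-threshold probes", {
  tt <- c(5, 0.3, 5.2, seq(0.05, 0.6, length.out = 7))
  pos <- c(100, 200, 300, seq(5000, 11000, by = 1000))
  x <- toyAssoc(pos, tt)
  strict <- findBumps(x$assoc, x$annot, quantileCut = 0.75)
  expect_length(strict, 0)        # the cold probe at 200 breaks the run
  loose <- findBumps(x$assoc, x$annot, quantileCut = 0.75, strict = FALSE)
  expect_length(loose, 1)
  expect_equal(S4Vectors::mcols(loose)$n_probes, 2L)
})

test_that("mixed-sign runs are split at sign changes", {
  tt <- c(5, 5.2, -5.1, -5.3, seq(0.05, 0.5, length.out = 6))
  pos <- c(100, 300, 500, 700, seq(5000, 10000, by = 1000))
  x <- toyAssoc(pos, tt)
  gr <- findBumps(x$assoc, x$annot, quantileCut = 0.55)
  expect_length(gr, 2)
  expect_equal(sign(S4Vectors::mcols(gr)$summary_effect), c(1, -1))
})

test_that("unsorted annotation raises and raising the quantile shrinks", {
  tt <- c(5, 0.1, 5.1, 0.2, 5.2, 0.3, 5.3, 0.4, 5.4, 0.5)
  x <- toyAssoc(c(100, 50, 300, 400, 500, 600, 700, 800, 900, 1000), tt)
  expect_error(findBumps(x$assoc, x$annot), "sorted")
  x2 <- toyAssoc(seq(100, 2000, length.out = 10), rnorm(10, 0, 3))
  n90 <- sum(abs(x2$assoc$t_stat) >=
               quantile(abs(x2$assoc$t_stat), 0.90))
  n99 <- sum(abs(x2$assoc$t_stat) >=
               quantile(abs(x2$assoc$t_stat), 0.99))
  expect_lte(n99, n90)
})

test_that("bump calls equal the brute-force maximal-run oracle", {
  set.seed(301)
  for (rep in 1:60) {
    n <- sample(20:120, 1)
    pos <- sort(sample(1:40000, n))
    t <- rnorm(n) * sample(c(1, 3), n, replace = TRUE)
    x <- toyAssoc(pos, t)
    q <- sample(c(0.8, 0.9, 0.95), 1)
    gr <- findBumps(x$assoc, x$annot, quantileCut = q, minProbes = 2)
    thr <- quantile(abs(t), q, names = FALSE)
    oracle <- bruteForceBumps(pos, t, t, thr, maxGap = 500, minProbes = 2)
    expect_equal(length(gr), nrow(oracle))
    if (nrow(oracle)) {
      ord <- order(oracle$start)
      expect_equal(GenomicRanges::start(gr), oracle$start[ord])
      expect_equal(GenomicRanges::end(gr), oracle$end[ord])
      expect_equal(S4Vectors::mcols(gr)$n_probes,
                   as.integer(oracle$n[ord]))
    }
    # output regions disjoint and sorted
    if (length(gr) > 1) {
      expect_true(all(GenomicRanges::start(gr)[-1] >
                        GenomicRanges::end(gr)[-length(gr)]))
    }
  }
})

test_that("validation candidates drop flagged peaks and rank by effect", {
  tt <- c(6, 5, seq(0.05, 0.2, length.out = 4), 7, 6.5,
          seq(0.25, 0.4, length.out = 4))
  pos <- c(100, 300, 2000, 3000, 4000, 5000,
           20000, 20200, 30000, 31000, 32000, 33000)
  x <- toyAssoc(pos, tt, effect = tt * 0.02)
  gr <- findBumps(x$assoc, x$annot, quantileCut = 0.6)
  expect_length(gr, 2)
  cand <- rankCandidatesForValidation(gr, x$assoc, x$annot,
                                      alphaPeak = 0.001)
  expect_equal(nrow(cand), 2)
  # larger |summary effect| (the 7/6.5 region) ranks first
  expect_gt(abs(cand$summary_effect[1]), abs(cand$summary_effect[2]))
  # flag the peak probe of the stronger region -> excluded
  ann2 <- x$annot
  ann2$snp_at_target[ann2$probe_id == cand$peak_probe[1]] <- TRUE
  cand2 <- rankCandidatesForValidation(gr, x$assoc, ann2,
                                       alphaPeak = 0.001)
  expect_equal(nrow(cand2), 1)
  expect_equal(attr(cand2, "excluded"), cand$peak_probe[1])
  # empty in, empty out
  x3 <- toyAssoc(c(100, 5000, seq(10000, 17000, by = 1000)),
                 c(5, 5.2, seq(0.05, 0.4, length.out = 8)))
  empty <- findBumps(x3$assoc, x3$annot, quantileCut = 0.97,
                     minProbes = 2)
  expect_length(empty, 0)
  expect_equal(nrow(rankCandidatesForValidation(empty, x$assoc,
                                                x$annot)), 0)
})

test_that("injected bumps are recovered from synthetic data", {
  d <- smallDesign(15, seed = 311)
  a <- smallAnnot(1200, seed = 312)
  m <- suppressWarnings(generateMethylation(
    d, a, methEffectConfig(nRegions = 2, regionEffect = 0.1,
                           regionSize = 5),
    seed = 313))
  b <- preprocessMethylation(m$intensities)
  tab <- runEWAS(b, modelFrame(d))
  gr <- findBumps(tab, probeAnnotation(b))
  tr <- GenomicRanges::GRanges(m$truth$regions$chrom,
                               IRanges::IRanges(m$truth$regions$start,
                                                m$truth$regions$end))
  expect_gte(sum(GenomicRanges::countOverlaps(tr, gr) > 0), 1)
})
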