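test_that("cohort generation respects the matched design", {
  d <- generateCohort(41, seed = 1)
  expect_equal(nrow(d), 82)
  expect_equal(sum(d$gdm), 41)
  byPair <- split(d, d$pair_id)
  expect_true(all(vapply(byPair, function(p) {
    nrow(p) == 2 && sum(p$gdm) == 1 &&
      length(unique(p$sex)) == 1 &&
      length(unique(p$smoking)) == 1 &&
      length(unique(p$ethnicity)) == 1 &&
      abs(diff(p$age)) <= 5
  }, logical(1))))
})

test_that("cohort generation is deterministic and validates nPairs", {
  expect_identical(generateCohort(8, seed = 42), generateCohort(8, seed = 42))
  expect_false(identical(generateCohort(8, seed = 42),
                         generateCohort(8, seed = 43)))
  expect_error(generateCohort(2, seed = 1), "invalid design")
  d <- generateCohort(3, seed = 7)
  expect_equal(nrow(d), 6)
  expect_true(all(tapply(d$sex, d$pair_id, function(s)
    length(unique(s)) == 1)))
})

test_that("ethnicity and chip are correlated when mixing is on", {
  d <- generateCohort(60, seed = 5, chipMixing = 0.7)
  tab <- table(d$ethnicity, d$chip)
  p <- suppressWarnings(stats::chisq.test(tab)$p.value)
  expect_lt(p, 0.01)
})

test_that("probe annotation is sorted with island structure and flags", {
  a <- smallAnnot(1200)
  byChrom <- split(a$pos, a$chrom)
  expect_true(all(vapply(byChrom, function(p) !is.unsorted(p), logical(1))))
  expect_true(any(a$chrom == "chrX"))
  expect_true(all(a$probe_type %in% c("I", "II")))
  gaps <- unlist(lapply(byChrom, diff))
  expect_gt(sum(gaps <= 500), 50)  # island bursts give bump-huntable runs
})

test_that("zero-noise methylation round-trips through the beta formula", {
  d <- smallDesign(5)
  a <- smallAnnot(300)
  m <- generateMethylation(d, a, methEffectConfig(noiseSd = 0, batchSd = 0,
                                                  typeIICompression = 1),
                           seed = 11)
  b <- computeBeta(m$intensities)
  base <- m$truth$baseline
  ctrl <- d$sample_id[d$gdm == 0]
  expect_equal(unname(getBeta(b)[, ctrl[1]]),
               unname(pmin(pmax(base, 0.01), 0.97)), tolerance = 1e-12)
})

test_that("null methylation dataset carries no systematic group difference", {
  d <- smallDesign(10)
  a <- smallAnnot(400)
  m <- generateMethylation(d, a, methEffectConfig(), seed = 12)
  b <- computeBeta(m$intensities)
  dif <- rowMeans(getBeta(b)[, d$gdm == 1]) -
    rowMeans(getBeta(b)[, d$gdm == 0])
  expect_lt(abs(mean(dif)), 0.005)
  expect_equal(nrow(m$truth$sites), 0)
})

test_that("methylation truth ledger records sites, regions and clipping", {
  d <- smallDesign(8)
  a <- smallAnnot(1500)
  m <- suppressWarnings(generateMethylation(
    d, a, methEffectConfig(nSites = 15, siteEffect = 0.1,
                           nRegions = 2, regionEffect = 0.08,
                           regionSize = 5),
    seed = 13))
  expect_equal(nrow(m$truth$sites), 15)
  expect_equal(nrow(m$truth$regions), 2)
  expect_true(all(m$truth$sites$probe_id %in% a$probe_id))
  expect_equal(m$truth$sites$realized_effect,
               rep(0.1, 15), tolerance = 1e-12)
  for (i in 1:2) {
    ids <- strsplit(m$truth$regions$probe_ids[i], ",")[[1]]
    expect_length(ids, 5)
    pos <- a$pos[match(ids, a$probe_id)]
    expect_true(all(diff(pos) <= 400))
  }
  # clipping: a huge effect must be clipped, warned about, and ledgered
  expect_warning(
    mc <- generateMethylation(d, a, methEffectConfig(nRegions = 1,
                                                     regionEffect = 0.9),
                              seed = 14),
    "clipped")
  expect_gt(nrow(mc$truth$clipped), 0)
})

test_that("expression generator is additive and ledger-complete", {
  d <- smallDesign(6)
  g <- smallGenes(60)
  e <- generateExpression(d, g, exprEffectConfig(noiseSd = 0, batchSd = 0,
                                                 latentSd = 0,
                                                 background = 0),
                          seed = 21)
  expect_equal(sort(e$truth$blockGenes), sort(g$gene_id[g$in_block]))
  # zero noise: median polish recovers the gene signal exactly
  gid <- e$truth$blockGenes[1]
  block <- log2(e$probes[e$probeMap$gene_id == gid, , drop = FALSE])
  rec <- medianPolishGene(block)
  truthSig <- e$truth$baseline[gid] +
    ifelse(d$gdm == 1, e$truth$blockEffect, 0)
  expect_equal(unname(rec - mean(rec)), unname(truthSig - mean(truthSig)),
               tolerance = 1e-9)
  e2 <- generateExpression(d, g, exprEffectConfig(nGenes = 10), seed = 22)
  expect_equal(nrow(e2$truth$genes), 10)
  expect_identical(e2$probes,
                   generateExpression(d, g, exprEffectConfig(nGenes = 10),
                                      seed = 22)$probes)
})

test_that("pyrosequencing counts are binomial draws of the true beta", {
  expect_error(generatePyroCounts(0.5, depth = 5), "depth")
  pc0 <- generatePyroCounts(matrix(0, 2, 30), depth = 10, seed = 3)
  expect_true(all(pc0$C == 0))
  pc <- generatePyroCounts(matrix(0.5, 1, 1000), depth = 200, seed = 4)
  prop <- mean(pc$C / (pc$C + pc$T))
  expect_gt(prop, 0.49)
  expect_lt(prop, 0.51)
  pc9 <- generatePyroCounts(matrix(0.9, 1, 2000), depth = 500, seed = 5)
  expect_equal(mean(pc9$C / 500), 0.9, tolerance = 0.005)
})

test_that("term universe generator plants sizes, duplicates and probe bias", {
  tu <- generateTermUniverse(2500, nTerms = 40, seed = 31)
  sizes <- lengths(termGenes(tu$universe))
  sizes <- sizes[names(sizes) != tu$universe@root]
  expect_gt(sum(sizes < 20), 0)
  expect_gt(sum(sizes >= 20 & sizes <= 1500), 0)
  expect_gt(sum(sizes > 1500), 0)
  expect_length(tu$duplicateClusters, 3)
  for (cl in tu$duplicateClusters) {
    g1 <- termGenes(tu$universe, cl[1])[[1]]
    g2 <- termGenes(tu$universe, cl[2])[[1]]
    ov <- length(intersect(g1, g2)) / length(union(g1, g2))
    expect_gt(ov, 0.85)
  }
  expect_true(all(tu$probeCounts >= 1 & tu$probeCounts <= 40))
  expect_gt(length(unique(tu$probeCounts)), 5)   # heterogeneous density
  expect_equal(informationContent(tu$universe)[[tu$universe@root]], 0)
})
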