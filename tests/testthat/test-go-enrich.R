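test_that("term universe propagates annotations and computes IC", {
  u <- tinyUniverse()
  expect_equal(informationContent(u)[["root"]], 0)
  # propagation: A's set includes its children's genes
  expect_true(all(unlist(termGenes(u, c("A1", "A2"))) %in%
                    termGenes(u, "A")[[1]]))
  # IC monotone from root toward leaves along each path
  ic <- informationContent(u)
  expect_gte(ic[["A1"]], ic[["A"]])
  expect_gte(ic[["B1"]], ic[["B"]])
  # manual IC check: |A| = 80 propagated, root = 200
  expect_equal(ic[["A"]], -log(80 / 200))
  expect_error(informationContent(u, "nope"), "unknown")
})

test_that("malformed DAGs are rejected", {
  expect_error(termUniverse(list(a = "b", b = "a"),
                            list(a = "g1", b = "g2")),
               "cycle|root")
  expect_error(termUniverse(list(r1 = character(0), r2 = character(0)),
                            list(r1 = "g1", r2 = "g2")),
               "exactly one root")
  expect_error(termUniverse(list(a = character(0), b = "zzz"),
                            list(a = "g1", b = "g2")), "unknown parent")
})

test_that("Jiang-Conrath similarity follows the IC formula", {
  u <- tinyUniverse()
  expect_equal(jiangConrath(u, "A1", "A1"), 1)
  ic <- informationContent(u)
  # disjoint branches: MICA is the root (IC 0)
  dAB <- ic[["A1"]] + ic[["B1"]]
  expect_equal(jiangConrath(u, "A1", "B1"), 1 / (1 + dAB))
  # shared branch: MICA is A
  dA <- ic[["A1"]] + ic[["A2"]] - 2 * ic[["A"]]
  expect_equal(jiangConrath(u, "A1", "A2"), 1 / (1 + dA))
  # linear scaling variant
  expect_equal(jiangConrath(u, "A1", "B1", scaling = "linear"),
               1 - min(1, dAB))
  # symmetry over random pairs
  terms <- setdiff(names(u@parents), "root")
  set.seed(601)
  for (i in 1:20) {
    ab <- sample(terms, 2)
    expect_equal(jiangConrath(u, ab[1], ab[2]),
                 jiangConrath(u, ab[2], ab[1]))
  }
})

test_that("identical terms collapse to one representative", {
  genes <- sprintf("g%03d", 1:100)
  # Y is a child of X carrying the identical gene set: a true duplicate
  parents <- list(root = character(0), X = "root", Y = "X",
                  Z = "root")
  annotation <- list(root = genes, X = genes[1:40], Y = genes[1:40],
                     Z = genes[60:90])
  u <- termUniverse(parents, annotation)
  expect_equal(jiangConrath(u, "X", "Y"), 1)
  reps <- reduceTerms(u, minGenes = 20, maxGenes = 90, simCutoff = 0.7)
  # X and Y identical -> one survives (tie broken lexicographically)
  expect_true("X" %in% reps)
  expect_false("Y" %in% reps)
  expect_true("Z" %in% reps)
})

test_that("term reduction filters sizes and picks the largest member", {
  tu <- generateTermUniverse(2500, nTerms = 40, seed = 611)
  u <- tu$universe
  reps <- reduceTerms(u)
  sizes <- lengths(termGenes(u))
  expect_true(all(sizes[reps] >= 20 & sizes[reps] <= 1500))
  # a 10-gene term can never survive the size window
  small <- names(sizes)[sizes < 20]
  expect_false(any(small %in% reps))
  # each planted near-duplicate cluster contributes one representative,
  # the member with the larger propagated gene count
  for (cl in tu$duplicateClusters) {
    inWindow <- cl[sizes[cl] >= 20 & sizes[cl] <= 1500]
    if (length(inWindow) < 2) next
    expect_equal(sum(reps %in% inWindow), 1)
    kept <- reps[reps %in% inWindow]
    expect_equal(unname(sizes[kept]), max(sizes[inWindow]))
  }
  # invariant to the order in which terms are listed
  set.seed(612)
  perm <- sample(names(u@parents))
  ann <- list()
  for (t in perm) ann[[t]] <- termGenes(u, t)[[1]]
  u2 <- termUniverse(u@parents[perm], ann)
  expect_equal(reduceTerms(u2), reduceTerms(u), ignore_attr = TRUE)
})

test_that("closest-gene assignment matches exhaustive search", {
  ga <- data.frame(gene_id = c("gA", "gB", "gC"), chrom = "chr1",
                   start = c(1000, 5000, 20000),
                   end = c(2000, 6000, 21000))
  pa <- data.frame(probe_id = c("p1", "p2", "p3", "p4"),
                   chrom = c("chr1", "chr1", "chr1", "chr2"),
                   pos = c(1500, 3500, 9000, 100))
  hit <- assignClosestGene(pa, ga)
  expect_equal(hit$gene_id, c("gA", "gA", "gB", NA))
  expect_equal(hit$distance[1], 0)       # inside the gene body
  # equidistant probe: 3500 is 1500 from gA end and 1500 from gB start
  expect_equal(hit$gene_id[2], "gA")     # tie -> smaller id
  # oracle equivalence on random layouts
  set.seed(621)
  for (i in 1:15) {
    g <- data.frame(gene_id = sprintf("g%02d", 1:8), chrom = "chr1",
                    start = sort(sample(seq(1e3, 9e4, by = 50), 8)))
    g$end <- g$start + sample(500:3000, 8)
    p <- data.frame(probe_id = sprintf("p%02d", 1:20), chrom = "chr1",
                    pos = sample(1:1e5, 20))
    got <- assignClosestGene(p, g)
    want <- vapply(p$pos, bruteForceClosestGene, "", chrom = "chr1",
                   geneAnnot = g)
    expect_equal(got$gene_id, unname(want))
  }
})

test_that("hypergeometric enrichment equals the exact tail sum", {
  genes <- sprintf("g%04d", 1:1000)
  parents <- list(root = character(0), T1 = "root")
  u <- termUniverse(parents, list(root = genes, T1 = genes[1:20]))
  sig <- c(genes[1:5], genes[501:545])   # 5 in-term of 50 significant
  res <- expressionEnrichment(sig, genes, u, terms = "T1")
  expect_equal(res$p, hyperTailBruteForce(5, 20, 50, 1000),
               tolerance = 1e-12)
  # significant set = universe -> p = 1 everywhere
  resAll <- expressionEnrichment(genes, genes, u, terms = "T1")
  expect_equal(resAll$p, 1)
  expect_error(expressionEnrichment("absent", genes, u), "contained")
})

test_that("planted expression enrichment ranks first", {
  tu <- generateTermUniverse(1000, nTerms = 25, seed = 631)
  u <- tu$universe
  sizes <- lengths(termGenes(u))
  terms <- setdiff(names(sizes)[sizes >= 20 & sizes <= 500], u@root)
  target <- terms[which.min(abs(sizes[terms] - 60))]
  tg <- termGenes(u, target)[[1]]
  set.seed(632)
  sig <- c(sample(tg, round(0.8 * min(length(tg), 50))),
           sample(setdiff(sprintf("G%05d", 1:1000), tg), 20))
  res <- expressionEnrichment(sig, sprintf("G%05d", 1:1000), u,
                              terms = terms)
  expect_equal(res$term_id[which.min(res$p)], target)
})

test_that("resampling enrichment honours the +1 permutation floor", {
  # two genes, all significant CpGs map into the term's gene
  ga <- data.frame(gene_id = c("gA", "gB"), chrom = "chr1",
                   start = c(1000, 50000), end = c(2000, 51000))
  pa <- data.frame(probe_id = sprintf("cg%02d", 1:40), chrom = "chr1",
                   pos = c(seq(1000, 2000, length.out = 20),
                           seq(50000, 51000, length.out = 20)))
  u <- termUniverse(list(root = character(0), T1 = "root"),
                    list(root = c("gA", "gB"), T1 = "gA"))
  res <- methylationEnrichment(pa$probe_id[1:20], pa, ga, u,
                               terms = "T1", nResamples = 1000, seed = 7)
  # every resample of 20 probes includes a gA probe with prob ~1, but the
  # observed table (all sig in gA, none in gB) is matched only when the
  # draw also misses gB entirely -> never; p attains the 1/(N+1) floor
  expect_gte(res$p, 1 / 1001)
  expect_lte(res$p, 0.05)
  expect_error(methylationEnrichment(character(0), pa, ga, u), "empty")
  expect_error(methylationEnrichment("zz", pa, ga, u), "retained")
})

test_that("balanced probe design makes resampling match hypergeometric", {
  # one probe per gene: closest-gene mapping is a uniform gene draw
  set.seed(641)
  nG <- 300
  ga <- data.frame(gene_id = sprintf("G%04d", 1:nG), chrom = "chr1",
                   start = seq(1e4, by = 1e4, length.out = nG))
  ga$end <- ga$start + 2000
  counts <- setNames(rep(1L, nG), ga$gene_id)
  pa <- generateProbesForGenes(ga, counts, seed = 642)
  tu <- generateTermUniverse(ga$gene_id, nTerms = 15, seed = 643)
  sizes <- lengths(termGenes(tu$universe))
  terms <- setdiff(names(sizes)[sizes >= 20 & sizes <= 200],
                   tu$universe@root)[1:5]
  sig <- sample(pa$probe_id, 40)
  resR <- methylationEnrichment(sig, pa, ga, tu$universe, terms = terms,
                                nResamples = 4000, seed = 644)
  sigGenes <- unique(pa$nearest_gene_id[match(sig, pa$probe_id)])
  resH <- expressionEnrichment(sigGenes, ga$gene_id, tu$universe,
                               terms = terms)
  expect_lt(mean(abs(resR$p - resH$p)), 0.05)
})
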