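test_that("window feature selection uses closed CpG flanks and TSS", {
  pa <- data.frame(probe_id = c("c1", "c2", "c3", "c4"),
                   chrom = "chr5",
                   pos = c(1e7 - 10000, 1e7 - 10001, 1.2e7, 1.5e7 + 10000))
  ga <- data.frame(gene_id = c("g1", "g2", "g3"), chrom = "chr5",
                   tss = c(1e7, 1.5e7, 1e7 - 1))
  w <- list(chrom = "chr5", start = 1e7, end = 1.5e7)
  f <- selectWindowFeatures(pa, ga, w)
  expect_setequal(f$cpgs, c("c1", "c3", "c4"))  # boundary CpGs included
  expect_setequal(f$genes, c("g1", "g2"))       # TSS 1 bp outside excluded
  expect_error(selectWindowFeatures(pa, ga,
                                    list(chrom = "chr5", start = 10,
                                         end = 5)), "empty")
})

test_that("permutation Spearman handles exact monotone and inverse pairs", {
  x <- 1:30
  r <- permutationSpearman(x, x^3, nPerm = 2000, seed = 7)
  expect_equal(r$rho, 1)
  expect_equal(r$p, 1e-6)          # zero permutations match -> imputed
  r2 <- permutationSpearman(x, -x, nPerm = 500, seed = 7)
  expect_equal(r2$rho, -1)
  expect_warning(r3 <- permutationSpearman(x, rep(1, 30), nPerm = 100),
                 "constant")
  expect_true(is.na(r3$rho))
  expect_error(permutationSpearman(1:5, 1:5), "at least 10")
  # reproducible under a fixed seed
  set.seed(99); xx <- rnorm(25); yy <- rnorm(25)
  a <- permutationSpearman(xx, yy, nPerm = 1000, seed = 12)
  b <- permutationSpearman(xx, yy, nPerm = 1000, seed = 12)
  expect_identical(a, b)
})

test_that("rho matches cor(method='spearman') including ties", {
  set.seed(501)
  for (i in 1:20) {
    x <- sample(1:8, 20, replace = TRUE)   # heavy ties
    y <- rnorm(20)
    r <- permutationSpearman(x, y, nPerm = 50, seed = 1)
    expect_equal(r$rho, cor(x, y, method = "spearman"), tolerance = 1e-12)
  }
})

test_that("network edges respect the regional FDR and truncation", {
  d <- smallDesign(20, seed = 511)
  g <- smallGenes(80, seed = 512)
  e <- generateExpression(d, g, exprEffectConfig(blockEffect = -0.3,
                                                 latentSd = 0.8),
                          seed = 513)
  em <- preprocessExpression(e$probes, e$probeMap)
  blk <- em[e$truth$blockGenes, ]
  nulls <- em[setdiff(rownames(em), e$truth$blockGenes)[1:10], ]
  betaW <- matrix(runif(5 * ncol(em), 0.2, 0.8), 5,
                  dimnames = list(paste0("cg", 1:5), colnames(em)))
  nets <- buildNetworks(betaW, rbind(blk, nulls), nPerm = 500, seed = 514)
  ee <- nets$exprExpr
  expect_true(!is.null(ee) && nrow(ee) > 10)
  inBlock <- ee$gene_a %in% e$truth$blockGenes &
    ee$gene_b %in% e$truth$blockGenes
  expect_gt(mean(inBlock), 0.5)              # block dominates the edges
  expect_gt(mean(ee$rho[inBlock] > 0), 0.9)  # positively co-regulated
  # truncation boundary: cap the co-expression family
  netsCap <- buildNetworks(betaW, rbind(blk, nulls), nPerm = 500,
                           seed = 514, maxExprEdges = 3)
  expect_lte(nrow(netsCap$exprExpr), 3)
  expect_equal(netsCap$exprExpr$rho,
               ee$rho[order(-abs(ee$rho))][1:3], tolerance = 1e-12)
})

test_that("null windows yield almost no significant edges", {
  set.seed(521)
  n <- 30
  betaW <- matrix(runif(8 * n, 0.2, 0.8), 8,
                  dimnames = list(paste0("cg", 1:8), paste0("s", 1:n)))
  exprW <- matrix(rnorm(6 * n, 8), 6,
                  dimnames = list(paste0("g", 1:6), paste0("s", 1:n)))
  nets <- buildNetworks(betaW, exprW, nPerm = 400, seed = 522)
  expect_lte(nrow(nets$methExpr) + nrow(nets$exprExpr), 2)
  all <- attr(nets, "all_methExpr")
  expect_equal(nrow(all), 48)
  expect_true(all(all$q >= all$p - 1e-12))
})

test_that("BH q-values match the brute-force definition", {
  expect_equal(fdrCorrect(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(fdrCorrect(rep(1, 5)), rep(1, 5))
  set.seed(531)
  for (i in 1:10) {
    p <- runif(sample(5:100, 1))^sample(1:3, 1)
    p[p == 0] <- 1e-8
    q <- fdrCorrect(p)
    expect_equal(q, bhBruteForce(p), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-15))
    expect_true(all(diff(q[order(p)]) >= -1e-15))  # monotone in p
  }
  expect_error(fdrCorrect(c(0.5, 0)), "0, 1")
})

test_that("cluster collapsing follows the greedy 5kb/10kb rule", {
  b <- matrix(seq(0.1, 0.6, length.out = 6), 3, 2)
  rownames(b) <- paste0("cg", 1:3)
  cl <- collapseClusters(b, c(100, 4000, 9000))
  expect_equal(nrow(cl$values), 1)        # gaps 3.9k/5k, span 8.9k
  expect_equal(unname(cl$values[1, ]), unname(colMeans(b)))
  cl2 <- collapseClusters(b, c(100, 9000, 15000))
  expect_equal(nrow(cl2$values), 3)       # both gaps exceed 5 kb
  cl3 <- collapseClusters(b[1, , drop = FALSE], 100)
  expect_equal(unname(cl3$values[1, ]), unname(b[1, ]))
  # max width: chain of 5kb steps must be cut at 10kb span
  b4 <- matrix(0.5, 4, 2, dimnames = list(paste0("cg", 1:4), NULL))
  cl4 <- collapseClusters(b4, c(0, 5000, 10000, 15000))
  expect_equal(nrow(cl4$values), 2)
  expect_equal(cl4$clusters$n, c(3L, 1L))
  # partition property on random instances
  set.seed(541)
  for (i in 1:10) {
    k <- sample(5:40, 1)
    pos <- sort(sample(1:60000, k))
    bb <- matrix(runif(k * 3), k, 3,
                 dimnames = list(paste0("cg", 1:k), NULL))
    cc <- collapseClusters(bb, pos)
    members <- unlist(strsplit(cc$clusters$members, ","))
    expect_setequal(members, rownames(bb))
    expect_equal(length(members), k)      # each CpG in exactly one cluster
  }
  expect_error(collapseClusters(b, c(5, 1, 10)), "sorted")
})

test_that("group difference profile is zero for identical groups", {
  v <- matrix(rep(c(1, 2, 3), 4), 3, 4)
  expect_equal(groupDifferenceProfile(v, c(1, 0, 1, 0))$difference,
               rep(0, 3))
  d <- smallDesign(15, seed = 551)
  g <- smallGenes(60, seed = 552)
  e <- generateExpression(d, g, exprEffectConfig(blockEffect = -0.4,
                                                 latentSd = 0),
                          seed = 553)
  em <- preprocessExpression(e$probes, e$probeMap)
  prof <- groupDifferenceProfile(em[e$truth$blockGenes, ], d$gdm)
  nullProf <- groupDifferenceProfile(
    em[setdiff(rownames(em), e$truth$blockGenes), ], d$gdm)
  expect_lt(mean(prof$difference), mean(nullProf$difference) - 0.1)
  expect_lt(abs(mean(nullProf$difference)), 0.15)
  expect_error(groupDifferenceProfile(v, c(1, 1, 1, 1)), "both groups")
})
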