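#' Generate a matched case-control cohort design
#'
#' Simulates the covariate table of a matched gestational-diabetes (GDM)
#' placenta study: each case is paired with one control sharing infant sex,
#' maternal smoking status and self-reported ethnicity, with maternal age
#' matched to within 5 years and pre-pregnancy BMI to within a few kg/m2.
#' Array batch labels (chip, chip row, chip column) are assigned so that
#' chip is partially confounded with ethnicity, which makes surrogate
#' adjustment downstream non-trivial but identifiable.
#'
#' @param nPairs number of case-control pairs (>= 3; smaller designs leave
#'   the adjusted models unidentifiable).
#' @param seed integer RNG seed; the same seed reproduces the table exactly.
#' @param ethnicities labels of the self-reported ethnicity categories.
#' @param pEthnicity sampling probabilities for `ethnicities`.
#' @param nChips number of array chips; default `max(2, ceiling(n/12))`
#'   (12 samples per 450K-style chip).
#' @param chipMixing in [0,1]: probability that a sample is placed on its
#'   ethnicity's "home" chip rather than a random chip. 0 = no
#'   ethnicity-batch confounding, 1 = complete confounding.
#' @return data.frame with one row per sample: `sample_id`, `pair_id`,
#'   `gdm` (1 = case), `age`, `bmi`, `sex`, `smoking`, `ethnicity`,
#'   `chip`, `row`, `column`.
#' @export
#' @examples
#' d <- generateCohort(10, seed = 1)
#' table(d$gdm)
generateCohort <- function(nPairs, seed,
                           ethnicities = c("white", "black", "asian"),
                           pEthnicity = c(0.6, 0.2, 0.2),
                           nChips = NULL,
                           chipMixing = 0.5) {
  assertPositiveCount(nPairs, "nPairs")
  if (nPairs < 3) {
    stop("invalid design: nPairs must be >= 3 for identifiable models")
  }
  n <- 2L * nPairs
  if (is.null(nChips)) nChips <- max(2L, ceiling(n / 12))
  withSeed(seed, {
    ageCase <- pmin(pmax(rnorm(nPairs, 32, 4.5), 18), 45)
    ageCtrl <- ageCase + runif(nPairs, -2.5, 2.5)
    bmiCase <- pmin(pmax(rnorm(nPairs, 24.5, 4), 16), 45)
    bmiCtrl <- pmin(pmax(bmiCase + rnorm(nPairs, 0, 1.5), 16), 45)
    sex <- rbinom(nPairs, 1, 0.5)
    smoking <- rbinom(nPairs, 1, 0.1)
    eth <- sample(ethnicities, nPairs, replace = TRUE, prob = pEthnicity)

    d <- data.frame(
      sample_id = sprintf("S%03d", seq_len(n)),
      pair_id = rep(seq_len(nPairs), each = 2L),
      gdm = rep(c(1L, 0L), nPairs),
      age = as.vector(rbind(ageCase, ageCtrl)),
      bmi = as.vector(rbind(bmiCase, bmiCtrl)),
      sex = rep(sex, each = 2L),
      smoking = rep(smoking, each = 2L),
      ethnicity = rep(eth, each = 2L),
      stringsAsFactors = FALSE)

    # chip partially tracks ethnicity: each ethnicity has a home chip
    homeChip <- setNames(
      rep(seq_len(nChips), length.out = length(ethnicities)), ethnicities)
    useHome <- rbinom(n, 1, chipMixing) == 1L
    chip <- ifelse(useHome, homeChip[d$ethnicity],
                   sample(seq_len(nChips), n, replace = TRUE))
    d$chip <- sprintf("chip%02d", chip)
    d$row <- sprintf("R%d", sample(1:6, n, replace = TRUE))
    d$column <- sprintf("C%d", sample(1:2, n, replace = TRUE))
    d
  })
}

#' Generate a 450K-like probe annotation
#'
#' Places CpG probes on a small synthetic genome (autosomes plus chrX for
#' exercising the sex-chromosome filter). Probe positions follow a
#' background Poisson process punctuated by dense "island" bursts of
#' closely spaced probes (gaps of a few hundred bp), giving bump hunting a
#' realistic gap structure. Probe chemistry type, SNP-at-target and
#' X-cross-hybridization flags are assigned independently of any
#' downstream effect injection.
#'
#' @param nProbes total number of probes.
#' @param seed integer RNG seed.
#' @param chromosomes chromosome names; anything not matching "X" or "Y"
#'   is treated as autosomal.
#' @param chromWeights relative probe allocation per chromosome.
#' @param pTypeII proportion of type II chemistry probes.
#' @param pSNP,pCrossHyb marginal rates of the two exclusion flags.
#' @param meanGap mean background inter-probe gap in bp.
#' @param pIsland probability that a background probe seeds an island burst.
#' @param geneAnnot optional gene table (see [generateGeneAnnotation()]);
#'   if supplied, `nearest_gene_id` and `distance_to_gene` are filled in
#'   by closest-gene assignment.
#' @return data.frame sorted by (chrom, pos): `probe_id`, `chrom`, `pos`
#'   (1-based), `probe_type` ("I"/"II"), `snp_at_target`, `cross_hyb_x`,
#'   `nearest_gene_id`, `distance_to_gene`.
#' @export
generateProbeAnnotation <- function(nProbes, seed,
                                    chromosomes = c(paste0("chr", 1:5), "chrX"),
                                    chromWeights = NULL,
                                    pTypeII = 0.8, pSNP = 0.02,
                                    pCrossHyb = 0.02,
                                    meanGap = 20000, pIsland = 0.2,
                                    geneAnnot = NULL) {
  assertPositiveCount(nProbes, "nProbes")
  if (is.null(chromWeights)) {
    chromWeights <- ifelse(grepl("X|Y", chromosomes), 0.05, 1)
  }
  withSeed(seed, {
    alloc <- as.vector(stats::rmultinom(1, nProbes,
                                        chromWeights / sum(chromWeights)))
    rows <- vector("list", length(chromosomes))
    for (ci in seq_along(chromosomes)) {
      k <- alloc[ci]
      if (k == 0L) next
      pos <- numeric(k)
      cur <- 1e5
      i <- 1L
      while (i <= k) {
        pos[i] <- cur
        i <- i + 1L
        if (i > k) break
        if (runif(1) < pIsland) {
          # island burst: a handful of probes with small gaps
          m <- min(k - i + 1L, 2L + rpois(1, 5))
          for (j in seq_len(m)) {
            cur <- cur + round(runif(1, 30, 450))
            pos[i] <- cur
            i <- i + 1L
            if (i > k) break
          }
          if (i > k) break
        }
        cur <- cur + round(rexp(1, 1 / meanGap)) + 500
      }
      rows[[ci]] <- data.frame(chrom = chromosomes[ci], pos = pos[seq_len(k)])
    }
    ann <- do.call(rbind, rows)
    ann <- ann[order(match(ann$chrom, chromosomes), ann$pos), , drop = FALSE]
    n <- nrow(ann)
    ann$probe_id <- sprintf("cg%06d", seq_len(n))
    ann$probe_type <- ifelse(runif(n) < pTypeII, "II", "I")
    ann$snp_at_target <- runif(n) < pSNP
    ann$cross_hyb_x <- runif(n) < pCrossHyb
    ann$nearest_gene_id <- NA_character_
    ann$distance_to_gene <- NA_real_
    rownames(ann) <- ann$probe_id
    ann <- ann[, c("probe_id", "chrom", "pos", "probe_type", "snp_at_target",
                   "cross_hyb_x", "nearest_gene_id", "distance_to_gene")]
    if (!is.null(geneAnnot)) {
      hit <- assignClosestGene(ann, geneAnnot)
      ann$nearest_gene_id <- hit$gene_id
      ann$distance_to_gene <- hit$distance
    }
    ann
  })
}

#' Generate a gene annotation with a coordinated-regulation block
#'
#' Genes are placed uniformly on the autosomes; a configurable contiguous
#' window (the synthetic analogue of the MHC region) is guaranteed to
#' contain `nBlockGenes` genes, which the expression generator can
#' down-shift coherently in cases.
#'
#' @param nGenes total genes.
#' @param seed integer RNG seed.
#' @param chromosomes autosome names to use.
#' @param chromLength length of each chromosome in bp.
#' @param blockWindow list(chrom, start, end) of the coordinated block.
#' @param nBlockGenes genes forced inside the block window.
#' @param pCoding proportion flagged as coding (reporting filter).
#' @return data.frame: `gene_id`, `chrom`, `start`, `end`, `strand`,
#'   `tss`, `coding`, `in_block`.
#' @export
generateGeneAnnotation <- function(nGenes, seed,
                                   chromosomes = paste0("chr", 1:5),
                                   chromLength = 5e7,
                                   blockWindow = list(chrom = "chr5",
                                                      start = 1e7,
                                                      end = 1.5e7),
                                   nBlockGenes = 15,
                                   pCoding = 0.9) {
  assertPositiveCount(nGenes, "nGenes")
  stopifnot(nBlockGenes < nGenes)
  withSeed(seed, {
    nFree <- nGenes - nBlockGenes
    chrom <- sample(chromosomes, nFree, replace = TRUE)
    start <- round(runif(nFree, 1e5, chromLength - 3e5))
    width <- round(runif(nFree, 5e3, 1e5))
    bStart <- round(seq(blockWindow$start + 5e4, blockWindow$end - 1e5,
                        length.out = nBlockGenes))
    g <- data.frame(
      chrom = c(chrom, rep(blockWindow$chrom, nBlockGenes)),
      start = c(start, bStart),
      end = c(start + width,
              bStart + round(runif(nBlockGenes, 5e3, 5e4))),
      in_block = c(rep(FALSE, nFree), rep(TRUE, nBlockGenes)))
    g <- g[order(match(g$chrom, chromosomes), g$start), , drop = FALSE]
    n <- nrow(g)
    g$gene_id <- sprintf("G%05d", seq_len(n))
    g$strand <- sample(c("+", "-"), n, replace = TRUE)
    g$tss <- ifelse(g$strand == "+", g$start, g$end)
    g$coding <- runif(n) < pCoding
    g$coding[g$in_block] <- TRUE
    rownames(g) <- g$gene_id
    g[, c("gene_id", "chrom", "start", "end", "strand", "tss", "coding",
          "in_block")]
  })
}

#' Effect configuration for the methylation generator
#'
#' @param nSites number of isolated CpGs carrying a site-specific GDM
#'   effect.
#' @param siteEffect beta-scale difference (cases minus controls) injected
#'   at those sites.
#' @param nRegions number of injected differentially methylated regions.
#' @param regionEffect beta-scale shift applied to every probe of a region.
#' @param regionSize probes per injected region (placed on runs with
#'   inter-probe gaps <= `regionMaxGap`).
#' @param regionMaxGap maximum inter-probe gap within an injected region.
#' @param blockWindow optional list(chrom, start, end); if given,
#'   `nBlockSites` scattered CpGs inside it receive `blockEffect`.
#' @param nBlockSites,blockEffect scattered within-block methylation shifts.
#' @param noiseSd log-normal sd of the multiplicative intensity noise on
#'   each channel (0.15 gives mid-range beta SD near 0.05, typical of
#'   450K technical replication).
#' @param batchSd log-normal sd of per-chip/row/column channel-specific
#'   intensity factors (0 disables batch effects).
#' @param batchVars which batch variables carry effects (any of "chip",
#'   "row", "column").
#' @param typeIICompression slope of the type II compression toward 0.5
#'   (1 = no probe-type bias).
#' @return list of class `methEffectConfig`.
#' @export
methEffectConfig <- function(nSites = 0, siteEffect = 0.1,
                             nRegions = 0, regionEffect = 0.08,
                             regionSize = 5, regionMaxGap = 400,
                             blockWindow = NULL, nBlockSites = 0,
                             blockEffect = 0.05,
                             noiseSd = 0.15, batchSd = 0,
                             batchVars = c("chip", "row", "column"),
                             typeIICompression = 0.8) {
  cfg <- as.list(environment())
  class(cfg) <- "methEffectConfig"
  cfg
}

#' Simulate paired methylation intensities with a truth ledger
#'
#' Draws per-probe baseline methylation from a bimodal beta mixture,
#' injects site-specific, regional and within-block case-control effects on
#' the beta scale, compresses type II probes toward 0.5 to emulate the
#' probe-type bias, and converts to methylated/unmethylated channel
#' intensities such that `M / (M + U + 100)` returns the intended beta
#' exactly when noise and batch effects are switched off. Noise is
#' log-normal and multiplicative per channel; chip/row/column batch
#' effects are channel-specific intensity factors, so they displace beta
#' values and must be removed by surrogate adjustment.
#'
#' Effects that would push a true beta outside [0.01, 0.97] are clipped
#' and the affected probes recorded in the truth ledger (`$clipped`), with
#' a warning.
#'
#' @param design cohort table from [generateCohort()].
#' @param annot probe annotation from [generateProbeAnnotation()].
#' @param effectCfg a [methEffectConfig()].
#' @param seed integer RNG seed.
#' @return list with elements `intensities` (a
#'   \linkS4class{MethIntensitySet}) and `truth`, a ledger list with
#'   `sites` (probe_id, effect), `regions` (chrom, start, end, effect,
#'   probe_ids), `blockSites`, `blockWindow` and `clipped`.
#' @export
generateMethylation <- function(design, annot,
                                effectCfg = methEffectConfig(),
                                seed = 1) {
  stopifnot(inherits(effectCfg, "methEffectConfig"))
  n <- nrow(design)
  p <- nrow(annot)
  autosomal <- !grepl("X|Y", annot$chrom)
  withSeed(seed, {
    comp <- sample(c("low", "mid", "high"), p, replace = TRUE,
                   prob = c(0.35, 0.3, 0.35))
    base <- numeric(p)
    base[comp == "low"] <- rbeta(sum(comp == "low"), 1.5, 12)
    base[comp == "mid"] <- rbeta(sum(comp == "mid"), 5, 5)
    base[comp == "high"] <- rbeta(sum(comp == "high"), 12, 1.5)
    base <- pmin(pmax(base, 0.02), 0.95)

    effect <- numeric(p)                      # per-probe injected effect
    names(effect) <- annot$probe_id

    # site-specific effects on isolated autosomal, unflagged probes whose
    # baseline leaves room for the full shift (no clipping at sites)
    eligible <- which(autosomal & !annot$snp_at_target & !annot$cross_hyb_x &
                        base + effectCfg$siteEffect <= 0.97 &
                        base + effectCfg$siteEffect >= 0.01)
    sites <- integer(0)
    if (effectCfg$nSites > 0) {
      sites <- sample(eligible, effectCfg$nSites)
      effect[sites] <- effect[sites] + effectCfg$siteEffect
    }

    # regional effects on runs of closely spaced probes
    regions <- data.frame(chrom = character(0), start = numeric(0),
                          end = numeric(0), effect = numeric(0),
                          n_probes = integer(0), probe_ids = character(0))
    if (effectCfg$nRegions > 0) {
      runs <- .findTightRuns(annot, effectCfg$regionMaxGap,
                             effectCfg$regionSize, autosomal,
                             exclude = sites)
      if (length(runs) < effectCfg$nRegions) {
        stop("annotation does not contain enough tight probe runs; ",
             "increase nProbes or pIsland")
      }
      pick <- sample(seq_along(runs), effectCfg$nRegions)
      for (ri in pick) {
        idx <- runs[[ri]][seq_len(effectCfg$regionSize)]
        effect[idx] <- effect[idx] + effectCfg$regionEffect
        regions <- rbind(regions, data.frame(
          chrom = annot$chrom[idx[1]],
          start = min(annot$pos[idx]), end = max(annot$pos[idx]),
          effect = effectCfg$regionEffect, n_probes = length(idx),
          probe_ids = paste(annot$probe_id[idx], collapse = ",")))
      }
    }

    blockSites <- character(0)
    if (!is.null(effectCfg$blockWindow) && effectCfg$nBlockSites > 0) {
      bw <- effectCfg$blockWindow
      inWin <- which(annot$chrom == bw$chrom & annot$pos >= bw$start &
                       annot$pos <= bw$end & effect == 0)
      take <- sample(inWin, min(effectCfg$nBlockSites, length(inWin)))
      effect[take] <- effect[take] + effectCfg$blockEffect
      blockSites <- annot$probe_id[take]
    }

    # true beta per probe x sample: effect applies to cases only
    caseCol <- design$gdm == 1L
    B <- matrix(base, nrow = p, ncol = n)
    B[, caseCol] <- B[, caseCol] + effect
    clippedIdx <- which(rowSums(B < 0.01 | B > 0.97) > 0 & effect != 0)
    if (length(clippedIdx)) {
      warning(length(clippedIdx),
              " probe(s) had injected effects clipped to keep beta in range")
    }
    B <- pmin(pmax(B, 0.01), 0.97)

    # type II probes report a value compressed toward 0.5
    isII <- annot$probe_type == "II"
    Bm <- B
    Bm[isII, ] <- 0.5 + effectCfg$typeIICompression * (B[isII, ] - 0.5)

    # channel intensities: exact inversion of beta = M/(M+U+100)
    S <- 4000 + rlnorm(p, log(2000), 0.4)    # total signal, floor keeps U>=0
    M <- Bm * S
    U <- (1 - Bm) * S - 100

    if (effectCfg$batchSd > 0) {
      # probe-specific batch effects (probe x batch-level interactions):
      # global per-sample shifts would be absorbed by between-array
      # normalization, but probe-wise chip/row/column effects survive it,
      # which is what surrogate adjustment has to remove
      for (v in effectCfg$batchVars) {
        lev <- unique(design[[v]])
        dM <- matrix(rnorm(p * length(lev), 0, effectCfg$batchSd), p,
                     dimnames = list(NULL, lev))
        dU <- matrix(rnorm(p * length(lev), 0, effectCfg$batchSd), p,
                     dimnames = list(NULL, lev))
        M <- M * exp(dM[, design[[v]], drop = FALSE])
        U <- U * exp(dU[, design[[v]], drop = FALSE])
      }
    }
    if (effectCfg$noiseSd > 0) {
      M <- M * matrix(rlnorm(p * n, 0, effectCfg$noiseSd), p, n)
      U <- U * matrix(rlnorm(p * n, 0, effectCfg$noiseSd), p, n)
    }
    dimnames(M) <- dimnames(U) <- list(annot$probe_id, design$sample_id)

    # realized per-probe effect after clipping (what a model can recover)
    realized <- pmin(pmax(base + effect, 0.01), 0.97) -
      pmin(pmax(base, 0.01), 0.97)

    truth <- list(
      sites = data.frame(probe_id = annot$probe_id[sites],
                         effect = rep(effectCfg$siteEffect,
                                      length(sites)),
                         realized_effect = realized[sites]),
      regions = regions,
      blockSites = data.frame(probe_id = blockSites,
                              effect = rep(effectCfg$blockEffect,
                                           length(blockSites))),
      blockWindow = effectCfg$blockWindow,
      clipped = data.frame(probe_id = annot$probe_id[clippedIdx]),
      baseline = setNames(base, annot$probe_id))

    list(intensities = MethIntensitySet(M, U, probeAnnot = annot,
                                        colData = design),
         truth = truth)
  })
}

# maximal runs of >= minLen consecutive autosomal probes with gaps <= maxGap
.findTightRuns <- function(annot, maxGap, minLen, autosomal,
                           exclude = integer(0)) {
  runs <- list()
  idx <- which(autosomal)
  byChrom <- split(idx, annot$chrom[idx])
  for (ix in byChrom) {
    ix <- ix[order(annot$pos[ix])]
    if (length(ix) < minLen) next
    gaps <- diff(annot$pos[ix])
    brk <- c(0, which(gaps > maxGap), length(ix))
    for (k in seq_len(length(brk) - 1L)) {
      run <- ix[(brk[k] + 1L):brk[k + 1L]]
      if (length(run) >= minLen && !any(run %in% exclude)) {
        runs[[length(runs) + 1L]] <- run
      }
    }
  }
  runs
}

#' Effect configuration for the expression generator
#'
#' @param nGenes number of genes given an individual GDM expression effect.
#' @param geneEffect log2-scale case-minus-control shift at those genes.
#' @param blockEffect shared log2 down-shift applied to all block genes in
#'   cases (the coordinated-regulation signal).
#' @param latentSd sd of the per-sample latent factor loading shared by
#'   block genes (creates dense positive co-expression inside the block).
#' @param probesPerGene mean probes per transcript (Poisson, floor 1).
#' @param affinitySd sd of fixed per-probe affinity offsets (log2).
#' @param noiseSd residual probe-level noise sd (log2).
#' @param batchSd per-chip additive batch sd (log2).
#' @param background additive linear-scale optical background.
#' @return list of class `exprEffectConfig`.
#' @export
exprEffectConfig <- function(nGenes = 0, geneEffect = -0.5,
                             blockEffect = -0.3, latentSd = 0.5,
                             probesPerGene = 21, affinitySd = 0.5,
                             noiseSd = 0.3, batchSd = 0,
                             background = 30) {
  cfg <- as.list(environment())
  class(cfg) <- "exprEffectConfig"
  cfg
}

#' Simulate probe-level expression intensities
#'
#' Gene-level log2 signal plus fixed probe affinities, optional chip batch
#' shifts and Gaussian noise, exponentiated to the linear intensity scale
#' with an additive optical background — an additive-on-log-scale model
#' that median polish can invert. Genes flagged `in_block` in the gene
#' annotation receive a common down-shift in cases plus a shared
#' per-sample latent factor, emulating coordinated regulation of the MHC
#' analogue.
#'
#' @param design cohort table from [generateCohort()].
#' @param geneAnnot gene table from [generateGeneAnnotation()].
#' @param effectCfg an [exprEffectConfig()].
#' @param seed integer RNG seed.
#' @return list: `probes` (probe x sample linear intensities), `probeMap`
#'   (probe_id, gene_id), `truth` (genes with injected effects, block gene
#'   ids, per-gene baseline).
#' @export
generateExpression <- function(design, geneAnnot,
                               effectCfg = exprEffectConfig(),
                               seed = 1) {
  stopifnot(inherits(effectCfg, "exprEffectConfig"))
  n <- nrow(design)
  G <- nrow(geneAnnot)
  withSeed(seed, {
    mu <- rnorm(G, 8, 1.5)
    effect <- numeric(G)
    names(effect) <- geneAnnot$gene_id
    free <- which(!geneAnnot$in_block)
    affected <- integer(0)
    if (effectCfg$nGenes > 0) {
      affected <- sample(free, effectCfg$nGenes)
      effect[affected] <- effectCfg$geneEffect
    }
    blockIdx <- which(geneAnnot$in_block)
    effect[blockIdx] <- effect[blockIdx] + effectCfg$blockEffect

    caseCol <- design$gdm == 1L
    sig <- matrix(mu, G, n)
    sig[, caseCol] <- sig[, caseCol] + effect
    if (length(blockIdx) && effectCfg$latentSd > 0) {
      lat <- rnorm(n, 0, effectCfg$latentSd)
      sig[blockIdx, ] <- sig[blockIdx, ] + rep(lat, each = length(blockIdx))
    }

    nProbes <- pmax(1L, rpois(G, effectCfg$probesPerGene))
    geneOf <- rep(seq_len(G), nProbes)
    P <- length(geneOf)
    affinity <- rnorm(P, 0, effectCfg$affinitySd)
    X <- sig[geneOf, , drop = FALSE] + affinity
    if (effectCfg$batchSd > 0) {
      lev <- unique(design$chip)
      f <- setNames(rnorm(length(lev), 0, effectCfg$batchSd), lev)
      X <- sweep(X, 2, f[design$chip], `+`)
    }
    if (effectCfg$noiseSd > 0) {
      X <- X + matrix(rnorm(P * n, 0, effectCfg$noiseSd), P, n)
    }
    probes <- 2^X + effectCfg$background
    probeIds <- sprintf("%s_p%02d", geneAnnot$gene_id[geneOf],
                        sequence(nProbes))
    dimnames(probes) <- list(probeIds, design$sample_id)

    list(probes = probes,
         probeMap = data.frame(probe_id = probeIds,
                               gene_id = geneAnnot$gene_id[geneOf]),
         truth = list(
           genes = data.frame(gene_id = geneAnnot$gene_id[affected],
                              effect = rep(effectCfg$geneEffect,
                                           length(affected))),
           blockGenes = geneAnnot$gene_id[blockIdx],
           blockEffect = effectCfg$blockEffect,
           baseline = setNames(mu, geneAnnot$gene_id)))
  })
}

#' Simulate pyrosequencing C/T read counts
#'
#' Cytosine counts are binomial with success probability equal to the true
#' methylation level, so `C/(C+T)` is an unbiased estimate of it.
#'
#' @param betaTruth numeric matrix (CpG x sample) of true methylation
#'   proportions in [0,1], or a vector (treated as one CpG).
#' @param depth read depth per CpG per sample (>= 10).
#' @param seed integer RNG seed.
#' @return list of integer matrices `C` and `T` with `C + T == depth`.
#' @export
generatePyroCounts <- function(betaTruth, depth, seed = 1) {
  if (is.null(dim(betaTruth))) betaTruth <- matrix(betaTruth, nrow = 1)
  stopifnot(all(betaTruth >= 0 & betaTruth <= 1))
  if (depth < 10) stop("depth must be >= 10")
  withSeed(seed, {
    C <- matrix(rbinom(length(betaTruth), depth, as.vector(betaTruth)),
                nrow(betaTruth), ncol(betaTruth),
                dimnames = dimnames(betaTruth))
    list(C = C, T = depth - C)
  })
}

#' Generate a synthetic term universe with planted structure
#'
#' Builds a rooted random DAG of ontology-like terms whose propagated
#' gene-set sizes span below, inside and above the 20-1500 size window,
#' plants clusters of near-duplicate terms (>= 90% gene overlap) to
#' exercise redundancy reduction, and draws a heterogeneous
#' probes-per-gene map (1-40) so the array-design bias corrected by the
#' resampling enrichment test is present and measurable.
#'
#' @param genes character vector of gene ids, or a single count (ids are
#'   then generated as G00001...).
#' @param nTerms number of non-root terms before duplication.
#' @param seed integer RNG seed.
#' @param nDupClusters planted near-duplicate clusters.
#' @param probeCountRange inclusive range of probes per gene.
#' @return list: `universe` (a \linkS4class{TermUniverse}),
#'   `probeCounts` (named integer per gene), `duplicateClusters` (list of
#'   term-id vectors).
#' @export
generateTermUniverse <- function(genes = 2500, nTerms = 40, seed = 1,
                                 nDupClusters = 3,
                                 probeCountRange = c(1, 40)) {
  if (is.numeric(genes) && length(genes) == 1) {
    genes <- sprintf("G%05d", seq_len(genes))
  }
  nG <- length(genes)
  assertPositiveCount(nTerms, "nTerms")
  if (nG < 50) stop("need at least 50 genes for a usable universe")
  withSeed(seed, {
    root <- "T000"
    ids <- sprintf("T%03d", seq_len(nTerms))
    # direct gene-set sizes spanning the 20-1500 filter window; the
    # smallest sizes go to the LAST terms, which have no children, so
    # their propagated sizes stay below the window
    smallN <- ceiling(nTerms / 5)
    midMax <- min(400L, floor(0.5 * nG))
    sizes <- pmin(nG - 1L,
                  round(exp(runif(nTerms, log(25), log(midMax)))))
    big <- if (nG > 1700) 2L else 0L
    if (big > 0) sizes[seq_len(big)] <-
        sample(1600:min(2200, nG - 10), big, replace = TRUE)
    sizes[(nTerms - smallN + 1L):nTerms] <- sample(5:15, smallN,
                                                   replace = TRUE)
    parents <- list()
    parents[[root]] <- character(0)
    annotation <- list()
    annotation[[root]] <- genes            # root annotates everything
    for (i in seq_len(nTerms)) {
      pool <- c(root, ids[seq_len(i - 1)])
      parents[[ids[i]]] <- sample(pool, min(length(pool),
                                            sample(1:2, 1)))
      annotation[[ids[i]]] <- sample(genes, sizes[i])
    }
    u0 <- termUniverse(parents, annotation)
    propSizes <- lengths(u0@termGenes)

    # near-duplicate clusters: each source term gets a child sharing
    # ~95% of its propagated genes, so the pair is both highly similar
    # by gene overlap and by Jiang-Conrath (child-parent MICA)
    midTerms <- ids[propSizes[ids] >= 30 & propSizes[ids] <= midMax]
    dupClusters <- list()
    for (k in seq_len(min(nDupClusters, length(midTerms)))) {
      src <- midTerms[k]
      dupId <- sprintf("%sdup", src)
      g <- u0@termGenes[[src]]
      swap <- max(1L, round(0.05 * length(g)))
      outside <- setdiff(genes, g)
      swap <- min(swap, length(outside))
      annotation[[dupId]] <- c(sample(g, length(g) - swap),
                               if (swap > 0) sample(outside, swap))
      parents[[dupId]] <- src
      dupClusters[[k]] <- c(src, dupId)
    }
    probeCounts <- pmin(probeCountRange[2],
                        probeCountRange[1] +
                          stats::rnbinom(nG, size = 0.8, mu = 6))
    names(probeCounts) <- genes
    list(universe = termUniverse(parents, annotation),
         probeCounts = probeCounts,
         duplicateClusters = dupClusters)
  })
}

#' Lay out array probes matching a probes-per-gene map
#'
#' Places `probeCounts[g]` CpG probes inside each gene body (so the
#' closest-gene assignment maps them back to that gene), producing a
#' minimal probe annotation for enrichment-resampling experiments where
#' the probe-density design bias must be controlled exactly.
#'
#' @param geneAnnot gene table from [generateGeneAnnotation()].
#' @param probeCounts named integer vector (genes; see
#'   [generateTermUniverse()]).
#' @param seed integer RNG seed.
#' @return probe annotation data.frame compatible with
#'   [assignClosestGene()].
#' @export
generateProbesForGenes <- function(geneAnnot, probeCounts, seed = 1) {
  counts <- probeCounts[geneAnnot$gene_id]
  counts[is.na(counts)] <- 1L
  withSeed(seed, {
    geneIdx <- rep(seq_len(nrow(geneAnnot)), counts)
    pos <- round(runif(length(geneIdx),
                       geneAnnot$start[geneIdx],
                       geneAnnot$end[geneIdx]))
    ann <- data.frame(
      probe_id = sprintf("cg%06d", seq_along(geneIdx)),
      chrom = geneAnnot$chrom[geneIdx],
      pos = pos,
      probe_type = "II",
      snp_at_target = FALSE,
      cross_hyb_x = FALSE,
      nearest_gene_id = geneAnnot$gene_id[geneIdx],
      distance_to_gene = 0,
      stringsAsFactors = FALSE)
    ann[order(match(ann$chrom, unique(geneAnnot$chrom)), ann$pos), ]
  })
}
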