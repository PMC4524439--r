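#' Default pipeline configuration
#'
#' All tunable parameters of the end-to-end synthetic-study run, with the
#' analysis defaults used throughout: site-level methylation alpha 0.001
#' and expression alpha 0.01; bump hunting at the 99th percentile of |t|
#' with a 500 bp gap; 10 kb CpG flank on the coordinated window; 5 kb/
#' 10 kb methylation cluster collapsing; GO size window 20-1500 with a
#' 0.7 Jiang-Conrath cutoff. Desk-scale problem sizes (probes, genes,
#' permutations, resamples) keep a full run in the minutes range.
#'
#' @param seed master seed; per-stage child seeds are derived from it so
#'   stages can be rerun independently.
#' @param ... overrides of any default (unknown names are an error).
#' @return named list of class `pipelineConfig`.
#' @export
pipelineConfig <- function(seed = 1, ...) {
  cfg <- list(
    seed = seed,
    n_pairs = 10,
    n_probes = 4000,
    n_genes = 400,
    n_terms = 40,
    chip_mixing = 0.5,
    # injected truth
    n_site_effects = 20, site_effect = 0.10,
    n_region_effects = 3, region_effect = 0.08, region_size = 5,
    n_block_meth_sites = 10, block_meth_effect = 0.05,
    n_gene_effects = 30, gene_effect = -0.5,
    block_expr_effect = -0.3,
    noise_sd = 0.15, batch_sd = 0.15,
    # window of coordinated regulation (synthetic MHC analogue)
    window_chrom = "chr5", window_start = 1e7, window_end = 1.5e7,
    n_block_genes = 15,
    # analysis thresholds
    alpha_meth = 0.001, alpha_expr = 0.01,
    bump_max_gap = 500, bump_quantile = 0.99, bump_min_probes = 2,
    window_flank = 10000, cluster_within = 5000, cluster_max_width = 10000,
    n_perm = 1000, n_resamples = 1000,
    go_min_genes = 20, go_max_genes = 1500, go_sim_cutoff = 0.7,
    surrogate_q = 0.05, k_max = NULL)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown config key(s): ",
                            paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  validatePipelineConfig(cfg)
  class(cfg) <- "pipelineConfig"
  cfg
}

#' @rdname pipelineConfig
#' @param cfg a configuration list.
#' @export
validatePipelineConfig <- function(cfg) {
  if (is.null(cfg$seed)) stop("config error: seed is mandatory")
  chk01 <- function(key) {
    v <- cfg[[key]]
    if (!is.numeric(v) || v <= 0 || v >= 1) {
      stop("config error: ", key, " must lie strictly in (0, 1)")
    }
  }
  for (k in c("alpha_meth", "alpha_expr", "bump_quantile",
              "surrogate_q", "go_sim_cutoff")) chk01(k)
  if (cfg$n_pairs < 3) stop("config error: n_pairs must be >= 3")
  if (cfg$n_perm < 100) stop("config error: n_perm must be >= 100")
  if (cfg$n_resamples < 100) stop("config error: n_resamples >= 100")
  invisible(TRUE)
}

#' Read a pipeline configuration from YAML
#'
#' Flat-key YAML with the same names as [pipelineConfig()]; `seed` is
#' mandatory in the file.
#'
#' @param path YAML file path.
#' @return validated `pipelineConfig`.
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$seed)) stop("config error: seed is mandatory in the file")
  do.call(pipelineConfig, y)
}

.writeTsv <- function(x, dir, name) {
  path <- file.path(dir, name)
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full synthetic-study pipeline
#'
#' Executes every stage in order — simulate cohort and arrays, preprocess
#' methylation and expression, estimate surrogates, site/gene association
#' models, bump hunting, window correlation network, GO enrichment, and
#' the recovery report against the truth ledger — writing each stage's
#' output as TSV (regions additionally as BED) into `outDir` together
#' with a structured log that echoes every parameter and the MD5 hash of
#' every file. Reruns with the same config are bit-identical.
#'
#' @param config a [pipelineConfig()].
#' @param outDir output directory (created if needed).
#' @return invisibly, a list with all in-memory stage results plus
#'   `files` (paths) and `hashes`.
#' @export
runPipeline <- function(config, outDir) {
  stopifnot(inherits(config, "pipelineConfig"))
  validatePipelineConfig(config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  log <- file.path(outDir, "run.log")
  cat("pipeline start\n", file = log)
  logLine <- function(...) cat(sprintf(...), "\n", sep = "", file = log,
                               append = TRUE)
  logLine("config: %s",
          paste(sprintf("%s=%s", names(config),
                        vapply(config, function(v)
                          paste(format(v), collapse = ","), "")),
                collapse = " "))
  files <- character(0)
  stage <- function(name, expr) {
    logLine("stage %s: start", name)
    out <- tryCatch(expr, error = function(e) {
      logLine("stage %s: FAILED: %s", name, conditionMessage(e))
      stop("pipeline halted at stage '", name, "': ",
           conditionMessage(e), call. = FALSE)
    })
    logLine("stage %s: done", name)
    out
  }
  window <- list(chrom = config$window_chrom, start = config$window_start,
                 end = config$window_end)

  # --- simulate ---------------------------------------------------------
  sim <- stage("simulate", {
    design <- generateCohort(config$n_pairs,
                             seed = childSeed(config$seed, "cohort"),
                             chipMixing = config$chip_mixing)
    geneAnnot <- generateGeneAnnotation(
      config$n_genes, seed = childSeed(config$seed, "annotation"),
      blockWindow = window, nBlockGenes = config$n_block_genes)
    annot <- generateProbeAnnotation(
      config$n_probes, seed = childSeed(config$seed, "annotation"),
      geneAnnot = geneAnnot)
    meth <- generateMethylation(
      design, annot,
      methEffectConfig(nSites = config$n_site_effects,
                       siteEffect = config$site_effect,
                       nRegions = config$n_region_effects,
                       regionEffect = config$region_effect,
                       regionSize = config$region_size,
                       blockWindow = window,
                       nBlockSites = config$n_block_meth_sites,
                       blockEffect = config$block_meth_effect,
                       noiseSd = config$noise_sd,
                       batchSd = config$batch_sd),
      seed = childSeed(config$seed, "methylation"))
    expr <- generateExpression(
      design, geneAnnot,
      exprEffectConfig(nGenes = config$n_gene_effects,
                       geneEffect = config$gene_effect,
                       blockEffect = config$block_expr_effect,
                       batchSd = config$batch_sd),
      seed = childSeed(config$seed, "expression"))
    terms <- generateTermUniverse(geneAnnot$gene_id,
                                  nTerms = config$n_terms,
                                  seed = childSeed(config$seed, "terms"))
    files <- c(files,
                .writeTsv(design, outDir, "covariates.tsv"),
                .writeTsv(annot, outDir, "probe_annotation.tsv"),
                .writeTsv(geneAnnot, outDir, "gene_annotation.tsv"),
                .writeTsv(meth$truth$sites, outDir, "truth_sites.tsv"),
                .writeTsv(meth$truth$regions, outDir, "truth_regions.tsv"),
                .writeTsv(expr$truth$genes, outDir, "truth_genes.tsv"))
    list(design = design, annot = annot, geneAnnot = geneAnnot,
         meth = meth, expr = expr, terms = terms)
  })

  # --- preprocess -------------------------------------------------------
  beta <- stage("preprocess_methylation",
                preprocessMethylation(sim$meth$intensities))
  exprMat <- stage("preprocess_expression",
                   preprocessExpression(sim$expr$probes, sim$expr$probeMap))
  files <- c(files,
             .writeTsv(data.frame(probe_id = rownames(getBeta(beta)),
                                  getBeta(beta), check.names = FALSE),
                       outDir, "beta_matrix.tsv"),
             .writeTsv(data.frame(gene_id = rownames(exprMat), exprMat,
                                  check.names = FALSE),
                       outDir, "expression_matrix.tsv"))

  # --- surrogates -------------------------------------------------------
  conf <- sim$design[, c("chip", "row", "column", "ethnicity")]
  primary <- sim$design[, c("gdm", "age", "bmi", "sex", "smoking")]
  sv <- stage("surrogates", suppressWarnings(
    estimateSurrogates(getBeta(beta), primary, conf,
                       kMax = config$k_max, qCut = config$surrogate_q,
                       seed = childSeed(config$seed, "surrogates"))))
  files <- c(files, .writeTsv(surrogateReport(sv), outDir,
                              "surrogate_report.tsv"))

  # --- association models -----------------------------------------------
  mf <- modelFrame(sim$design, sv)
  ewas <- stage("ewas", runEWAS(beta, mf, alpha = config$alpha_meth))
  twas <- stage("twas", runTWAS(exprMat, mf, geneAnnot = sim$geneAnnot,
                                codingOnly = TRUE,
                                alpha = config$alpha_expr))
  files <- c(files, .writeTsv(ewas, outDir, "ewas.tsv"),
             .writeTsv(twas, outDir, "twas.tsv"))

  # --- bump hunting ------------------------------------------------------
  bumps <- stage("bumps", findBumps(ewas, probeAnnotation(beta),
                                    maxGap = config$bump_max_gap,
                                    quantileCut = config$bump_quantile,
                                    minProbes = config$bump_min_probes))
  candidates <- rankCandidatesForValidation(bumps, ewas,
                                            probeAnnotation(beta))
  bumpDf <- as.data.frame(bumps)
  files <- c(files, .writeTsv(bumpDf, outDir, "bumps.tsv"),
             .writeTsv(candidates, outDir, "bump_candidates.tsv"))
  # BED export: 0-based half-open
  if (nrow(bumpDf)) {
    bed <- data.frame(chrom = bumpDf$seqnames, start = bumpDf$start - 1L,
                      end = bumpDf$end,
                      name = sprintf("DMR%03d", seq_len(nrow(bumpDf))),
                      score = round(bumpDf$max_abs_t, 3),
                      strand = ".")
    write.table(bed, file.path(outDir, "bumps.bed"), sep = "\t",
                quote = FALSE, row.names = FALSE, col.names = FALSE)
    files <- c(files, file.path(outDir, "bumps.bed"))
  }

  # --- window network ----------------------------------------------------
  net <- stage("network", {
    feats <- selectWindowFeatures(probeAnnotation(beta), sim$geneAnnot,
                                  window, flank = config$window_flank)
    betaW <- getBeta(beta)[intersect(rownames(getBeta(beta)), feats$cpgs),
                           , drop = FALSE]
    exprW <- exprMat[intersect(rownames(exprMat), feats$genes), ,
                     drop = FALSE]
    nets <- buildNetworks(betaW, exprW, nPerm = config$n_perm,
                          seed = childSeed(config$seed, "network"))
    pos <- probeAnnotation(beta)[rownames(betaW), "pos"]
    coll <- collapseClusters(betaW, pos,
                             within = config$cluster_within,
                             maxWidth = config$cluster_max_width)
    prof <- rbind(
      cbind(type = "methylation",
            groupDifferenceProfile(coll$values, sim$design$gdm)),
      cbind(type = "expression",
            groupDifferenceProfile(exprW, sim$design$gdm)))
    list(networks = nets, clusters = coll, profile = prof)
  })
  if (!is.null(net$networks$methExpr)) {
    files <- c(files, .writeTsv(net$networks$methExpr, outDir,
                                "network_meth_expr.tsv"))
  }
  if (!is.null(net$networks$exprExpr)) {
    files <- c(files, .writeTsv(net$networks$exprExpr, outDir,
                                "network_expr_expr.tsv"))
  }
  files <- c(files, .writeTsv(net$profile, outDir,
                              "window_difference_profile.tsv"))

  # --- enrichment --------------------------------------------------------
  enrich <- stage("enrichment", {
    reduced <- reduceTerms(sim$terms$universe,
                           minGenes = config$go_min_genes,
                           maxGenes = config$go_max_genes,
                           simCutoff = config$go_sim_cutoff)
    sigCpgs <- ewas$feature_id[ewas$p_value < config$alpha_meth]
    methGo <- if (length(sigCpgs)) {
      methylationEnrichment(sigCpgs, probeAnnotation(beta),
                            sim$geneAnnot, sim$terms$universe,
                            terms = reduced,
                            nResamples = config$n_resamples,
                            seed = childSeed(config$seed, "enrichment"))
    } else NULL
    sigGenes <- twas$feature_id[twas$p_value < config$alpha_expr]
    exprGo <- expressionEnrichment(sigGenes, rownames(exprMat),
                                   sim$terms$universe, terms = reduced)
    list(reduced = reduced, meth = methGo, expr = exprGo)
  })
  if (!is.null(enrich$meth)) {
    files <- c(files, .writeTsv(enrich$meth, outDir, "go_methylation.tsv"))
  }
  files <- c(files, .writeTsv(enrich$expr, outDir, "go_expression.tsv"))

  # --- recovery report ---------------------------------------------------
  recovery <- stage("report", recoveryReport(
    list(ewas = ewas, twas = twas, bumps = bumps,
         alpha_meth = config$alpha_meth, alpha_expr = config$alpha_expr),
    list(meth = sim$meth$truth, expr = sim$expr$truth)))
  files <- c(files, .writeTsv(recovery, outDir, "recovery_report.tsv"))

  hashes <- tools::md5sum(sort(unique(files)))
  logLine("hashes:")
  for (f in names(hashes)) logLine("  %s  %s", hashes[[f]], basename(f))
  logLine("pipeline complete")
  files <- c(files, log)

  invisible(list(sim = sim, beta = beta, expr = exprMat, surrogates = sv,
                 ewas = ewas, twas = twas, bumps = bumps,
                 candidates = candidates, network = net,
                 enrichment = enrich, recovery = recovery,
                 files = sort(unique(files)), hashes = hashes))
}

#' Recovery metrics against the truth ledger
#'
#' Sensitivity and empirical false-discovery proportion of each discovery
#' stage, counting a discovery as true only when it appears in the
#' injected-truth ledger. Defined (zero) for empty discovery sets.
#'
#' @param results list with `ewas`, `twas`, `bumps` and the alpha
#'   thresholds (as produced inside [runPipeline()]).
#' @param truth list with `meth` and `expr` truth ledgers.
#' @return data.frame: `stage`, `n_discoveries`, `true_positives`,
#'   `sensitivity`, `fdp`.
#' @export
recoveryReport <- function(results, truth) {
  if (is.null(truth$meth)) stop("truth ledger missing")
  metrow <- function(stage, disc, truthSet) {
    tp <- sum(disc %in% truthSet)
    data.frame(stage = stage, n_discoveries = length(disc),
               true_positives = tp,
               sensitivity = if (length(truthSet)) tp / length(truthSet)
                             else NA_real_,
               fdp = if (length(disc)) 1 - tp / length(disc) else 0)
  }
  sigCpg <- results$ewas$feature_id[
    results$ewas$p_value < results$alpha_meth]
  trueCpg <- c(truth$meth$sites$probe_id,
               unlist(strsplit(truth$meth$regions$probe_ids, ",")),
               truth$meth$blockSites$probe_id)
  sigGene <- results$twas$feature_id[
    results$twas$p_value < results$alpha_expr]
  trueGene <- c(truth$expr$genes$gene_id, truth$expr$blockGenes)

  bumpHit <- character(0)
  trueRegions <- truth$meth$regions
  if (length(results$bumps) && nrow(trueRegions)) {
    tr <- GenomicRanges::GRanges(trueRegions$chrom,
                                 IRanges::IRanges(trueRegions$start,
                                                  trueRegions$end))
    ov <- GenomicRanges::countOverlaps(tr, results$bumps)
    bumpHit <- which(ov > 0)
  }
  rbind(
    metrow("ewas_sites", sigCpg, trueCpg),
    metrow("twas_genes", sigGene, trueGene),
    data.frame(stage = "bump_regions",
               n_discoveries = length(results$bumps),
               true_positives = length(bumpHit),
               sensitivity = if (nrow(trueRegions))
                 length(bumpHit) / nrow(trueRegions) else NA_real_,
               fdp = NA_real_))
}
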