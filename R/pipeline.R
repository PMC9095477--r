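## Config-driven orchestration: scenario simulation (all inputs + truth),
## config validation, the end-to-end analysis (curation -> matching -> DE ->
## HAR/TE association -> loci enrichment), deterministic outputs with a
## hash manifest, and scoring of results against planted truth.

#' Derive a per-stage seed from the global seed
#'
#' Stable hash of the stage name folded into the global seed, so adding or
#' reordering stages does not reshuffle the randomness of the others. Result
#' is kept below 2^31.
#'
#' @param seed Global integer seed.
#' @param stage Stage name.
#' @return Integer seed.
#' @export
stageSeed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_len(nchar(stage))) %% 10000L
  as.integer((as.numeric(seed) * 10007 + h) %% 2147483647)
}

#' Default analysis configuration
#'
#' All thresholds default to the study's stated values: TPM > 0.1 in >= 10%
#' of samples, FDR < 0.05, HAR window 100 kb (1 kb sensitivity), TE upstream
#' window 2 kb, GWAS strata 1e-2..1e-7, clumping p < 1e-4 / r2 < 0.1 / 3 Mb,
#' loci r2 > 0.5 within 250 kb, 5000 permutations per enrichment round, and
#' 4000 noise-filter quantile bins.
#'
#' @param outDir Output directory for [runPipeline()].
#' @param seed Global seed.
#' @return Named list of settings.
#' @export
defaultConfig <- function(outDir = tempfile("norfscan_out"), seed = 1L) {
  list(
    tpm_min = 0.1, sample_frac = 0.10, q_threshold = 0.05,
    har_window = 100000, har_window_sensitivity = 1000,
    te_upstream = 2000, strata_bounds = 10^-(2:7),
    clump_index_p = 1e-4, clump_r2 = 0.1, clump_window = 3e6,
    locus_r2 = 0.5, locus_span = 250000,
    hwe_p_min = 1e-4, maf_min = 0.05,
    n_perm = 5000, noise_Q = 4000,
    mhc = NULL,                       # list(chrom, start, end) to enable
    float_sig = 6,
    seed = as.integer(seed), out_dir = outDir,
    paths = list()
  )
}

#' Validate a pipeline configuration
#'
#' Collects all problems (missing input files, thresholds out of range,
#' cross-field inconsistencies) instead of failing on the first.
#'
#' @param config List from [defaultConfig()] (possibly with `paths` filled).
#' @param requirePaths Require the input files to exist.
#' @return The config, invisibly, if valid; otherwise stops with the full
#'   error list.
#' @export
validateConfig <- function(config, requirePaths = length(config$paths) > 0) {
  errs <- character()
  chk <- function(cond, msg) if (!isTRUE(cond)) errs <<- c(errs, msg)
  chk(config$tpm_min >= 0, "tpm_min must be >= 0")
  chk(config$sample_frac >= 0 && config$sample_frac <= 1,
      "sample_frac must be in [0, 1]")
  chk(config$q_threshold > 0 && config$q_threshold <= 1,
      "q_threshold must be in (0, 1]")
  chk(config$har_window >= 0, "har_window must be >= 0")
  chk(config$te_upstream > 0, "te_upstream must be > 0")
  chk(!is.unsorted(rev(config$strata_bounds)),
      "strata_bounds must be descending")
  chk(config$n_perm >= 1, "n_perm must be >= 1")
  chk(config$noise_Q >= 1, "noise_Q must be >= 1")
  chk(config$clump_r2 >= 0 && config$clump_r2 <= 1, "clump_r2 must be in [0, 1]")
  chk(config$locus_r2 >= 0 && config$locus_r2 <= 1, "locus_r2 must be in [0, 1]")
  if (requirePaths) {
    for (p in names(config$paths))
      chk(file.exists(config$paths[[p]]),
          paste0("missing input path '", p, "': ", config$paths[[p]]))
  }
  if (length(errs))
    stop("invalid config:\n  - ", paste(errs, collapse = "\n  - "))
  invisible(config)
}

#' Serialize / restore a configuration or scenario description as JSON
#'
#' @param config Configuration list.
#' @param path JSON file path.
#' @return `writeConfig` returns `path` invisibly; `readConfig` the list.
#' @export
writeConfig <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname writeConfig
#' @export
readConfig <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg$strata_bounds <- as.numeric(cfg$strata_bounds)
  cfg
}

#' Simulate a complete analysis scenario with planted truth
#'
#' Drives every generator in dependency order from one global seed:
#' annotation, nORFs, Ribo-seq counts with planted noise strata,
#' case-control counts with planted DE, HAR/TE features with planted
#' co-locations, and a GWAS panel whose causal loci are planted around a
#' subset of HAR-associated nORFs (so the pHAR target family is genuinely
#' enriched and a decoy family is not).
#'
#' @param seed Global integer seed.
#' @param nGenes,nNorfs,nSamples,nHars,nTes,nSnps Scenario sizes (defaults
#'   give a desk-scale but structurally complete scenario).
#' @param deFraction Planted DE fraction per case group.
#' @param ... Passed through to [generateCaseControlCounts()].
#' @return Named list with every generated object plus a `truth` list.
#' @export
simulateScenario <- function(seed, nGenes = 80, nNorfs = 60,
                             nSamples = c(cnt = 20, caseA = 15, caseB = 15),
                             nHars = 80, nTes = 100, nSnps = 1500,
                             deFraction = 0.15, ...) {
  annotation <- generateAnnotation(stageSeed(seed, "annotation"), nGenes = nGenes)
  norfs <- generateNorfs(stageSeed(seed, "norfs"), annotation, nNorfs = nNorfs)
  ids <- norfIds(norfs)
  set.seed(stageSeed(seed, "noise_plan"))
  noise_plan <- stats::setNames(
    sample(c(0.5, 2.0), length(ids), replace = TRUE, prob = c(0.75, 0.25)), ids)
  ribo <- generateRiboseqCounts(stageSeed(seed, "riboseq"), ids,
                                noisePlan = noise_plan)
  cc <- generateCaseControlCounts(stageSeed(seed, "case_control"), annotation,
                                  nCnt = nSamples[[1]], nCaseA = nSamples[[2]],
                                  nCaseB = nSamples[[3]],
                                  deFraction = deFraction, ...)
  md <- mcols(norfs@exons)
  ## plant co-locations among nORFs that will survive curation (hosted in
  ## non-coding transcripts and planted low-noise), mirroring the study
  ## where HAR/TE/locus association is assessed on the curated database
  all_sp <- featureSpans(norfs)
  clen <- .SYN_CHROMS[as.character(seqnames(all_sp))]
  away_from_edge <- start(all_sp) > 3e4 & end(all_sp) < clen - 3e4
  hosted <- ids[md$planted_kind == "hosted" & noise_plan[ids] < 1 &
                  away_from_edge]
  set.seed(stageSeed(seed, "feature_pick"))
  ## two planted HAR families: a pHAR family whose nORFs sit inside the
  ## planted causal loci, and a vHAR decoy family whose nORFs do not
  n_fam <- min(8, floor(length(hosted) / 2))
  har_targets_p <- sample(hosted, n_fam)
  har_targets_v <- sample(setdiff(hosted, har_targets_p), n_fam)
  har_targets <- c(har_targets_p, har_targets_v)
  te_targets <- sample(hosted, min(8, length(hosted)))
  feats <- generateFeatures(stageSeed(seed, "features"), norfs,
                            nHars = nHars, nTes = nTes,
                            plantedHarPairs = har_targets,
                            plantedTePairs = te_targets,
                            plantedHarGroups = rep(c("pHAR", "vHAR"),
                                                   c(n_fam, n_fam)))
  causal_norfs <- har_targets_p
  sp <- featureSpans(norfs)[causal_norfs]
  causal <- reduce(GRanges(seqnames(sp),
                           IRanges(pmax(1, start(sp) - 10000), end(sp) + 10000)),
                   ignore.strand = TRUE)
  gwas <- generateGwas(stageSeed(seed, "gwas"), nSnps = nSnps,
                       causalLoci = causal)
  list(
    seed = seed,
    annotation = annotation, norfs = norfs,
    riboseq = ribo$counts, case_counts = cc$counts,
    hars = feats$hars, tes = feats$tes,
    snps = gwas$snps, r2 = gwas$r2,
    truth = list(noise = ribo$truth, de = cc$truth,
                 har_pairs = feats$truth$har_pairs,
                 te_pairs = feats$truth$te_pairs,
                 causal_loci = causal, causal_norfs = causal_norfs,
                 causal_snps = gwas$truth)
  )
}

#' Write a simulated scenario to disk as plain-text files
#'
#' GTF annotation, BED12 nORFs (with category column), Ribo-seq and
#' case-control count TSVs, sample metadata TSV, HAR/TE BEDs with their
#' extra columns, SNP and sparse-r2 TSVs, and the truth tables.
#'
#' @param scenario List from [simulateScenario()].
#' @param dir Output directory (created).
#' @return Named character vector of written paths, invisibly.
#' @export
writeScenario <- function(scenario, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  writeGtf(scenario$annotation, p("annotation.gtf"))
  writeNorfBed(scenario$norfs, p("norfs.bed"))
  writeExpressionTsv(scenario$riboseq, p("riboseq_counts.tsv"))
  writeTsv(data.frame(orf_id = rownames(scenario$riboseq),
                      is_canonical = rowData(scenario$riboseq)$is_canonical),
           p("riboseq_canonical.tsv"))
  writeExpressionTsv(scenario$case_counts, p("case_counts.tsv"))
  writeTsv(as.data.frame(colData(scenario$case_counts)), p("sample_metadata.tsv"))
  writeFeatureBed(scenario$hars, p("hars.bed"))
  writeFeatureBed(scenario$tes, p("tes.bed"))
  writeTsv(scenario$snps, p("snps.tsv"))
  writeTsv(scenario$r2, p("ld_r2.tsv"))
  writeTsv(scenario$truth$noise, p("truth_noise.tsv"))
  writeTsv(scenario$truth$de, p("truth_de.tsv"))
  writeTsv(scenario$truth$har_pairs, p("truth_har_pairs.tsv"))
  writeTsv(scenario$truth$te_pairs, p("truth_te_pairs.tsv"))
  writeTsv(data.frame(norf_id = scenario$truth$causal_norfs),
           p("truth_causal_norfs.tsv"))
  files <- list.files(dir, full.names = TRUE)
  invisible(stats::setNames(files, basename(files)))
}

#' Read a scenario directory back into memory
#'
#' @param dir Directory written by [writeScenario()].
#' @return List shaped like [simulateScenario()] output (without truth
#'   unless present).
#' @export
readScenario <- function(dir) {
  p <- function(f) file.path(dir, f)
  canon <- readTsv(p("riboseq_canonical.tsv"))
  meta <- readTsv(p("sample_metadata.tsv"))
  ribo <- readExpressionTsv(p("riboseq_counts.tsv"), unit = "count")
  rowData(ribo)$is_canonical <- canon$is_canonical[match(rownames(ribo), canon$orf_id)]
  out <- list(
    annotation = readGtf(p("annotation.gtf")),
    norfs = readNorfBed(p("norfs.bed")),
    riboseq = ribo,
    case_counts = readExpressionTsv(p("case_counts.tsv"), unit = "count",
                                    colData = meta),
    hars = readFeatureBed(p("hars.bed"),
                          extraCols = c(source = "character", group = "character")),
    tes = readFeatureBed(p("tes.bed"),
                         extraCols = c(family = "character",
                                       te_class = "character",
                                       clade = "character")),
    snps = readTsv(p("snps.tsv")),
    r2 = readTsv(p("ld_r2.tsv"))
  )
  tf <- p("truth_de.tsv")
  if (file.exists(tf)) {
    out$truth <- list(
      noise = readTsv(p("truth_noise.tsv")),
      de = readTsv(tf),
      har_pairs = readTsv(p("truth_har_pairs.tsv")),
      te_pairs = readTsv(p("truth_te_pairs.tsv")),
      causal_norfs = readTsv(p("truth_causal_norfs.tsv"))$norf_id)
  }
  out
}

.sig <- function(df, digits) {
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], signif, digits = digits)
  df
}

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order on an in-memory scenario (or a
#' scenario directory named in `config$paths$scenario_dir`): nORF curation
#' (TPM conversion, low-noise filter, frame classification, in-frame
#' removal, deduplication), transcript matching (expression filter, PAR
#' removal, containment/intron-chain matching), differential expression
#' (TMM, log-CPM, mixed models per case group, BH, DE nORFs, Fisher check,
#' sex QC), HAR/TE association (unique HARs, windowed and upstream
#' association, DE designation, correlation screen), and loci enrichment
#' (QC, stratification, clumping, MHC collapse, locus definition, two-round
#' permutation enrichment of the nORF-HAR families). Writes deterministic
#' TSV outputs plus a manifest of md5 hashes.
#'
#' @param config List from [defaultConfig()], validated.
#' @param scenario Optional in-memory scenario (from [simulateScenario()] or
#'   [readScenario()]); otherwise read from `config$paths$scenario_dir`.
#' @return List of all stage results plus `manifest` (`data.frame`: file,
#'   md5).
#' @export
runPipeline <- function(config = defaultConfig(), scenario = NULL) {
  validateConfig(config, requirePaths = is.null(scenario))
  if (is.null(scenario)) scenario <- readScenario(config$paths$scenario_dir)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- list()

  ## --- nORF curation -------------------------------------------------------
  ribo_tpm <- countsToTpm(scenario$riboseq)
  is_canon <- rowData(scenario$riboseq)$is_canonical
  ## Effective bin count: the configured Q, but never so many bins that the
  ## canonical baseline becomes empty — keep ~20 ORFs per bin at desk scale.
  q_eff <- max(1L, min(config$noise_Q, floor(nrow(ribo_tpm) / 20)))
  noise <- lowNoiseFilter(ribo_tpm, is_canon, Q = q_eff)
  low_ids <- noise$orf_id[!is.na(noise$low_noise) & noise$low_noise]
  covered <- norfIds(scenario$norfs) %in% noise$orf_id[!is_canon]
  keep_noise <- !covered | norfIds(scenario$norfs) %in% low_ids
  norfs <- scenario$norfs[which(keep_noise)]
  norfs <- classifyNorfFrame(norfs, scenario$annotation)
  norfs <- applyInframeRemoval(norfs)
  norfs <- deduplicateNorfs(norfs)
  out$noise_filter <- noise
  out$curated_norfs <- norfs

  ## --- transcript matching -------------------------------------------------
  tx <- removeParFeatures(scenario$annotation)
  tx_tpm <- countsToTpm(scenario$case_counts)
  retained <- expressionFilter(tx_tpm, tpmMin = config$tpm_min,
                               sampleFrac = config$sample_frac)
  matches <- matchNorfs(norfs, tx, retained)
  out$retained_transcripts <- retained
  out$matches <- matches
  expressed_norfs <- unique(matches$norf_id)

  ## --- differential expression --------------------------------------------
  counts <- scenario$case_counts
  meta <- as.data.frame(colData(counts))
  factors <- tmmFactors(counts)
  lcpm <- logCpm(counts, factors)
  conds <- setdiff(unique(meta$diagnosis), "CNT")
  de <- list()
  for (g in conds) {
    sel <- meta$diagnosis %in% c("CNT", g)
    sub <- OrfExperiment(assay(lcpm)[, sel, drop = FALSE],
                         colData = meta[sel, , drop = FALSE], unit = "logCPM")
    d <- meta[sel, , drop = FALSE]
    d$diagnosis <- factor(d$diagnosis, levels = c("CNT", g))
    de[[g]] <- fitMixedModels(sub, ~ diagnosis + age,
                              coef = paste0("diagnosis", g),
                              group = d$individual_id, data = d)
  }
  den <- deNorfs(de, matches, qThreshold = config$q_threshold)
  ## Fisher sanity check: DE status vs nORF presence over retained transcripts
  fisher <- lapply(de, function(d) {
    de_tx <- d$transcript_id[!is.na(d$q) & d$q < config$q_threshold]
    has_norf <- d$transcript_id %in% matches$transcript_id
    is_de <- d$transcript_id %in% de_tx
    a <- sum(is_de & has_norf); b <- sum(is_de & !has_norf)
    cc <- sum(!is_de & has_norf); dd <- sum(!is_de & !has_norf)
    if (any(c(a + b, cc + dd, a + cc, b + dd) == 0)) {
      list(odds_ratio = NA_real_, p = NA_real_)
    } else fisherEnrichment(a, b, cc, dd)
  })
  ychr <- grep("^txY", rownames(lcpm), value = TRUE)
  sexqc <- if (length(ychr) && "sex" %in% colnames(meta)) {
    sexQc(lcpm, chrYFeatureIds = ychr, xistId = "XIST", sex = meta$sex)
  } else NULL
  out$tmm <- factors; out$de <- de; out$de_norfs <- den
  out$fisher <- fisher; out$sex_qc <- sexqc

  ## --- HAR / TE association ------------------------------------------------
  uhars <- buildUniqueHars(scenario$hars)
  expressed <- norfs[which(norfIds(norfs) %in% expressed_norfs)]
  har_assoc <- associateNorfHar(expressed, uhars, window = config$har_window)
  te_assoc <- associateNorfTe(expressed, scenario$tes,
                              upstreamWindow = config$te_upstream)
  de_tx_ids <- unique(unlist(lapply(de, function(d)
    d$transcript_id[!is.na(d$q) & d$q < config$q_threshold])))
  de_tx <- scenario$annotation[which(txIds(scenario$annotation) %in% de_tx_ids)]
  uhars_de <- designateDeFeatures(uhars, de_tx)
  tes_de <- designateDeFeatures(scenario$tes, de_tx)
  ## correlation screen: DE nORF x associated DE TE, expression inherited
  ## from the matched / containing DE transcript's log-CPM
  de_norf_ids <- unique(den$norfs$norf_id)
  cand <- te_assoc[te_assoc$norf_id %in% de_norf_ids &
                     te_assoc$feature_id %in%
                       names(tes_de)[mcols(tes_de)$de], , drop = FALSE]
  correlations <- NULL
  if (nrow(cand)) {
    tx_span <- featureSpans(scenario$annotation)[de_tx_ids]
    norf_tx <- vapply(cand$norf_id, function(nf) {
      hit <- matches$transcript_id[matches$norf_id == nf]
      hit <- intersect(hit, de_tx_ids)
      if (length(hit)) sort(hit)[1] else NA_character_
    }, "")
    te_tx <- vapply(cand$feature_id, function(te) {
      g <- scenario$tes[te]
      ov <- which(intervalsOverlap(rep(g, length(tx_span)), tx_span))
      if (length(ov)) sort(names(tx_span)[ov])[1] else NA_character_
    }, "")
    ok <- !is.na(norf_tx) & !is.na(te_tx)
    if (any(ok)) {
      cand <- cand[ok, , drop = FALSE]
      em <- assay(lcpm)[unique(c(norf_tx[ok], te_tx[ok])), , drop = FALSE]
      comb <- rbind(
        `rownames<-`(assay(lcpm)[norf_tx[ok], , drop = FALSE],
                     paste0("n:", cand$norf_id)),
        `rownames<-`(assay(lcpm)[te_tx[ok], , drop = FALSE],
                     paste0("t:", cand$feature_id)))
      pr <- data.frame(norf_id = paste0("n:", cand$norf_id),
                       te_id = paste0("t:", cand$feature_id),
                       stringsAsFactors = FALSE)
      pr <- unique(pr)
      correlations <- correlatePairs(OrfExperiment(comb, unit = "logCPM"), pr)
      correlations$norf_id <- sub("^n:", "", correlations$norf_id)
      correlations$te_id <- sub("^t:", "", correlations$te_id)
    }
  }
  out$unique_hars <- uhars_de; out$tes <- tes_de
  out$har_assoc <- har_assoc; out$te_assoc <- te_assoc
  out$correlations <- correlations

  ## --- loci enrichment -----------------------------------------------------
  snps <- snpQc(scenario$snps, hwePMin = config$hwe_p_min,
                mafMin = config$maf_min)
  strata <- stratifySnps(snps, bounds = config$strata_bounds)
  loci_list <- list()
  for (st in names(strata)) {
    ss <- strata[[st]]
    if (!nrow(ss)) next
    clumps <- ldClump(ss, scenario$r2, indexPMax = config$clump_index_p,
                      r2Min = config$clump_r2, window = config$clump_window)
    if (!is.null(config$mhc))
      clumps <- mhcCollapse(clumps, config$mhc$chrom, config$mhc$start,
                            config$mhc$end)
    if (!nrow(clumps)) next
    idx <- clumps[clumps$is_index, c("rsid", "chrom", "pos")]
    colnames(idx) <- c("rsid", "chrom", "pos")
    loci_list[[st]] <- defineLoci(idx, snps, scenario$r2,
                                  r2Locus = config$locus_r2,
                                  span = config$locus_span)
  }
  enrichment <- NULL
  if (length(loci_list) && nrow(har_assoc)) {
    ref_sp <- featureSpans(expressed)
    har_norf_ids <- unique(har_assoc$norf_id)
    grp_of <- mcols(uhars)$group_set
    sets <- list(all = featureSpans(expressed)[har_norf_ids])
    for (g in c("vHAR", "mHAR", "pHAR")) {
      in_g <- har_assoc$feature_id %in%
        names(uhars)[grepl(g, grp_of, fixed = TRUE)]
      ids_g <- unique(har_assoc$norf_id[in_g])
      if (length(ids_g)) sets[[g]] <- featureSpans(expressed)[ids_g]
    }
    enrichment <- enrichLociFamily(sets, ref_sp, loci_list,
                                   nPerm = config$n_perm,
                                   seed = stageSeed(config$seed, "enrichment"))
  }
  out$loci <- loci_list
  out$enrichment <- enrichment

  ## --- outputs + manifest --------------------------------------------------
  o <- function(f) file.path(config$out_dir, f)
  writeTsv(.sig(as.data.frame(noise), config$float_sig), o("noise_filter.tsv"))
  writeNorfBed(norfs, o("curated_norfs.bed"))
  writeTsv(matches, o("matches.tsv"))
  for (g in names(de))
    writeTsv(.sig(de[[g]], config$float_sig), o(paste0("de_", g, ".tsv")))
  writeTsv(den$summary, o("de_summary.tsv"))
  writeTsv(den$norfs, o("de_norfs.tsv"))
  writeFeatureBed(uhars_de, o("unique_hars.bed"))
  writeTsv(.sig(har_assoc, config$float_sig), o("har_associations.tsv"))
  writeTsv(.sig(te_assoc, config$float_sig), o("te_associations.tsv"))
  if (!is.null(correlations))
    writeTsv(.sig(correlations, config$float_sig), o("correlations.tsv"))
  if (!is.null(enrichment))
    writeTsv(.sig(enrichment, config$float_sig), o("enrichment.tsv"))
  files <- list.files(config$out_dir, full.names = TRUE)
  out$manifest <- data.frame(file = basename(files),
                             md5 = unname(tools::md5sum(files)),
                             stringsAsFactors = FALSE)
  writeTsv(out$manifest, o("manifest.tsv"))
  out
}

#' Score pipeline results against planted truth
#'
#' Computes recall / empirical FDR of the planted DE transcripts and DE
#' nORFs, recall of planted nORF-HAR and nORF-TE pairs, and sensitivity /
#' specificity of the low-noise filter.
#'
#' @param results List from [runPipeline()].
#' @param truth Truth list from [simulateScenario()].
#' @param matches Optional match table (defaults to `results$matches`).
#' @return Named list of scores.
#' @export
scorePipeline <- function(results, truth, matches = results$matches) {
  scores <- list()
  ## DE transcripts per condition
  for (g in names(results$de)) {
    d <- results$de[[g]]
    called <- d$transcript_id[!is.na(d$q) & d$q < 0.05]
    planted <- truth$de$transcript_id[truth$de$condition == g]
    planted <- intersect(planted, d$transcript_id)
    scores[[paste0("de_recall_", g)]] <-
      if (length(planted)) mean(planted %in% called) else NA
    scores[[paste0("de_fdr_", g)]] <-
      if (length(called)) mean(!(called %in% truth$de$transcript_id)) else 0
  }
  ## noise filter
  nf <- results$noise_filter
  tr <- truth$noise
  got <- nf$low_noise[match(tr$orf_id, nf$orf_id)]
  scores$noise_sensitivity <- mean(got[tr$low_noise], na.rm = TRUE)
  scores$noise_specificity <- mean(!got[!tr$low_noise], na.rm = TRUE)
  ## planted association pairs (only those whose nORF survived curation
  ## and matching can be recovered)
  seen <- unique(matches$norf_id)
  hp <- truth$har_pairs[truth$har_pairs$placed &
                          truth$har_pairs$norf_id %in% seen, , drop = FALSE]
  scores$har_pair_recall <- if (nrow(hp)) {
    mean(vapply(seq_len(nrow(hp)), function(i)
      any(results$har_assoc$norf_id == hp$norf_id[i]), TRUE))
  } else NA
  tp <- truth$te_pairs[truth$te_pairs$placed &
                         truth$te_pairs$norf_id %in% seen, , drop = FALSE]
  scores$te_pair_recall <- if (nrow(tp)) {
    mean(vapply(seq_len(nrow(tp)), function(i)
      any(results$te_assoc$norf_id == tp$norf_id[i] &
            results$te_assoc$feature_id == tp$feature_id[i]), TRUE))
  } else NA
  scores
}
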