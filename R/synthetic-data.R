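## Synthetic inputs with planted ground truth. The generators emulate the
## statistical structure of the study's real inputs (consortium brain
## RNA-seq, Ribo-seq ORF abundance tables, multi-source HAR compilations,
## RepeatMasker TEs, GWAS summary statistics with block LD) on three
## synthetic chromosomes: chrS1/chrS2 for autosomal features and chrSY for
## male-only features used by the sex QC. Every generator is a pure function
## of (seed, parameters): identical seeds give identical outputs.

.SYN_CHROMS <- c(chrS1 = 5e6, chrS2 = 5e6, chrSY = 4e5)

.TE_FAMILIES <- data.frame(
  family = c("L1MC2", "L2a", "MIRb", "MIR3", "AluJo", "MER65A", "MER90a", "L1PA3"),
  te_class = c("LINE", "LINE", "SINE", "SINE", "SINE", "LTR", "LTR", "LINE"),
  clade = c("Eutheria", "Theria", "Mammalia", "Mammalia", "Primates",
            "Primates", "Eutheria", "Primates"),
  stringsAsFactors = FALSE)

.HAR_SOURCES <- paste0("harset", 1:7)

## Map a spliced interval [from, to] (1-based, translation order) back to a
## genomic exon sub-chain, on plain start/end vectors (sorted ascending).
## Returns a two-column matrix of genomic (start, end), sorted.
.splicedToGenomicV <- function(es, ee, strand, from, to) {
  w <- ee - es + 1L
  if (strand == "-") {
    ord <- rev(seq_along(es)); starts <- ee[ord]; dir <- -1L
  } else {
    ord <- seq_along(es); starts <- es[ord]; dir <- 1L
  }
  before <- cumsum(w[ord]) - w[ord]
  out <- matrix(integer(0), ncol = 2)
  for (k in seq_along(ord)) {
    lo <- max(from, before[k] + 1L); hi <- min(to, before[k] + w[ord][k])
    if (lo > hi) next
    g1 <- starts[k] + dir * (lo - before[k] - 1L)
    g2 <- starts[k] + dir * (hi - before[k] - 1L)
    out <- rbind(out, c(min(g1, g2), max(g1, g2)))
  }
  out[order(out[, 1]), , drop = FALSE]
}

.splicedToGenomic <- function(exons, strand, from, to) {
  m <- .splicedToGenomicV(start(exons), end(exons), strand, from, to)
  GRanges(as.character(seqnames(exons))[1], IRanges(m[, 1], m[, 2]),
          strand = strand)
}

#' Generate a synthetic transcript annotation
#'
#' Places non-overlapping single-transcript genes on two autosomal synthetic
#' chromosomes (chrS1, chrS2), with the biotype mix of brain transcriptome
#' assemblies (protein-coding, retained intron, processed transcript,
#' lincRNA, antisense). Protein-coding transcripts carry a CDS occupying
#' most of their spliced length. When `sexFeatures = TRUE`, three male-only
#' genes are placed on chrSY and an XIST-like lincRNA on chrS1, for the
#' sex-metadata QC.
#'
#' @param seed Integer seed.
#' @param nGenes Number of autosomal genes (>= 1).
#' @param exonsPerGene Range (min, max) of exon counts.
#' @param biotypeMix Named probability vector over biotypes.
#' @param chromLengths Named lengths of the synthetic chromosomes.
#' @param sexFeatures Add chrSY genes and XIST.
#' @return A [TranscriptSet] with seqlengths set.
#' @export
generateAnnotation <- function(seed, nGenes = 60, exonsPerGene = c(1, 4),
                               biotypeMix = c(protein_coding = 0.4,
                                              retained_intron = 0.2,
                                              processed_transcript = 0.15,
                                              lincRNA = 0.15,
                                              antisense = 0.1),
                               chromLengths = .SYN_CHROMS,
                               sexFeatures = TRUE) {
  stopifnot(nGenes >= 1, abs(sum(biotypeMix) - 1) < 1e-8)
  set.seed(seed)
  autosomes <- setdiff(names(chromLengths), "chrSY")
  chrom_of <- rep_len(autosomes, nGenes)
  ## plain-vector accumulators; GRanges built once at the end
  acc <- list(ch = character(), s = integer(), e = integer(),
              st = character(), tx = character())
  cac <- acc
  add <- function(a, ch, s, e, st, tx) {
    list(ch = c(a$ch, rep(ch, length(s))), s = c(a$s, s), e = c(a$e, e),
         st = c(a$st, rep(st, length(s))), tx = c(a$tx, rep(tx, length(s))))
  }
  gene <- character(); bt <- character()
  slot_of <- split(seq_len(nGenes), chrom_of)
  for (ch in autosomes) {
    ids <- slot_of[[ch]]
    slot_w <- floor(chromLengths[[ch]] / length(ids))
    if (slot_w < 6000)
      stop("infeasible packing: ", length(ids), " genes on ", ch,
           " (slot width ", slot_w, " < 6000)")
    for (k in seq_along(ids)) {
      i <- ids[k]
      n_ex <- sample(seq(exonsPerGene[1], exonsPerGene[2]), 1)
      ex_w <- sample(100:300, n_ex, replace = TRUE)
      in_w <- if (n_ex > 1) sample(200:800, n_ex - 1, replace = TRUE) else integer()
      span <- sum(ex_w) + sum(in_w)
      offset <- sample.int(max(1L, slot_w - span - 200L), 1)
      gstart <- (k - 1L) * slot_w + offset
      starts <- gstart + cumsum(c(0L, ex_w[-n_ex] + in_w))
      strand <- sample(c("+", "-"), 1)
      id <- sprintf("tx%03d", i)
      biotype <- sample(names(biotypeMix), 1, prob = biotypeMix)
      acc <- add(acc, ch, starts, starts + ex_w - 1L, strand, id)
      gene[id] <- sprintf("gene%03d", i)
      bt[id] <- biotype
      if (biotype == "protein_coding") {
        L <- sum(ex_w)
        cds_len <- 3L * max(10L, floor((L - 60L) / 3L))
        cds_from <- sample(1:30, 1)
        m <- .splicedToGenomicV(starts, starts + ex_w - 1L, strand, cds_from,
                                min(L, cds_from + cds_len - 1L))
        cac <- add(cac, ch, m[, 1], m[, 2], strand, id)
      }
    }
  }
  if (sexFeatures) {
    ylen <- chromLengths[["chrSY"]]
    for (j in 1:3) {
      gstart <- floor(ylen * j / 4)
      id <- sprintf("txY%02d", j)
      acc <- add(acc, "chrSY", gstart, gstart + 399L, "+", id)
      cac <- add(cac, "chrSY", gstart + 3L, gstart + 302L, "+", id)
      gene[id] <- sprintf("geneY%02d", j); bt[id] <- "protein_coding"
    }
    xs <- chromLengths[["chrS1"]] - 5000
    acc <- add(acc, "chrS1", xs, xs + 1199L, "+", "XIST")
    gene["XIST"] <- "XIST"; bt["XIST"] <- "lincRNA"
  }
  gr <- GRanges(acc$ch, IRanges(acc$s, acc$e), strand = acc$st)
  exl <- GenomicRanges::split(gr, factor(acc$tx, levels = unique(acc$tx)))
  mcols(exl) <- DataFrame(gene_id = unname(gene[names(exl)]),
                          biotype = unname(bt[names(exl)]))
  exl <- .setSeqLengths(exl, chromLengths)
  cgr <- GRanges(cac$ch, IRanges(cac$s, cac$e), strand = cac$st)
  cdsl <- GenomicRanges::split(cgr, factor(cac$tx, levels = unique(cac$tx)))
  TranscriptSet(exl, cds = cdsl)
}

.setSeqLengths <- function(grl, chromLengths) {
  sl <- GenomeInfoDb::Seqinfo(seqnames = names(chromLengths),
                              seqlengths = unname(as.integer(chromLengths)))
  suppressWarnings(GenomeInfoDb::seqinfo(grl) <-
    GenomeInfoDb::merge(GenomeInfoDb::seqinfo(grl), sl))
  grl
}

#' Generate synthetic nORFs hosted in (and between) annotated transcripts
#'
#' Three kinds of nORFs are planted, with the mix controlled by `mix`:
#' `hosted` nORFs are spliced sub-chains of non-protein-coding transcripts
#' (guaranteed containment with shared junctions, so the matching stage can
#' recover them); `cds` nORFs sit inside the CDS of protein-coding
#' transcripts, half in frame and half frame-shifted; `intergenic` nORFs
#' fall between genes. Category labels are drawn from [orfCategories()]
#' (in-frame nORFs get a mix of exception and non-exception categories so
#' the removal rule has work to do).
#'
#' @param seed Integer seed.
#' @param transcripts A [TranscriptSet] from [generateAnnotation()].
#' @param nNorfs Total nORF count.
#' @param mix Named proportions over `hosted`, `cds`, `intergenic`.
#' @return A [NorfSet]; `mcols()` carry the planting truth (`planted_kind`,
#'   `host_transcript`, `planted_frame`).
#' @export
generateNorfs <- function(seed, transcripts, nNorfs = 40,
                          mix = c(hosted = 0.6, cds = 0.25, intergenic = 0.15)) {
  set.seed(seed)
  stopifnot(abs(sum(mix) - 1) < 1e-8)
  bt <- txBiotype(transcripts)
  hosts <- names(bt)[!(bt %in% "protein_coding") & !grepl("^txY|^XIST", names(bt))]
  coding <- intersect(names(transcripts@cds), names(bt)[!grepl("^txY", names(bt))])
  n_hosted <- round(nNorfs * mix[["hosted"]])
  n_cds <- round(nNorfs * mix[["cds"]])
  n_inter <- nNorfs - n_hosted - n_cds
  exc <- .chainsOf(transcripts@exons)
  cdc <- .chainsOf(transcripts@cds)
  acc <- list(ch = character(), s = integer(), e = integer(),
              st = character(), id = character())
  add <- function(a, ch, m, st, id) {
    list(ch = c(a$ch, rep(ch, nrow(m))), s = c(a$s, m[, 1]),
         e = c(a$e, m[, 2]), st = c(a$st, rep(st, nrow(m))),
         id = c(a$id, rep(id, nrow(m))))
  }
  kind <- character(); host <- character(); frame <- character()
  mk_id <- function(i) sprintf("norf%03d", i)
  i <- 0L
  for (k in seq_len(n_hosted)) {
    i <- i + 1L
    tx <- sample(hosts, 1)
    ti <- match(tx, names(transcripts@exons))
    es <- exc$s[[ti]]; ee <- exc$e[[ti]]
    L <- sum(ee - es + 1L)
    len <- 3L * sample(10:max(11, floor((L - 6) / 3)), 1)
    len <- min(len, L - 3L)
    from <- sample.int(max(1L, L - len), 1)
    m <- .splicedToGenomicV(es, ee, exc$strand[ti], from, from + len - 1L)
    acc <- add(acc, exc$chrom[ti], m, exc$strand[ti], mk_id(i))
    kind[mk_id(i)] <- "hosted"; host[mk_id(i)] <- tx; frame[mk_id(i)] <- NA
  }
  for (k in seq_len(n_cds)) {
    i <- i + 1L
    tx <- sample(coding, 1)
    ti <- match(tx, names(transcripts@cds))
    cs <- cdc$s[[ti]]; ce <- cdc$e[[ti]]
    Lc <- sum(ce - cs + 1L)
    in_frame <- k %% 2L == 1L
    len <- 3L * sample(8:max(9, floor(Lc / 6)), 1)
    len <- min(len, Lc - 6L)
    max_cod <- max(0L, floor((Lc - len - 1L) / 3L))
    from <- 1L + 3L * sample.int(max_cod + 1L, 1) - 3L   # codon-aligned
    if (!in_frame) from <- from + 1L
    m <- .splicedToGenomicV(cs, ce, cdc$strand[ti], from, from + len - 1L)
    acc <- add(acc, cdc$chrom[ti], m, cdc$strand[ti], mk_id(i))
    kind[mk_id(i)] <- "cds"; host[mk_id(i)] <- tx
    frame[mk_id(i)] <- if (in_frame) "in_frame_cds" else "alt_frame_cds"
  }
  spans <- unlist(range(transcripts@exons), use.names = FALSE)
  span_tab <- lapply(stats::setNames(c("chrS1", "chrS2"), c("chrS1", "chrS2")),
                     function(ch) {
                       s <- spans[as.character(seqnames(spans)) == ch]
                       cbind(start(s), end(s))
                     })
  for (k in seq_len(n_inter)) {
    i <- i + 1L
    repeat {
      ch <- sample(c("chrS1", "chrS2"), 1)
      pos <- sample.int(4.5e6, 1) + 1e4
      w <- 3L * sample(15:60, 1)
      f <- span_tab[[ch]]
      if (!any(pos <= f[, 2] & pos + w - 1L >= f[, 1])) {
        acc <- add(acc, ch, cbind(pos, pos + w - 1L),
                   sample(c("+", "-"), 1), mk_id(i))
        break
      }
    }
    kind[mk_id(i)] <- "intergenic"; host[mk_id(i)] <- NA; frame[mk_id(i)] <- NA
  }
  gr <- GRanges(acc$ch, IRanges(acc$s, acc$e), strand = acc$st)
  exl <- GenomicRanges::split(gr, factor(acc$id, levels = unique(acc$id)))
  ids <- names(exl)
  categories <- ifelse(kind[ids] == "cds",
                       sample(c("uORF", "truncated", "internal", "polycistronic",
                                "readthrough", "extended"),
                              length(ids), replace = TRUE),
                       sample(c("non_coding", "external", "uORF"),
                              length(ids), replace = TRUE))
  mcols(exl) <- DataFrame(category = categories,
                          frame_class = NA_character_,
                          planted_kind = unname(kind[ids]),
                          host_transcript = unname(host[ids]),
                          planted_frame = unname(frame[ids]))
  NorfSet(exl)
}

#' Generate Ribo-seq ORF counts with planted noise strata
#'
#' Canonical and non-canonical ORFs share the same grid of mean abundances,
#' so mean-quantile bins contain both classes. Sample counts are the mean
#' plus multiplicative noise scaled by a per-ORF SD multiplier: canonical
#' ORFs have multiplier 1; nORFs take the multipliers of `noisePlan`
#' (default: half 0.5 = planted low-noise, half 2.0 = planted high-noise).
#' A multiplier of 0 gives exactly constant counts.
#'
#' @param seed Integer seed.
#' @param norfIds Character ids for the non-canonical ORFs.
#' @param nCorfs Number of canonical ORFs.
#' @param nSamples Number of samples (>= 2).
#' @param noisePlan Named numeric SD multipliers for `norfIds`; default
#'   alternating 0.5 / 2.0.
#' @param baseCv Coefficient of variation at multiplier 1 (default 0.3).
#' @param orfLength Common ORF length in bases (kept constant so TPM
#'   conversion preserves the planted mean matching).
#' @return List: `counts` (an [OrfExperiment], unit count, with
#'   `rowData()$is_canonical` and lengths), `truth` (`data.frame` with
#'   `orf_id`, `multiplier`, `low_noise`).
#' @export
generateRiboseqCounts <- function(seed, norfIds, nCorfs = 200, nSamples = 50,
                                  noisePlan = NULL, baseCv = 0.3,
                                  orfLength = 300) {
  if (nSamples < 2) stop("nSamples must be >= 2 (SD undefined otherwise)")
  set.seed(seed)
  if (is.null(noisePlan))
    noisePlan <- stats::setNames(rep(c(0.5, 2.0), length.out = length(norfIds)),
                                 norfIds)
  stopifnot(all(norfIds %in% names(noisePlan)))
  corf_ids <- sprintf("corf%03d", seq_len(nCorfs))
  ids <- c(corf_ids, norfIds)
  grid <- 2^seq(log2(20), log2(2000), length.out = 25)
  mu <- stats::setNames(grid[(seq_along(ids) - 1L) %% length(grid) + 1L], ids)
  mult <- c(stats::setNames(rep(1, nCorfs), corf_ids), noisePlan[norfIds])
  z <- matrix(stats::rnorm(length(ids) * nSamples), length(ids), nSamples)
  m <- round(mu + mult * baseCv * mu * z)
  m[m < 0] <- 0
  dimnames(m) <- list(ids, sprintf("rs%02d", seq_len(nSamples)))
  oe <- OrfExperiment(m, lengths = orfLength, unit = "count")
  rowData(oe)$is_canonical <- ids %in% corf_ids
  truth <- data.frame(orf_id = norfIds, multiplier = unname(noisePlan[norfIds]),
                      low_noise = unname(noisePlan[norfIds]) < 1,
                      stringsAsFactors = FALSE)
  list(counts = oe, truth = truth)
}

#' Generate case-control RNA-seq counts with planted differential expression
#'
#' Counts are negative binomial on a log link:
#' `count ~ NB(mu = exp(baseline + diagnosis lfc log 2 + covariates +
#' individual intercept), size = 1/dispersion)`. Some individuals contribute
#' two samples, giving the random intercept signal to exploit. Diagnosis has
#' three levels (CNT and two case groups, by default labelled SCZ and BD);
#' each case group gets its own planted DE transcript set (the two sets may
#' overlap). chrSY transcripts are expressed only in males and the XIST-like
#' transcript only in females.
#'
#' @param seed Integer seed.
#' @param transcripts A [TranscriptSet] from [generateAnnotation()].
#' @param nCnt,nCaseA,nCaseB Samples per diagnosis group.
#' @param caseLabels Labels for the two case groups.
#' @param deFraction Fraction of autosomal transcripts DE per case group.
#' @param lfcRange Magnitude range of planted log2 fold changes (positive
#'   width required when `deFraction > 0`).
#' @param nbDispersion NB dispersion (default 0.2; 0 = Poisson).
#' @param interceptSd SD of the per-individual log-scale intercept (0.3).
#' @param covariateSpec Named list of covariate effects on the log scale,
#'   e.g. `list(age = 0.005)`; covariate values are simulated per individual.
#' @param resampleFrac Fraction of individuals contributing two samples.
#' @return List: `counts` ([OrfExperiment], unit count, with transcript
#'   lengths and full sample metadata in `colData()`), `truth`
#'   (`data.frame`: `transcript_id`, `condition`, `lfc`).
#' @export
generateCaseControlCounts <- function(seed, transcripts, nCnt = 20,
                                      nCaseA = 15, nCaseB = 15,
                                      caseLabels = c("SCZ", "BD"),
                                      deFraction = 0.15,
                                      lfcRange = c(0.8, 2),
                                      nbDispersion = 0.2,
                                      interceptSd = 0.3,
                                      covariateSpec = list(age = 0.005),
                                      resampleFrac = 0.25) {
  stopifnot(deFraction >= 0, deFraction <= 1)
  if (deFraction > 0 && diff(range(lfcRange)) <= 0 && lfcRange[1] == 0)
    stop("zero-width lfcRange at 0 with deFraction > 0")
  set.seed(seed)
  ids <- txIds(transcripts)
  sexless <- ids[!grepl("^txY", ids) & ids != "XIST"]
  n_samp <- c(CNT = nCnt, stats::setNames(c(nCaseA, nCaseB), caseLabels))
  diagnosis <- rep(names(n_samp), n_samp)
  n <- length(diagnosis)
  ## individuals: a fraction contribute two samples, within diagnosis
  ind <- integer(n); next_id <- 0L
  for (g in names(n_samp)) {
    rows <- which(diagnosis == g)
    n_pairs <- floor(length(rows) * resampleFrac / 2)
    lab <- c(rep(seq_len(n_pairs), each = 2),
             n_pairs + seq_len(length(rows) - 2 * n_pairs))
    ind[rows] <- next_id + lab
    next_id <- max(ind)
  }
  individual_id <- sprintf("ind%03d", ind)
  u_ind <- unique(individual_id)
  sex_of <- stats::setNames(sample(c("M", "F"), length(u_ind), replace = TRUE),
                            u_ind)
  age_of <- stats::setNames(round(stats::rnorm(length(u_ind), 55, 10)), u_ind)
  b_of <- stats::setNames(stats::rnorm(length(u_ind), 0, interceptSd), u_ind)
  meta <- data.frame(
    sample_id = sprintf("s%03d", seq_len(n)),
    diagnosis = diagnosis, individual_id = individual_id,
    sex = unname(sex_of[individual_id]),
    age = unname(age_of[individual_id]),
    stringsAsFactors = FALSE)
  ## planted DE sets
  truth <- list()
  lfc <- matrix(0, length(ids), 2,
                dimnames = list(ids, caseLabels))
  for (g in caseLabels) {
    n_de <- round(deFraction * length(sexless))
    de_tx <- sample(sexless, n_de)
    if (n_de > 0) {
      mag <- stats::runif(n_de, lfcRange[1], lfcRange[2])
      sgn <- sample(c(-1, 1), n_de, replace = TRUE)
      lfc[de_tx, g] <- mag * sgn
      truth[[g]] <- data.frame(transcript_id = de_tx, condition = g,
                               lfc = mag * sgn, stringsAsFactors = FALSE)
    }
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(transcript_id = character(), condition = character(),
               lfc = numeric(), stringsAsFactors = FALSE)
  rownames(truth) <- NULL
  base <- stats::setNames(2^stats::runif(length(ids), 4, 9), ids)
  eta <- matrix(log(base), length(ids), n, dimnames = list(ids, meta$sample_id))
  for (g in caseLabels)
    eta[, diagnosis == g] <- eta[, diagnosis == g] + log(2) * lfc[, g]
  for (cv in names(covariateSpec))
    eta <- eta + matrix(covariateSpec[[cv]] * meta[[cv]], length(ids), n,
                        byrow = TRUE)
  eta <- eta + matrix(b_of[individual_id], length(ids), n, byrow = TRUE)
  ## sex-linked expression
  is_y <- grepl("^txY", ids)
  female <- meta$sex == "F"
  mu <- exp(eta)
  mu[is_y, female] <- 0
  if ("XIST" %in% ids) mu["XIST", !female] <- 0.01
  counts <- matrix(0L, length(ids), n, dimnames = dimnames(mu))
  pos <- mu > 0
  counts[pos] <- if (nbDispersion > 0) {
    stats::rnbinom(sum(pos), size = 1 / nbDispersion, mu = mu[pos])
  } else stats::rpois(sum(pos), mu[pos])
  lens <- sum(width(transcripts@exons))[ids]
  oe <- OrfExperiment(counts, colData = meta, lengths = unname(lens),
                      unit = "count")
  list(counts = oe, truth = truth)
}

#' Generate HAR and TE interval sets with planted nORF co-locations
#'
#' Planted HARs are placed within the +/- `harWindow` association window of
#' their nORF (some overlapping it); planted TEs inside the 2 kb upstream
#' window of theirs, never overlapping the nORF span. Decoy features are
#' placed well outside every nORF's window so association recall/specificity
#' can be scored exactly. HARs carry a source (seven synthetic compilation
#' labels) and a conservation group drawn from `harGroupMix`; TEs carry
#' family/class/clade from a RepeatMasker-style vocabulary. Planted pairs
#' whose window is infeasible (nORF at a contig edge) are skipped with a
#' warning and recorded in the truth table with `placed = FALSE`.
#'
#' @param seed Integer seed.
#' @param norfs A [NorfSet] (with seqlengths available on its exons, as
#'   produced by the generators here).
#' @param nHars,nTes Total feature counts (planted + decoys).
#' @param plantedHarPairs,plantedTePairs Character vectors of nORF ids to
#'   receive a planted HAR / TE (must exist in `norfs`).
#' @param plantedHarGroups Optional conservation group per planted HAR
#'   (recycled along `plantedHarPairs`); default drawn from `harGroupMix`.
#' @param harGroupMix Probabilities over vHAR/mHAR/pHAR (defaults follow the
#'   published unique-HAR composition 45.4/11.0/43.6%).
#' @param harWindow Association window emulated (default 100 kb).
#' @param chromLengths Chromosome lengths (default the synthetic genome).
#' @return List: `hars` (`GRanges` + `source`, `group`), `tes` (`GRanges` +
#'   `family`, `te_class`, `clade`), `truth` (list of two `data.frame`s,
#'   `har_pairs` and `te_pairs`, with `norf_id`, `feature_id`, `placed`).
#' @export
generateFeatures <- function(seed, norfs, nHars = 60, nTes = 80,
                             plantedHarPairs = character(),
                             plantedTePairs = character(),
                             plantedHarGroups = NULL,
                             harGroupMix = c(vHAR = 0.454, mHAR = 0.110,
                                             pHAR = 0.436),
                             harWindow = 100000,
                             chromLengths = .SYN_CHROMS) {
  set.seed(seed)
  stopifnot(all(plantedHarPairs %in% norfIds(norfs)),
            all(plantedTePairs %in% norfIds(norfs)))
  sp <- featureSpans(norfs)
  autosomes <- setdiff(names(chromLengths), "chrSY")
  ## forbidden zones for decoys: nORF spans +/- (window + margin)
  margin <- 20000
  forb_har <- reduce(GRanges(seqnames(sp),
                             IRanges(pmax(1, start(sp) - harWindow - margin),
                                     end(sp) + harWindow + margin)),
                     ignore.strand = TRUE)
  forb_te <- reduce(GRanges(seqnames(sp),
                            IRanges(pmax(1, start(sp) - 3000),
                                    end(sp) + 3000)),
                    ignore.strand = TRUE)
  .forb_tab <- function(forbidden) {
    lapply(stats::setNames(autosomes, autosomes), function(ch) {
      f <- forbidden[as.character(seqnames(forbidden)) == ch]
      cbind(start(f), end(f))
    })
  }
  .decoy_pos_factory <- function(forbidden) {
    tab <- .forb_tab(forbidden)
    function(w) {
      repeat {
        ch <- sample(autosomes, 1)
        pos <- sample.int(chromLengths[[ch]] - w - 1L, 1)
        f <- tab[[ch]]
        if (!nrow(f) || !any(pos <= f[, 2] & pos + w - 1L >= f[, 1]))
          return(GRanges(ch, IRanges(pos, width = w)))
      }
    }
  }
  ## HARs
  har_rows <- list(); truth_har <- list()
  hid <- 0L
  for (nf in plantedHarPairs) {
    hid <- hid + 1L
    s <- sp[nf]
    w <- sample(150:600, 1)
    side <- sample(c("left", "right", "overlap"), 1)
    cand <- switch(side,
      overlap = GRanges(seqnames(s), IRanges(start(s) + 1L, width = w)),
      left = {
        gap <- sample.int(harWindow, 1) - 1L
        st <- start(s) - gap - w
        if (st < 1) NULL else GRanges(seqnames(s), IRanges(st, width = w))
      },
      right = GRanges(seqnames(s), IRanges(end(s) + sample.int(harWindow, 1),
                                           width = w)))
    if (is.null(cand) || end(cand) > chromLengths[[as.character(seqnames(s))]]) {
      warning("planted HAR for ", nf, " infeasible; skipped")
      truth_har[[length(truth_har) + 1L]] <-
        data.frame(norf_id = nf, feature_id = NA, placed = FALSE)
      next
    }
    har_rows[[sprintf("har%03d", hid)]] <- cand
    truth_har[[length(truth_har) + 1L]] <-
      data.frame(norf_id = nf, feature_id = sprintf("har%03d", hid),
                 placed = TRUE)
  }
  decoy_har <- .decoy_pos_factory(forb_har)
  while (hid < nHars) {
    hid <- hid + 1L
    har_rows[[sprintf("har%03d", hid)]] <- decoy_har(sample(150:600, 1))
  }
  hars <- unlist(GRangesList(har_rows))
  mcols(hars)$source <- sample(.HAR_SOURCES, length(hars), replace = TRUE)
  grp <- sample(names(harGroupMix), length(hars), replace = TRUE,
                prob = harGroupMix)
  if (!is.null(plantedHarGroups) && length(truth_har)) {
    planted_df <- do.call(rbind, truth_har)
    want <- rep_len(plantedHarGroups, length(plantedHarPairs))
    ids <- planted_df$feature_id[planted_df$placed]
    grp[match(ids, names(hars))] <- want[planted_df$placed]
  }
  mcols(hars)$group <- grp
  ## TEs
  te_rows <- list(); truth_te <- list()
  tid <- 0L
  for (nf in plantedTePairs) {
    tid <- tid + 1L
    s <- sp[nf]
    w <- sample(80:300, 1)
    minus <- as.character(strand(s)) == "-"
    win_lo <- if (minus) end(s) + 1L else start(s) - 2000L
    win_hi <- if (minus) end(s) + 2000L else start(s) - 1L
    ok <- win_lo >= 1 && (win_hi - win_lo + 1L) >= w &&
      win_hi <= chromLengths[[as.character(seqnames(s))]]
    if (!ok) {
      warning("planted TE for ", nf, " infeasible; skipped")
      truth_te[[length(truth_te) + 1L]] <-
        data.frame(norf_id = nf, feature_id = NA, placed = FALSE)
      next
    }
    st <- win_lo + sample.int(win_hi - win_lo - w + 2L, 1) - 1L
    te_rows[[sprintf("te%03d", tid)]] <- GRanges(seqnames(s), IRanges(st, width = w))
    truth_te[[length(truth_te) + 1L]] <-
      data.frame(norf_id = nf, feature_id = sprintf("te%03d", tid),
                 placed = TRUE)
  }
  decoy_te <- .decoy_pos_factory(forb_te)
  while (tid < nTes) {
    tid <- tid + 1L
    te_rows[[sprintf("te%03d", tid)]] <- decoy_te(sample(80:300, 1))
  }
  tes <- unlist(GRangesList(te_rows))
  fam <- .TE_FAMILIES[sample.int(nrow(.TE_FAMILIES), length(tes), replace = TRUE), ]
  mcols(tes)$family <- fam$family
  mcols(tes)$te_class <- fam$te_class
  mcols(tes)$clade <- fam$clade
  bind <- function(x) if (length(x)) do.call(rbind, x) else
    data.frame(norf_id = character(), feature_id = character(),
               placed = logical())
  list(hars = hars, tes = tes,
       truth = list(har_pairs = bind(truth_har), te_pairs = bind(truth_te)))
}

#' Generate a GWAS summary-statistic panel with block LD
#'
#' SNPs are laid out along the autosomal synthetic chromosomes in LD blocks
#' of `blockSize` consecutive SNPs: within a block pairwise r2 is high
#' (0.6-0.95), between blocks r2 is absent (0). Association p-values are
#' uniform except inside the supplied causal loci, where small p-values are
#' planted (10^-U(4.5, 8.5)). MAF and HWE columns include a fraction of
#' QC-failing SNPs.
#'
#' @param seed Integer seed.
#' @param nSnps Total SNP count.
#' @param blockSize SNPs per LD block (>= 1; 1 gives no off-diagonal r2).
#' @param causalLoci `GRanges` of planted causal loci (may be empty); must
#'   lie within the SNP span.
#' @param chromLengths Chromosome lengths.
#' @param qcFailFrac Fraction of SNPs given failing MAF or HWE values.
#' @return List: `snps` (`data.frame`: `rsid`, `chrom`, `pos`, `p`, `maf`,
#'   `hwe_p`, `block`), `r2` (sparse `data.frame`: `rsid_a`, `rsid_b`,
#'   `r2`), `truth` (`data.frame` of causal SNPs).
#' @export
generateGwas <- function(seed, nSnps = 1000, blockSize = 8,
                         causalLoci = GRanges(),
                         chromLengths = .SYN_CHROMS,
                         qcFailFrac = 0.05) {
  stopifnot(blockSize >= 1)
  set.seed(seed)
  autosomes <- setdiff(names(chromLengths), "chrSY")
  per <- ceiling(nSnps / length(autosomes))
  rows <- list()
  for (ch in autosomes) {
    k <- min(per, nSnps - sum(vapply(rows, nrow, 0L)))
    if (k <= 0) break
    pos <- sort(sample.int(chromLengths[[ch]] - 2e4, k) + 1e4)
    rows[[ch]] <- data.frame(chrom = ch, pos = pos, stringsAsFactors = FALSE)
  }
  snps <- do.call(rbind, rows)
  rownames(snps) <- NULL
  snps$rsid <- sprintf("rs%05d", seq_len(nrow(snps)))
  snps$block <- paste0(snps$chrom, "_b",
                       ceiling(stats::ave(seq_along(snps$pos), snps$chrom,
                                          FUN = seq_along) / blockSize))
  if (length(causalLoci)) {
    span <- range(GRanges(snps$chrom, IRanges(snps$pos, width = 1)))
    inside <- IRanges::overlapsAny(causalLoci, span, ignore.strand = TRUE)
    if (!all(inside)) stop("causal locus outside the SNP span")
  }
  snps$p <- stats::runif(nrow(snps))
  causal <- rep(FALSE, nrow(snps))
  if (length(causalLoci)) {
    sgr <- GRanges(snps$chrom, IRanges(snps$pos, width = 1))
    causal <- IRanges::overlapsAny(sgr, causalLoci, ignore.strand = TRUE)
    snps$p[causal] <- 10^-stats::runif(sum(causal), 4.5, 8.5)
  }
  snps$maf <- stats::runif(nrow(snps), 0.05, 0.5)
  snps$hwe_p <- stats::runif(nrow(snps), 0.001, 1)
  fail <- sample.int(nrow(snps), round(qcFailFrac * nrow(snps)))
  half <- fail[seq_len(floor(length(fail) / 2))]
  snps$maf[half] <- stats::runif(length(half), 0.001, 0.049)
  rest <- setdiff(fail, half)
  snps$hwe_p[rest] <- stats::runif(length(rest), 0, 0.9e-4)
  ## sparse r2: all within-block pairs
  r2_rows <- lapply(split(snps$rsid, snps$block), function(ids) {
    if (length(ids) < 2) return(NULL)
    pr <- t(utils::combn(ids, 2))
    data.frame(rsid_a = pr[, 1], rsid_b = pr[, 2],
               r2 = stats::runif(nrow(pr), 0.6, 0.95),
               stringsAsFactors = FALSE)
  })
  r2 <- do.call(rbind, r2_rows)
  if (is.null(r2)) r2 <- data.frame(rsid_a = character(), rsid_b = character(),
                                    r2 = numeric(), stringsAsFactors = FALSE)
  rownames(r2) <- NULL
  truth <- data.frame(rsid = snps$rsid[causal], chrom = snps$chrom[causal],
                      pos = snps$pos[causal], stringsAsFactors = FALSE)
  snps <- snps[c("rsid", "chrom", "pos", "p", "maf", "hwe_p", "block")]
  list(snps = snps, r2 = r2, truth = truth)
}
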