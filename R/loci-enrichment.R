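## Disorder-associated SNP loci from GWAS summary statistics: QC,
## p-value stratification, greedy LD clumping, MHC collapse, locus
## definition, and the two-round permutation enrichment of nORF target sets
## within loci.

#' Quality-control filter for GWAS SNPs
#'
#' Removes SNPs out of Hardy-Weinberg equilibrium (HWE p strictly below
#' `hwePMin`) or with minor allele frequency strictly below `mafMin`.
#'
#' @param snps `data.frame` with columns `rsid`, `chrom`, `pos`, `p`, `maf`,
#'   `hwe_p`.
#' @param hwePMin HWE p-value threshold (default 1e-4).
#' @param mafMin MAF threshold (default 0.05).
#' @return The filtered `data.frame`.
#' @export
snpQc <- function(snps, hwePMin = 0.0001, mafMin = 0.05) {
  stopifnot(all(c("rsid", "chrom", "pos", "p", "maf", "hwe_p") %in% colnames(snps)))
  snps[!(snps$hwe_p < hwePMin | snps$maf < mafMin), , drop = FALSE]
}

#' Stratify SNPs by association p-value
#'
#' Returns one SNP subset per upper bound (`p` strictly below the bound);
#' subsets are nested: every SNP in the `1e-3` stratum is also in the `1e-2`
#' stratum.
#'
#' @param snps SNP `data.frame` (see [snpQc()]).
#' @param bounds Descending vector of p-value upper bounds.
#' @return Named list of `data.frame`s, one per bound.
#' @export
stratifySnps <- function(snps, bounds = 10^-(2:7)) {
  stopifnot(!is.unsorted(rev(bounds)))
  out <- lapply(bounds, function(b) snps[snps$p < b, , drop = FALSE])
  names(out) <- formatC(bounds, format = "e", digits = 0)
  out
}

## r2 lookup table: environment keyed on "rsidA|rsidB" with sorted ids.
.r2Lookup <- function(r2) {
  stopifnot(all(c("rsid_a", "rsid_b", "r2") %in% colnames(r2)))
  key <- ifelse(r2$rsid_a < r2$rsid_b,
                paste(r2$rsid_a, r2$rsid_b, sep = "|"),
                paste(r2$rsid_b, r2$rsid_a, sep = "|"))
  dup <- duplicated(key)
  if (any(dup)) {
    first <- match(key[dup], key)
    if (any(abs(r2$r2[dup] - r2$r2[first]) > 1e-9))
      stop("asymmetric r2 entries")
  }
  env <- new.env(hash = TRUE, size = length(key))
  for (i in which(!dup)) assign(key[i], r2$r2[i], envir = env)
  function(a, b) {
    k <- ifelse(a < b, paste(a, b, sep = "|"), paste(b, a, sep = "|"))
    vapply(k, function(kk) {
      v <- mget(kk, envir = env, ifnotfound = list(0))[[1]]
      as.numeric(v)
    }, 0, USE.NAMES = FALSE)
  }
}

#' Greedy LD clumping of GWAS SNPs
#'
#' SNPs are processed in ascending association p (ties broken by position,
#' then rsid). An unassigned SNP with `p < indexPMax` becomes an index SNP;
#' all still-unassigned SNPs on the same chromosome within `window` bases
#' and with `r2 >= r2Min` against the index join its clump. Missing r2
#' entries are treated as 0, so the resulting index SNPs are pairwise in low
#' LD (`r2 < r2Min`) or far apart.
#'
#' @param snps SNP `data.frame` (see [snpQc()]), typically QC-filtered.
#' @param r2 Sparse LD table: `data.frame` with `rsid_a`, `rsid_b`, `r2`
#'   (symmetric where both directions are present; asymmetry is an error).
#' @param indexPMax Maximum p for a SNP to seed a clump (default 1e-4).
#' @param r2Min Minimum r2 to join a clump (default 0.1).
#' @param window Clump window in bases (default 3 Mb).
#' @return `data.frame` with one row per clumped SNP: `clump`, `index_rsid`,
#'   `rsid`, `chrom`, `pos`, `p`, `is_index`.
#' @export
ldClump <- function(snps, r2, indexPMax = 1e-4, r2Min = 0.1, window = 3e6) {
  lk <- .r2Lookup(r2)
  ord <- order(snps$p, snps$pos, snps$rsid)
  s <- snps[ord, , drop = FALSE]
  n <- nrow(s)
  assigned <- rep(NA_integer_, n)
  index_of <- integer(0)
  clump <- 0L
  for (i in seq_len(n)) {
    if (!is.na(assigned[i])) next
    if (s$p[i] >= indexPMax) next
    clump <- clump + 1L
    assigned[i] <- clump
    index_of[clump] <- i
    cand <- which(is.na(assigned) & s$chrom == s$chrom[i] &
                    abs(s$pos - s$pos[i]) <= window)
    if (length(cand)) {
      r2v <- lk(s$rsid[cand], rep(s$rsid[i], length(cand)))
      assigned[cand[r2v >= r2Min]] <- clump
    }
  }
  keep <- which(!is.na(assigned))
  if (!length(keep))
    return(data.frame(clump = integer(), index_rsid = character(),
                      rsid = character(), chrom = character(),
                      pos = numeric(), p = numeric(), is_index = logical(),
                      stringsAsFactors = FALSE))
  cl <- assigned[keep]
  data.frame(
    clump = cl,
    index_rsid = s$rsid[index_of[cl]],
    rsid = s$rsid[keep], chrom = s$chrom[keep], pos = s$pos[keep],
    p = s$p[keep], is_index = keep == index_of[cl],
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Collapse MHC clumps to the most median index SNP
#'
#' Among clumps whose index SNP lies inside the MHC interval, only the clump
#' whose index position is the median is kept (lower median on even counts);
#' the extreme LD of the region otherwise floods the locus list. The default
#' interval is the hg19 MHC, chr6:28,477,797-33,448,354.
#'
#' @param clumps Clump table from [ldClump()].
#' @param mhcChrom,mhcStart,mhcEnd MHC interval (1-based inclusive).
#' @return The filtered clump table.
#' @export
mhcCollapse <- function(clumps, mhcChrom = "chr6",
                        mhcStart = 28477797, mhcEnd = 33448354) {
  idx <- clumps[clumps$is_index, , drop = FALSE]
  inm <- normalizeChrom(idx$chrom) == normalizeChrom(mhcChrom) &
    idx$pos >= mhcStart & idx$pos <= mhcEnd
  if (sum(inm) <= 1L) return(clumps)
  pos <- sort(idx$pos[inm])
  keep_pos <- pos[ceiling(length(pos) / 2)]   # lower median on even counts
  drop_clumps <- idx$clump[inm & idx$pos != keep_pos]
  clumps[!(clumps$clump %in% drop_clumps), , drop = FALSE]
}

#' Define disorder-associated loci around index SNPs
#'
#' A locus spans the index SNP and every SNP with `r2 > r2Locus` (strict)
#' within `span` bases of it, on the index chromosome. An index with no
#' linked SNP yields a single-base locus.
#'
#' @param indexSnps `data.frame` of index SNPs (`rsid`, `chrom`, `pos`).
#' @param snps Full SNP table to draw linked SNPs from.
#' @param r2 Sparse LD table (as in [ldClump()]).
#' @param r2Locus Strict lower r2 bound (default 0.5).
#' @param span Maximum distance from the index (default 250 kb).
#' @return `GRanges` of loci with `mcols()`: `index_rsid`, `n_snps`.
#' @export
defineLoci <- function(indexSnps, snps, r2, r2Locus = 0.5, span = 250000) {
  lk <- .r2Lookup(r2)
  rows <- lapply(seq_len(nrow(indexSnps)), function(i) {
    rs <- indexSnps$rsid[i]
    cand <- snps[snps$chrom == indexSnps$chrom[i] &
                   abs(snps$pos - indexSnps$pos[i]) <= span &
                   snps$rsid != rs, , drop = FALSE]
    linked <- if (nrow(cand)) {
      cand[lk(cand$rsid, rep(rs, nrow(cand))) > r2Locus, , drop = FALSE]
    } else cand
    pos <- c(indexSnps$pos[i], linked$pos)
    data.frame(chrom = indexSnps$chrom[i], start = min(pos), end = max(pos),
               index_rsid = rs, n_snps = length(pos),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  gr <- GRanges(normalizeChrom(df$chrom), IRanges(df$start, df$end))
  mcols(gr)$index_rsid <- df$index_rsid
  mcols(gr)$n_snps <- df$n_snps
  names(gr) <- df$index_rsid
  gr
}

## ---------------------------------------------------------------------------
## Permutation enrichment
## ---------------------------------------------------------------------------

## Round-1 engine: null distribution of the locus-overlap statistic for one
## target set, given a precomputed reference-by-locus membership matrix.
.nullStats <- function(membership, nTarget, nPerm) {
  nRef <- nrow(membership)
  vapply(seq_len(nPerm), function(r) {
    rows <- sample.int(nRef, nTarget)
    sum(colSums(membership[rows, , drop = FALSE]) > 0)
  }, 0L)
}

#' Permutation enrichment of nORF target sets within loci
#'
#' Overlapping target nORFs and overlapping reference nORFs are merged
#' first. The statistic is the number of loci overlapping at least one
#' merged target. Round 1 draws `nPerm` random same-size subsets of the
#' merged reference (uniform, without replacement) and reports the empirical
#' p-value `(1 + #{T* >= T}) / (1 + nPerm)`. When several target sets are
#' tested as a family (see [enrichLociFamily()]), a second round of `nPerm`
#' replicates builds the null distribution of the minimum empirical p across
#' the family, giving multiple-testing-corrected p-values.
#'
#' Sex-chromosome features should be excluded by the caller before testing;
#' `sexChroms` features are dropped here with a message as a guard.
#'
#' @param targets `GRanges` of target nORF spans (must all be present in
#'   `reference`).
#' @param reference `GRanges` of all expressed nORF spans (the sampling
#'   universe).
#' @param loci `GRanges` of disorder-associated loci (non-empty).
#' @param nPerm Permutations per round (default 5000; < 100 warns).
#' @param seed Integer seed for the permutation stream.
#' @param lengthMatched Draw null sets within reference length quintiles
#'   instead of uniformly (off by default).
#' @param sexChroms Chromosome names stripped from targets and reference.
#' @return List: `n_targets` (merged), `observed` (loci overlapped),
#'   `n_overlapping_targets`, `empirical_p`, `null` (the null statistics),
#'   `n_perm`, `seed`.
#' @export
intervalEnrichment <- function(targets, reference, loci, nPerm = 5000,
                               seed = 1L, lengthMatched = FALSE,
                               sexChroms = c("chrX", "chrY", "chrSY")) {
  stopifnot(length(loci) > 0)
  if (nPerm < 100) warning("nPerm < 100: empirical p will be coarse")
  drop_t <- as.character(seqnames(targets)) %in% sexChroms
  drop_r <- as.character(seqnames(reference)) %in% sexChroms
  if (any(drop_t) || any(drop_r))
    message("dropping ", sum(drop_t), " target / ", sum(drop_r),
            " reference feature(s) on sex chromosomes")
  targets <- targets[!drop_t]; reference <- reference[!drop_r]
  mt <- reduce(granges(targets), ignore.strand = TRUE, min.gapwidth = 1L)
  mr <- reduce(granges(reference), ignore.strand = TRUE, min.gapwidth = 1L)
  if (length(mt) > length(mr))
    stop("more merged targets than merged reference features")
  membership <- matrix(FALSE, length(mr), length(loci))
  hits <- findOverlaps(mr, loci, ignore.strand = TRUE)
  membership[cbind(queryHits(hits), subjectHits(hits))] <- TRUE
  t_hits <- findOverlaps(mt, loci, ignore.strand = TRUE)
  observed <- length(unique(subjectHits(t_hits)))
  n_ov_targets <- length(unique(queryHits(t_hits)))
  set.seed(seed)
  null <- if (lengthMatched) {
    qs <- stats::quantile(width(mr), probs = seq(0, 1, 0.2))
    bin_r <- cut(width(mr), unique(qs), include.lowest = TRUE)
    bin_t <- cut(width(mt), unique(qs), include.lowest = TRUE)
    need <- table(bin_t)
    vapply(seq_len(nPerm), function(r) {
      rows <- unlist(lapply(names(need), function(b) {
        pool <- which(bin_r == b)
        sample(pool, min(need[[b]], length(pool)))
      }))
      sum(colSums(membership[rows, , drop = FALSE]) > 0)
    }, 0L)
  } else {
    .nullStats(membership, length(mt), nPerm)
  }
  list(n_targets = length(mt), observed = observed,
       n_overlapping_targets = n_ov_targets,
       empirical_p = (1 + sum(null >= observed)) / (1 + nPerm),
       null = null, n_perm = nPerm, seed = seed)
}

#' Family-wise corrected enrichment across strata and target subsets
#'
#' Runs [intervalEnrichment()] for every combination of locus stratum and
#' target subset, then applies the second permutation round within the
#' family: each round-1 null statistic is converted to its own empirical p
#' against the round-1 null distribution of its test, the minimum of these
#' pseudo-p values across the family forms the null of the family minimum,
#' and the corrected p of a test is the fraction of replicates whose minimum
#' is at or below the test's observed empirical p (with the +1 guard). This
#' reuse of the round-1 statistics guarantees corrected p >= empirical p.
#'
#' @param targetSets Named list of `GRanges` target sets.
#' @param reference `GRanges` reference (sampling universe).
#' @param lociList Named list of `GRanges` loci, one per stratum.
#' @param nPerm Permutations per round.
#' @param seed Integer seed.
#' @param ... Passed to [intervalEnrichment()].
#' @return `data.frame`: `stratum`, `target_set`, `n_targets`, `n_overlap`,
#'   `n_overlapping_targets`, `empirical_p`, `corrected_p`, `n_perm`.
#' @export
enrichLociFamily <- function(targetSets, reference, lociList, nPerm = 5000,
                             seed = 1L, ...) {
  runs <- list()
  k <- 0L
  for (st in names(lociList)) for (ts in names(targetSets)) {
    k <- k + 1L
    runs[[k]] <- c(list(stratum = st, target_set = ts),
                   intervalEnrichment(targetSets[[ts]], reference,
                                      lociList[[st]], nPerm = nPerm,
                                      seed = seed + k, ...))
  }
  ## round 2: per-replicate pseudo empirical p from the round-1 nulls
  pseudo <- vapply(runs, function(r) {
    null <- r$null
    vapply(null, function(t0) (1 + sum(null >= t0)) / (1 + r$n_perm), 0)
  }, numeric(nPerm))
  min_p <- apply(pseudo, 1L, min)
  out <- do.call(rbind, lapply(runs, function(r) data.frame(
    stratum = r$stratum, target_set = r$target_set,
    n_targets = r$n_targets, n_overlap = r$observed,
    n_overlapping_targets = r$n_overlapping_targets,
    empirical_p = r$empirical_p,
    corrected_p = (1 + sum(min_p <= r$empirical_p)) / (1 + nPerm),
    n_perm = r$n_perm, stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}
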