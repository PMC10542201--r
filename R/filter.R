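# Variant-level filters of the design cascade: VCF intake, proximity
# thinning, LD pruning, gene-pool MAF classification and even random
# selection.

#' Filter VCF records into SNP candidates
#'
#' Parses a VCF (path or `vcfR` object) and applies the per-record filter
#' cascade used during array design: biallelic SNPs only, missing-data cap,
#' mean-depth cap, MAF floor, and exclusion of A/T and C/G SNPs (their
#' alleles are complement-ambiguous on an array probe). Records are never
#' dropped: failing rows carry `removed:<reason>` with exactly one reason,
#' assigned in the documented order `not_snp`, `multiallelic`, `missing`,
#' `depth`, `maf`, `at_cg_exclusion`. Input order is preserved.
#'
#' Site statistics come from the genotype matrix: `missing_rate` is the
#' fraction of samples without a GT call, `mean_depth` the mean of the
#' per-sample FORMAT/DP values (NA when absent), and MAF the minor allele
#' count fraction over called alleles.
#'
#' @param vcf path to a VCF file or a `vcfR::vcfR` object.
#' @param params a [filter_params()] list.
#' @param species_id species label stored on the candidates.
#' @return a `snp_candidates` data.frame covering every input record.
#' @export
filter_variants <- function(vcf, params = filter_params(), species_id = "species") {
  stopifnot(inherits(params, "filter_params"))
  if (is.character(vcf)) vcf <- vcfR::read.vcfR(vcf, verbose = FALSE)
  stopifnot(methods::is(vcf, "vcfR"))
  fix <- vcfR::getFIX(vcf)
  if (is.null(fix) || nrow(fix) == 0L) {
    out <- snp_candidates(character(), character(), integer(),
                          character(), character())
    return(out)
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  dp <- suppressWarnings(vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE))

  n <- nrow(fix)
  ref <- toupper(fix[, "REF"])
  alt <- toupper(fix[, "ALT"])
  alt1 <- sub(",.*$", "", alt)
  multi <- grepl(",", alt)
  is_snp <- nchar(ref) == 1L & nchar(alt1) == 1L &
    ref %in% c("A", "C", "G", "T") & alt1 %in% c("A", "C", "G", "T") &
    ref != alt1

  miss <- rep(NA_real_, n)
  mafv <- rep(NA_real_, n)
  depth <- rep(NA_real_, n)
  if (!is.null(gt)) {
    gtm <- matrix(as.character(gt), nrow = n)
    called <- !is.na(gtm) & gtm != "." & gtm != "./." & gtm != ".|."
    miss <- 1 - rowMeans(called)
    # allele dosage of ALT among called genotypes
    clean <- gsub("[|]", "/", gtm)
    n_alt <- matrix(NA_real_, nrow = n, ncol = ncol(gtm))
    for (code in c("0/0", "0/1", "1/0", "1/1")) {
      n_alt[clean == code] <- sum(strsplit(code, "/")[[1]] == "1")
    }
    alt_cnt <- rowSums(n_alt, na.rm = TRUE)
    tot_cnt <- 2 * rowSums(!is.na(n_alt))
    p <- ifelse(tot_cnt > 0, alt_cnt / tot_cnt, NA_real_)
    mafv <- pmin(p, 1 - p)
  }
  if (!is.null(dp)) depth <- rowMeans(matrix(as.numeric(dp), nrow = n), na.rm = TRUE)
  depth[is.nan(depth)] <- NA_real_

  # alleles may be non-ACGT for failing records; coerce to placeholders so the
  # container invariants hold (those rows are removed anyway)
  ref_ok <- ifelse(is_snp, ref, "A")
  alt_ok <- ifelse(is_snp, alt1, "C")
  out <- snp_candidates(species_id, fix[, "CHROM"], as.integer(fix[, "POS"]),
                        ref_ok, alt_ok,
                        maf = pmin(mafv, 0.5), missing_rate = miss,
                        mean_depth = depth)
  # keep the true alleles visible for the log even on removed rows
  at_cg <- is_snp & ((ref %in% c("A", "T") & alt1 %in% c("A", "T")) |
                       (ref %in% c("C", "G") & alt1 %in% c("C", "G")))
  reason <- rep(NA_character_, n)
  reason[is.na(reason) & !is_snp & !multi] <- "not_snp"
  reason[is.na(reason) & multi] <- "multiallelic"
  reason[is.na(reason) & !is.na(miss) & miss > params$max_missing] <- "missing"
  reason[is.na(reason) & !is.na(depth) & depth > params$max_depth] <- "depth"
  reason[is.na(reason) & !is.na(mafv) & mafv < params$min_maf] <- "maf"
  reason[is.na(reason) & at_cg] <- "at_cg_exclusion"
  hit <- !is.na(reason)
  out$status[hit] <- paste0("removed:", reason[hit])
  validate_candidates(out)
  out
}

#' Thin candidates by physical proximity
#'
#' Removes SNPs that sit too close to another polymorphism on the same
#' chromosome. Two modes:
#' * `"exclusive"` (default): a SNP is kept only if no other input SNP lies
#'   within `window` bp — both members of a close pair drop. This matches
#'   the "unique SNPs with no other neighboring polymorphism" rule.
#' * `"keep_first"`: scanning by position, a SNP is kept only if it lies at
#'   least `window` bp beyond the last kept SNP (the 30 bp-window preset).
#'
#' Distances are `|pos_i - pos_j|`; "within window" means distance `< window`.
#' Only active rows participate; removed rows pass through untouched. The
#' operation is idempotent in both modes.
#'
#' @param candidates a `snp_candidates` data.frame.
#' @param window window width in bp (nonnegative).
#' @param mode `"exclusive"` or `"keep_first"`.
#' @return the candidates with newly removed rows marked
#'   `removed:proximity`.
#' @export
thin_by_proximity <- function(candidates, window,
                              mode = c("exclusive", "keep_first")) {
  mode <- match.arg(mode)
  if (!is.numeric(window) || length(window) != 1L || window < 0)
    stop("window must be a single nonnegative number")
  act <- which(candidates$status == "active")
  if (length(act) == 0L) return(candidates)
  key <- paste(candidates$species_id[act], candidates$chrom[act], sep = "\r")
  for (k in unique(key)) {
    idx <- act[key == k]
    idx <- idx[order(candidates$pos[idx])]
    pos <- candidates$pos[idx]
    if (mode == "exclusive") {
      d_prev <- c(Inf, diff(pos))
      d_next <- c(diff(pos), Inf)
      drop <- d_prev < window | d_next < window
    } else {
      drop <- logical(length(pos))
      last_kept <- -Inf
      for (i in seq_along(pos)) {
        if (pos[i] - last_kept >= window) last_kept <- pos[i] else drop[i] <- TRUE
      }
    }
    candidates <- .mark_removed(candidates, idx[drop], "proximity")
  }
  candidates
}

#' Prune candidates in linkage disequilibrium
#'
#' Greedy left-to-right pruning within a sliding window: scanning candidates
#' of one chromosome in input order, SNP `j` is dropped when some earlier
#' kept SNP `i` within `ld_window` positions (input-index distance on that
#' chromosome) has squared dosage correlation `r^2 >` `ld_r2_max` with it.
#' `r^2` uses pairwise-complete observations; pairs involving a monomorphic
#' column have undefined correlation and are treated as `r^2 = 0` (kept,
#' counted in the returned attribute `monomorphic`).
#'
#' @param genotypes numeric samples-by-SNP dosage matrix (0/1/2, NA allowed)
#'   whose columns align with the *active* rows of `candidates`.
#' @param candidates a `snp_candidates` data.frame.
#' @param params a [filter_params()] list supplying `ld_r2_max`, `ld_window`.
#' @return candidates with pruned rows marked `removed:ld`.
#' @export
prune_ld <- function(genotypes, candidates, params = filter_params()) {
  act <- which(candidates$status == "active")
  if (ncol(genotypes) != length(act))
    stop("genotype columns must align with active candidates")
  n_mono <- 0L
  chroms <- paste(candidates$species_id[act], candidates$chrom[act], sep = "\r")
  for (k in unique(chroms)) {
    local <- which(chroms == k)         # positions within act / genotype cols
    kept <- integer(0)
    for (jj in seq_along(local)) {
      j <- local[jj]                    # kept stores jj indices
      drop <- FALSE
      for (ii in rev(kept)) {
        if (jj - ii > params$ld_window) break
        x <- genotypes[, local[ii]]
        y <- genotypes[, j]
        r <- suppressWarnings(stats::cor(x, y, use = "pairwise.complete.obs"))
        if (is.na(r)) { n_mono <- n_mono + 1L; r <- 0 }
        if (r^2 > params$ld_r2_max) { drop <- TRUE; break }
      }
      if (drop) {
        candidates <- .mark_removed(candidates, act[j], "ld")
      } else {
        kept <- c(kept, jj)
      }
    }
  }
  attr(candidates, "monomorphic") <- n_mono
  candidates
}

#' Classify candidates by gene-pool MAF pattern
#'
#' Applies a user-supplied ordered rule list over the per-pool MAF columns
#' (`maf.<pool>`); the first matching rule wins. Each rule is a predicate
#' `function(maf)` receiving a named numeric vector of pool MAFs for one
#' candidate. The published class scheme lives in configuration, not code.
#'
#' @param candidates a `snp_candidates` data.frame with `maf.<pool>` columns.
#' @param class_rules named list of predicate functions; names are the class
#'   labels.
#' @param pools optional character vector restricting/ordering the pools; all
#'   `maf.` columns by default. Rules referencing a pool absent from the
#'   table raise an error.
#' @return character vector of class labels (NA where no rule matches).
#' @export
classify_by_pool_maf <- function(candidates, class_rules, pools = NULL) {
  maf_cols <- grep("^maf\\.", names(candidates), value = TRUE)
  have <- sub("^maf\\.", "", maf_cols)
  if (is.null(pools)) pools <- have
  unknown <- setdiff(pools, have)
  if (length(unknown))
    stop("rules reference unknown pool(s): ", paste(unknown, collapse = ", "))
  stopifnot(is.list(class_rules), length(names(class_rules)) == length(class_rules))
  labels <- rep(NA_character_, nrow(candidates))
  if (nrow(candidates) == 0L) return(labels)
  m <- as.matrix(candidates[, paste0("maf.", pools), drop = FALSE])
  colnames(m) <- pools
  for (i in seq_len(nrow(candidates))) {
    maf <- m[i, ]
    for (rn in names(class_rules)) {
      ok <- isTRUE(class_rules[[rn]](maf))
      if (ok) { labels[i] <- rn; break }
    }
  }
  labels
}

#' Select a random, genome-even subset of candidates
#'
#' Partitions each chromosome into fixed-width bins and draws candidates by
#' round-robin over the non-empty bins (one per bin per round, bins visited
#' in chromosome/bin order, within-bin order randomized once) until `n` are
#' selected. This caps dense regions and approaches one-per-bin when
#' `n` equals the bin count under uniform density. Deterministic per seed.
#'
#' @param candidates a `snp_candidates` data.frame (active rows are sampled).
#' @param n number of candidates to select; `min(n, n_active)` are returned.
#' @param genome_bins bin width in bp.
#' @param seed integer seed.
#' @return the selected subset of `candidates` (active rows, original order).
#' @export
select_even_random <- function(candidates, n, genome_bins = 1e6, seed = 1) {
  stopifnot(n >= 0)
  act <- which(candidates$status == "active")
  if (n >= length(act)) {
    out <- candidates[act, , drop = FALSE]
    class(out) <- class(candidates)
    return(out)
  }
  bin <- paste(candidates$species_id[act], candidates$chrom[act],
               (candidates$pos[act] - 1L) %/% genome_bins, sep = "\r")
  picked <- withr::with_seed(seed, {
    keys <- sort(unique(bin))
    queues <- lapply(keys, function(k) sample(act[bin == k]))
    sel <- integer(0)
    round <- 1L
    while (length(sel) < n) {
      for (q in seq_along(queues)) {
        if (length(sel) >= n) break
        if (length(queues[[q]]) >= round) sel <- c(sel, queues[[q]][round])
      }
      round <- round + 1L
    }
    sel
  })
  out <- candidates[sort(picked), , drop = FALSE]
  class(out) <- class(candidates)
  out
}
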