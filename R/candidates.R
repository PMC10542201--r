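# SNP candidate container and filter parameter set.
#
# Candidates flow through the design cascade as a data.frame; filters never
# drop rows, they mark them "removed:<reason>" so that the removal log is a
# by-product of the pipeline itself.

#' Construct a SNP candidate table
#'
#' A candidate is a biallelic SNP for one species, optionally annotated with
#' 60 bp flanks and per-gene-pool minor allele frequencies. All design-stage
#' filters take and return this container, marking rows `removed:<reason>`
#' rather than dropping them.
#'
#' @param species_id species label (recycled).
#' @param chrom sequence (chromosome/scaffold) name.
#' @param pos 1-based position of the variant base.
#' @param ref,alt single-nucleotide alleles in `A,C,G,T`; must differ.
#' @param maf overall minor allele frequency in `[0, 0.5]` (NA allowed).
#' @param missing_rate fraction of samples without a genotype, in `[0, 1]`.
#' @param mean_depth mean read depth at the site (>= 0).
#' @param flank_up,flank_down 60-base flanking sequences or NA.
#' @param pool_maf optional data.frame (or named list of numeric vectors) of
#'   per-pool MAFs; stored as `maf.<pool>` columns.
#' @return a `snp_candidates` data.frame with a `status` column set to
#'   `"active"`.
#' @export
snp_candidates <- function(species_id, chrom, pos, ref, alt,
                           maf = NA_real_, missing_rate = NA_real_,
                           mean_depth = NA_real_,
                           flank_up = NA_character_, flank_down = NA_character_,
                           pool_maf = NULL) {
  n <- length(chrom)
  rl <- function(x) rep(x, length.out = n)
  df <- data.frame(
    species_id = rl(as.character(species_id)),
    chrom = as.character(chrom),
    pos = as.integer(pos),
    ref = rl(toupper(as.character(ref))),
    alt = rl(toupper(as.character(alt))),
    maf = rl(as.numeric(maf)),
    missing_rate = rl(as.numeric(missing_rate)),
    mean_depth = rl(as.numeric(mean_depth)),
    flank_up = rl(as.character(flank_up)),
    flank_down = rl(as.character(flank_down)),
    status = rl("active"),
    stringsAsFactors = FALSE
  )
  if (!is.null(pool_maf)) {
    pool_maf <- as.data.frame(pool_maf)
    names(pool_maf) <- paste0("maf.", names(pool_maf))
    df <- cbind(df, pool_maf)
  }
  class(df) <- c("snp_candidates", "data.frame")
  validate_candidates(df)
  df
}

#' Validate a candidate table's invariants
#'
#' Checks allele domain and distinctness, MAF bounds, flank length/alphabet,
#' and the single-reason form of removed statuses. Called by the constructor;
#' exported so pipelines can re-assert after manual edits.
#'
#' @param x a `snp_candidates` data.frame.
#' @return `x`, invisibly; errors on violation.
#' @export
validate_candidates <- function(x) {
  stopifnot(is.data.frame(x))
  need <- c("species_id", "chrom", "pos", "ref", "alt", "status")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols))
    stop("candidate table lacks columns: ", paste(missing_cols, collapse = ", "))
  if (nrow(x) == 0L) return(invisible(x))
  ok_allele <- x$ref %in% c("A", "C", "G", "T") & x$alt %in% c("A", "C", "G", "T")
  if (any(!ok_allele))
    stop("alleles must be single bases in {A,C,G,T}")
  if (any(x$ref == x$alt))
    stop("ref and alt alleles must differ")
  if (any(x$pos < 1L))
    stop("positions are 1-based and must be >= 1")
  maf_cols <- c("maf", grep("^maf\\.", names(x), value = TRUE))
  for (mc in maf_cols) {
    v <- x[[mc]]
    if (any(!is.na(v) & (v < 0 | v > 0.5)))
      stop("column ", mc, " must lie in [0, 0.5]")
  }
  for (fc in c("flank_up", "flank_down")) {
    if (!fc %in% names(x)) next
    v <- x[[fc]]
    has <- !is.na(v)
    if (any(has & nchar(v) != 60L))
      stop(fc, " must be exactly 60 bases when present")
    if (any(has & !vapply(v[has], .is_iupac_string, logical(1))))
      stop(fc, " contains non-IUPAC characters")
  }
  bad_status <- !(x$status == "active" | grepl("^removed:[^:]+$", x$status))
  if (any(bad_status))
    stop("status must be 'active' or 'removed:<one reason>'")
  invisible(x)
}

#' Subset a candidate table to active rows
#'
#' @param x a `snp_candidates` data.frame.
#' @return the rows whose status is `"active"`.
#' @export
active_candidates <- function(x) {
  out <- x[x$status == "active", , drop = FALSE]
  class(out) <- class(x)
  out
}

#' Removal log of a candidate table
#'
#' @param x a `snp_candidates` data.frame.
#' @return data.frame with columns `species_id, chrom, pos, reason` for the
#'   removed rows.
#' @export
removed_candidates <- function(x) {
  r <- x[x$status != "active", c("species_id", "chrom", "pos", "status"), drop = FALSE]
  r$reason <- sub("^removed:", "", r$status)
  r$status <- NULL
  rownames(r) <- NULL
  r
}

# mark rows removed (only rows currently active are touched)
.mark_removed <- function(x, idx, reason) {
  idx <- idx[x$status[idx] == "active"]
  x$status[idx] <- paste0("removed:", reason)
  x
}

#' Filter parameter set for the design cascade
#'
#' Bundles the thresholds of the variant filter, thinning, LD pruning and
#' cross-hybridization screen. Defaults follow the array-design presets used
#' for the fish panels: at most 20% missing data, depth cap, MAF floor, a
#' 30 bp thinning window, and a blastn-like cross-hybridization screen at
#' E-value 1e-5 and 80% identity. LD-pruning settings (r^2 > 0.2 within a
#' 50-SNP window) are package defaults; all values are configurable.
#'
#' @param max_missing maximum per-site missing-genotype fraction.
#' @param max_depth maximum mean read depth (guards against repeats).
#' @param min_maf minimum minor allele frequency.
#' @param thin_window proximity-thinning window in bp.
#' @param ld_r2_max r-squared above which the later SNP of a pair is pruned.
#' @param ld_window LD-pruning window, counted in SNPs.
#' @param crosshyb_evalue E-value threshold of the cross-taxon screen.
#' @param crosshyb_identity identity threshold (fraction in (0,1]) of the
#'   cross-taxon screen.
#' @param edge_min_bp minimum distance of a SNP from a scaffold end (bp).
#' @return a `filter_params` list.
#' @export
filter_params <- function(max_missing = 0.2, max_depth = 100, min_maf = 0.05,
                          thin_window = 30, ld_r2_max = 0.2, ld_window = 50,
                          crosshyb_evalue = 1e-5, crosshyb_identity = 0.8,
                          edge_min_bp = 60) {
  p <- list(max_missing = max_missing, max_depth = max_depth, min_maf = min_maf,
            thin_window = thin_window, ld_r2_max = ld_r2_max, ld_window = ld_window,
            crosshyb_evalue = crosshyb_evalue, crosshyb_identity = crosshyb_identity,
            edge_min_bp = edge_min_bp)
  num <- vapply(p, is.numeric, logical(1))
  if (!all(num)) stop("all filter parameters must be numeric")
  if (any(unlist(p) < 0)) stop("all filter thresholds must be nonnegative")
  if (crosshyb_identity <= 0 || crosshyb_identity > 1)
    stop("crosshyb_identity must lie in (0, 1]")
  class(p) <- "filter_params"
  p
}
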