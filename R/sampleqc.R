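# Two-stage sample QC and the per-species genotyping pipeline.

#' Two-stage sample quality control and genotyping pipeline
#'
#' Runs the full per-species genotyping workflow on one species' intensity
#' matrix:
#' 1. DQC per sample from the species' DQC probes;
#' 2. QC call rate: percent of a designated QC SNP subset (a seeded random
#'    `qc_fraction` of the species' genotyping probes, fixed by `qc_seed`)
#'    called under generic priors;
#' 3. stage 1: samples pass when `dqc >= dqc_min` *and*
#'    `qc_call_rate >= qccr_min` (both inclusive);
#' 4. stage-1 passers are genotyped over all SNPs, the OTV caller is run,
#'    and SNPs are classified;
#' 5. stage 2: `allele_deviation_mean` — the mean over a sample's called
#'    SNPs of `min(1, |contrast - assigned cluster mean| / (3 * cluster sd))`
#'    (larger is worse) — removes samples exceeding `adm_max`;
#' 6. call rate (percent called over all SNPs) is reported for final samples
#'    only.
#'
#' @param im_sp per-species `intensity_matrix` (from [split_by_species()]).
#' @param manifest the `array_manifest`.
#' @param dqc_min DQC threshold (default 0.82).
#' @param qccr_min QC call-rate threshold in percent (default 95).
#' @param adm_max allele-deviation-mean removal threshold (default 0.85).
#' @param cr_min SNP-category call-rate threshold passed to [classify_snp()].
#' @param qc_fraction fraction of genotyping probes in the QC subset.
#' @param qc_seed seed fixing the QC subset.
#' @param ploidy 2 (default) or 4; tetraploid mode calls dosages 0..4 and
#'   skips OTV recall and SNP classification.
#' @param ... further arguments passed to [call_genotypes()] /
#'   [call_dosage_tetraploid()].
#' @return list with `sample_qc` (a `sample_qc` data.frame: `sample_id`,
#'   `dqc`, `qc_call_rate`, `call_rate`, `allele_deviation_mean`,
#'   `pass_stage1`, `pass_stage2`), `fit` (`genotype_calls` for stage-1
#'   passers), `classes` (`snp_class`), `contrast`, `strength`, and the
#'   thresholds used.
#' @export
genotype_species <- function(im_sp, manifest, dqc_min = 0.82, qccr_min = 95,
                             adm_max = 0.85, cr_min = 97,
                             qc_fraction = 0.1, qc_seed = 1, ploidy = 2, ...) {
  trans <- transform_intensities(im_sp)
  samples <- rownames(trans$contrast)
  dqc <- compute_dqc(trans, manifest, im_sp$species)

  geno_probes <- intersect(colnames(trans$contrast),
                           manifest$probe_id[manifest$probe_type == "genotyping"])
  qc_subset <- withr::with_seed(qc_seed,
    sort(sample(geno_probes, max(1L, ceiling(qc_fraction * length(geno_probes))))))

  qc_fit <- call_genotypes(trans$contrast[, qc_subset, drop = FALSE], ...)
  qc_call_rate <- 100 * rowMeans(!is.na(qc_fit$calls))

  pass1 <- !is.na(dqc) & dqc >= dqc_min & qc_call_rate >= qccr_min
  qc <- data.frame(sample_id = samples, dqc = unname(dqc),
                   qc_call_rate = unname(qc_call_rate),
                   call_rate = NA_real_, allele_deviation_mean = NA_real_,
                   pass_stage1 = unname(pass1), pass_stage2 = NA,
                   stringsAsFactors = FALSE)

  fit <- NULL; classes <- NULL
  if (any(pass1)) {
    ctr <- trans$contrast[pass1, geno_probes, drop = FALSE]
    stn <- trans$strength[pass1, geno_probes, drop = FALSE]
    if (ploidy == 4) {
      fit <- call_dosage_tetraploid(ctr, ...)
    } else {
      fit <- call_genotypes(ctr, ...)
      fit <- call_otv(fit, stn)
      classes <- classify_snp(fit, cr_min = cr_min)
    }
    adm <- allele_deviation_mean(fit, ctr)
    qc$allele_deviation_mean[pass1] <- adm
    pass2 <- pass1
    pass2[pass1] <- !is.na(adm) & adm <= adm_max
    qc$pass_stage2 <- unname(pass2)
    cr <- 100 * rowMeans(!is.na(fit$calls))  # OTV-recoded samples count as called
    qc$call_rate[match(rownames(fit$calls)[pass2[pass1]], qc$sample_id)] <-
      cr[pass2[pass1]]
  } else {
    qc$pass_stage2 <- FALSE
  }
  attr(qc, "thresholds") <- list(dqc_min = dqc_min, qccr_min = qccr_min,
                                 adm_max = adm_max, cr_min = cr_min)
  attr(qc, "qc_subset") <- qc_subset
  class(qc) <- c("sample_qc", "data.frame")
  list(sample_qc = qc, fit = fit, classes = classes,
       contrast = trans$contrast, strength = trans$strength)
}

#' Per-sample allele deviation mean
#'
#' Mean over a sample's called SNPs (OTV codes excluded) of
#' `min(1, |contrast - mu_assigned| / (3 * sd_assigned))`, where `mu`/`sd`
#' are the assigned cluster's fitted parameters. 0 for a sample sitting
#' exactly on its cluster means; larger values mean the sample falls between
#' clusters (worse).
#'
#' @param fit a `genotype_calls` object.
#' @param contrast the contrast matrix the calls were made from (same rows).
#' @return named numeric vector per sample.
#' @export
allele_deviation_mean <- function(fit, contrast) {
  n <- nrow(fit$calls)
  dev_sum <- numeric(n); dev_n <- numeric(n)
  for (j in seq_len(ncol(fit$calls))) {
    model <- fit$models[[j]]
    if (is.null(model)) next
    cj <- fit$calls[, j]
    called <- !is.na(cj) & cj != OTV_CODE
    if (!any(called)) next
    comp <- match(cj[called], model$levels)
    d <- pmin(1, abs(contrast[called, j] - model$mu[comp]) / (3 * model$sd[comp]))
    dev_sum[called] <- dev_sum[called] + d
    dev_n[called] <- dev_n[called] + 1
  }
  out <- ifelse(dev_n > 0, dev_sum / dev_n, NA_real_)
  stats::setNames(out, rownames(fit$calls))
}

#' Summarize SNP classification for one species
#'
#' Per-category counts (a partition of the species' SNPs), the conversion
#' rate `(PHR + NMH) / total` and the good-quality polymorphic share
#' `(PHR + NMH + OTV) / total`, as percentages rounded half-up to the
#' nearest integer (headline figures) with one-decimal values alongside.
#'
#' @param categories character vector (or factor) of per-SNP categories for
#'   one species.
#' @param species species label for the report.
#' @return list with `species`, `counts` (named, summing to `total`),
#'   `total`, `conversion_rate`, `conversion_rate_1dp`,
#'   `polymorphic_good_rate` (all NA when `categories` is empty).
#' @export
summarize_classification <- function(categories, species = "species") {
  lev <- c("PolyHighResolution", "NoMinorHom", "MonoHighResolution", "OTV",
           "CallRateBelowThreshold", "Other")
  counts <- table(factor(categories, levels = lev))
  total <- length(categories)
  if (total == 0L) {
    return(list(species = species, counts = stats::setNames(rep(0L, length(lev)), lev),
                total = 0L, conversion_rate = NA_real_,
                conversion_rate_1dp = NA_real_, polymorphic_good_rate = NA_real_))
  }
  conv <- 100 * (counts[["PolyHighResolution"]] + counts[["NoMinorHom"]]) / total
  poly <- 100 * (counts[["PolyHighResolution"]] + counts[["NoMinorHom"]] +
                   counts[["OTV"]]) / total
  list(species = species,
       counts = stats::setNames(as.integer(counts), lev),
       total = total,
       conversion_rate = round_half_up(conv),
       conversion_rate_1dp = round_half_up(conv, 1),
       polymorphic_good_rate = round_half_up(poly))
}
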