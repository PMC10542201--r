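# Cluster-based genotype calling from two-channel intensities.
#
# The proprietary array-calling algorithm is replaced by a documented
# stand-in with the same category semantics: per SNP, constrained Gaussian
# mixtures on the contrast axis are fitted by EM for every subset of the
# prior genotype clusters, the subset is selected by BIC, and samples are
# assigned their maximum-posterior cluster subject to a confidence floor.

#' Code used for off-target-variant (null allele) calls
#'
#' Genotype matrices are integer dosage matrices with `NA` for missing;
#' samples re-coded by the OTV caller carry this sentinel value.
#' @export
OTV_CODE <- -1L

#' Contrast/strength transform of two-channel intensities
#'
#' `contrast = log2(a/b)`, `strength = (log2 a + log2 b)/2`, computed after
#' adding a floor `eps` to each channel; the exact inverse of the
#' simulator's channel reconstruction at `eps = 0`.
#'
#' @param im an `intensity_matrix`, or a list with matrices `a` and `b`.
#' @param eps channel floor (default 1e-3). Negative channels are an error.
#' @return list with matrices `contrast` and `strength`.
#' @export
transform_intensities <- function(im, eps = 1e-3) {
  a <- im$a; b <- im$b
  if (any(a < 0) || any(b < 0)) stop("intensity channels must be nonnegative")
  la <- log2(a + eps); lb <- log2(b + eps)
  list(contrast = la - lb, strength = (la + lb) / 2)
}

#' Split intensities per species
#'
#' Each output holds only that species' probes (genotyping and DQC) and only
#' the samples mapped to that species (a related species may be mapped onto
#' another's probes through the plan's effective species).
#'
#' @param im an `intensity_matrix` from [simulate_intensities()].
#' @param manifest the `array_manifest`; every probe must carry a species tag.
#' @return named list of `intensity_matrix` objects.
#' @export
split_by_species <- function(im, manifest) {
  if (any(is.na(manifest$species_id) | manifest$species_id == ""))
    stop("every probe must carry a species tag")
  out <- list()
  for (sp in unique(im$species)) {
    cols <- manifest$probe_id[manifest$species_id == sp]
    rows <- names(im$species)[im$species == sp]
    if (length(cols) == 0L) next
    out[[sp]] <- structure(list(
      a = im$a[rows, cols, drop = FALSE],
      b = im$b[rows, cols, drop = FALSE],
      plan = im$plan[im$plan$sample_id %in% rows, , drop = FALSE],
      species = im$species[rows],
      truth = list(otv_loci = im$truth$otv_loci[sp],
                   null_carrier = im$truth$null_carrier[sp]),
      signal_model = im$signal_model), class = "intensity_matrix")
  }
  out
}

#' Per-sample Dish Quality Control metric
#'
#' DQC is the fraction of a sample's species DQC probes that behave as
#' expected for clean DNA: contrast of the expected sign with magnitude at
#' least `tau` and strength at least `strength_min` (above hybridization
#' background). Values lie in `[0, 1]` and are near 1 for high-quality
#' samples. Samples of a species with no DQC probes get `NA` (they fail
#' stage-1 QC conservatively).
#'
#' @param trans list with `contrast` and `strength` matrices (samples x
#'   probes) from [transform_intensities()].
#' @param manifest the `array_manifest`.
#' @param sample_species named character vector (sample -> species) for the
#'   rows of the matrices.
#' @param tau minimum contrast magnitude (default 0.75, half the nominal
#'   homozygous contrast).
#' @param strength_min minimum strength in log2 units (default 5.5: the 2%
#'   crosstalk background of a nominal strength-10 signal plus one log2 unit
#'   of margin).
#' @return named numeric vector of DQC values.
#' @export
compute_dqc <- function(trans, manifest, sample_species,
                        tau = 0.75, strength_min = 5.5) {
  samples <- rownames(trans$contrast)
  dqc <- stats::setNames(rep(NA_real_, length(samples)), samples)
  for (s in samples) {
    sp <- sample_species[[s]]
    cols <- manifest$probe_id[manifest$species_id == sp & manifest$probe_type == "dqc"]
    cols <- intersect(cols, colnames(trans$contrast))
    if (length(cols) == 0L) next
    dqc[s] <- mean(trans$contrast[s, cols] >= tau &
                     trans$strength[s, cols] >= strength_min)
  }
  dqc
}

# --- constrained mixture machinery ------------------------------------------

# EM for a Gaussian mixture with means boxed to [lo, hi] per component.
# Deterministic: fixed initialization, no randomness.
.mix_em <- function(x, mu0, lo, hi, sd_init = 0.15, sd_floor = 0.05,
                    sd_cap = 1.0, max_iter = 100, tol = 1e-6) {
  n <- length(x); k <- length(mu0)
  mu <- mu0; sdv <- rep(sd_init, k); w <- rep(1 / k, k)
  ll_old <- -Inf
  X <- matrix(x, n, k)
  for (it in seq_len(max_iter)) {
    M <- matrix(mu, n, k, byrow = TRUE)
    S <- matrix(sdv, n, k, byrow = TRUE)
    dens <- exp(-0.5 * ((X - M) / S)^2) / (sqrt(2 * pi) * S)
    dens <- dens * matrix(w, n, k, byrow = TRUE)
    tot <- rowSums(dens)
    tot[tot < 1e-300] <- 1e-300
    ll <- sum(log(tot))
    r <- dens / tot
    nk <- pmax(colSums(r), 1e-8)
    w <- nk / sum(nk)
    mu <- pmin(pmax(colSums(r * X) / nk, lo), hi)
    M <- matrix(mu, n, k, byrow = TRUE)
    sdv <- pmin(pmax(sqrt(colSums(r * (X - M)^2) / nk), sd_floor), sd_cap)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (abs(ll_old) + tol)) break
    ll_old <- ll
  }
  npar <- 3 * k - 1
  list(mu = mu, sd = sdv, w = w, loglik = ll, bic = -2 * ll + npar * log(n),
       posterior = r, iter = it, converged = it < max_iter)
}

# Fit all plausible subsets of the prior clusters to one SNP's contrasts and
# select by BIC. levels are dosage codes 0..(length(priors)-1) matching
# priors (ordered decreasing contrast: dosage 0 = ref homozygote, highest
# contrast).
.fit_genotype_mixture <- function(x, priors, mean_window = 0.75,
                                  sd_init = 0.15, ...) {
  L <- length(priors)
  occupied <- which(vapply(seq_len(L), function(j)
    any(abs(x - priors[j]) <= mean_window), logical(1)))
  if (length(occupied) == 0L) occupied <- seq_len(L)
  subsets <- list()
  for (sz in seq_along(occupied))
    subsets <- c(subsets, utils::combn(occupied, sz, simplify = FALSE))
  best <- NULL
  for (s in subsets) {
    fit <- .mix_em(x, mu0 = priors[s], lo = priors[s] - mean_window,
                   hi = priors[s] + mean_window, sd_init = sd_init, ...)
    if (!is.finite(fit$bic)) next
    if (is.null(best) || fit$bic < best$bic) {
      fit$levels <- s - 1L
      best <- fit
    }
  }
  best
}

#' Call genotypes from contrast/strength matrices
#'
#' Per SNP, constrained Gaussian mixtures (1 to 3 components for diploids,
#' up to 5 in tetraploid mode) are fitted by EM on the contrast axis for
#' every plausible subset of the prior cluster positions, with component
#' means boxed to `prior +/- mean_window` (which also enforces the ordering
#' of cluster means); the subset is selected by BIC. Each sample is assigned
#' its maximum-posterior component's dosage if that posterior reaches
#' `confidence_min`, else missing. The procedure is deterministic given the
#' data and configuration. SNPs with fewer than `min_samples` samples are
#' left uncalled (model `NULL`; classified `Other` downstream).
#'
#' @param contrast samples x SNPs contrast matrix.
#' @param priors prior cluster contrasts, ordered decreasing; the component
#'   at `priors[j]` is dosage `j - 1` (default diploid `c(1.5, 0, -1.5)`).
#' @param confidence_min posterior floor below which a call is missing.
#' @param min_samples minimum samples per SNP (default 20).
#' @param mean_window half-width of the box constraint on component means.
#' @param sd_init initial component standard deviation.
#' @return a `genotype_calls` list: `calls` (dosage matrix, NA = missing),
#'   `posterior` (max posterior per call), `models` (per-SNP component
#'   summaries), `priors`.
#' @export
call_genotypes <- function(contrast, priors = c(1.5, 0, -1.5),
                           confidence_min = 0.85, min_samples = 20,
                           mean_window = 0.75, sd_init = 0.15) {
  n <- nrow(contrast); p <- ncol(contrast)
  calls <- matrix(NA_integer_, n, p, dimnames = dimnames(contrast))
  post <- matrix(NA_real_, n, p, dimnames = dimnames(contrast))
  models <- vector("list", p)
  names(models) <- colnames(contrast)
  for (j in seq_len(p)) {
    x <- contrast[, j]
    ok <- is.finite(x)
    if (sum(ok) < min_samples) next
    fit <- .fit_genotype_mixture(x[ok], priors, mean_window = mean_window,
                                 sd_init = sd_init)
    if (is.null(fit)) next
    comp <- max.col(fit$posterior, ties.method = "first")
    conf <- fit$posterior[cbind(seq_len(nrow(fit$posterior)), comp)]
    call_j <- ifelse(conf >= confidence_min, fit$levels[comp], NA_integer_)
    calls[ok, j] <- as.integer(call_j)
    post[ok, j] <- conf
    models[[j]] <- list(levels = fit$levels, mu = fit$mu, sd = fit$sd,
                        w = fit$w, bic = fit$bic, k = length(fit$levels),
                        converged = fit$converged)
  }
  structure(list(calls = calls, posterior = post, models = models,
                 priors = priors, confidence_min = confidence_min),
            class = "genotype_calls")
}

#' Re-call off-target variants (null alleles)
#'
#' For each SNP, looks for a separate low-strength sample cluster: the
#' strength vector is split at its best 1D 2-means partition, and the SNP is
#' flagged OTV when the 2-cluster model improves BIC over a single cluster,
#' the two cluster means are at least `min_sep` log2 units apart, and the
#' low cluster holds at least `min_size` samples. Samples in the low cluster
#' are re-coded [OTV_CODE] (they carry a null allele: the probe sees only
#' background signal).
#'
#' @param fit a `genotype_calls` object.
#' @param strength samples x SNPs strength matrix aligned with the calls.
#' @param min_sep minimum separation of the strength clusters (default 2
#'   log2 units, i.e. the low cluster below 25% of full signal).
#' @param min_size minimum size of the low-strength cluster.
#' @return `fit` with updated `calls` and a logical `otv_flag` per SNP.
#' @export
call_otv <- function(fit, strength, min_sep = 2, min_size = 2) {
  p <- ncol(fit$calls)
  flag <- stats::setNames(logical(p), colnames(fit$calls))
  for (j in seq_len(p)) {
    if (is.null(fit$models[[j]])) next
    s <- strength[, j]
    ok <- is.finite(s)
    x <- s[ok]
    n <- length(x)
    if (n < 2 * min_size) next
    o <- order(x)
    xs <- x[o]
    csum <- cumsum(xs); csq <- cumsum(xs^2)
    tot_sse <- csq[n] - csum[n]^2 / n
    m <- seq_len(n - 1)
    sse_lo <- csq[m] - csum[m]^2 / m
    sse_hi <- (csq[n] - csq[m]) - (csum[n] - csum[m])^2 / (n - m)
    sse2 <- sse_lo + sse_hi
    split <- which.min(sse2)
    bic1 <- n * log(max(tot_sse, 1e-12) / n) + 1 * log(n)
    bic2 <- n * log(max(sse2[split], 1e-12) / n) + 2 * log(n)
    mu_lo <- csum[split] / split
    mu_hi <- (csum[n] - csum[split]) / (n - split)
    if (bic2 < bic1 && (mu_hi - mu_lo) >= min_sep && split >= min_size) {
      flag[j] <- TRUE
      low_samples <- which(ok)[o[seq_len(split)]]
      fit$calls[low_samples, j] <- OTV_CODE
    }
  }
  fit$otv_flag <- flag
  fit
}

#' Classify SNPs into array quality categories
#'
#' First-match category logic per SNP:
#' 1. `CallRateBelowThreshold` — SNP call rate below `cr_min` (default 97%;
#'    OTV-recoded samples count as called);
#' 2. `OTV` — flagged by [call_otv()];
#' 3. `Other` — no mixture model could be fitted;
#' 4. `MonoHighResolution` — a single genotype cluster;
#' 5. `PolyHighResolution` — polymorphic with at least 2 minor-homozygote
#'    examples and cluster separation `>= sep_min`;
#' 6. `NoMinorHom` — polymorphic, fewer than 2 minor homozygotes, separation
#'    `>= sep_min`;
#' 7. `Other` — anything else (poor clustering).
#'
#' Separation is the minimum over adjacent components of
#' `|delta mean| / pooled sd`. Category assignment is a total function: every
#' SNP gets exactly one category.
#'
#' @param fit a `genotype_calls` object (after [call_otv()] if OTV recall is
#'   wanted).
#' @param cr_min SNP call-rate threshold in percent (default 97, the array
#'   convention; distinct from the sample QC call-rate threshold 95).
#' @param sep_min minimum cluster separation (default 3).
#' @return a `snp_class` data.frame: `probe_id`, `category`,
#'   `snp_call_rate`, `n_components`, `minor_hom_count`, `separation`.
#' @export
classify_snp <- function(fit, cr_min = 97, sep_min = 3) {
  p <- ncol(fit$calls)
  otv_flag <- fit$otv_flag %||% stats::setNames(logical(p), colnames(fit$calls))
  out <- data.frame(probe_id = colnames(fit$calls) %||% sprintf("SNP%d", seq_len(p)),
                    category = NA_character_, snp_call_rate = NA_real_,
                    n_components = NA_integer_, minor_hom_count = NA_integer_,
                    separation = NA_real_, stringsAsFactors = FALSE)
  max_dos <- length(fit$priors) - 1L
  for (j in seq_len(p)) {
    cj <- fit$calls[, j]
    cr <- 100 * mean(!is.na(cj))
    out$snp_call_rate[j] <- cr
    model <- fit$models[[j]]
    if (!is.null(model)) {
      out$n_components[j] <- model$k
      if (model$k >= 2) {
        pooled <- sqrt((model$sd[-model$k]^2 + model$sd[-1]^2) / 2)
        out$separation[j] <- min(abs(diff(model$mu)) / pooled)
      }
      out$minor_hom_count[j] <- min(sum(cj == 0L, na.rm = TRUE),
                                    sum(cj == max_dos, na.rm = TRUE))
    }
    out$category[j] <-
      if (cr < cr_min) "CallRateBelowThreshold"
      else if (otv_flag[j]) "OTV"
      else if (is.null(model)) "Other"
      else if (model$k == 1L) "MonoHighResolution"
      else if (out$separation[j] >= sep_min && out$minor_hom_count[j] >= 2L) "PolyHighResolution"
      else if (out$separation[j] >= sep_min) "NoMinorHom"
      else "Other"
  }
  class(out) <- c("snp_class", "data.frame")
  out
}

#' Call tetraploid allele dosages
#'
#' Fits ordered mixtures of up to five components (dosages 0..4) on the
#' contrast axis with the same constrained-EM/BIC machinery as
#' [call_genotypes()], assigning dosage by maximum posterior subject to
#' `confidence_min`. A SNP is rejected (all calls missing) when the selected
#' multi-component model does not achieve cluster separation `sep_min`.
#'
#' @param contrast samples x SNPs contrast matrix.
#' @param priors five prior cluster contrasts, decreasing (default
#'   `c(1.5, 0.75, 0, -0.75, -1.5)`).
#' @param confidence_min posterior floor.
#' @param min_samples minimum samples per SNP.
#' @param sep_min separation below which a fitted multi-cluster SNP is
#'   rejected.
#' @return a `genotype_calls` object with dosage codes 0..4.
#' @export
call_dosage_tetraploid <- function(contrast, priors = c(1.5, 0.75, 0, -0.75, -1.5),
                                   confidence_min = 0.85, min_samples = 20,
                                   sep_min = 2) {
  fit <- call_genotypes(contrast, priors = priors,
                        confidence_min = confidence_min,
                        min_samples = min_samples,
                        mean_window = min(diff(rev(priors))) / 2,
                        sd_init = 0.1)
  for (j in seq_len(ncol(fit$calls))) {
    model <- fit$models[[j]]
    if (is.null(model) || model$k < 2) next
    pooled <- sqrt((model$sd[-model$k]^2 + model$sd[-1]^2) / 2)
    if (min(abs(diff(model$mu)) / pooled) < sep_min) {
      fit$calls[, j] <- NA_integer_
      fit$models[[j]]$rejected <- TRUE
    }
  }
  fit
}
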