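# Synthetic data generator: population genotypes under a Balding-Nichols
# island model, pedigree offspring, and two-channel probe intensities for
# pooled two-species reactions.
#
# The generator defines the study conditions under which the caller and the
# validation layer are exercised; defaults are chosen so that a clean sample
# produces "clear and well-separated" genotype clusters, degradable through
# the per-sample quality scalar.

#' Population model for genotype simulation
#'
#' Per-locus pool allele frequencies are drawn from a Balding-Nichols
#' distribution: with ancestral frequency `p` and differentiation target
#' `F`, each pool's frequency is `Beta(p (1-F)/F, (1-p)(1-F)/F)`, giving
#' expected FST `F` among pools. `fst_target = 0` makes all pools share the
#' ancestral frequency exactly.
#'
#' @param n_pools number of pools (populations).
#' @param fst_target differentiation among pools, in `[0, 1)`.
#' @param ancestral_maf_range interval in `(0, 0.5]` from which ancestral
#'   minor allele frequencies are drawn uniformly. The default lower bound
#'   0.02 keeps a realistic tail of rare alleles, so that a fraction of
#'   loci is monomorphic in any finite screened set (as on a real array).
#' @param samples_per_pool diploid individuals per pool.
#' @return a `pop_model` list.
#' @export
pop_model <- function(n_pools = 4, fst_target = 0.2,
                      ancestral_maf_range = c(0.02, 0.5),
                      samples_per_pool = 50) {
  stopifnot(fst_target >= 0, fst_target < 1,
            ancestral_maf_range[1] > 0, ancestral_maf_range[2] <= 0.5,
            n_pools >= 1, samples_per_pool >= 1)
  structure(list(n_pools = n_pools, fst_target = fst_target,
                 ancestral_maf_range = ancestral_maf_range,
                 samples_per_pool = samples_per_pool),
            class = "pop_model")
}

#' Simulate population genotypes
#'
#' Hardy-Weinberg sampling within pools from Balding-Nichols pool
#' frequencies. The returned truth (ancestral and pool frequencies, pool
#' labels) supports parameter-recovery tests.
#'
#' @param loci number of loci, or a character vector of locus (probe) names.
#' @param pop a [pop_model()].
#' @param seed integer seed; identical seeds give bit-identical output.
#' @param prefix sample-id prefix.
#' @return list with `genotypes` (samples x loci dosage matrix, 0/1/2),
#'   `pools` (factor), `ancestral_p`, `pool_p` (pools x loci ALT frequency).
#' @export
simulate_population_genotypes <- function(loci, pop = pop_model(), seed = 1,
                                          prefix = "S") {
  locus_names <- if (is.character(loci)) loci else sprintf("L%05d", seq_len(loci))
  L <- length(locus_names)
  withr::with_seed(seed, {
    p_anc <- stats::runif(L, pop$ancestral_maf_range[1], pop$ancestral_maf_range[2])
    flip <- stats::runif(L) < 0.5   # minor allele is REF for half the loci
    p_anc <- ifelse(flip, 1 - p_anc, p_anc)
    if (pop$fst_target == 0) {
      pool_p <- matrix(rep(p_anc, each = pop$n_pools), nrow = pop$n_pools)
    } else {
      F <- pop$fst_target
      a <- p_anc * (1 - F) / F
      b <- (1 - p_anc) * (1 - F) / F
      pool_p <- matrix(stats::rbeta(pop$n_pools * L, rep(a, each = pop$n_pools),
                                    rep(b, each = pop$n_pools)),
                       nrow = pop$n_pools)
    }
    n <- pop$n_pools * pop$samples_per_pool
    pools <- factor(rep(seq_len(pop$n_pools), each = pop$samples_per_pool))
    g <- matrix(0L, nrow = n, ncol = L)
    for (k in seq_len(pop$n_pools)) {
      rows <- which(pools == k)
      g[rows, ] <- stats::rbinom(length(rows) * L, 2L,
                                 rep(pool_p[k, ], each = length(rows)))
    }
    dimnames(g) <- list(sprintf("%s%s_%03d", prefix, pools, seq_len(n)),
                        locus_names)
    list(genotypes = g, pools = pools, ancestral_p = p_anc, pool_p = pool_p)
  })
}

#' Simulate pedigree offspring
#'
#' Offspring receive one allele per parent per locus (Mendelian
#' transmission); each resulting call is then corrupted with probability
#' `error_rate` by replacement with a uniformly chosen *different* genotype.
#' Missing parental genotypes transmit a fair-coin allele and are counted in
#' the `n_missing_transmitted` attribute.
#'
#' @param parents samples x loci dosage matrix of the candidate parents.
#' @param families list of `list(sire =, dam =, n_offspring =)` (row names of
#'   `parents`); unknown ids raise an error.
#' @param error_rate per-call error probability.
#' @param seed integer seed.
#' @return offspring dosage matrix with a `pedigree` attribute
#'   (data.frame `offspring`, `sire`, `dam`).
#' @export
simulate_pedigree <- function(parents, families, error_rate = 0, seed = 1) {
  ids <- rownames(parents)
  for (f in families) {
    if (!all(c(f$sire, f$dam) %in% ids))
      stop("unknown parent id in family: ", f$sire, " x ", f$dam)
  }
  L <- ncol(parents)
  withr::with_seed(seed, {
    off <- list(); ped <- list(); n_missing <- 0L; counter <- 0L
    for (f in families) {
      gs <- parents[f$sire, ]; gd <- parents[f$dam, ]
      for (k in seq_len(f$n_offspring)) {
        counter <- counter + 1L
        transmit <- function(g) {
          miss <- is.na(g)
          n_missing <<- n_missing + sum(miss)
          p <- ifelse(miss, 0.5, g / 2)
          stats::rbinom(L, 1L, p)
        }
        o <- transmit(gs) + transmit(gd)
        err <- stats::runif(L) < error_rate
        if (any(err)) {
          o[err] <- vapply(o[err], function(x) sample(setdiff(0:2, x), 1L),
                           integer(1))
        }
        id <- sprintf("OFF_%04d", counter)
        off[[id]] <- o
        ped[[id]] <- data.frame(offspring = id, sire = f$sire, dam = f$dam)
      }
    }
    g <- do.call(rbind, off)
    colnames(g) <- colnames(parents)
    attr(g, "pedigree") <- do.call(rbind, ped)
    attr(g, "n_missing_transmitted") <- n_missing
    g
  })
}

#' Signal model for intensity simulation
#'
#' Cluster geometry and noise of the two-channel signal. On the contrast
#' axis (`log2(A/B)`) diploid genotype clusters sit at
#' `cluster_contrast_means` (AA > 0 > BB, AB = 0) with standard deviation
#' `cluster_sd / quality`; the strength axis (`(log2 A + log2 B)/2`) is
#' `N(strength_mean * quality, strength_sd)`. Probes of species absent from
#' a reaction — and null-allele carriers at OTV loci — emit only background
#' signal at `crosstalk` times full strength. Defaults
#' (+1.5/0/-1.5, sd 0.15, strength 10, crosstalk 0.02) put a clean sample in
#' the well-separated-cluster regime.
#'
#' @param cluster_contrast_means contrasts of the AA/AB/BB clusters.
#' @param cluster_sd contrast standard deviation at quality 1.
#' @param strength_mean,strength_sd log2-intensity strength distribution at
#'   quality 1.
#' @param otv_fraction fraction of each species' SNPs carrying a segregating
#'   null allele (off-target variants).
#' @param null_allele_freq frequency of the null allele at those loci.
#' @param crosstalk background signal fraction of full strength.
#' @param tetraploid_means contrasts of the five dosage clusters (0..4 ALT
#'   copies) in tetraploid mode.
#' @param dqc_contrast expected contrast of a DQC probe (homozygous
#'   A-signal).
#' @return a `signal_model` list.
#' @export
signal_model <- function(cluster_contrast_means = c(1.5, 0, -1.5),
                         cluster_sd = 0.15,
                         strength_mean = 10, strength_sd = 0.25,
                         otv_fraction = 0.05, null_allele_freq = 0.2,
                         crosstalk = 0.02,
                         tetraploid_means = c(1.5, 0.75, 0, -0.75, -1.5),
                         dqc_contrast = 1.5) {
  stopifnot(cluster_contrast_means[1] > 0, cluster_contrast_means[2] == 0,
            cluster_contrast_means[3] < 0,
            cluster_sd > 0, strength_sd > 0, crosstalk >= 0)
  structure(list(cluster_contrast_means = cluster_contrast_means,
                 cluster_sd = cluster_sd, strength_mean = strength_mean,
                 strength_sd = strength_sd, otv_fraction = otv_fraction,
                 null_allele_freq = null_allele_freq, crosstalk = crosstalk,
                 tetraploid_means = tetraploid_means,
                 dqc_contrast = dqc_contrast),
            class = "signal_model")
}

#' Reaction plan for (pooled) genotyping reactions
#'
#' Each reaction holds one or two samples: at most one plant and at most one
#' fish (DNA of two distantly related taxa pooled in equal quantities). A
#' sample appears in exactly one reaction.
#'
#' @param members data.frame with columns `reaction_id`, `sample_id`,
#'   `species_id`.
#' @param taxon named character vector mapping species to taxon group
#'   (`"plant"`/`"fish"`).
#' @return a `reaction_plan` data.frame.
#' @export
reaction_plan <- function(members,
                          taxon = c(rubus = "plant", manuka = "plant",
                                    snapper = "fish", trevally = "fish",
                                    seabream = "fish", kingfish = "fish")) {
  stopifnot(all(c("reaction_id", "sample_id", "species_id") %in% names(members)))
  if (anyDuplicated(members$sample_id))
    stop("a sample may appear in exactly one reaction")
  unknown <- setdiff(unique(members$species_id), names(taxon))
  if (length(unknown))
    stop("species without taxon assignment: ", paste(unknown, collapse = ", "))
  members$taxon <- unname(taxon[members$species_id])
  tab <- table(members$reaction_id, members$taxon)
  if (any(tab > 1L))
    stop("a reaction may hold at most one plant and one fish sample")
  class(members) <- c("reaction_plan", "data.frame")
  members
}

#' Simulate two-channel probe intensities
#'
#' For each planned sample and each genotyping probe of its (effective)
#' species, a contrast is drawn around the genotype's cluster mean and a
#' strength around `strength_mean * quality`; channels are reconstructed as
#' `A = 2^(strength + contrast/2)`, `B = 2^(strength - contrast/2)` — the
#' exact inverse of the caller's transform. A seeded `otv_fraction` of each
#' species' SNPs segregates a null allele: carrier samples emit only
#' background-level strength there. Probes of species absent from a sample's
#' reaction sit at crosstalk background. DQC probes behave as fixed
#' homozygous A-signal probes. `species_map` lets a related species hybridize
#' to another species' probes (e.g. seabream on snapper probes) with a
#' per-sample `divergence` fraction of probes nulled, each behaving like an
#' OTV locus for that sample.
#'
#' @param manifest an `array_manifest`.
#' @param genotypes named list (species -> samples x loci dosage matrix whose
#'   columns are that species' genotyping probe ids).
#' @param plan a [reaction_plan()].
#' @param sig a [signal_model()].
#' @param quality named per-sample quality scalar in (0, 1]; default 1.
#' @param divergence named per-sample fraction of probes nulled; default 0.
#' @param species_map named character vector mapping a sample's species to
#'   the species whose probes it hybridizes (identity by default).
#' @param ploidy named per-species ploidy (2 or 4); default 2.
#' @param seed integer seed; identical seeds give bit-identical matrices.
#' @return an `intensity_matrix`: list with nonnegative matrices `a`, `b`
#'   (samples x probes), the `plan`, per-sample `species` (effective), and a
#'   `truth` list (`otv_loci`, `null_carrier` per species).
#' @export
simulate_intensities <- function(manifest, genotypes, plan, sig = signal_model(),
                                 quality = NULL, divergence = NULL,
                                 species_map = NULL, ploidy = NULL, seed = 1) {
  samples <- plan$sample_id
  qual <- stats::setNames(rep(1, length(samples)), samples)
  if (!is.null(quality)) qual[names(quality)] <- quality
  div <- stats::setNames(rep(0, length(samples)), samples)
  if (!is.null(divergence)) div[names(divergence)] <- divergence
  eff_species <- plan$species_id
  if (!is.null(species_map)) {
    mapped <- eff_species %in% names(species_map)
    eff_species[mapped] <- species_map[eff_species[mapped]]
  }
  names(eff_species) <- samples

  probes <- manifest$probe_id
  n <- length(samples); p <- length(probes)
  bg_strength <- sig$strength_mean + log2(max(sig$crosstalk, 1e-6))

  withr::with_seed(seed, {
    contrast <- matrix(stats::rnorm(n * p, 0, 0.5), n, p,
                       dimnames = list(samples, probes))
    strength <- matrix(stats::rnorm(n * p, bg_strength, 0.3), n, p,
                       dimnames = list(samples, probes))
    truth <- list(otv_loci = list(), null_carrier = list())
    for (sp in unique(eff_species)) {
      geno_cols <- which(manifest$species_id == sp & manifest$probe_type == "genotyping")
      dqc_cols <- which(manifest$species_id == sp & manifest$probe_type == "dqc")
      rows <- which(unname(eff_species) == sp)
      if (length(rows) == 0L) next
      g <- genotypes[[sp]]
      if (is.null(g)) stop("no genotypes supplied for species ", sp)
      pl <- if (!is.null(ploidy) && sp %in% names(ploidy)) ploidy[[sp]] else 2L
      means <- if (pl == 4L) sig$tetraploid_means else sig$cluster_contrast_means
      # seeded OTV designation, fixed per species
      n_otv <- round(sig$otv_fraction * length(geno_cols))
      otv_local <- if (n_otv > 0) sort(sample(length(geno_cols), n_otv)) else integer(0)
      truth$otv_loci[[sp]] <- manifest$probe_id[geno_cols][otv_local]
      carrier <- matrix(FALSE, length(rows), length(geno_cols),
                        dimnames = list(samples[rows], manifest$probe_id[geno_cols]))
      if (length(otv_local) > 0) {
        carrier[, otv_local] <- matrix(
          stats::rbinom(length(rows) * length(otv_local), 2, sig$null_allele_freq) > 0,
          length(rows), length(otv_local))
      }
      for (ri in seq_along(rows)) {
        s <- rows[ri]; sid <- samples[s]; q <- qual[sid]
        gvec <- g[sid, manifest$probe_id[geno_cols]]
        mu <- means[gvec + 1L]
        ctr <- stats::rnorm(length(geno_cols), mu, sig$cluster_sd / q)
        stn <- stats::rnorm(length(geno_cols), sig$strength_mean * q, sig$strength_sd)
        # null-allele carriers and diverged probes: background only
        nulled <- carrier[ri, ]
        if (div[sid] > 0) {
          extra <- stats::runif(length(geno_cols)) < div[sid]
          nulled <- nulled | extra
          carrier[ri, ] <- nulled
        }
        if (any(nulled)) {
          ctr[nulled] <- stats::rnorm(sum(nulled), 0, 0.5)
          stn[nulled] <- stats::rnorm(sum(nulled), bg_strength, 0.5)
        }
        contrast[s, geno_cols] <- ctr
        strength[s, geno_cols] <- stn
        if (length(dqc_cols) > 0) {
          contrast[s, dqc_cols] <- stats::rnorm(length(dqc_cols), sig$dqc_contrast,
                                                sig$cluster_sd / q)
          strength[s, dqc_cols] <- stats::rnorm(length(dqc_cols),
                                                sig$strength_mean * q, sig$strength_sd)
        }
      }
      truth$null_carrier[[sp]] <- carrier
    }
    a <- 2^(strength + contrast / 2)
    b <- 2^(strength - contrast / 2)
    structure(list(a = a, b = b, plan = plan, species = eff_species,
                   truth = truth, signal_model = sig),
              class = "intensity_matrix")
  })
}
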