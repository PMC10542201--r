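# Genotype calling, OTV recall, SNP classification, sample QC.

test_that("the contrast/strength transform is exact arithmetic", {
  im <- list(a = matrix(c(4, 2), 1), b = matrix(c(1, 2), 1))
  tr <- transform_intensities(im, eps = 0)
  expect_equal(tr$contrast[1, ], c(2, 0))
  expect_equal(tr$strength[1, ], c(1, 1))
})

test_that("well-separated clusters are called perfectly and monomorphic SNPs get k = 1", {
  set.seed(31)
  n <- 60
  g <- cbind(poly = sample(0:2, n, TRUE, prob = c(.36, .48, .16)),
             mono = rep(0L, n))
  priors <- c(1.5, 0, -1.5)
  contrast <- matrix(rnorm(2 * n, priors[g + 1L], 0.1), n, 2,
                     dimnames = list(sprintf("s%d", 1:n), colnames(g)))
  fit <- call_genotypes(contrast)
  expect_equal(unname(fit$calls[, "poly"]), unname(g[, "poly"]))
  expect_equal(fit$models$mono$k, 1L)
  expect_equal(fit$models$mono$levels, 0L)
  expect_equal(fit$models$poly$k, 3L)
})

test_that("low-confidence samples go missing and undersized SNPs stay uncalled", {
  set.seed(32)
  n <- 40
  x <- c(rnorm(n - 1, 1.5, 0.1), 0.75)  # last sample halfway between clusters
  contrast <- cbind(amb = x, tiny = rnorm(n, 0, 0.1))
  contrast_small <- contrast[1:10, , drop = FALSE]
  fit_small <- call_genotypes(contrast_small, min_samples = 20)
  expect_true(all(is.na(fit_small$calls)))
  expect_null(fit_small$models$amb)
})

test_that("OTV recall finds a low-strength cluster and leaves clean SNPs alone", {
  set.seed(33)
  n <- 80
  carriers <- 1:25
  contrast <- cbind(otv = c(rnorm(25, 0, 0.5), rnorm(55, 1.5, 0.15)),
                    clean = rnorm(n, 1.5, 0.15))
  strength <- cbind(otv = c(rnorm(25, 4.3, 0.5), rnorm(55, 10, 0.25)),
                    clean = rnorm(n, 10, 0.25))
  fit <- call_genotypes(contrast)
  fit <- call_otv(fit, strength)
  expect_true(fit$otv_flag[["otv"]])
  expect_false(fit$otv_flag[["clean"]])
  expect_true(all(fit$calls[carriers, "otv"] == OTV_CODE))
  expect_true(all(fit$calls[26:80, "otv"] != OTV_CODE, na.rm = TRUE))
})

test_that("SNP classification follows the category ladder", {
  # construct calls/models directly to exercise the pure category logic
  mk_fit <- function(calls, model, otv = FALSE) {
    structure(list(calls = matrix(calls, ncol = 1,
                                  dimnames = list(NULL, "s")),
                   models = list(s = model), priors = c(1.5, 0, -1.5),
                   otv_flag = c(s = otv)), class = "genotype_calls")
  }
  model3 <- list(levels = 0:2, mu = c(1.5, 0, -1.5), sd = rep(0.1, 3),
                 w = rep(1/3, 3), k = 3L)
  model2 <- list(levels = 0:1, mu = c(1.5, 0), sd = rep(0.1, 2),
                 w = c(.5, .5), k = 2L)
  model1 <- list(levels = 0L, mu = 1.5, sd = 0.1, w = 1, k = 1L)
  bad_sep <- list(levels = 0:1, mu = c(0.4, 0), sd = c(0.2, 0.2),
                  w = c(.5, .5), k = 2L)

  calls100 <- c(rep(0L, 50), rep(1L, 40), rep(2L, 10))
  expect_equal(classify_snp(mk_fit(calls100, model3))$category, "PolyHighResolution")
  # one minor homozygote only -> NoMinorHom
  calls_nmh <- c(rep(0L, 59), rep(1L, 40), 2L)
  expect_equal(classify_snp(mk_fit(calls_nmh, model3))$category, "NoMinorHom")
  expect_equal(classify_snp(mk_fit(c(rep(0L, 60), rep(1L, 40)), model2))$category,
               "NoMinorHom")
  expect_equal(classify_snp(mk_fit(rep(0L, 100), model1))$category,
               "MonoHighResolution")
  # call rate 90% < 97 -> CallRateBelowThreshold even when otv-flagged
  calls_cr <- c(rep(0L, 90), rep(NA_integer_, 10))
  expect_equal(classify_snp(mk_fit(calls_cr, model1, otv = TRUE))$category,
               "CallRateBelowThreshold")
  # otv flag wins over the shape categories at full call rate
  calls_otv <- c(rep(0L, 90), rep(OTV_CODE, 10))
  expect_equal(classify_snp(mk_fit(calls_otv, model1, otv = TRUE))$category, "OTV")
  expect_equal(classify_snp(mk_fit(c(rep(0L, 60), rep(1L, 40)), bad_sep))$category,
               "Other")
  # every SNP gets exactly one category
  cls <- classify_snp(mk_fit(calls100, model3))
  expect_equal(nrow(cls), 1L)
  expect_false(any(is.na(cls$category)))
})

test_that("a rare allele with no minor homozygotes classifies as NoMinorHom", {
  set.seed(35)
  n <- 100
  g <- rbinom(n, 2, 0.05)
  g[g == 2L] <- 1L                       # force minor homozygotes absent
  contrast <- cbind(s = rnorm(n, c(1.5, 0, -1.5)[g + 1L], 0.12))
  fit <- call_genotypes(contrast)
  expect_equal(classify_snp(fit)$category, "NoMinorHom")
})

test_that("tetraploid dosages are exact at low noise and HWE frequencies are recovered", {
  set.seed(36)
  n <- 150
  priors <- c(1.5, 0.75, 0, -0.75, -1.5)
  d <- rbinom(n, 4, 0.5)                 # HWE dosages 1:4:6:4:1
  contrast <- cbind(s1 = rnorm(n, priors[d + 1L], 0.08),
                    s2 = rnorm(n, priors[d + 1L], 0.08))
  fit <- call_dosage_tetraploid(contrast)
  conc <- mean(fit$calls[, "s1"] == d, na.rm = TRUE)
  expect_gte(conc, 0.98)
  called <- mean(!is.na(fit$calls[, "s1"]))
  expect_gte(called, 0.9)
})

test_that("diploid signal in tetraploid mode yields almost no intermediate dosages", {
  set.seed(37)
  n <- 150
  g2 <- sample(0:2, n, TRUE, prob = c(.3, .5, .2))       # diploid clusters
  contrast <- cbind(s = rnorm(n, c(1.5, 0, -1.5)[g2 + 1L], 0.08))
  fit <- call_dosage_tetraploid(contrast)
  calls <- fit$calls[!is.na(fit$calls)]
  expect_gt(length(calls), 0)
  expect_lt(mean(calls %in% c(1L, 3L)), 0.01)
})

test_that("DQC is 1 for clean samples and fails stage 1 below the 0.82 threshold", {
  man <- toy_manifest(n_snp = 40, n_dqc = 50)
  toy <- toy_intensities(man, n_samples = 30,
                         sig = signal_model(cluster_sd = 0.05,
                                            strength_sd = 0.05,
                                            otv_fraction = 0),
                         seed = 41)
  trans <- transform_intensities(toy$im)
  dqc <- compute_dqc(trans, man, toy$im$species)
  expect_true(all(dqc == 1))

  # boundary semantics: dqc = 0.82 passes, 0.80 fails
  res <- genotype_species(toy$im, man)
  qc <- res$sample_qc
  expect_true(all(qc$pass_stage1))
  th <- attr(qc, "thresholds")
  expect_true(0.82 >= th$dqc_min && !(0.80 >= th$dqc_min))
  expect_true(95 >= th$qccr_min)
})

test_that("allele deviation is near zero for clean samples and flags blended samples", {
  man <- toy_manifest(n_snp = 60, n_dqc = 10)
  sig <- signal_model(cluster_sd = 1e-4, strength_sd = 1e-4, otv_fraction = 0)
  toy <- toy_intensities(man, n_samples = 40, sig = sig, seed = 42)
  res <- genotype_species(toy$im, man)
  adm <- res$sample_qc$allele_deviation_mean
  expect_true(all(adm < 0.05))
  expect_true(all(res$sample_qc$pass_stage2))
  expect_true(all(res$sample_qc$call_rate == 100))
})

test_that("classification summaries reproduce the published accounting arithmetic", {
  # trevally-style counts: partition of 20,234 and conversion rate
  trevally <- rep(c("PolyHighResolution", "NoMinorHom", "OTV",
                    "MonoHighResolution", "CallRateBelowThreshold", "Other"),
                  c(10157, 1556, 2521, 146, 1100, 4754))
  s <- summarize_classification(trevally, "trevally")
  expect_equal(s$total, 20234L)
  expect_equal(sum(s$counts), s$total)
  expect_equal(s$conversion_rate, 58)

  # manuka-style counts: good-quality polymorphic share 68%
  manuka <- rep(c("PolyHighResolution", "OTV", "NoMinorHom",
                  "MonoHighResolution", "CallRateBelowThreshold", "Other"),
                c(4969, 1026, 124, 19, 761, 2103))
  m <- summarize_classification(manuka, "manuka")
  expect_equal(m$total, 9002L)
  expect_equal(m$polymorphic_good_rate, 68)

  # Rubus diploid-style counts: conversion 58%
  rubus <- rep(c("PolyHighResolution", "NoMinorHom", "OTV",
                 "MonoHighResolution", "Other", "CallRateBelowThreshold"),
               c(6141, 1211, 612, 1669, 2622, 468))
  expect_equal(summarize_classification(rubus, "rubus")$conversion_rate, 58)

  empty <- summarize_classification(character(0))
  expect_true(is.na(empty$conversion_rate))
  expect_equal(sum(empty$counts), 0L)
})

test_that("species splitting routes pooled reactions into both matrices", {
  fish_cand <- make_candidates("chr1", seq(1000, by = 500, length.out = 30),
                               species = "snapper")
  plant_cand <- make_candidates("chr1", seq(1000, by = 500, length.out = 30),
                                species = "manuka")
  man <- build_manifest(list(snapper = fish_cand, manuka = plant_cand))
  pf <- man$probe_id[man$species_id == "snapper" & man$probe_type == "genotyping"]
  pp <- man$probe_id[man$species_id == "manuka" & man$probe_type == "genotyping"]
  pmod <- pop_model(1, 0, samples_per_pool = 6)
  gf <- simulate_population_genotypes(pf, pmod, seed = 1, prefix = "F")$genotypes
  gp <- simulate_population_genotypes(pp, pmod, seed = 2, prefix = "P")$genotypes
  plan <- reaction_plan(data.frame(
    reaction_id = c(paste0("R", 1:6), paste0("R", 1:6), "R7"),
    sample_id = c(rownames(gf), rownames(gp)[1:6],
                  paste0(rownames(gp)[1], "x")),
    species_id = c(rep("snapper", 6), rep("manuka", 7))))
  gp2 <- rbind(gp[1:6, ], gp[1, , drop = FALSE])
  rownames(gp2) <- plan$sample_id[plan$species_id == "manuka"]
  im <- simulate_intensities(man, list(snapper = gf, manuka = gp2), plan, seed = 3)
  sp <- split_by_species(im, man)
  # each pooled reaction contributes members to exactly two matrices
  pooled <- intersect(plan$reaction_id[plan$species_id == "snapper"],
                      plan$reaction_id[plan$species_id == "manuka"])
  for (r in pooled) {
    mem <- plan$sample_id[plan$reaction_id == r]
    hits <- sum(mem %in% rownames(sp$snapper$a)) + sum(mem %in% rownames(sp$manuka$a))
    expect_equal(hits, 2L)
  }
  # fish-only samples are absent from the plant matrix
  expect_false(any(rownames(gf) %in% rownames(sp$manuka$a)))
  # probe columns conserved
  expect_equal(ncol(sp$snapper$a) + ncol(sp$manuka$a), nrow(man))
})

test_that("related-species divergence elevates the OTV flag rate", {
  man <- toy_manifest(n_snp = 120, n_dqc = 10)
  probes <- man$probe_id[man$probe_type == "genotyping"]
  pmod <- pop_model(1, 0, c(0.1, 0.5), samples_per_pool = 50)
  g <- simulate_population_genotypes(probes, pmod, seed = 95)$genotypes
  plan <- reaction_plan(data.frame(reaction_id = paste0("R", 1:50),
                                   sample_id = rownames(g),
                                   species_id = "snapper"))
  sig <- signal_model(otv_fraction = 0)
  rate_at <- function(divg) {
    div <- stats::setNames(rep(divg, 25), rownames(g)[26:50])
    im <- simulate_intensities(man, list(snapper = g), plan, sig = sig,
                               divergence = div, seed = 96)   # paired seed
    trans <- transform_intensities(im)
    fit <- call_genotypes(trans$contrast[, probes])
    fit <- call_otv(fit, trans$strength[, probes])
    mean(fit$otv_flag)
  }
  expect_gt(rate_at(0.3), rate_at(0))
})
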