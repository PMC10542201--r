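# Variant intake and the positional/LD filters of the design cascade.

make_vcf_records <- function() {
  # 20 records with controlled per-record statistics over 10 samples:
  # a mix of clean SNPs, an A/T and a C/G SNP, an indel, a multiallelic
  # record, a high-missing record, a high-depth record and a rare allele.
  gt_clean <- c(rep("0/0", 5), rep("0/1", 3), rep("1/1", 2))
  recs <- data.frame(
    chrom = rep("chr1", 20),
    pos = seq(100, by = 1000, length.out = 20),
    ref = rep(c("A", "C", "G", "T"), 5),
    alt = rep(c("C", "T", "A", "G"), 5),
    stringsAsFactors = FALSE
  )
  recs$gt <- rep(list(gt_clean), 20)
  recs$dp <- rep(list(rep(20, 10)), 20)
  recs$ref[3] <- "A"; recs$alt[3] <- "T"          # A/T exclusion
  recs$ref[4] <- "C"; recs$alt[4] <- "G"          # C/G exclusion
  recs$ref[5] <- "AT"; recs$alt[5] <- "A"         # indel
  recs$alt[6] <- "C,G"                            # multiallelic
  recs$gt[[7]] <- c(rep("./.", 4), rep("0/1", 6)) # 40% missing
  recs$dp[[8]] <- rep(500, 10)                    # depth 500
  recs$gt[[9]] <- c(rep("0/0", 9), "0/1")         # MAF 0.05 boundary
  recs$gt[[10]] <- rep("0/0", 10)                 # monomorphic, MAF 0
  recs
}

test_that("VCF records pass or fail each rule with the right single reason", {
  recs <- make_vcf_records()
  path <- withr::local_tempfile(fileext = ".vcf")
  write_test_vcf(recs, path)
  params <- filter_params(max_missing = 0.2, max_depth = 100, min_maf = 0.05)
  cand <- filter_variants(path, params, species_id = "toy")

  expect_equal(nrow(cand), 20L)
  expect_equal(cand$pos, recs$pos)  # input order preserved
  expect_equal(cand$status[3], "removed:at_cg_exclusion")
  expect_equal(cand$status[4], "removed:at_cg_exclusion")
  expect_equal(cand$status[5], "removed:not_snp")
  expect_equal(cand$status[6], "removed:multiallelic")
  expect_equal(cand$status[7], "removed:missing")
  expect_equal(cand$status[8], "removed:depth")
  expect_equal(cand$status[9], "active")  # MAF exactly at the floor passes
  expect_equal(cand$status[10], "removed:maf")

  # independent record-by-record oracle over the same description
  oracle_active <- vapply(seq_len(20), function(i) {
    gt <- recs$gt[[i]]
    if (nchar(recs$ref[i]) != 1 || grepl(",", recs$alt[i]) ||
        nchar(recs$alt[i]) != 1) return(FALSE)
    called <- gt != "./."
    if (mean(!called) > params$max_missing) return(FALSE)
    if (mean(recs$dp[[i]]) > params$max_depth) return(FALSE)
    alt_n <- sum(vapply(strsplit(gt[called], "/"), function(a) sum(a == "1"),
                        numeric(1)))
    p <- alt_n / (2 * sum(called))
    if (min(p, 1 - p) < params$min_maf) return(FALSE)
    pair <- sort(c(recs$ref[i], recs$alt[i]))
    !(identical(pair, c("A", "T")) || identical(pair, c("C", "G")))
  }, logical(1))
  expect_equal(cand$status == "active", oracle_active)

  # site statistics computed from the genotype matrix
  expect_equal(cand$missing_rate[7], 0.4)
  expect_equal(cand$mean_depth[8], 500)
  expect_equal(cand$maf[1], 7 / 20)
})

test_that("an empty VCF yields an empty candidate table", {
  path <- withr::local_tempfile(fileext = ".vcf")
  write_test_vcf(make_vcf_records()[0, , drop = FALSE], path, n_samples = 2)
  cand <- filter_variants(path)
  expect_s3_class(cand, "snp_candidates")
  expect_equal(nrow(cand), 0L)
})

test_that("proximity thinning matches the forced examples in both modes", {
  cand <- make_candidates("chr1", c(100, 120, 200))
  ex <- thin_by_proximity(cand, 30, mode = "exclusive")
  expect_equal(active_candidates(ex)$pos, 200)
  expect_equal(removed_candidates(ex)$reason, rep("proximity", 2))
  kf <- thin_by_proximity(cand, 30, mode = "keep_first")
  expect_equal(active_candidates(kf)$pos, c(100, 200))
  expect_error(thin_by_proximity(cand, -1), "nonnegative")
})

test_that("exclusive thinning equals the all-pairs distance oracle and is idempotent", {
  pos <- withr::with_seed(42, sort(sample(1:20000, 500)))
  cand <- make_candidates(rep(c("chr1", "chr2"), length.out = 500), pos)
  out <- thin_by_proximity(cand, 30, mode = "exclusive")
  # O(n^2) oracle: keep iff no other SNP on the same chrom within < 30 bp
  keep_oracle <- vapply(seq_len(500), function(i) {
    same <- cand$chrom == cand$chrom[i]
    d <- abs(cand$pos[same] - cand$pos[i])
    sum(d < 30) == 1L   # only itself
  }, logical(1))
  expect_equal(out$status == "active", keep_oracle)
  again <- thin_by_proximity(out, 30, mode = "exclusive")
  expect_equal(again$status, out$status)
})

test_that("LD pruning drops duplicated columns and matches a brute-force greedy oracle", {
  n <- 120
  g <- withr::with_seed(1, matrix(rbinom(n * 2, 2, 0.4), n, 2))
  g[, 2] <- g[, 1]                        # perfect duplicate
  cand <- make_candidates("chr1", c(100, 5000))
  out <- prune_ld(g, cand, filter_params(ld_r2_max = 0.2, ld_window = 50))
  expect_equal(out$status, c("active", "removed:ld"))

  # 50-SNP toy matrix with blocks of correlated SNPs
  set.seed(7)
  base <- matrix(rbinom(80 * 10, 2, 0.5), 80, 10)
  g50 <- base[, rep(1:10, each = 5)]
  flip <- matrix(runif(80 * 50) < 0.15, 80, 50)
  g50[flip] <- (g50[flip] + sample(1:2, sum(flip), replace = TRUE)) %% 3
  cand50 <- make_candidates("chr1", seq(100, by = 200, length.out = 50))
  params <- filter_params(ld_r2_max = 0.2, ld_window = 10)
  out50 <- prune_ld(g50, cand50, params)
  # independent oracle: same contract, separate implementation
  kept <- integer(0)
  for (j in 1:50) {
    drop <- FALSE
    for (i in kept) {
      if (j - i <= params$ld_window) {
        r2 <- suppressWarnings(cor(g50[, i], g50[, j],
                                   use = "pairwise.complete.obs"))^2
        if (!is.na(r2) && r2 > params$ld_r2_max) drop <- TRUE
      }
    }
    if (!drop) kept <- c(kept, j)
  }
  expect_equal(which(out50$status == "active"), kept)
})

test_that("independent columns survive LD pruning and monomorphic columns are kept", {
  n <- 200
  g <- withr::with_seed(11, matrix(rbinom(n * 100, 2, 0.5), n, 100))
  g[, 13] <- 1L  # monomorphic: r^2 undefined, treated as 0
  cand <- make_candidates("chr1", seq(1, by = 1000, length.out = 100))
  out <- prune_ld(g, cand, filter_params(ld_r2_max = 0.2, ld_window = 50))
  expect_gte(mean(out$status == "active"), 0.95)
  expect_equal(out$status[13], "active")
  expect_gte(attr(out, "monomorphic"), 1L)
})

test_that("pool-MAF classification follows the first matching rule", {
  pools <- c("NNI", "CSNI", "ECNI", "NESI", "SWSI")
  pm <- as.data.frame(matrix(0, 3, 5, dimnames = list(NULL, pools)))
  pm$NNI <- c(0.40, 0, 0.2)
  pm$CSNI[3] <- 0.2
  cand <- snp_candidates("manuka", "chr1", c(10, 20, 30), "A", "C",
                         pool_maf = pm)
  rules <- list(
    NNI = function(maf) maf["NNI"] >= 0.05 && all(maf[setdiff(names(maf), "NNI")] < 0.05),
    NI_shared = function(maf) all(maf[c("NNI", "CSNI")] >= 0.05)
  )
  expect_equal(classify_by_pool_maf(cand, rules),
               c("NNI", NA, "NI_shared"))
  expect_error(classify_by_pool_maf(cand, rules, pools = c("NNI", "XX")),
               "unknown pool")
})

test_that("simulated candidates get the same class labels as a per-candidate predicate oracle", {
  pools <- c("P1", "P2", "P3")
  n <- 1000
  pm <- withr::with_seed(3, as.data.frame(matrix(runif(n * 3, 0, 0.5), n, 3,
                                                 dimnames = list(NULL, pools))))
  cand <- snp_candidates("sp", "chr1", seq_len(n), "A", "C", pool_maf = pm)
  t <- 0.1
  rules <- list(
    common_all = function(maf) all(maf >= t),
    private_P1 = function(maf) maf["P1"] >= t && all(maf[c("P2", "P3")] < t),
    private_P2 = function(maf) maf["P2"] >= t && all(maf[c("P1", "P3")] < t),
    rare_everywhere = function(maf) all(maf < 0.05)
  )
  got <- classify_by_pool_maf(cand, rules)
  oracle <- apply(as.matrix(pm), 1, function(m) {
    if (all(m >= t)) "common_all"
    else if (m[1] >= t && m[2] < t && m[3] < t) "private_P1"
    else if (m[2] >= t && m[1] < t && m[3] < t) "private_P2"
    else if (all(m < 0.05)) "rare_everywhere"
    else NA_character_
  })
  expect_equal(got, unname(oracle))
})

test_that("even random selection fills bins round-robin and is seed-stable", {
  cand <- make_candidates("chr1", seq(1, 10000, by = 10))  # uniform density
  sel_all <- select_even_random(cand, 5000, genome_bins = 1000, seed = 1)
  expect_equal(nrow(sel_all), nrow(cand))                  # n >= available
  # 10 bins of width 1000 -> n = 10 picks exactly one per bin
  sel10 <- select_even_random(cand, 10, genome_bins = 1000, seed = 1)
  expect_equal(nrow(sel10), 10L)
  expect_equal(sort(unique((sel10$pos - 1) %/% 1000)), 0:9)
  # deterministic per seed, different across seeds
  again <- select_even_random(cand, 10, genome_bins = 1000, seed = 1)
  expect_identical(sel10$pos, again$pos)
  other <- select_even_random(cand, 10, genome_bins = 1000, seed = 2)
  expect_false(identical(sel10$pos, other$pos))
})

test_that("the published selection size is reproduced from the recommended pool", {
  n_rec <- 33484
  cand <- make_candidates(sprintf("chr%d", rep(1:11, length.out = n_rec)),
                          rep(seq(1, 3.05e6, by = 1000), length.out = n_rec))
  sel <- select_even_random(cand, 9002, genome_bins = 1e5, seed = 4)
  expect_equal(nrow(sel), 9002L)
  expect_true(all(sel$status == "active"))
})
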