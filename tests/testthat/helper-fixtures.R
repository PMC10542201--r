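# Fixture builders shared across the test files. Everything is generated in
# code; no binary fixtures.

# Write a minimal VCF with GT:DP per sample from a record description.
# records: data.frame with chrom, pos, ref, alt and a list-column `gt` of
# character vectors (one genotype string per sample, "./." = missing) and
# `dp` of numeric vectors.
write_test_vcf <- function(records, path, n_samples = NULL) {
  if (is.null(n_samples)) n_samples <- length(records$gt[[1]])
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sprintf("S%02d", seq_len(n_samples))), collapse = "\t"))
  body <- vapply(seq_len(nrow(records)), function(i) {
    fields <- paste(records$gt[[i]], records$dp[[i]], sep = ":")
    paste(c(records$chrom[i], records$pos[i], ".", records$ref[i],
            records$alt[i], ".", "PASS", ".", "GT:DP", fields), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  path
}

# Random ACGT genome as a DNAStringSet
random_genome <- function(lengths, seed = 1) {
  withr::with_seed(seed, {
    seqs <- vapply(lengths, function(L)
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
      character(1))
    g <- Biostrings::DNAStringSet(seqs)
    names(g) <- names(lengths) %||% sprintf("chr%d", seq_along(lengths))
    g
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Quick candidate table with valid distinct non-complementary alleles
make_candidates <- function(chrom, pos, species = "sp", ref = NULL, alt = NULL) {
  n <- length(pos)
  if (is.null(ref)) ref <- rep(c("A", "C", "G", "T"), length.out = n)
  if (is.null(alt)) alt <- rep(c("C", "A", "T", "G"), length.out = n)
  snp_candidates(species, chrom, pos, ref, alt)
}

# One-species manifest: `n_snp` genotyping probes plus `n_dqc` DQC probes
# (dummy coordinates; signal-level tests do not need sequence).
toy_manifest <- function(species = "snapper", n_snp = 200, n_dqc = 40) {
  cand <- make_candidates("chr1", seq(1000, by = 500, length.out = n_snp),
                          species = species)
  dqc <- data.frame(probe_id = sprintf("DQC_%s_%03d", species, seq_len(n_dqc)),
                    species_id = species, probe_type = "dqc", chrom = "chrZ",
                    pos = seq(100, by = 200, length.out = n_dqc),
                    allele_ref = NA_character_, allele_alt = NA_character_,
                    flank121 = NA_character_, stringsAsFactors = FALSE)
  build_manifest(stats::setNames(list(cand), species), dqc)
}

# Simulate genotypes + intensities + a single-species plan for a manifest
toy_intensities <- function(man, species = "snapper", n_samples = 60,
                            sig = signal_model(), quality = NULL, seed = 1,
                            pop = NULL) {
  probes <- man$probe_id[man$species_id == species & man$probe_type == "genotyping"]
  if (is.null(pop))
    pop <- pop_model(n_pools = 1, fst_target = 0, samples_per_pool = n_samples,
                     ancestral_maf_range = c(0.1, 0.5))
  sim <- simulate_population_genotypes(probes, pop, seed = seed)
  g <- sim$genotypes
  plan <- reaction_plan(data.frame(reaction_id = paste0("R", seq_len(nrow(g))),
                                   sample_id = rownames(g),
                                   species_id = species))
  im <- simulate_intensities(man, stats::setNames(list(g), species), plan,
                             sig = sig, quality = quality, seed = seed + 1)
  list(im = im, genotypes = g, plan = plan, sim = sim)
}
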