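# Array manifest assembly: genotyping probes from per-species selections,
# Dish Quality Control (DQC) probes from non-polymorphic genome windows.

#' Design Dish Quality Control probes
#'
#' Samples `n_per_species` non-overlapping 121-base windows from
#' non-polymorphic genome locations: a window may not overlap any known
#' variant position and may not contain a non-ACGT base. Sampling is seeded
#' and exhaustive — if fewer clean windows than requested exist, the error
#' reports the achievable count.
#'
#' @param genome FASTA path or `DNAStringSet` for one species.
#' @param variant_positions data.frame with columns `chrom`, `pos`: the union
#'   of all known variants for that species.
#' @param n_per_species number of probes to design.
#' @param species_id label used in probe ids.
#' @param probe_len window length (default 121).
#' @param seed integer seed.
#' @return data.frame of DQC probe entries (`probe_id`, `species_id`,
#'   `probe_type = "dqc"`, `chrom`, `pos` (window center), `flank121`).
#' @export
design_dqc_probes <- function(genome, variant_positions, n_per_species,
                              species_id = "species", probe_len = 121, seed = 1) {
  genome <- .as_genome(genome)
  starts <- list()
  for (chrom in names(genome)) {
    L <- Biostrings::width(genome)[match(chrom, names(genome))]
    if (L < probe_len) next
    s <- strsplit(toupper(as.character(genome[[chrom]])), "")[[1]]
    bad <- as.integer(!(s %in% c("A", "C", "G", "T")))
    vp <- sort(variant_positions$pos[variant_positions$chrom == chrom])
    varmask <- integer(L)
    varmask[vp[vp >= 1 & vp <= L]] <- 1L
    cum_bad <- cumsum(bad)
    cum_var <- cumsum(varmask)
    st <- seq_len(L - probe_len + 1L)
    en <- st + probe_len - 1L
    clean <- (cum_bad[en] - c(0, cum_bad)[st]) == 0L &
      (cum_var[en] - c(0, cum_var)[st]) == 0L
    if (any(clean)) starts[[chrom]] <- st[clean]
  }
  all_starts <- do.call(rbind, lapply(names(starts), function(ch)
    data.frame(chrom = ch, start = starts[[ch]], stringsAsFactors = FALSE)))
  if (is.null(all_starts)) all_starts <- data.frame(chrom = character(), start = integer())

  chosen <- withr::with_seed(seed, {
    ord <- sample.int(nrow(all_starts))
    taken <- list()   # per chrom, accepted starts
    sel <- integer(0)
    for (idx in ord) {
      ch <- all_starts$chrom[idx]; st <- all_starts$start[idx]
      prev <- taken[[ch]]
      if (is.null(prev) || all(abs(prev - st) >= probe_len)) {
        taken[[ch]] <- c(prev, st)
        sel <- c(sel, idx)
        if (length(sel) == n_per_species) break
      }
    }
    sel
  })
  if (length(chosen) < n_per_species)
    stop("insufficient non-polymorphic sequence: requested ", n_per_species,
         " DQC probes but only ", length(chosen), " achievable")
  ch <- all_starts$chrom[chosen]
  st <- all_starts$start[chosen]
  half <- (probe_len - 1L) %/% 2L
  flank <- vapply(seq_along(chosen), function(k)
    as.character(Biostrings::subseq(genome[[ch[k]]], st[k], st[k] + probe_len - 1L)),
    character(1))
  data.frame(
    probe_id = sprintf("DQC_%s_%04d", species_id, seq_along(chosen)),
    species_id = species_id,
    probe_type = "dqc",
    chrom = ch,
    pos = st + half,
    allele_ref = NA_character_,
    allele_alt = NA_character_,
    flank121 = flank,
    stringsAsFactors = FALSE
  )
}

#' Assemble the multi-species array manifest
#'
#' Concatenates per-species genotyping selections and DQC probes into one
#' manifest. Genotyping entries carry both alleles and (when available) the
#' 121-base probe window with the variant at index 61; DQC entries carry no
#' alleles. Probe ids must be unique across the whole array.
#'
#' @param per_species_selections named list (species -> `snp_candidates` of
#'   selected, active candidates).
#' @param dqc_probes optional data.frame from [design_dqc_probes()] (several
#'   species may be row-bound).
#' @param seed optional seed recorded in the manifest metadata.
#' @return an `array_manifest` data.frame with columns `probe_id`,
#'   `species_id`, `probe_type`, `chrom`, `pos`, `allele_ref`, `allele_alt`,
#'   `flank121`; per-species counts via [manifest_counts()].
#' @export
build_manifest <- function(per_species_selections, dqc_probes = NULL, seed = NULL) {
  entries <- list()
  for (sp in names(per_species_selections)) {
    sel <- active_candidates(per_species_selections[[sp]])
    if (nrow(sel) == 0L) next
    entries[[sp]] <- data.frame(
      probe_id = sprintf("AX_%s_%s_%d", sp, sel$chrom, sel$pos),
      species_id = sp,
      probe_type = "genotyping",
      chrom = sel$chrom,
      pos = sel$pos,
      allele_ref = sel$ref,
      allele_alt = sel$alt,
      flank121 = .flank121(sel),
      stringsAsFactors = FALSE
    )
  }
  man <- do.call(rbind, c(entries, list(dqc_probes)))
  if (is.null(man))
    man <- data.frame(probe_id = character(), species_id = character(),
                      probe_type = character(), chrom = character(),
                      pos = integer(), allele_ref = character(),
                      allele_alt = character(), flank121 = character(),
                      stringsAsFactors = FALSE)
  rownames(man) <- NULL
  dup <- duplicated(man$probe_id)
  if (any(dup))
    stop("duplicate probe id(s): ", paste(utils::head(unique(man$probe_id[dup]), 5),
                                          collapse = ", "))
  bad_geno <- man$probe_type == "genotyping" &
    (is.na(man$allele_ref) | is.na(man$allele_alt))
  if (any(bad_geno)) stop("genotyping entries must carry both alleles")
  if (any(man$probe_type == "dqc" & (!is.na(man$allele_ref) | !is.na(man$allele_alt))))
    stop("dqc entries must not carry alleles")
  attr(man, "seed") <- seed
  class(man) <- c("array_manifest", "data.frame")
  man
}

#' Per-species probe counts of a manifest
#'
#' @param manifest an `array_manifest`.
#' @return data.frame with per-species genotyping and dqc probe counts plus a
#'   `total` row.
#' @export
manifest_counts <- function(manifest) {
  sp <- unique(manifest$species_id)
  rows <- lapply(sp, function(s) {
    data.frame(species_id = s,
               genotyping = sum(manifest$species_id == s &
                                  manifest$probe_type == "genotyping"),
               dqc = sum(manifest$species_id == s & manifest$probe_type == "dqc"))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(species_id = character(),
                                      genotyping = integer(), dqc = integer())
  rbind(out, data.frame(species_id = "total",
                        genotyping = sum(out$genotyping), dqc = sum(out$dqc)))
}

#' Write / read a manifest as TSV
#'
#' @param manifest an `array_manifest`.
#' @param path file path.
#' @return `read_manifest` returns an `array_manifest`.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.table(manifest, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  man <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = "character", stringsAsFactors = FALSE)
  man$pos <- as.integer(man$pos)
  man$allele_ref[man$allele_ref == "NA" | man$allele_ref == ""] <- NA
  man$allele_alt[man$allele_alt == "NA" | man$allele_alt == ""] <- NA
  class(man) <- c("array_manifest", "data.frame")
  man
}
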