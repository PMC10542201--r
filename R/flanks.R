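# Flank extraction from reference genomes and the probe-quality proxy score.

#' Extract 60 bp flanks from a reference genome
#'
#' Fills `flank_up` (the 60 bases ending at `pos - 1`) and `flank_down` (the
#' 60 bases starting at `pos + 1`), 1-based inclusive. Candidates too close
#' to a scaffold end (`pos <= edge_min_bp` or `pos > len - edge_min_bp`) are
#' marked `removed:edge`; candidates whose reference base does not match
#' `ref` are marked `removed:ref_mismatch`.
#'
#' @param candidates a `snp_candidates` data.frame.
#' @param genome FASTA path or `Biostrings::DNAStringSet`; must contain every
#'   active candidate's chromosome (error otherwise, naming the candidate).
#' @param edge_min_bp minimum distance from either scaffold end (default 60,
#'   the flank length).
#' @return candidates with flanks filled on surviving rows.
#' @export
extract_flanks <- function(candidates, genome, edge_min_bp = 60) {
  genome <- .as_genome(genome)
  act <- which(candidates$status == "active")
  if (length(act) == 0L) return(candidates)
  lens <- stats::setNames(Biostrings::width(genome), names(genome))
  for (i in act) {
    chrom <- candidates$chrom[i]
    if (!chrom %in% names(genome))
      stop("chromosome '", chrom, "' of candidate ", candidates$species_id[i],
           ":", chrom, ":", candidates$pos[i], " not found in genome")
    pos <- candidates$pos[i]
    L <- lens[[chrom]]
    if (pos <= edge_min_bp || pos > L - edge_min_bp) {
      candidates <- .mark_removed(candidates, i, "edge")
      next
    }
    seq <- genome[[chrom]]
    ref_base <- as.character(Biostrings::subseq(seq, pos, pos))
    if (!identical(toupper(ref_base), candidates$ref[i])) {
      candidates <- .mark_removed(candidates, i, "ref_mismatch")
      next
    }
    candidates$flank_up[i] <- as.character(Biostrings::subseq(seq, pos - 60L, pos - 1L))
    candidates$flank_down[i] <- as.character(Biostrings::subseq(seq, pos + 1L, pos + 60L))
  }
  validate_candidates(candidates)
  candidates
}

# 121-base probe window (flank_up + ref + flank_down); variant at index 61
.flank121 <- function(candidates) {
  ifelse(is.na(candidates$flank_up) | is.na(candidates$flank_down),
         NA_character_,
         paste0(candidates$flank_up, candidates$ref, candidates$flank_down))
}

#' Probe convertibility proxy score
#'
#' A deterministic stand-in for a vendor probe score. A candidate is
#' `recommended` when all three conditions hold:
#' 1. no IUPAC ambiguity code ("wobble") in either flank;
#' 2. no other known variant inside the 121-base probe window
#'    ("poly count = 0");
#' 3. proxy score `> 0.6`.
#'
#' The proxy score starts at 1 and subtracts two documented penalties over
#' the 121-base window: `2 * max(0, |GC - 0.5| - 0.2)` (no penalty while GC
#' is within `[0.3, 0.7]`) and `0.1 * max(0, run - 6)` where `run` is the
#' longest homopolymer; the result is clamped to `[0, 1]`.
#'
#' @param candidates a `snp_candidates` data.frame with flanks present on
#'   active rows (error otherwise).
#' @param nearby_variants data.frame of known variant positions with columns
#'   `chrom`, `pos` (the candidates themselves need not be excluded; a
#'   candidate's own position does not count against it).
#' @return data.frame with columns `recommended` (logical) and `score`.
#' @export
score_probe_proxy <- function(candidates, nearby_variants = NULL) {
  act_flags <- candidates$status == "active"
  if (any(act_flags & (is.na(candidates$flank_up) | is.na(candidates$flank_down))))
    stop("flanks must be present before probe scoring")
  n <- nrow(candidates)
  rec <- rep(NA, n)
  score <- rep(NA_real_, n)
  for (i in which(act_flags)) {
    window <- paste0(candidates$flank_up[i], candidates$ref[i], candidates$flank_down[i])
    gc <- .gc_fraction(window)
    run <- .max_homopolymer(window)
    s <- 1 - 2 * max(0, abs(gc - 0.5) - 0.2) - 0.1 * max(0, run - 6)
    s <- min(1, max(0, s))
    score[i] <- s
    wobble <- .has_wobble(candidates$flank_up[i]) || .has_wobble(candidates$flank_down[i])
    poly <- 0L
    if (!is.null(nearby_variants)) {
      same <- nearby_variants$chrom == candidates$chrom[i] &
        abs(nearby_variants$pos - candidates$pos[i]) <= 60 &
        nearby_variants$pos != candidates$pos[i]
      poly <- sum(same)
    }
    rec[i] <- !wobble && poly == 0L && s > 0.6
  }
  data.frame(recommended = rec, score = score)
}

#' Drop candidates whose probes are not recommended
#'
#' Convenience wrapper around [score_probe_proxy()] marking non-recommended
#' active candidates `removed:not_recommended`.
#'
#' @inheritParams score_probe_proxy
#' @return candidates with non-recommended rows removed.
#' @export
filter_recommended_probes <- function(candidates, nearby_variants = NULL) {
  sc <- score_probe_proxy(candidates, nearby_variants)
  bad <- which(!is.na(sc$recommended) & !sc$recommended)
  .mark_removed(candidates, bad, "not_recommended")
}
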