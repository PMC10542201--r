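# Sequence-similarity screens: cross-taxon cross-hybridization removal and
# the secondary-genome uniqueness check.

# Karlin-Altschul parameters for ungapped nucleotide scoring at
# match +1 / mismatch -2 (blastn-like defaults)
.KA_LAMBDA <- 1.33
.KA_K <- 0.621

.subst_mat <- function() {
  Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                           baseOnly = TRUE)
}

# seeded local-alignment search of one query against one subject sequence.
# Returns best hit as list(score, identity) or NULL. Seeds are exact
# word_size-mers; each seed neighborhood is locally aligned with
# Smith-Waterman (Biostrings::pairwiseAlignment).
.seeded_best_hit <- function(query, subject, word_size = 11) {
  q <- toupper(query)
  n_kmer <- nchar(q) - word_size + 1L
  if (n_kmer < 1L) return(NULL)
  kmers <- substring(q, seq_len(n_kmer), seq_len(n_kmer) + word_size - 1L)
  kmers <- unique(kmers[!vapply(kmers, .has_wobble, logical(1))])
  if (length(kmers) == 0L) return(NULL)
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(kmers))
  hits <- Biostrings::matchPDict(pd, subject)
  starts <- unlist(lapply(hits, IRanges::start), use.names = FALSE)
  if (length(starts) == 0L) return(NULL)
  margin <- nchar(q) + 10L
  win <- IRanges::reduce(IRanges::IRanges(pmax(1L, starts - margin),
                                          pmin(length(subject), starts + margin)))
  best <- NULL
  qd <- Biostrings::DNAString(q)
  for (w in seq_along(win)) {
    sub <- Biostrings::subseq(subject, IRanges::start(win)[w], IRanges::end(win)[w])
    aln <- Biostrings::pairwiseAlignment(qd, sub, type = "local",
                                         substitutionMatrix = .subst_mat(),
                                         gapOpening = 5, gapExtension = 2)
    sc <- Biostrings::score(aln)
    if (is.null(best) || sc > best$score) {
      best <- list(score = sc, identity = Biostrings::pid(aln, type = "PID1") / 100)
    }
  }
  best
}

# Karlin-Altschul E-value for an ungapped-scaled local alignment score
.ka_evalue <- function(score, query_len, db_len) {
  .KA_K * query_len * db_len * exp(-.KA_LAMBDA * score)
}

#' Screen candidate probes against other-taxon genomes
#'
#' Removes candidates whose 121-base probe window shows high similarity to
#' any genome of the other taxon group (plants screened against fish genomes
#' and vice versa), to prevent cross-hybridization in pooled reactions. Both
#' strands are searched by a seeded local alignment (exact `word_size`-mer
#' seeds extended with Smith-Waterman); a candidate is removed when some hit
#' has E-value `<= evalue` *and* identity `>= identity` over the aligned
#' span. E-values use the Karlin-Altschul formula with fixed nucleotide
#' parameters (lambda = 1.33, K = 0.621 for match +1 / mismatch -2) and
#' database length equal to the total other-taxon genome length. The
#' contract is alignment-engine agnostic: an external aligner honoring the
#' same thresholds may back it.
#'
#' @param candidates a `snp_candidates` data.frame with flanks on active rows.
#' @param other_genomes list of FASTA paths or `DNAStringSet`s of the other
#'   taxon group only. Empty list: no-op with a warning.
#' @param evalue E-value threshold (default 1e-5).
#' @param identity identity threshold as a fraction (default 0.8).
#' @param word_size seed length for hit detection (default 11).
#' @return candidates with hits marked `removed:cross_hyb`; the removal log
#'   distinguishes retained vs removed.
#' @export
screen_cross_hybridization <- function(candidates, other_genomes,
                                       evalue = 1e-5, identity = 0.8,
                                       word_size = 11) {
  if (length(other_genomes) == 0L) {
    warning("no other-taxon genomes supplied; cross-hybridization screen skipped")
    return(candidates)
  }
  genomes <- lapply(other_genomes, .as_genome)
  db_len <- sum(vapply(genomes, function(g) sum(Biostrings::width(g)), numeric(1)))
  act <- which(candidates$status == "active")
  flk <- .flank121(candidates)
  if (any(is.na(flk[act])))
    stop("flanks must be present before the cross-hybridization screen")
  for (i in act) {
    q_fwd <- flk[i]
    q_rev <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(q_fwd)))
    hit <- FALSE
    for (g in genomes) {
      for (chrom in seq_along(g)) {
        subject <- g[[chrom]]
        for (q in c(q_fwd, q_rev)) {
          b <- .seeded_best_hit(q, subject, word_size = word_size)
          if (!is.null(b)) {
            e <- .ka_evalue(b$score, nchar(q), db_len)
            if (e <= evalue && b$identity >= identity) { hit <- TRUE; break }
          }
        }
        if (hit) break
      }
      if (hit) break
    }
    if (hit) candidates <- .mark_removed(candidates, i, "cross_hyb")
  }
  candidates
}

#' Check probe uniqueness against a secondary genome
#'
#' Retains a candidate only when its 121-base probe window aligns to the
#' secondary genome (either strand, full length, no indels) at *exactly one
#' best location* with at most `max_mismatch` mismatches. Candidates with no
#' such hit ("no hits") or with more than `max_mismatch` mismatches at every
#' location are removed, as are candidates whose best mismatch count is
#' achieved at several locations (ambiguous placement).
#'
#' @param candidates a `snp_candidates` data.frame with flanks on active rows.
#' @param secondary_genome FASTA path or `DNAStringSet`.
#' @param max_mismatch maximum Hamming mismatches over the full window
#'   (default 1).
#' @return candidates with failing rows marked `removed:secondary_genome`.
#' @export
check_secondary_genome <- function(candidates, secondary_genome, max_mismatch = 1) {
  genome <- .as_genome(secondary_genome)
  act <- which(candidates$status == "active")
  flk <- .flank121(candidates)
  if (any(is.na(flk[act])))
    stop("flanks must be present before the secondary-genome check")
  for (i in act) {
    mm_counts <- integer(0)
    qd <- Biostrings::DNAString(flk[i])
    for (q in list(qd, Biostrings::reverseComplement(qd))) {
      for (chrom in seq_along(genome)) {
        m <- Biostrings::matchPattern(q, genome[[chrom]], max.mismatch = max_mismatch)
        if (length(m) == 0L) next
        qs <- strsplit(as.character(q), "")[[1]]
        for (h in seq_along(m)) {
          hs <- strsplit(as.character(m[[h]]), "")[[1]]
          if (length(hs) == length(qs)) mm_counts <- c(mm_counts, sum(hs != qs))
        }
      }
    }
    ok <- length(mm_counts) > 0L && sum(mm_counts == min(mm_counts)) == 1L &&
      min(mm_counts) <= max_mismatch
    if (!ok) candidates <- .mark_removed(candidates, i, "secondary_genome")
  }
  candidates
}
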