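# Shared internal helpers.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; array reports conventionally round
#' half up, so percentage tables use this helper.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# fraction of GC bases in an ACGT string
.gc_fraction <- function(s) {
  chars <- strsplit(toupper(s), "", fixed = TRUE)[[1]]
  mean(chars %in% c("G", "C"))
}

# length of the longest single-base run
.max_homopolymer <- function(s) {
  chars <- strsplit(toupper(s), "", fixed = TRUE)[[1]]
  if (length(chars) == 0L) return(0L)
  max(rle(chars)$lengths)
}

.IUPAC <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "N")

.is_iupac_string <- function(s) {
  chars <- strsplit(toupper(s), "", fixed = TRUE)[[1]]
  all(chars %in% .IUPAC)
}

.has_wobble <- function(s) {
  chars <- strsplit(toupper(s), "", fixed = TRUE)[[1]]
  any(!(chars %in% c("A", "C", "G", "T")))
}

# read a FASTA path or pass a DNAStringSet through
.as_genome <- function(genome) {
  if (is.character(genome)) {
    genome <- Biostrings::readDNAStringSet(genome)
    names(genome) <- sub("\\s.*$", "", names(genome))
  }
  stopifnot(methods::is(genome, "DNAStringSet"))
  genome
}
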