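#' Coordinate conventions
#'
#' All on-disk, user-facing files use 1-based inclusive coordinates (the style
#' of clinical variant tables); everything inside the package uses 0-based
#' half-open intervals, which make interval arithmetic (lengths, unions,
#' intersections for the indel-overlap metric) unambiguous.
#'
#' `coords_to_internal()` converts a 1-based inclusive `(start, end)` pair to
#' 0-based half-open; `coords_to_user()` is its inverse.
#'
#' @param start,end integer vectors; for `coords_to_internal()` 1-based
#'   inclusive, for `coords_to_user()` 0-based half-open.
#' @return A tibble with columns `start` and `end` in the other convention.
#' @examples
#' coords_to_internal(55174772, 55174786) # width 15 interval
#' @export
coords_to_internal <- function(start, end) {
  stopifnot(all(start <= end))
  tibble::tibble(start = as.numeric(start) - 1, end = as.numeric(end))
}

#' @rdname coords_to_internal
#' @export
coords_to_user <- function(start, end) {
  stopifnot(all(start < end))
  tibble::tibble(start = as.numeric(start) + 1, end = as.numeric(end))
}

# internal helpers ------------------------------------------------------------

DNA_BASES <- c("A", "C", "G", "T")

is_dna <- function(x) {
  !is.na(x) & nchar(x) > 0 & !grepl("[^ACGT]", x)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

random_dna <- function(n_seq, len) {
  vapply(seq_len(n_seq), function(i) {
    paste(sample(DNA_BASES, len, replace = TRUE), collapse = "")
  }, character(1))
}

#' Haploid genome copies in a DNA mass
#'
#' Converts a DNA input mass to the approximate number of haploid human genome
#' equivalents, the quantity that bounds how many independent template
#' molecules a cfDNA assay can possibly see. 10 ng corresponds to roughly
#' 2,900 copies at 3.44 pg per haploid genome.
#'
#' @param ng DNA mass in nanograms.
#' @param pg_per_genome mass of one haploid genome in picograms.
#' @return numeric, genome-equivalent copy number.
#' @examples
#' genome_copies(10) # ~ 2907
#' @export
genome_copies <- function(ng, pg_per_genome = 3.44) {
  stopifnot(ng >= 0, pg_per_genome > 0)
  ng * 1000 / pg_per_genome
}
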