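#' Synthetic seven-target reference panel
#'
#' Builds a fully synthetic, self-contained reference design mirroring a
#' seven-target cfDNA panel: five positive SNVs (two sharing one target), two
#' positive overlapping deletions on a single target, one negative codon target
#' and one negative SNV. Genomic coordinates follow the panel's public variant
#' table; the amplicon sequences themselves are pseudo-random DNA (no genome
#' download), so the panel is synthetic by construction and labelled as such.
#'
#' Deletion junction bases are rewritten so that the optimal gapped alignment
#' of a deletion-carrying read places the gap uniquely at the truth
#' coordinates; without this, affine-gap alignment may report an equally
#' scoring shifted interval, which the strict (>0.9) overlap assignment rule
#' then rejects.
#'
#' @param vaf known allele fraction given to every positive variant (the
#'   spike-in level of the emulated reference standard).
#' @param amplicon_len genomic length of each amplicon, primers included.
#' @param primer_len length of each target-specific primer.
#' @param seed seed for the panel's pseudo-random sequence content. The panel
#'   is a fixture: the same seed always yields byte-identical sequences.
#' @return an object of class `amplicon_panel`: a list with `primers`,
#'   `targets`, `truth` tibbles (internal 0-based half-open coordinates),
#'   `reference` (named character vector of amplicon sequences) and geometry
#'   fields.
#' @examples
#' panel <- synthetic_panel(vaf = 0.01)
#' panel$truth[, c("name", "vtype", "classification", "known_vaf")]
#' @export
synthetic_panel <- function(vaf = 0.01, amplicon_len = 160, primer_len = 20,
                            seed = 20240601) {
  stopifnot(vaf >= 0, vaf <= 1, amplicon_len >= 6 * primer_len)
  set.seed(seed)
  defs <- panel_variant_defs()
  target_ids <- unique(defs$target_id)

  # one amplicon per target, centered on the span of its variants
  targets <- defs %>%
    dplyr::group_by(.data$target_id) %>%
    dplyr::summarise(chrom = .data$chrom[1],
                     v_start = min(.data$pos_start),
                     v_end = max(.data$pos_end), .groups = "drop") %>%
    dplyr::mutate(
      center = floor((.data$v_start + .data$v_end) / 2),
      amplicon_start = .data$center - amplicon_len %/% 2,
      amplicon_end = .data$amplicon_start + amplicon_len,
      insert_start = .data$amplicon_start + primer_len,
      insert_end = .data$amplicon_end - primer_len
    ) %>%
    dplyr::arrange(.data$target_id)

  reference <- setNames(random_dna(nrow(targets), amplicon_len),
                        targets$target_id)

  # disambiguate deletion junctions
  for (i in seq_len(nrow(defs))) {
    if (defs$vtype[i] != "deletion") next
    tid <- defs$target_id[i]
    a0 <- targets$amplicon_start[targets$target_id == tid]
    s <- defs$pos_start[i] - a0
    e <- defs$pos_end[i] - a0
    reference[tid] <- fix_deletion_junction(reference[tid], s, e)
  }

  targets$gc_fraction <- gc_content(reference[targets$target_id])

  # truth alleles from the (final) synthetic sequence
  defs$ref_allele <- defs$alt_allele <- NA_character_
  for (i in seq_len(nrow(defs))) {
    tid <- defs$target_id[i]
    a0 <- targets$amplicon_start[targets$target_id == tid]
    s <- defs$pos_start[i] - a0
    e <- defs$pos_end[i] - a0
    refseq <- substr(reference[tid], s + 1, e)
    defs$ref_allele[i] <- refseq
    defs$alt_allele[i] <- switch(
      defs$vtype[i],
      SNV = other_base(refseq),
      deletion = "-",
      codon = paste0(substr(refseq, 1, 1), other_base(substr(refseq, 2, 2)),
                     substr(refseq, 3, 3))
    )
  }
  defs$known_vaf <- ifelse(defs$classification == "positive", vaf, 0)

  tags <- panel_fixed_tags(length(target_ids))
  primers <- purrr::map_dfr(seq_along(target_ids), function(k) {
    tid <- target_ids[k]
    row <- targets[targets$target_id == tid, ]
    seq <- reference[tid]
    tibble::tibble(
      primer_id = paste0(tid, c("F", "R")),
      target_id = tid,
      side = c("forward", "reverse"),
      adapter_seq = c(ADAPTER_READ1, ADAPTER_READ2),
      fixed_tag = tags[[k]],
      barcode_len = 10L,
      target_specific_seq = c(
        substr(seq, 1, primer_len),
        revcomp(substr(seq, amplicon_len - primer_len + 1, amplicon_len))),
      chrom = row$chrom,
      bind_start = c(row$amplicon_start, row$insert_end),
      bind_end = c(row$insert_start, row$amplicon_end),
      strand = c("+", "-")
    )
  })
  validate_primers(primers)

  structure(list(
    primers = primers,
    targets = dplyr::select(targets, "target_id", "chrom", "amplicon_start",
                            "amplicon_end", "insert_start", "insert_end",
                            "gc_fraction"),
    truth = tibble::as_tibble(defs[, c("gene", "name", "vtype",
                                       "classification", "target_id", "chrom",
                                       "pos_start", "pos_end", "ref_allele",
                                       "alt_allele", "known_vaf")]),
    reference = reference,
    amplicon_len = amplicon_len,
    primer_len = primer_len,
    seed = seed
  ), class = "amplicon_panel")
}

#' @export
print.amplicon_panel <- function(x, ...) {
  cat(sprintf("<amplicon_panel> %d targets, %d primers, %d truth variants (%d positive)\n",
              nrow(x$targets), nrow(x$primers), nrow(x$truth),
              sum(x$truth$classification == "positive")))
  invisible(x)
}

# the panel's variant table (coordinates converted to 0-based half-open)
panel_variant_defs <- function() {
  u <- tibble::tribble(
    ~gene, ~name, ~vtype, ~classification, ~target_id, ~chrom, ~p1, ~p2,
    "BRAF", "BRAF c.1799T>A (p.V600E)", "SNV", "positive", "RP01", "chr7", 140753336, 140753336,
    "EGFR", "EGFR c.2235_2249del (p.E746_A750delELREA)", "deletion", "positive", "RP02", "chr7", 55174772, 55174786,
    "EGFR", "EGFR c.2240_2257del (p.L747_P753>S)", "deletion", "positive", "RP02", "chr7", 55174777, 55174794,
    "EGFR", "EGFR c.2573T>G (p.L858R)", "SNV", "positive", "RP03", "chr7", 55191822, 55191822,
    "EGFR", "EGFR c.2369C>T (p.T790M)", "SNV", "positive", "RP04", "chr7", 55181378, 55181378,
    "KRAS", "KRAS c.35G>T (p.G12C)", "SNV", "positive", "RP05", "chr12", 25245351, 25245351,
    "KRAS", "KRAS c.35G>A (p.G12D)", "SNV", "positive", "RP05", "chr12", 25245350, 25245350,
    "EGFR", "EGFR G719X codon", "codon", "negative", "RP06", "chr7", 55174014, 55174016,
    "EGFR", "EGFR c.2303G>T (p.S768I)", "SNV", "negative", "RP07", "chr7", 55181312, 55181312
  )
  int <- coords_to_internal(u$p1, u$p2)
  u$pos_start <- int$start
  u$pos_end <- int$end
  u$p1 <- u$p2 <- NULL
  u
}

# standard paired-end library adapters read through at the 3' ends
ADAPTER_READ1 <- "AGATCGGAAGAGCACACGTCTGAACTCCAGTCAC"
ADAPTER_READ2 <- "AGATCGGAAGAGCGTCGTGTAGGGAAAGAGTGTAGATCTCGGTGGTCGCCGTATCATT"

other_base <- function(b) {
  vapply(b, function(x) setdiff(DNA_BASES, x)[1], character(1), USE.NAMES = FALSE)
}

# Ensure a deletion [s, e) (0-based offsets within `seq`) aligns uniquely:
# shifting the gap k positions left or right must change the resulting
# sequence, i.e. the k-mers flanking the two junctions must differ.
fix_deletion_junction <- function(seq, s, e, kmax = 2L) {
  x <- strsplit(seq, "")[[1]]
  for (k in seq_len(kmax)) {
    # left shift by k: requires x[s-k+1 .. s] == x[e-k+1 .. e] (1-based here)
    li <- s - k + 1L; lj <- e - k + 1L
    if (li >= 1L && identical(x[li:s], x[lj:e])) {
      x[lj] <- setdiff(DNA_BASES, c(x[li], x[lj]))[1]
    }
    # right shift by k: requires x[s+1 .. s+k] == x[e+1 .. e+k]
    ri <- s + 1L; rj <- e + 1L
    if (e + k <= length(x) && identical(x[ri:(s + k)], x[rj:(e + k)])) {
      x[rj + k - 1L] <- setdiff(DNA_BASES, c(x[ri + k - 1L], x[rj + k - 1L]))[1]
    }
  }
  paste(x, collapse = "")
}

panel_fixed_tags <- function(n) {
  all3 <- apply(expand.grid(DNA_BASES, DNA_BASES, DNA_BASES), 1, paste,
                collapse = "")
  picked <- sample(all3, 2 * n)
  lapply(seq_len(n), function(k) picked[c(2 * k - 1, 2 * k)])
}
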