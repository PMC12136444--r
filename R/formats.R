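#' Read a UID primer manifest
#'
#' The manifest is a tab-delimited file with one row per primer and columns
#' `primer_id`, `target_id`, `side` (`forward`/`reverse`), `adapter_seq`,
#' `fixed_tag` (3 bases), `barcode_len`, `target_specific_seq`, `chrom`,
#' `bind_start`, `bind_end` (1-based inclusive), `strand`. Coordinates are
#' converted to the internal 0-based half-open convention on read.
#'
#' Each target must have exactly one forward and one reverse primer; the fixed
#' tag is the 3-base primer-identity block that precedes the 10-base random
#' barcode in the 13-base UID.
#'
#' @param path path to a tab-delimited manifest.
#' @return A tibble of validated primer records (coordinates 0-based
#'   half-open).
#' @seealso [write_primer_manifest()], [synthetic_panel()]
#' @export
read_primer_manifest <- function(path) {
  df <- read_tsv_strict(path, "primer manifest")
  req <- c("primer_id", "target_id", "side", "adapter_seq", "fixed_tag",
           "barcode_len", "target_specific_seq", "chrom", "bind_start",
           "bind_end", "strand")
  check_columns(df, req, "primer manifest")
  if (nrow(df) == 0) abort("no records in primer manifest")
  int <- coords_to_internal(df$bind_start, df$bind_end)
  primers <- tibble::tibble(
    primer_id = as.character(df$primer_id),
    target_id = as.character(df$target_id),
    side = as.character(df$side),
    adapter_seq = toupper(df$adapter_seq),
    fixed_tag = toupper(df$fixed_tag),
    barcode_len = as.integer(df$barcode_len),
    target_specific_seq = toupper(df$target_specific_seq),
    chrom = as.character(df$chrom),
    bind_start = int$start,
    bind_end = int$end,
    strand = as.character(df$strand)
  )
  validate_primers(primers)
  primers
}

#' Write a primer manifest
#'
#' Inverse of [read_primer_manifest()]: coordinates are written 1-based
#' inclusive so that read-then-write round-trips exactly.
#'
#' @param primers a primer tibble (internal coordinates).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_primer_manifest <- function(primers, path) {
  out <- primers
  usr <- coords_to_user(primers$bind_start, primers$bind_end)
  out$bind_start <- usr$start
  out$bind_end <- usr$end
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_primers <- function(primers, line_offset = 0L) {
  bad <- which(nchar(primers$fixed_tag) != 3 | !is_dna(primers$fixed_tag))
  if (length(bad)) {
    abort(sprintf("parse error at line %d: fixed_tag must be 3 DNA bases",
                  bad[1] + line_offset + 1L))
  }
  bad <- which(!is_dna(primers$target_specific_seq))
  if (length(bad)) {
    abort(sprintf(
      "parse error at line %d: non-DNA characters in target_specific_seq",
      bad[1] + line_offset + 1L))
  }
  if (!all(primers$side %in% c("forward", "reverse"))) {
    abort("side must be 'forward' or 'reverse'")
  }
  if (any(primers$bind_start >= primers$bind_end)) {
    abort("bind_start must be < bind_end")
  }
  sides <- table(primers$target_id, primers$side)
  ok <- nrow(sides) > 0 &&
    all(sides == 1) && ncol(sides) == 2
  if (!ok) {
    counts <- tapply(primers$side, primers$target_id, function(s) {
      sum(s == "forward") == 1 && sum(s == "reverse") == 1
    })
    missing <- names(counts)[!counts]
    abort(sprintf(
      "validation error: target(s) %s lack exactly one forward and one reverse primer",
      paste(missing, collapse = ", ")))
  }
  # two targets sharing identical target-specific primers would make exact-match
  # extraction ambiguous; reject at load time
  fwd <- primers$target_specific_seq[primers$side == "forward"]
  rev <- primers$target_specific_seq[primers$side == "reverse"]
  if (anyDuplicated(fwd) || anyDuplicated(rev)) {
    abort("configuration error: identical target-specific primer sequences across targets")
  }
  invisible(primers)
}

#' Read a truth-variant table
#'
#' Tab-delimited table of the variants an experiment is expected to interrogate,
#' one row per variant: `gene`, `name`, `vtype` (`SNV`/`deletion`/`codon`),
#' `classification` (`positive`/`negative`), `target_id`, `chrom`, `pos_start`,
#' `pos_end` (1-based inclusive), `ref_allele`, `alt_allele`, `known_vaf`.
#' Coordinates are converted to 0-based half-open on read.
#'
#' @param path path to a tab-delimited truth table.
#' @return tibble of validated truth variants (internal coordinates).
#' @export
read_truth_table <- function(path) {
  df <- read_tsv_strict(path, "truth table")
  req <- c("gene", "name", "vtype", "classification", "target_id", "chrom",
           "pos_start", "pos_end", "ref_allele", "alt_allele", "known_vaf")
  check_columns(df, req, "truth table")
  if (nrow(df) == 0) abort("no records in truth table")
  if (!all(df$vtype %in% c("SNV", "deletion", "codon"))) {
    abort(sprintf("unknown vtype: %s",
                  paste(setdiff(df$vtype, c("SNV", "deletion", "codon")),
                        collapse = ", ")))
  }
  if (!all(df$classification %in% c("positive", "negative"))) {
    abort("classification must be 'positive' or 'negative'")
  }
  int <- coords_to_internal(df$pos_start, df$pos_end)
  tv <- tibble::tibble(
    gene = as.character(df$gene),
    name = as.character(df$name),
    vtype = as.character(df$vtype),
    classification = as.character(df$classification),
    target_id = as.character(df$target_id),
    chrom = as.character(df$chrom),
    pos_start = int$start,
    pos_end = int$end,
    ref_allele = toupper(as.character(df$ref_allele)),
    alt_allele = toupper(as.character(df$alt_allele)),
    known_vaf = as.numeric(df$known_vaf)
  )
  validate_truth(tv)
  tv
}

#' Write a truth-variant table
#'
#' @param truth a truth tibble (internal coordinates).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth_table <- function(truth, path) {
  out <- truth
  usr <- coords_to_user(truth$pos_start, truth$pos_end)
  out$pos_start <- usr$start
  out$pos_end <- usr$end
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_truth <- function(tv) {
  w <- tv$pos_end - tv$pos_start
  if (any(tv$vtype == "SNV" & w != 1)) {
    abort("SNV rows must have pos_end = pos_start + 1 (1-based: pos_end = pos_start)")
  }
  if (any(tv$vtype == "deletion" & w < 1)) {
    abort("deletion rows must span at least one base")
  }
  if (any(tv$vtype == "codon" & w != 3)) {
    abort("codon rows must span exactly 3 bases")
  }
  if (any(tv$known_vaf < 0 | tv$known_vaf > 1)) {
    abort("known_vaf must be in [0, 1]")
  }
  invisible(tv)
}

# shared TSV plumbing ----------------------------------------------------------

read_tsv_strict <- function(path, what) {
  if (!file.exists(path)) abort(sprintf("%s not found: %s", what, path))
  if (file.size(path) == 0) abort(sprintf("no records in %s (empty file)", what))
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          comment.char = "", quote = "")
  tibble::as_tibble(df)
}

check_columns <- function(df, req, what) {
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    abort(sprintf("%s is missing column(s): %s", what,
                  paste(miss, collapse = ", ")))
  }
}

#' Read paired FASTQ files into a read-pair tibble
#'
#' Gzip-aware (delegates decompression to R connections). Mates are matched by
#' file order; read ids are taken from mate 1 with any `/1` suffix and
#' name-encoded metadata preserved. A `tube:<k>` token in the read description
#' (as written by [write_fastq_pairs()]) populates `tube_id`; otherwise
#' `tube_id` is 1.
#'
#' @param path1,path2 FASTQ paths for mate 1 and mate 2.
#' @return tibble with `read_id`, `seq1`, `qual1`, `seq2`, `qual2`, `tube_id`.
#' @export
read_fastq_pairs <- function(path1, path2) {
  r1 <- parse_fastq(path1)
  r2 <- parse_fastq(path2)
  if (nrow(r1) != nrow(r2)) abort("mate files have different read counts")
  tube <- stringr::str_match(r1$desc, "tube:(\\d+)")[, 2]
  tibble::tibble(
    read_id = sub("/1$", "", r1$id),
    seq1 = r1$seq, qual1 = r1$qual,
    seq2 = r2$seq, qual2 = r2$qual,
    tube_id = ifelse(is.na(tube), 1L, as.integer(tube))
  )
}

parse_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4 != 0) abort(sprintf("truncated FASTQ: %s", path))
  hdr <- lines[seq(1, length(lines), by = 4)]
  seqs <- lines[seq(2, length(lines), by = 4)]
  qual <- lines[seq(4, length(lines), by = 4)]
  id <- sub("^@", "", hdr)
  desc <- sub("^\\S+\\s*", "", id)
  id <- sub("\\s.*$", "", id)
  if (any(nchar(seqs) != nchar(qual))) {
    abort(sprintf("FASTQ record with len(seq) != len(qual): %s", path))
  }
  tibble::tibble(id = id, desc = desc, seq = seqs, qual = qual)
}

#' Write a read-pair tibble as paired FASTQ
#'
#' Qualities are Phred+33. The tube of origin is carried in the description
#' field (`tube:<k>`), so [read_fastq_pairs()] round-trips it.
#'
#' @param reads tibble as returned by [sequence_reads()] or
#'   [read_fastq_pairs()].
#' @param path1,path2 output paths; a `.gz` suffix triggers gzip compression.
#' @return `c(path1, path2)`, invisibly.
#' @export
write_fastq_pairs <- function(reads, path1, path2) {
  w <- function(path, seq, qual, mate) {
    con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
    on.exit(close(con))
    rec <- paste0("@", reads$read_id, "/", mate, " tube:", reads$tube_id,
                  "\n", seq, "\n+\n", qual, "\n")
    writeLines(paste(rec, collapse = ""), con, sep = "")
  }
  w(path1, reads$seq1, reads$qual1, 1)
  w(path2, reads$seq2, reads$qual2, 2)
  invisible(c(path1, path2))
}

#' Ingest externally aligned fragments from SAM/BAM
#'
#' Alternative entry into the clustering stage for reads aligned by an external
#' aligner. Read names must carry the UID pair as a `#LEFTUID+RIGHTUID` suffix
#' (and may carry a `tube:<k>` token before it); one fragment is emitted per
#' proper pair. The soft-clip flag is set when either mate's CIGAR contains an
#' `S` operation; mapping quality is the minimum of the two mates' MAPQ.
#' Unpaired reads and reads without a UID suffix are skipped and counted.
#'
#' @param path SAM or BAM file.
#' @param primers primer tibble; used to map reference names to targets.
#' @return list with `fragments` (tibble: `read_id`, `target_id`, `left_uid`,
#'   `right_uid`, `tube_id`, `softclip`, `mapq`, `pos1`, `pos2`, `calls1`,
#'   `calls2`) and `skipped` (named counts).
#' @export
read_sam_fragments <- function(path, primers) {
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq"))
  x <- Rsamtools::scanBam(bam, param = p)[[1]]
  flag <- x$flag
  primary <- bitwAnd(flag, 256L) == 0 & bitwAnd(flag, 2048L) == 0 &
    bitwAnd(flag, 4L) == 0
  proper <- bitwAnd(flag, 2L) != 0
  first <- bitwAnd(flag, 64L) != 0
  keep <- primary
  df <- tibble::tibble(
    qname = x$qname[keep], rname = as.character(x$rname)[keep],
    pos = x$pos[keep], mapq = x$mapq[keep], cigar = x$cigar[keep],
    seq = as.character(x$seq)[keep],
    proper = proper[keep], first = first[keep]
  )
  n_unpaired <- sum(!df$proper)
  df <- df[df$proper, , drop = FALSE]
  has_uid <- grepl("#[ACGT]+\\+[ACGT]+$", df$qname)
  n_nouid <- sum(!has_uid)
  df <- df[has_uid, , drop = FALSE]
  key <- sub("#.*$", "", df$qname)
  m1 <- df[df$first, , drop = FALSE]
  m2 <- df[!df$first, , drop = FALSE]
  k1 <- sub("#.*$", "", m1$qname)
  k2 <- sub("#.*$", "", m2$qname)
  common <- intersect(k1, k2)
  m1 <- m1[match(common, k1), , drop = FALSE]
  m2 <- m2[match(common, k2), , drop = FALSE]
  n_orphan <- nrow(df) - 2 * length(common)
  uid <- stringr::str_match(m1$qname, "#([ACGT]+)\\+([ACGT]+)$")
  tube <- stringr::str_match(m1$qname, "tube:(\\d+)")[, 2]
  tgt_of_ref <- unique(primers[, c("target_id", "chrom")])
  # reference names in per-amplicon SAMs are target ids themselves
  target <- ifelse(m1$rname %in% primers$target_id, m1$rname,
                   tgt_of_ref$target_id[match(m1$rname, tgt_of_ref$chrom)])
  softclip <- grepl("S", m1$cigar) | grepl("S", m2$cigar)
  fragments <- tibble::tibble(
    read_id = sub("#.*$", "", m1$qname),
    target_id = target,
    left_uid = uid[, 2], right_uid = uid[, 3],
    tube_id = ifelse(is.na(tube), 1L, as.integer(tube)),
    softclip = softclip,
    mapq = pmin(m1$mapq, m2$mapq),
    pos1 = m1$pos, pos2 = m2$pos,
    calls1 = calls_from_cigar(m1$seq, m1$cigar),
    calls2 = calls_from_cigar(m2$seq, m2$cigar)
  )
  list(fragments = fragments,
       skipped = c(unpaired = n_unpaired + max(n_orphan, 0),
                   missing_uid = n_nouid))
}

# Reference-projected base calls from a CIGAR string: M consumes both, I read
# only, D emits '-', S consumed from read and not emitted.
calls_from_cigar <- function(seq, cigar) {
  vapply(seq_along(seq), function(i) {
    ops <- stringr::str_match_all(cigar[i], "(\\d+)([MIDNSHP=X])")[[1]]
    lens <- as.integer(ops[, 2]); op <- ops[, 3]
    rpos <- 1L
    out <- character(0)
    for (j in seq_along(op)) {
      L <- lens[j]
      if (op[j] %in% c("M", "=", "X")) {
        out <- c(out, substr(seq[i], rpos, rpos + L - 1L)); rpos <- rpos + L
      } else if (op[j] %in% c("I", "S")) {
        rpos <- rpos + L
      } else if (op[j] %in% c("D", "N")) {
        out <- c(out, strrep("-", L))
      }
    }
    paste(out, collapse = "")
  }, character(1))
}
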