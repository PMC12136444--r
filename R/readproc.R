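#' Trim 3' sequencing adapters from read pairs
#'
#' Removes 3' adapter read-through: for each read, the leftmost position where
#' the remainder of the read matches a prefix of the adapter with at most one
#' mismatch per 10 matched bases is truncated. Pairs in which either mate drops
#' below `min_len` after trimming are removed and counted.
#'
#' In the simulated default design the library molecule is longer than the
#' read, so trimming is a no-op; the operation matters for short-fragment
#' libraries and for real data.
#'
#' @param reads read-pair tibble (`seq1`, `qual1`, `seq2`, `qual2`, ...).
#' @param adapter1,adapter2 adapter sequences read through on mates 1 and 2.
#' @param min_len minimum post-trim read length.
#' @return list with `reads` (trimmed tibble) and `n_dropped`.
#' @export
trim_adapter <- function(reads, adapter1 = ADAPTER_READ1,
                         adapter2 = ADAPTER_READ2, min_len = 30) {
  t1 <- trim_one_side(reads$seq1, adapter1)
  t2 <- trim_one_side(reads$seq2, adapter2)
  out <- reads
  out$seq1 <- substr(out$seq1, 1, t1)
  out$qual1 <- substr(out$qual1, 1, t1)
  out$seq2 <- substr(out$seq2, 1, t2)
  out$qual2 <- substr(out$qual2, 1, t2)
  keep <- nchar(out$seq1) >= min_len & nchar(out$seq2) >= min_len
  list(reads = out[keep, , drop = FALSE], n_dropped = sum(!keep))
}

# returns, per read, the last base to keep (trim point - 1)
trim_one_side <- function(seqs, adapter) {
  n <- length(seqs)
  len <- nchar(seqs)
  cut <- len + 1L
  if (n == 0) return(len)
  max_len <- max(len)
  subj <- Biostrings::DNAStringSet(seqs)
  for (start in seq_len(max_len)) {
    todo <- which(cut > len & start <= len)
    if (!length(todo)) break
    m_len <- pmin(len[todo] - start + 1L, nchar(adapter))
    # group by match length so comparisons are vectorised per length
    for (L in unique(m_len)) {
      rows <- todo[m_len == L]
      pat <- substr(adapter, 1, L)
      frag <- substr(seqs[rows], start, start + L - 1L)
      mm <- mismatch_count(frag, pat)
      hit <- rows[mm <= L %/% 10]
      cut[hit] <- pmin(cut[hit], start)
    }
  }
  pmin(cut - 1L, len)
}

# vectorised Hamming distance of equal-length strings against one pattern
mismatch_count <- function(strings, pattern) {
  if (!length(strings)) return(integer(0))
  as.integer(Biostrings::neditStartingAt(
    Biostrings::BString(pattern), Biostrings::BStringSet(strings),
    starting.at = 1, with.indels = FALSE))
}

#' Extract target reads by exact primer match
#'
#' A read pair is assigned to a target if and only if mate 1 carries the
#' target's forward target-specific primer sequence exactly (immediately after
#' the 13-base UID block) and mate 2 likewise carries the reverse primer
#' exactly. UIDs are the first 13 bases of each mate; their leading 3-base
#' fixed tag must equal the assigned primer's tag, otherwise the pair is
#' discarded as a tag mismatch (the fixed bases act as an integrity check).
#' All pairs matching no target count as off-target: they form the denominator
#' of the on-target ratio.
#'
#' @param reads read-pair tibble.
#' @param primers primer tibble (see [read_primer_manifest()]).
#' @return list with `fragments` (assigned pairs: `read_id`, `target_id`,
#'   `tube_id`, `left_uid`, `right_uid`, `seq1`, `seq2`) and `counts`
#'   (named: `assigned`, `off_target`, `tag_mismatch`).
#' @export
extract_target_reads <- function(reads, primers) {
  validate_primers(primers)
  fwd <- primers[primers$side == "forward", ]
  rev <- primers[primers$side == "reverse", ]
  rev <- rev[match(fwd$target_id, rev$target_id), ]
  uid_len <- 3L + fwd$barcode_len[1]
  n <- nrow(reads)
  target <- rep(NA_character_, n)
  for (k in seq_len(nrow(fwd))) {
    f <- fwd$target_specific_seq[k]
    r <- rev$target_specific_seq[k]
    hit <- is.na(target) &
      substr(reads$seq1, uid_len + 1L, uid_len + nchar(f)) == f &
      substr(reads$seq2, uid_len + 1L, uid_len + nchar(r)) == r
    target[hit] <- fwd$target_id[k]
  }
  assigned <- !is.na(target)
  frag <- reads[assigned, , drop = FALSE]
  tgt <- target[assigned]
  left_uid <- substr(frag$seq1, 1, uid_len)
  right_uid <- substr(frag$seq2, 1, uid_len)
  ftag <- setNames(fwd$fixed_tag, fwd$target_id)
  rtag <- setNames(rev$fixed_tag, rev$target_id)
  tag_ok <- substr(left_uid, 1, 3) == ftag[tgt] &
    substr(right_uid, 1, 3) == rtag[tgt]
  fragments <- tibble::tibble(
    read_id = frag$read_id[tag_ok],
    target_id = tgt[tag_ok],
    tube_id = frag$tube_id[tag_ok],
    left_uid = left_uid[tag_ok],
    right_uid = right_uid[tag_ok],
    seq1 = frag$seq1[tag_ok],
    seq2 = frag$seq2[tag_ok]
  )
  list(fragments = fragments,
       counts = c(assigned = nrow(fragments),
                  off_target = sum(!assigned),
                  tag_mismatch = sum(assigned) - nrow(fragments)))
}

#' Align extracted fragments to their amplicon references
#'
#' Amplicon-anchored alignment: because every read begins with the UID block
#' followed by the exactly matched primer, the error-free register of the read
#' on its amplicon is fixed. Each mate is first compared at that register; a
#' read whose mismatch count exceeds `gap_trigger` (an indel or junk insert) is
#' re-aligned with an affine-gap global-local alignment (match +1, mismatch -4,
#' gap open -6, gap extend -1). The mapping-quality surrogate is 60 when the
#' alignment score reaches 80% of the maximum attainable and scales toward 0
#' below that; `softclip` is set when a terminal run of `softclip_run` or more
#' pattern bases disagrees with the reference (bases an aligner would clip).
#'
#' @param extracted result of [extract_target_reads()] (or a compatible
#'   fragments tibble).
#' @param panel the reference panel.
#' @param gap_trigger mismatch count at the fixed register that triggers the
#'   gapped aligner.
#' @param softclip_run terminal mismatch run length interpreted as a soft clip.
#' @param min_insert fragments whose post-primer insert is shorter are dropped.
#' @return tibble of aligned fragments: `read_id`, `target_id`, `tube_id`,
#'   `left_uid`, `right_uid`, `calls1`, `calls2` (reference-projected per-base
#'   calls, `N` = not covered, `-` = deleted), `mapq`, `softclip`.
#' @export
align_to_amplicon <- function(extracted, panel, gap_trigger = 6,
                              softclip_run = 5, min_insert = 20) {
  frags <- if (is.list(extracted) && !is.data.frame(extracted)) {
    extracted$fragments
  } else {
    extracted
  }
  uid_len <- 3L + panel$primers$barcode_len[1]
  out <- vector("list", length(panel$reference))
  names(out) <- names(panel$reference)
  for (tid in unique(frags$target_id)) {
    f <- frags[frags$target_id == tid, , drop = FALSE]
    ref <- panel$reference[[tid]]
    plen <- nchar(
      panel$primers$target_specific_seq[panel$primers$target_id == tid &
                                          panel$primers$side == "forward"])
    region1 <- substr(f$seq1, uid_len + 1L, nchar(f$seq1))
    region2 <- revcomp(substr(f$seq2, uid_len + 1L, nchar(f$seq2)))
    keep <- nchar(region1) - plen >= min_insert &
      nchar(region2) - plen >= min_insert
    f <- f[keep, , drop = FALSE]
    region1 <- region1[keep]
    region2 <- region2[keep]
    if (!nrow(f)) next
    a1 <- align_mate(region1, ref, anchor = "left", gap_trigger, softclip_run)
    a2 <- align_mate(region2, ref, anchor = "right", gap_trigger, softclip_run)
    out[[tid]] <- tibble::tibble(
      read_id = f$read_id, target_id = tid, tube_id = f$tube_id,
      left_uid = f$left_uid, right_uid = f$right_uid,
      calls1 = a1$calls, calls2 = a2$calls,
      mapq = pmin(a1$mapq, a2$mapq),
      softclip = a1$softclip | a2$softclip
    )
  }
  dplyr::bind_rows(out)
}

# Align one mate's region (already in reference orientation) to the amplicon.
# anchor = "left": error-free register starts at reference position 1;
# anchor = "right": it ends at the last reference position.
align_mate <- function(region, ref, anchor, gap_trigger, softclip_run) {
  n <- length(region)
  rlen <- nchar(region)
  ref_len <- nchar(ref)
  calls <- character(n)
  mapq <- integer(n)
  softclip <- logical(n)
  # fixed-register comparison (all regions from one run share a length)
  for (L in unique(rlen)) {
    rows <- which(rlen == L)
    exp_l <- if (anchor == "left") substr(ref, 1, L)
             else substr(ref, ref_len - L + 1L, ref_len)
    mm <- mismatch_count(region[rows], exp_l)
    fast <- mm <= gap_trigger
    fr <- rows[fast]
    if (length(fr)) {
      pad <- strrep("N", ref_len - L)
      calls[fr] <- if (anchor == "left") paste0(region[fr], pad)
                   else paste0(pad, region[fr])
      mapq[fr] <- score_to_mapq(L - 5 * mm[fast], L)
      softclip[fr] <- FALSE
    }
    sr <- rows[!fast]
    if (length(sr)) {
      g <- gapped_align(region[sr], ref)
      calls[sr] <- g$calls
      mapq[sr] <- score_to_mapq(g$score, L)
      softclip[sr] <- terminal_mismatch_run(g$calls, ref) >= softclip_run
    }
  }
  list(calls = calls, mapq = mapq, softclip = softclip)
}

score_to_mapq <- function(score, len) {
  full <- 0.8 * len
  ifelse(score >= full, 60L, pmax(0L, as.integer(round(60 * score / full))))
}

# affine-gap global-local alignment of reads against one amplicon reference,
# projected to reference coordinates ('-' = deletion, insertions dropped)
gapped_align <- function(regions, ref) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -4,
                                                  baseOnly = FALSE)
  al <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAStringSet(regions),
    subject = ref, type = "global-local",
    substitutionMatrix = mat, gapOpening = 6, gapExtension = 1)
  starts <- Biostrings::start(Biostrings::subject(al))
  ends <- Biostrings::end(Biostrings::subject(al))
  ref_len <- nchar(ref)
  # aligned() projects the pattern into subject coordinates (insertions
  # dropped, deletions as '-'); mask the uncovered subject flanks as N
  a <- as.character(Biostrings::aligned(al))
  calls <- paste0(strrep("N", starts - 1L), substr(a, starts, ends),
                  strrep("N", ref_len - ends))
  list(calls = calls, score = Biostrings::score(al))
}

# longest run of covered-but-mismatching bases at either end of the calls
terminal_mismatch_run <- function(calls, ref) {
  rv <- strsplit(ref, "")[[1]]
  vapply(calls, function(cl) {
    cv <- strsplit(cl, "")[[1]]
    cov <- which(cv != "N")
    if (!length(cov)) return(length(rv))
    mism <- cv != rv & cv != "N"
    lead <- 0L
    for (i in cov) { if (mism[i]) lead <- lead + 1L else break }
    trail <- 0L
    for (i in base::rev(cov)) { if (mism[i]) trail <- trail + 1L else break }
    max(lead, trail)
  }, integer(1), USE.NAMES = FALSE)
}

#' Filter aligned fragments on mapping quality and soft clips
#'
#' Keeps fragments with `softclip == FALSE` and `mapq >= mapq_min`. The
#' default threshold excludes mapping quality strictly below 45.
#'
#' @param fragments tibble from [align_to_amplicon()].
#' @param mapq_min minimum mapping quality retained.
#' @return the retained rows.
#' @export
filter_fragments <- function(fragments, mapq_min = 45) {
  dplyr::filter(fragments, !.data$softclip, .data$mapq >= mapq_min)
}
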