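# Combine the two mates' reference-projected calls at one position:
# one covering mate -> its call; both covering and agreeing -> the call;
# disagreeing mates -> N (no confident call).
combine_mate_chars <- function(c1, c2) {
  out <- ifelse(c1 == "N", c2, c1)
  both <- c1 != "N" & c2 != "N"
  out[both & c1 != c2] <- "N"
  out
}

# The representative-base rule: the unique base (or gap) holding at least 50%
# of the pooled non-missing calls; a 50/50 tie or no majority gives N.
consensus_base <- function(counts) {
  counts <- counts[counts > 0]
  if (!length(counts)) return("N")
  total <- sum(counts)
  mx <- max(counts)
  if (2 * mx < total) return("N")
  if (2 * mx == total && sum(counts == mx) > 1) return("N")
  names(counts)[which.max(counts)]
}

#' Per-position consensus of one UID cluster
#'
#' Pools every base call of every read pair in the cluster and reports, at each
#' reference position, the representative base: the unique base accounting for
#' at least 50% of the pooled calls at that position. Positions with a 50/50
#' tie, no majority base, or no coverage are reported as `N`; `-` marks a
#' deleted reference base.
#'
#' @param fragments the cluster's member fragments (rows of an
#'   [align_to_amplicon()] tibble).
#' @param ref_len amplicon reference length.
#' @return a single character string of length `ref_len` over
#'   `A/C/G/T/-/N`.
#' @export
cluster_consensus <- function(fragments, ref_len) {
  ch <- vapply(seq_len(ref_len), function(off) {
    c1 <- substr(fragments$calls1, off, off)
    c2 <- substr(fragments$calls2, off, off)
    comb <- combine_mate_chars(c1, c2)
    consensus_base(table(comb[comb != "N"]))
  }, character(1))
  paste(ch, collapse = "")
}

# Vectorised per-cluster representative base at one amplicon offset.
# frag_cid maps each fragment row to its cluster id (NA = unclustered).
cluster_site_reps <- function(fragments, frag_cid, offset) {
  c1 <- substr(fragments$calls1, offset, offset)
  c2 <- substr(fragments$calls2, offset, offset)
  comb <- combine_mate_chars(c1, c2)
  dt <- data.table::data.table(cid = frag_cid, ch = comb)
  dt <- dt[!is.na(dt$cid) & dt$ch != "N", ]
  if (!nrow(dt)) {
    return(tibble::tibble(cid = character(0), base = character(0)))
  }
  tal <- dt[, .N, by = c("cid", "ch")]
  rep_dt <- tal[, .(base = {
    counts <- setNames(N, ch)
    consensus_base(counts)
  }), by = "cid"]
  tibble::as_tibble(rep_dt)
}

#' Call a single-nucleotide variant from cluster representatives
#'
#' Counts clusters whose representative base at the site equals the alternate
#' allele (`n_alt`), the reference allele (`n_ref`), a third allele
#' (`n_third`) or no unique majority (`n_N`), and computes the cluster-based
#' allele fraction `VAF = n_alt / (n_alt + n_ref)`. Clusters with `N` or third
#' alleles are excluded from the VAF denominator. When `n_alt + n_ref = 0` the
#' call is a no-call (`vaf = NA`), not 0.
#'
#' @param reps tibble of per-cluster representatives: `cid`, `base`, and
#'   optionally `tube_id`.
#' @param ref_base,alt_base reference and alternate alleles (single bases).
#' @return one-row tibble: `n_alt`, `n_ref`, `n_third`, `n_N`, `vaf`,
#'   `tubes_observed` (tube count with alternate support; 0 when `tube_id`
#'   absent), `per_tube` (list of per-tube VAF tibble).
#' @export
call_snv <- function(reps, ref_base, alt_base) {
  status <- snv_status(reps$base, ref_base, alt_base)
  n_alt <- sum(status == "alt")
  n_ref <- sum(status == "ref")
  vaf <- if (n_alt + n_ref > 0) n_alt / (n_alt + n_ref) else NA_real_
  per_tube <- tibble::tibble(tube_id = integer(0), n_alt = integer(0),
                             n_ref = integer(0), vaf = numeric(0))
  tubes_observed <- 0L
  if (!is.null(reps$tube_id)) {
    per_tube <- tibble::tibble(tube_id = reps$tube_id, status = status) %>%
      dplyr::group_by(.data$tube_id) %>%
      dplyr::summarise(n_alt = sum(.data$status == "alt"),
                       n_ref = sum(.data$status == "ref"),
                       .groups = "drop") %>%
      dplyr::mutate(vaf = ifelse(.data$n_alt + .data$n_ref > 0,
                                 .data$n_alt / (.data$n_alt + .data$n_ref),
                                 NA_real_))
    tubes_observed <- sum(per_tube$n_alt > 0)
  }
  tibble::tibble(n_alt = n_alt, n_ref = n_ref,
                 n_third = sum(status == "third"), n_N = sum(status == "N"),
                 vaf = vaf, tubes_observed = tubes_observed,
                 per_tube = list(per_tube))
}

snv_status <- function(base, ref_base, alt_base) {
  dplyr::case_when(
    base == "N" ~ "N",
    base == ref_base ~ "ref",
    base == alt_base ~ "alt",
    TRUE ~ "third"
  )
}

#' Apply the per-primer-set depth filter
#'
#' The depth threshold is `frac` (default 0.05%) of the maximum cluster count
#' observed across the primer set's targets; a call passes when its
#' `n_alt + n_ref` reaches the threshold. With a maximum of 252,000 clusters
#' the default threshold is 126.
#'
#' @param calls variant-call tibble with `n_alt`, `n_ref` columns.
#' @param cluster_totals per-target cluster totals (numeric vector or tibble
#'   with `n` column).
#' @param frac threshold fraction of the maximum per-target total.
#' @return `calls` with `depth_threshold` and `depth_pass` columns.
#' @export
apply_depth_filter <- function(calls, cluster_totals, frac = 5e-4) {
  totals <- if (is.data.frame(cluster_totals)) cluster_totals$n else cluster_totals
  thr <- frac * max(totals)
  dplyr::mutate(calls, depth_threshold = thr,
                depth_pass = (.data$n_alt + .data$n_ref) >= thr)
}

#' Detect a deletion in a cluster consensus
#'
#' Scans the representative bases of one cluster over a reference window and
#' reports the maximal run of deleted positions (representative `-`). Under
#' the representative-base rule a position counts as deleted only when the gap
#' is the unique at-least-50% majority of the cluster's calls, so a 50/50
#' gapped/ungapped split yields no deletion.
#'
#' @param consensus consensus string (e.g. from [cluster_consensus()]), or a
#'   character vector of per-position representatives.
#' @param region_start 0-based genomic coordinate of the first consensus
#'   position.
#' @param chrom chromosome label.
#' @return tibble with 0 or 1 row: `chrom`, `start`, `end` (0-based half-open
#'   genomic interval of the longest deleted run).
#' @export
detect_deletion <- function(consensus, region_start, chrom = "chr") {
  ch <- if (length(consensus) == 1L) strsplit(consensus, "")[[1]] else consensus
  r <- rle(ch == "-")
  if (!any(r$values)) {
    return(tibble::tibble(chrom = character(0), start = numeric(0),
                          end = numeric(0)))
  }
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  del <- which(r$values)
  best <- del[which.max(r$lengths[del])]
  tibble::tibble(chrom = chrom,
                 start = region_start + starts[best] - 1L,
                 end = region_start + ends[best])
}

#' Overlap fraction of two genomic intervals
#'
#' Length of the intersection divided by the length of the union (the combined
#' region covered by either interval). Symmetric, 1 only for identical
#' intervals, 0 for disjoint intervals or different chromosomes. Intervals are
#' 0-based half-open lists/rows with `chrom`, `start`, `end`.
#'
#' @param a,b intervals (`list(chrom =, start =, end =)` or one-row data
#'   frames).
#' @return numeric fraction in `[0, 1]`.
#' @examples
#' a <- list(chrom = "chr7", start = 55174771, end = 55174786)
#' b <- list(chrom = "chr7", start = 55174776, end = 55174794)
#' indel_overlap(a, b) # 10/23
#' @export
indel_overlap <- function(a, b) {
  if (a$chrom != b$chrom) return(0)
  inter <- max(0, min(a$end, b$end) - max(a$start, b$start))
  uni <- max(a$end, b$end) - min(a$start, b$start)
  # disjoint intervals: the union of two intervals is their covered length,
  # not the enclosing span; intersection 0 makes the distinction moot
  if (inter == 0) return(0)
  inter / uni
}

#' Assign an observed deletion to panel deletion targets
#'
#' The observation is assigned to every deletion target whose interval overlap
#' (intersection over union) strictly exceeds `cutoff`. Overlapping but
#' distinct panel deletions (e.g. two deletions sharing 10 of 23 combined
#' bases, overlap 0.435) are never cross-assigned at the default cutoff.
#'
#' @param observed observed interval (`list(chrom =, start =, end =)`).
#' @param deletion_targets tibble of deletion truth variants (`name`, `chrom`,
#'   `pos_start`, `pos_end`).
#' @param cutoff assignment threshold (strict inequality).
#' @return character vector of assigned target names (may be empty).
#' @export
assign_indel <- function(observed, deletion_targets, cutoff = 0.9) {
  ov <- vapply(seq_len(nrow(deletion_targets)), function(j) {
    indel_overlap(observed, list(chrom = deletion_targets$chrom[j],
                                 start = deletion_targets$pos_start[j],
                                 end = deletion_targets$pos_end[j]))
  }, numeric(1))
  deletion_targets$name[ov > cutoff]
}

#' Average indel VAF across observations
#'
#' Indel allele fractions are averaged across observations; the averaging unit
#' is the per-tube VAF, each tube being an independently amplified aliquot.
#'
#' @param vafs numeric vector of per-observation VAFs.
#' @return their arithmetic mean, or `NA` (no-call) for zero observations.
#' @export
aggregate_indel_vaf <- function(vafs) {
  vafs <- vafs[!is.na(vafs)]
  if (!length(vafs)) return(NA_real_)
  mean(vafs)
}

#' Tube-concordance filter
#'
#' In VAF-comparison mode only variants observed (alternate support) in at
#' least `min_tubes` tubes are retained; sensitivity/specificity analysis
#' bypasses the filter.
#'
#' @param calls variant-call tibble with a `tubes_observed` column.
#' @param min_tubes minimum tube count.
#' @param mode `"vaf"` applies the filter; `"sens-spec"` is the identity.
#' @return the retained calls.
#' @export
tube_concordance <- function(calls, min_tubes = 2, mode = c("vaf", "sens-spec")) {
  mode <- match.arg(mode)
  if (mode == "sens-spec" || min_tubes <= 1) return(calls)
  dplyr::filter(calls, .data$tubes_observed >= min_tubes)
}
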