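#' GC content of a DNA sequence
#'
#' @param seq character vector of DNA strings (A/C/G/T).
#' @return numeric vector of GC fractions in `[0, 1]`.
#' @examples
#' gc_content("ACGT") # 0.5
#' @export
gc_content <- function(seq) {
  if (any(!is_dna(seq))) abort("gc_content: empty or non-DNA sequence")
  gc <- nchar(gsub("[AT]", "", seq))
  gc / nchar(seq)
}

# SantaLucia unified nearest-neighbor parameters: dH (kcal/mol), dS (cal/mol/K)
NN_DH <- c("AA" = -7.9, "TT" = -7.9, "AT" = -7.2, "TA" = -7.2,
           "CA" = -8.5, "TG" = -8.5, "GT" = -8.4, "AC" = -8.4,
           "CT" = -7.8, "AG" = -7.8, "GA" = -8.2, "TC" = -8.2,
           "CG" = -10.6, "GC" = -9.8, "GG" = -8.0, "CC" = -8.0)
NN_DS <- c("AA" = -22.2, "TT" = -22.2, "AT" = -20.4, "TA" = -21.3,
           "CA" = -22.7, "TG" = -22.7, "GT" = -22.4, "AC" = -22.4,
           "CT" = -21.0, "AG" = -21.0, "GA" = -22.2, "TC" = -22.2,
           "CG" = -27.2, "GC" = -24.4, "GG" = -19.9, "CC" = -19.9)
NN_INIT_AT <- c(dH = 2.3, dS = 4.1)
NN_INIT_GC <- c(dH = 0.1, dS = -2.8)

#' Nearest-neighbor melting temperature
#'
#' Duplex melting temperature from the unified nearest-neighbor thermodynamic
#' parameter set with terminal initiation terms, an entropic monovalent-salt
#' correction (`0.368 (N-1) ln[Na+]`), and the excess-primer two-state formula
#' `Tm = dH / (dS + R ln CT) - 273.15` with `CT` the primer concentration.
#' Monotone increasing in GC content at fixed length and conditions.
#'
#' @param seq character vector of DNA sequences, each at least 8 nt.
#' @param salt_mM monovalent cation concentration in mM.
#' @param oligo_nM primer concentration in nM.
#' @return numeric vector of melting temperatures in degrees Celsius.
#' @examples
#' melting_temperature("AGCTTGCAATGCCGTAAGGT")
#' @export
melting_temperature <- function(seq, salt_mM = 50, oligo_nM = 250) {
  if (any(!is_dna(seq))) abort("melting_temperature: empty or non-DNA sequence")
  if (any(nchar(seq) < 8)) {
    abort("melting_temperature: sequence below minimum length (8 nt)")
  }
  vapply(toupper(seq), function(s) {
    n <- nchar(s)
    steps <- substring(s, 1:(n - 1), 2:n)
    dH <- sum(NN_DH[steps])
    dS <- sum(NN_DS[steps])
    for (term in c(substr(s, 1, 1), substr(s, n, n))) {
      ini <- if (term %in% c("A", "T")) NN_INIT_AT else NN_INIT_GC
      dH <- dH + ini["dH"]
      dS <- dS + ini["dS"]
    }
    dS <- dS + 0.368 * (n - 1) * log(salt_mM / 1000)
    R <- 1.987
    unname(dH * 1000 / (dS + R * log(oligo_nM * 1e-9)) - 273.15)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Positional bias of a variant within an amplicon
#'
#' Half the absolute difference between the distances from the variant to the
#' two primer boundaries; 0 means the variant sits at the amplicon center, and
#' larger values indicate a variant pushed toward one primer.
#'
#' @param dist_left,dist_right non-negative distances (bases) from the variant
#'   to the left and right primer boundaries.
#' @return numeric vector of biases in bases.
#' @examples
#' positional_bias(40, 60) # 10
#' @export
positional_bias <- function(dist_left, dist_right) {
  if (any(dist_left < 0 | dist_right < 0)) {
    abort("positional_bias: distances must be >= 0")
  }
  abs(dist_left - dist_right) / 2
}

#' Screen a primer pair for cross-complementary overlap
#'
#' Finds the longest contiguous stretch of one sequence that is
#' reverse-complementary to a stretch of the other (equivalently, the longest
#' common substring of `a` and the reverse complement of `b`). The pair is
#' flagged as a potential dimer when that stretch is at least `min_olap` bases
#' long and includes the 3' terminal base of either primer, the geometry that
#' lets a polymerase extend the duplex.
#'
#' @param a,b DNA strings.
#' @param min_olap minimum overlap length (>= 4) that triggers a flag.
#' @return one-row tibble: `olap_len`, `a_end3` / `b_end3` (whether the stretch
#'   reaches the respective 3' end), `flagged`.
#' @examples
#' screen_pair_overlap("AATTGGCCACGTACGT", "TTAACCACGTACGTAA")
#' @export
screen_pair_overlap <- function(a, b, min_olap = 8) {
  if (min_olap < 4) abort("min_olap must be >= 4")
  stopifnot(is_dna(a), is_dna(b))
  rb <- revcomp(b)
  na <- nchar(a); nb <- nchar(rb)
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(rb, "")[[1]]
  # longest common substring DP between a and revcomp(b), tracking end points
  best <- 0L; best_ai <- 0L; best_bj <- 0L
  a_end3 <- FALSE; b_end3 <- FALSE
  prev <- integer(nb)
  for (i in seq_len(na)) {
    cur <- integer(nb)
    match_j <- which(bv == av[i])
    for (j in match_j) {
      cur[j] <- if (j > 1L) prev[j - 1L] + 1L else 1L
      if (cur[j] > best) {
        best <- cur[j]; best_ai <- i; best_bj <- j
      }
    }
    prev <- cur
  }
  if (best > 0L) {
    # position j in revcomp(b) = position nb - j + 1 in b; the 3' end of b is
    # b's last base = revcomp(b)'s first base
    a_end3 <- best_ai == na
    b_end3 <- (best_bj - best + 1L) == 1L
  }
  flagged <- best >= min_olap && (a_end3 || b_end3)
  tibble::tibble(olap_len = best, a_end3 = a_end3, b_end3 = b_end3,
                 flagged = flagged)
}

#' Filter candidate primer pairs by melting temperature
#'
#' Keeps pairs where both primers have Tm inside `[tm_lo, tm_hi]` (inclusive
#' bounds).
#'
#' @param candidates tibble with columns `fwd_tm` and `rev_tm` (degrees C).
#' @param tm_lo,tm_hi window bounds in degrees Celsius.
#' @return the surviving rows, same columns.
#' @export
filter_candidates <- function(candidates, tm_lo = 57.5, tm_hi = 62.5) {
  dplyr::filter(candidates,
                .data$fwd_tm >= tm_lo, .data$fwd_tm <= tm_hi,
                .data$rev_tm >= tm_lo, .data$rev_tm <= tm_hi)
}

#' Rank candidate primer pairs
#'
#' Lexicographic priority: (1) amplicon length, ascending, so the variant is
#' always reachable within one read; (2) GC adherence, counting how many of the
#' pair's primers have GC content in the optimal window `[0.40, 0.60)` (2
#' before 1 before 0); (3) positional bias, ascending. Ties preserve input
#' order (stable sort by `pair_id` order of appearance).
#'
#' @param candidates tibble with `pair_id`, `amplicon_len`, `fwd_gc`, `rev_gc`,
#'   `positional_bias`.
#' @return the same tibble, reordered, with a `gc_in_window` column added.
#' @export
rank_candidates <- function(candidates) {
  gc_ok <- function(gc) gc >= 0.40 & gc < 0.60
  out <- dplyr::mutate(candidates,
                       gc_in_window = gc_ok(.data$fwd_gc) + gc_ok(.data$rev_gc))
  ord <- order(out$amplicon_len, -out$gc_in_window, out$positional_bias)
  out[ord, , drop = FALSE]
}

#' Merge adjacent variant targets into shared amplicon regions
#'
#' Variants whose padded intervals overlap on the same chromosome are merged
#' into a single target region, so that e.g. two overlapping deletions are
#' covered by one primer pair. Merging uses the maximum padding (`pad_hi`) on
#' each side as the reach of a single amplicon; the emitted insert interval is
#' the merged variant span padded by `pad_lo` (the guaranteed minimum flank).
#'
#' @param variants truth-variant tibble (internal coordinates), sorted by
#'   position within chromosome.
#' @param pad_lo,pad_hi padding bounds in bases.
#' @return tibble of merged target regions: `target_id`, `chrom`,
#'   `insert_start`, `insert_end`, `n_variants`, `members` (list of variant
#'   names).
#' @export
merge_adjacent_targets <- function(variants, pad_lo = 20, pad_hi = 80) {
  v <- dplyr::arrange(variants, .data$chrom, .data$pos_start)
  grp <- integer(nrow(v))
  g <- 0L
  last_chrom <- ""
  reach_end <- -Inf
  for (i in seq_len(nrow(v))) {
    s <- v$pos_start[i] - pad_hi
    e <- v$pos_end[i] + pad_hi
    if (v$chrom[i] != last_chrom || s >= reach_end) {
      g <- g + 1L
      reach_end <- e
    } else {
      reach_end <- max(reach_end, e)
    }
    grp[i] <- g
    last_chrom <- v$chrom[i]
  }
  v$`..grp` <- grp
  out <- v %>%
    dplyr::group_by(.data$`..grp`) %>%
    dplyr::summarise(
      chrom = .data$chrom[1],
      insert_start = min(.data$pos_start) - pad_lo,
      insert_end = max(.data$pos_end) + pad_lo,
      n_variants = dplyr::n(),
      members = list(.data$name),
      .groups = "drop")
  out$target_id <- sprintf("T%02d", seq_len(nrow(out)))
  dplyr::select(out, "target_id", "chrom", "insert_start", "insert_end",
                "n_variants", "members")
}
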