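#' On-target ratio
#'
#' Percentage of all sequenced read pairs mapped to each target region; the
#' overall on-target ratio is the sum of the target-level ratios.
#'
#' @param total_pairs total sequenced read pairs.
#' @param mapped tibble with `target_id` and `n` (mapped pair counts), or a
#'   named numeric vector.
#' @return list with `per_target` (tibble: `target_id`, `n`, `ratio` in %)
#'   and `overall` (%).
#' @export
on_target_ratio <- function(total_pairs, mapped) {
  if (total_pairs <= 0) abort("on_target_ratio: total_pairs must be > 0")
  if (!is.data.frame(mapped)) {
    mapped <- tibble::tibble(target_id = names(mapped), n = as.numeric(mapped))
  }
  if (sum(mapped$n) > total_pairs) {
    abort("on_target_ratio: mapped pairs exceed total pairs")
  }
  per <- dplyr::mutate(mapped, ratio = .data$n / total_pairs * 100)
  list(per_target = per, overall = sum(per$ratio))
}

#' Fold enrichment of capture libraries over PCR-only libraries
#'
#' Per target, the mean target-level on-target ratio of the capture group
#' divided by the mean of the PCR-only group; the summary is the mean fold
#' across targets. Targets with a zero PCR-only average get an infinite fold
#' and are excluded from the summary (and counted).
#'
#' @param magnet,pcr_only tibbles with `target_id` and `ratio` (one row per
#'   target per replicate).
#' @return list with `per_target` (tibble: `target_id`, `magnet_mean`,
#'   `pcr_mean`, `fold`), `mean_fold`, `n_infinite`.
#' @export
enrichment <- function(magnet, pcr_only) {
  m <- magnet %>% dplyr::group_by(.data$target_id) %>%
    dplyr::summarise(magnet_mean = mean(.data$ratio), .groups = "drop")
  p <- pcr_only %>% dplyr::group_by(.data$target_id) %>%
    dplyr::summarise(pcr_mean = mean(.data$ratio), .groups = "drop")
  per <- dplyr::inner_join(m, p, by = "target_id") %>%
    dplyr::mutate(fold = ifelse(.data$pcr_mean > 0,
                                .data$magnet_mean / .data$pcr_mean, Inf))
  finite <- is.finite(per$fold)
  list(per_target = per,
       mean_fold = mean(per$fold[finite]),
       n_infinite = sum(!finite))
}

#' Coverage uniformity
#'
#' Percentage of targets whose read-pair count lies within 0.5 to 1.5 times
#' the mean per-target count (bounds inclusive).
#'
#' @param counts numeric vector of per-target read-pair counts.
#' @return uniformity percentage in `[0, 100]`.
#' @examples
#' uniformity(c(1, 10, 10, 19)) # 50
#' @export
uniformity <- function(counts) {
  if (!length(counts)) abort("uniformity: need at least one target")
  m <- mean(counts)
  100 * mean(counts >= 0.5 * m & counts <= 1.5 * m)
}

#' Classify variant calls against truth
#'
#' Positive-truth variants are true positives when the observed VAF reaches
#' 0.4 times the known VAF, otherwise false negatives. Negative-truth variants
#' are true negatives when the non-reference cluster share is at most 0.1
#' times the reference share (codon targets use the two-step codon rule),
#' otherwise false positives. In a 0%-VAF sample (`zero_sample = TRUE`)
#' positive-panel variants are specific only with exactly zero mutant
#' clusters.
#'
#' @param calls variant-call tibble carrying `classification`, `known_vaf`,
#'   `vaf`, `n_alt`, `n_ref`, `n_third` and, for codon rows, a `base_stats`
#'   list-column (tibbles with `n_nonref`, `n_ref`).
#' @param zero_sample whether the sample's known VAF is 0 for all positives.
#' @return `calls` with a `class` column in `{TP, FP, TN, FN}`.
#' @export
classify_variant <- function(calls, zero_sample = FALSE) {
  cls <- character(nrow(calls))
  for (i in seq_len(nrow(calls))) {
    row <- calls[i, ]
    if (row$classification == "positive" && !zero_sample) {
      ok <- !is.na(row$vaf) && row$vaf >= 0.4 * row$known_vaf
      cls[i] <- if (ok) "TP" else "FN"
    } else if (row$classification == "positive" && zero_sample) {
      cls[i] <- if (row$n_alt == 0) "TN" else "FP"
    } else if ("base_stats" %in% names(calls) &&
               !is.null(row$base_stats[[1]]) &&
               nrow(row$base_stats[[1]]) == 3) {
      cls[i] <- if (codon_specificity(row$base_stats[[1]])) "TN" else "FP"
    } else {
      nonref <- row$n_alt + row$n_third
      cls[i] <- if (nonref <= 0.1 * row$n_ref) "TN" else "FP"
    }
  }
  calls$class <- cls
  calls
}

#' Codon-level specificity
#'
#' Two-step rule for a 3-base codon target: a base is specific when its
#' non-reference cluster count is at most 0.1 times its reference cluster
#' count; the target is specific when at least two of the three bases are.
#'
#' @param base_stats tibble of 3 rows: `n_nonref`, `n_ref`.
#' @return logical: target-level specificity.
#' @export
codon_specificity <- function(base_stats) {
  stopifnot(nrow(base_stats) == 3)
  specific <- base_stats$n_nonref <= 0.1 * base_stats$n_ref
  sum(specific) >= 2
}

#' Sensitivity and specificity of a classified call set
#'
#' Computed with the assay's operating formulas: sensitivity =
#' TP / (TP + FP) and specificity = TN / (TN + FN). These differ from the
#' textbook definitions (which `standard = TRUE` provides for comparison:
#' TP / (TP + FN) and TN / (TN + FP)). Zero denominators give `NA`.
#'
#' @param class character vector of classes in `{TP, FP, TN, FN}` (or a
#'   classified calls tibble with a `class` column).
#' @param standard use the textbook formulas instead.
#' @return tibble: `TP`, `FP`, `TN`, `FN`, `sensitivity`, `specificity`.
#' @export
sensitivity_specificity <- function(class, standard = FALSE) {
  if (is.data.frame(class)) class <- class$class
  tp <- sum(class == "TP"); fp <- sum(class == "FP")
  tn <- sum(class == "TN"); fn <- sum(class == "FN")
  div <- function(a, b) if (b > 0) a / b else NA_real_
  if (standard) {
    tibble::tibble(TP = tp, FP = fp, TN = tn, FN = fn,
                   sensitivity = div(tp, tp + fn),
                   specificity = div(tn, tn + fp))
  } else {
    tibble::tibble(TP = tp, FP = fp, TN = tn, FN = fn,
                   sensitivity = div(tp, tp + fp),
                   specificity = div(tn, tn + fn))
  }
}

#' Sensitivity under tube downsampling
#'
#' Emulates reduced DNA input by re-evaluating sensitivity on random subsets
#' of tubes: per iteration, `n_tubes` tubes are drawn without replacement,
#' their clusters pooled, variants re-called and classified, and sensitivity
#' recomputed; the mean over iterations is reported. Using all available tubes
#' is a single deterministic evaluation.
#'
#' @param run an `amplicon_run` object (see [run_pipeline()]).
#' @param n_tubes tubes per draw.
#' @param iterations Monte-Carlo iterations.
#' @param seed RNG seed for the draws.
#' @return one-row tibble: `n_tubes`, `iterations`, `mean_sensitivity`.
#' @export
downsample_tubes <- function(run, n_tubes, iterations = 1000, seed = 1) {
  all_tubes <- sort(unique(run$cluster_calls$tube_id))
  if (n_tubes > length(all_tubes)) {
    abort("downsample_tubes: n_tubes exceeds available tubes")
  }
  if (n_tubes == length(all_tubes)) iterations <- 1L
  set.seed(seed)
  sens <- vapply(seq_len(iterations), function(i) {
    tubes <- if (n_tubes == length(all_tubes)) all_tubes
             else sample(all_tubes, n_tubes)
    calls <- calls_from_cluster_status(
      run$cluster_calls[run$cluster_calls$tube_id %in% tubes, ],
      run$truth)
    cl <- classify_variant(calls)
    sensitivity_specificity(cl)$sensitivity
  }, numeric(1))
  tibble::tibble(n_tubes = n_tubes, iterations = iterations,
                 mean_sensitivity = mean(sens, na.rm = TRUE))
}

#' Per-GC-bin on-target summary
#'
#' Summarises target-level on-target ratios in the four standard GC bins
#' (GC < 40%, 40% <= GC < 50%, 50% <= GC < 60%, GC >= 60%). Empty bins are
#' absent from the output, not zero.
#'
#' @param targets tibble with `target_id` and `gc_fraction`.
#' @param ratios tibble with `target_id` and `ratio`.
#' @return tibble: `gc_bin`, `n_targets`, `mean_ratio`, `median_ratio`.
#' @export
gc_bin_report <- function(targets, ratios) {
  labs <- c("GC<40%", "40%<=GC<50%", "50%<=GC<60%", "GC>=60%")
  df <- dplyr::inner_join(targets, ratios, by = "target_id") %>%
    dplyr::mutate(gc_bin = cut(.data$gc_fraction,
                               breaks = c(-Inf, 0.4, 0.5, 0.6, Inf),
                               labels = labs, right = FALSE))
  df %>%
    dplyr::group_by(.data$gc_bin) %>%
    dplyr::summarise(n_targets = dplyr::n(),
                     mean_ratio = mean(.data$ratio),
                     median_ratio = stats::median(.data$ratio),
                     .groups = "drop")
}
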