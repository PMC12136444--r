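#' Call all panel variants from clustered fragments
#'
#' The cluster-consensus calling stage: for every truth variant, each valid
#' cluster contributes one representative call (its consensus base at an SNV
#' site, per-base calls over a codon, or a detected deletion interval assigned
#' by strict interval overlap), and calls are aggregated into cluster counts
#' and a cluster-based VAF. Indel VAFs are averaged across per-tube
#' observations. The per-primer-set depth filter is applied to the aggregated
#' calls.
#'
#' @param fragments filtered, aligned fragment tibble.
#' @param groups UID-pair groups from [group_by_uid_pair()].
#' @param clusters valid clusters from [filter_clusters()].
#' @param panel the reference panel.
#' @param depth_filter_frac depth threshold as a fraction of the maximum
#'   per-target cluster count.
#' @param indel_cutoff interval-overlap cutoff for deletion assignment.
#' @return list with `calls` (one row per truth variant), `cluster_calls`
#'   (per-cluster per-variant statuses, the downsampling substrate) and
#'   `cluster_totals` (per-target cluster counts).
#' @export
call_variants <- function(fragments, groups, clusters, panel,
                          depth_filter_frac = 5e-4, indel_cutoff = 0.9) {
  truth <- panel$truth
  # fragment row -> cid
  gid_cid <- setNames(rep(clusters$cid, lengths(clusters$members)),
                      unlist(clusters$members))
  frag_cid <- rep(NA_character_, nrow(fragments))
  frag_gid <- rep(NA_integer_, nrow(fragments))
  frag_gid[unlist(groups$frag_rows)] <- rep(groups$group_id,
                                            lengths(groups$frag_rows))
  mapped <- !is.na(frag_gid)
  frag_cid[mapped] <- gid_cid[as.character(frag_gid[mapped])]
  cl_tube <- setNames(clusters$tube_id, clusters$cid)

  cc <- list()
  for (tid in unique(truth$target_id)) {
    tgt_clusters <- clusters$cid[clusters$target_id == tid]
    if (!length(tgt_clusters)) next
    f_idx <- which(fragments$target_id == tid & !is.na(frag_cid))
    f <- fragments[f_idx, , drop = FALSE]
    f_cid <- frag_cid[f_idx]
    a0 <- panel$targets$amplicon_start[panel$targets$target_id == tid]
    tv <- truth[truth$target_id == tid, , drop = FALSE]

    snvs <- tv[tv$vtype == "SNV", , drop = FALSE]
    for (j in seq_len(nrow(snvs))) {
      off <- snvs$pos_start[j] - a0 + 1
      reps <- cluster_site_reps(f, f_cid, off)
      cc[[length(cc) + 1]] <- status_rows(
        snvs$name[j], "SNV", tgt_clusters, reps,
        snvs$ref_allele[j], snvs$alt_allele[j], cl_tube)
    }

    codons <- tv[tv$vtype == "codon", , drop = FALSE]
    for (j in seq_len(nrow(codons))) {
      for (b in 1:3) {
        off <- codons$pos_start[j] - a0 + b
        reps <- cluster_site_reps(f, f_cid, off)
        rows <- status_rows(
          codons$name[j], "codon", tgt_clusters, reps,
          substr(codons$ref_allele[j], b, b),
          substr(codons$alt_allele[j], b, b), cl_tube)
        rows$base_index <- b
        cc[[length(cc) + 1]] <- rows
      }
    }

    dels <- tv[tv$vtype == "deletion", , drop = FALSE]
    if (nrow(dels)) {
      cc[[length(cc) + 1]] <- deletion_status_rows(
        f, f_cid, tgt_clusters, dels, a0, indel_cutoff, cl_tube)
    }
  }
  cluster_calls <- dplyr::bind_rows(cc)
  calls <- calls_from_cluster_status(cluster_calls, truth)
  totals <- dplyr::count(clusters, .data$target_id)
  calls <- apply_depth_filter(calls, totals, depth_filter_frac)
  list(calls = calls, cluster_calls = cluster_calls, cluster_totals = totals)
}

status_rows <- function(name, vtype, tgt_clusters, reps, ref_base, alt_base,
                        cl_tube) {
  status <- setNames(rep("N", length(tgt_clusters)), tgt_clusters)
  hit <- reps$cid %in% tgt_clusters
  status[reps$cid[hit]] <- snv_status(reps$base[hit], ref_base, alt_base)
  tibble::tibble(name = name, vtype = vtype, cid = tgt_clusters,
                 tube_id = unname(cl_tube[tgt_clusters]),
                 status = unname(status), base_index = NA_integer_)
}

# per-cluster deletion detection over the deletion window, assignment by
# strict interval overlap against each panel deletion
deletion_status_rows <- function(f, f_cid, tgt_clusters, dels, a0,
                                 indel_cutoff, cl_tube) {
  off_lo <- min(dels$pos_start) - a0 + 1 - 5
  off_hi <- max(dels$pos_end) - a0 + 5
  rep_list <- lapply(off_lo:off_hi, function(off) {
    r <- cluster_site_reps(f, f_cid, off)
    r$off <- off
    r
  })
  reps <- dplyr::bind_rows(rep_list)
  covered <- unique(reps$cid)
  obs <- reps %>%
    dplyr::group_by(.data$cid) %>%
    dplyr::arrange(.data$off, .by_group = TRUE) %>%
    dplyr::summarise(del = list(longest_gap_run(.data$base, .data$off)),
                     .groups = "drop")
  has_del <- vapply(obs$del, function(d) !is.null(d), logical(1))
  assigned <- vector("list", nrow(obs))
  for (i in which(has_del)) {
    iv <- list(chrom = dels$chrom[1],
               start = a0 + obs$del[[i]][1] - 1,
               end = a0 + obs$del[[i]][2])
    assigned[[i]] <- assign_indel(iv, dels, indel_cutoff)
  }
  purrr::map_dfr(seq_len(nrow(dels)), function(j) {
    status <- setNames(rep("N", length(tgt_clusters)), tgt_clusters)
    status[intersect(covered, tgt_clusters)] <- "ref"
    with_del <- obs$cid[has_del]
    status[intersect(with_del, tgt_clusters)] <- "third"
    mine <- obs$cid[has_del][vapply(assigned[has_del],
                                    function(a) dels$name[j] %in% a,
                                    logical(1))]
    status[intersect(mine, tgt_clusters)] <- "alt"
    tibble::tibble(name = dels$name[j], vtype = "deletion",
                   cid = tgt_clusters,
                   tube_id = unname(cl_tube[tgt_clusters]),
                   status = unname(status), base_index = NA_integer_)
  })
}

# maximal '-' run over consecutive offsets; returns c(start_off, end_off)
# (1-based amplicon offsets, inclusive) or NULL
longest_gap_run <- function(base, off) {
  r <- rle(base == "-")
  if (!any(r$values)) return(NULL)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  del <- which(r$values)
  best <- del[which.max(r$lengths[del])]
  c(off[starts[best]], off[ends[best]])
}

# Shared aggregation: per-cluster statuses -> one call per truth variant.
# Also the substrate of tube downsampling (subset rows by tube, re-aggregate).
calls_from_cluster_status <- function(cluster_calls, truth) {
  purrr::map_dfr(seq_len(nrow(truth)), function(j) {
    v <- truth[j, ]
    rows <- cluster_calls[cluster_calls$name == v$name, , drop = FALSE]
    base_stats <- NULL
    if (v$vtype == "codon") {
      base_stats <- rows %>%
        dplyr::group_by(.data$base_index) %>%
        dplyr::summarise(n_nonref = sum(.data$status %in% c("alt", "third")),
                         n_ref = sum(.data$status == "ref"),
                         .groups = "drop")
      rows <- rows[rows$base_index == 2, , drop = FALSE]  # counts from one base
    }
    n_alt <- sum(rows$status == "alt")
    n_ref <- sum(rows$status == "ref")
    per_tube <- rows %>%
      dplyr::group_by(.data$tube_id) %>%
      dplyr::summarise(n_alt = sum(.data$status == "alt"),
                       n_ref = sum(.data$status == "ref"), .groups = "drop") %>%
      dplyr::mutate(vaf = ifelse(.data$n_alt + .data$n_ref > 0,
                                 .data$n_alt / (.data$n_alt + .data$n_ref),
                                 NA_real_))
    vaf <- if (v$vtype == "deletion") {
      aggregate_indel_vaf(per_tube$vaf)
    } else if (n_alt + n_ref > 0) {
      n_alt / (n_alt + n_ref)
    } else {
      NA_real_
    }
    tibble::tibble(
      name = v$name, vtype = v$vtype, classification = v$classification,
      target_id = v$target_id, known_vaf = v$known_vaf,
      n_alt = n_alt, n_ref = n_ref,
      n_third = sum(rows$status == "third"), n_N = sum(rows$status == "N"),
      vaf = vaf, tubes_observed = sum(per_tube$n_alt > 0),
      per_tube = list(per_tube),
      base_stats = list(base_stats)
    )
  })
}

#' Run the full processing pipeline on a set of read pairs
#'
#' Extraction by exact primer match, amplicon alignment, soft-clip/MAPQ
#' filtering, UID-pair grouping (minimum depth 2), peer-to-peer network
#' clustering with genealogy-bound filters, cluster-consensus variant calling,
#' classification against the panel truth, and the run-level metrics
#' (on-target ratio, uniformity, sensitivity, specificity). Every stage logs
#' how many records it dropped.
#'
#' @param reads read-pair tibble ([sequence_reads()] output or
#'   [read_fastq_pairs()]).
#' @param panel the reference panel.
#' @param config a [sim_config()] (supplies `uid_cycles` and seed bookkeeping).
#' @param mode `"sens-spec"` (no tube filter) or `"vaf"` (depth filter and
#'   >= `min_tubes` tube concordance applied to the reported calls).
#' @param mapq_min,min_depth,min_uid_pairs,depth_filter_frac,indel_cutoff,min_tubes
#'   pipeline thresholds; defaults are the protocol's stated values.
#' @param trim run the adapter trimmer first (off by default: the simulated
#'   library is longer than the read).
#' @return object of class `amplicon_run`.
#' @export
run_pipeline <- function(reads, panel, config,
                         mode = c("sens-spec", "vaf"),
                         mapq_min = 45, min_depth = 2, min_uid_pairs = 2,
                         depth_filter_frac = 5e-4, indel_cutoff = 0.9,
                         min_tubes = 2, trim = FALSE) {
  mode <- match.arg(mode)
  n_trimmed_out <- 0L
  if (trim) {
    tr <- trim_adapter(reads)
    reads <- tr$reads
    n_trimmed_out <- tr$n_dropped
  }
  total_pairs <- nrow(reads)
  ex <- extract_target_reads(reads, panel$primers)
  aligned <- align_to_amplicon(ex, panel)
  fragments <- filter_fragments(aligned, mapq_min)
  groups <- group_by_uid_pair(fragments, min_depth)
  network <- build_uid_network(groups)
  raw_clusters <- find_clusters(groups, network)
  clusters <- filter_clusters(raw_clusters, config$uid_cycles, min_uid_pairs)
  vc <- call_variants(fragments, groups, clusters, panel,
                      depth_filter_frac, indel_cutoff)
  calls <- vc$calls

  mapped <- dplyr::count(fragments, .data$target_id)
  otr <- on_target_ratio(total_pairs, mapped)
  unif_counts <- mapped$n[match(panel$targets$target_id, mapped$target_id)]
  unif_counts[is.na(unif_counts)] <- 0
  unif <- uniformity(unif_counts)
  pos <- calls$classification == "positive"
  zero_sample <- all(calls$known_vaf[pos] == 0)
  classified <- classify_variant(calls, zero_sample = zero_sample)
  ss <- sensitivity_specificity(classified)
  reported <- classified
  if (mode == "vaf") {
    reported <- reported[reported$depth_pass, , drop = FALSE]
    reported <- tube_concordance(reported, min_tubes, "vaf")
  }

  counts <- tibble::tribble(
    ~stage, ~kept, ~dropped,
    "trim", total_pairs, n_trimmed_out,
    "extract", unname(ex$counts["assigned"]),
      unname(ex$counts["off_target"] + ex$counts["tag_mismatch"]),
    "align", nrow(aligned), nrow(ex$fragments) - nrow(aligned),
    "mapq_softclip", nrow(fragments), nrow(aligned) - nrow(fragments),
    "uid_depth", nrow(groups), attr(groups, "dropped_low_depth"),
    "cluster_filter", nrow(clusters),
      attr(clusters, "dropped_small") + attr(clusters, "dropped_oversize")
  )

  structure(list(
    config = config, mode = mode, counts = counts,
    total_pairs = total_pairs,
    clusters = dplyr::select(clusters, -"members"),
    cluster_calls = vc$cluster_calls,
    cluster_totals = vc$cluster_totals,
    calls = classified, reported = reported, truth = panel$truth,
    metrics = list(on_target = otr, uniformity = unif, sens_spec = ss)
  ), class = "amplicon_run")
}

#' Simulate an experiment and run the pipeline on it
#'
#' @param panel the reference panel.
#' @param config a [sim_config()].
#' @param ... passed to [run_pipeline()].
#' @return an `amplicon_run` with the simulation truth attached (`$sim`).
#' @export
run_experiment <- function(panel, config, ...) {
  sim <- simulate_experiment(panel, config)
  run <- run_pipeline(sim$reads, panel, config, ...)
  run$sim <- list(truth = sim$truth, read_truth = sim$read_truth,
                  molecules = sim$molecules[, c("molecule_id", "genome_id",
                                                "target_id", "tube_id",
                                                "variants")])
  run
}

#' @export
print.amplicon_run <- function(x, ...) {
  ss <- x$metrics$sens_spec
  cat(sprintf(
    paste0("<amplicon_run> %d read pairs, %d clusters | on-target %.1f%%, ",
           "uniformity %.1f%% | sensitivity %.2f, specificity %.2f\n"),
    x$total_pairs, nrow(x$clusters), x$metrics$on_target$overall,
    x$metrics$uniformity, ss$sensitivity, ss$specificity))
  invisible(x)
}

#' Tidy a pipeline run into per-variant calls
#'
#' @param x an `amplicon_run`.
#' @param ... unused.
#' @return tibble with one row per truth variant: counts, VAF, depth-filter
#'   status, tube concordance and TP/FP/TN/FN class.
#' @export
tidy.amplicon_run <- function(x, ...) {
  dplyr::select(x$calls, "name", "vtype", "classification", "target_id",
                "known_vaf", "n_alt", "n_ref", "n_third", "n_N", "vaf",
                "tubes_observed", "depth_pass", "class")
}

#' One-row summary of a pipeline run
#'
#' @param x an `amplicon_run`.
#' @param ... unused.
#' @return one-row tibble: read pairs, on-target ratio, uniformity, cluster
#'   count, sensitivity, specificity.
#' @export
glance.amplicon_run <- function(x, ...) {
  ss <- x$metrics$sens_spec
  tibble::tibble(
    total_pairs = x$total_pairs,
    on_target = x$metrics$on_target$overall,
    uniformity = x$metrics$uniformity,
    n_clusters = nrow(x$clusters),
    TP = ss$TP, FP = ss$FP, TN = ss$TN, FN = ss$FN,
    sensitivity = ss$sensitivity,
    specificity = ss$specificity
  )
}

#' Plot a pipeline run
#'
#' `type = "vaf"` shows observed versus known VAF per variant (log scale,
#' detection threshold at 0.4 x known); `type = "on_target"` shows the
#' per-target on-target ratios.
#'
#' @param object an `amplicon_run`.
#' @param type which panel to draw.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.amplicon_run <- function(object, type = c("vaf", "on_target"), ...) {
  type <- match.arg(type)
  if (type == "vaf") {
    df <- tidy(object)
    df$short <- sub(" .*$", "", df$name)
    ggplot2::ggplot(df, ggplot2::aes(x = .data$short, y = .data$vaf,
                                     fill = .data$class)) +
      ggplot2::geom_col() +
      ggplot2::geom_point(ggplot2::aes(y = .data$known_vaf), shape = 4,
                          size = 3, show.legend = FALSE) +
      ggplot2::labs(x = NULL, y = "cluster-based VAF",
                    title = "Observed VAF per panel variant (x = known VAF)") +
      ggplot2::theme_minimal() +
      ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                         hjust = 1))
  } else {
    df <- object$metrics$on_target$per_target
    ggplot2::ggplot(df, ggplot2::aes(x = .data$target_id, y = .data$ratio)) +
      ggplot2::geom_col(fill = "steelblue") +
      ggplot2::labs(x = NULL, y = "on-target ratio (%)",
                    title = sprintf("Overall on-target ratio %.1f%%",
                                    object$metrics$on_target$overall)) +
      ggplot2::theme_minimal()
  }
}
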