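#' Simulator configuration
#'
#' Collects every tunable of the synthetic experiment generator. Defaults are
#' the emulated assay's study conditions: 2,900 haploid genome equivalents
#' (10 ng of cfDNA at 3.44 pg/genome) split across 8 tubes, 10 UID-tagging PCR
#' cycles, 10 index plus 20 final amplification cycles, 2 x 150 bp paired-end
#' reads. `n_molecules` counts genome equivalents: every equivalent contributes
#' one template fragment at every target locus, since cell-free DNA covers the
#' genome.
#'
#' Parameters the emulated protocol does not pin down are set to values chosen
#' once as realistic for multiplex cfDNA amplicon work and documented in the
#' methods vignette: per-cycle priming efficiency 0.15, byproduct rate 0.30,
#' capture retentions 0.95 (on-target) and 0.01 (byproduct), 250,000 read
#' pairs (mean UID-pair depth around 5), cfDNA fragment length N(166, 10).
#'
#' @param n_molecules haploid genome-equivalent copies.
#' @param n_tubes number of initial-PCR aliquots.
#' @param uid_cycles UID-tagging PCR cycles (>= 2: a complete UID pair needs
#'   two priming events).
#' @param index_cycles,final_cycles later amplification cycles (no new UIDs).
#' @param efficiency per-cycle priming probability in (0, 1].
#' @param pcr_error substitution rate per base per synthesis.
#' @param seq_error substitution rate per sequenced base.
#' @param fragment_len_mean,fragment_len_sd cfDNA fragment length (bases).
#' @param read_len read length (bases).
#' @param n_read_pairs read pairs sequenced.
#' @param byproduct_rate fraction of the final library that is off-target
#'   artifact.
#' @param capture_on_target_retention,capture_byproduct_retention per-copy
#'   retention probabilities of the hybrid-capture step; `(1, 1)` is the
#'   PCR-only (no capture) protocol.
#' @param seed integer seed; expanded deterministically into one sub-seed per
#'   stage so identical configs give byte-identical outputs.
#' @return a validated list of class `sim_config`.
#' @examples
#' cfg <- sim_config(seed = 7)
#' @export
sim_config <- function(n_molecules = 2900,
                       n_tubes = 8,
                       uid_cycles = 10,
                       index_cycles = 10,
                       final_cycles = 20,
                       efficiency = 0.15,
                       pcr_error = 1e-5,
                       seq_error = 1e-3,
                       fragment_len_mean = 166,
                       fragment_len_sd = 10,
                       read_len = 150,
                       n_read_pairs = 250000,
                       byproduct_rate = 0.30,
                       capture_on_target_retention = 0.95,
                       capture_byproduct_retention = 0.01,
                       seed = 1) {
  cfg <- list(
    n_molecules = as.integer(n_molecules), n_tubes = as.integer(n_tubes),
    uid_cycles = as.integer(uid_cycles),
    index_cycles = as.integer(index_cycles),
    final_cycles = as.integer(final_cycles),
    efficiency = efficiency, pcr_error = pcr_error, seq_error = seq_error,
    fragment_len_mean = fragment_len_mean, fragment_len_sd = fragment_len_sd,
    read_len = as.integer(read_len), n_read_pairs = as.integer(n_read_pairs),
    byproduct_rate = byproduct_rate,
    capture_on_target_retention = capture_on_target_retention,
    capture_byproduct_retention = capture_byproduct_retention,
    seed = as.integer(seed)
  )
  probs <- c("efficiency", "pcr_error", "seq_error", "byproduct_rate",
             "capture_on_target_retention", "capture_byproduct_retention")
  for (p in probs) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1) {
      abort(sprintf("sim_config: %s must be in [0, 1]", p))
    }
  }
  if (cfg$efficiency <= 0) abort("sim_config: efficiency must be > 0")
  if (cfg$uid_cycles < 2) {
    abort("sim_config: uid_cycles must be >= 2 (a complete UID pair needs two cycles)")
  }
  if (cfg$n_molecules < 1 || cfg$n_tubes < 1 || cfg$n_read_pairs < 1) {
    abort("sim_config: counts must be positive")
  }
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> %d genome equivalents x %d tubes, %d UID + %d index + %d final cycles, eff %.2f, %d read pairs, seed %d\n",
    x$n_molecules, x$n_tubes, x$uid_cycles, x$index_cycles, x$final_cycles,
    x$efficiency, x$n_read_pairs, x$seed))
  invisible(x)
}

# one sub-seed per stage, derived deterministically from the master seed
derive_stage_seeds <- function(seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  s <- sample.int(2147483646L, 6)
  names(s) <- c("spike", "uid_pcr", "amplify", "byproducts", "capture",
                "sequencing")
  s
}

#' Read a pipeline run configuration from YAML
#'
#' The YAML file may contain a `sim:` block (any [sim_config()] argument) and a
#' `pipeline:` block (`mapq_min`, `min_depth`, `min_uid_pairs`, `uid_cycles`,
#' `depth_filter_frac`, `indel_cutoff`, `min_tubes`, `mode`, `pcr_only`).
#' Unset values take the package defaults, which are the emulated protocol's
#' stated thresholds.
#'
#' @param path YAML file.
#' @return list with elements `sim` (a `sim_config`) and `pipeline` (named
#'   list of thresholds).
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- do.call(sim_config, as.list(y$sim %||% list()))
  defaults <- list(mapq_min = 45, min_depth = 2, min_uid_pairs = 2,
                   uid_cycles = sim$uid_cycles, depth_filter_frac = 5e-4,
                   indel_cutoff = 0.9, min_tubes = 2, mode = "sens-spec",
                   pcr_only = FALSE)
  pl <- utils::modifyList(defaults, as.list(y$pipeline %||% list()))
  if (isTRUE(pl$pcr_only)) {
    sim$capture_on_target_retention <- 1
    sim$capture_byproduct_retention <- 1
  }
  list(sim = sim, pipeline = pl)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
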