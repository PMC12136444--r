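#' Spike template molecules across targets and tubes
#'
#' Generates the template pool of one synthetic experiment: each haploid genome
#' equivalent contributes one cfDNA fragment at every target locus, fragments
#' are assigned to tubes round-robin by genome equivalent, and each fragment
#' carries each variant overlapping its target independently with probability
#' equal to the variant's known allele fraction. Fragment lengths are drawn
#' from N(`fragment_len_mean`, `fragment_len_sd`) truncated below at the
#' amplicon span, so every template is amplifiable.
#'
#' Overlapping variants (e.g. two deletions sharing sequence) are mutually
#' exclusive on one physical molecule: when a draw selects both, the variant
#' earlier in coordinate order is applied and the overlapping one skipped.
#'
#' @param panel an [synthetic_panel()] object (or compatible list).
#' @param config a [sim_config()].
#' @return tibble of molecules: `molecule_id`, `genome_id`, `target_id`,
#'   `tube_id`, `frag_len`, `variants` (comma-joined names, "" if none),
#'   `mol_seq` (amplicon-region sequence with variants applied).
#' @export
spike_molecules <- function(panel, config) {
  if (any(panel$truth$known_vaf < 0 | panel$truth$known_vaf > 1)) {
    abort("spike_molecules: known VAF outside [0, 1]")
  }
  set.seed(derive_stage_seeds(config$seed)[["spike"]])
  n <- config$n_molecules
  targets <- panel$targets
  out <- vector("list", nrow(targets))
  next_id <- 0L
  for (k in seq_len(nrow(targets))) {
    tgt <- targets[k, ]
    ref <- panel$reference[[tgt$target_id]]
    amp_span <- nchar(ref)
    tv <- panel$truth[panel$truth$target_id == tgt$target_id, , drop = FALSE]
    tv <- tv[order(tv$pos_start), , drop = FALSE]
    carries <- matrix(FALSE, n, nrow(tv))
    for (j in seq_len(nrow(tv))) {
      carries[, j] <- runif(n) < tv$known_vaf[j]
    }
    frag_len <- pmax(round(rnorm(n, config$fragment_len_mean,
                                 config$fragment_len_sd)), amp_span)
    mol_seq <- rep(ref, n)
    var_lab <- rep("", n)
    mut_rows <- which(rowSums(carries) > 0)
    for (i in mut_rows) {
      res <- apply_variants(ref, tv[carries[i, ], , drop = FALSE],
                            tgt$amplicon_start)
      mol_seq[i] <- res$seq
      var_lab[i] <- paste(res$applied, collapse = ",")
    }
    out[[k]] <- tibble::tibble(
      molecule_id = next_id + seq_len(n),
      genome_id = seq_len(n),
      target_id = tgt$target_id,
      tube_id = ((seq_len(n) - 1L) %% config$n_tubes) + 1L,
      frag_len = frag_len,
      variants = var_lab,
      mol_seq = mol_seq
    )
    next_id <- next_id + n
  }
  dplyr::bind_rows(out)
}

# apply a set of truth variants (rows of the truth tibble, coordinate-sorted)
# to one amplicon sequence; overlapping later variants are skipped
apply_variants <- function(ref, tv, amplicon_start) {
  seq <- ref
  applied <- character(0)
  shift <- 0L   # accumulated length change from applied deletions
  last_end <- -Inf
  for (j in seq_len(nrow(tv))) {
    s <- tv$pos_start[j] - amplicon_start
    e <- tv$pos_end[j] - amplicon_start
    if (s < last_end) next  # overlaps an already applied variant
    s2 <- s + shift
    e2 <- e + shift
    if (tv$vtype[j] == "deletion") {
      seq <- paste0(substr(seq, 1, s2), substr(seq, e2 + 1, nchar(seq)))
      shift <- shift - (e - s)
    } else {
      seq <- paste0(substr(seq, 1, s2), tv$alt_allele[j],
                    substr(seq, e2 + 1, nchar(seq)))
    }
    applied <- c(applied, tv$name[j])
    last_end <- e
  }
  list(seq = seq, applied = applied)
}

#' Simulate the UID-tagging PCR genealogy
#'
#' Runs the initial multiplex PCR in which every priming event installs a fresh
#' 13-base UID (3 fixed bases identifying the primer plus a 10-base random
#' barcode). The genealogy model: each original genomic strand templates a
#' UID primer exactly once; every UID-bearing strand (single or complete) is
#' primed in each cycle with probability `efficiency` by the opposite-side
#' primer, and the daughter copies the template through its far end, so parent
#' and daughter share exactly one UID. Under this model the number of distinct
#' complete UID pairs per molecule never exceeds `2^cycles - 2`, with equality
#' at efficiency 1 (the two original strands are the "-2").
#'
#' Polymerase substitution errors are drawn per synthesis at `pcr_error` per
#' base and inherited by all descendants of a strand.
#'
#' @param molecules tibble from [spike_molecules()].
#' @param panel the reference panel.
#' @param config a [sim_config()].
#' @return list with `strands` (tibble: `strand_id`, `molecule_id`,
#'   `target_id`, `tube_id`, `kind` 0/1/2 = original/one UID/complete,
#'   `left_uid`, `right_uid` (13-base strings, NA when absent), `err`
#'   (semicolon-joined `pos:base` substitutions), `born` cycle) and `truth`
#'   (list: `uid_pairs` per-molecule genealogy tibble, `vaf` realised mutant
#'   fractions per variant).
#' @export
simulate_uid_pcr <- function(molecules, panel, config) {
  set.seed(derive_stage_seeds(config$seed)[["uid_pcr"]])
  eff <- config$efficiency
  n_mol <- nrow(molecules)
  mol_len <- nchar(molecules$mol_seq)

  # strand state vectors (grown per cycle); originals: 2 per molecule, one to
  # be primed by each side
  mol <- rep(seq_len(n_mol), each = 2)
  next_side <- rep(c("F", "R"), n_mol)
  kind <- rep(0L, 2L * n_mol)
  left <- rep(NA_integer_, 2L * n_mol)
  right <- rep(NA_integer_, 2L * n_mol)
  err <- rep("", 2L * n_mol)
  born <- rep(0L, 2L * n_mol)
  active <- rep(TRUE, 2L * n_mol)
  uid_n <- 0L

  for (cyc in seq_len(config$uid_cycles)) {
    primed <- which(active & runif(length(mol)) < eff)
    if (!length(primed)) next
    k <- length(primed)
    new_uid <- uid_n + seq_len(k)
    uid_n <- uid_n + k
    d_side <- ifelse(next_side[primed] == "F", "R", "F")
    d_left <- ifelse(next_side[primed] == "F", new_uid, left[primed])
    d_right <- ifelse(next_side[primed] == "R", new_uid, right[primed])
    d_kind <- pmin(kind[primed] + 1L, 2L)
    d_err <- add_synthesis_errors(err[primed], mol_len[mol[primed]],
                                  config$pcr_error)
    # an original strand templates a UID primer only once
    orig <- primed[kind[primed] == 0L]
    active[orig] <- FALSE
    mol <- c(mol, mol[primed])
    next_side <- c(next_side, d_side)
    kind <- c(kind, d_kind)
    left <- c(left, d_left)
    right <- c(right, d_right)
    err <- c(err, d_err)
    born <- c(born, rep(cyc, k))
    active <- c(active, rep(TRUE, k))
  }

  # materialise UIDs: fixed tag of the creating primer + random 10-base barcode
  fwd <- panel$primers[panel$primers$side == "forward", ]
  rev <- panel$primers[panel$primers$side == "reverse", ]
  ftag <- setNames(fwd$fixed_tag, fwd$target_id)
  rtag <- setNames(rev$fixed_tag, rev$target_id)
  bc_len <- fwd$barcode_len[1]
  barcodes <- encode_barcodes(
    sample.int(4^bc_len, uid_n, replace = TRUE) - 1, bc_len)
  tgt <- molecules$target_id[mol]
  strands <- tibble::tibble(
    strand_id = seq_along(mol),
    molecule_id = molecules$molecule_id[mol],
    target_id = tgt,
    tube_id = molecules$tube_id[mol],
    kind = kind,
    left_uid = ifelse(is.na(left), NA_character_,
                      paste0(ftag[tgt], barcodes[left])),
    right_uid = ifelse(is.na(right), NA_character_,
                       paste0(rtag[tgt], barcodes[right])),
    err = err,
    born = born
  )
  complete <- strands[strands$kind == 2L, , drop = FALSE]
  truth <- list(
    uid_pairs = complete[, c("molecule_id", "target_id", "tube_id",
                             "left_uid", "right_uid")],
    vaf = realised_vaf(molecules, panel$truth)
  )
  list(strands = strands, truth = truth)
}

realised_vaf <- function(molecules, truth) {
  purrr::map_dfr(seq_len(nrow(truth)), function(j) {
    m <- molecules[molecules$target_id == truth$target_id[j], ]
    hit <- vapply(strsplit(m$variants, ",", fixed = TRUE),
                  function(v) truth$name[j] %in% v, logical(1))
    tibble::tibble(name = truth$name[j], known_vaf = truth$known_vaf[j],
                   n_molecules = nrow(m), n_mutant = sum(hit),
                   true_vaf = mean(hit))
  })
}

# sparse substitution errors: returns err strings with new "pos:base" tokens
add_synthesis_errors <- function(err, seq_len, rate) {
  if (rate <= 0) return(err)
  n_new <- rbinom(length(err), seq_len, rate)
  hit <- which(n_new > 0)
  for (i in hit) {
    pos <- sample.int(seq_len[i], n_new[i])
    tok <- paste(pos, sample(DNA_BASES, n_new[i], replace = TRUE),
                 sep = ":", collapse = ";")
    err[i] <- if (nzchar(err[i])) paste(err[i], tok, sep = ";") else tok
  }
  err
}

apply_err_tokens <- function(seq, err) {
  hit <- which(nzchar(err))
  for (i in hit) {
    for (tok in strsplit(err[i], ";", fixed = TRUE)[[1]]) {
      kv <- strsplit(tok, ":", fixed = TRUE)[[1]]
      p <- as.integer(kv[1])
      if (p <= nchar(seq[i])) substr(seq[i], p, p) <- kv[2]
    }
  }
  seq
}

encode_barcodes <- function(ints, len) {
  m <- matrix("", length(ints), len)
  x <- ints
  for (k in seq_len(len)) {
    m[, k] <- DNA_BASES[(x %% 4) + 1]
    x <- x %/% 4
  }
  apply(m, 1, paste, collapse = "")
}

#' Simulate index and final amplification
#'
#' Complete amplicons (both UIDs present) are amplified over
#' `index_cycles + final_cycles` rounds of an independent branching process:
#' each copy duplicates in each cycle with probability `efficiency`. No new
#' UIDs are introduced. Copy numbers are exact per-cycle binomial draws;
#' polymerase substitutions accumulated in these later cycles are applied per
#' sequenced read (at `pcr_error` times the expected number of syntheses per
#' surviving lineage) rather than stored per copy.
#'
#' @param strands strand tibble from [simulate_uid_pcr()] (incomplete strands
#'   are dropped here: they cannot form sequenceable library).
#' @param config a [sim_config()].
#' @return pool tibble: one row per complete amplicon with `copies`,
#'   `is_byproduct = FALSE` and the identifying columns of the strand.
#' @export
simulate_index_final_pcr <- function(strands, config) {
  set.seed(derive_stage_seeds(config$seed)[["amplify"]])
  pool <- strands[strands$kind == 2L, , drop = FALSE]
  copies <- rep(1, nrow(pool))
  for (cyc in seq_len(config$index_cycles + config$final_cycles)) {
    copies <- copies + rbinom(length(copies), copies, config$efficiency)
  }
  tibble::tibble(
    pair_id = seq_len(nrow(pool)),
    molecule_id = pool$molecule_id,
    target_id = pool$target_id,
    tube_id = pool$tube_id,
    left_uid = pool$left_uid,
    right_uid = pool$right_uid,
    err = pool$err,
    copies = copies,
    is_byproduct = FALSE,
    byproduct_seq = NA_character_
  )
}

#' Add off-target byproducts to a library pool
#'
#' Artifacts emulate what a multiplex PCR produces besides the intended
#' amplicons: primer-dimer chimeras (a forward primer region, a long random
#' insert, a reverse primer region of the same or a different target) and pure
#' random-insert molecules, with total lengths around 500-700 bp. The number
#' added makes artifacts an expected fraction `byproduct_rate` of the final
#' pool. Artifact sequences never contain a full-length target insert.
#'
#' @param pool pool tibble from [simulate_index_final_pcr()].
#' @param panel the reference panel.
#' @param config a [sim_config()].
#' @return the pool with artifact rows appended (`is_byproduct = TRUE`,
#'   full library sequence in `byproduct_seq`).
#' @export
inject_byproducts <- function(pool, panel, config) {
  rate <- config$byproduct_rate
  if (rate <= 0) return(pool)
  set.seed(derive_stage_seeds(config$seed)[["byproducts"]])
  n_on <- nrow(pool)
  n_art <- stats::rpois(1, n_on * rate / (1 - rate))
  if (n_art == 0) return(pool)
  fwd <- panel$primers[panel$primers$side == "forward", ]
  rev <- panel$primers[panel$primers$side == "reverse", ]
  kind <- sample(c("chimera_same", "chimera_cross", "random"), n_art,
                 replace = TRUE, prob = c(0.25, 0.25, 0.5))
  ins_len <- round(runif(n_art, 440, 640))
  t1 <- sample(fwd$target_id, n_art, replace = TRUE)
  t2 <- ifelse(kind == "chimera_same", t1,
               fwd$target_id[(match(t1, fwd$target_id) %% nrow(fwd)) + 1L])
  junk <- random_dna_vec(ins_len + ifelse(kind == "random", 40L, 0L))
  fwd_seq <- setNames(fwd$target_specific_seq, fwd$target_id)
  rev_rc <- setNames(revcomp(rev$target_specific_seq), rev$target_id)
  core <- ifelse(kind == "random", junk,
                 paste0(fwd_seq[t1], junk, rev_rc[t2]))
  ends <- random_dna_vec(rep(13L, 2 * n_art))
  seqs <- paste0(ends[seq_len(n_art)], core, ends[n_art + seq_len(n_art)])
  art <- tibble::tibble(
    pair_id = n_on + seq_len(n_art),
    molecule_id = NA_integer_,
    target_id = NA_character_,
    tube_id = sample.int(config$n_tubes, n_art, replace = TRUE),
    left_uid = NA_character_,
    right_uid = NA_character_,
    err = "",
    copies = sample(pool$copies, n_art, replace = TRUE),
    is_byproduct = TRUE,
    byproduct_seq = seqs
  )
  dplyr::bind_rows(pool, art)
}

#' Simulate hybrid capture
#'
#' Each library copy is retained independently: on-target copies with
#' probability `capture_on_target_retention`, byproduct copies with
#' `capture_byproduct_retention`. Retentions of `(1, 1)` reproduce the
#' PCR-only protocol exactly (the pool is returned unchanged).
#'
#' @param pool pool tibble (possibly with byproducts).
#' @param config a [sim_config()].
#' @return the pool with thinned `copies`; rows reduced to zero copies are
#'   dropped.
#' @export
simulate_capture <- function(pool, config) {
  r_on <- config$capture_on_target_retention
  r_by <- config$capture_byproduct_retention
  if (r_on == 1 && r_by == 1) return(pool)
  set.seed(derive_stage_seeds(config$seed)[["capture"]])
  p <- ifelse(pool$is_byproduct, r_by, r_on)
  pool$copies <- rbinom(nrow(pool), pool$copies, p)
  pool[pool$copies > 0, , drop = FALSE]
}

#' Sequence a library pool into paired reads
#'
#' Read pairs are sampled with probability proportional to copy number. Read 1
#' is `[left UID (13 nt)][forward primer][insert...]`; read 2 mirrors it from
#' the other end with the right UID and reverse primer. Substitution errors are
#' applied at `seq_error` per base plus the expected later-PCR error per
#' lineage; qualities are constant Phred+33 'I'.
#'
#' @param pool pool tibble after capture.
#' @param molecules molecule tibble (for template sequences).
#' @param panel the reference panel.
#' @param config a [sim_config()].
#' @return list with `reads` (tibble: `read_id`, `seq1`, `qual1`, `seq2`,
#'   `qual2`, `tube_id`) and `read_truth` (read_id to pair/molecule/target
#'   map).
#' @export
sequence_reads <- function(pool, molecules, panel, config) {
  if (nrow(pool) == 0 || sum(pool$copies) == 0) {
    abort("sequence_reads: empty pool")
  }
  set.seed(derive_stage_seeds(config$seed)[["sequencing"]])
  # library molecule strings (sense): leftUID + amplicon(+errors) + rc(rightUID)
  lib <- pool$byproduct_seq
  on_t <- which(!pool$is_byproduct)
  if (length(on_t)) {
    body <- molecules$mol_seq[match(pool$molecule_id[on_t],
                                    molecules$molecule_id)]
    body <- apply_err_tokens(body, pool$err[on_t])
    lib[on_t] <- paste0(pool$left_uid[on_t], body,
                        revcomp(pool$right_uid[on_t]))
  }
  lib_rc <- revcomp(lib)
  idx <- sample.int(nrow(pool), config$n_read_pairs, replace = TRUE,
                    prob = pool$copies)
  seq1 <- substr(lib[idx], 1, config$read_len)
  seq2 <- substr(lib_rc[idx], 1, config$read_len)
  late_pcr <- config$pcr_error * (config$index_cycles + config$final_cycles) *
    config$efficiency / (1 + config$efficiency)
  err_rate <- config$seq_error + late_pcr
  seq1 <- apply_subst_errors(seq1, err_rate)
  seq2 <- apply_subst_errors(seq2, err_rate)
  qual <- strrep("I", nchar(seq1))
  read_id <- sprintf("r%08d", seq_along(idx))
  reads <- tibble::tibble(
    read_id = read_id, seq1 = seq1, qual1 = qual,
    seq2 = seq2, qual2 = strrep("I", nchar(seq2)),
    tube_id = pool$tube_id[idx]
  )
  read_truth <- tibble::tibble(
    read_id = read_id,
    pair_id = pool$pair_id[idx],
    molecule_id = pool$molecule_id[idx],
    target_id = pool$target_id[idx],
    tube_id = pool$tube_id[idx],
    is_byproduct = pool$is_byproduct[idx]
  )
  list(reads = reads, read_truth = read_truth)
}

apply_subst_errors <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  n_err <- rbinom(length(seqs), nchar(seqs), rate)
  # single-error reads (the vast majority) handled in one vectorised pass:
  # substitute by rotating the original base 1-3 steps through the alphabet
  one <- which(n_err == 1L)
  if (length(one)) {
    pos <- 1L + floor(runif(length(one)) * nchar(seqs[one]))
    old <- match(substr(seqs[one], pos, pos), DNA_BASES)
    new <- DNA_BASES[((old - 1L +
                         sample.int(3, length(one), replace = TRUE)) %% 4) + 1L]
    new[is.na(old)] <- "A"   # non-ACGT character: overwrite arbitrarily
    substr(seqs[one], pos, pos) <- new
  }
  multi <- which(n_err > 1L)
  for (i in multi) {
    pos <- sample.int(nchar(seqs[i]), n_err[i])
    for (k in seq_along(pos)) {
      old <- substr(seqs[i], pos[k], pos[k])
      substr(seqs[i], pos[k], pos[k]) <- sample(setdiff(DNA_BASES, old), 1)
    }
  }
  seqs
}

# one draw per base, concatenated and split at the requested lengths
random_dna_vec <- function(lens) {
  if (!length(lens)) return(character(0))
  total <- sum(lens)
  all <- paste(sample(DNA_BASES, total, replace = TRUE), collapse = "")
  ends <- cumsum(lens)
  substring(all, ends - lens + 1, ends)
}

#' Simulate a complete experiment
#'
#' Chains [spike_molecules()], [simulate_uid_pcr()],
#' [simulate_index_final_pcr()], [inject_byproducts()], [simulate_capture()]
#' and [sequence_reads()]. Identical `config` (including seed) gives
#' byte-identical output.
#'
#' @param panel an [synthetic_panel()] object.
#' @param config a [sim_config()].
#' @return object of class `amplicon_sim`: list with `reads`, `read_truth`,
#'   `molecules`, `strands`, `truth`, `pool_summary`, `panel`, `config`.
#' @examples
#' \donttest{
#' panel <- synthetic_panel(vaf = 0.01)
#' sim <- simulate_experiment(panel, sim_config(n_molecules = 50,
#'                                              n_read_pairs = 2000, seed = 1))
#' }
#' @export
simulate_experiment <- function(panel, config) {
  molecules <- spike_molecules(panel, config)
  pcr <- simulate_uid_pcr(molecules, panel, config)
  pool <- simulate_index_final_pcr(pcr$strands, config)
  pool <- inject_byproducts(pool, panel, config)
  pool <- simulate_capture(pool, config)
  sr <- sequence_reads(pool, molecules, panel, config)
  structure(list(
    reads = sr$reads,
    read_truth = sr$read_truth,
    molecules = molecules,
    strands = pcr$strands,
    truth = pcr$truth,
    pool_summary = dplyr::count(pool, .data$is_byproduct,
                                wt = .data$copies, name = "copies"),
    panel = panel,
    config = config
  ), class = "amplicon_sim")
}

#' @export
print.amplicon_sim <- function(x, ...) {
  cat(sprintf(
    "<amplicon_sim> %d read pairs, %d molecules, %d complete UID pairs, seed %d\n",
    nrow(x$reads), nrow(x$molecules), sum(x$strands$kind == 2L),
    x$config$seed))
  invisible(x)
}
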