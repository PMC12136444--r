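test_that("spiked mutant counts follow the binomial expectation", {
  # one SNV target, VAF 5e-4, 2900 genome equivalents: expected 1.45 mutants
  panel <- subset_panel(synthetic_panel(vaf = 5e-4), "RP01")
  counts <- vapply(1:1000, function(s) {
    m <- spike_molecules(panel, sim_config(n_molecules = 2900, seed = s))
    sum(m$variants != "")
  }, numeric(1))
  expected <- 2900 * 5e-4
  se <- sqrt(2900 * 5e-4 * (1 - 5e-4) / 1000)
  expect_lt(abs(mean(counts) - expected), 3 * se)
})

test_that("VAF 0 and VAF 1 are degenerate spikes", {
  cfg <- sim_config(n_molecules = 200, seed = 2)
  m0 <- spike_molecules(synthetic_panel(vaf = 0), cfg)
  expect_true(all(m0$variants == ""))
  m1 <- spike_molecules(synthetic_panel(vaf = 1), cfg)
  pos_targets <- c("RP01", "RP03", "RP04", "RP05")  # single-SNV and SNV-pair targets
  expect_true(all(m1$variants[m1$target_id %in% pos_targets] != ""))
  expect_error(
    spike_molecules(local({
      p <- synthetic_panel(); p$truth$known_vaf[1] <- 1.5; p
    }), cfg), "VAF")
})

test_that("molecules spread across tubes round-robin and cover every target", {
  cfg <- sim_config(n_molecules = 64, n_tubes = 8, seed = 3)
  m <- spike_molecules(test_panel(), cfg)
  expect_equal(nrow(m), 64 * 7)
  expect_equal(as.integer(table(m$tube_id)), rep(56L, 8))  # 64*7/8 per tube
  expect_equal(sort(unique(m$target_id)), sort(test_panel()$targets$target_id))
})

test_that("UID genealogy attains the per-molecule ceiling at full efficiency", {
  panel <- synthetic_panel(vaf = 0)
  for (cyc in 2:6) {
    cfg <- sim_config(n_molecules = 3, n_tubes = 1, uid_cycles = cyc,
                      efficiency = 1, n_read_pairs = 10, seed = 5)
    mol <- spike_molecules(panel, cfg)
    mol <- mol[mol$target_id == "RP01", ]
    pcr <- simulate_uid_pcr(mol, panel, cfg)
    complete <- pcr$strands[pcr$strands$kind == 2, ]
    per_mol <- table(complete$molecule_id)
    oracle <- length(oracle_genealogy_pairs(cyc))
    expect_equal(oracle, 2^cyc - 2)
    expect_true(all(per_mol == oracle))
  }
})

test_that("UID-pair counts never exceed 2^cycles - 2 at any efficiency", {
  panel <- synthetic_panel(vaf = 0)
  set.seed(42)
  for (i in 1:8) {
    eff <- runif(1, 0.2, 0.95)
    cyc <- sample(2:6, 1)
    cfg <- sim_config(n_molecules = 8, n_tubes = 1, uid_cycles = cyc,
                      efficiency = eff, n_read_pairs = 10, seed = i)
    mol <- spike_molecules(panel, cfg)
    pcr <- simulate_uid_pcr(mol, panel, cfg)
    complete <- pcr$strands[pcr$strands$kind == 2, ]
    if (nrow(complete)) {
      expect_lte(max(table(complete$molecule_id)), 2^cyc - 2)
    }
  }
})

test_that("a daughter shares exactly one UID with its template lineage", {
  panel <- synthetic_panel(vaf = 0)
  cfg <- sim_config(n_molecules = 5, n_tubes = 1, uid_cycles = 6,
                    efficiency = 0.8, n_read_pairs = 10, seed = 9)
  mol <- spike_molecules(panel, cfg)
  mol <- mol[mol$target_id == "RP02", ]
  pcr <- simulate_uid_pcr(mol, panel, cfg)
  complete <- pcr$strands[pcr$strands$kind == 2, ]
  # within a molecule the complete pairs form one or two connected families
  # under the share-a-UID relation (one per original strand)
  for (mid in unique(complete$molecule_id)) {
    cp <- complete[complete$molecule_id == mid, ]
    if (nrow(cp) < 2) next
    edges <- which(outer(cp$left_uid, cp$left_uid, "==") |
                     outer(cp$right_uid, cp$right_uid, "=="), arr.ind = TRUE)
    edges <- edges[edges[, 1] < edges[, 2], , drop = FALSE]
    comp <- oracle_components(nrow(cp),
                              tibble::tibble(from = edges[, 1],
                                             to = edges[, 2]))
    expect_lte(length(unique(comp)), 2)
  }
})

test_that("index/final amplification is an exact branching process", {
  strands <- tibble::tibble(
    strand_id = 1, molecule_id = 1, target_id = "RP01", tube_id = 1,
    kind = 2L, left_uid = "AAAAAAAAAAAAA", right_uid = "CCCCCCCCCCCCC",
    err = "", born = 2L)
  cfg1 <- sim_config(index_cycles = 3, final_cycles = 0, efficiency = 1,
                     seed = 1)
  expect_equal(simulate_index_final_pcr(strands, cfg1)$copies, 8)  # 2^3
  # efficiency ~0: copy number unchanged
  cfg0 <- sim_config(index_cycles = 3, final_cycles = 0, efficiency = 1e-12,
                     seed = 1)
  expect_equal(simulate_index_final_pcr(strands, cfg0)$copies, 1)
  # mean copies approaches (1 + eff)^cycles
  cfg <- sim_config(index_cycles = 5, final_cycles = 5, efficiency = 0.4,
                    seed = 1)
  many <- strands[rep(1, 3000), ]
  copies <- simulate_index_final_pcr(many, cfg)$copies
  expected <- (1.4)^10
  se <- stats::sd(copies) / sqrt(length(copies))
  expect_lt(abs(mean(copies) - expected), 4 * se)
  # incomplete strands never enter the library
  half <- strands
  half$kind <- 1L
  expect_equal(nrow(simulate_index_final_pcr(half, cfg)), 0)
})

test_that("byproduct injection hits its expected fraction and stays off-target", {
  panel <- test_panel()
  pool <- tibble::tibble(
    pair_id = 1:1000, molecule_id = 1:1000, target_id = "RP01", tube_id = 1L,
    left_uid = "x", right_uid = "y", err = "", copies = 10,
    is_byproduct = FALSE, byproduct_seq = NA_character_)
  cfg <- sim_config(byproduct_rate = 0.5, seed = 21)
  out <- inject_byproducts(pool, panel, cfg)
  n_art <- sum(out$is_byproduct)
  expect_lt(abs(n_art - 1000), 4 * sqrt(1000))   # ~1000 artifacts for rate 0.5
  # artifacts never contain a full-length target insert
  inserts <- substr(panel$reference, panel$primer_len + 1,
                    panel$amplicon_len - panel$primer_len)
  art_seq <- out$byproduct_seq[out$is_byproduct]
  hits <- vapply(inserts, function(ins) any(grepl(ins, art_seq, fixed = TRUE)),
                 logical(1))
  expect_false(any(hits))
  # rate 0: pool unchanged
  cfg0 <- sim_config(byproduct_rate = 0, seed = 21)
  expect_identical(inject_byproducts(pool, panel, cfg0), pool)
})

test_that("capture retains by class and (1,1) is the PCR-only identity", {
  pool <- tibble::tibble(
    pair_id = 1:200, molecule_id = 1:200, target_id = "RP01", tube_id = 1L,
    left_uid = "x", right_uid = "y", err = "",
    copies = rep(100, 200),
    is_byproduct = rep(c(FALSE, TRUE), each = 100),
    byproduct_seq = NA_character_)
  cfg <- sim_config(capture_on_target_retention = 1,
                    capture_byproduct_retention = 0, seed = 2)
  out <- simulate_capture(pool, cfg)
  expect_true(all(!out$is_byproduct))
  expect_equal(sum(out$copies), 100 * 100)
  cfg11 <- sim_config(capture_on_target_retention = 1,
                      capture_byproduct_retention = 1, seed = 2)
  expect_identical(simulate_capture(pool, cfg11), pool)
  # enrichment arithmetic: 0.95 vs 0.01 retention on a 50/50 pool -> ~0.99
  cfg2 <- sim_config(capture_on_target_retention = 0.95,
                     capture_byproduct_retention = 0.01, seed = 2)
  out2 <- simulate_capture(pool, cfg2)
  frac <- sum(out2$copies[!out2$is_byproduct]) / sum(out2$copies)
  expect_lt(abs(frac - 0.95 / 0.96), 0.02)
})

test_that("sequencing emits the requested pairs and is seed-deterministic", {
  panel <- test_panel()
  cfg <- small_config(seed = 8)
  sim1 <- simulate_experiment(panel, cfg)
  expect_equal(nrow(sim1$reads), cfg$n_read_pairs)
  sim2 <- simulate_experiment(panel, cfg)
  expect_identical(sim1$reads, sim2$reads)   # byte-identical repeat
  p1a <- withr::local_tempfile(fileext = ".fastq.gz")
  p2a <- withr::local_tempfile(fileext = ".fastq.gz")
  p1b <- withr::local_tempfile(fileext = ".fastq.gz")
  p2b <- withr::local_tempfile(fileext = ".fastq.gz")
  write_fastq_pairs(sim1$reads, p1a, p2a)
  write_fastq_pairs(sim2$reads, p1b, p2b)
  expect_identical(readLines(p1a), readLines(p1b))
  # different seed, different reads
  sim3 <- simulate_experiment(panel, small_config(seed = 9))
  expect_false(identical(sim1$reads$seq1, sim3$reads$seq1))
  empty_pool <- tibble::tibble(copies = numeric(0), is_byproduct = logical(0))
  expect_error(sequence_reads(empty_pool, sim1$molecules, panel, cfg),
               "empty pool")
})

test_that("error-free reads reproduce their template exactly", {
  panel <- test_panel()
  cfg <- sim_config(n_molecules = 30, n_read_pairs = 500, pcr_error = 0,
                    seq_error = 0, byproduct_rate = 0, seed = 6)
  sim <- simulate_experiment(panel, cfg)
  mol <- sim$molecules
  idx <- match(sim$read_truth$molecule_id, mol$molecule_id)
  body <- mol$mol_seq[idx]
  insert1 <- substr(sim$reads$seq1, 14, nchar(sim$reads$seq1))
  expect_true(all(insert1 == substr(body, 1, nchar(insert1))))
})

test_that("simulation truth records the realised VAF exactly", {
  panel <- synthetic_panel(vaf = 0.05)
  cfg <- sim_config(n_molecules = 400, n_read_pairs = 100, seed = 13)
  mol <- spike_molecules(panel, cfg)
  pcr <- simulate_uid_pcr(mol, panel, cfg)
  v <- pcr$truth$vaf
  for (j in seq_len(nrow(v))) {
    m <- mol[mol$target_id == panel$truth$target_id[match(v$name[j],
                                                          panel$truth$name)], ]
    manual <- mean(vapply(strsplit(m$variants, ","),
                          function(x) v$name[j] %in% x, logical(1)))
    expect_equal(v$true_vaf[j], manual)
  }
})
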