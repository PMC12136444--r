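make_clean_reads <- function(panel, n = 40, seed = 6) {
  cfg <- sim_config(n_molecules = n, n_read_pairs = 25 * n, pcr_error = 0,
                    seq_error = 0, byproduct_rate = 0, seed = seed)
  simulate_experiment(panel, cfg)
}

test_that("adapter trimmer removes 3' read-through and drops short survivors", {
  insert <- "ACGTTGCAGGCATTACGGATCCAGTTGCAAT"   # 31 nt
  ad1 <- ADAPTER_READ1
  reads <- tibble::tibble(
    read_id = c("with", "without", "short"),
    seq1 = c(paste0(insert, ad1),
             insert,
             paste0(substr(insert, 1, 12), ad1)),
    qual1 = strrep("I", nchar(c(paste0(insert, ad1), insert,
                                paste0(substr(insert, 1, 12), ad1)))),
    seq2 = insert, qual2 = strrep("I", nchar(insert)), tube_id = 1L
  )
  out <- trim_adapter(reads, adapter1 = ad1, adapter2 = ad1)
  expect_equal(out$n_dropped, 1)                       # "short" falls under 30
  expect_equal(out$reads$seq1[out$reads$read_id == "with"], insert)
  expect_equal(out$reads$seq1[out$reads$read_id == "without"], insert)
  # one mismatch per 10 bases is tolerated
  ad_err <- paste0("T", substr(ad1, 2, 34))
  r2 <- tibble::tibble(read_id = "mm", seq1 = paste0(insert, ad_err),
                       qual1 = strrep("I", nchar(insert) + 34),
                       seq2 = insert, qual2 = strrep("I", nchar(insert)),
                       tube_id = 1L)
  out2 <- trim_adapter(r2, adapter1 = ad1, adapter2 = ad1)
  expect_equal(out2$reads$seq1, insert)
})

test_that("extraction demands exact primer matches on both mates", {
  panel <- test_panel()
  sim <- make_clean_reads(panel)
  ex <- extract_target_reads(sim$reads, panel$primers)
  # zero-error simulation: every pair assigned, to its true target
  expect_equal(unname(ex$counts["assigned"]), nrow(sim$reads))
  expect_equal(unname(ex$counts["off_target"]), 0)
  truth_target <- sim$read_truth$target_id[match(ex$fragments$read_id,
                                                 sim$read_truth$read_id)]
  expect_equal(ex$fragments$target_id, truth_target)

  # one mismatch inside the primer region: unassigned
  broken <- sim$reads[1:10, ]
  p <- 20L  # inside the forward target-specific primer (positions 14..33)
  old <- substr(broken$seq1, p, p)
  substr(broken$seq1, p, p) <- ifelse(old == "A", "C", "A")
  ex2 <- extract_target_reads(broken, panel$primers)
  expect_equal(unname(ex2$counts["assigned"]), 0)
  expect_equal(unname(ex2$counts["off_target"]), 10)

  # matching primer but corrupted fixed tag: discarded and logged separately
  tagged <- sim$reads[1:10, ]
  old <- substr(tagged$seq1, 1, 1)
  substr(tagged$seq1, 1, 1) <- ifelse(old == "A", "C", "A")
  ex3 <- extract_target_reads(tagged, panel$primers)
  expect_equal(unname(ex3$counts["tag_mismatch"]), 10)
  expect_equal(unname(ex3$counts["assigned"]), 0)

  # conservation: assigned + off-target + tag mismatches = input pairs
  expect_equal(sum(ex$counts), nrow(sim$reads))
  expect_equal(sum(ex2$counts), nrow(broken))
  expect_equal(sum(ex3$counts), nrow(tagged))
})

test_that("identical primers across targets are rejected at load time", {
  panel <- test_panel()
  primers <- panel$primers
  primers$target_specific_seq[primers$side == "forward"][2] <-
    primers$target_specific_seq[primers$side == "forward"][1]
  expect_error(extract_target_reads(tibble::tibble(), primers),
               "identical target-specific")
})

test_that("error-free fragments align at full mapping quality", {
  panel <- test_panel()
  sim <- make_clean_reads(panel)
  ex <- extract_target_reads(sim$reads, panel$primers)
  al <- align_to_amplicon(ex, panel)
  expect_equal(nrow(al), nrow(ex$fragments))
  expect_true(all(al$mapq == 60))
  expect_true(all(!al$softclip))
  # calls equal the reference wherever covered (wild-type molecules)
  mol <- sim$molecules
  wt <- al[mol$variants[match(sim$read_truth$molecule_id[
    match(al$read_id, sim$read_truth$read_id)], mol$molecule_id)] == "", ]
  one <- wt[1, ]
  ref <- panel$reference[[one$target_id]]
  covered <- which(strsplit(one$calls1, "")[[1]] != "N")
  expect_equal(substr(one$calls1, min(covered), max(covered)),
               substr(ref, min(covered), max(covered)))
})

test_that("a deletion read aligns with the gap at the truth coordinates", {
  panel <- test_panel()
  tv <- panel$truth[panel$truth$vtype == "deletion", ]
  a0 <- panel$targets$amplicon_start[panel$targets$target_id == "RP02"]
  fwd <- panel$primers[panel$primers$target_id == "RP02" &
                         panel$primers$side == "forward", ]
  for (j in 1:2) {
    res <- ampliclust:::apply_variants(panel$reference[["RP02"]], tv[j, ], a0)
    lib <- paste0(fwd$fixed_tag, strrep("A", 10), res$seq)
    reads <- tibble::tibble(
      read_id = "d", target_id = "RP02", tube_id = 1L,
      left_uid = substr(lib, 1, 13), right_uid = "XXXXXXXXXXXXX",
      seq1 = substr(lib, 1, 150),
      seq2 = paste0("TTTTTTTTTTTTT", ampliclust:::revcomp(res$seq)))
    al <- align_to_amplicon(reads, panel)
    gap <- detect_deletion(strsplit(al$calls1, "")[[1]], a0, "chr7")
    expect_equal(gap$start, tv$pos_start[j])
    expect_equal(gap$end, tv$pos_end[j])
    expect_gte(al$mapq, 45)
    expect_false(al$softclip)
  }
})

test_that("junk reads score low and terminal junk is soft-clipped", {
  panel <- test_panel()
  fwd <- panel$primers[panel$primers$target_id == "RP01" &
                         panel$primers$side == "forward", ]
  rev <- panel$primers[panel$primers$target_id == "RP01" &
                         panel$primers$side == "reverse", ]
  set.seed(5)
  junk <- paste(sample(c("A", "C", "G", "T"), 117, replace = TRUE),
                collapse = "")
  reads <- tibble::tibble(
    read_id = "junk", target_id = "RP01", tube_id = 1L,
    left_uid = paste0(fwd$fixed_tag, strrep("A", 10)),
    right_uid = paste0(rev$fixed_tag, strrep("C", 10)),
    seq1 = paste0(fwd$fixed_tag, strrep("A", 10), fwd$target_specific_seq,
                  junk),
    seq2 = paste0(rev$fixed_tag, strrep("C", 10), rev$target_specific_seq,
                  junk))
  al <- align_to_amplicon(reads, panel)
  expect_true(al$mapq < 45 || al$softclip)
  expect_equal(nrow(filter_fragments(al)), 0)
})

test_that("gapped aligner scores match the exhaustive affine DP", {
  set.seed(31)
  ref_pool <- c("A", "C", "G", "T")
  for (i in 1:200) {
    ns <- sample(30:60, 1)
    subj <- paste(sample(ref_pool, ns, replace = TRUE), collapse = "")
    kind <- sample(1:3, 1)
    pat <- if (kind == 1) {
      a <- sample(1:(ns - 12), 1)
      substr(subj, a, a + sample(10:12, 1))
    } else if (kind == 2) {
      mid <- sample(6:(ns - 10), 1)
      paste0(substr(subj, 2, mid), substr(subj, mid + sample(2:6, 1) + 1,
                                          ns - 1))
    } else {
      paste(sample(ref_pool, sample(10:30, 1), replace = TRUE), collapse = "")
    }
    if (nchar(pat) < 8) next
    got <- ampliclust:::gapped_align(pat, subj)$score
    expect_equal(got, oracle_align_score(pat, subj), info = paste(pat, subj))
  }
})

test_that("MAPQ/soft-clip filter keeps the stated boundary", {
  fr <- tibble::tibble(read_id = c("a", "b", "c"),
                       mapq = c(45, 44, 60),
                       softclip = c(FALSE, FALSE, TRUE))
  kept <- filter_fragments(fr)
  expect_equal(kept$read_id, "a")
})

test_that("zero-error, byproduct-free runs keep every pair through filtering", {
  panel <- test_panel()
  sim <- make_clean_reads(panel, n = 30, seed = 12)
  ex <- extract_target_reads(sim$reads, panel$primers)
  al <- align_to_amplicon(ex, panel)
  kept <- filter_fragments(al)
  expect_equal(nrow(kept), nrow(sim$reads))
})
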