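# Independent oracles used to freeze expected values. Each re-derives the
# quantity with a brute-force method that shares no code with the package.

# --- brute-force cross-overlap scan -------------------------------------------
# longest common substring of a and revcomp(b) by scanning all substrings
oracle_overlap <- function(a, b) {
  rc <- c(A = "T", C = "G", G = "C", T = "A")
  bv <- strsplit(b, "")[[1]]
  rb <- paste(rev(unname(rc[bv])), collapse = "")
  av <- strsplit(a, "")[[1]]
  rv <- strsplit(rb, "")[[1]]
  best <- 0L
  for (i in seq_along(av)) {
    for (j in seq_along(rv)) {
      k <- 0L
      while (i + k <= length(av) && j + k <= length(rv) &&
             av[i + k] == rv[j + k]) {
        k <- k + 1L
      }
      best <- max(best, k)
    }
  }
  best
}

# --- exhaustive affine-gap DP (global in pattern, local in subject) ----------
# match +1, mismatch -4, gap of length L costs open + L * ext; no banding.
# States: M = last op aligned pair, X = last op pattern insertion (gap in
# subject), Y = last op subject deletion (gap in pattern). Leading/trailing
# subject bases are free (local in subject); the whole pattern is consumed.
oracle_align_score <- function(pattern, subject, match = 1, mismatch = -4,
                               open = 6, ext = 1) {
  p <- strsplit(pattern, "")[[1]]
  s <- strsplit(subject, "")[[1]]
  np <- length(p); ns <- length(s)
  NEG <- -1e9
  M <- matrix(NEG, np + 1, ns + 1)
  X <- matrix(NEG, np + 1, ns + 1)
  Y <- matrix(NEG, np + 1, ns + 1)
  for (i in 1:np) {
    for (j in 0:ns) {
      jc <- j + 1L
      if (j > 0) {
        sc <- if (p[i] == s[j]) match else mismatch
        prev <- max(M[i, jc - 1], X[i, jc - 1], Y[i, jc - 1],
                    if (i == 1) 0 else NEG)   # free subject prefix
        M[i + 1, jc] <- prev + sc
      }
      X[i + 1, jc] <- max(M[i, jc] - open - ext, X[i, jc] - ext,
                          Y[i, jc] - open - ext,
                          if (i == 1) -open - ext else NEG)
      if (j > 0) {
        Y[i + 1, jc] <- max(M[i + 1, jc - 1] - open - ext,
                            Y[i + 1, jc - 1] - ext,
                            X[i + 1, jc - 1] - open - ext)
      }
    }
  }
  max(M[np + 1, ], X[np + 1, ])   # free subject suffix
}

# --- transitive closure components (Warshall) --------------------------------
oracle_components <- function(n, edges) {
  A <- diag(TRUE, n)
  if (nrow(edges)) {
    for (k in seq_len(nrow(edges))) {
      A[edges$from[k], edges$to[k]] <- TRUE
      A[edges$to[k], edges$from[k]] <- TRUE
    }
  }
  for (k in seq_len(n)) {
    A <- A | (A[, k] %o% A[k, ])
  }
  comp <- integer(n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (comp[i] == 0L) {
      cid <- cid + 1L
      comp[A[i, ]] <- cid
    }
  }
  comp
}

# --- exhaustive genealogy enumerator at efficiency 1 -------------------------
# Recursive tree expansion, one molecule: two original strands each template a
# UID primer once; every UID-bearing strand is primed every cycle; daughters
# share the template's far-end UID and carry one fresh UID.
oracle_genealogy_pairs <- function(cycles) {
  uid <- 0L
  new_uid <- function() { uid <<- uid + 1L; uid }
  # strand: list(left, right, next_side); originals tracked separately
  strands <- list()
  originals <- list(list(side = "F", used = FALSE),
                    list(side = "R", used = FALSE))
  for (cyc in seq_len(cycles)) {
    daughters <- list()
    for (k in seq_along(originals)) {
      if (!originals[[k]]$used) {
        u <- new_uid()
        d <- if (originals[[k]]$side == "F") {
          list(left = u, right = NA, next_side = "R")
        } else {
          list(left = NA, right = u, next_side = "F")
        }
        daughters[[length(daughters) + 1]] <- d
        originals[[k]]$used <- TRUE
      }
    }
    for (s in strands) {
      u <- new_uid()
      d <- if (s$next_side == "F") {
        list(left = u, right = s$right, next_side = "R")
      } else {
        list(left = s$left, right = u, next_side = "F")
      }
      daughters[[length(daughters) + 1]] <- d
    }
    strands <- c(strands, daughters)
  }
  pairs <- vapply(strands, function(s) {
    if (!is.na(s$left) && !is.na(s$right)) paste(s$left, s$right)
    else NA_character_
  }, character(1))
  unique(pairs[!is.na(pairs)])
}

# --- shared fixtures ---------------------------------------------------------
test_panel <- function(vaf = 0.01) synthetic_panel(vaf = vaf)

# restrict a panel to a subset of targets (keeps the object consistent)
subset_panel <- function(panel, target_ids) {
  panel$targets <- panel$targets[panel$targets$target_id %in% target_ids, ]
  panel$primers <- panel$primers[panel$primers$target_id %in% target_ids, ]
  panel$truth <- panel$truth[panel$truth$target_id %in% target_ids, ]
  panel$reference <- panel$reference[target_ids]
  panel
}

small_config <- function(seed = 1, ...) {
  sim_config(n_molecules = 60, n_read_pairs = 6000, seed = seed, ...)
}

# memoised full-scale runs shared across acceptance checks
.run_cache <- new.env(parent = emptyenv())
acceptance_run <- function(vaf, seed) {
  key <- sprintf("v%s_s%d", vaf, seed)
  if (is.null(.run_cache[[key]])) {
    panel <- synthetic_panel(vaf = vaf)
    .run_cache[[key]] <- run_experiment(panel, sim_config(seed = seed))
  }
  .run_cache[[key]]
}
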