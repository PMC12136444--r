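#' Group fragments by UID pair
#'
#' One group per distinct `(target_id, left_uid, right_uid)` combination.
#' Groups below `min_depth` read pairs are discarded (a UID pair must be seen
#' at least twice to be trusted) and counted in the `dropped_low_depth`
#' attribute.
#'
#' @param fragments filtered fragment tibble (see [filter_fragments()]).
#' @param min_depth minimum read-pair depth per UID pair.
#' @return tibble of UID-pair groups: `group_id`, `target_id`, `left_uid`,
#'   `right_uid`, `tube_id` (modal member tube), `depth`, `frag_rows` (list of
#'   row indices into `fragments`); attribute `dropped_low_depth` carries the
#'   discarded group count.
#' @export
group_by_uid_pair <- function(fragments, min_depth = 2) {
  dt <- data.table::data.table(
    row = seq_len(nrow(fragments)),
    target_id = fragments$target_id,
    left_uid = fragments$left_uid,
    right_uid = fragments$right_uid,
    tube_id = fragments$tube_id
  )
  g <- dt[, .(depth = .N, tube_id = modal_int(tube_id),
              frag_rows = list(row)),
          by = c("target_id", "left_uid", "right_uid")]
  dropped <- sum(g$depth < min_depth)
  g <- g[g$depth >= min_depth, ]
  out <- tibble::as_tibble(g)
  out$group_id <- seq_len(nrow(out))
  out <- dplyr::select(out, "group_id", "target_id", "left_uid", "right_uid",
                       "tube_id", "depth", "frag_rows")
  attr(out, "dropped_low_depth") <- dropped
  out
}

modal_int <- function(x) {
  ux <- unique(x)
  ux[which.max(tabulate(match(x, ux)))]
}

#' Build the peer-to-peer UID-pair network
#'
#' Two UID-pair groups of the same target are connected when they share the
#' left UID or the right UID. Left and right UIDs live in disjoint namespaces
#' (the two ends are chemically distinct primers), so a left UID never links to
#' a right UID. Networks are per target: UID reuse across targets cannot
#' connect groups.
#'
#' @param groups tibble from [group_by_uid_pair()].
#' @return tibble of undirected edges: `from`, `to` (group ids, `from < to`).
#' @export
build_uid_network <- function(groups) {
  dt <- data.table::data.table(id = groups$group_id,
                               target_id = groups$target_id,
                               left_uid = groups$left_uid,
                               right_uid = groups$right_uid)
  edges_for <- function(key) {
    b <- dt[, .(ids = list(id)), by = c("target_id", key)]
    b <- b[vapply(b$ids, length, integer(1)) > 1, ]
    if (!nrow(b)) return(data.table::data.table(from = integer(0),
                                                to = integer(0)))
    data.table::rbindlist(lapply(b$ids, function(v) {
      v <- sort(v)
      p <- utils::combn(v, 2)
      data.table::data.table(from = p[1, ], to = p[2, ])
    }))
  }
  e <- data.table::rbindlist(list(edges_for("left_uid"),
                                  edges_for("right_uid")))
  e <- unique(e)
  tibble::as_tibble(e[order(e$from, e$to), ])
}

#' Find UID clusters as connected components
#'
#' Connected components of the UID-pair network, found with an iterative
#' depth-first search over an explicit stack (no recursion, so components of
#' 10^5 nodes are safe). Each cluster descends from one original template
#' strand; its pooled base tallies are the sum over member groups.
#'
#' @param groups tibble from [group_by_uid_pair()].
#' @param network edge tibble from [build_uid_network()].
#' @return tibble of clusters: `cluster_id`, `target_id`, `tube_id` (modal
#'   member tube), `n_uid_pairs`, `depth` (total read pairs), `members` (list
#'   of group ids).
#' @export
find_clusters <- function(groups, network) {
  n <- nrow(groups)
  comp <- integer(n)               # 0 = unvisited
  adj <- vector("list", n)
  if (nrow(network)) {
    ft <- c(network$from, network$to)
    tf <- c(network$to, network$from)
    o <- order(ft)
    adj_split <- split(tf[o], ft[o])
    adj[as.integer(names(adj_split))] <- adj_split
  }
  n_comp <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    n_comp <- n_comp + 1L
    stack <- s
    comp[s] <- n_comp
    while (length(stack)) {
      v <- stack[length(stack)]
      stack <- stack[-length(stack)]
      nb <- adj[[v]]
      new <- nb[comp[nb] == 0L]
      comp[new] <- n_comp
      stack <- c(stack, new)
    }
  }
  dt <- data.table::data.table(comp = comp,
                               target_id = groups$target_id,
                               tube_id = groups$tube_id,
                               depth = groups$depth,
                               gid = groups$group_id)
  cl <- dt[, .(target_id = target_id[1], tube_id = modal_int(tube_id),
               n_uid_pairs = .N, depth = sum(depth), members = list(gid)),
           by = "comp"]
  out <- tibble::as_tibble(cl[order(cl$comp), ])
  out$cluster_id <- out$comp
  dplyr::select(out, "cluster_id", "target_id", "tube_id", "n_uid_pairs",
                "depth", "members")
}

#' Filter clusters by the UID-genealogy bounds and assign CIDs
#'
#' Discards clusters with fewer than `min_uid_pairs` unique UID pairs (too
#' little evidence of independent amplification) and clusters with more than
#' `2^uid_cycles - 2` pairs (more than the genealogy can produce from one
#' template — a barcode-collision chimera). Survivors receive sequential
#' cluster identifiers `T<target>#<serial>`, deterministic given input order.
#'
#' @param clusters tibble from [find_clusters()].
#' @param uid_cycles UID-tagging PCR cycle count.
#' @param min_uid_pairs minimum unique UID pairs per cluster.
#' @return the surviving clusters with a `cid` column; attributes
#'   `dropped_small` and `dropped_oversize` carry the excluded counts.
#' @export
filter_clusters <- function(clusters, uid_cycles = 10, min_uid_pairs = 2) {
  if (uid_cycles < 2) abort("filter_clusters: uid_cycles must be >= 2")
  max_pairs <- 2^uid_cycles - 2
  small <- clusters$n_uid_pairs < min_uid_pairs
  big <- clusters$n_uid_pairs > max_pairs
  out <- clusters[!small & !big, , drop = FALSE]
  out <- out[order(out$target_id), , drop = FALSE]
  serial <- stats::ave(seq_len(nrow(out)), out$target_id,
                       FUN = seq_along)
  out$cid <- sprintf("T%s#%d", out$target_id, serial)
  attr(out, "dropped_small") <- sum(small)
  attr(out, "dropped_oversize") <- sum(big)
  out
}
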