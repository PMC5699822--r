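#' Robinson-Foulds distance between two topologies
#'
#' Size of the symmetric difference of the two trees' sets of non-trivial
#' bipartitions, on unrooted topologies; branch lengths are ignored and
#' multifurcations are allowed.
#'
#' @param t1,t2 `ape::phylo` trees over the same leaf set.
#' @param restrict_to_shared If `TRUE`, prune both trees to their common
#'   leaf set first (with a warning) instead of erroring on a mismatch.
#' @return Even non-negative integer; 0 iff the topologies agree.
#' @export
rf_distance <- function(t1, t2, restrict_to_shared = FALSE) {
  ts <- match_leaf_sets(t1, t2, restrict_to_shared)
  s1 <- tree_splits(ts[[1L]]); s2 <- tree_splits(ts[[2L]])
  length(setdiff(s1, s2)) + length(setdiff(s2, s1))
}

match_leaf_sets <- function(t1, t2, restrict_to_shared) {
  shared <- intersect(t1$tip.label, t2$tip.label)
  if (length(shared) == 0L) stop("trees have disjoint leaf sets")
  same <- setequal(t1$tip.label, t2$tip.label)
  if (!same) {
    if (!restrict_to_shared) stop("trees have different leaf sets")
    warning("pruning trees to the ", length(shared), " shared leaves")
    t1 <- ape::keep.tip(t1, shared)
    t2 <- ape::keep.tip(t2, shared)
  }
  list(t1, t2)
}

# tip-pair topological path lengths (edge counts), unrooted; named vector
# over sorted unordered pairs
pair_path_lengths <- function(tree) {
  tree <- ape::unroot(tree)
  tree$edge.length <- rep(1, nrow(tree$edge))
  m <- stats::cophenetic(tree)
  taxa <- sort(rownames(m))
  m <- m[taxa, taxa]
  v <- m[upper.tri(m)]
  names(v) <- outer(taxa, taxa, paste, sep = "~")[upper.tri(m)]
  v
}

#' Path distance between two topologies
#'
#' For each unordered leaf pair, the topological path length (number of
#' edges) between the two leaves is computed in both trees; the distance is
#' the Euclidean norm of the difference of the two pair vectors.
#'
#' @param t1,t2 `ape::phylo` trees over the same leaf set.
#' @return Non-negative numeric; 0 iff the topologies agree.
#' @export
path_distance <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label))
    stop("trees have different leaf sets")
  sqrt(sum((pair_path_lengths(t1) - pair_path_lengths(t2))^2))
}

## ---- unrooted topologies as adjacency lists (for SPR enumeration) -------

# convert a phylo to an adjacency-list topology: nb[[node]] = neighbor ids,
# label[node] = tip label or NA for internal nodes
adj_from_phylo <- function(tree) {
  tree <- ape::unroot(tree)
  ntip <- length(tree$tip.label)
  nnode <- max(tree$edge)
  nb <- vector("list", nnode)
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1L]; c <- tree$edge[e, 2L]
    nb[[p]] <- c(nb[[p]], c); nb[[c]] <- c(nb[[c]], p)
  }
  label <- rep(NA_character_, nnode)
  label[seq_len(ntip)] <- tree$tip.label
  list(nb = nb, label = label)
}

# leaves reachable from `start` without crossing `blocked`
adj_component_leaves <- function(adj, start, blocked) {
  seen <- integer(0); stack <- start
  leaves <- character(0)
  while (length(stack) > 0L) {
    v <- stack[[length(stack)]]; stack <- stack[-length(stack)]
    if (v %in% seen || v == blocked) next
    seen <- c(seen, v)
    if (!is.na(adj$label[v])) leaves <- c(leaves, adj$label[v])
    stack <- c(stack, setdiff(adj$nb[[v]], c(seen, blocked)))
  }
  leaves
}

# canonical topology key: sorted non-trivial split keys joined
adj_topology_key <- function(adj) {
  tips <- which(!is.na(adj$label))
  ntip <- length(tips)
  ref <- sort(adj$label[tips])[1L]
  all_t <- adj$label[tips]
  keys <- character(0)
  for (u in seq_along(adj$nb)) {
    if (is.null(adj$nb[[u]])) next
    for (v in adj$nb[[u]]) {
      if (v < u) next
      side <- adj_component_leaves(adj, v, u)
      if (ref %in% side) side <- setdiff(all_t, side)
      if (length(side) >= 2L && length(side) <= ntip - 2L)
        keys <- c(keys, paste(sort(side), collapse = "|"))
    }
  }
  paste(sort(unique(keys)), collapse = ";")
}

# all single-SPR neighbors of an unrooted binary topology; returns a list of
# adjacency topologies (may contain duplicates; callers dedupe by key)
spr_neighbors <- function(adj) {
  out <- list()
  nodes <- which(!vapply(adj$nb, is.null, TRUE))
  for (u in nodes) {
    if (length(adj$nb[[u]]) != 3L) next        # prune point must be internal
    for (v in adj$nb[[u]]) {
      # prune the component containing v; suppress u (neighbors a, b remain)
      ab <- setdiff(adj$nb[[u]], v)
      a <- ab[1L]; b <- ab[2L]
      # edges of the remaining component (reachable from a or b avoiding u)
      seen <- integer(0); stack <- c(a, b)
      edges <- list()
      while (length(stack) > 0L) {
        x <- stack[[length(stack)]]; stack <- stack[-length(stack)]
        if (x %in% seen) next
        seen <- c(seen, x)
        for (y in setdiff(adj$nb[[x]], u)) {
          if (y > x) edges[[length(edges) + 1L]] <- c(x, y)
          if (!(y %in% seen)) stack <- c(stack, y)
        }
      }
      edges[[length(edges) + 1L]] <- c(a, b)   # edge created by suppression
      for (ed in edges) {
        x <- ed[1L]; y <- ed[2L]
        if ((x == a && y == b) || (x == b && y == a)) {
          # regrafting onto the suppressed edge restores the original tree
          next
        }
        nb2 <- adj$nb
        nb2[[a]] <- c(setdiff(nb2[[a]], u), b)
        nb2[[b]] <- c(setdiff(nb2[[b]], u), a)
        nb2[[x]] <- c(setdiff(nb2[[x]], y), u)
        nb2[[y]] <- c(setdiff(nb2[[y]], x), u)
        nb2[[u]] <- c(v, x, y)
        out[[length(out) + 1L]] <- list(nb = nb2, label = adj$label)
      }
    }
  }
  out
}

#' Exact SPR distance by breadth-first search (small trees)
#'
#' Explores unrooted SPR neighborhoods outward from `t1` until `t2` is
#' reached or `max_d` is exceeded. Exponential in the distance; intended as
#' the reference oracle for [spr_distance_approx()] on trees with at most
#' 10 leaves.
#'
#' @param t1,t2 Binary `ape::phylo` trees over one leaf set (<= 10 leaves).
#' @param max_d Search depth cap (default 4).
#' @return The minimal number of SPR moves, or `Inf` when it exceeds
#'   `max_d`.
#' @export
spr_distance_exact <- function(t1, t2, max_d = 4L) {
  if (!setequal(t1$tip.label, t2$tip.label))
    stop("trees have different leaf sets")
  if (length(t1$tip.label) > 10L)
    stop("exact SPR search limited to 10 leaves")
  target <- adj_topology_key(adj_from_phylo(t2))
  a1 <- adj_from_phylo(t1)
  if (adj_topology_key(a1) == target) return(0L)
  frontier <- list(a1)
  visited <- adj_topology_key(a1)
  for (d in seq_len(max_d)) {
    nxt <- list(); nxt_keys <- character(0)
    for (adj in frontier) {
      for (nbr in spr_neighbors(adj)) {
        key <- adj_topology_key(nbr)
        if (key == target) return(d)
        if (!(key %in% visited) && !(key %in% nxt_keys)) {
          nxt[[length(nxt) + 1L]] <- nbr
          nxt_keys <- c(nxt_keys, key)
        }
      }
    }
    visited <- c(visited, nxt_keys)
    frontier <- nxt
    if (length(frontier) == 0L) break
  }
  Inf
}

# collapse identical shared cherries of both trees to single leaves,
# iteratively (SPR-distance-preserving kernelization)
kernelize_pair <- function(t1, t2) {
  repeat {
    c1 <- tree_cherries(t1)
    c2 <- tree_cherries(t2)
    shared <- intersect(c1, c2)
    if (length(shared) == 0L) return(list(t1, t2))
    pair <- strsplit(shared[[1L]], "\\|")[[1L]]
    t1 <- ape::drop.tip(t1, pair[2L])
    t2 <- ape::drop.tip(t2, pair[2L])
    if (length(t1$tip.label) < 4L) return(list(t1, t2))
  }
}

tree_cherries <- function(tree) {
  tree <- ape::unroot(tree)
  ntip <- length(tree$tip.label)
  par <- tree$edge[match(seq_len(ntip), tree$edge[, 2L]), 1L]
  out <- character(0)
  for (p in unique(par)) {
    tips <- which(par == p)
    if (length(tips) == 2L)
      out <- c(out, paste(sort(tree$tip.label[tips]), collapse = "|"))
  }
  out
}

#' Approximate SPR distance
#'
#' Upper-bound heuristic for the SPR distance: (1) identical pendant
#' cherries shared by both trees are iteratively collapsed to single leaves
#' (kernelization); (2) the leaf whose deletion most reduces the RF
#' distance is removed greedily (lexicographic tie-break), one SPR move
#' counted per removal, until the RF distance reaches zero. Returns 0 iff
#' the topologies are identical; validated against [spr_distance_exact()]
#' rather than any particular published implementation.
#'
#' @param t1,t2 `ape::phylo` trees over one leaf set.
#' @return Non-negative integer move count.
#' @export
spr_distance_approx <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label))
    stop("trees have different leaf sets")
  if (rf_distance(t1, t2) == 0L) return(0L)
  kt <- kernelize_pair(t1, t2)
  t1 <- kt[[1L]]; t2 <- kt[[2L]]
  moves <- 0L
  while (rf_distance(t1, t2) > 0L) {
    leaves <- sort(t1$tip.label)
    rfs <- vapply(leaves, function(l) {
      a <- ape::drop.tip(t1, l); b <- ape::drop.tip(t2, l)
      if (length(a$tip.label) < 4L) 0L else rf_distance(a, b)
    }, 0L)
    pick <- leaves[which.min(rfs)]   # which.min: first (lexicographic) tie
    t1 <- ape::drop.tip(t1, pick); t2 <- ape::drop.tip(t2, pick)
    moves <- moves + 1L
    if (length(t1$tip.label) < 4L) break
  }
  moves
}

#' Pairwise topological distance tables for a set of trees
#'
#' Computes lower-triangle matrices of the Robinson-Foulds, path, and
#' approximate SPR distances for every tree pair, in the order given.
#'
#' @param trees Named list of `ape::phylo` over a shared leaf set.
#' @param restrict_to_shared Passed to [rf_distance()]; when `TRUE`, every
#'   pair is pruned to its common leaves.
#' @param out_path Optional TSV path; one labelled block per metric,
#'   lower triangle only.
#' @return List of full symmetric matrices `rf`, `path`, `spr`.
#' @export
pairwise_distance_table <- function(trees, restrict_to_shared = FALSE,
                                    out_path = NULL) {
  stopifnot(length(trees) >= 2L)
  if (is.null(names(trees))) names(trees) <- paste0("tree", seq_along(trees))
  n <- length(trees)
  rf <- pd <- sp <- matrix(0, n, n, dimnames = list(names(trees),
                                                    names(trees)))
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      ti <- trees[[i]]; tj <- trees[[j]]
      if (restrict_to_shared) {
        ts <- match_leaf_sets(ti, tj, TRUE)
        ti <- ts[[1L]]; tj <- ts[[2L]]
      }
      rf[j, i] <- rf[i, j] <- rf_distance(ti, tj)
      pd[j, i] <- pd[i, j] <- path_distance(ti, tj)
      sp[j, i] <- sp[i, j] <- spr_distance_approx(ti, tj)
    }
  }
  if (!is.null(out_path)) {
    con <- file(out_path, "w")
    for (metric in c("rf", "path", "spr")) {
      m <- switch(metric, rf = rf, path = pd, spr = sp)
      writeLines(paste0("# ", toupper(metric)), con)
      writeLines(paste(c("tree", names(trees)), collapse = "\t"), con)
      for (i in seq_len(n)) {
        vals <- if (i == 1L) character(0) else
          format(m[i, seq_len(i - 1L)], digits = 6)
        writeLines(paste(c(names(trees)[i], vals), collapse = "\t"), con)
      }
    }
    close(con)
  }
  list(rf = rf, path = pd, spr = sp)
}
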