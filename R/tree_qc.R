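#' Mean internal-edge support of a gene tree
#'
#' Arithmetic mean of the support values attached to internal edges
#' (trivial splits excluded). The support scale is auto-detected: values
#' all within [0, 1] are rescaled to [0, 100].
#'
#' @param tree `ape::phylo` with internal-node labels carrying support.
#' @return Mean support on the [0, 100] scale.
#' @export
mean_support <- function(tree) {
  if (is.null(tree$node.label)) stop("tree carries no support values")
  lab <- tree$node.label[-1L]  # drop the root node: no associated edge
  sup <- suppressWarnings(as.numeric(lab))
  sup <- sup[!is.na(sup)]
  if (length(sup) == 0L) stop("no internal-edge support values present")
  if (max(sup) <= 1) sup <- sup * 100
  mean(sup)
}

#' Flag loci in the lowest support quantile
#'
#' Computes the `q` quantile of per-locus mean support by linear
#' interpolation (type-7 convention) and flags records strictly below it.
#'
#' @param records Data.frame with a `mean_support` column (>= 2 rows).
#' @param q Quantile (default 0.10).
#' @return `records` with a logical `dropped_low_support` column.
#' @export
filter_low_support_loci <- function(records, q = 0.10) {
  stopifnot(nrow(records) >= 2L)
  cut <- stats::quantile(records$mean_support, probs = q, type = 7,
                         names = FALSE)
  records$dropped_low_support <- records$mean_support < cut
  records
}

#' Uncorrected pairwise p-distance matrix
#'
#' Per taxon pair, the proportion of mismatched sites among sites where
#' both taxa carry an unambiguous nucleotide. Pairs with no overlapping
#' sites get `NA` with a warning.
#'
#' @param aln A [locus_alignment()] (>= 2 taxa).
#' @return Symmetric matrix with zero diagonal, dimnames = taxa.
#' @export
pdistance_matrix <- function(aln) {
  seqs <- if (inherits(aln, "locus_alignment")) aln$seq else aln
  stopifnot(nrow(seqs) >= 2L)
  n <- nrow(seqs)
  code <- matrix(match(seqs, NUC_STATES, nomatch = 0L), nrow = n)
  d <- matrix(0, n, n, dimnames = list(rownames(seqs), rownames(seqs)))
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      ok <- code[i, ] > 0L & code[j, ] > 0L
      if (!any(ok)) {
        warning("no overlapping sites between ", rownames(seqs)[i], " and ",
                rownames(seqs)[j])
        d[i, j] <- d[j, i] <- NA_real_
      } else {
        d[i, j] <- d[j, i] <- mean(code[i, ok] != code[j, ok])
      }
    }
  }
  d
}

#' Patristic (branch-length path) distance matrix
#'
#' @param tree `ape::phylo` with branch lengths.
#' @return Symmetric tip-to-tip matrix of path-summed branch lengths.
#' @export
patristic_matrix <- function(tree) {
  if (is.null(tree$edge.length) || anyNA(tree$edge.length))
    stop("tree has missing branch lengths")
  stats::cophenetic(tree)
}

#' Saturation regression of p-distance on patristic distance
#'
#' OLS with intercept of the uncorrected p-distance (response) on the
#' tree-inferred patristic distance (predictor), over upper-triangle taxon
#' pairs; pairs missing in either matrix are excluded. A shallow slope
#' indicates substitution saturation (multiple hits flattening observed
#' divergence).
#'
#' @param p P-distance matrix from [pdistance_matrix()].
#' @param patristic Patristic matrix from [patristic_matrix()]; matched by
#'   dimnames.
#' @return List with `slope`, `intercept`, `r2`, `n_pairs`.
#' @export
saturation_regression <- function(p, patristic) {
  taxa <- intersect(rownames(p), rownames(patristic))
  p <- p[taxa, taxa]; patristic <- patristic[taxa, taxa]
  ut <- upper.tri(p)
  x <- patristic[ut]; y <- p[ut]
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3L) stop("need >= 3 complete taxon pairs")
  fit <- stats::lm(y[ok] ~ x[ok])
  sst <- sum((y[ok] - mean(y[ok]))^2)
  r2 <- if (sst > 0) 1 - sum(stats::resid(fit)^2) / sst else 1
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r2 = r2, n_pairs = sum(ok))
}

#' Flag potentially saturated loci by the lower Tukey fence
#'
#' Loci whose saturation slope falls below `Q1 - multiplier * IQR` of the
#' slope distribution are flagged as potentially over-saturated.
#'
#' @param records Data.frame with a `sat_slope` column (>= 4 rows).
#' @param multiplier Fence multiplier (default 1.5).
#' @return `records` with a logical `dropped_saturated` column.
#' @export
flag_saturated_loci <- function(records, multiplier = 1.5) {
  if (nrow(records) < 4L) stop("need >= 4 loci to estimate the fence")
  qs <- stats::quantile(records$sat_slope, c(0.25, 0.75), type = 7,
                        names = FALSE)
  fence <- qs[1] - multiplier * (qs[2] - qs[1])
  records$dropped_saturated <- records$sat_slope < fence
  records
}

#' QC records for a set of gene trees and their alignments
#'
#' Computes per-locus mean bootstrap support and the saturation regression,
#' then applies the low-support quantile filter and the Tukey-fence
#' saturation filter.
#'
#' @param trees Named list of `ape::phylo` gene trees with support labels
#'   and branch lengths.
#' @param alns Named list of [locus_alignment()] matching `trees` by name.
#' @param support_quantile Passed to [filter_low_support_loci()].
#' @param fence_multiplier Passed to [flag_saturated_loci()].
#' @return Data.frame: locus_id, mean_support, sat_slope, sat_intercept,
#'   sat_r2, dropped_low_support, dropped_saturated.
#' @export
qc_gene_trees <- function(trees, alns, support_quantile = 0.10,
                          fence_multiplier = 1.5) {
  ids <- intersect(names(trees), names(alns))
  rec <- do.call(rbind, lapply(ids, function(id) {
    sat <- saturation_regression(pdistance_matrix(alns[[id]]),
                                 patristic_matrix(trees[[id]]))
    data.frame(locus_id = id, mean_support = mean_support(trees[[id]]),
               sat_slope = sat$slope, sat_intercept = sat$intercept,
               sat_r2 = sat$r2)
  }))
  rec <- filter_low_support_loci(rec, support_quantile)
  flag_saturated_loci(rec, fence_multiplier)
}

#' Posterior tree sample from one MCMC run
#'
#' @param trees List of `ape::phylo` (or `multiPhylo`) sharing one leaf set.
#' @param burnin_fraction Fraction of initial samples to discard (default
#'   0.25).
#' @param sample_interval Generations between samples (metadata).
#' @return A `tree_sample` object.
#' @export
tree_sample <- function(trees, burnin_fraction = 0.25, sample_interval = 1L) {
  trees <- unclass(trees)
  stopifnot(length(trees) >= 1L, burnin_fraction >= 0, burnin_fraction < 1)
  tips <- lapply(trees, function(t) sort(t$tip.label))
  if (length(unique(vapply(tips, paste, "", collapse = "|"))) != 1L)
    stop("trees in a sample must share one leaf set")
  structure(list(trees = trees, burnin_fraction = burnin_fraction,
                 sample_interval = sample_interval),
            class = "tree_sample")
}

#' Remove the burn-in fraction from a posterior sample
#'
#' Drops the first `floor(burnin_fraction * N)` trees.
#'
#' @param sample A [tree_sample()].
#' @return The truncated `tree_sample` (burnin_fraction reset to 0).
#' @export
apply_burnin <- function(sample) {
  stopifnot(inherits(sample, "tree_sample"))
  n <- length(sample$trees)
  drop <- floor(sample$burnin_fraction * n)
  if (drop >= n) stop("burn-in removes the whole sample")
  tree_sample(sample$trees[seq.int(drop + 1L, n)], 0,
              sample$sample_interval)
}

# canonical non-trivial bipartition keys of an unrooted topology: each split
# is represented by the side NOT containing the lexicographically first taxon
tree_splits <- function(tree) {
  tree <- ape::reorder.phylo(ape::unroot(tree), "postorder")
  ntip <- length(tree$tip.label)
  ref <- sort(tree$tip.label)[1L]
  nnode <- max(tree$edge)
  below <- vector("list", nnode)
  for (i in seq_len(ntip)) below[[i]] <- tree$tip.label[i]
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1L]; c <- tree$edge[e, 2L]
    below[[p]] <- c(below[[p]], below[[c]])
  }
  keys <- character(0)
  for (e in seq_len(nrow(tree$edge))) {
    c <- tree$edge[e, 2L]
    if (c <= ntip) next
    side <- below[[c]]
    if (ref %in% side) side <- setdiff(tree$tip.label, side)
    if (length(side) >= 2L && length(side) <= ntip - 2L)
      keys <- c(keys, paste(sort(side), collapse = "|"))
  }
  unique(keys)
}

#' Per-run split (bipartition) frequencies across MCMC runs
#'
#' Splits are keyed canonically by the side not containing the
#' lexicographically first taxon; a split absent from a run has frequency 0
#' there.
#'
#' @param samples List of post-burn-in [tree_sample()] objects over one
#'   leaf set.
#' @return A `split_freq_table`: data.frame with `split` plus one frequency
#'   column per run.
#' @export
split_frequencies <- function(samples) {
  stopifnot(length(samples) >= 1L)
  leaf_sets <- vapply(samples, function(s)
    paste(sort(s$trees[[1L]]$tip.label), collapse = "|"), "")
  if (length(unique(leaf_sets)) != 1L)
    stop("runs have mismatched leaf sets")
  per_run <- lapply(samples, function(s) {
    counts <- table(unlist(lapply(s$trees, tree_splits)))
    counts / length(s$trees)
  })
  splits <- sort(unique(unlist(lapply(per_run, names))))
  tab <- data.frame(split = splits)
  for (r in seq_along(per_run)) {
    f <- as.numeric(per_run[[r]][splits])
    f[is.na(f)] <- 0
    tab[[paste0("run", r)]] <- f
  }
  class(tab) <- c("split_freq_table", "data.frame")
  tab
}

#' Average standard deviation of split frequencies (ASDSF)
#'
#' Over splits reaching `min_freq` in at least one run, the sample standard
#' deviation (denominator n_runs - 1) of per-run frequencies, averaged over
#' those splits. The standard between-run convergence diagnostic for
#' Bayesian phylogenetic MCMC.
#'
#' @param table A [split_frequencies()] table with >= 2 runs.
#' @param min_freq Inclusion threshold (default 0.10).
#' @return The ASDSF value.
#' @export
asdsf <- function(table, min_freq = 0.10) {
  freq <- as.matrix(table[, grep("^run", names(table)), drop = FALSE])
  if (ncol(freq) < 2L) stop("ASDSF needs >= 2 runs")
  keep <- apply(freq, 1L, function(f) any(f >= min_freq))
  if (!any(keep)) stop("no split reaches the inclusion threshold")
  mean(apply(freq[keep, , drop = FALSE], 1L, stats::sd))
}

# rooted clade keys of a tree (tip sets below internal nodes, root included)
tree_clades <- function(tree) {
  ntip <- length(tree$tip.label)
  tree <- ape::reorder.phylo(tree, "postorder")
  nnode <- max(tree$edge)
  below <- vector("list", nnode)
  for (i in seq_len(ntip)) below[[i]] <- tree$tip.label[i]
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1L]; c <- tree$edge[e, 2L]
    below[[p]] <- c(below[[p]], below[[c]])
  }
  keys <- vapply(seq.int(ntip + 1L, nnode), function(nd)
    paste(sort(below[[nd]]), collapse = "|"), "")
  unique(keys)
}

#' Maximum clade credibility topology of a posterior sample
#'
#' Among the sampled trees, returns the one maximizing the sum of log clade
#' frequencies (clades taken from the rooted representation; frequencies
#' estimated from the full sample). Ties are broken by first occurrence.
#' Internal nodes of the returned tree are annotated with their clade
#' posterior frequency.
#'
#' @param sample A post-burn-in [tree_sample()].
#' @return The MCC tree (`ape::phylo`) with node labels giving clade
#'   frequencies.
#' @export
mcct <- function(sample) {
  stopifnot(inherits(sample, "tree_sample"))
  trees <- sample$trees
  if (length(trees) == 0L) stop("empty tree sample")
  clade_lists <- lapply(trees, tree_clades)
  freq <- table(unlist(clade_lists)) / length(trees)
  scores <- vapply(clade_lists, function(cl) sum(log(freq[cl])), 0)
  best <- which.max(scores)  # first occurrence wins ties
  tr <- trees[[best]]
  ntip <- length(tr$tip.label)
  ord <- ape::reorder.phylo(tr, "postorder")
  below <- vector("list", max(ord$edge))
  for (i in seq_len(ntip)) below[[i]] <- ord$tip.label[i]
  for (e in seq_len(nrow(ord$edge))) {
    p <- ord$edge[e, 1L]; c <- ord$edge[e, 2L]
    below[[p]] <- c(below[[p]], below[[c]])
  }
  tr$node.label <- vapply(seq.int(ntip + 1L, max(ord$edge)), function(nd)
    format(as.numeric(freq[paste(sort(below[[nd]]), collapse = "|")]),
           digits = 4), "")
  tr
}
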