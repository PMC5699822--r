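#' Neighbor-joining guide tree from Jukes-Cantor distances
#'
#' Builds the fixed tree on which partition-scheme models are scored: NJ on
#' JC69-corrected p-distances, negative NJ branch lengths clamped to zero,
#' unrooted. P-distances above 0.74 are clamped before correction so the
#' JC transform stays finite.
#'
#' @param aln A [locus_alignment()] with at least 3 taxa.
#' @return An unrooted `ape::phylo` tree.
#' @export
nj_guide_tree <- function(aln) {
  stopifnot(inherits(aln, "locus_alignment"))
  if (length(aln$taxa) < 3L) stop("need >= 3 taxa for a guide tree")
  p <- pdistance_matrix(aln)
  if (anyNA(p[upper.tri(p)]))
    stop("taxon pair with no overlapping sites in locus ", aln$locus_id)
  p <- pmin(p, 0.74)
  d <- -0.75 * log(1 - 4 * p / 3)
  tr <- ape::nj(stats::as.dist(d))
  tr$edge.length[tr$edge.length < 0] <- 0
  ape::unroot(tr)
}

#' Optimize branch lengths under GTR+Gamma on a fixed topology
#'
#' Coordinate ascent over branch lengths, each optimized by bounded scalar
#' search; the topology and model are held fixed. Used once per locus to
#' refine the guide tree before subset models are fitted.
#'
#' @param aln A [locus_alignment()].
#' @param tree `ape::phylo` with starting branch lengths.
#' @param model A [gtr_gamma_model()].
#' @param max_sweeps Sweeps over all branches (default 2).
#' @param tol Stop when a sweep improves lnL by less than this (default 0.01).
#' @return The tree with optimized branch lengths.
#' @export
optimize_branch_lengths <- function(aln, tree, model, max_sweeps = 2L,
                                    tol = 0.01) {
  seqs <- if (inherits(aln, "locus_alignment")) aln$seq else aln
  tree <- ape::reorder.phylo(ape::unroot(tree), "postorder")
  ll <- make_loglik(seqs, tree)
  elen <- tree$edge.length
  cur <- ll(model, elen)
  for (sw in seq_len(max_sweeps)) {
    prev <- cur
    for (e in seq_along(elen)) {
      f <- function(b) {
        el <- elen; el[e] <- b
        ll(model, el)
      }
      op <- stats::optimize(f, c(1e-9, 10), maximum = TRUE, tol = 1e-4)
      if (op$objective > cur) {
        elen[e] <- op$maximum
        cur <- op$objective
      }
    }
    if (cur - prev < tol) break
  }
  tree$edge.length <- elen
  tree
}

#' Small-sample corrected Akaike information criterion
#'
#' `AICc = 2K - 2 lnL + 2K(K+1) / (n - K - 1)`.
#'
#' @param lnL Log-likelihood.
#' @param K Free parameter count.
#' @param n Sample size (number of sites).
#' @param aic_fallback If `TRUE`, return plain AIC with a warning when
#'   `n - K - 1 <= 0`; otherwise that is an error.
#' @return The AICc value.
#' @export
aicc <- function(lnL, K, n, aic_fallback = FALSE) {
  if (n - K - 1 <= 0) {
    if (!aic_fallback)
      stop("AICc undefined: n - K - 1 <= 0 (n = ", n, ", K = ", K, ")")
    warning("n - K - 1 <= 0; falling back to plain AIC")
    return(2 * K - 2 * lnL)
  }
  2 * K - 2 * lnL + 2 * K * (K + 1) / (n - K - 1)
}

# free parameters of one GTR+Gamma subset model, excluding the multiplier:
# 5 exchangeabilities + 3 frequencies + alpha
SUBSET_BASE_PARAMS <- 9L

#' Fit a GTR+Gamma model to an alignment subset by coordinate ascent
#'
#' Maximizes the log-likelihood over the five free exchangeabilities, the
#' base frequencies (three free weights), the gamma shape and, optionally,
#' the subset rate multiplier, by repeated bounded scalar optimization on a
#' log scale (bounds: rates 1e-6..100, alpha 0.02..100, multiplier
#' 1e-3..100). Guide-tree branch lengths are not re-optimized per subset.
#' Convergence: lnL improvement below `tol` between sweeps, or `max_sweeps`
#' reached (then a warning and `converged = FALSE`). The returned lnL never
#' falls below the lnL at initialization.
#'
#' @param aln A [locus_alignment()] or character matrix.
#' @param tree Guide tree (`ape::phylo`) with branch lengths.
#' @param sites Optional 0-based site indices of the subset.
#' @param member_charsets Charset names making up the subset (metadata).
#' @param fit_multiplier Fit the subset-relative rate multiplier (default
#'   `TRUE`).
#' @param n_categories Gamma categories (default 4).
#' @param tol Convergence tolerance on lnL (default 1e-6).
#' @param max_sweeps Maximum coordinate-ascent sweeps (default 200).
#' @param init Optional [gtr_gamma_model()] to start the ascent from (warm
#'   start); by default empirical base frequencies with equal rates.
#' @return A `subset_fit` list: `member_charsets`, `n_sites`, `model`,
#'   `lnL`, `k` (free parameters incl. multiplier if fitted), `converged`.
#' @export
fit_subset_model <- function(aln, tree, sites = NULL, member_charsets = NULL,
                             fit_multiplier = TRUE, n_categories = 4L,
                             tol = 1e-6, max_sweeps = 200L, init = NULL) {
  seqs <- if (inherits(aln, "locus_alignment")) aln$seq else aln
  if (!is.null(sites)) seqs <- seqs[, sites + 1L, drop = FALSE]
  n_sites <- ncol(seqs)
  if (!is.null(init)) {                 # warm start from a previous fit
    par <- list(exch = init$exch, w = init$base_freqs / init$base_freqs[4],
                alpha = init$alpha, mult = init$rate_multiplier)
  } else {
    counts <- table(factor(seqs[seqs %in% NUC_STATES], levels = NUC_STATES))
    freq0 <- (as.numeric(counts) + 1) / (sum(counts) + 4)  # add-one smoothed
    par <- list(exch = rep(1, 6), w = freq0 / freq0[4], alpha = 1, mult = 1)
  }
  build <- function(p) gtr_gamma_model(p$exch, p$w / sum(p$w), p$alpha,
                                       n_categories, p$mult)
  ll <- make_loglik(seqs, tree)
  obj <- function(p) ll(build(p))
  cur <- obj(par)
  # bounded scalar ascent on the log scale; brackets narrow around the
  # current value and re-expand to the full bounds when the optimum lands
  # on a bracket edge
  ascend <- function(get, set, lo, hi, width = 1.5) {
    f <- function(x) obj(set(par, exp(x)))
    v0 <- log(get(par))
    bracket <- c(max(log(lo), v0 - width), min(log(hi), v0 + width))
    op <- stats::optimize(f, bracket, maximum = TRUE, tol = 1e-3)
    if (min(abs(op$maximum - bracket)) < 5e-3 &&
        (bracket[1] > log(lo) + 1e-9 || bracket[2] < log(hi) - 1e-9))
      op <- stats::optimize(f, log(c(lo, hi)), maximum = TRUE, tol = 1e-3)
    if (op$objective > cur) {
      par <<- set(par, exp(op$maximum))
      cur <<- op$objective
    }
  }
  converged <- FALSE
  for (sw in seq_len(max_sweeps)) {
    prev <- cur
    for (i in 1:5)
      ascend(function(p) p$exch[i],
             function(p, v) { p$exch[i] <- v; p }, 1e-6, 100)
    # joint rescaling of the free exchangeabilities: cuts through the
    # ridge between the relative rates and the GT-anchored scale
    ascend(function(p) 1,
           function(p, v) {
             p$exch[1:5] <- pmin(pmax(p$exch[1:5] * v, 1e-6), 100); p
           }, 0.05, 20)
    for (i in 1:3)
      ascend(function(p) p$w[i],
             function(p, v) { p$w[i] <- v; p }, 1e-3, 1e3)
    ascend(function(p) p$alpha,
           function(p, v) { p$alpha <- v; p }, 0.02, 100)
    if (fit_multiplier)
      ascend(function(p) p$mult,
             function(p, v) { p$mult <- v; p }, 1e-3, 100)
    if (cur - prev < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("subset fit did not converge after ", max_sweeps, " sweeps")
  structure(list(member_charsets = member_charsets, n_sites = n_sites,
                 model = build(par), lnL = cur,
                 k = SUBSET_BASE_PARAMS + as.integer(fit_multiplier),
                 converged = converged),
            class = "subset_fit")
}

# Scheme-level free-parameter count: shared branch lengths once, base
# parameters per subset, and S - 1 free rate multipliers (one multiplier is
# fixed by the mean-rate-1 convention).
scheme_K <- function(n_subsets, n_taxa) {
  (2L * n_taxa - 3L) + n_subsets * SUBSET_BASE_PARAMS + (n_subsets - 1L)
}

make_scheme <- function(fits, n_taxa, n_sites_total, aic_fallback = FALSE) {
  K <- scheme_K(length(fits), n_taxa)
  lnL <- sum(vapply(fits, `[[`, 0, "lnL"))
  structure(list(subsets = fits, n_subsets = length(fits),
                 total_lnL = lnL, total_K = K,
                 aicc = aicc(lnL, K, n_sites_total, aic_fallback)),
            class = "partition_scheme")
}

#' @export
print.partition_scheme <- function(x, ...) {
  cat("<partition_scheme>", x$n_subsets, "subset(s), lnL =",
      round(x$total_lnL, 3), ", K =", x$total_K, ", AICc =",
      round(x$aicc, 3), "\n")
  for (s in x$subsets)
    cat("  {", paste(s$member_charsets, collapse = ", "), "}:",
        s$n_sites, "sites\n")
  invisible(x)
}

subset_key <- function(members) paste(sort(members), collapse = "+")

fit_subset_cached <- function(members, cache, charsets, aln, tree, ...) {
  key <- subset_key(members)
  if (is.null(cache[[key]])) {
    sites <- sort(unlist(lapply(charsets[members], charset_sites)))
    init <- NULL
    if (length(members) > 1L) {
      # warm start from the largest member's singleton fit (computed on
      # demand, so a subset's fit never depends on the search path)
      sizes <- vapply(members, function(m) charsets[[m]]$n_sites, 0L)
      big <- members[order(-sizes, members)][1L]
      init <- fit_subset_cached(big, cache, charsets, aln, tree, ...)$model
    }
    cache[[key]] <- fit_subset_model(aln, tree, sites = sites,
                                     member_charsets = sort(members),
                                     init = init, ...)
  }
  cache[[key]]
}

#' Greedy AICc search for the best charset grouping of a locus
#'
#' Starts with every charset in its own model subset, then repeatedly
#' evaluates all pairwise subset merges, refits the merged subset, and
#' accepts the merge that most decreases the scheme AICc; stops when no
#' merge improves. Scheme AICc uses n = locus length and K = shared branch
#' lengths + per-subset parameters + (S - 1) free rate multipliers. Ties are
#' broken lexicographically on the merged subset's charset names. Fit
#' errors cause the offending merge to be skipped with a warning.
#'
#' @param charsets Charset list from [build_charsets()].
#' @param aln The locus alignment.
#' @param tree Guide tree from [nj_guide_tree()] /
#'   [optimize_branch_lengths()].
#' @param aic_fallback Passed to [aicc()].
#' @param ... Passed to [fit_subset_model()].
#' @return The best `partition_scheme` found.
#' @export
greedy_scheme_search <- function(charsets, aln, tree, aic_fallback = FALSE,
                                 ...) {
  stopifnot(length(charsets) >= 1L)
  n_taxa <- length(tree$tip.label)
  L <- if (inherits(aln, "locus_alignment")) aln$length else ncol(aln)
  cache <- new.env(parent = emptyenv())
  groups <- lapply(names(charsets), identity)
  fits <- lapply(groups, fit_subset_cached, cache, charsets, aln, tree, ...)
  best <- make_scheme(fits, n_taxa, L, aic_fallback)
  while (length(groups) > 1L) {
    cand <- list()
    for (i in seq_along(groups)[-length(groups)]) {
      for (j in seq.int(i + 1L, length(groups))) {
        merged <- c(groups[[i]], groups[[j]])
        fit <- tryCatch(
          fit_subset_cached(merged, cache, charsets, aln, tree, ...),
          error = function(e) {
            warning("merge {", subset_key(merged), "} skipped: ",
                    conditionMessage(e))
            NULL
          })
        if (is.null(fit)) next
        newfits <- c(fits[-c(i, j)], list(fit))
        sc <- make_scheme(newfits, n_taxa, L, aic_fallback)
        cand[[length(cand) + 1L]] <-
          list(i = i, j = j, scheme = sc, key = subset_key(merged))
      }
    }
    if (length(cand) == 0L) break
    aiccs <- vapply(cand, function(x) x$scheme$aicc, 0)
    keys <- vapply(cand, `[[`, "", "key")
    pick <- order(aiccs, keys)[1L]
    if (cand[[pick]]$scheme$aicc >= best$aicc) break
    i <- cand[[pick]]$i; j <- cand[[pick]]$j
    groups <- c(groups[-c(i, j)],
                list(c(groups[[i]], groups[[j]])))
    fits <- cand[[pick]]$scheme$subsets
    best <- cand[[pick]]$scheme
  }
  best
}

# all set-partitions of a character vector (restricted growth strings)
set_partitions <- function(items) {
  n <- length(items)
  out <- list()
  rec <- function(assign, k) {
    i <- length(assign) + 1L
    if (i > n) {
      blocks <- split(items, assign)
      out[[length(out) + 1L]] <<- unname(blocks)
      return(invisible(NULL))
    }
    for (b in seq_len(k + 1L)) rec(c(assign, b), max(k, b))
  }
  rec(integer(0), 0L)
  out
}

#' Exhaustive AICc search over all charset groupings
#'
#' Evaluates every set-partition of the charsets (at most 6 charsets; 203
#' schemes) and returns the AICc-minimal one. Intended as the reference
#' against which the greedy search is validated.
#'
#' @inheritParams greedy_scheme_search
#' @return The AICc-optimal `partition_scheme`.
#' @export
exhaustive_scheme_search <- function(charsets, aln, tree,
                                     aic_fallback = FALSE, ...) {
  stopifnot(length(charsets) >= 1L)
  if (length(charsets) > 6L)
    stop("exhaustive search limited to 6 charsets")
  n_taxa <- length(tree$tip.label)
  L <- if (inherits(aln, "locus_alignment")) aln$length else ncol(aln)
  cache <- new.env(parent = emptyenv())
  best <- NULL
  for (part in set_partitions(names(charsets))) {
    fits <- lapply(part, fit_subset_cached, cache, charsets, aln, tree, ...)
    sc <- make_scheme(fits, n_taxa, L, aic_fallback)
    if (is.null(best) || sc$aicc < best$aicc) best <- sc
  }
  best
}

#' Select partition schemes for a set of loci
#'
#' Runs guide-tree construction and the greedy (or exhaustive) AICc search
#' per locus, returning a per-locus report.
#'
#' @param alns Named list of [locus_alignment()].
#' @param spec A [core_spec()].
#' @param search `"greedy"` or `"exhaustive"`.
#' @param optimize_bl Refine guide-tree branch lengths (default `TRUE`).
#' @param ... Passed to the search.
#' @return List with `schemes` (per locus) and `report` (data.frame:
#'   locus_id, n_charsets, n_subsets, lnL, K, aicc, subsets).
#' @export
select_schemes <- function(alns, spec = core_spec(), search = "greedy",
                           optimize_bl = TRUE, ...) {
  fun <- switch(search, greedy = greedy_scheme_search,
                exhaustive = exhaustive_scheme_search,
                stop("unknown search: ", search))
  schemes <- lapply(alns, function(a) {
    cs <- build_charsets(a, spec)
    tr <- nj_guide_tree(a)
    if (optimize_bl) {
      m0 <- gtr_gamma_model(base_freqs = empirical_base_freqs(a$seq))
      tr <- optimize_branch_lengths(a, tr, m0)
    }
    fun(cs, a, tr, ...)
  })
  report <- do.call(rbind, lapply(names(schemes), function(id) {
    sc <- schemes[[id]]
    data.frame(locus_id = id,
               n_charsets = length(unlist(lapply(sc$subsets, `[[`,
                                                 "member_charsets"))),
               n_subsets = sc$n_subsets, lnL = sc$total_lnL,
               K = sc$total_K, aicc = sc$aicc,
               subsets = paste(vapply(sc$subsets, function(s)
                 paste(s$member_charsets, collapse = "+"), ""),
                 collapse = " | "))
  }))
  list(schemes = schemes, report = report)
}

empirical_base_freqs <- function(seqs) {
  counts <- table(factor(seqs[seqs %in% NUC_STATES], levels = NUC_STATES))
  (as.numeric(counts) + 1) / (sum(counts) + 4)
}
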