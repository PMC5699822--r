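#' GTR+Gamma substitution model
#'
#' General time-reversible nucleotide model with discrete-gamma among-site
#' rate variation. Exchangeabilities are relative to r_GT = 1; the rate
#' matrix is normalized to one expected substitution per site per unit
#' branch length, and a subset-relative `rate_multiplier` scales branch
#' lengths when several data subsets share one tree.
#'
#' @param exch Six non-negative exchangeabilities in the order
#'   AC, AG, AT, CG, CT, GT; rescaled internally so that GT = 1.
#' @param base_freqs Four non-negative frequencies (A, C, G, T) summing to 1.
#' @param alpha Gamma shape (> 0).
#' @param n_categories Number of discrete gamma categories (default 4).
#' @param rate_multiplier Subset-relative rate (> 0, default 1).
#' @return A `gtr_gamma_model` list.
#' @export
gtr_gamma_model <- function(exch = rep(1, 6), base_freqs = rep(0.25, 4),
                            alpha = 1, n_categories = 4L,
                            rate_multiplier = 1) {
  if (length(exch) != 6L || any(exch < 0) || exch[6] <= 0)
    stop("need 6 non-negative exchangeabilities with GT > 0")
  if (length(base_freqs) != 4L || any(base_freqs < 0) ||
      abs(sum(base_freqs) - 1) > 1e-8)
    stop("base frequencies must be 4 non-negative values summing to 1")
  if (alpha <= 0) stop("alpha must be > 0")
  if (rate_multiplier <= 0) stop("rate_multiplier must be > 0")
  structure(list(exch = exch / exch[6],
                 base_freqs = base_freqs / sum(base_freqs),
                 alpha = alpha, n_categories = as.integer(n_categories),
                 rate_multiplier = rate_multiplier),
            class = "gtr_gamma_model")
}

#' Discrete gamma category rates (category means)
#'
#' Mean rate of each of `k` equal-probability slices of Gamma(alpha, alpha)
#' (mean 1), the standard discretization for among-site rate variation.
#'
#' @param alpha Gamma shape.
#' @param k Number of categories.
#' @return Numeric vector of `k` rates with mean 1.
#' @export
discrete_gamma_rates <- function(alpha, k = 4L) {
  stopifnot(alpha > 0, k >= 1L)
  if (k == 1L) return(1)
  q <- stats::qgamma(seq_len(k - 1L) / k, shape = alpha, rate = alpha)
  p <- c(0, stats::pgamma(q, shape = alpha + 1, rate = alpha), 1)
  k * diff(p)
}

# GTR rate matrix (rows A,C,G,T), normalized to mean rate 1, and its
# eigendecomposition exploiting reversibility:
# Q = A diag(lambda) B with A = D^{-1/2} U, B = U^T D^{1/2}.
gtr_eigen <- function(model) {
  r <- model$exch; pi <- model$base_freqs
  # symmetric exchangeability matrix R (R[i,j] = r_ij), Q = R diag(pi)
  R <- matrix(c(0,    r[1], r[2], r[3],
                r[1], 0,    r[4], r[5],
                r[2], r[4], 0,    r[6],
                r[3], r[5], r[6], 0), 4, 4)
  Q <- R * rep(pi, each = 4)
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))
  if (mu <= 0) stop("degenerate rate matrix")
  Q <- Q / mu
  sp <- sqrt(pi)
  S <- Q * outer(sp, 1 / sp)            # D^{1/2} Q D^{-1/2}, symmetric
  es <- eigen((S + t(S)) / 2, symmetric = TRUE)
  list(Q = Q, lambda = es$values,
       A = es$vectors / sp,             # D^{-1/2} U (row scaling)
       B = t(es$vectors) * rep(sp, each = 4))  # U^T D^{1/2} (col scaling)
}

# Compress alignment columns into unique site patterns.
# Returns integer matrix (ntaxa x npat; 0..3 = A,C,G,T; 4 = gap/ambiguity)
# and pattern weights. Row order follows `taxa`.
compress_patterns <- function(seqs, taxa = rownames(seqs)) {
  m <- seqs[taxa, , drop = FALSE]
  code <- matrix(match(m, NUC_STATES, nomatch = 5L) - 1L, nrow = nrow(m),
                 dimnames = dimnames(m))
  key <- apply(code, 2L, paste, collapse = ",")
  tab <- table(key)
  first <- match(names(tab), key)
  list(states = code[, first, drop = FALSE], weights = as.numeric(tab))
}

# Precompute pattern compression and tree ordering once; returns
# function(model, elen) evaluating the pruning lnL cheaply (used by the
# optimizers, where thousands of evaluations share one alignment).
make_loglik <- function(seqs, tree) {
  taxa <- rownames(seqs)
  if (!all(taxa %in% tree$tip.label))
    stop("tree does not cover all alignment taxa")
  if (length(setdiff(tree$tip.label, taxa)) > 0L)
    tree <- ape::keep.tip(tree, taxa)
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (length(tree$tip.label) > 2L) tree <- ape::unroot(tree)
  tree <- ape::reorder.phylo(tree, "postorder")
  pat <- compress_patterns(seqs, tree$tip.label)
  edge <- tree$edge
  ntip <- length(tree$tip.label)
  elen0 <- tree$edge.length
  eg_key <- NULL; eg <- NULL; rt_key <- NULL; rt <- NULL
  function(model, elen = elen0) {
    k1 <- c(model$exch, model$base_freqs)
    if (is.null(eg_key) || !identical(k1, eg_key)) {
      eg <<- gtr_eigen(model); eg_key <<- k1
    }
    k2 <- c(model$alpha, model$n_categories)
    if (is.null(rt_key) || !identical(k2, rt_key)) {
      rt <<- discrete_gamma_rates(model$alpha, model$n_categories)
      rt_key <<- k2
    }
    cpp_pruning_loglik(edge, elen * model$rate_multiplier, ntip,
                       pat$states, pat$weights, model$base_freqs,
                       eg$lambda, eg$A, eg$B, rt)
  }
}

#' GTR+Gamma log-likelihood of an alignment on a fixed tree
#'
#' Felsenstein-pruning log-likelihood summed over discrete gamma rate
#' categories, with identical site patterns compressed and weighted. Missing
#' data (gaps, N, ?, ambiguity codes) contribute all-ones partial
#' likelihoods. Branch lengths are scaled by the model's `rate_multiplier`.
#'
#' @param aln A [locus_alignment()], or a character matrix of sequences.
#' @param tree An `ape::phylo` tree covering the alignment's taxa (extra
#'   tips are pruned); branch lengths in expected substitutions/site.
#' @param model A [gtr_gamma_model()].
#' @param sites Optional 0-based column indices restricting the alignment
#'   (e.g. from [charset_sites()]).
#' @return The log-likelihood (a scalar, <= 0 for any non-degenerate input).
#' @export
gtr_gamma_loglik <- function(aln, tree, model, sites = NULL) {
  stopifnot(inherits(model, "gtr_gamma_model"))
  seqs <- if (inherits(aln, "locus_alignment")) aln$seq else aln
  if (!is.null(sites)) seqs <- seqs[, sites + 1L, drop = FALSE]
  make_loglik(seqs, tree)(model)
}
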