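# Independent oracles used across the suite. These deliberately avoid the
# package's own computational path: the rate matrix is hand-built, matrix
# exponentials use scaling-and-squaring, and the likelihood sums over all
# internal ancestral state combinations.

NUC <- c("A", "C", "G", "T")

# GTR rate matrix, mean rate 1 (hand construction)
oracle_gtr_q <- function(exch, pi) {
  r <- exch / exch[6]
  R <- matrix(c(0,    r[1], r[2], r[3],
                r[1], 0,    r[4], r[5],
                r[2], r[4], 0,    r[6],
                r[3], r[5], r[6], 0), 4, 4)
  Q <- R * rep(pi, each = 4)
  diag(Q) <- -rowSums(Q)
  Q / -sum(pi * diag(Q))
}

# matrix exponential by scaling and squaring of the Taylor series
oracle_expm <- function(M) {
  k <- max(0L, ceiling(log2(max(1e-12, norm(M, "1")))) + 4L)
  A <- M / 2^k
  P <- diag(4); term <- diag(4)
  for (i in 1:20) {
    term <- term %*% A / i
    P <- P + term
  }
  for (i in seq_len(k)) P <- P %*% P
  P
}

# mean rates of k equal-probability gamma slices (same closed form the
# package uses, re-derived here from the incomplete-gamma identity)
oracle_gamma_rates <- function(alpha, k) {
  if (k == 1L) return(1)
  q <- qgamma(seq_len(k - 1L) / k, shape = alpha, rate = alpha)
  p <- c(0, pgamma(q, shape = alpha + 1, rate = alpha), 1)
  k * diff(p)
}

# brute-force GTR+Gamma log-likelihood: explicit summation over all internal
# ancestral state combinations, per site and per rate category
oracle_loglik <- function(m, tree, exch, pi, alpha, ncat = 4L, mult = 1) {
  Q <- oracle_gtr_q(exch, pi)
  rates <- oracle_gamma_rates(alpha, ncat)
  tree <- ape::reorder.phylo(ape::unroot(tree), "postorder")
  nt <- length(tree$tip.label)
  nn <- max(tree$edge)
  ints <- seq.int(nt + 1L, nn)
  states <- match(m[tree$tip.label, , drop = FALSE], NUC)
  dim(states) <- dim(m)
  root <- tree$edge[nrow(tree$edge), 1L]
  combos <- as.matrix(expand.grid(rep(list(1:4), length(ints))))
  total <- 0
  for (site in seq_len(ncol(m))) {
    lik <- 0
    for (r in rates) {
      Ps <- lapply(seq_len(nrow(tree$edge)), function(e)
        oracle_expm(Q * tree$edge.length[e] * r * mult))
      for (ci in seq_len(nrow(combos))) {
        st <- integer(nn)
        st[seq_len(nt)] <- states[, site]
        st[ints] <- combos[ci, ]
        pr <- pi[st[root]]
        for (e in seq_len(nrow(tree$edge)))
          pr <- pr * Ps[[e]][st[tree$edge[e, 1L]], st[tree$edge[e, 2L]]]
        lik <- lik + pr / length(rates)
      }
    }
    total <- total + log(lik)
  }
  total
}

# closed-form two-sequence Jukes-Cantor log-likelihood at total path d
oracle_jc_two_seq <- function(n_sites, n_mismatch, d) {
  p <- 0.75 * (1 - exp(-4 * d / 3))
  (n_sites - n_mismatch) * log(0.25 * (1 - p)) +
    n_mismatch * log(0.25 * p / 3)
}

# Welch t statistic and degrees of freedom from the textbook formulas
oracle_welch <- function(x, y) {
  vx <- var(x) / length(x); vy <- var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# small alignment constructor for hand-written examples
aln_from_rows <- function(..., id = "test") {
  rows <- list(...)
  m <- do.call(rbind, lapply(rows, function(s) strsplit(s, "")[[1]]))
  rownames(m) <- names(rows)
  locus_alignment(id, m)
}

# rebuild a phylo from an adjacency-list topology (test plumbing)
adj_to_phylo_for_test <- function(adj) {
  root <- which(lengths(adj$nb) == 3L)[1L]
  rec <- function(v, parent) {
    kids <- setdiff(adj$nb[[v]], parent)
    if (length(kids) == 0L) return(adj$label[v])
    paste0("(", paste(vapply(kids, rec, "", v), collapse = ","), ")")
  }
  tr <- ape::read.tree(text = paste0(rec(root, 0L), ";"))
  tr$edge.length <- rep(1, nrow(tr$edge))
  tr
}

# random unrooted binary topology with unit branch lengths
rand_topology <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tr <- ape::unroot(ape::rtree(n, br = NULL))
  tr$edge.length <- rep(1, nrow(tr$edge))
  tr
}
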