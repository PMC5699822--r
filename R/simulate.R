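#' Simulation configuration for UCE-like data
#'
#' Defaults emulate the study conditions of a weevil UCE matrix: 33 taxa,
#' locus lengths 231-802 sites, a 160 bp conserved core, and a per-charset
#' substitution-rate profile rising from the core (0.2) to the outermost
#' flank bin (1.5), which qualitatively reproduces the observed U-shaped
#' profile of per-site variability along a captured locus.
#'
#' @param n_taxa Number of taxa (default 33).
#' @param n_loci Number of loci (default 50).
#' @param locus_length_range Length range in sites (default c(231, 802)).
#' @param core_length Core width (default 160).
#' @param n_flank_bins Flank bins per side (default 5).
#' @param flank_rate_profile Named rate multipliers for core, flank1..5.
#' @param model A [gtr_gamma_model()] (default: empirical-flavoured GTR
#'   with alpha 0.5).
#' @param tree_height Expected root-to-tip path length in substitutions per
#'   site at rate 1 (default 0.3).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_taxa = 33L, n_loci = 50L,
                       locus_length_range = c(231L, 802L),
                       core_length = 160L, n_flank_bins = 5L,
                       flank_rate_profile = c(core = 0.2, flank1 = 0.4,
                                              flank2 = 0.7, flank3 = 1.0,
                                              flank4 = 1.25, flank5 = 1.5),
                       model = gtr_gamma_model(
                         exch = c(1.5, 4, 1, 1.2, 5, 1),
                         base_freqs = c(0.3, 0.2, 0.2, 0.3), alpha = 0.5),
                       tree_height = 0.3) {
  stopifnot(all(flank_rate_profile > 0), tree_height > 0)
  structure(list(n_taxa = as.integer(n_taxa), n_loci = as.integer(n_loci),
                 locus_length_range = as.integer(locus_length_range),
                 core_length = as.integer(core_length),
                 n_flank_bins = as.integer(n_flank_bins),
                 flank_rate_profile = flank_rate_profile, model = model,
                 tree_height = tree_height),
            class = "sim_config")
}

#' Simulate a Yule tree
#'
#' Random pure-birth topology; branch lengths are redrawn i.i.d.
#' exponential and rescaled so the mean root-to-tip path equals
#' `tree_height`. Deterministic for a fixed seed.
#'
#' @param n_taxa Number of tips (>= 3).
#' @param seed Integer seed (optional; `NULL` uses the current RNG state).
#' @param tree_height Mean root-to-tip height (default 0.3).
#' @return A rooted binary `ape::phylo`.
#' @export
simulate_tree <- function(n_taxa, seed = NULL, tree_height = 0.3) {
  if (n_taxa < 3L) stop("need >= 3 taxa")
  if (!is.null(seed)) set.seed(seed)
  tr <- ape::rphylo(n_taxa, birth = 1, death = 0)
  tr$edge.length <- stats::rexp(nrow(tr$edge))
  depths <- ape::node.depth.edgelength(tr)
  tr$edge.length <- tr$edge.length *
    (tree_height / mean(depths[seq_len(n_taxa)]))
  tr$tip.label <- sprintf("t%02d", seq_len(n_taxa))
  tr
}

# simulate nsites of sequence down `tree` under `model`, with total rate
# scale `scale`; returns character matrix (tips x sites)
sim_sites <- function(tree, model, nsites, scale = 1) {
  if (nsites == 0L)
    return(matrix(character(0), nrow = length(tree$tip.label), ncol = 0,
                  dimnames = list(tree$tip.label, NULL)))
  eg <- gtr_eigen(model)
  rates <- discrete_gamma_rates(model$alpha, model$n_categories)
  cat_of_site <- sample.int(length(rates), nsites, replace = TRUE)
  tree <- ape::reorder.phylo(tree, "postorder")
  nnode <- max(tree$edge)
  ntip <- length(tree$tip.label)
  root <- tree$edge[nrow(tree$edge), 1L]
  states <- matrix(0L, nnode, nsites)
  states[root, ] <- sample.int(4L, nsites, replace = TRUE,
                               prob = model$base_freqs)
  pm <- function(t) {
    P <- eg$A %*% diag(exp(eg$lambda * t)) %*% eg$B
    P[P < 0] <- 0
    P / rowSums(P)
  }
  for (e in rev(seq_len(nrow(tree$edge)))) {  # preorder: root to tips
    p <- tree$edge[e, 1L]; ch <- tree$edge[e, 2L]
    bl <- tree$edge.length[e] * scale * model$rate_multiplier
    for (k in seq_along(rates)) {
      P <- pm(bl * rates[k])
      for (s in 1:4) {
        idx <- which(cat_of_site == k & states[p, ] == s)
        if (length(idx) > 0L)
          states[ch, idx] <- sample.int(4L, length(idx), replace = TRUE,
                                        prob = P[s, ])
      }
    }
  }
  m <- matrix(NUC_STATES[states[seq_len(ntip), , drop = FALSE]], nrow = ntip,
              dimnames = list(tree$tip.label, NULL))
  m
}

#' Simulate one UCE-like locus
#'
#' Draws the locus length uniformly from the configured range, builds the
#' core/flank charsets, and evolves each charset's sites down the tree
#' under GTR+Gamma with the charset's rate multiplier times `branch_scale`.
#' Root states are drawn from the model's base frequencies.
#'
#' @param tree Generating `ape::phylo` covering `cfg$n_taxa` tips.
#' @param cfg A [sim_config()].
#' @param branch_scale Global branch-length multiplier (default 1); large
#'   values produce saturated loci.
#' @param seed Integer seed (optional).
#' @param locus_id Locus name (default "locus").
#' @return A [locus_alignment()] with attribute `truth`: list of the
#'   charsets, per-charset true rates, and `branch_scale`.
#' @export
simulate_locus <- function(tree, cfg, branch_scale = 1, seed = NULL,
                           locus_id = "locus") {
  if (!is.null(seed)) set.seed(seed)
  L <- sample.int(cfg$locus_length_range[2L] - cfg$locus_length_range[1L] +
                    1L, 1L) + cfg$locus_length_range[1L] - 1L
  spec <- core_spec(cfg$core_length, cfg$n_flank_bins)
  cs <- build_charsets(L, spec)
  blocks <- matrix("", nrow = length(tree$tip.label), ncol = L,
                   dimnames = list(tree$tip.label, NULL))
  rates_used <- numeric(0)
  for (nm in names(cs)) {
    r <- unname(cfg$flank_rate_profile[nm])  # NA when unspecified
    if (is.na(r)) r <- 1
    rates_used[nm] <- r
    sites <- charset_sites(cs[[nm]])
    blocks[, sites + 1L] <- sim_sites(tree, cfg$model, length(sites),
                                      scale = r * branch_scale)
  }
  aln <- locus_alignment(locus_id, blocks)
  attr(aln, "truth") <- list(charsets = cs, rates = rates_used,
                             branch_scale = branch_scale, tree = tree)
  aln
}

#' Simulate a set of loci from one generating tree
#'
#' @param cfg A [sim_config()].
#' @param seed Integer seed for the whole dataset.
#' @param branch_scales Per-locus branch scale (recycled; default 1).
#' @return List with `tree` and named list `alignments` (plus per-locus
#'   truth attributes).
#' @export
simulate_loci <- function(cfg, seed = 1L, branch_scales = 1) {
  set.seed(seed)
  tree <- simulate_tree(cfg$n_taxa, seed = NULL,
                        tree_height = cfg$tree_height)
  scales <- rep_len(branch_scales, cfg$n_loci)
  alns <- lapply(seq_len(cfg$n_loci), function(i)
    simulate_locus(tree, cfg, branch_scale = scales[i],
                   locus_id = sprintf("uce-%04d", i)))
  names(alns) <- vapply(alns, `[[`, "", "locus_id")
  list(tree = tree, alignments = alns, branch_scales = scales)
}

#' Degrade loci for museum specimens
#'
#' Age-dependent locus dropout: each specimen retains each locus
#' independently with probability `plogis(a + b * age)` (b < 0 gives the
#' decline of capture with age). Surviving sequences of pinned specimens
#' are additionally truncated from both ends (flanks lost first), each end
#' by a Uniform(0, truncation_rate) fraction of the locus, mirroring the
#' shorter contigs recovered from degraded DNA.
#'
#' @param alns Named list of [locus_alignment()].
#' @param specimens Data.frame with `specimen_id` (matching alignment
#'   taxa), `age_years`, `preservation`.
#' @param dropout_intercept Logit-scale intercept `a` (default 4).
#' @param dropout_slope Per-year logit slope `b` (default -0.05).
#' @param truncation_rate Maximum truncated fraction per end for pinned
#'   specimens (default 0.2).
#' @param seed Integer seed (optional).
#' @return List with `alignments` (degraded; taxa with dropped loci
#'   removed) and `records` (specimen_id, age_years, preservation,
#'   loci_count).
#' @export
degrade_museum_specimens <- function(alns, specimens, dropout_intercept = 4,
                                     dropout_slope = -0.05,
                                     truncation_rate = 0.2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  keep_p <- stats::plogis(dropout_intercept +
                            dropout_slope * specimens$age_years)
  counts <- setNames(integer(nrow(specimens)), specimens$specimen_id)
  out <- lapply(alns, function(a) {
    m <- a$seq
    drop_taxa <- character(0)
    for (i in seq_len(nrow(specimens))) {
      sp <- specimens$specimen_id[i]
      if (!(sp %in% rownames(m))) next
      if (stats::runif(1) > keep_p[i]) {
        drop_taxa <- c(drop_taxa, sp)
      } else {
        counts[sp] <<- counts[sp] + 1L
        if (specimens$preservation[i] == "pinned" && truncation_rate > 0) {
          L <- ncol(m)
          lcut <- floor(L * stats::runif(1, 0, truncation_rate))
          rcut <- floor(L * stats::runif(1, 0, truncation_rate))
          if (lcut > 0L) m[sp, seq_len(lcut)] <- "-"
          if (rcut > 0L) m[sp, seq.int(L - rcut + 1L, L)] <- "-"
        }
      }
    }
    keep <- setdiff(rownames(m), drop_taxa)
    if (length(keep) == 0L) return(NULL)
    locus_alignment(a$locus_id, m[keep, , drop = FALSE])
  })
  out <- out[!vapply(out, is.null, TRUE)]
  records <- data.frame(specimen_id = specimens$specimen_id,
                        age_years = specimens$age_years,
                        preservation = specimens$preservation,
                        loci_count = as.integer(counts))
  list(alignments = out, records = records)
}

#' Simulate a posterior tree sample by random SPR perturbation
#'
#' Each sampled tree is the true tree modified by `Poisson(perturbation)`
#' random SPR moves; perturbation 0 yields identical samples.
#'
#' @param true_tree Generating `ape::phylo`.
#' @param n_samples Sample size.
#' @param perturbation Expected SPR moves per sampled tree (>= 0).
#' @param seed Integer seed (optional).
#' @param burnin_fraction Stored on the sample (default 0).
#' @return A [tree_sample()].
#' @export
simulate_posterior_sample <- function(true_tree, n_samples, perturbation,
                                      seed = NULL, burnin_fraction = 0) {
  stopifnot(perturbation >= 0)
  if (!is.null(seed)) set.seed(seed)
  base <- if (length(true_tree$tip.label) > 3L)
    ape::unroot(true_tree) else true_tree
  trees <- lapply(seq_len(n_samples), function(i) {
    k <- stats::rpois(1L, perturbation)
    if (k == 0L) base else phangorn::rSPR(base, moves = k)
  })
  tree_sample(trees, burnin_fraction = burnin_fraction)
}

#' Simulate a multi-study specimen capture table
#'
#' Per specimen, logit capture fraction = intercept + slope * age +
#' Normal(0, sd); fractions are mapped back to locus counts through each
#' study's maximum locus constant. Each study additionally contains one
#' freshly collected reference specimen captured at the study maximum —
#' in real tables the within-clade maximum is attained by construction,
#' and anchoring it keeps the fraction denominator a constant.
#'
#' @param studies Data.frame with columns `study`, `intercept`, `slope`,
#'   `sd`, `max_loci`.
#' @param n_per_study Aged specimens per study in addition to the
#'   reference specimen (recycled).
#' @param age_range Ages drawn uniformly from this range (default c(0, 60)).
#' @param seed Integer seed (optional).
#' @return Data.frame of specimen records (specimen_id, study, age_years,
#'   preservation, loci_count) with attribute `truth` = `studies`.
#' @export
simulate_capture_table <- function(studies, n_per_study = 30L,
                                   age_range = c(0, 60), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_per <- rep_len(n_per_study, nrow(studies))
  out <- do.call(rbind, lapply(seq_len(nrow(studies)), function(i) {
    s <- studies[i, ]
    age <- stats::runif(n_per[i], age_range[1L], age_range[2L])
    lg <- s$intercept + s$slope * age + stats::rnorm(n_per[i], 0, s$sd)
    cnt <- pmin(pmax(round(stats::plogis(lg) * s$max_loci), 0L), s$max_loci)
    data.frame(specimen_id = c(sprintf("%s_ref", s$study),
                               sprintf("%s_%02d", s$study,
                                       seq_len(n_per[i]))),
               study = s$study,
               age_years = c(age_range[1L], age),
               preservation = "pinned",
               loci_count = as.integer(c(s$max_loci, cnt)))
  }))
  rownames(out) <- NULL
  attr(out, "truth") <- studies
  out
}

#' Write simulated loci as per-locus FASTA files
#'
#' @param alns Named list of [locus_alignment()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the file paths written.
#' @export
write_locus_fastas <- function(alns, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(alns, function(a) {
    path <- file.path(dir, paste0(a$locus_id, ".fasta"))
    con <- file(path, "w")
    for (t in a$taxa)
      writeLines(c(paste0(">", t), paste(a$seq[t, ], collapse = "")), con)
    close(con)
    path
  }, "")
  invisible(paths)
}
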