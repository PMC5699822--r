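test_that("simulated trees are reproducible binary trees of the right size", {
  tr <- simulate_tree(5, seed = 71)
  expect_equal(length(tr$tip.label), 5L)
  expect_equal(nrow(ape::unroot(tr)$edge), 7L)   # 2n - 3 unrooted edges
  expect_identical(ape::write.tree(simulate_tree(8, seed = 3)),
                   ape::write.tree(simulate_tree(8, seed = 3)))
  set.seed(72)
  keys <- replicate(20, ape::write.tree(simulate_tree(10)))
  expect_gt(length(unique(keys)), 15L)           # seeds diversify topologies
  expect_error(simulate_tree(2), ">= 3")
})

test_that("tree height scaling sets the mean root-to-tip depth", {
  tr <- simulate_tree(20, seed = 73, tree_height = 0.42)
  depths <- ape::node.depth.edgelength(tr)[1:20]
  expect_equal(mean(depths), 0.42, tolerance = 1e-9)
})

test_that("zero-rate loci are invariant; seeds reproduce alignments", {
  gen <- simulate_tree(6, seed = 74)
  cfg <- sim_config(n_taxa = 6, locus_length_range = c(300L, 300L),
                    flank_rate_profile = c(core = 1))
  a0 <- simulate_locus(gen, cfg, branch_scale = 0, seed = 75)
  expect_equal(count_informative_sites(a0), 0L)
  expect_equal(length(unique(apply(a0$seq, 2, function(x)
    length(unique(x))))), 1L)
  a1 <- simulate_locus(gen, cfg, seed = 76)
  a2 <- simulate_locus(gen, cfg, seed = 76)
  expect_identical(a1$seq, a2$seq)
})

test_that("the outward rate profile yields rising per-bin variability", {
  set.seed(77)
  gen <- simulate_tree(12, tree_height = 0.3)
  cfg <- sim_config(n_taxa = 12, locus_length_range = c(560L, 560L))
  per_bin <- matrix(0, 20, 6)
  for (i in 1:20) {
    a <- simulate_locus(gen, cfg, locus_id = sprintf("l%d", i))
    cs <- attr(a, "truth")$charsets
    per_bin[i, ] <- vapply(cs, function(s) {
      sites <- charset_sites(s)
      sub <- locus_alignment("b", a$seq[, sites + 1L, drop = FALSE])
      count_informative_sites(sub) / length(sites)
    }, 0)
  }
  dens <- colMeans(per_bin)                      # core, flank1..flank5
  expect_equal(which.min(dens), 1L)              # core least variable
  expect_true(all(diff(dens) > -0.02))           # rising outward (near-monotone)
  expect_gt(dens[6], dens[1] * 2)
})

test_that("simulated base composition converges to the model frequencies", {
  gen <- simulate_tree(4, seed = 78)
  cfg <- sim_config(n_taxa = 4, locus_length_range = c(20000L, 20000L),
                    flank_rate_profile = c(core = 1))
  cfg$core_length <- 30000L
  a <- simulate_locus(gen, cfg, seed = 79)
  freqs <- table(factor(a$seq, levels = NUC)) / length(a$seq)
  expect_equal(as.numeric(freqs), cfg$model$base_freqs, tolerance = 0.02)
})

test_that("museum degradation drops loci by age and truncates flanks", {
  set.seed(80)
  gen <- simulate_tree(8, tree_height = 0.3)
  cfg <- sim_config(n_taxa = 8, n_loci = 40,
                    locus_length_range = c(231L, 400L))
  sim <- simulate_loci(cfg, seed = 80)
  specimens <- data.frame(
    specimen_id = sim$tree$tip.label[1:6],
    age_years = c(0, 0, 25, 25, 50, 50),
    preservation = c("ethanol", "ethanol", "pinned", "pinned",
                     "pinned", "pinned"))
  deg <- degrade_museum_specimens(sim$alignments, specimens,
                                  dropout_intercept = 2,
                                  dropout_slope = -0.05, seed = 81)
  counts <- deg$records$loci_count
  by_age <- tapply(counts, deg$records$age_years, mean)
  expect_true(by_age[["0"]] > by_age[["25"]] &&
                by_age[["25"]] > by_age[["50"]])
  # b = 0: no age effect in expectation (all retention probs equal)
  deg0 <- degrade_museum_specimens(sim$alignments, specimens,
                                   dropout_intercept = 1,
                                   dropout_slope = 0, seed = 82)
  expect_lt(abs(mean(deg0$records$loci_count[specimens$age_years == 0]) -
                  mean(deg0$records$loci_count[specimens$age_years == 50])),
            12)
  # huge intercept: nothing is lost
  degA <- degrade_museum_specimens(sim$alignments, specimens,
                                   dropout_intercept = 30,
                                   dropout_slope = -0.05, seed = 83)
  expect_true(all(degA$records$loci_count == length(sim$alignments)))
  # pinned sequences acquire leading/trailing gaps (flank truncation)
  has_gap <- vapply(deg$alignments, function(a)
    any(a$seq[, 1] == "-") || any(a$seq[, ncol(a$seq)] == "-"), TRUE)
  expect_gt(mean(has_gap), 0.3)
})

test_that("posterior perturbation controls between-sample disagreement", {
  gen <- simulate_tree(8, seed = 84)
  s0 <- simulate_posterior_sample(gen, 20, 0, seed = 85)
  expect_true(all(vapply(s0$trees, function(t) rf_distance(t, gen), 0L) == 0L))
  tab <- split_frequencies(list(s0, simulate_posterior_sample(gen, 20, 0,
                                                              seed = 86)))
  expect_equal(asdsf(tab), 0)
  mean_rf <- vapply(c(0.1, 0.5, 2), function(p) {
    s <- simulate_posterior_sample(gen, 30, p, seed = 87)
    mean(vapply(s$trees, function(t) rf_distance(t, gen), 0L))
  }, 0)
  expect_true(all(diff(mean_rf) > 0))
})

test_that("capture tables follow the per-study decay model", {
  studies <- data.frame(study = c("w", "b"), intercept = c(2, 3),
                        slope = c(-0.05, -0.05), sd = 0,
                        max_loci = c(600, 1000))
  tab <- simulate_capture_table(studies, n_per_study = 25, seed = 88)
  expect_identical(tab, simulate_capture_table(studies, 25, seed = 88))
  # each study carries its own maximum: a fresh reference specimen
  expect_true(all(tapply(tab$loci_count, tab$study, max) ==
                    c(b = 1000, w = 600)))
  w <- tab[tab$study == "w" & tab$specimen_id != "w_ref", ]
  # sd = 0: logit counts sit on the study line up to count rounding
  r <- cor(log((w$loci_count / 600) / (1 - w$loci_count / 600 + 1e-9)),
           w$age_years)
  expect_lt(r, -0.99)
})

test_that("locus FASTA writer round-trips through the reader", {
  cfg <- sim_config(n_taxa = 5, n_loci = 3,
                    locus_length_range = c(240L, 300L))
  sim <- simulate_loci(cfg, seed = 89)
  d <- withr::local_tempdir()
  write_locus_fastas(sim$alignments, d)
  back <- read_locus_alignments(d)
  expect_identical(names(back), names(sim$alignments))
  for (id in names(back))
    expect_identical(back[[id]]$seq, sim$alignments[[id]]$seq)
})
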