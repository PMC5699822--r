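test_that("mean support averages internal-edge values on a 0-100 scale", {
  tr <- ape::read.tree(text = "((a,b)100,(c,(d,e)50)); ")
  # ape assigns the empty root label too; only the two real supports count
  expect_equal(mean_support(tr), 75)
  tr2 <- ape::read.tree(text = "((a,b)0.9,(c,(d,e)0.7));")
  expect_equal(mean_support(tr2), 80)           # 0-1 scale normalized
  tr3 <- ape::read.tree(text = "((a,b)88,(c,d)88);")
  expect_equal(mean_support(tr3), 88)
  star <- ape::read.tree(text = "(a,b,c,d);")
  expect_error(mean_support(star), "support")
})

test_that("low-support filter uses the type-7 quantile, strict below", {
  rec <- data.frame(locus_id = letters[1:10], mean_support = 1:10)
  out <- filter_low_support_loci(rec, 0.10)
  # type-7 0.1 quantile of 1..10 is 1.9: only the mean-1 locus falls below
  expect_identical(out$dropped_low_support, c(TRUE, rep(FALSE, 9)))
  same <- data.frame(mean_support = rep(80, 5))
  expect_false(any(filter_low_support_loci(same, 0.10)$dropped_low_support))
  expect_false(any(filter_low_support_loci(rec, 0)$dropped_low_support))
})

test_that("p-distances count mismatches over unambiguous overlap", {
  a <- aln_from_rows(x = "ACGT", y = "AGGT")
  expect_equal(pdistance_matrix(a)["x", "y"], 0.25)
  b <- aln_from_rows(x = "ACGT", y = "ACGT")
  expect_equal(pdistance_matrix(b)["x", "y"], 0)
  expect_warning(d <- pdistance_matrix(aln_from_rows(x = "A---", y = "-AAA")),
                 "overlap")
  expect_true(is.na(d["x", "y"]))
  # symmetry, zero diagonal
  set.seed(2)
  m <- matrix(sample(c(NUC, "-"), 5 * 60, TRUE), 5, 60,
              dimnames = list(paste0("t", 1:5), NULL))
  dm <- pdistance_matrix(locus_alignment("r", m))
  expect_equal(dm, t(dm))
  expect_equal(unname(diag(dm)), rep(0, 5))
})

test_that("patristic distances sum branch lengths along tip paths", {
  tr <- ape::read.tree(text = "((a:1,b:2):1,(c:1,d:1):0);")
  pm <- patristic_matrix(tr)
  expect_equal(pm["a", "b"], 3)
  expect_equal(pm["a", "c"], 3)
  expect_equal(pm, t(pm))
  z <- tr; z$edge.length[] <- 0
  expect_true(all(patristic_matrix(z) == 0))
  nb <- tr; nb$edge.length <- NULL
  expect_error(patristic_matrix(nb), "branch lengths")
})

test_that("saturation regression matches closed forms", {
  tr <- rand_topology(6, seed = 4)
  tr$edge.length <- runif(nrow(tr$edge), 0.05, 0.3)
  pat <- patristic_matrix(tr)
  p_half <- pat * 0.5
  s <- saturation_regression(p_half, pat)
  expect_equal(s$slope, 0.5, tolerance = 1e-12)
  expect_equal(s$r2, 1.0)
  p_const <- pat; p_const[] <- 0.2
  s2 <- saturation_regression(p_const, pat)     # constant response
  expect_equal(s2$slope, 0, tolerance = 1e-12)
  expect_equal(saturation_regression(pat * 0.3 + 0.01, pat)$slope, 0.3,
               tolerance = 1e-12)
})

test_that("branch-scale inflation lowers the saturation slope", {
  set.seed(9)
  gen <- simulate_tree(6, tree_height = 0.3)
  cfg <- sim_config(n_taxa = 6, locus_length_range = c(500L, 500L),
                    flank_rate_profile = c(core = 1))
  slopes <- vapply(c(1, 10), function(scale) {
    aln <- simulate_locus(gen, cfg, branch_scale = scale,
                          locus_id = paste0("s", scale))
    scaled <- gen; scaled$edge.length <- gen$edge.length * scale
    saturation_regression(pdistance_matrix(aln),
                          patristic_matrix(scaled))$slope
  }, 0)
  expect_lt(slopes[2], slopes[1])
})

test_that("Tukey-fence flagging catches the low-slope outlier", {
  rec <- data.frame(locus_id = sprintf("l%02d", 1:20),
                    sat_slope = c(rep(0.9, 19), 0.2))
  out <- flag_saturated_loci(rec)
  expect_identical(which(out$dropped_saturated), 20L)
  same <- data.frame(sat_slope = rep(0.8, 6))
  expect_false(any(flag_saturated_loci(same)$dropped_saturated))
  expect_error(flag_saturated_loci(data.frame(sat_slope = c(1, 2, 3))),
               ">= 4")
})

test_that("burn-in removal drops the first floor(f * N) trees", {
  tr <- rand_topology(5, seed = 6)
  s <- tree_sample(rep(list(tr), 40), burnin_fraction = 0.25)
  expect_length(apply_burnin(s)$trees, 30L)
  s0 <- tree_sample(rep(list(tr), 8), burnin_fraction = 0)
  expect_length(apply_burnin(s0)$trees, 8L)
  s4 <- tree_sample(rep(list(tr), 4), burnin_fraction = 0.5)
  expect_length(apply_burnin(s4)$trees, 2L)
  # two runs of 10000 at 25% burn-in leave 15000 combined
  big1 <- tree_sample(rep(list(tr), 10000), burnin_fraction = 0.25)
  big2 <- tree_sample(rep(list(tr), 10000), burnin_fraction = 0.25)
  expect_equal(length(apply_burnin(big1)$trees) +
                 length(apply_burnin(big2)$trees), 15000L)
  expect_error(tree_sample(list(tr), burnin_fraction = 1), "burnin")
})

test_that("split frequencies are canonical and per-run", {
  t1 <- ape::read.tree(text = "((a,b),(c,d),e);")
  t2 <- ape::read.tree(text = "((a,c),(b,d),e);")
  r1 <- tree_sample(list(t1, t1, t2), 0)
  r2 <- tree_sample(list(t1, t2, t2), 0)
  tab <- split_frequencies(list(r1, r2))
  expect_s3_class(tab, "split_freq_table")
  # canonical keys name the side not containing taxon "a"
  expect_setequal(tab$split, c("c|d|e", "c|d", "b|d|e", "b|d"))
  expect_equal(unlist(tab[tab$split == "c|d", c("run1", "run2")]),
               c(run1 = 2/3, run2 = 1/3))
  expect_equal(unlist(tab[tab$split == "b|d|e", c("run1", "run2")]),
               c(run1 = 1/3, run2 = 2/3))
  # identical runs agree split by split
  tab2 <- split_frequencies(list(r1, r1))
  expect_equal(tab2$run1, tab2$run2)
  # single-tree run: every split has frequency 1
  tab3 <- split_frequencies(list(tree_sample(list(t1), 0)))
  expect_true(all(tab3$run1 == 1))
  expect_equal(nrow(tab3), 2L)                  # two non-trivial splits
  t3 <- ape::read.tree(text = "((a,b),(c,f),e);")
  expect_error(split_frequencies(list(r1, tree_sample(list(t3), 0))),
               "leaf sets")
})

test_that("ASDSF averages per-split standard deviations above threshold", {
  tab <- data.frame(split = c("x", "y"), run1 = c(0.8, 0.05),
                    run2 = c(0.6, 0.08))
  class(tab) <- c("split_freq_table", "data.frame")
  # only the first split passes min_freq = 0.10; sd({0.8, 0.6}) = 0.1414
  expect_equal(asdsf(tab), sd(c(0.8, 0.6)), tolerance = 1e-12)
  expect_equal(round(asdsf(tab), 4), 0.1414)
  tab_id <- data.frame(split = "x", run1 = 0.7, run2 = 0.7)
  class(tab_id) <- c("split_freq_table", "data.frame")
  expect_equal(asdsf(tab_id), 0)
  low <- data.frame(split = "x", run1 = 0.05, run2 = 0.08)
  class(low) <- c("split_freq_table", "data.frame")
  expect_error(asdsf(low), "threshold")
  expect_error(asdsf(data.frame(split = "x", run1 = 0.5)), "2 runs")
})

test_that("MCCT picks the sampled tree with maximal clade credibility", {
  t1 <- ape::read.tree(text = "((a,b),((c,d),e));")
  t2 <- ape::read.tree(text = "((a,c),((b,d),e));")
  s <- tree_sample(list(t1, t1, t1, t2), 0)
  expect_equal(rf_distance(mcct(s), t1), 0L)
  # all identical: clade supports are all 1
  s1 <- tree_sample(list(t2, t2), 0)
  m <- mcct(s1)
  expect_true(all(as.numeric(m$node.label) == 1))
  # seeded 5-taxon sample: agrees with exhaustive scoring over the sample
  set.seed(14)
  gen <- simulate_tree(5)
  samp <- simulate_posterior_sample(gen, 30, perturbation = 0.8, seed = 14)
  got <- mcct(samp)
  freq <- table(unlist(lapply(samp$trees, corepart:::tree_clades))) /
    length(samp$trees)
  scores <- vapply(samp$trees, function(t)
    sum(log(freq[corepart:::tree_clades(t)])), 0)
  expect_equal(sum(log(freq[corepart:::tree_clades(got)])), max(scores))
})

test_that("gene-tree QC assembles per-locus records with both filters", {
  set.seed(17)
  gen <- simulate_tree(6, tree_height = 0.3)
  cfg <- sim_config(n_taxa = 6, locus_length_range = c(400L, 400L),
                    flank_rate_profile = c(core = 1))
  alns <- list(); trees <- list()
  for (i in 1:6) {
    id <- sprintf("l%d", i)
    scale <- if (i == 6) 12 else 1
    alns[[id]] <- simulate_locus(gen, cfg, branch_scale = scale,
                                 locus_id = id)
    tr <- nj_guide_tree(alns[[id]])
    tr$node.label <- c("", as.character(sample(60:100,
                                               tr$Nnode - 1L, TRUE)))
    trees[[id]] <- tr
  }
  rec <- qc_gene_trees(trees, alns)
  expect_identical(names(rec)[1:5],
                   c("locus_id", "mean_support", "sat_slope",
                     "sat_intercept", "sat_r2"))
  expect_true(all(rec$sat_r2 >= 0 & rec$sat_r2 <= 1))
  expect_true(is.logical(rec$dropped_low_support))
  expect_true(is.logical(rec$dropped_saturated))
})
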