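write_fasta <- function(dir, id, seqs) {
  path <- file.path(dir, paste0(id, ".fasta"))
  writeLines(unlist(Map(function(n, s) c(paste0(">", n), s),
                        names(seqs), seqs)), path)
  path
}

test_that("read_locus_alignments reads a directory of per-locus FASTA", {
  d <- withr::local_tempdir()
  write_fasta(d, "uce-2", c(a = "ACGT", b = "ACGA"))
  write_fasta(d, "uce-1", c(a = "GGTT", b = "GCTT", c = "GGTA"))
  write_fasta(d, "uce-3", c(a = "acgt", b = "nn-t"))
  alns <- read_locus_alignments(d)
  expect_length(alns, 3L)
  expect_identical(names(alns), c("uce-1", "uce-2", "uce-3"))
  expect_identical(alns[["uce-3"]]$seq["b", ], c("N", "N", "-", "T"))
  expect_equal(alns[["uce-1"]]$length, 4L)
})

test_that("ragged and duplicated inputs are rejected, empty dir warns", {
  d <- withr::local_tempdir()
  write_fasta(d, "bad-locus", c(a = paste(rep("A", 100), collapse = ""),
                                b = paste(rep("A", 98), collapse = "")))
  expect_error(read_locus_alignments(d), "bad-locus")
  d2 <- withr::local_tempdir()
  writeLines(c(">a", "ACGT", ">a", "ACGT"), file.path(d2, "dup.fasta"))
  expect_error(read_locus_alignments(d2), "dup")
  d3 <- withr::local_tempdir()
  expect_warning(res <- read_locus_alignments(d3), "no FASTA")
  expect_length(res, 0L)
})

test_that("drop_empty_columns removes all-missing columns and is idempotent", {
  a <- aln_from_rows(x = "A-C", y = "A-N", z = "A-C")
  cleaned <- drop_empty_columns(a)
  expect_equal(cleaned$length, 2L)
  expect_identical(cleaned$seq[, 2L], c(x = "C", y = "N", z = "C"))
  # mixed missing symbols -, n, ? form an empty column
  b <- aln_from_rows(x = "G-A", y = "GnA", z = "G?A")
  expect_equal(drop_empty_columns(b)$length, 2L)
  # no empty columns: unchanged; applying twice changes nothing
  c1 <- aln_from_rows(x = "ACGT", y = "A-GT")
  expect_identical(drop_empty_columns(c1), c1)
  expect_identical(drop_empty_columns(cleaned), cleaned)
  # fully-missing alignment is degenerate
  expect_error(drop_empty_columns(aln_from_rows(x = "--", y = "NN")),
               "non-missing")
})

test_that("parsimony-informative sites need two states in two taxa each", {
  a <- aln_from_rows(t1 = "ACGA", t2 = "ACGA", t3 = "GCTA", t4 = "GCTA")
  expect_equal(count_informative_sites(a), 2L)
  # singleton state or gap does not make a site informative
  b <- aln_from_rows(t1 = "AA", t2 = "AA", t3 = "GA", t4 = "-A")
  expect_equal(count_informative_sites(b), 0L)
  expect_equal(count_informative_sites(
    aln_from_rows(t1 = "ACGT", t2 = "ACGT", t3 = "ACGT")), 0L)
})

test_that("informative-site count is invariant to taxon and site order", {
  set.seed(42)
  m <- matrix(sample(c("A", "C", "G", "T", "-"), 8 * 40, TRUE,
                     prob = c(.24, .24, .24, .24, .04)), nrow = 8,
              dimnames = list(paste0("t", 1:8), NULL))
  a <- locus_alignment("x", m)
  base <- count_informative_sites(a)
  for (i in 1:5) {
    perm <- locus_alignment("x", m[sample(8), sample(40), drop = FALSE])
    expect_equal(count_informative_sites(perm), base)
  }
})

test_that("completeness filter keeps loci reaching ceil(p * T) taxa", {
  mk <- function(n) {
    m <- matrix("A", n, 4, dimnames = list(paste0("t", seq_len(n)), NULL))
    locus_alignment(paste0("n", n), m)
  }
  cfg <- matrix_filter_config(paste0("t", 1:10), 0.7)
  kept <- filter_by_completeness(list(mk(7), mk(6), mk(10)), cfg)
  expect_equal(vapply(kept, function(a) length(a$taxa), 0L), c(7L, 10L))
  cfg1 <- matrix_filter_config(paste0("t", 1:10), 1.0)
  expect_length(filter_by_completeness(list(mk(9), mk(10)), cfg1), 1L)
  # a tiny threshold still enforces the >2-taxa usability floor
  cfg0 <- matrix_filter_config(paste0("t", 1:10), 1e-6)
  expect_length(filter_by_completeness(list(mk(3), mk(10)), cfg0), 2L)
  expect_error(matrix_filter_config(character(0)), "non-empty")
})

test_that("summarize_loci aggregates and regresses PIS on length", {
  mk <- function(id, len, pis) {
    # pis informative sites: two taxa pairs differing; rest constant
    m <- matrix("A", 4, len, dimnames = list(paste0("t", 1:4), NULL))
    if (pis > 0) m[3:4, seq_len(pis)] <- "G"
    locus_alignment(id, m)
  }
  s <- summarize_loci(list(mk("a", 100, 10), mk("b", 200, 20)),
                      paste0("t", 1:4))
  expect_equal(s$aggregate$mean_length, 150)
  expect_equal(s$aggregate$mean_pis, 15)
  expect_equal(s$aggregate$slope, 0.1)
  expect_equal(s$aggregate$r2, 1.0)
  # constant PIS: flat regression
  s0 <- summarize_loci(list(mk("a", 100, 5), mk("b", 300, 5)),
                       paste0("t", 1:4))
  expect_equal(s0$aggregate$slope, 0)
  expect_error(summarize_loci(list(), "t1"), "no loci")
})

test_that("PIS ~ length slope is recovered from noisy synthetic loci", {
  set.seed(7)
  lens <- sample(231:802, 40)
  pis <- round(0.4 * lens + rnorm(40, 0, 12))
  mk <- function(id, len, k) {
    m <- matrix("A", 4, len, dimnames = list(paste0("t", 1:4), NULL))
    m[3:4, seq_len(k)] <- "G"
    locus_alignment(id, m)
  }
  alns <- Map(mk, sprintf("l%02d", 1:40), lens, pis)
  s <- summarize_loci(alns, paste0("t", 1:4))
  # closed-form OLS oracle
  fit <- lm(pis ~ lens)
  expect_equal(s$aggregate$slope, unname(coef(fit)[2]), tolerance = 1e-10)
  se <- summary(fit)$coefficients[2, 2]
  expect_lt(abs(s$aggregate$slope - 0.4), 2 * se)
})

test_that("concatenated matrix writer/reader round-trips with padding", {
  a1 <- aln_from_rows(t1 = "ACGTAC", t2 = "ACGTAA", t3 = "ACGTAT",
                      id = "uce-b")
  a2 <- aln_from_rows(t1 = "GGG", t2 = "GGC", id = "uce-a")
  pre <- file.path(withr::local_tempdir(), "mat")
  coords <- write_concatenated_matrix(list(a1, a2), pre)
  # lexicographic locus order, 1-based inclusive coordinates
  expect_identical(coords$locus_id, c("uce-a", "uce-b"))
  expect_equal(coords$start, c(1L, 4L))
  expect_equal(coords$end, c(3L, 9L))
  part <- readLines(paste0(pre, ".partitions"))
  expect_identical(part, c("DNA, uce-a = 1-3", "DNA, uce-b = 4-9"))
  expect_true(any(grepl("charset uce-b = 4-9;", readLines(paste0(pre, ".nex")))))
  back <- read_concatenated_matrix(paste0(pre, ".fasta"), coords)
  expect_identical(back[["uce-b"]]$seq, a1$seq)
  expect_identical(back[["uce-a"]]$seq, a2$seq[c("t1", "t2"), ])
  # t3 absent from uce-a: padded with ? in the matrix
  recs <- ape::read.FASTA(paste0(pre, ".fasta"))
  m <- toupper(as.character(as.matrix(recs)))
  expect_identical(unname(m["t3", 1:3]), c("?", "?", "?"))
})
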