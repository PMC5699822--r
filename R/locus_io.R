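#' Construct a locus alignment
#'
#' A locus alignment is a character matrix of aligned sequences (rows = taxa,
#' columns = sites) over the alphabet A, C, G, T plus the missing symbols
#' `-`, `N` and `?`. Other IUPAC ambiguity codes are accepted and treated as
#' missing data by downstream statistics, but never trigger column removal.
#'
#' @param locus_id Character scalar naming the locus.
#' @param seqs Character matrix with unique rownames (taxon labels); entries
#'   are single characters. Lower-case input is upper-cased.
#' @return An object of class `locus_alignment`: a list with elements
#'   `locus_id`, `seq` (the character matrix), `taxa` and `length`.
#' @export
locus_alignment <- function(locus_id, seqs) {
  stopifnot(is.character(locus_id), length(locus_id) == 1L)
  if (!is.matrix(seqs) || !is.character(seqs))
    stop("'seqs' must be a character matrix for locus ", locus_id)
  if (is.null(rownames(seqs)) || anyDuplicated(rownames(seqs)))
    stop("duplicate or missing taxon labels in locus ", locus_id)
  if (ncol(seqs) < 1L)
    stop("alignment of locus ", locus_id, " has zero sites")
  seqs[] <- toupper(seqs)
  structure(
    list(locus_id = locus_id, seq = seqs,
         taxa = rownames(seqs), length = ncol(seqs)),
    class = "locus_alignment")
}

#' @export
print.locus_alignment <- function(x, ...) {
  cat("<locus_alignment>", x$locus_id, ":", length(x$taxa), "taxa x",
      x$length, "sites\n")
  invisible(x)
}

MISSING_CHARS <- c("-", "N", "?")
NUC_STATES <- c("A", "C", "G", "T")

#' Read per-locus FASTA alignments from a directory
#'
#' One FASTA file per UCE locus; the locus id is the filename stem. Sequences
#' are upper-cased. Ragged alignments (unequal sequence lengths within a file)
#' and duplicate taxon labels are errors naming the offending locus.
#'
#' @param directory_path Directory containing `.fasta`/`.fa`/`.fas` files.
#' @return Named list of [locus_alignment()] objects, sorted by locus id.
#' @export
read_locus_alignments <- function(directory_path) {
  if (!dir.exists(directory_path)) stop("no such directory: ", directory_path)
  files <- list.files(directory_path, pattern = "\\.(fa|fas|fasta)$",
                      ignore.case = TRUE, full.names = TRUE)
  files <- sort(files)
  if (length(files) == 0L) {
    warning("no FASTA files found in ", directory_path)
    return(list())
  }
  alns <- lapply(files, function(f) {
    id <- tools::file_path_sans_ext(basename(f))
    recs <- ape::read.FASTA(f)
    if (length(recs) == 0L) stop("empty FASTA file for locus ", id)
    if (anyDuplicated(names(recs)))
      stop("duplicate taxon label in locus ", id)
    lens <- lengths(recs)
    if (length(unique(lens)) != 1L)
      stop("ragged alignment in locus ", id, ": sequence lengths ",
           paste(sort(unique(lens)), collapse = ", "))
    m <- toupper(as.character(as.matrix(recs)))
    locus_alignment(id, m)
  })
  names(alns) <- vapply(alns, `[[`, "", "locus_id")
  alns[order(names(alns))]
}

#' Remove columns composed entirely of missing symbols
#'
#' Drops every column in which all taxa carry one of `-`, `N` or `?`
#' (case-insensitive). The relative order of the remaining columns is kept;
#' the operation is idempotent. An alignment that would become empty is a
#' degenerate locus and raises an error.
#'
#' @param aln A [locus_alignment()].
#' @return The cleaned `locus_alignment`.
#' @export
drop_empty_columns <- function(aln) {
  stopifnot(inherits(aln, "locus_alignment"))
  empty <- apply(aln$seq, 2L, function(col) all(col %in% MISSING_CHARS))
  if (all(empty))
    stop("locus ", aln$locus_id, " has no non-missing columns")
  if (!any(empty)) return(aln)
  locus_alignment(aln$locus_id, aln$seq[, !empty, drop = FALSE])
}

#' Count parsimony-informative sites
#'
#' A site is parsimony-informative when at least two distinct unambiguous
#' nucleotide states (A/C/G/T) each occur in at least two taxa. Gaps, N, ?
#' and other ambiguity codes are not states.
#'
#' @param aln A [locus_alignment()].
#' @return Integer count of informative sites.
#' @export
count_informative_sites <- function(aln) {
  stopifnot(inherits(aln, "locus_alignment"))
  sum(apply(aln$seq, 2L, function(col) {
    tab <- table(col[col %in% NUC_STATES])
    sum(tab >= 2L) >= 2L
  }))
}

#' Matrix completeness filter configuration
#'
#' @param taxon_set Character vector: the full study taxon list.
#' @param min_completeness Fraction of the taxon set a locus must contain to
#'   be retained (default 0.70). A locus is kept when its taxon count is at
#'   least `ceiling(min_completeness * length(taxon_set))`.
#' @param min_taxa_for_alignment Minimum taxa for a locus to be usable at all
#'   (default 3, i.e. more than 2).
#' @return A `matrix_filter_config` list.
#' @export
matrix_filter_config <- function(taxon_set, min_completeness = 0.70,
                                 min_taxa_for_alignment = 3L) {
  if (length(taxon_set) == 0L) stop("taxon_set must be non-empty")
  if (!(min_completeness > 0 && min_completeness <= 1))
    stop("min_completeness must be in (0, 1]")
  structure(list(taxon_set = taxon_set,
                 min_completeness = min_completeness,
                 min_taxa_for_alignment = as.integer(min_taxa_for_alignment)),
            class = "matrix_filter_config")
}

#' Filter loci by taxon completeness
#'
#' @param alns List of [locus_alignment()].
#' @param cfg A [matrix_filter_config()].
#' @return The subset of `alns` (order preserved) whose taxon count reaches
#'   `ceiling(min_completeness * T)` and `min_taxa_for_alignment`.
#' @export
filter_by_completeness <- function(alns, cfg) {
  stopifnot(inherits(cfg, "matrix_filter_config"))
  need <- max(ceiling(cfg$min_completeness * length(cfg$taxon_set)),
              cfg$min_taxa_for_alignment)
  keep <- vapply(alns, function(a) length(a$taxa) >= need, TRUE)
  alns[keep]
}

#' Summarize loci and regress informative sites on length
#'
#' Per-locus summaries (length, taxon count, parsimony-informative sites,
#' completeness against the study taxon set) plus aggregate statistics:
#' mean length, mean PIS, and the OLS regression (with intercept) of PIS on
#' locus length.
#'
#' @param alns Non-empty list of [locus_alignment()].
#' @param taxon_set Full study taxon list (for the completeness fraction).
#' @return List with `summaries` (data.frame: locus_id, length, n_taxa, pis,
#'   completeness) and `aggregate` (mean_length, mean_pis, slope, intercept,
#'   r2 of PIS ~ length).
#' @export
summarize_loci <- function(alns, taxon_set) {
  if (length(alns) == 0L) stop("no loci to summarize")
  df <- do.call(rbind, lapply(alns, function(a) {
    data.frame(locus_id = a$locus_id, length = a$length,
               n_taxa = length(a$taxa),
               pis = count_informative_sites(a),
               completeness = length(a$taxa) / length(taxon_set))
  }))
  rownames(df) <- NULL
  if (nrow(df) >= 2L && stats::var(df$length) > 0) {
    fit <- stats::lm(pis ~ length, data = df)
    slope <- unname(stats::coef(fit)[2L])
    intercept <- unname(stats::coef(fit)[1L])
    r2 <- summary(fit)$r.squared
  } else {
    slope <- NA_real_; intercept <- NA_real_; r2 <- NA_real_
  }
  list(summaries = df,
       aggregate = list(mean_length = mean(df$length),
                        mean_pis = mean(df$pis),
                        slope = slope, intercept = intercept, r2 = r2))
}

#' Write a concatenated matrix with per-locus character sets
#'
#' Concatenates loci in lexicographic locus-id order over the union of their
#' taxa, padding absent taxa with `?`. Writes a FASTA matrix, a RAxML-style
#' partition file (`DNA, locus = start-end`, 1-based inclusive) and a NEXUS
#' sets block.
#'
#' @param alns List of [locus_alignment()].
#' @param out_prefix Path prefix; writes `<prefix>.fasta`,
#'   `<prefix>.partitions` and `<prefix>.nex`.
#' @return Invisibly, a data.frame of locus coordinates (locus_id, start,
#'   end; 1-based inclusive).
#' @export
write_concatenated_matrix <- function(alns, out_prefix) {
  if (length(alns) == 0L) stop("no loci to concatenate")
  ids <- vapply(alns, `[[`, "", "locus_id")
  if (anyDuplicated(ids)) stop("duplicate locus ids")
  alns <- alns[order(ids)]
  taxa <- sort(unique(unlist(lapply(alns, `[[`, "taxa"))))
  blocks <- lapply(alns, function(a) {
    m <- matrix("?", nrow = length(taxa), ncol = a$length,
                dimnames = list(taxa, NULL))
    m[a$taxa, ] <- a$seq
    m
  })
  mat <- do.call(cbind, blocks)
  lens <- vapply(alns, `[[`, 0L, "length")
  end <- cumsum(lens)
  coords <- data.frame(locus_id = vapply(alns, `[[`, "", "locus_id"),
                       start = end - lens + 1L, end = end)
  fasta <- file(paste0(out_prefix, ".fasta"), "w")
  for (t in taxa)
    writeLines(c(paste0(">", t), paste(mat[t, ], collapse = "")), fasta)
  close(fasta)
  writeLines(sprintf("DNA, %s = %d-%d", coords$locus_id, coords$start,
                     coords$end),
             paste0(out_prefix, ".partitions"))
  writeLines(c("#NEXUS", "begin sets;",
               sprintf("  charset %s = %d-%d;", coords$locus_id,
                       coords$start, coords$end),
               "end;"),
             paste0(out_prefix, ".nex"))
  invisible(coords)
}

#' Read a concatenated FASTA matrix and split it at charset boundaries
#'
#' Inverse of [write_concatenated_matrix()] up to the `?` padding of taxa
#' absent from a locus.
#'
#' @param fasta_path Concatenated FASTA matrix.
#' @param coords Data.frame with columns locus_id, start, end (1-based
#'   inclusive), as returned by [write_concatenated_matrix()].
#' @return Named list of [locus_alignment()].
#' @export
read_concatenated_matrix <- function(fasta_path, coords) {
  recs <- ape::read.FASTA(fasta_path)
  m <- toupper(as.character(as.matrix(recs)))
  out <- lapply(seq_len(nrow(coords)), function(i) {
    sub <- m[, coords$start[i]:coords$end[i], drop = FALSE]
    pad <- apply(sub, 1L, function(r) all(r == "?"))
    locus_alignment(coords$locus_id[i], sub[!pad, , drop = FALSE])
  })
  names(out) <- coords$locus_id
  out
}
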