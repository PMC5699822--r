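#' Core/flank character-set specification
#'
#' UCE loci have a conserved central core (the bait region, ~160 bp) and
#' flanks whose per-site variability rises with distance from the core. The
#' spec fixes the core length and the number of mirrored flank bins on each
#' side.
#'
#' @param core_length Core width in sites (default 160).
#' @param n_flank_bins Number of flank bins per side (default 5).
#' @return A `core_spec` list.
#' @export
core_spec <- function(core_length = 160L, n_flank_bins = 5L) {
  stopifnot(core_length >= 1L, n_flank_bins >= 1L)
  structure(list(core_length = as.integer(core_length),
                 n_flank_bins = as.integer(n_flank_bins)),
            class = "core_spec")
}

#' Locate the central core interval of a locus
#'
#' For a locus of `length` sites the core is the central `core_length`
#' columns, left offset `floor((length - core_length) / 2)` (the extra
#' column, when the flank total is odd, goes to the right flank). Loci
#' shorter than the core are returned whole with `core_only = TRUE`.
#'
#' @param length Locus length in sites.
#' @param spec A [core_spec()].
#' @return List with `start`, `end` (0-based half-open) and `core_only`.
#' @export
locate_core <- function(length, spec = core_spec()) {
  stopifnot(length >= 1L)
  if (length < spec$core_length)
    return(list(start = 0L, end = as.integer(length), core_only = TRUE))
  off <- (length - spec$core_length) %/% 2L
  list(start = as.integer(off), end = as.integer(off + spec$core_length),
       core_only = FALSE)
}

# Flank bin widths, inner (adjacent to core) to outer. The remainder sites
# go to the outermost bins so the inner bins, where the rate profile changes
# fastest, stay homogeneous.
flank_bin_widths <- function(flank_len, n_bins) {
  base <- flank_len %/% n_bins
  r <- flank_len %% n_bins
  w <- rep(base, n_bins)
  if (r > 0L) w[(n_bins - r + 1L):n_bins] <- base + 1L
  w
}

#' Build the core and mirrored flank character sets of a locus
#'
#' Returns the core charset plus up to `n_flank_bins` flank charsets. Each
#' flank is divided independently into contiguous bins of width
#' `floor(F / n_bins)` with the remainder distributed one extra site to each
#' of the outermost bins; bin k of the left flank is unioned with bin k of
#' the right flank into charset `flank_k`, k = 1 adjacent to the core.
#' Empty charsets are dropped; together the charsets partition the columns.
#'
#' @param aln A [locus_alignment()] (only its length is used) or an integer
#'   locus length.
#' @param spec A [core_spec()].
#' @return Named list of charsets, each a list with `name`, `ranges`
#'   (data.frame of 0-based half-open `start`,`end`) and `n_sites`; ordered
#'   core, flank1, ..., flank5.
#' @export
build_charsets <- function(aln, spec = core_spec()) {
  L <- if (inherits(aln, "locus_alignment")) aln$length else as.integer(aln)
  core <- locate_core(L, spec)
  cs <- list(core = list(
    name = "core",
    ranges = data.frame(start = core$start, end = core$end),
    n_sites = core$end - core$start))
  if (core$core_only) return(cs)
  nb <- spec$n_flank_bins
  lw <- flank_bin_widths(core$start, nb)          # left flank, inner->outer
  rw <- flank_bin_widths(L - core$end, nb)        # right flank, inner->outer
  lcum <- cumsum(lw); rcum <- cumsum(rw)
  for (k in seq_len(nb)) {
    rngs <- list()
    if (lw[k] > 0L)
      rngs[[length(rngs) + 1L]] <-
        data.frame(start = core$start - lcum[k],
                   end = core$start - lcum[k] + lw[k])
    if (rw[k] > 0L)
      rngs[[length(rngs) + 1L]] <-
        data.frame(start = core$end + rcum[k] - rw[k],
                   end = core$end + rcum[k])
    if (length(rngs) == 0L) next
    nm <- paste0("flank", k)
    rd <- do.call(rbind, rngs)
    cs[[nm]] <- list(name = nm, ranges = rd, n_sites = sum(rd$end - rd$start))
  }
  cs
}

#' Expand a charset to its 0-based column indices
#'
#' @param cs A charset as returned by [build_charsets()].
#' @return Sorted integer vector of 0-based column indices.
#' @export
charset_sites <- function(cs) {
  sort(unlist(Map(function(s, e) seq.int(s, e - 1L),
                  cs$ranges$start, cs$ranges$end)))
}

#' Write NEXUS charset definitions for one or more loci
#'
#' Coordinates are written 1-based inclusive; multi-range charsets as
#' space-separated ranges; charsets in order core, flank1...flank5. Loci in
#' lexicographic order.
#'
#' @param schemes Named list (by locus id) of charset lists from
#'   [build_charsets()].
#' @param out_path Output file path.
#' @return Invisibly, the lines written.
#' @export
write_charset_definitions <- function(schemes, out_path) {
  lines <- c("#NEXUS", "begin sets;")
  for (locus in sort(names(schemes))) {
    cs_list <- schemes[[locus]]
    allsites <- unlist(lapply(cs_list, charset_sites))
    if (anyDuplicated(allsites))
      stop("overlapping charsets in locus ", locus)
    for (cs in cs_list) {
      rng <- sprintf("%d-%d", cs$ranges$start + 1L, cs$ranges$end)
      lines <- c(lines, sprintf("  charset %s_%s = %s;", locus, cs$name,
                                paste(rng, collapse = " ")))
    }
  }
  lines <- c(lines, "end;")
  writeLines(lines, out_path)
  invisible(lines)
}

#' Parse a NEXUS charset file written by [write_charset_definitions()]
#'
#' @param path File path.
#' @return Named list (by locus) of named lists (by charset) of 0-based site
#'   index vectors.
#' @export
read_charset_definitions <- function(path) {
  lines <- grep("^\\s*charset ", readLines(path), value = TRUE)
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("charset (\\S+)_(core|flank\\d+) = ([0-9 -]+);", ln))[[1]]
    locus <- m[2]; nm <- m[3]
    sites <- unlist(lapply(strsplit(m[4], " ")[[1]], function(r) {
      se <- as.integer(strsplit(r, "-")[[1]])
      seq.int(se[1] - 1L, se[2] - 1L)
    }))
    out[[locus]][[nm]] <- sort(sites)
  }
  out
}
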