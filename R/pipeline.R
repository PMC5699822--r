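PIPELINE_DEFAULTS <- list(
  loci_dir = NULL, trees_dir = NULL, specimen_table = NULL,
  simulate = NULL,                 # list(preset = "weevil-like", n_loci, ...)
  output_dir = "corepart-out", seed = 1L,
  min_completeness = 0.70, core_length = 160L, n_flank_bins = 5L,
  search = "greedy", drop_quantile = 0.10, saturation_multiplier = 1.5,
  burnin = 0.25, asdsf_min_freq = 0.10,
  stages = c("ingest", "clean", "charsets", "model_select", "treeqc",
             "treedist", "capture"))

#' Validate and default a pipeline configuration
#'
#' Reads a YAML file (or takes a list), fills defaults, rejects unknown
#' keys (suggesting the nearest known key) and out-of-range parameters.
#'
#' @param cfg Path to a YAML file, or a named list.
#' @return The fully-resolved `pipeline_config` list.
#' @export
validate_config <- function(cfg) {
  if (is.character(cfg)) cfg <- yaml::read_yaml(cfg)
  stopifnot(is.list(cfg))
  known <- names(PIPELINE_DEFAULTS)
  bad <- setdiff(names(cfg), known)
  if (length(bad) > 0L) {
    hint <- vapply(bad, function(k) {
      m <- agrep(k, known, max.distance = 0.3, value = TRUE)
      if (length(m) > 0L) paste0(" (did you mean '", m[1L], "'?)") else ""
    }, "")
    stop("unknown config key(s): ",
         paste0(bad, hint, collapse = ", "))
  }
  out <- utils::modifyList(PIPELINE_DEFAULTS, cfg)
  if (!(out$burnin >= 0 && out$burnin < 1)) stop("burnin must be in [0, 1)")
  if (!(out$min_completeness > 0 && out$min_completeness <= 1))
    stop("min_completeness must be in (0, 1]")
  if (!(out$drop_quantile >= 0 && out$drop_quantile < 1))
    stop("drop_quantile must be in [0, 1)")
  if (out$core_length < 1L) stop("core_length must be >= 1")
  if (is.null(out$simulate)) {
    if (is.null(out$loci_dir))
      stop("missing required key: loci_dir (or simulate)")
    if (!dir.exists(out$loci_dir)) stop("loci_dir does not exist")
  }
  if ("treedist" %in% out$stages && is.null(out$trees_dir) &&
      !identical(out$stages, PIPELINE_DEFAULTS$stages))
    stop("treedist stage enabled but no trees_dir given")
  structure(out, class = "pipeline_config")
}

#' Run the pipeline end-to-end
#'
#' Executes the enabled stages in order (simulate/ingest, clean + filter,
#' charsets, model selection, gene-tree QC, capture statistics), writing
#' every artifact under the configured output directory plus a manifest of
#' files, parameters and checksums. Identical config and seed give
#' identical manifest checksums.
#'
#' @param cfg A [validate_config()] result (or anything it accepts).
#' @return The manifest, invisibly: list of `parameters`, `files`
#'   (path + md5), `results` (key stage summaries).
#' @export
run_pipeline <- function(cfg) {
  if (!inherits(cfg, "pipeline_config")) cfg <- validate_config(cfg)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)
  results <- list()

  if (!is.null(cfg$simulate)) {
    simargs <- cfg$simulate
    scfg <- sim_config(n_taxa = simargs$n_taxa %||% 12L,
                       n_loci = simargs$n_loci %||% 12L,
                       core_length = cfg$core_length,
                       n_flank_bins = cfg$n_flank_bins)
    sim <- simulate_loci(scfg, seed = cfg$seed)
    alns <- sim$alignments
    message("simulated ", length(alns), " loci on ", scfg$n_taxa, " taxa")
  } else {
    alns <- read_locus_alignments(cfg$loci_dir)
  }

  if ("clean" %in% cfg$stages) {
    alns <- lapply(alns, drop_empty_columns)
    taxon_set <- sort(unique(unlist(lapply(alns, `[[`, "taxa"))))
    fcfg <- matrix_filter_config(taxon_set, cfg$min_completeness)
    alns <- filter_by_completeness(alns, fcfg)
    summ <- summarize_loci(alns, taxon_set)
    utils::write.table(summ$summaries,
                       file.path(cfg$output_dir, "locus_summary.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    results$locus_summary <- summ$aggregate
  }

  if ("charsets" %in% cfg$stages) {
    spec <- core_spec(cfg$core_length, cfg$n_flank_bins)
    schemes <- lapply(alns, build_charsets, spec = spec)
    write_charset_definitions(schemes,
                              file.path(cfg$output_dir, "charsets.nex"))
  }

  if ("model_select" %in% cfg$stages) {
    sel <- select_schemes(alns, core_spec(cfg$core_length,
                                          cfg$n_flank_bins),
                          search = cfg$search)
    utils::write.table(sel$report,
                       file.path(cfg$output_dir, "scheme_report.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    results$subset_counts <- table(sel$report$n_subsets)
  }

  if ("treeqc" %in% cfg$stages && !is.null(cfg$trees_dir)) {
    tf <- list.files(cfg$trees_dir, pattern = "\\.(nwk|tre|tree)$",
                     full.names = TRUE)
    trees <- lapply(tf, ape::read.tree)
    names(trees) <- tools::file_path_sans_ext(basename(tf))
    rec <- qc_gene_trees(trees, alns, cfg$drop_quantile,
                         cfg$saturation_multiplier)
    utils::write.table(rec, file.path(cfg$output_dir, "treeqc.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    results$treeqc <- rec
  }

  if ("treedist" %in% cfg$stages && !is.null(cfg$trees_dir)) {
    tf <- list.files(cfg$trees_dir, pattern = "\\.(nwk|tre|tree)$",
                     full.names = TRUE)
    if (length(tf) >= 2L) {
      trees <- lapply(tf, ape::read.tree)
      names(trees) <- tools::file_path_sans_ext(basename(tf))
      dists <- pairwise_distance_table(
        trees, restrict_to_shared = TRUE,
        out_path = file.path(cfg$output_dir, "tree_distances.tsv"))
      results$tree_distances <- dists
    }
  }

  if ("capture" %in% cfg$stages && !is.null(cfg$specimen_table)) {
    recs <- read_specimen_table(cfg$specimen_table)
    glm_fit <- fit_capture_glm(recs)
    fr <- logit_capture_fraction(recs)
    utils::write.table(glm_fit$coefficients,
                       file.path(cfg$output_dir, "capture_glm.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    results$capture_glm <- glm_fit
    if (length(unique(recs$study)) >= 2L)
      results$capture_lrt <- common_slope_lrt(fr)
  }

  files <- list.files(cfg$output_dir, full.names = TRUE)
  manifest <- list(
    parameters = unclass(cfg),
    files = data.frame(path = basename(files),
                       md5 = unname(tools::md5sum(files))),
    results = results)
  saveRDS_path <- file.path(cfg$output_dir, "manifest.yaml")
  yaml::write_yaml(list(parameters = manifest$parameters,
                        files = manifest$files$path,
                        md5 = manifest$files$md5), saveRDS_path)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
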