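#' Welch two-sample t-test
#'
#' Two-sided Welch test (unequal variances, Welch-Satterthwaite degrees of
#' freedom), as used to compare locus capture between ethanol-preserved and
#' pinned museum specimens.
#'
#' @param x,y Numeric vectors, each with >= 2 values and positive variance.
#' @return List with `t`, `df`, `p`.
#' @export
welch_t_test <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L) stop("each group needs >= 2 values")
  if (stats::var(x) == 0 && stats::var(y) == 0 && mean(x) == mean(y))
    return(list(t = 0, df = length(x) + length(y) - 2, p = 1))
  ht <- stats::t.test(x, y, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' GLM of captured locus count on specimen age and preservation
#'
#' Fits `loci_count ~ age_years + preservation` by maximum likelihood
#' (Gaussian identity link by default; Poisson log link optionally), with
#' ethanol as the reference preservation level, and reports Wald
#' per-coefficient p-values.
#'
#' @param records Data.frame with columns `loci_count`, `age_years`,
#'   `preservation` (values "ethanol"/"pinned"); >= 4 rows.
#' @param family `"gaussian"` (default) or `"poisson"`.
#' @return List with `coefficients` (estimate, std_error, p_value per term)
#'   and `lnL`.
#' @export
fit_capture_glm <- function(records, family = c("gaussian", "poisson")) {
  family <- match.arg(family)
  stopifnot(nrow(records) >= 4L)
  records$preservation <- stats::relevel(
    factor(records$preservation, levels = c("ethanol", "pinned")),
    ref = "ethanol")
  records$preservation <- droplevels(records$preservation)
  form <- if (nlevels(records$preservation) > 1L)
    loci_count ~ age_years + preservation else loci_count ~ age_years
  fam <- switch(family, gaussian = stats::gaussian(),
                poisson = stats::poisson())
  fit <- stats::glm(form, data = records, family = fam)
  if (fit$rank < length(stats::coef(fit)) || anyNA(stats::coef(fit)))
    stop("degenerate (collinear) design")
  sm <- summary(fit)$coefficients
  list(coefficients = data.frame(term = rownames(sm),
                                 estimate = sm[, 1L],
                                 std_error = sm[, 2L],
                                 p_value = sm[, 4L],
                                 row.names = NULL),
       lnL = as.numeric(stats::logLik(fit)))
}

#' Logit-transformed capture fractions, per study
#'
#' Within each study the capture fraction is the specimen's deduplicated
#' locus count divided by the study maximum. The fraction of the maximum
#' specimen is exactly 1, whose logit is infinite, so the squeeze transform
#' `p' = (p (n - 1) + 0.5) / n` (n = study sample size) is applied before
#' `logit(p') = ln(p' / (1 - p'))`.
#'
#' @param records Data.frame with columns `specimen_id`, `loci_count`,
#'   `study` and (carried through) `age_years`.
#' @return Data.frame with `specimen_id`, `study`, `age_years`, `fraction`,
#'   `logit_value`.
#' @export
logit_capture_fraction <- function(records) {
  out <- do.call(rbind, lapply(split(records, records$study), function(d) {
    mx <- max(d$loci_count)
    if (mx <= 0) stop("study ", d$study[1L], " has no captured loci")
    n <- nrow(d)
    p <- d$loci_count / mx
    ps <- (p * (n - 1) + 0.5) / n
    data.frame(specimen_id = d$specimen_id, study = d$study,
               age_years = d$age_years, fraction = p,
               logit_value = log(ps / (1 - ps)))
  }))
  rownames(out) <- NULL
  out
}

#' Likelihood-ratio test of study-specific vs common capture-decay slope
#'
#' Fits two Gaussian ML regressions of the logit capture fraction on
#' specimen age: the full model with per-study intercepts and per-study
#' slopes, and the reduced model with per-study intercepts but one shared
#' slope. Twice the log-likelihood difference is compared to a chi-squared
#' distribution with (#studies - 1) degrees of freedom.
#'
#' @param fractions Output of [logit_capture_fraction()] (needs columns
#'   `logit_value`, `age_years`, `study`), >= 2 studies, each with >= 3
#'   specimens and age variation.
#' @return List with `lnL_full`, `lnL_reduced`, `lr_stat`, `df`, `p_value`,
#'   and `common_slope` (the reduced-model slope and its standard error).
#' @export
common_slope_lrt <- function(fractions) {
  fractions$study <- factor(fractions$study)
  ns <- nlevels(fractions$study)
  if (ns < 2L) stop("need >= 2 studies")
  per <- split(fractions, fractions$study)
  if (any(vapply(per, nrow, 0L) < 3L))
    stop("each study needs >= 3 specimens")
  if (any(vapply(per, function(d) stats::var(d$age_years), 0) == 0))
    stop("each study needs age variation")
  full <- stats::lm(logit_value ~ study + study:age_years, data = fractions)
  red <- stats::lm(logit_value ~ study + age_years, data = fractions)
  lnL_full <- as.numeric(stats::logLik(full))
  lnL_red <- as.numeric(stats::logLik(red))
  lr <- max(0, 2 * (lnL_full - lnL_red))
  sm <- summary(red)$coefficients
  list(lnL_full = lnL_full, lnL_reduced = lnL_red, lr_stat = lr,
       df = ns - 1L,
       p_value = stats::pchisq(lr, df = ns - 1L, lower.tail = FALSE),
       common_slope = unname(sm["age_years", 1L]),
       common_slope_se = unname(sm["age_years", 2L]))
}

#' Read a specimen metadata table
#'
#' CSV/TSV with columns `specimen_id`, `year_collected`, `preservation`,
#' `loci_count`, `study`; ages are computed as
#' `sequencing_year - year_collected`.
#'
#' @param path File path (delimiter inferred from the extension).
#' @param sequencing_year Year of sequencing (default 2017).
#' @return Data.frame of specimen records with an `age_years` column.
#' @export
read_specimen_table <- function(path, sequencing_year = 2017) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  d <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE)
  need <- c("specimen_id", "year_collected", "preservation", "loci_count",
            "study")
  if (!all(need %in% names(d)))
    stop("missing columns: ", paste(setdiff(need, names(d)), collapse = ", "))
  d$age_years <- sequencing_year - d$year_collected
  if (any(d$age_years < 0)) stop("negative specimen age")
  d
}
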