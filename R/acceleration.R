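#' Adjust predicted methylation age for technical covariates
#'
#' Removes technical batch structure (plate, array, chip position,
#' hybridisation date, ...) from m_age by ordinary least squares: m_age is
#' regressed on the covariates, all treated as fixed-effect factors, and the
#' residuals are added back to the mean predicted age, so the grand mean is
#' preserved exactly. With no covariates the input is returned unchanged.
#'
#' @param m_age Tibble with `sample_id` and `m_age` columns, as returned by
#'   [apply_clock()].
#' @param covariates Data frame with `sample_id` plus one column per
#'   technical factor (coerced to factor), or `NULL` for no adjustment.
#' @param numeric_ok Treat numeric covariate columns as numeric rather than
#'   coercing to factor (used for cell counts).
#' @return `m_age` with its `m_age` column replaced by the adjusted values.
#' @export
adjust_technical <- function(m_age, covariates = NULL, numeric_ok = FALSE) {
  stopifnot(is.data.frame(m_age), all(c("sample_id", "m_age") %in% names(m_age)))
  vars <- if (is.null(covariates)) character(0) else setdiff(names(covariates), "sample_id")
  if (length(vars) == 0) {
    return(m_age)
  }
  if (!"sample_id" %in% names(covariates)) {
    abort("`covariates` must have a `sample_id` column.",
          class = "methage_format_error")
  }
  dat <- dplyr::inner_join(m_age, covariates, by = "sample_id")
  if (nrow(dat) != nrow(m_age)) {
    abort("Covariate table does not cover every sample.",
          class = "methage_validation_error")
  }
  for (v in vars) {
    if (!(numeric_ok && is.numeric(dat[[v]]))) dat[[v]] <- factor(dat[[v]])
  }
  fml <- stats::reformulate(vars, response = "m_age")
  fit <- lm(fml, data = dat)
  if (anyNA(coef(fit))) {
    abort(paste0("Rank-deficient technical design; aliased terms: ",
                 paste(names(coef(fit))[is.na(coef(fit))], collapse = ", ")),
          class = "methage_validation_error")
  }
  out <- m_age
  out$m_age <- unname(resid(fit)[match(m_age$sample_id, dat$sample_id)]) +
    mean(dat$m_age)
  out
}

#' Adjust predicted methylation age for white blood cell counts
#'
#' Sensitivity adjustment entering measured cell counts (basophils,
#' eosinophils, monocytes, lymphocytes, neutrophils) as numeric covariates,
#' optionally alongside technical factors, using the same
#' residual-plus-mean construction as [adjust_technical()].
#'
#' @inheritParams adjust_technical
#' @param cells Data frame with `sample_id` plus numeric cell-count columns.
#' @return `m_age` with its `m_age` column replaced by the adjusted values.
#' @export
adjust_cell_counts <- function(m_age, cells, covariates = NULL) {
  stopifnot(is.data.frame(cells), "sample_id" %in% names(cells))
  cell_vars <- setdiff(names(cells), "sample_id")
  constant <- vapply(cell_vars, function(v) var(cells[[v]], na.rm = TRUE) == 0,
                     logical(1))
  cells <- cells[c("sample_id", cell_vars[!constant])]
  combined <- if (is.null(covariates)) cells else {
    dplyr::inner_join(covariates, cells, by = "sample_id")
  }
  adjust_technical(m_age, combined, numeric_ok = TRUE)
}

#' Compute delta-age
#'
#' Delta-age is the accelerated-aging statistic: adjusted methylation age
#' minus chronological age, in years. Positive values indicate an
#' epigenetically "older" profile than the calendar age.
#'
#' @param m_age Tibble with `sample_id`, `m_age`.
#' @param pheno Data frame with `sample_id` and `chron_age` (years).
#' @return Tibble with `sample_id` and `delta` (years).
#' @export
compute_delta_age <- function(m_age, pheno) {
  stopifnot(all(c("sample_id", "chron_age") %in% names(pheno)))
  if (!all(m_age$sample_id %in% pheno$sample_id)) {
    abort("Samples in `m_age` missing from the phenotype table.",
          class = "methage_validation_error")
  }
  dat <- dplyr::inner_join(m_age, pheno[c("sample_id", "chron_age")], by = "sample_id")
  tibble::tibble(sample_id = dat$sample_id, delta = dat$m_age - dat$chron_age)
}

#' Residual-based age acceleration
#'
#' Residuals from a simple regression of predicted age on chronological
#' age. Unlike delta-age, this index is uncorrelated with chronological age
#' by construction, which prevents spurious correlations when relating it
#' to age-dependent quantities such as cell abundances.
#'
#' @inheritParams compute_delta_age
#' @return Tibble with `sample_id` and `accel` (years; zero mean, zero
#'   correlation with chronological age).
#' @export
compute_age_acceleration <- function(m_age, pheno) {
  dat <- dplyr::inner_join(m_age, pheno[c("sample_id", "chron_age")], by = "sample_id")
  if (nrow(dat) < 3) {
    abort("Need at least 3 samples.", class = "methage_validation_error")
  }
  if (var(dat$chron_age) == 0) {
    abort("Chronological age is constant; regression slope unidentifiable.",
          class = "methage_validation_error")
  }
  fit <- lm(m_age ~ chron_age, data = dat)
  tibble::tibble(sample_id = dat$sample_id, accel = unname(resid(fit)))
}

#' Cohort summary of clock performance
#'
#' Per-cohort descriptives of a scored clock: mean and SD of m_age and of
#' delta-age, the median absolute error `median(|m_age - chron_age|)`, and
#' the Pearson correlation between predicted and chronological age.
#'
#' @inheritParams compute_delta_age
#' @return One-row tibble: `n`, `mean_m_age`, `sd_m_age`, `mean_delta`,
#'   `sd_delta`, `median_error`, `r_age`.
#' @export
cohort_summary <- function(m_age, pheno) {
  dat <- dplyr::inner_join(m_age, pheno[c("sample_id", "chron_age")], by = "sample_id")
  dat <- dat[stats::complete.cases(dat[c("m_age", "chron_age")]), ]
  stopifnot(nrow(dat) >= 2)
  delta <- dat$m_age - dat$chron_age
  tibble::tibble(
    n = nrow(dat),
    mean_age = mean(dat$chron_age), sd_age = sd(dat$chron_age),
    mean_m_age = mean(dat$m_age), sd_m_age = sd(dat$m_age),
    mean_delta = mean(delta), sd_delta = sd(delta),
    median_error = median(abs(delta)),
    r_age = cor(dat$m_age, dat$chron_age))
}

#' Correlate age acceleration with cell abundances
#'
#' Pearson correlation of the residual age-acceleration index with each
#' (measured or methylation-predicted) cell-abundance column; columns with
#' zero variance yield `NA` with a warning.
#'
#' @param accel Tibble with `sample_id`, `accel` (see
#'   [compute_age_acceleration()]).
#' @param cells Data frame with `sample_id` plus numeric abundance columns.
#' @return Tibble with `cell` and `r`.
#' @export
correlate_acceleration_with_cells <- function(accel, cells) {
  dat <- dplyr::inner_join(accel, cells, by = "sample_id")
  if (nrow(dat) < 3) {
    abort("Need at least 3 aligned samples.", class = "methage_validation_error")
  }
  vars <- setdiff(names(cells), "sample_id")
  r <- vapply(vars, function(v) {
    x <- dat[[v]]
    if (var(x, na.rm = TRUE) == 0) {
      warn(sprintf("Cell column '%s' has zero variance; correlation undefined.", v))
      return(NA_real_)
    }
    cor(dat$accel, x, use = "complete.obs")
  }, numeric(1))
  tibble::tibble(cell = vars, r = unname(r))
}
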