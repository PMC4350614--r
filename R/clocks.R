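#' Define an epigenetic clock
#'
#' A clock is a named linear predictor of age from CpG beta values:
#' `raw = intercept + sum_j weight_j * beta_j`, optionally followed by the
#' inverse of a log-linear age calibration (`transform = "horvath"`), under
#' which the linear part predicts transformed age and
#' [inverse_horvath()] maps the raw score back to years.
#'
#' @param name Clock name.
#' @param intercept Intercept, in years (identity transform) or
#'   transformed-age units (horvath transform).
#' @param weights Named numeric vector of per-probe coefficients
#'   (names are CpG probe IDs).
#' @param transform `"identity"` or `"horvath"`.
#' @param adult_age Calibration knot in years, used only by the horvath
#'   transform; defaults to 20.
#' @return An object of class `clock_definition`.
#' @examples
#' clock_definition("toy", 0, c(cg01 = 20, cg02 = -10))
#' @export
clock_definition <- function(name, intercept, weights,
                             transform = c("identity", "horvath"),
                             adult_age = 20) {
  transform <- match.arg(transform)
  if (length(weights) == 0) {
    abort("A clock needs at least one probe weight.",
          class = "methage_validation_error")
  }
  if (is.null(names(weights)) || anyDuplicated(names(weights))) {
    abort("Clock weights must have unique probe-ID names.",
          class = "methage_format_error")
  }
  if (transform == "horvath" && (!is.numeric(adult_age) || adult_age <= 0)) {
    abort("`adult_age` must be > 0 for the horvath transform.",
          class = "methage_validation_error")
  }
  structure(
    list(name = name, intercept = as.numeric(intercept),
         weights = weights, transform = transform,
         adult_age = as.numeric(adult_age)),
    class = "clock_definition")
}

#' @export
print.clock_definition <- function(x, ...) {
  cat(sprintf("<clock_definition '%s': %d probes, intercept %.4g, transform %s>\n",
              x$name, length(x$weights), x$intercept, x$transform))
  invisible(x)
}

#' Read a clock coefficient file
#'
#' Coefficients live in a CSV with columns `probe_id,weight` (mirroring
#' published clock supplementary tables); clock metadata (`name`,
#' `intercept`, `transform`, `adult_age`) lives in a YAML sidecar at
#' `<path-without-extension>.yml`. Missing sidecar fields fall back to the
#' file stem, intercept 0 and the identity transform; a horvath clock
#' without `adult_age` falls back to 20 with a warning.
#'
#' @param path Path to the coefficient CSV.
#' @return A [clock_definition()].
#' @export
read_clock <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    probe_id = readr::col_character(), weight = readr::col_double()))
  if (!all(c("probe_id", "weight") %in% names(df))) {
    abort("Clock CSV must have `probe_id` and `weight` columns.",
          class = "methage_format_error")
  }
  if (anyDuplicated(df$probe_id)) {
    abort(paste0("Duplicate probe in clock file: ",
                 paste(unique(df$probe_id[duplicated(df$probe_id)]), collapse = ", ")),
          class = "methage_format_error")
  }
  stem <- sub("\\.[^.]*$", "", path)
  sidecar <- paste0(stem, c(".yml", ".yaml"))
  sidecar <- sidecar[file.exists(sidecar)]
  meta <- if (length(sidecar) > 0) yaml::read_yaml(sidecar[1]) else list()
  transform <- meta$transform %||% "identity"
  if (!transform %in% c("identity", "horvath")) {
    abort(sprintf("Unknown clock transform '%s'.", transform),
          class = "methage_validation_error")
  }
  adult_age <- meta$adult_age
  if (transform == "horvath" && is.null(adult_age)) {
    warn("horvath transform without `adult_age` in sidecar; defaulting to 20.")
    adult_age <- 20
  }
  clock_definition(
    name = meta$name %||% basename(stem),
    intercept = meta$intercept %||% 0,
    weights = setNames(df$weight, df$probe_id),
    transform = transform,
    adult_age = adult_age %||% 20)
}

#' Write a clock to CSV plus YAML sidecar
#'
#' @param clock A [clock_definition()].
#' @param path Output CSV path; the metadata sidecar is written next to it
#'   as `<stem>.yml`.
#' @return `path`, invisibly.
#' @export
write_clock <- function(clock, path) {
  readr::write_csv(
    tibble::tibble(probe_id = names(clock$weights), weight = unname(clock$weights)),
    path)
  yaml::write_yaml(
    list(name = clock$name, intercept = clock$intercept,
         transform = clock$transform, adult_age = clock$adult_age),
    paste0(sub("\\.[^.]*$", "", path), ".yml"))
  invisible(path)
}

#' Log-linear age calibration
#'
#' Maps age in years to the transformed scale used by multi-tissue clocks:
#' logarithmic below `adult_age`, linear above, continuous at the knot.
#' `horvath_transform(age) = log(age + 1) - log(adult_age + 1)` for
#' `age <= adult_age`, else `(age - adult_age) / (adult_age + 1)`
#' (natural logarithm).
#'
#' @param age Age in years; must be `> -1`.
#' @param adult_age Calibration knot in years (default 20).
#' @return Transformed age (dimensionless), vectorised over `age`.
#' @examples
#' horvath_transform(20)          # 0 at the knot
#' inverse_horvath(horvath_transform(65))  # 65
#' @export
horvath_transform <- function(age, adult_age = 20) {
  if (any(!is.finite(age)) || any(age <= -1)) {
    abort("`age` must be finite and > -1.", class = "methage_domain_error")
  }
  ifelse(age <= adult_age,
         log(age + 1) - log(adult_age + 1),
         (age - adult_age) / (adult_age + 1))
}

#' @rdname horvath_transform
#' @param x Transformed age.
#' @return `inverse_horvath()`: age in years.
#' @export
inverse_horvath <- function(x, adult_age = 20) {
  if (any(!is.finite(x))) {
    abort("`x` must be finite.", class = "methage_domain_error")
  }
  ifelse(x <= 0,
         (adult_age + 1) * exp(x) - 1,
         adult_age + x * (adult_age + 1))
}

#' Score an epigenetic clock on a beta matrix
#'
#' Computes the predicted methylation age (m_age) for every sample as the
#' clock intercept plus the weighted sum of beta values, mapped back to
#' years through [inverse_horvath()] when the clock is calibrated on the
#' transformed age scale. Clock probes absent from the matrix (or `NA` in a
#' sample) are handled per `missing_policy`: `"drop_term"` omits their terms
#' (the default; published clocks have been applied with one probe missing
#' and no imputation), `"mean_impute"` substitutes the probe's mean beta
#' across samples where it is observed.
#'
#' @param betas A [beta_matrix()].
#' @param clock A [clock_definition()].
#' @param missing_policy `"drop_term"` or `"mean_impute"`.
#' @return A tibble with one row per sample: `sample_id`, `m_age` (years;
#'   `NA` when every clock probe is missing for the sample) and `coverage`
#'   (fraction of the clock's probes contributing for that sample).
#' @examples
#' m <- matrix(c(0.5, 0.3), nrow = 2, dimnames = list(c("cg01", "cg02"), "s1"))
#' cl <- clock_definition("toy", 0, c(cg01 = 20, cg02 = -10))
#' apply_clock(beta_matrix(m), cl)   # m_age = 20*0.5 - 10*0.3 = 7
#' @export
apply_clock <- function(betas, clock,
                        missing_policy = c("drop_term", "mean_impute")) {
  missing_policy <- match.arg(missing_policy)
  stopifnot(inherits(betas, "beta_matrix"), inherits(clock, "clock_definition"))
  present <- intersect(names(clock$weights), rownames(betas))
  if (length(present) == 0) {
    abort(sprintf("None of the %d probes of clock '%s' are in the beta matrix.",
                  length(clock$weights), clock$name),
          class = "methage_validation_error")
  }
  w <- clock$weights[present]
  sub <- unclass(betas)[present, , drop = FALSE]
  if (missing_policy == "mean_impute") {
    probe_means <- rowMeans(sub, na.rm = TRUE)
    for (j in seq_len(ncol(sub))) {
      miss <- is.na(sub[, j])
      sub[miss, j] <- probe_means[miss]
    }
  }
  observed <- !is.na(sub)
  # per-sample weighted sum over the terms that remain after the policy
  sub0 <- sub
  sub0[is.na(sub0)] <- 0
  raw <- clock$intercept + as.vector(crossprod(sub0, w))
  n_used <- colSums(observed)
  if (missing_policy == "mean_impute") {
    # imputed terms count as used unless the probe had no observation at all
    n_used <- colSums(!is.na(sub))
  }
  coverage <- n_used / length(clock$weights)
  m_age <- if (clock$transform == "horvath") {
    inverse_horvath(raw, clock$adult_age)
  } else {
    raw
  }
  m_age[coverage == 0] <- NA_real_
  tibble::tibble(sample_id = colnames(betas), m_age = unname(m_age),
                 coverage = unname(coverage))
}
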