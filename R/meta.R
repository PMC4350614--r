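#' Fixed-effect inverse-variance meta-analysis
#'
#' Pools per-cohort log hazard ratios (per 5 years of delta-age) assuming a
#' common effect: each study is weighted by the inverse of its squared
#' standard error, `w_i = 1/se_i^2`; the pooled estimate is
#' `sum(w_i * logHR_i) / sum(w_i)` with standard error `1/sqrt(sum(w_i))`.
#' With two or more studies the DerSimonian-Laird heterogeneity statistics
#' (Q, tau^2) are attached for reporting; they never re-weight the pooling.
#'
#' @param effects Data frame with `label`, `log_hr` (per-5-year log hazard
#'   ratio) and `se` (> 0) columns, one row per study.
#' @return Object of class `meta_result`: a list with `pooled_log_hr`,
#'   `pooled_se`, `hr`, `ci` (95%), `p` (Wald), `k`, a `studies` tibble
#'   carrying `weight_pct`, and (for k >= 2) `Q`, `tau2`, `df`, `p_q`.
#' @examples
#' fixed_effect_meta(data.frame(label = c("A", "B"),
#'                              log_hr = c(0.1, 0.3), se = 0.1))
#' @export
fixed_effect_meta <- function(effects) {
  effects <- validate_effects(effects, min_k = 1)
  w <- 1 / effects$se^2
  pooled <- sum(w * effects$log_hr) / sum(w)
  pooled_se <- 1 / sqrt(sum(w))
  het <- if (nrow(effects) >= 2) dl_heterogeneity(effects) else
    tibble::tibble(Q = NA_real_, tau2 = NA_real_, df = NA_integer_, p_q = NA_real_)
  structure(list(
    pooled_log_hr = pooled, pooled_se = pooled_se,
    hr = exp(pooled),
    ci = exp(pooled + c(-1, 1) * 1.96 * pooled_se),
    p = 2 * pnorm(-abs(pooled / pooled_se)),
    k = nrow(effects),
    Q = het$Q, tau2 = het$tau2, df = het$df, p_q = het$p_q,
    studies = dplyr::mutate(tibble::as_tibble(effects),
                            weight_pct = 100 * w / sum(w))),
    class = "meta_result")
}

#' DerSimonian-Laird heterogeneity
#'
#' Cochran's Q under fixed-effect weights and the DerSimonian-Laird moment
#' estimator of between-study variance:
#' `Q = sum(w_i * (logHR_i - pooled)^2)`, `df = k - 1`,
#' `tau2 = max(0, (Q - df) / C)` with `C = sum(w) - sum(w^2)/sum(w)`.
#'
#' @inheritParams fixed_effect_meta
#' @return One-row tibble: `Q`, `tau2`, `df`, `p_q` (chi-squared test of
#'   homogeneity).
#' @export
dl_heterogeneity <- function(effects) {
  effects <- validate_effects(effects, min_k = 2)
  w <- 1 / effects$se^2
  pooled <- sum(w * effects$log_hr) / sum(w)
  Q <- sum(w * (effects$log_hr - pooled)^2)
  df <- nrow(effects) - 1L
  C <- sum(w) - sum(w^2) / sum(w)
  tibble::tibble(Q = Q, tau2 = max(0, (Q - df) / C), df = df,
                 p_q = pchisq(Q, df, lower.tail = FALSE))
}

validate_effects <- function(effects, min_k) {
  stopifnot(is.data.frame(effects))
  if (!all(c("log_hr", "se") %in% names(effects))) {
    abort("`effects` needs `log_hr` and `se` columns.",
          class = "methage_format_error")
  }
  if (nrow(effects) < min_k) {
    abort(sprintf("Need at least %d studies.", min_k),
          class = "methage_validation_error")
  }
  if (any(effects$se <= 0)) {
    abort("Standard errors must be > 0.", class = "methage_validation_error")
  }
  if (!"label" %in% names(effects)) {
    effects$label <- paste0("study_", seq_len(nrow(effects)))
  }
  effects
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf(
    "<meta_result: %d studies>\n  pooled HR %.3f (95%% CI %.3f-%.3f), p = %.3g\n",
    x$k, x$hr, x$ci[1], x$ci[2], x$p))
  if (!is.na(x$Q)) {
    cat(sprintf("  heterogeneity: Q = %.3f (df %d, p = %.3g), tau2 = %.4f\n",
                x$Q, x$df, x$p_q, x$tau2))
  }
  invisible(x)
}

#' @export
tidy.meta_result <- function(x, ...) {
  dplyr::select(x$studies, "label", "log_hr", "se", "weight_pct")
}

#' @export
glance.meta_result <- function(x, ...) {
  tibble::tibble(k = x$k, pooled_log_hr = x$pooled_log_hr,
                 pooled_se = x$pooled_se, hr = x$hr,
                 ci_lower = x$ci[1], ci_upper = x$ci[2], p = x$p,
                 Q = x$Q, tau2 = x$tau2, df = x$df)
}

#' Forest-plot-ready table for a pooled analysis
#'
#' @param x A [fixed_effect_meta()] result.
#' @return Tibble with one row per study plus a pooled row: `label`, `hr`,
#'   `ci_lower`, `ci_upper`, `weight_pct`, `pooled` flag.
#' @export
forest_table <- function(x) {
  stopifnot(inherits(x, "meta_result"))
  studies <- x$studies |>
    dplyr::transmute(
      label = .data$label, hr = exp(.data$log_hr),
      ci_lower = exp(.data$log_hr - 1.96 * .data$se),
      ci_upper = exp(.data$log_hr + 1.96 * .data$se),
      weight_pct = .data$weight_pct, pooled = FALSE)
  dplyr::bind_rows(studies, tibble::tibble(
    label = "Pooled (fixed effect)", hr = x$hr,
    ci_lower = x$ci[1], ci_upper = x$ci[2],
    weight_pct = 100, pooled = TRUE))
}

#' @export
autoplot.meta_result <- function(object, ...) {
  tab <- forest_table(object)
  tab$label <- factor(tab$label, levels = rev(tab$label))
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$hr, y = .data$label)) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey60") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_lower, xmax = .data$ci_upper), height = 0.2) +
    ggplot2::geom_point(ggplot2::aes(size = .data$weight_pct,
                                     shape = .data$pooled)) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 15, `TRUE` = 18),
                                guide = "none") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Hazard ratio per 5 years of Δ-age", y = NULL,
                  size = "Weight (%)") +
    ggplot2::theme_minimal()
}
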