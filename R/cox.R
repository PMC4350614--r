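#' Fit a Cox proportional-hazards model for delta-age
#'
#' Associates delta-age (and any further covariates) with all-cause
#' mortality by maximum partial likelihood. The first covariate is taken to
#' be delta-age in years; its hazard ratio is re-expressed per 5 years of
#' methylation age acceleration with a Wald 95% confidence interval,
#' `hr5 = exp(5 * beta)`, `ci5 = exp(5 * (beta +/- 1.96 * se))`.
#'
#' @param data Data frame with `time` (years of follow-up, > 0), `event`
#'   (0 = censored, 1 = death) and the covariate columns.
#' @param covariates Character vector of covariate column names; the first
#'   must be the delta-age term.
#' @param ties Tie handling for the partial likelihood: `"efron"` (default)
#'   or `"breslow"`.
#' @return An object of class `cox_fit` with elements `beta`, `se` (named,
#'   per covariate), `loglik` (partial log-likelihood at the optimum and at
#'   zero), `n`, `n_events`, `hr5`, `ci5`, `p` (Wald, for the delta-age
#'   term) and the underlying [survival::coxph()] fit.
#' @examples
#' d <- data.frame(time = c(1, 2, 3), event = 1, x = c(1, 0, 1))
#' fit_cox(d, "x", ties = "breslow")$beta  # -log(2)/2
#' @export
fit_cox <- function(data, covariates = "delta", ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  stopifnot(all(c("time", "event") %in% names(data)),
            all(covariates %in% names(data)))
  if (any(data$time <= 0)) {
    abort("Follow-up times must be > 0.", class = "methage_validation_error")
  }
  if (!all(data$event %in% c(0, 1))) {
    abort("`event` must be 0/1.", class = "methage_validation_error")
  }
  if (sum(data$event) < 1) {
    abort("Need at least one event.", class = "methage_validation_error")
  }
  keep <- stats::complete.cases(data[c("time", "event", covariates)])
  data <- data[keep, , drop = FALSE]
  fml <- stats::reformulate(covariates, response = "survival::Surv(time, event)")
  fit <- tryCatch(
    survival::coxph(fml, data = data, ties = ties, model = TRUE),
    error = function(e) abort(conditionMessage(e), class = "methage_fit_error"))
  if (!is.null(fit$info) || anyNA(coef(fit))) {
    abort("Singular information matrix; covariates collinear.",
          class = "methage_fit_error")
  }
  beta <- coef(fit)
  se <- sqrt(diag(fit$var))
  names(se) <- names(beta)
  b1 <- beta[[1]]
  s1 <- se[[1]]
  new_cox_fit(list(
    beta = beta, se = se, loglik = fit$loglik,
    n = fit$n, n_events = fit$nevent,
    hr5 = exp(5 * b1),
    ci5 = exp(5 * (b1 + c(-1, 1) * 1.96 * s1)),
    p = 2 * pnorm(-abs(b1 / s1)),
    covariates = covariates, ties = ties, coxph = fit))
}

new_cox_fit <- function(x) structure(x, class = "cox_fit")

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf(
    "<cox_fit: n = %d, events = %d (%s ties)>\n  HR per 5 years of delta-age: %.3f (95%% CI %.3f-%.3f), p = %.3g\n",
    x$n, x$n_events, x$ties, x$hr5, x$ci5[1], x$ci5[2], x$p))
  invisible(x)
}

#' @export
tidy.cox_fit <- function(x, ...) {
  tibble::tibble(
    term = names(x$beta),
    estimate = unname(x$beta),
    std.error = unname(x$se),
    statistic = unname(x$beta / x$se),
    p.value = 2 * pnorm(-abs(unname(x$beta / x$se))))
}

#' @export
glance.cox_fit <- function(x, ...) {
  tibble::tibble(n = x$n, n_events = x$n_events,
                 logLik = x$loglik[length(x$loglik)],
                 hr5 = x$hr5, ci5_lower = x$ci5[1], ci5_upper = x$ci5[2],
                 p.value = x$p)
}

#' Hazard ratio per 5 years of delta-age
#'
#' @param fit A [fit_cox()] result.
#' @return One-row tibble: `hr5`, `ci5_lower`, `ci5_upper`, `p`.
#' @export
hr_per_5_years <- function(fit) {
  stopifnot(inherits(fit, "cox_fit"))
  tibble::tibble(hr5 = fit$hr5, ci5_lower = fit$ci5[1],
                 ci5_upper = fit$ci5[2], p = fit$p)
}

#' Proportional-hazards diagnostic from Schoenfeld residuals
#'
#' At each event time the Schoenfeld residual is the covariate value of the
#' subject who died minus the risk-set-weighted mean covariate under the
#' fitted model. Under proportional hazards the residuals show no trend in
#' time; the check reports, per covariate, the Pearson correlation of the
#' residuals with the rank of the event time and its t-test p-value.
#'
#' @param fit A [fit_cox()] result (fitted on at least 3 events).
#' @return Tibble with `term`, `cor`, `p`.
#' @export
schoenfeld_check <- function(fit) {
  stopifnot(inherits(fit, "cox_fit"))
  if (fit$n_events < 3) {
    abort("Need at least 3 events for the proportional-hazards check.",
          class = "methage_validation_error")
  }
  res <- stats::residuals(fit$coxph, type = "schoenfeld")
  res <- as.matrix(res)
  colnames(res) <- names(fit$beta)
  times <- as.numeric(rownames(res))
  rk <- rank(times)
  out <- purrr::map_dfr(colnames(res), function(term) {
    ct <- cor.test(res[, term], rk)
    tibble::tibble(term = term, cor = unname(ct$estimate), p = ct$p.value)
  })
  out
}

#' Exclude early deaths
#'
#' Sensitivity filter removing subjects who died within the first `window`
#' years of follow-up (to limit reverse causation from terminal illness at
#' blood draw); censored subjects are always retained, and deaths at
#' exactly `window` are retained (strict inequality).
#'
#' @param data Data frame with `time` and `event` columns.
#' @param window Years (default 2).
#' @return `data` without the early deaths.
#' @export
exclude_early_deaths <- function(data, window = 2) {
  stopifnot(window >= 0, all(c("time", "event") %in% names(data)))
  data[!(data$event == 1 & data$time < window), , drop = FALSE]
}

#' Kaplan-Meier curves by delta-age quartile
#'
#' Splits samples into quartiles of delta-age (linear-interpolation sample
#' quantiles; boundary ties go to the lower group) and computes the
#' product-limit survival estimate within each group. Descriptive only.
#'
#' @param delta Tibble with `sample_id`, `delta`.
#' @param records Data frame with `sample_id`, `time`, `event`.
#' @return A tibble of class `km_quartiles`: `quartile` (factor Q1-Q4),
#'   `time`, `n_risk`, `n_event`, `surv`; each group's curve starts at
#'   `time = 0`, `surv = 1`.
#' @export
km_by_quartile <- function(delta, records) {
  dat <- dplyr::inner_join(delta, records, by = "sample_id")
  if (nrow(dat) < 4) {
    abort("Need at least 4 samples for quartiles.",
          class = "methage_validation_error")
  }
  breaks <- quantile(dat$delta, probs = seq(0, 1, 0.25), type = 7)
  breaks[1] <- -Inf
  grp <- cut(dat$delta, breaks = breaks, labels = paste0("Q", 1:4),
             right = TRUE)
  sf <- survival::survfit(survival::Surv(time, event) ~ grp, data = dat)
  smry <- summary(sf, censored = FALSE)
  lab <- if (is.null(smry$strata)) {
    factor(rep("Q1", length(smry$time)), levels = paste0("Q", 1:4))
  } else {
    factor(sub("^grp=", "", as.character(smry$strata)), levels = paste0("Q", 1:4))
  }
  curves <- tibble::tibble(
    quartile = lab, time = smry$time,
    n_risk = smry$n.risk, n_event = smry$n.event, surv = smry$surv)
  origin <- dat |>
    dplyr::mutate(quartile = grp) |>
    dplyr::count(.data$quartile, name = "n_risk") |>
    dplyr::mutate(time = 0, n_event = 0L, surv = 1) |>
    dplyr::select("quartile", "time", "n_risk", "n_event", "surv")
  out <- dplyr::bind_rows(origin, curves) |>
    dplyr::arrange(.data$quartile, .data$time)
  class(out) <- c("km_quartiles", class(out))
  out
}

#' @export
autoplot.km_quartiles <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$time, y = .data$surv,
                               colour = .data$quartile)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Follow-up (years)", y = "Survival probability",
                  colour = "Δ-age quartile") +
    ggplot2::theme_minimal()
}
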