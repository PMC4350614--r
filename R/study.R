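#' Published reference summaries for the four mortality cohorts
#'
#' Printed summary statistics (one decimal place) for the Hannum and
#' Horvath clocks in the four cohorts the mortality meta-analysis was run
#' on — LBC1921, LBC1936, the Framingham Heart Study offspring sample and
#' the Normative Aging Study. Used for arithmetic consistency checks (mean
#' delta-age must equal mean methylation age minus mean chronological age,
#' to printed precision) and as the calibration point for the simulator's
#' default cohort sizes and age distributions.
#'
#' @return Tibble with `cohort`, `clock`, `n`, `n_deaths`, `mean_age`,
#'   `sd_age`, `mean_m_age`, `sd_m_age`, `mean_delta`, `sd_delta`,
#'   `median_error` (years throughout).
#' @export
reference_cohort_table <- function() {
  tibble::tribble(
    ~cohort,   ~clock,    ~n,   ~n_deaths, ~mean_age, ~sd_age, ~mean_m_age, ~sd_m_age, ~mean_delta, ~sd_delta, ~median_error,
    "LBC1921", "hannum",  446L, 292L,      79.1,      0.6,     85.0,        5.6,       5.9,         5.6,       5.5,
    "LBC1936", "hannum",  920L, 106L,      69.5,      0.8,     75.8,        5.0,       6.2,         5.1,       6.4,
    "FHS",     "hannum",  2635L, 238L,     66.3,      8.9,     68.2,        8.7,       1.9,         4.8,       1.9,
    "NAS",     "hannum",  657L, 226L,      72.9,      6.9,     77.6,        6.7,       4.6,         4.8,       4.6,
    "LBC1921", "horvath", 446L, 292L,      79.1,      0.6,     73.7,        6.2,       -5.4,        6.3,       6.0,
    "LBC1936", "horvath", 920L, 106L,      69.5,      0.8,     66.0,        5.8,       -3.6,        5.8,       4.7,
    "FHS",     "horvath", 2635L, 238L,     66.3,      8.9,     65.7,        8.3,       -0.6,        5.2,       0.69,
    "NAS",     "horvath", 657L, 226L,      72.9,      6.9,     73.5,        7.4,       0.6,         5.8,       3.4)
}

#' Run the full synthetic study end to end
#'
#' Orchestrates every stage on generator output: per cohort, simulate
#' phenotypes, clock-probe betas and survival; score the true clock; adjust
#' m_age for plate; form delta-age and the Table-1-style summary; fit the
#' basic Cox model (delta-age, chronological age, sex) plus the
#' early-death-exclusion and cell-count-adjusted sensitivity variants with
#' a proportional-hazards check; pool each model across cohorts by
#' fixed-effect meta-analysis; and, when the configuration includes
#' families, run the heritability block (within-generation
#' standardization, per-class ICCs, REML variance components).
#'
#' @param config A [sim_config()].
#' @param out Optional path; when given, the report is written there as
#'   JSON.
#' @return A `study_report` list: `cohorts` (per-cohort summary tibble),
#'   `fits` (per cohort and model: [fit_cox()] results), `meta` (per
#'   model: [fixed_effect_meta()] results), `heritability` (per-class ICC
#'   tibble and [fit_variance_components()] result, or `NULL`), and
#'   `provenance` (seed, configuration, package version).
#' @export
run_study <- function(config = sim_config(), out = NULL) {
  stopifnot(inherits(config, "sim_config"))
  cohorts <- list()
  fits <- list()
  for (i in seq_len(config$n_cohorts)) {
    label <- sprintf("cohort%d", i)
    sim <- simulate_cohort(config, i)
    bb <- simulate_betas(sim$true, config, plate = sim$pheno$plate, cohort = i)
    surv <- simulate_survival(sim$true$delta_true, config, cohort = i)
    m_age <- apply_clock(bb$betas, bb$clock)
    if (config$batch_levels > 1) {
      m_age <- adjust_technical(m_age, sim$pheno[c("sample_id", "plate")])
    }
    delta <- compute_delta_age(m_age, sim$pheno)
    cohorts[[label]] <- dplyr::bind_cols(
      tibble::tibble(cohort = label),
      cohort_summary(m_age, sim$pheno),
      tibble::tibble(n_events = sum(surv$event)))
    records <- dplyr::bind_cols(sim$pheno, surv) |>
      dplyr::left_join(delta, by = "sample_id") |>
      dplyr::mutate(sex_male = as.integer(.data$sex == "male"))
    covs <- c("delta", "chron_age",
              if (length(unique(records$sex_male)) > 1) "sex_male")
    basic <- fit_cox(records, covs)
    early <- fit_cox(exclude_early_deaths(records, 2), covs)
    m_cells <- adjust_cell_counts(
      m_age, sim$pheno[c("sample_id", "basophils", "eosinophils", "monocytes",
                         "lymphocytes", "neutrophils")])
    rec_cells <- records |>
      dplyr::select(-"delta") |>
      dplyr::left_join(compute_delta_age(m_cells, sim$pheno), by = "sample_id")
    cells <- fit_cox(rec_cells, covs)
    fits[[label]] <- list(basic = basic, early_exclusion = early,
                          cell_adjusted = cells,
                          ph_check = schoenfeld_check(basic))
  }
  metas <- lapply(
    setNames(nm = c("basic", "early_exclusion", "cell_adjusted")),
    function(model) {
      fixed_effect_meta(purrr::map_dfr(names(fits), function(label) {
        f <- fits[[label]][[model]]
        tibble::tibble(label = label,
                       log_hr = 5 * f$beta[["delta"]],
                       se = 5 * f$se[["delta"]])
      }))
    })
  heritability <- NULL
  if (config$n_mz + config$n_dz > 0) {
    pedsim <- simulate_pedigree(config)
    z <- standardize_within_generation(pedsim$delta, pedsim$ped)
    pairs <- enumerate_pairs(pedsim$ped)
    A <- build_relationship_matrix(pedsim$ped)
    heritability <- list(
      icc = icc_by_class(pairs, z),
      vc = fit_variance_components(z, A))
  }
  report <- structure(
    list(cohorts = dplyr::bind_rows(cohorts), fits = fits, meta = metas,
         heritability = heritability,
         provenance = list(seed = config$seed, config = unclass(config),
                           package = as.character(utils::packageVersion("methage")))),
    class = "study_report")
  if (!is.null(out)) {
    write_study_report(report, out)
  }
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report: %d cohorts%s>\n", nrow(x$cohorts),
              if (is.null(x$heritability)) "" else " + heritability block"))
  print(x$meta$basic)
  invisible(x)
}

#' Serialize a study report to JSON
#'
#' @param report A [run_study()] result.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_study_report <- function(report, path) {
  stopifnot(inherits(report, "study_report"))
  meta_json <- lapply(report$meta, function(m) {
    c(as.list(glance(m)), list(weights_pct = setNames(
      m$studies$weight_pct, m$studies$label)))
  })
  fits_json <- lapply(report$fits, function(fl) {
    lapply(fl[c("basic", "early_exclusion", "cell_adjusted")], function(f) {
      list(beta = as.list(f$beta), se = as.list(f$se),
           hr5 = f$hr5, ci5 = f$ci5, p = f$p, n = f$n, n_events = f$n_events)
    })
  })
  herit_json <- if (is.null(report$heritability)) NULL else list(
    icc = report$heritability$icc,
    vc = as.list(glance(report$heritability$vc)))
  jsonlite::write_json(
    list(schema = "methage-study-report/1",
         cohorts = report$cohorts, fits = fits_json, meta = meta_json,
         heritability = herit_json, provenance = report$provenance),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE, force = TRUE)
  invisible(path)
}
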