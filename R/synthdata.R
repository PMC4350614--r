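#' Simulation configuration
#'
#' Collects every knob of the synthetic-data generator, with defaults that
#' emulate the study design the pipeline targets: four older-adult cohorts
#' of sizes 446, 920, 2635 and 657 (two of them narrow birth cohorts with
#' age SDs below one year), a latent "biological age" that deviates from
#' chronological age by an additive genetic plus environmental component
#' with total SD 5 years and heritability 0.4, a true per-5-year mortality
#' hazard ratio of 1.21, and a twin-family panel of MZ- and DZ-twin
#' families with extra siblings and both parents.
#'
#' @param n_cohorts Number of cohorts.
#' @param n_per_cohort Integer vector of cohort sizes (recycled).
#' @param age_mean,age_sd Per-cohort chronological-age distribution in
#'   years (SD 0 emulates a single-birth-year cohort; recycled).
#' @param prop_male Per-cohort proportion of male participants (recycled).
#' @param sigma_delta SD (years) of the latent delta-age `g + u`.
#' @param h2 Heritability of latent delta-age: `var(g) = h2 * sigma_delta^2`.
#' @param n_probes Number of clock CpG probes simulated.
#' @param beta_noise_sd Per-probe technical noise SD on the beta scale; the
#'   induced noise on m_age has SD `200 * beta_noise_sd / sqrt(n_probes)`.
#' @param sign_vector Probe slope signs (+1/-1); default alternates,
#'   recycled to `n_probes`.
#' @param batch_levels Number of technical batch (plate) levels; 1 disables
#'   batch structure.
#' @param batch_offset Beta-scale offset applied (along each probe's slope
#'   sign) to samples on plates 2 and above.
#' @param log_hr_per_year True log hazard ratio per year of delta-age.
#' @param lambda0 Baseline exponential hazard (per year) at delta-age 0.
#' @param horizon Administrative censoring horizon, years.
#' @param n_mz,n_dz Numbers of families with an MZ / DZ twin pair.
#' @param n_extra_sib Number of families additionally given one non-twin
#'   sibling.
#' @param parent_age_mean,parent_age_sd,offspring_age_mean,offspring_age_sd
#'   Age distributions (years) of the two pedigree generations.
#' @param seed Master seed; every generator derives its stream from it by a
#'   fixed offset.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_cohorts = 4,
                       n_per_cohort = c(446, 920, 2635, 657),
                       age_mean = c(79.1, 69.5, 66.3, 72.9),
                       age_sd = c(0.6, 0.8, 8.9, 6.9),
                       prop_male = c(0.4, 0.51, 0.46, 1),
                       sigma_delta = 5,
                       h2 = 0.4,
                       n_probes = 64,
                       beta_noise_sd = 0.01,
                       sign_vector = NULL,
                       batch_levels = 2,
                       batch_offset = 0.01,
                       log_hr_per_year = log(1.21) / 5,
                       lambda0 = 0.07,
                       horizon = 12,
                       n_mz = 67, n_dz = 111, n_extra_sib = 119,
                       parent_age_mean = 47, parent_age_sd = 5,
                       offspring_age_mean = 14, offspring_age_sd = 3,
                       seed = 1) {
  cfg <- list(
    n_cohorts = n_cohorts,
    n_per_cohort = rep_len(n_per_cohort, n_cohorts),
    age_mean = rep_len(age_mean, n_cohorts),
    age_sd = rep_len(age_sd, n_cohorts),
    prop_male = rep_len(prop_male, n_cohorts),
    sigma_delta = sigma_delta, h2 = h2,
    n_probes = n_probes, beta_noise_sd = beta_noise_sd,
    sign_vector = rep_len(sign_vector %||% c(1, -1), n_probes),
    batch_levels = batch_levels, batch_offset = batch_offset,
    log_hr_per_year = log_hr_per_year, lambda0 = lambda0, horizon = horizon,
    n_mz = n_mz, n_dz = n_dz, n_extra_sib = n_extra_sib,
    parent_age_mean = parent_age_mean, parent_age_sd = parent_age_sd,
    offspring_age_mean = offspring_age_mean, offspring_age_sd = offspring_age_sd,
    seed = seed)
  if (cfg$sigma_delta < 0 || cfg$beta_noise_sd < 0 ||
      cfg$h2 < 0 || cfg$h2 > 1 || cfg$lambda0 <= 0 ||
      any(cfg$age_sd < 0) || any(cfg$n_per_cohort < 1) ||
      cfg$n_probes < 2 ||
      any(c(cfg$n_mz, cfg$n_dz, cfg$n_extra_sib) < 0)) {
    abort("Invalid simulation configuration.", class = "methage_validation_error")
  }
  structure(cfg, class = "sim_config")
}

# per-module fixed offsets on the master seed (one stream per generator)
seed_for <- function(config, module, index = 0) {
  offsets <- c(cohort = 100000, betas = 200000, survival = 300000,
               pedigree = 400000)
  (config$seed + offsets[[module]] + 97 * index) %% .Machine$integer.max
}

#' Simulate a cohort and its latent state
#'
#' Draws chronological ages, sex, a plate assignment, white blood cell
#' counts, and the latent additive-genetic (`g`) and environmental (`u`)
#' deviations whose sum is the true delta-age; biological age is
#' `chron_age + g + u` exactly. Deterministic given `(config, cohort)`.
#'
#' @param config A [sim_config()].
#' @param cohort Cohort index (1-based), selecting the per-cohort size/age
#'   parameters.
#' @return List with `pheno` (tibble: `sample_id`, `chron_age`, `sex`,
#'   `plate`, five cell-count columns) and `true` (tibble: `sample_id`,
#'   `g`, `u`, `b_age`, `delta_true`).
#' @export
simulate_cohort <- function(config, cohort = 1) {
  stopifnot(inherits(config, "sim_config"), cohort <= config$n_cohorts)
  n <- config$n_per_cohort[cohort]
  with_seed(seed_for(config, "cohort", cohort), {
    sample_id <- sprintf("c%d_s%04d", cohort, seq_len(n))
    chron_age <- rnorm(n, config$age_mean[cohort], config$age_sd[cohort])
    sex <- ifelse(runif(n) < config$prop_male[cohort], "male", "female")
    plate <- factor(sprintf("plate%d", 1 + (seq_len(n) - 1) %% config$batch_levels))
    g <- rnorm(n, 0, sqrt(config$h2) * config$sigma_delta)
    u <- rnorm(n, 0, sqrt(1 - config$h2) * config$sigma_delta)
    cells <- purrr::map(c(basophils = 0.05, eosinophils = 0.2, monocytes = 0.5,
                          lymphocytes = 2, neutrophils = 4),
                        function(mu) mu * exp(rnorm(n, 0, 0.3)))
    list(
      pheno = tibble::tibble(sample_id = sample_id, chron_age = chron_age,
                             sex = sex, plate = plate, !!!cells),
      true = tibble::tibble(sample_id = sample_id, g = g, u = u,
                            b_age = chron_age + g + u,
                            delta_true = g + u))
  })
}

#' Simulate clock-probe beta values and return the true clock
#'
#' Each probe's beta value is
#' `clamp_[0,1](0.5 + s_j * (b_age - 70)/200 + eps)` with
#' `eps ~ N(0, beta_noise_sd^2)`; the returned clock has weights
#' `(200/m) * s_j` and intercept `70 - (100/m) * sum(s_j)`, so scoring it
#' with [apply_clock()] recovers biological age up to noise of SD
#' `200 * beta_noise_sd / sqrt(m)` years. When a `plate` assignment is
#' given, samples on plates other than the first receive an additional
#' `batch_offset * s_j` shift per probe (a batch effect aligned with the
#' clock's slope direction, so it propagates into m_age).
#'
#' @param true_state The `true` tibble from [simulate_cohort()] (needs
#'   `sample_id`, `b_age`).
#' @param config A [sim_config()].
#' @param plate Optional factor of plate assignments per sample.
#' @param cohort Index used only to decorrelate the noise stream between
#'   cohorts.
#' @return List with `betas` (a [beta_matrix()]) and `clock` (the true
#'   [clock_definition()]).
#' @export
simulate_betas <- function(true_state, config, plate = NULL, cohort = 1) {
  stopifnot(inherits(config, "sim_config"))
  m <- config$n_probes
  s <- config$sign_vector
  n <- nrow(true_state)
  with_seed(seed_for(config, "betas", cohort), {
    eps <- matrix(rnorm(m * n, 0, config$beta_noise_sd), nrow = m)
    raw <- 0.5 + outer(s, true_state$b_age - 70) / 200 + eps
    if (!is.null(plate) && config$batch_offset != 0) {
      shifted <- as.integer(plate) > 1
      raw[, shifted] <- raw[, shifted] + config$batch_offset * s
    }
    clamped <- pmin(pmax(raw, 0), 1)
    frac_clamped <- mean(clamped != raw)
    if (frac_clamped > 0.05) {
      warn(sprintf("%.1f%% of beta values clamped to [0, 1]; noise SD likely too large.",
                   100 * frac_clamped))
    }
    dimnames(clamped) <- list(sprintf("cg%06d", seq_len(m)), true_state$sample_id)
    list(
      betas = beta_matrix(clamped),
      clock = clock_definition(
        name = "true_clock",
        intercept = 70 - (100 / m) * sum(s),
        weights = setNames((200 / m) * s, sprintf("cg%06d", seq_len(m)))))
  })
}

#' Simulate proportional-hazards survival times
#'
#' Death times are exponential with rate
#' `lambda0 * exp(log_hr_per_year * delta_true)`, so the model generating
#' the data is exactly the proportional-hazards model the analysis fits.
#' Censoring is the minimum of a uniform draw on `(0, 1.5 * horizon)` and
#' the administrative horizon.
#'
#' @param delta_true Numeric vector of true delta-age values (years).
#' @param config A [sim_config()].
#' @param cohort Index decorrelating the stream between cohorts.
#' @return Tibble with `time` (> 0, years) and `event` (0/1).
#' @export
simulate_survival <- function(delta_true, config, cohort = 1) {
  stopifnot(inherits(config, "sim_config"))
  n <- length(delta_true)
  with_seed(seed_for(config, "survival", cohort), {
    t_death <- rexp(n, rate = config$lambda0 * exp(config$log_hr_per_year * delta_true))
    censor <- pmin(runif(n, 0, 1.5 * config$horizon), config$horizon)
    tibble::tibble(time = pmin(t_death, censor),
                   event = as.integer(t_death <= censor))
  })
}

#' Simulate a twin-family pedigree with a heritable phenotype
#'
#' Builds two-generation families (`n_mz` with an MZ twin pair, `n_dz` with
#' a DZ pair, the first `n_extra_sib` families with one extra non-twin
#' sibling, all with both parents). Additive genetic values follow the
#' standard transmission model: parents draw independent
#' `g ~ N(0, sigma_g^2)`, each offspring receives the mid-parent value plus
#' an independent Mendelian-segregation deviation `N(0, sigma_g^2 / 2)`,
#' and MZ co-twins share a single draw. The phenotype is `g + u` with
#' `u ~ N(0, sigma_e^2)` iid, so MZ pairs have expected ICC `h2`, DZ/sib
#' pairs `h2/2`, and parent-offspring covariance `sigma_g^2 / 2`.
#'
#' @param config A [sim_config()].
#' @return List with `ped` (pedigree tibble, see [read_pedigree()]) and
#'   `delta` (tibble: `sample_id`, `delta`).
#' @export
simulate_pedigree <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n_fam <- config$n_mz + config$n_dz
  if (n_fam == 0) {
    abort("Need at least one family.", class = "methage_validation_error")
  }
  sg <- sqrt(config$h2) * config$sigma_delta
  se_ <- sqrt(1 - config$h2) * config$sigma_delta
  with_seed(seed_for(config, "pedigree"), {
    rows <- vector("list", n_fam)
    gvals <- numeric(0)
    for (f in seq_len(n_fam)) {
      fam_id <- sprintf("fam%03d", f)
      zyg <- if (f <= config$n_mz) "MZ" else "DZ"
      father <- paste0(fam_id, "_f")
      mother <- paste0(fam_id, "_m")
      g_f <- rnorm(1, 0, sg)
      g_m <- rnorm(1, 0, sg)
      mid <- (g_f + g_m) / 2
      kid_ids <- paste0(fam_id, c("_t1", "_t2"))
      twin_sex <- sample(c("male", "female"), 2, replace = zyg != "MZ")
      if (zyg == "MZ") {
        g_kids <- rep(mid + rnorm(1, 0, sg / sqrt(2)), 2)
        twin_sex <- rep(twin_sex[1], 2)
      } else {
        g_kids <- mid + rnorm(2, 0, sg / sqrt(2))
      }
      kid_sex <- twin_sex
      kid_zyg <- c(zyg, zyg)
      if (f <= config$n_extra_sib) {
        kid_ids <- c(kid_ids, paste0(fam_id, "_s1"))
        g_kids <- c(g_kids, mid + rnorm(1, 0, sg / sqrt(2)))
        kid_sex <- c(kid_sex, sample(c("male", "female"), 1))
        kid_zyg <- c(kid_zyg, "none")
      }
      kid_age <- rnorm(1, config$offspring_age_mean, config$offspring_age_sd)
      kid_ages <- c(kid_age, kid_age,
                    if (length(kid_ids) == 3)
                      rnorm(1, config$offspring_age_mean, config$offspring_age_sd))
      rows[[f]] <- tibble::tibble(
        family_id = fam_id,
        individual_id = c(father, mother, kid_ids),
        father_id = c("0", "0", rep(father, length(kid_ids))),
        mother_id = c("0", "0", rep(mother, length(kid_ids))),
        sex = c("male", "female", kid_sex),
        generation = c("parent", "parent", rep("offspring", length(kid_ids))),
        zygosity = c("none", "none", kid_zyg),
        age = c(rnorm(2, config$parent_age_mean, config$parent_age_sd), kid_ages))
      gvals <- c(gvals, g_f, g_m, g_kids)
    }
    ped <- dplyr::bind_rows(rows)
    u <- rnorm(nrow(ped), 0, se_)
    list(ped = validate_pedigree(ped),
         delta = tibble::tibble(sample_id = ped$individual_id,
                                delta = gvals + u))
  })
}

#' Write a complete synthetic fixture set to disk
#'
#' Materialises the generator's output as plain-text files: per-cohort beta
#' TSVs and phenotype CSVs (including survival columns), the true clock CSV
#' with its YAML sidecar, the pedigree TSV with its phenotype CSV, and a
#' manifest JSON recording the configuration, seed and per-file MD5
#' checksums. Re-running with the same configuration reproduces
#' byte-identical files.
#'
#' @param config A [sim_config()].
#' @param outdir Output directory.
#' @param force Overwrite a non-empty `outdir` (default `FALSE`).
#' @return The manifest, invisibly (list with `config`, `seed`, `files`).
#' @export
write_fixture_set <- function(config, outdir, force = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  if (dir.exists(outdir) && length(dir(outdir)) > 0 && !force) {
    abort(sprintf("Output directory '%s' is not empty; use force = TRUE.", outdir),
          class = "methage_validation_error")
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (i in seq_len(config$n_cohorts)) {
    sim <- simulate_cohort(config, i)
    bb <- simulate_betas(sim$true, config, plate = sim$pheno$plate, cohort = i)
    surv <- simulate_survival(sim$true$delta_true, config, cohort = i)
    pheno <- dplyr::bind_cols(sim$pheno, surv)
    beta_path <- file.path(outdir, sprintf("cohort%d_betas.tsv", i))
    pheno_path <- file.path(outdir, sprintf("cohort%d_phenotypes.csv", i))
    write_beta_matrix(bb$betas, beta_path)
    readr::write_csv(pheno, pheno_path)
    files <- c(files, beta_path, pheno_path)
    if (i == 1) {
      clock_path <- file.path(outdir, "true_clock.csv")
      write_clock(bb$clock, clock_path)
      files <- c(files, clock_path, file.path(outdir, "true_clock.yml"))
    }
  }
  if (config$n_mz + config$n_dz > 0) {
    pedsim <- simulate_pedigree(config)
    ped_path <- file.path(outdir, "pedigree.tsv")
    delta_path <- file.path(outdir, "pedigree_delta.csv")
    readr::write_tsv(pedsim$ped, ped_path)
    readr::write_csv(pedsim$delta, delta_path)
    files <- c(files, ped_path, delta_path)
  }
  manifest <- list(
    config = unclass(config), seed = config$seed,
    files = lapply(setNames(files, basename(files)),
                   function(f) list(path = basename(f),
                                    md5 = unname(tools::md5sum(f)))))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
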