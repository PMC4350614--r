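test_that("generators are pure functions of (config, seed)", {
  cfg <- sim_config(n_cohorts = 1, n_per_cohort = 50, n_mz = 5, n_dz = 5,
                    n_extra_sib = 3, seed = 77)
  expect_identical(simulate_cohort(cfg), simulate_cohort(cfg))
  s1 <- simulate_cohort(cfg)
  expect_identical(simulate_betas(s1$true, cfg), simulate_betas(s1$true, cfg))
  expect_identical(simulate_survival(s1$true$delta_true, cfg),
                   simulate_survival(s1$true$delta_true, cfg))
  expect_identical(simulate_pedigree(cfg), simulate_pedigree(cfg))
  # a different seed changes the draw
  cfg2 <- sim_config(n_cohorts = 1, n_per_cohort = 50, seed = 78)
  expect_false(identical(simulate_cohort(cfg2)$true$delta_true,
                         s1$true$delta_true))
})

test_that("cohort draws honour the configured moments", {
  # birth cohort: age SD zero
  cfg0 <- sim_config(n_cohorts = 1, n_per_cohort = 30, age_mean = 79,
                     age_sd = 0, seed = 4)
  expect_equal(var(simulate_cohort(cfg0)$pheno$chron_age), 0)

  cfg <- sim_config(n_cohorts = 1, n_per_cohort = 5000, sigma_delta = 5,
                    seed = 10)
  tr <- simulate_cohort(cfg)$true
  expect_lt(abs(var(tr$delta_true) / 25 - 1), 0.1)
  expect_equal(tr$b_age, tr$delta_true +
                 simulate_cohort(cfg)$pheno$chron_age, tolerance = 1e-12)
})

test_that("the true clock inverts the beta construction", {
  cfg <- sim_config(n_cohorts = 1, n_per_cohort = 100, beta_noise_sd = 0,
                    batch_offset = 0, seed = 21)
  sim <- simulate_cohort(cfg)
  bb <- simulate_betas(sim$true, cfg)
  m_age <- apply_clock(bb$betas, bb$clock)
  expect_lt(max(abs(m_age$m_age - sim$true$b_age)), 1e-8)

  # noise propagates as 200 * sd / sqrt(m) years
  cfgn <- sim_config(n_cohorts = 1, n_per_cohort = 2000, n_probes = 64,
                     beta_noise_sd = 0.2, batch_offset = 0, age_sd = 2,
                     age_mean = 70, seed = 22)
  simn <- simulate_cohort(cfgn)
  bbn <- simulate_betas(simn$true, cfgn)
  man <- apply_clock(bbn$betas, bbn$clock)
  expect_lt(abs(sd(man$m_age - simn$true$b_age) / 5 - 1), 0.15)
})

test_that("plate offsets propagate into m_age and are removed by adjustment", {
  cfg <- sim_config(n_cohorts = 1, n_per_cohort = 400, beta_noise_sd = 0.005,
                    batch_levels = 2, batch_offset = 0.02, seed = 33)
  sim <- simulate_cohort(cfg)
  bb <- simulate_betas(sim$true, cfg, plate = sim$pheno$plate)
  m_age <- apply_clock(bb$betas, bb$clock)
  err <- m_age$m_age - sim$true$b_age
  by_plate <- split(err, sim$pheno$plate)
  # offset 0.02 along the slope direction shifts m_age by ~4 years
  expect_gt(mean(by_plate$plate2) - mean(by_plate$plate1), 2)
  adj <- adjust_technical(m_age, sim$pheno[c("sample_id", "plate")])
  # adjustment equalizes the plate means of m_age exactly (OLS property)
  adj_means <- tapply(adj$m_age, sim$pheno$plate, mean)
  expect_lt(abs(diff(adj_means)), 1e-8)
  expect_equal(mean(adj$m_age), mean(m_age$m_age), tolerance = 1e-10)
})

test_that("survival generator is proportional-hazards with the configured effect", {
  # null: fitted beta near zero
  cfg0 <- sim_config(n_cohorts = 1, n_per_cohort = 2000, log_hr_per_year = 0,
                     seed = 40)
  sim0 <- simulate_cohort(cfg0)
  sv0 <- simulate_survival(sim0$true$delta_true, cfg0)
  d0 <- data.frame(sv0, delta = sim0$true$delta_true)
  expect_lt(abs(fit_cox(d0, "delta")$beta[["delta"]]), 0.01)

  # truth HR5 = 1.2 recovered within 0.05
  cfg <- sim_config(n_cohorts = 1, n_per_cohort = 4000,
                    log_hr_per_year = log(1.2) / 5, seed = 13)
  sim <- simulate_cohort(cfg)
  sv <- simulate_survival(sim$true$delta_true, cfg)
  d <- data.frame(sv, delta = sim$true$delta_true)
  expect_lt(abs(fit_cox(d, "delta")$hr5 - 1.2), 0.05)

  # a shorter horizon cannot increase the number of events
  events_at <- function(h) {
    cfg_h <- sim_config(n_cohorts = 1, n_per_cohort = 500, horizon = h,
                        seed = 50)
    sum(simulate_survival(rep(0, 500), cfg_h)$event)
  }
  ev <- vapply(c(2, 5, 10, 20), events_at, numeric(1))
  expect_true(all(diff(ev) >= 0))
  expect_true(all(sv$time > 0))
})

test_that("pedigree phenotype carries the configured genetic architecture", {
  # h2 = 1: MZ co-twins are phenotypically identical
  cfg1 <- sim_config(n_mz = 30, n_dz = 0, n_extra_sib = 0, h2 = 1, seed = 6)
  ps1 <- simulate_pedigree(cfg1)
  v <- setNames(ps1$delta$delta, ps1$delta$sample_id)
  tw <- ps1$ped[ps1$ped$zygosity == "MZ", ]
  for (fam in split(tw, tw$family_id)) {
    expect_equal(v[[fam$individual_id[1]]], v[[fam$individual_id[2]]])
  }

  # h2 = 0.4 at scale: MZ ICC ~ 0.4, DZ ICC ~ 0.2, parent-offspring cov ~
  # Vg/2 (averaged over a few 500-family draws so the Monte-Carlo error of
  # the check is well below the 0.05 tolerance)
  reps <- purrr::map_dfr(9:13, function(s) {
    cfg <- sim_config(n_mz = 250, n_dz = 250, n_extra_sib = 0, h2 = 0.4,
                      sigma_delta = 5, seed = s)
    ps <- simulate_pedigree(cfg)
    pairs <- enumerate_pairs(ps$ped)
    iccs <- icc_by_class(pairs, ps$delta)
    po <- pairs[pairs$class == "parent-offspring", ]
    vv <- setNames(ps$delta$delta, ps$delta$sample_id)
    tibble::tibble(mz = iccs$icc[iccs$class == "MZ"],
                   dz = iccs$icc[iccs$class == "DZ"],
                   po_cov = cov(vv[po$id1], vv[po$id2]))
  })
  expect_lt(abs(mean(reps$mz) - 0.4), 0.05)
  expect_lt(abs(mean(reps$dz) - 0.2), 0.05)
  expect_lt(abs(mean(reps$po_cov) - 0.4 * 25 / 2), 1.5)
})

test_that("fixture sets are complete, reproducible, and protected", {
  cfg <- sim_config(n_cohorts = 2, n_per_cohort = c(20, 25), n_mz = 4,
                    n_dz = 4, n_extra_sib = 2, seed = 14)
  dir1 <- withr::local_tempdir()
  man1 <- write_fixture_set(cfg, file.path(dir1, "fx"))
  files <- names(man1$files)
  expect_true(all(c("cohort1_betas.tsv", "cohort2_phenotypes.csv",
                    "true_clock.csv", "true_clock.yml", "pedigree.tsv",
                    "pedigree_delta.csv") %in% files))
  # identical checksums on re-generation
  man2 <- write_fixture_set(cfg, file.path(dir1, "fx2"))
  expect_identical(purrr::map_chr(man1$files, "md5"),
                   purrr::map_chr(man2$files, "md5"))
  # refuses to clobber without force
  expect_error(write_fixture_set(cfg, file.path(dir1, "fx")),
               class = "methage_validation_error")
  expect_no_error(write_fixture_set(cfg, file.path(dir1, "fx"), force = TRUE))

  # written fixtures read back through the package loaders
  betas <- read_beta_matrix(file.path(dir1, "fx", "cohort1_betas.tsv"))
  clock <- read_clock(file.path(dir1, "fx", "true_clock.csv"))
  expect_equal(ncol(betas), 20)
  expect_equal(length(clock$weights), cfg$n_probes)
  ped <- read_pedigree(file.path(dir1, "fx", "pedigree.tsv"))
  expect_equal(nrow(ped), nrow(simulate_pedigree(cfg)$ped))
})

test_that("default cohort sizes mirror the reference studies", {
  cfg <- sim_config()
  expect_equal(cfg$n_per_cohort, c(446, 920, 2635, 657))
  sizes <- vapply(1:4, function(i) nrow(simulate_cohort(cfg, i)$pheno),
                  numeric(1))
  expect_equal(sizes, c(446, 920, 2635, 657))
})
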