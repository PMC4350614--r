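test_that("within-generation standardization yields unit variance and removes trends", {
  cfg <- sim_config(n_mz = 20, n_dz = 20, n_extra_sib = 10, seed = 5)
  ps <- simulate_pedigree(cfg)
  z <- standardize_within_generation(ps$delta, ps$ped)
  gen <- ps$ped$generation[match(z$sample_id, ps$ped$individual_id)]
  for (g in c("parent", "offspring")) {
    expect_equal(var(z$z[gen == g]), 1, tolerance = 1e-10)
  }

  # location shifts within a generation are absorbed by the intercept
  shifted <- ps$delta
  shifted$delta[gen == "parent"] <- shifted$delta[gen == "parent"] + 10
  z2 <- standardize_within_generation(shifted, ps$ped)
  expect_equal(z2$z, z$z, tolerance = 1e-10)

  # a quadratic age trend in the offspring is removed
  quad <- ps$delta
  age <- ps$ped$age[match(quad$sample_id, ps$ped$individual_id)]
  off <- gen == "offspring"
  quad$delta[off] <- quad$delta[off] + 0.1 * (age[off] - 14)^2
  z3 <- standardize_within_generation(quad, ps$ped)
  expect_lt(abs(cor(z3$z[off], age[off]^2)), 1e-8)

  tiny <- nuclear_mz_family()  # 2 parents only
  expect_error(
    standardize_within_generation(
      tibble::tibble(sample_id = tiny$individual_id, delta = rnorm(4)), tiny),
    class = "methage_validation_error")
})

test_that("relative pairs are enumerated by class and kept disjoint", {
  fam <- nuclear_mz_family()
  pairs <- enumerate_pairs(fam)
  counts <- table(pairs$class)
  expect_equal(unname(counts[["MZ"]]), 1)
  expect_equal(unname(counts[["spouse"]]), 1)
  # 4 parent-offspring candidates collapse to 2 disjoint pairs
  expect_equal(unname(counts[["parent-offspring"]]), 2)
  expect_false("DZ" %in% pairs$class)
  expect_false("full-sib" %in% pairs$class)

  # three full sibs admit exactly one disjoint pair
  sibs <- tibble::tibble(
    family_id = "f2",
    individual_id = c("p1", "p2", "k1", "k2", "k3"),
    father_id = c("0", "0", "p1", "p1", "p1"),
    mother_id = c("0", "0", "p2", "p2", "p2"),
    sex = c("male", "female", "male", "male", "female"),
    generation = c("parent", "parent", rep("offspring", 3)),
    zygosity = "none",
    age = c(50, 48, 15, 13, 11))
  p2 <- enumerate_pairs(sibs)
  expect_equal(sum(p2$class == "full-sib"), 1)

  # disjointness within every class, across a larger pedigree
  big <- simulate_pedigree(sim_config(n_mz = 15, n_dz = 15, n_extra_sib = 15,
                                      seed = 8))$ped
  pb <- enumerate_pairs(big)
  for (cls in split(pb, pb$class)) {
    expect_false(anyDuplicated(c(cls$id1, cls$id2)) > 0)
  }
  # seeded selection is reproducible
  expect_identical(enumerate_pairs(big, seed = 2015),
                   enumerate_pairs(big, seed = 2015))

  # zygosity labels on non-siblings are invalid
  bad <- fam
  bad$zygosity[1] <- "MZ"
  expect_error(enumerate_pairs(bad), class = "methage_validation_error")
})

test_that("ICC matches the hand ANOVA and its invariants", {
  res <- icc(data.frame(v1 = c(1, 3), v2 = c(2, 5)))
  expect_equal(res$ms_between, 6.25)
  expect_equal(res$ms_within, 1.25)
  expect_equal(res$icc, 2 / 3, tolerance = 1e-12)

  # identical members within pairs: MS_W = 0, ICC = 1
  expect_equal(icc(data.frame(v1 = c(1, 4, 9), v2 = c(1, 4, 9)))$icc, 1)

  # affine transforms leave ICC unchanged
  withr::local_seed(13)
  m <- matrix(rnorm(40), ncol = 2)
  expect_equal(icc(3 * m + 7)$icc, icc(m)$icc, tolerance = 1e-10)

  expect_error(icc(data.frame(v1 = c(2, 2), v2 = c(2, 2))),
               class = "methage_validation_error")
  expect_error(icc(data.frame(v1 = 1, v2 = 2)),
               class = "methage_validation_error")
})

test_that("relationship matrix encodes expected genome sharing", {
  singles <- tibble::tibble(
    family_id = c("f1", "f2", "f3"),
    individual_id = c("a", "b", "c"),
    father_id = "0", mother_id = "0",
    sex = "male", generation = "parent", zygosity = "none", age = 50)
  expect_equal(unname(build_relationship_matrix(singles)), diag(3))

  A <- build_relationship_matrix(nuclear_mz_family())
  expect_equal(A["t1", "t2"], 1)          # MZ co-twins
  expect_equal(A["dad", "t1"], 0.5)       # parent-offspring
  expect_equal(A["dad", "mum"], 0)        # spouses

  # nuclear family with two ordinary children, tabulated by hand
  fam <- tibble::tibble(
    family_id = "f1",
    individual_id = c("p1", "p2", "k1", "k2"),
    father_id = c("0", "0", "p1", "p1"),
    mother_id = c("0", "0", "p2", "p2"),
    sex = c("male", "female", "male", "female"),
    generation = c("parent", "parent", "offspring", "offspring"),
    zygosity = "none", age = c(50, 48, 15, 13))
  expected <- matrix(c(1, 0, 0.5, 0.5,
                       0, 1, 0.5, 0.5,
                       0.5, 0.5, 1, 0.5,
                       0.5, 0.5, 0.5, 1), nrow = 4,
                     dimnames = list(fam$individual_id, fam$individual_id))
  expect_equal(build_relationship_matrix(fam), expected)

  # symmetric PSD on a generated pedigree
  big <- simulate_pedigree(sim_config(n_mz = 10, n_dz = 10, seed = 2))$ped
  Abig <- build_relationship_matrix(big)
  expect_equal(Abig, t(Abig))
  expect_gt(min(eigen(Abig, symmetric = TRUE, only.values = TRUE)$values), -1e-10)
})

test_that("REML variance components recover limits, nulls, and truth", {
  # identity A: not identifiable
  singles <- diag(4)
  dimnames(singles) <- list(letters[1:4], letters[1:4])
  expect_error(fit_variance_components(rnorm(4), singles),
               class = "methage_validation_error")

  # MZ-pair-only data, identical within pairs: h2 at the upper boundary
  k <- 40
  ped_mz <- tibble::tibble(
    family_id = rep(sprintf("f%d", 1:k), each = 2),
    individual_id = sprintf("i%d", 1:(2 * k)),
    father_id = rep(sprintf("fa%d", 1:k), each = 2),
    mother_id = rep(sprintf("mo%d", 1:k), each = 2),
    sex = "female", generation = "offspring", zygosity = "MZ",
    age = 14)
  A_mz <- build_relationship_matrix(ped_mz)
  y_mz <- rep(rnorm(k), each = 2)
  vc_mz <- fit_variance_components(y_mz, A_mz)
  expect_gt(vc_mz$h2, 0.97)

  # pure noise, large sample: h2 near zero
  cfg <- sim_config(n_mz = 200, n_dz = 300, n_extra_sib = 150, h2 = 0, seed = 5)
  ps0 <- simulate_pedigree(cfg)
  A0 <- build_relationship_matrix(ps0$ped)
  vc0 <- fit_variance_components(
    setNames(ps0$delta$delta, ps0$delta$sample_id), A0)
  expect_lt(vc0$h2, 0.05)

  # generative truth h2 = 0.5, 300 families
  cfg5 <- sim_config(n_mz = 113, n_dz = 187, n_extra_sib = 100, h2 = 0.5,
                     seed = 1)
  ps5 <- simulate_pedigree(cfg5)
  A5 <- build_relationship_matrix(ps5$ped)
  vc5 <- fit_variance_components(
    setNames(ps5$delta$delta, ps5$delta$sample_id), A5)
  expect_lt(abs(vc5$h2 - 0.5), 0.05)
  expect_equal(vc5$h2, vc5$Va / (vc5$Va + vc5$Ve), tolerance = 1e-10)

  # optimizer agrees with a dense grid scan of the profile REML
  eig5 <- eigen(A5, symmetric = TRUE)
  grid <- seq(0, 0.999, length.out = 2000)
  profile_ll <- function(h2) {
    lam <- h2 * pmax(eig5$values, 0) + (1 - h2)
    ty <- crossprod(eig5$vectors, setNames(ps5$delta$delta,
                                           ps5$delta$sample_id)[rownames(A5)])
    tx <- crossprod(eig5$vectors, rep(1, nrow(A5)))
    xvx <- sum(tx^2 / lam)
    mu <- sum(tx * ty / lam) / xvx
    s2 <- sum((ty - mu * tx)^2 / lam) / (nrow(A5) - 1)
    -0.5 * ((nrow(A5) - 1) * (log(2 * pi) + log(s2) + 1) +
              sum(log(lam)) + log(xvx))
  }
  lls <- vapply(grid, profile_ll, numeric(1))
  expect_lt(abs(vc5$h2 - grid[which.max(lls)]), 1e-3)
})
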