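#' Read a pedigree table
#'
#' FAM-like TSV with header columns `family_id`, `individual_id`,
#' `father_id`, `mother_id`, `sex` (`male`/`female`), `generation`
#' (`parent`/`offspring`), `zygosity` (`MZ`/`DZ`/`none`) and `age` (years);
#' `0` encodes a missing parent.
#'
#' @param path Path to the TSV file.
#' @return A pedigree tibble with those columns (parent IDs as character,
#'   `"0"` for missing).
#' @export
read_pedigree <- function(path) {
  ped <- readr::read_tsv(path, col_types = readr::cols(
    family_id = readr::col_character(),
    individual_id = readr::col_character(),
    father_id = readr::col_character(),
    mother_id = readr::col_character(),
    sex = readr::col_character(),
    generation = readr::col_character(),
    zygosity = readr::col_character(),
    age = readr::col_double()))
  validate_pedigree(ped)
}

validate_pedigree <- function(ped) {
  needed <- c("family_id", "individual_id", "father_id", "mother_id",
              "sex", "generation", "zygosity", "age")
  if (!all(needed %in% names(ped))) {
    abort(paste0("Pedigree must have columns: ", paste(needed, collapse = ", ")),
          class = "methage_format_error")
  }
  if (anyDuplicated(ped$individual_id)) {
    abort("Duplicate individual IDs in pedigree.", class = "methage_format_error")
  }
  if (!all(ped$generation %in% c("parent", "offspring"))) {
    abort("`generation` must be 'parent' or 'offspring'.",
          class = "methage_validation_error")
  }
  if (!all(ped$zygosity %in% c("MZ", "DZ", "none"))) {
    abort("`zygosity` must be 'MZ', 'DZ' or 'none'.",
          class = "methage_validation_error")
  }
  # twin labels must mark exactly two full siblings within a family
  for (fam in split(ped, ped$family_id)) {
    for (z in c("MZ", "DZ")) {
      tw <- fam[fam$zygosity == z, ]
      if (nrow(tw) == 0) next
      if (nrow(tw) != 2 ||
          length(unique(tw$father_id)) != 1 ||
          length(unique(tw$mother_id)) != 1 ||
          any(tw$father_id == "0")) {
        abort(sprintf(
          "Zygosity label %s in family %s does not mark a full-sibling twin pair.",
          z, fam$family_id[1]), class = "methage_validation_error")
      }
    }
  }
  tibble::as_tibble(ped)
}

#' Standardize a phenotype within generations
#'
#' Clock predictions track chronological age differently in adults and
#' adolescents, so before pooling a family phenotype across generations it
#' is residualized separately within parents and offspring: each
#' generation's values are regressed on age and sex (offspring additionally
#' on age squared, for the non-linear adolescent age trend) and the
#' residuals are scaled to unit variance before the generations are
#' recombined.
#'
#' @param delta Tibble with `sample_id` and a phenotype column `delta`.
#' @param ped Pedigree tibble (see [read_pedigree()]); `sample_id` is
#'   matched against `individual_id`.
#' @return Tibble with `sample_id` and `z`, the standardized phenotype.
#' @export
standardize_within_generation <- function(delta, ped) {
  ped <- validate_pedigree(ped)
  dat <- dplyr::inner_join(
    delta, ped, by = c(sample_id = "individual_id"))
  if (!all(c("parent", "offspring") %in% dat$generation)) {
    abort("Both generations must be represented.",
          class = "methage_validation_error")
  }
  pieces <- lapply(split(dat, dat$generation), function(g) {
    if (nrow(g) < 4) {
      abort(sprintf("Generation '%s' has fewer than 4 members.",
                    g$generation[1]), class = "methage_validation_error")
    }
    terms <- "age"
    if (g$generation[1] == "offspring") terms <- c(terms, "I(age^2)")
    if (length(unique(g$sex)) > 1) terms <- c(terms, "sex")
    fit <- lm(stats::reformulate(terms, response = "delta"), data = g)
    r <- resid(fit)
    tibble::tibble(sample_id = g$sample_id, z = r / sd(r))
  })
  out <- dplyr::bind_rows(pieces)
  out[match(dat$sample_id, out$sample_id), ]
}

#' Enumerate pseudo-independent relative pairs
#'
#' Builds pair lists per relationship class — MZ twins (expected additive
#' relatedness 1), DZ twins, full siblings, parent-offspring (all 0.5) and
#' spouses (0) — from a pedigree. Within each class, overlapping candidate
#' pairs are reduced to a disjoint ("pseudo-independent") set, in which no
#' individual appears twice, by a seeded random greedy selection.
#'
#' @param ped Pedigree tibble.
#' @param seed Seed for the disjoint-pair selection (default 2015).
#' @return Tibble with `class`, `id1`, `id2`, `relatedness`.
#' @export
enumerate_pairs <- function(ped, seed = 2015) {
  ped <- validate_pedigree(ped)
  candidates <- list(MZ = list(), DZ = list(), `full-sib` = list(),
                     `parent-offspring` = list(), spouse = list())
  for (fam in split(ped, ped$family_id)) {
    kids <- fam[fam$generation == "offspring", ]
    for (z in c("MZ", "DZ")) {
      tw <- kids[kids$zygosity == z, ]
      if (nrow(tw) == 2) {
        candidates[[z]] <- c(candidates[[z]], list(tw$individual_id))
      }
    }
    # full sibs: same two parents, not an intact twin pair
    if (nrow(kids) >= 2) {
      for (i in seq_len(nrow(kids) - 1)) {
        for (j in seq(i + 1, nrow(kids))) {
          same_parents <- kids$father_id[i] == kids$father_id[j] &&
            kids$mother_id[i] == kids$mother_id[j] && kids$father_id[i] != "0"
          both_twins <- kids$zygosity[i] != "none" &&
            kids$zygosity[i] == kids$zygosity[j]
          if (same_parents && !both_twins) {
            candidates$`full-sib` <- c(candidates$`full-sib`,
                                       list(c(kids$individual_id[i],
                                              kids$individual_id[j])))
          }
        }
      }
    }
    ids <- fam$individual_id
    for (i in seq_len(nrow(kids))) {
      for (p in c(kids$father_id[i], kids$mother_id[i])) {
        if (p != "0" && p %in% ids) {
          candidates$`parent-offspring` <- c(
            candidates$`parent-offspring`, list(c(p, kids$individual_id[i])))
        }
      }
    }
    couples <- unique(kids[kids$father_id != "0" & kids$mother_id != "0",
                           c("father_id", "mother_id")])
    for (i in seq_len(nrow(couples))) {
      if (all(unlist(couples[i, ]) %in% ids)) {
        candidates$spouse <- c(candidates$spouse, list(unlist(couples[i, ])))
      }
    }
  }
  rel <- c(MZ = 1, DZ = 0.5, `full-sib` = 0.5, `parent-offspring` = 0.5,
           spouse = 0)
  with_seed(seed, {
    purrr::map_dfr(names(candidates), function(cls) {
      pairs <- candidates[[cls]]
      if (length(pairs) == 0) return(NULL)
      pairs <- pairs[sample.int(length(pairs))]
      used <- character(0)
      keep <- list()
      for (p in pairs) {
        if (!any(p %in% used)) {
          keep <- c(keep, list(p))
          used <- c(used, p)
        }
      }
      tibble::tibble(class = cls,
                     id1 = vapply(keep, `[`, "", 1),
                     id2 = vapply(keep, `[`, "", 2),
                     relatedness = rel[[cls]])
    })
  })
}

#' Intraclass correlation over relative pairs
#'
#' One-way ANOVA over pair groupings of size two:
#' `ICC = (MS_B - MS_W) / (MS_B + MS_W)` where `MS_B` is the mean square
#' between pairs and `MS_W` the mean square within. The 95% CI uses the
#' Fisher z transform with the number of pseudo-independent pairs.
#'
#' @param pairs Data frame (or 2-column matrix) whose first two numeric
#'   columns hold the two members' phenotype values, one row per pair.
#' @return One-row tibble: `icc`, `ms_between`, `ms_within`, `n_pairs`,
#'   `ci_lower`, `ci_upper`.
#' @examples
#' icc(data.frame(v1 = c(1, 3), v2 = c(2, 5)))  # ICC = 2/3
#' @export
icc <- function(pairs) {
  m <- as.matrix(as.data.frame(pairs)[, 1:2])
  storage.mode(m) <- "double"
  m <- m[stats::complete.cases(m), , drop = FALSE]
  k <- nrow(m)
  if (k < 2) {
    abort("Need at least 2 pairs.", class = "methage_validation_error")
  }
  grand <- mean(m)
  pair_means <- rowMeans(m)
  ms_b <- sum(2 * (pair_means - grand)^2) / (k - 1)
  ms_w <- sum((m - pair_means)^2) / k
  if (ms_b + ms_w == 0) {
    abort("All values identical; ICC undefined.",
          class = "methage_validation_error")
  }
  val <- (ms_b - ms_w) / (ms_b + ms_w)
  ci <- c(NA_real_, NA_real_)
  if (k > 3 && abs(val) < 1) {
    z <- atanh(val)
    half <- 1.96 / sqrt(k - 3)
    ci <- tanh(z + c(-1, 1) * half)
  }
  tibble::tibble(icc = val, ms_between = ms_b, ms_within = ms_w,
                 n_pairs = k, ci_lower = ci[1], ci_upper = ci[2])
}

#' Per-class intraclass correlations
#'
#' Convenience wrapper joining an [enumerate_pairs()] table with a
#' phenotype vector and computing [icc()] per relationship class.
#'
#' @param pairs Tibble from [enumerate_pairs()].
#' @param values Tibble with `sample_id` and a numeric phenotype column
#'   (the first non-ID column is used).
#' @return Tibble with one row per class: `class`, `relatedness`, and the
#'   [icc()] columns.
#' @export
icc_by_class <- function(pairs, values) {
  vcol <- setdiff(names(values), "sample_id")[1]
  v <- setNames(values[[vcol]], values$sample_id)
  pairs |>
    dplyr::group_by(.data$class, .data$relatedness) |>
    dplyr::group_modify(function(g, key) {
      icc(data.frame(v1 = unname(v[g$id1]), v2 = unname(v[g$id2])))
    }) |>
    dplyr::ungroup()
}

#' Expected additive relationship matrix from a pedigree
#'
#' Pairwise expected genome sharing: 1 on the diagonal and between MZ
#' co-twins, 0.5 between parent and offspring and between (DZ or ordinary)
#' full siblings, 0 between spouses and across families (founders assumed
#' unrelated and non-inbred).
#'
#' @param ped Pedigree tibble.
#' @return Symmetric numeric matrix with individual IDs as dimnames.
#' @export
build_relationship_matrix <- function(ped) {
  ped <- validate_pedigree(ped)
  n <- nrow(ped)
  A <- diag(1, n)
  dimnames(A) <- list(ped$individual_id, ped$individual_id)
  idx <- setNames(seq_len(n), ped$individual_id)
  for (fam in split(ped, ped$family_id)) {
    m <- nrow(fam)
    if (m < 2) next
    for (i in seq_len(m - 1)) {
      for (j in seq(i + 1, m)) {
        a <- fam[i, ]
        b <- fam[j, ]
        r <- 0
        parent_child <- a$individual_id %in% c(b$father_id, b$mother_id) ||
          b$individual_id %in% c(a$father_id, a$mother_id)
        full_sibs <- a$father_id != "0" && a$father_id == b$father_id &&
          a$mother_id == b$mother_id
        mz <- full_sibs && a$zygosity == "MZ" && b$zygosity == "MZ"
        if (mz) r <- 1 else if (parent_child || full_sibs) r <- 0.5
        A[idx[[a$individual_id]], idx[[b$individual_id]]] <- r
        A[idx[[b$individual_id]], idx[[a$individual_id]]] <- r
      }
    }
  }
  A
}

#' Pedigree variance components by REML
#'
#' Fits the additive genetic model `y = mu + Z a + e` with
#' `y ~ N(mu 1, Va * A + Ve * I)`, where `A` is the expected relationship
#' matrix, by restricted maximum likelihood. The REML criterion is profiled
#' over the heritability `h2 = Va / (Va + Ve)` on `[0, 0.999]` using a
#' single eigendecomposition of `A` (reusable across fits on the same
#' pedigree via `eig`); the total variance and mean are profiled out in
#' closed form. The standard error of `h2` comes from the numeric curvature
#' of the profile restricted log-likelihood; both a boundary-corrected
#' likelihood-ratio p-value (against `h2 = 0`, 50:50 chi-square mixture)
#' and a Wald p-value are reported, since they can differ appreciably.
#'
#' @param y Numeric phenotype vector aligned with the rows of `A` (or a
#'   tibble with `sample_id`/`z` columns matched against `rownames(A)`).
#' @param A Relationship matrix from [build_relationship_matrix()].
#' @param eig Optional precomputed `eigen(A, symmetric = TRUE)`.
#' @return Object of class `variance_components`: `Va`, `Ve`, `h2`,
#'   `se_h2`, `loglik` (profile REML at the optimum), `p_lrt`, `p_wald`,
#'   `n`.
#' @export
fit_variance_components <- function(y, A, eig = NULL) {
  if (is.data.frame(y)) {
    vcol <- setdiff(names(y), "sample_id")[1]
    y <- setNames(y[[vcol]], y$sample_id)[rownames(A)]
  }
  y <- as.numeric(y)
  n <- length(y)
  stopifnot(n == nrow(A), n == ncol(A), !anyNA(y))
  if (all(A[upper.tri(A)] == 0)) {
    abort("A is the identity: Va and Ve are not identifiable.",
          class = "methage_validation_error")
  }
  if (is.null(eig)) eig <- eigen(A, symmetric = TRUE)
  if (min(eig$values) < -1e-8) {
    abort("A is not positive semi-definite.", class = "methage_validation_error")
  }
  d <- pmax(eig$values, 0)
  ty <- as.vector(crossprod(eig$vectors, y))
  tx <- as.vector(crossprod(eig$vectors, rep(1, n)))
  reml <- function(h2) {
    lam <- h2 * d + (1 - h2)
    xvx <- sum(tx^2 / lam)
    mu <- sum(tx * ty / lam) / xvx
    rss <- sum((ty - mu * tx)^2 / lam)
    s2 <- rss / (n - 1)
    ll <- -0.5 * ((n - 1) * (log(2 * pi) + log(s2) + 1) +
                    sum(log(lam)) + log(xvx))
    list(ll = ll, s2 = s2)
  }
  ll_fun <- function(h2) reml(h2)$ll
  opt <- optimize(ll_fun, c(0, 0.999), maximum = TRUE, tol = 1e-7)
  # the optimum can sit at either boundary; compare explicitly
  cand <- c(opt$maximum, 0, 0.999)
  lls <- vapply(cand, ll_fun, numeric(1))
  h2 <- cand[which.max(lls)]
  at <- reml(h2)
  s2 <- at$s2
  h <- 1e-3
  lo <- max(h2 - h, 0)
  hi <- min(h2 + h, 0.999)
  curv <- (ll_fun(lo) - 2 * at$ll + ll_fun(hi)) / ((hi - lo) / 2)^2
  se_h2 <- if (is.finite(curv) && curv < 0) sqrt(-1 / curv) else NA_real_
  lrt <- max(0, 2 * (at$ll - ll_fun(0)))
  p_lrt <- if (h2 == 0) 1 else 0.5 * pchisq(lrt, df = 1, lower.tail = FALSE)
  p_wald <- if (is.na(se_h2)) NA_real_ else 2 * pnorm(-abs(h2 / se_h2))
  structure(list(Va = h2 * s2, Ve = (1 - h2) * s2, h2 = h2, se_h2 = se_h2,
                 loglik = at$ll, p_lrt = p_lrt, p_wald = p_wald, n = n),
            class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf(
    "<variance_components: n = %d>\n  h2 = %.3f (SE %.3f), Va = %.3f, Ve = %.3f\n  p (LRT) = %.3g, p (Wald) = %.3g\n",
    x$n, x$h2, x$se_h2, x$Va, x$Ve, x$p_lrt, x$p_wald))
  invisible(x)
}

#' @export
tidy.variance_components <- function(x, ...) {
  tibble::tibble(term = c("Va", "Ve", "h2"),
                 estimate = c(x$Va, x$Ve, x$h2),
                 std.error = c(NA_real_, NA_real_, x$se_h2))
}

#' @export
glance.variance_components <- function(x, ...) {
  tibble::tibble(n = x$n, h2 = x$h2, se_h2 = x$se_h2, Va = x$Va, Ve = x$Ve,
                 logLik = x$loglik, p_lrt = x$p_lrt, p_wald = x$p_wald)
}
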