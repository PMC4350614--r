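# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Breslow partial log-likelihood for a single covariate, computed directly
# from its definition (used to grid-search the Cox MLE).
breslow_loglik <- function(beta, x, time, event) {
  ll <- 0
  for (t in sort(unique(time[event == 1]))) {
    dead <- which(time == t & event == 1)
    risk <- which(time >= t)
    ll <- ll + sum(beta * x[dead]) -
      length(dead) * log(sum(exp(beta * x[risk])))
  }
  ll
}

grid_search_cox <- function(x, time, event, lo = -3, hi = 3, n = 200001) {
  grid <- seq(lo, hi, length.out = n)
  ll <- vapply(grid, breslow_loglik, numeric(1), x = x, time = time, event = event)
  grid[which.max(ll)]
}

# Normal-equations least squares (explicit (X'X)^-1 X'y) for adjustment oracles
normal_equations_residuals <- function(X, y) {
  b <- solve(t(X) %*% X, t(X) %*% y)
  as.vector(y - X %*% b)
}

# toy beta matrix with known values
toy_betas <- function() {
  beta_matrix(matrix(c(0.5, 0.3, 0.1, 0.9), nrow = 2,
                     dimnames = list(c("p1", "p2"), c("s1", "s2"))))
}

random_beta_matrix <- function(n_probes, n_samples, seed) {
  withr::with_seed(seed, {
    m <- matrix(runif(n_probes * n_samples), nrow = n_probes,
                dimnames = list(sprintf("cg%03d", seq_len(n_probes)),
                                sprintf("s%03d", seq_len(n_samples))))
    beta_matrix(m)
  })
}

# minimal nuclear family: two parents, one MZ twin pair
nuclear_mz_family <- function() {
  tibble::tibble(
    family_id = "f1",
    individual_id = c("dad", "mum", "t1", "t2"),
    father_id = c("0", "0", "dad", "dad"),
    mother_id = c("0", "0", "mum", "mum"),
    sex = c("male", "female", "female", "female"),
    generation = c("parent", "parent", "offspring", "offspring"),
    zygosity = c("none", "none", "MZ", "MZ"),
    age = c(47, 45, 14, 14))
}
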