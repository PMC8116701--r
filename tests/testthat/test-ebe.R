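# MAP objective and empirical Bayes estimation.

test_that("MAP objective reduces correctly in analytic special cases", {
  pop <- pop_model()
  cov <- dog_covariates(0, 0.98)
  tt <- c(30, 90, 180)
  f_typ <- two_cpt_concentration(individual_from_effects(pop, cov), 64.7, tt)
  # eta = 0 with y equal to the typical curve: only the log-variance terms
  val <- map_objective(c(0, 0, 0), f_typ, tt, pop, cov, 64.7)
  expect_equal(val, sum(log((pop$sigma_prop * f_typ)^2)), tolerance = 1e-12)
  # flat-prior limit: huge omegas leave weighted least squares + log terms
  pop_flat <- pop_model(omega_cl = 1e6, omega_v1 = 1e6, omega_v2 = 1e6)
  y <- f_typ * c(1.05, 0.95, 1.02)
  eta <- c(0.1, -0.05, 0.2)
  v_flat <- map_objective(eta, y, tt, pop_flat, cov, 64.7)
  phi <- individual_from_effects(pop_flat, cov, eta)
  f <- two_cpt_concentration(phi, 64.7, tt)
  g2 <- (pop_flat$sigma_prop * f)^2
  expect_equal(v_flat, sum((y - f)^2 / g2 + log(g2)), tolerance = 1e-6)
})

test_that("MAP objective matches an independent transcription to 1e-12", {
  set.seed(99)
  for (i in 1:25) {
    pop <- pop_model(theta_cl = runif(1, 0.001, 0.004),
                     omega_cl = runif(1, 0.1, 0.4),
                     sigma_prop = runif(1, 0.03, 0.12))
    cov <- dog_covariates(rbinom(1, 1, 0.5), runif(1, 0.7, 4))
    m <- sample(1:3, 1)
    tt <- sort(sample(seq(30, 180, 30), m))
    eta <- rnorm(3, 0, 0.3)
    phi <- individual_from_effects(pop, cov, eta)
    y <- two_cpt_concentration(phi, 64.7, tt) * runif(m, 0.9, 1.1)
    expect_equal(map_objective(eta, y, tt, pop, cov, 64.7),
                 oracle_map_objective(eta, y, tt, pop, cov, 64.7),
                 tolerance = 1e-12)
  }
})

test_that("estimator attains the dense-grid global minimum on random cases", {
  set.seed(12)
  pop <- pop_model()
  g <- seq(-1, 1, by = 0.05)
  grid <- as.matrix(expand.grid(g, g, g))
  for (i in 1:8) {
    cov <- dog_covariates(rbinom(1, 1, 0.5), runif(1, 0.8, 2.5))
    m <- sample(1:3, 1)
    tt <- sort(sample(seq(30, 180, 30), m))
    eta_true <- c(rnorm(1, 0, 0.208), rnorm(1, 0, 0.248), rnorm(1, 0, 0.199))
    phi <- individual_from_effects(pop, cov, eta_true)
    y <- two_cpt_concentration(phi, 64.7, tt) *
      (1 + 0.0617 * rnorm(m))
    fit <- estimate_ebe(y, tt, pop, cov, 64.7)
    grid_min <- min(oracle_objective_grid(grid, y, tt, pop, cov, 64.7))
    expect_lte(fit$objective_value, grid_min + 1e-8)
  }
})

test_that("estimation error vanishes as the residual noise shrinks", {
  # noise-free data generated at the typical subject: the MAP optimum
  # approaches eta = 0 as the proportional error coefficient b -> 0
  # (at finite b the log-variance term displaces the optimum by O(b^2))
  cov <- dog_covariates(0, 0.98)
  tt <- c(30, 60, 90)
  devs <- vapply(c(0.0617, 0.01, 1e-4), function(b) {
    pop_b <- pop_model(sigma_prop = b)
    y <- two_cpt_concentration(individual_from_effects(pop_b, cov), 64.7, tt)
    fit <- estimate_ebe(y, tt, pop_b, cov, 64.7)
    expect_true(fit$converged)
    max(abs(fit$eta_hat))
  }, numeric(1))
  expect_true(all(diff(devs) < 0))
  expect_lt(devs[3], 1e-6)
})

test_that("estimate is invariant to observation order and flags solver state", {
  set.seed(3)
  pop <- pop_model()
  cov <- dog_covariates(1, 1.7)
  tt <- c(30, 90, 180)
  y <- two_cpt_concentration(individual_from_effects(pop, cov,
                                                     c(0.2, -0.1, 0.1)),
                             64.7, tt) * (1 + 0.0617 * rnorm(3))
  f1 <- estimate_ebe(y, tt, pop, cov, 64.7)
  f2 <- estimate_ebe(rev(y), rev(tt), pop, cov, 64.7)
  expect_equal(f1$eta_hat, f2$eta_hat, tolerance = 1e-10)
  expect_true(f1$converged)
  expect_gt(f1$gfr_hat, 0)
  expect_equal(f1$gfr_ml_min_kg, 1000 * f1$gfr_hat)
  # descent relative to the origin start
  expect_lte(f1$objective_value,
             map_objective(c(0, 0, 0), y, tt, pop, cov, 64.7) + 1e-12)
})

test_that("single-sample designs are regularized by the prior, not special-cased", {
  set.seed(8)
  pop <- pop_model()
  cov <- dog_covariates(0, 0.98)
  y <- two_cpt_concentration(individual_from_effects(pop, cov,
                                                     c(0.3, 0, 0)),
                             64.7, 120) * 1.03
  fit <- estimate_ebe(y, 120, pop, cov, 64.7)
  expect_true(fit$converged)
  # shrinkage toward the prior mean: estimate between 0 and the value a
  # pure curve-inversion would give
  expect_gt(fit$eta_hat[["eta_cl"]], 0)
  expect_lt(fit$eta_hat[["eta_cl"]], 0.3)
})

test_that("mean estimation error grows with the residual noise level", {
  pop_at <- function(b) pop_model(sigma_prop = b)
  cov <- dog_covariates(0, 0.98)
  tt <- c(60, 120, 180)
  err <- vapply(c(0.01, 0.0617, 0.2), function(b) {
    pop <- pop_at(b)
    cfg <- simulation_config(times = tt, n_replicates = 80, seed = 31)
    sim <- simulate_profiles(pop, cov, cfg)
    e <- vapply(1:80, function(i) {
      fit <- estimate_ebe(sim$conc[i, ], tt, pop, cov, 64.7)
      abs(fit$eta_hat[["eta_cl"]] - sim$eta[i, 1])
    }, numeric(1))
    mean(e)
  }, numeric(1))
  expect_true(all(diff(err) > 0))
})

test_that("dense sampling with small noise recovers the generating effects", {
  set.seed(21)
  pop <- pop_model(sigma_prop = 0.005)
  cov <- dog_covariates(0, 1.2)
  tt <- exp(seq(log(5), log(400), length.out = 20))
  for (i in 1:5) {
    eta <- c(rnorm(1, 0, 0.208), rnorm(1, 0, 0.248), rnorm(1, 0, 0.199))
    phi <- individual_from_effects(pop, cov, eta)
    y <- two_cpt_concentration(phi, 64.7, tt) * (1 + 0.005 * rnorm(20))
    fit <- estimate_ebe(y, tt, pop, cov, 64.7)
    expect_lt(max(abs(fit$eta_hat - eta)), 0.05)
  }
})

test_that("shrinkage diagnostics behave as information decreases", {
  pop <- pop_model()
  # all estimates at the prior mean: full shrinkage
  expect_equal(unname(shrinkage(matrix(0, 40, 3), pop)), c(1, 1, 1))
  # estimates distributed exactly as the generating distribution: ~0
  set.seed(17)
  etas <- cbind(rnorm(4000, 0, 0.208), rnorm(4000, 0, 0.248),
                rnorm(4000, 0, 0.199))
  expect_true(all(shrinkage(etas, pop) < 0.05))
  expect_error(shrinkage(matrix(0, 10, 3), pop), "30")
  # sparse designs shrink harder than richer designs on the same cohort
  cov <- dog_covariates(0, 0.98)
  cfg <- simulation_config(times = c(30, 120, 180), n_replicates = 60,
                           seed = 5)
  sim <- simulate_profiles(pop, cov, cfg)
  eta1 <- t(vapply(1:60, function(i)
    unname(estimate_ebe(sim$conc[i, 3], 180, pop, cov, 64.7)$eta_hat),
    numeric(3)))
  eta3 <- t(vapply(1:60, function(i)
    unname(estimate_ebe(sim$conc[i, ], c(30, 120, 180), pop, cov,
                        64.7)$eta_hat), numeric(3)))
  s1 <- shrinkage(eta1, pop)
  s3 <- shrinkage(eta3, pop)
  expect_gt(s1[["eta_cl"]], s3[["eta_cl"]])
})

test_that("input contracts are enforced", {
  pop <- pop_model()
  cov <- dog_covariates(0, 1)
  expect_error(estimate_ebe(numeric(0), numeric(0), pop, cov, 64.7),
               "non-empty")
  expect_error(estimate_ebe(c(10, 20), 30, pop, cov, 64.7), "equal length")
  expect_error(estimate_ebe(-5, 30, pop, cov, 64.7), "positive")
  expect_error(estimate_ebe(10, 0, pop, cov, 64.7), "> 0")
  expect_error(map_objective(c(0, 0, 0), 10, -5, pop, cov, 64.7), "> 0")
})
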