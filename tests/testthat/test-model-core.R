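# Structural model, covariate map and residual model.

test_that("covariate map reproduces typical and CKD-adjusted clearance", {
  pop <- pop_model()
  # typical healthy dog at the centering creatinine
  phi <- individual_from_effects(pop, dog_covariates(0, 1.47))
  expect_equal(phi$cl, 0.00212, tolerance = 1e-10)
  expect_equal(phi$v1, 0.163)
  expect_equal(phi$v2, 0.058)
  expect_equal(phi$q, 0.0034)
  # diseased status multiplies clearance by exp(beta_ckd)
  phi_ckd <- individual_from_effects(pop, dog_covariates(1, 1.47))
  expect_equal(phi_ckd$cl, 0.00212 * exp(-0.379), tolerance = 1e-10)
  expect_equal(phi_ckd$cl, 0.001451237, tolerance = 1e-6)
  # identity case: no covariate effects, eta = 0
  pop0 <- pop_model(beta_ckd = 0, beta_creat = 0)
  phi0 <- individual_from_effects(pop0, dog_covariates(1, 5))
  expect_equal(unlist(phi0[c("cl", "v1", "v2", "q")]),
               c(cl = pop0$theta_cl, v1 = pop0$theta_v1,
                 v2 = pop0$theta_v2, q = pop0$theta_q))
})

test_that("covariate map is monotone in creatinine and CKD status", {
  pop <- pop_model()  # beta_creat < 0
  creats <- c(0.7, 1.2, 2, 4, 8)
  cls <- vapply(creats, function(cr)
    individual_from_effects(pop, dog_covariates(0, cr))$cl, numeric(1))
  expect_true(all(diff(cls) < 0))
  for (cr in creats) {
    r <- individual_from_effects(pop, dog_covariates(1, cr))$cl /
      individual_from_effects(pop, dog_covariates(0, cr))$cl
    expect_equal(r, exp(pop$beta_ckd), tolerance = 1e-12)
  }
})

test_that("type validation rejects degenerate models and covariates", {
  expect_error(pop_model(omega_cl = 0), "strictly positive")
  expect_error(pop_model(sigma_prop = -0.1), "strictly positive")
  expect_error(pop_model(theta_cl = NA), "finite")
  expect_error(dog_covariates(2, 1), "ckd")
  expect_error(dog_covariates(0, -1), "creatinine")
  expect_error(random_effects(Inf, 0, 0), "finite")
  expect_error(individual_from_effects(pop_model(), dog_covariates(0, 1),
                                       c(0, 0)), "three finite")
})

test_that("bolus initial condition and hybrid rate constants are correct", {
  pop <- pop_model()
  phi <- individual_from_effects(pop, dog_covariates(0, 1.47))
  # C(0) = D/V1
  expect_equal(two_cpt_concentration(phi, 64.7, 0), 64.7 / 0.163,
               tolerance = 1e-12)
  expect_equal(two_cpt_concentration(phi, 64.7, 0), 396.9325,
               tolerance = 1e-6)
  # terminal log-slope equals the smaller quadratic root 0.0091487/min
  t_late <- c(2000, 2001)
  cc <- two_cpt_concentration(phi, 64.7, t_late)
  beta_emp <- -diff(log(cc)) / diff(t_late)
  expect_equal(beta_emp, 0.009148743, tolerance = 1e-6)
})

test_that("one-compartment limit is recovered as Q -> 0", {
  phi <- structure(list(cl = 0.003, v1 = 0.2, v2 = 0.05, q = 1e-14),
                   class = "individual_params")
  tt <- c(0, 10, 60, 200, 500)
  mono <- (50 / 0.2) * exp(-(0.003 / 0.2) * tt)
  expect_equal(two_cpt_concentration(phi, 50, tt), mono, tolerance = 1e-9)
})

test_that("closed form matches an ODE integrator on random parameter sets", {
  skip_if_not_installed("deSolve")
  set.seed(42)
  for (i in 1:12) {
    phi <- structure(list(cl = runif(1, 5e-4, 0.01),
                          v1 = runif(1, 0.05, 0.5),
                          v2 = runif(1, 0.01, 0.3),
                          q = runif(1, 5e-4, 0.02)),
                     class = "individual_params")
    tt <- sort(runif(6, 1, 400))
    expect_equal(two_cpt_concentration(phi, 64.7, tt),
                 oracle_conc_ode(phi, 64.7, tt), tolerance = 1e-6)
  }
})

test_that("repeated-root branch is continuous with the two-root solution", {
  # parameters tuned so the discriminant is ~0: k10*k21 close to (s/2)^2
  v1 <- 0.2; v2 <- 0.2; q <- 0.004
  # choose cl so that s^2 = 4 k10 k21: k10 = k21 gives equality when k12 -> 0
  # perturb around near-equal roots instead
  cl_star <- v1 * (q / v2)          # k10 = k21
  tt <- c(5, 60, 200)
  conc_with <- function(eps) {
    phi <- structure(list(cl = cl_star * (1 + eps), v1 = v1, v2 = v2, q = q),
                     class = "individual_params")
    two_cpt_concentration(phi, 64.7, tt)
  }
  expect_equal(conc_with(1e-13), conc_with(1e-4), tolerance = 1e-3)
})

test_that("concentration is positive, eventually decreasing, and vanishes", {
  pop <- pop_model()
  phi <- individual_from_effects(pop, dog_covariates(1, 2.25),
                                 random_effects(0.3, -0.2, 0.1))
  tt <- seq(0, 2000, by = 5)
  cc <- two_cpt_concentration(phi, 64.7, tt)
  expect_true(all(cc > 0))
  expect_true(all(diff(cc) < 0))   # IV bolus: monotone decline
  expect_lt(two_cpt_concentration(phi, 64.7, 1e5), 1e-6)
})

test_that("quadrature of the curve conserves dose: AUC(0-Inf) = D/Cl", {
  pop <- pop_model()
  for (cov in list(dog_covariates(0, 0.98), dog_covariates(1, 2.25))) {
    phi <- individual_from_effects(pop, cov)
    auc <- integrate(function(t) two_cpt_concentration(phi, 64.7, t),
                     0, Inf, rel.tol = 1e-10)$value
    expect_equal(auc, 64.7 / phi$cl, tolerance = 1e-3)
  }
})

test_that("proportional residual model scales with the prediction", {
  pop <- pop_model()
  expect_equal(residual_sd(pop, 100), 6.17, tolerance = 1e-12)
  expect_equal(residual_sd(pop, 0), 0)
  expect_equal(residual_sd(pop_model(sigma_prop = 0.1), 396.9), 39.69,
               tolerance = 1e-12)
  expect_error(residual_sd(pop, -1), "non-negative")
})
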