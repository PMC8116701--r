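# Laplace-approximate population fitting.

test_that("information criteria follow their defining formulas", {
  fake <- list(neg2ll = 100, n_par = 10, n_subjects = 49)
  ic <- information_criteria(fake)
  expect_equal(ic[["AIC"]], 120)
  expect_equal(ic[["BIC"]], 100 + 10 * log(49), tolerance = 1e-12)
  expect_equal(ic[["BIC"]], 138.9182, tolerance = 1e-4)
  # p = 0: both collapse onto -2LL
  ic0 <- information_criteria(list(neg2ll = 55.5, n_par = 0,
                                   n_subjects = 12))
  expect_equal(unname(ic0), c(55.5, 55.5))
})

test_that("near-noise-free data reduce to nonlinear regression on theta", {
  pop_true <- pop_model(omega_cl = 1e-6, omega_v1 = 1e-6, omega_v2 = 1e-6,
                        sigma_prop = 1e-4)
  coh <- generate_cohort(pop_true, 8, 6, seed = 14)
  init <- pop_model(theta_cl = 0.0018, theta_v1 = 0.19, theta_v2 = 0.05,
                    theta_q = 0.004, beta_ckd = -0.3, beta_creat = -0.35,
                    omega_cl = 0.05, omega_v1 = 0.05, omega_v2 = 0.05,
                    sigma_prop = 0.01)
  fit <- fit_population(coh$data, init = init, control = list(se = FALSE))
  for (th in c("theta_cl", "theta_v1", "theta_v2", "theta_q"))
    expect_equal(fit$pop[[th]], pop_model()[[th]], tolerance = 1e-3)
  expect_equal(fit$pop$beta_ckd, -0.379, tolerance = 0.01)
  expect_equal(fit$pop$beta_creat, -0.421, tolerance = 0.01)
})

test_that("fit is invariant to subject relabeling and row reordering", {
  pop <- pop_model()
  coh <- generate_cohort(pop, 7, 5, seed = 60)
  d1 <- coh$data
  # permute subjects and shuffle observation rows within the dataset
  set.seed(1)
  ids <- unique(d1$ID)
  perm <- sample(ids)
  d2 <- do.call(rbind, lapply(perm, function(id) {
    sub <- d1[d1$ID == id, ]
    rbind(sub[1, ], sub[-1, ][sample(nrow(sub) - 1), ])
  }))
  init <- pop_model(theta_cl = 0.0025, omega_cl = 0.25)
  ctrl <- list(se = FALSE, rel.tol = 1e-10)
  f1 <- fit_population(d1, init = init, control = ctrl)
  f2 <- fit_population(d2, init = init, control = ctrl)
  expect_equal(coef(f1), coef(f2), tolerance = 1e-4)
})

test_that("accepted outer steps decrease the objective monotonically", {
  pop <- pop_model()
  coh <- generate_cohort(pop, 6, 4, seed = 8)
  fit <- fit_population(coh$data,
                        init = pop_model(theta_cl = 0.003, omega_cl = 0.3),
                        control = list(se = FALSE, iter.max = 40))
  expect_true(all(diff(fit$trace) < 0))
  expect_true(is.finite(fit$neg2ll))
  expect_equal(fit$AIC, fit$neg2ll + 2 * fit$n_par)
  expect_equal(fit$BIC, fit$neg2ll + fit$n_par * log(fit$n_subjects))
})

test_that("refitting data simulated from a fitted model is self-consistent", {
  pop <- pop_model()
  coh <- generate_cohort(pop, 10, 8, seed = 26)
  init <- pop_model(theta_cl = 0.0026, omega_cl = 0.25, sigma_prop = 0.08)
  f1 <- fit_population(coh$data, init = init, control = list(se = FALSE))
  sim <- simulate(f1, nsim = 1, seed = 99)[[1]]
  f2 <- fit_population(sim, init = init, control = list(se = FALSE))
  # stochastic tolerance on 18 dogs: fixed effects on the log scale
  expect_equal(log(f2$pop$theta_cl), log(f1$pop$theta_cl), tolerance = 0.15)
  expect_equal(log(f2$pop$theta_v1), log(f1$pop$theta_v1), tolerance = 0.15)
  expect_equal(f2$pop$beta_ckd, f1$pop$beta_ckd, tolerance = 0.5)
})

test_that("fit object methods expose predictions, residuals and simulation", {
  pop <- pop_model()
  coh <- generate_cohort(pop, 5, 3, seed = 44)
  fit <- fit_population(coh$data, init = pop_model(),
                        control = list(se = FALSE, iter.max = 25))
  pr_ind <- predict(fit, type = "individual")
  pr_pop <- predict(fit, type = "population")
  expect_equal(nrow(pr_ind), 40)          # 8 dogs x 5 times
  expect_equal(pr_ind$TIME, pr_pop$TIME)
  # individual predictions fit the data at least as well as typical ones
  y <- coh$data$DV[!is.na(coh$data$DV)]
  expect_lte(sum((log(y) - log(pr_ind$pred))^2),
             sum((log(y) - log(pr_pop$pred))^2))
  r <- residuals(fit, type = "iwres")
  expect_length(r, 40)
  expect_lt(sd(r), 3)
  sims <- simulate(fit, nsim = 2, seed = 5)
  expect_length(sims, 2)
  expect_equal(dim(sims[[1]]), dim(coh$data))
  ll <- logLik(fit)
  expect_equal(as.numeric(ll), -fit$neg2ll / 2)
  expect_equal(attr(ll, "df"), 10)
})

test_that("degenerate inputs are rejected", {
  pop <- pop_model()
  coh <- generate_cohort(pop, 1, 0, seed = 3)
  expect_error(fit_population(coh$data), "2 subjects")
  bad <- generate_cohort(pop, 2, 1, seed = 3)$data
  bad <- bad[!(bad$TIME == 0), ]          # drop dose rows
  expect_error(fit_population(bad), "dose record")
})
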