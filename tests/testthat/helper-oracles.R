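# Independent oracles used across the test files.  These deliberately do
# not share code with the package internals they check.

# Literal transcription of the penalized MAP criterion: sum over observed
# times of squared weighted residual plus log error variance, plus the
# quadratic random-effect penalty.
oracle_map_objective <- function(eta, y, times, pop, cov, dose) {
  cl <- pop$theta_cl * exp(pop$beta_ckd * cov$ckd +
                           pop$beta_creat * (cov$creatinine - pop$creat_center) +
                           eta[1])
  v1 <- pop$theta_v1 * exp(eta[2])
  v2 <- pop$theta_v2 * exp(eta[3])
  q <- pop$theta_q
  k10 <- cl / v1; k12 <- q / v1; k21 <- q / v2
  s <- k10 + k12 + k21
  disc <- sqrt(s^2 - 4 * k10 * k21)
  al <- (s + disc) / 2; be <- (s - disc) / 2
  f <- (dose / v1) * ((al - k21) / (al - be) * exp(-al * times) +
                        (k21 - be) / (al - be) * exp(-be * times))
  g2 <- (pop$sigma_prop * f)^2
  sum((y - f)^2 / g2 + log(g2)) +
    eta[1]^2 / pop$omega_cl^2 + eta[2]^2 / pop$omega_v1^2 +
    eta[3]^2 / pop$omega_v2^2
}

# Vectorised evaluation of the same criterion over a matrix of eta rows
# (grid-search oracle for the global-minimum property).
oracle_objective_grid <- function(etas, y, times, pop, cov, dose) {
  cl <- pop$theta_cl * exp(pop$beta_ckd * cov$ckd +
                           pop$beta_creat * (cov$creatinine - pop$creat_center) +
                           etas[, 1])
  v1 <- pop$theta_v1 * exp(etas[, 2])
  v2 <- pop$theta_v2 * exp(etas[, 3])
  q <- pop$theta_q
  k10 <- cl / v1; k12 <- q / v1; k21 <- q / v2
  s <- k10 + k12 + k21
  disc <- sqrt(s^2 - 4 * k10 * k21)
  al <- (s + disc) / 2; be <- (s - disc) / 2
  total <- etas[, 1]^2 / pop$omega_cl^2 + etas[, 2]^2 / pop$omega_v1^2 +
    etas[, 3]^2 / pop$omega_v2^2
  for (j in seq_along(times)) {
    f <- (dose / v1) * ((al - k21) / (al - be) * exp(-al * times[j]) +
                          (k21 - be) / (al - be) * exp(-be * times[j]))
    g2 <- (pop$sigma_prop * f)^2
    total <- total + (y[j] - f)^2 / g2 + log(g2)
  }
  total
}

# Two-compartment concentrations by numerical integration of the
# mass-balance ODE system (amounts in central/peripheral compartments).
oracle_conc_ode <- function(phi, dose, times) {
  rhs <- function(t, state, parms) {
    with(as.list(c(state, parms)), {
      dA1 <- -(cl / v1) * A1 - (q / v1) * A1 + (q / v2) * A2
      dA2 <- (q / v1) * A1 - (q / v2) * A2
      list(c(dA1, dA2))
    })
  }
  out <- deSolve::lsoda(c(A1 = dose, A2 = 0), c(0, times), rhs,
                        c(cl = phi$cl, v1 = phi$v1, v2 = phi$v2, q = phi$q),
                        rtol = 1e-10, atol = 1e-12)
  out[match(times, out[, "time"]), "A1"] / phi$v1
}

# -2 log marginal likelihood for a single subject with one random effect
# on clearance, by adaptive quadrature of the exact integrand.
oracle_neg2ll_quadrature <- function(pop, cov, times, y, dose) {
  cl_typ <- pop$theta_cl * exp(pop$beta_ckd * cov$ckd +
                               pop$beta_creat * (cov$creatinine - pop$creat_center))
  dens <- function(e) vapply(e, function(ei) {
    phi <- list(cl = cl_typ * exp(ei), v1 = pop$theta_v1,
                v2 = pop$theta_v2, q = pop$theta_q)
    k10 <- phi$cl / phi$v1; k12 <- phi$q / phi$v1; k21 <- phi$q / phi$v2
    s <- k10 + k12 + k21
    disc <- sqrt(max(s^2 - 4 * k10 * k21, 0))
    al <- (s + disc) / 2; be <- (s - disc) / 2
    f <- if (disc > 0)
      (dose / phi$v1) * ((al - k21) / (al - be) * exp(-al * times) +
                           (k21 - be) / (al - be) * exp(-be * times))
    else (dose / phi$v1) * exp(-al * times)
    prod(stats::dnorm(y, f, pop$sigma_prop * f)) *
      stats::dnorm(ei, 0, pop$omega_cl)
  }, numeric(1))
  -2 * log(stats::integrate(dens, -8 * pop$omega_cl, 8 * pop$omega_cl,
                            rel.tol = 1e-10)$value)
}

# small fixture: a fast near-default population model
test_pop <- function(...) pop_model(...)
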