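# Population-parameter estimation by Laplace-approximate marginal
# likelihood.  The inner per-subject MAP problems reuse the Gauss-Newton
# EBE engine; the outer problem is quasi-Newton on transformed (log /
# natural) scales with box constraints.

# central-difference Hessian of a scalar function
num_hessian <- function(fn, x, h = 1e-4, ...) {
  p <- length(x)
  H <- matrix(0, p, p)
  f0 <- fn(x, ...)
  for (i in seq_len(p)) {
    ei <- numeric(p); ei[i] <- h
    H[i, i] <- (fn(x + ei, ...) - 2 * f0 + fn(x - ei, ...)) / h^2
    if (i < p) for (j in seq.int(i + 1L, p)) {
      ej <- numeric(p); ej[j] <- h
      H[i, j] <- H[j, i] <-
        (fn(x + ei + ej, ...) - fn(x + ei - ej, ...) -
           fn(x - ei + ej, ...) + fn(x - ei - ej, ...)) / (4 * h^2)
    }
  }
  H
}

# split a long-format dataset into per-subject records
split_subjects <- function(data) {
  ids <- unique(data$ID)
  lapply(ids, function(id) {
    sub <- data[data$ID == id, , drop = FALSE]
    dose <- sub$AMT[!is.na(sub$AMT) & sub$TIME == 0][1L]
    if (is.na(dose))
      stop("subject '", id, "' has no dose record at TIME = 0", call. = FALSE)
    obs <- sub[!is.na(sub$DV), , drop = FALSE]
    list(id = id,
         cov = dog_covariates(obs$CKD[1L], obs$CREAT[1L],
                              if ("WT" %in% names(obs)) obs$WT[1L] else NA_real_,
                              id),
         times = obs$TIME, y = obs$DV, dose = dose)
  })
}

popfit_par_names <- function(random) {
  c("log_theta_cl", "log_theta_v1", "log_theta_v2", "log_theta_q",
    "beta_ckd", "beta_creat",
    paste0("log_omega_", random), "log_sigma_prop")
}

pop_from_par <- function(par, random, creat_center) {
  om <- c(cl = 0.2, v1 = 0.2, v2 = 0.2)  # placeholders for inactive effects
  om[random] <- exp(par[paste0("log_omega_", random)])
  pop_model(theta_cl = exp(par[["log_theta_cl"]]),
            theta_v1 = exp(par[["log_theta_v1"]]),
            theta_v2 = exp(par[["log_theta_v2"]]),
            theta_q = exp(par[["log_theta_q"]]),
            beta_ckd = par[["beta_ckd"]],
            beta_creat = par[["beta_creat"]],
            creat_center = creat_center,
            omega_cl = om[["cl"]], omega_v1 = om[["v1"]],
            omega_v2 = om[["v2"]], sigma_prop = exp(par[["log_sigma_prop"]]))
}

#' Laplace-approximate -2 log marginal likelihood
#'
#' For each subject the marginal likelihood integrates the conditional
#' likelihood over the random effects; the Laplace approximation expands
#' the MAP objective \eqn{J(\eta)} to second order around its minimiser:
#' \deqn{-2\log L_i \approx J_i(\hat\eta_i) + n_i\log 2\pi +
#'   \log|\Omega| + \log|A_i/2|,}
#' with \eqn{A_i} the Hessian of \eqn{J_i} at \eqn{\hat\eta_i}.
#'
#' @param pop A [pop_model()].
#' @param data Long-format dataset (columns \code{ID, TIME, DV, AMT, CKD,
#'   CREAT}).
#' @param random Which random effects are in the model (subset of
#'   \code{c("cl","v1","v2")}).
#' @param eta_start Optional matrix of warm-start values (subjects x
#'   effects).
#' @return Scalar -2 log-likelihood, with attribute \code{"eta"} holding
#'   the per-subject MAP random effects.
#' @export
laplace_neg2ll <- function(pop, data, random = c("cl", "v1", "v2"),
                           eta_start = NULL) {
  subjects <- if (is.list(data) && !is.data.frame(data)) data
              else split_subjects(data)
  p <- length(random)
  omegas <- c(cl = pop$omega_cl, v1 = pop$omega_v1, v2 = pop$omega_v2)[random]
  log_det_omega <- sum(log(omegas^2))
  eta_hat <- matrix(0, length(subjects), p)
  total <- 0
  for (i in seq_along(subjects)) {
    s <- subjects[[i]]
    ctx <- ebe_context(pop, s$cov, s$dose, s$times, random)
    start <- if (!is.null(eta_start)) eta_start[i, ] else NULL
    fit <- ebe_solve(s$y, ctx, grad_tol = 1e-7, warm = start,
                     hessian = TRUE)
    eta_hat[i, ] <- fit$eta
    A <- fit$hessian
    detA <- det(A / 2)
    if (!is.finite(detA) || detA <= 0) {
      A <- A + diag(1e-6, p)
      detA <- abs(det(A / 2))
      if (detA == 0) return(structure(1e10, eta = eta_hat))
    }
    total <- total + fit$obj + length(s$y) * log(2 * pi) +
      log_det_omega + log(detA)
  }
  structure(total, eta = eta_hat)
}

#' Fit the population PK model by Laplace-approximate maximum likelihood
#'
#' Estimates the fixed effects, covariate coefficients, random-effect SDs
#' and the proportional residual coefficient of the two-compartment model
#' from a long-format concentration dataset.  The marginal likelihood is
#' approximated by the Laplace method (the inner problem per subject is the
#' MAP objective minimised by Gauss-Newton); the outer optimisation runs on
#' log scales for positive parameters and natural scale for the covariate
#' coefficients, under a quasi-Newton method with box constraints.  The
#' covariate structure (CKD status and centered creatinine on clearance) is
#' fixed; no covariate search is performed.
#'
#' @param data Long-format dataset with columns \code{ID, TIME, DV, AMT,
#'   CKD, CREAT} (and optionally \code{WT}); one dose row per subject at
#'   TIME = 0.
#' @param init A [pop_model()] of starting values (also supplies the fixed
#'   creatinine centering constant).
#' @param random Random-effect structure, subset of \code{c("cl","v1","v2")}.
#' @param control List: \code{iter.max} (default 300), \code{rel.tol}
#'   (1e-9), \code{se} (TRUE: compute standard errors from the numerical
#'   Hessian of the outer objective).
#' @return Object of class \code{"popfit"}: the estimated [pop_model()]
#'   (\code{$pop}), natural-scale estimates/SE/RSE%% (\code{$estimates}),
#'   \code{$neg2ll}, \code{$AIC}, \code{$BIC}, \code{$n_par},
#'   \code{$n_subjects}, \code{$n_obs}, per-subject MAP random effects
#'   (\code{$ebe}), convergence info and the accepted-step objective trace.
#' @export
fit_population <- function(data, init = pop_model(),
                           random = c("cl", "v1", "v2"),
                           control = list()) {
  stopifnot(inherits(init, "pop_model"))
  random <- match.arg(random, c("cl", "v1", "v2"), several.ok = TRUE)
  ctrl <- utils::modifyList(list(iter.max = 300, rel.tol = 1e-8, se = TRUE),
                            control)
  subjects <- split_subjects(data)
  n_subj <- length(subjects)
  n_obs <- sum(vapply(subjects, function(s) length(s$y), integer(1)))
  if (n_subj < 2L)
    stop("at least 2 subjects are required to fit a population model",
         call. = FALSE)

  pnames <- popfit_par_names(random)
  omegas0 <- c(cl = init$omega_cl, v1 = init$omega_v1, v2 = init$omega_v2)
  start <- stats::setNames(
    c(log(init$theta_cl), log(init$theta_v1), log(init$theta_v2),
      log(init$theta_q), init$beta_ckd, init$beta_creat,
      log(omegas0[random]), log(init$sigma_prop)), pnames)
  lower <- stats::setNames(
    c(rep(log(1e-6), 4), -5, -5, rep(log(1e-3), length(random)), log(1e-4)),
    pnames)
  upper <- stats::setNames(
    c(rep(log(10), 4), 5, 5, rep(log(3), length(random)), log(1)), pnames)

  cache <- new.env(parent = emptyenv())
  cache$eta <- matrix(0, n_subj, length(random))
  cache$trace <- numeric(0)

  objective <- function(par) {
    par <- stats::setNames(par, pnames)
    pop <- tryCatch(pop_from_par(par, random, init$creat_center),
                    error = function(e) NULL)
    if (is.null(pop)) return(1e10)
    val <- laplace_neg2ll(pop, subjects, random, eta_start = cache$eta)
    cache$eta <- attr(val, "eta")
    v <- as.numeric(val)
    if (length(cache$trace) == 0L || v < min(cache$trace))
      cache$trace <- c(cache$trace, v)
    v
  }

  opt <- stats::nlminb(start, objective, lower = lower, upper = upper,
                       control = list(iter.max = ctrl$iter.max,
                                      rel.tol = ctrl$rel.tol))
  par_hat <- stats::setNames(opt$par, pnames)
  pop_hat <- pop_from_par(par_hat, random, init$creat_center)
  final <- laplace_neg2ll(pop_hat, subjects, random, eta_start = cache$eta)
  neg2ll <- as.numeric(final)
  converged <- opt$convergence == 0 ||
    grepl("relative convergence|X-convergence|both X", opt$message)
  n_par <- length(pnames)

  # delta-method SEs on the natural scale
  se_nat <- rep(NA_real_, n_par)
  se_ok <- FALSE
  if (isTRUE(ctrl$se)) {
    H <- num_hessian(objective, par_hat, h = 1e-3)
    cov_t <- tryCatch(2 * solve(H), error = function(e) NULL)
    if (!is.null(cov_t) && all(diag(cov_t) > 0)) {
      se_t <- sqrt(diag(cov_t))
      scale <- ifelse(grepl("^log_", pnames), exp(par_hat), 1)
      se_nat <- se_t * scale
      se_ok <- TRUE
    } else {
      warning("outer Hessian not positive definite; standard errors withheld",
              call. = FALSE)
    }
  }

  est_nat <- ifelse(grepl("^log_", pnames), exp(par_hat), par_hat)
  nat_names <- sub("^log_", "", pnames)
  estimates <- data.frame(
    parameter = nat_names,
    estimate = unname(est_nat),
    se = unname(se_nat),
    rse_pct = unname(100 * se_nat / abs(est_nat)),
    stringsAsFactors = FALSE)

  structure(list(pop = pop_hat,
                 estimates = estimates,
                 par = par_hat,
                 neg2ll = neg2ll,
                 AIC = neg2ll + 2 * n_par,
                 BIC = neg2ll + n_par * log(n_subj),
                 n_par = n_par, n_subjects = n_subj, n_obs = n_obs,
                 random = random,
                 ebe = attr(final, "eta"),
                 subjects = subjects,
                 converged = converged,
                 message = opt$message,
                 trace = cache$trace,
                 se_ok = se_ok,
                 data = data),
            class = "popfit")
}

#' Information criteria of a population fit
#'
#' \eqn{AIC = -2LL + 2p} and \eqn{BIC = -2LL + p\ln N} with \eqn{N} the
#' number of subjects.
#'
#' @param fit A [fit_population()] result (or any list with \code{neg2ll}
#'   and \code{n_par}).
#' @param n_subjects Number of subjects (defaults to \code{fit$n_subjects}).
#' @return Named vector \code{c(AIC, BIC)}.
#' @export
information_criteria <- function(fit, n_subjects = fit$n_subjects) {
  c(AIC = fit$neg2ll + 2 * fit$n_par,
    BIC = fit$neg2ll + fit$n_par * log(n_subjects))
}

#' @export
print.popfit <- function(x, digits = 4, ...) {
  cat(sprintf("Population PK fit (Laplace): %d subjects, %d observations\n",
              x$n_subjects, x$n_obs))
  cat(sprintf("  -2LL %.3f, AIC %.3f, BIC %.3f, %s\n", x$neg2ll, x$AIC,
              x$BIC, if (x$converged) "converged" else "NOT converged"))
  print(x$pop, digits = digits)
  invisible(x)
}

#' @export
summary.popfit <- function(object, digits = 4, ...) {
  cat(sprintf("Population PK model fit by Laplace-approximate ML\n"))
  cat(sprintf("%d subjects, %d observations, %d parameters\n",
              object$n_subjects, object$n_obs, object$n_par))
  cat(sprintf("-2LL %.3f   AIC %.3f   BIC %.3f\n\n", object$neg2ll,
              object$AIC, object$BIC))
  est <- object$estimates
  est$estimate <- signif(est$estimate, digits)
  est$se <- signif(est$se, digits)
  est$rse_pct <- signif(est$rse_pct, 3)
  print(est, row.names = FALSE)
  invisible(object$estimates)
}

#' @export
coef.popfit <- function(object, ...) {
  stats::setNames(object$estimates$estimate, object$estimates$parameter)
}

#' @export
logLik.popfit <- function(object, ...) {
  structure(-object$neg2ll / 2, df = object$n_par,
            nobs = object$n_subjects, class = "logLik")
}

#' @export
predict.popfit <- function(object, newdata = NULL,
                           type = c("individual", "population"), ...) {
  type <- match.arg(type)
  subjects <- if (is.null(newdata)) object$subjects
              else split_subjects(newdata)
  use_ebe <- type == "individual" && is.null(newdata)
  out <- lapply(seq_along(subjects), function(i) {
    s <- subjects[[i]]
    eta <- c(0, 0, 0)
    if (use_ebe) {
      idx <- match(object$random, c("cl", "v1", "v2"))
      eta[idx] <- object$ebe[i, ]
    }
    phi <- individual_from_effects(object$pop, s$cov, eta)
    data.frame(ID = s$id, TIME = s$times,
               pred = two_cpt_concentration(phi, s$dose, s$times),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' @export
residuals.popfit <- function(object, type = c("iwres", "raw"), ...) {
  type <- match.arg(type)
  pr <- predict(object, type = "individual")
  y <- unlist(lapply(object$subjects, function(s) s$y))
  r <- y - pr$pred
  if (type == "iwres") r <- r / (object$pop$sigma_prop * pr$pred)
  r
}

#' @export
simulate.popfit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  pop <- object$pop
  idx <- match(object$random, c("cl", "v1", "v2"))
  om <- c(pop$omega_cl, pop$omega_v1, pop$omega_v2)
  one <- function() {
    rows <- lapply(object$subjects, function(s) {
      eta <- c(0, 0, 0)
      eta[idx] <- stats::rnorm(length(idx), 0, om[idx])
      phi <- individual_from_effects(pop, s$cov, eta)
      f <- two_cpt_concentration(phi, s$dose, s$times)
      dv <- f * (1 + pop$sigma_prop * stats::rnorm(length(f)))
      data.frame(ID = s$id,
                 TIME = c(0, s$times),
                 DV = c(NA_real_, dv),
                 AMT = c(s$dose, rep(NA_real_, length(f))),
                 CKD = s$cov$ckd, CREAT = s$cov$creatinine,
                 WT = s$cov$weight, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  }
  replicate(nsim, one(), simplify = FALSE)
}

#' @export
plot.popfit <- function(x, ...) {
  pr <- predict(x, type = "individual")
  y <- unlist(lapply(x$subjects, function(s) s$y))
  graphics::plot(pr$pred, y, xlab = "Individual prediction (µg/ml)",
                 ylab = "Observed (µg/ml)", log = "xy", ...)
  graphics::abline(0, 1, col = "steelblue")
  invisible(x)
}
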