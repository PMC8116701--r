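#' Population pharmacokinetic model for iohexol
#'
#' Constructs the population model object holding the fixed effects of the
#' two-compartment disposition model, the covariate coefficients acting on
#' clearance, the standard deviations of the log-scale random effects and the
#' proportional residual-error coefficient.  The defaults are the published
#' estimates for client-owned dogs receiving a 64.7 mg/kg intravenous iohexol
#' bolus; all volumes and clearances are expressed per kg body weight so that
#' body weight cancels throughout.
#'
#' The individual model is log-normal around the covariate-adjusted typical
#' value:
#' \deqn{\ln Cl_i = \ln\theta_{Cl} + \beta_{CKD}\,1[\mathrm{CKD+}] +
#'   \beta_{creat}(creat_i - c_0) + \eta_{Cl,i}}
#' with \eqn{\eta \sim N(0, \Omega)}, \eqn{\Omega} diagonal, and a
#' proportional residual model \eqn{g = b f}.  The intercompartmental
#' clearance Q carries no random effect.
#'
#' @param theta_cl Typical elimination clearance (L/min/kg).  Iohexol is
#'   cleared almost exclusively by glomerular filtration, so this is the
#'   typical GFR per kg.
#' @param theta_v1 Typical central volume of distribution (L/kg).
#' @param theta_v2 Typical peripheral volume of distribution (L/kg).
#' @param theta_q Typical intercompartmental clearance (L/min/kg); no
#'   inter-individual variability.
#' @param beta_ckd Covariate coefficient for diseased (CKD+) status on log
#'   clearance (dimensionless).
#' @param beta_creat Covariate coefficient for centered serum creatinine on
#'   log clearance (dl/mg).
#' @param creat_center Centering constant for creatinine (mg/dl); default is
#'   the study-cohort mean.
#' @param omega_cl,omega_v1,omega_v2 Standard deviations of the log-scale
#'   random effects on Cl, V1 and V2 (dimensionless); must be strictly
#'   positive.
#' @param sigma_prop Proportional residual-error coefficient b
#'   (dimensionless): residual SD is \code{sigma_prop} times the predicted
#'   concentration.
#'
#' @return An object of class \code{"pop_model"}: a validated named list with
#'   the fields above.
#' @examples
#' pop <- pop_model()
#' pop$theta_cl    # 0.00212 L/min/kg
#' @export
pop_model <- function(theta_cl = 0.00212,
                      theta_v1 = 0.163,
                      theta_v2 = 0.058,
                      theta_q = 0.0034,
                      beta_ckd = -0.379,
                      beta_creat = -0.421,
                      creat_center = 1.47,
                      omega_cl = 0.208,
                      omega_v1 = 0.248,
                      omega_v2 = 0.199,
                      sigma_prop = 0.0617) {
  pop <- list(theta_cl = theta_cl, theta_v1 = theta_v1,
              theta_v2 = theta_v2, theta_q = theta_q,
              beta_ckd = beta_ckd, beta_creat = beta_creat,
              creat_center = creat_center,
              omega_cl = omega_cl, omega_v1 = omega_v1,
              omega_v2 = omega_v2, sigma_prop = sigma_prop)
  validate_pop_model(pop)
  structure(pop, class = "pop_model")
}

#' @rdname pop_model
#' @param x A candidate population model (named list).
#' @export
validate_pop_model <- function(x) {
  fields <- pop_model_fields()
  missing <- setdiff(fields, names(x))
  if (length(missing) > 0L)
    stop("population model is missing fields: ",
         paste(missing, collapse = ", "), call. = FALSE)
  for (fld in fields) {
    v <- x[[fld]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("population model field '", fld,
           "' must be a single finite number", call. = FALSE)
  }
  positive <- setdiff(fields, c("beta_ckd", "beta_creat"))
  for (fld in positive) {
    if (x[[fld]] <= 0)
      stop("population model field '", fld,
           "' must be strictly positive (singular or degenerate model)",
           call. = FALSE)
  }
  invisible(x)
}

pop_model_fields <- function() {
  c("theta_cl", "theta_v1", "theta_v2", "theta_q",
    "beta_ckd", "beta_creat", "creat_center",
    "omega_cl", "omega_v1", "omega_v2", "sigma_prop")
}

#' @export
print.pop_model <- function(x, digits = 4, ...) {
  cat("Population PK model for iohexol (two-compartment, IV bolus)\n")
  cat("Fixed effects (per kg):\n")
  cat(sprintf("  Cl %s L/min/kg   V1 %s L/kg   V2 %s L/kg   Q %s L/min/kg\n",
              signif(x$theta_cl, digits), signif(x$theta_v1, digits),
              signif(x$theta_v2, digits), signif(x$theta_q, digits)))
  cat("Covariates on log Cl:\n")
  cat(sprintf("  CKD+ %s   creatinine %s dl/mg (centered at %s mg/dl)\n",
              signif(x$beta_ckd, digits), signif(x$beta_creat, digits),
              signif(x$creat_center, digits)))
  cat("Random-effect SDs (log scale):\n")
  cat(sprintf("  omega_cl %s   omega_v1 %s   omega_v2 %s\n",
              signif(x$omega_cl, digits), signif(x$omega_v1, digits),
              signif(x$omega_v2, digits)))
  cat(sprintf("Proportional residual error b: %s\n",
              signif(x$sigma_prop, digits)))
  invisible(x)
}

#' Covariate record for one dog
#'
#' The covariates retained in the final clearance model: kidney status
#' (healthy CKD- coded 0, diseased CKD+ coded 1) and serum creatinine.
#' Body weight is carried as metadata only — the model is fully per-kg.
#'
#' @param ckd 0/1 chronic kidney disease indicator.
#' @param creatinine Serum creatinine, mg/dl (> 0).
#' @param weight Body weight in kg (optional, informational).
#' @param id Subject label.
#' @return An object of class \code{"dog_covariates"}.
#' @examples
#' dog_covariates(ckd = 1, creatinine = 1.7)
#' @export
dog_covariates <- function(ckd, creatinine, weight = NA_real_, id = "dog") {
  if (!is.numeric(ckd) || length(ckd) != 1L || !(ckd %in% c(0, 1)))
    stop("'ckd' must be 0 (healthy) or 1 (diseased)", call. = FALSE)
  if (!is.numeric(creatinine) || length(creatinine) != 1L ||
      !is.finite(creatinine) || creatinine <= 0)
    stop("'creatinine' must be a positive number (mg/dl)", call. = FALSE)
  structure(list(ckd = as.numeric(ckd), creatinine = creatinine,
                 weight = weight, id = as.character(id)),
            class = "dog_covariates")
}

#' @export
print.dog_covariates <- function(x, ...) {
  cat(sprintf("Dog '%s': %s, creatinine %.3g mg/dl%s\n", x$id,
              if (x$ckd == 1) "CKD+" else "CKD-", x$creatinine,
              if (is.finite(x$weight)) sprintf(", %.3g kg", x$weight) else ""))
  invisible(x)
}

#' Log-scale random effects
#'
#' @param eta_cl,eta_v1,eta_v2 Log-scale deviations of the individual
#'   clearance, central and peripheral volumes from their typical values.
#' @return Named numeric vector of class \code{"random_effects"}.
#' @export
random_effects <- function(eta_cl = 0, eta_v1 = 0, eta_v2 = 0) {
  eta <- c(eta_cl = eta_cl, eta_v1 = eta_v1, eta_v2 = eta_v2)
  if (!all(is.finite(eta)))
    stop("random effects must be finite", call. = FALSE)
  structure(eta, class = "random_effects")
}

#' Individual PK parameters from covariates and random effects
#'
#' Maps the population model, one dog's covariates and a random-effect
#' vector to that dog's parameters:
#' \code{cl = theta_cl * exp(beta_ckd*ckd + beta_creat*(creat - c0) + eta_cl)},
#' \code{v1 = theta_v1 * exp(eta_v1)}, \code{v2 = theta_v2 * exp(eta_v2)},
#' \code{q = theta_q}.
#'
#' @param pop A [pop_model()].
#' @param cov A [dog_covariates()].
#' @param eta A [random_effects()] vector (defaults to zero, i.e. the
#'   covariate-typical dog).
#' @return An object of class \code{"individual_params"} with fields
#'   \code{cl}, \code{v1}, \code{v2}, \code{q} (all per kg).
#' @examples
#' individual_from_effects(pop_model(), dog_covariates(0, 1.47))$cl
#' @export
individual_from_effects <- function(pop, cov, eta = random_effects()) {
  stopifnot(inherits(pop, "pop_model"), inherits(cov, "dog_covariates"))
  eta <- as.numeric(eta)
  if (length(eta) != 3L || !all(is.finite(eta)))
    stop("'eta' must be three finite log-scale deviations", call. = FALSE)
  cl <- pop$theta_cl * exp(pop$beta_ckd * cov$ckd +
                           pop$beta_creat * (cov$creatinine - pop$creat_center) +
                           eta[1L])
  v1 <- pop$theta_v1 * exp(eta[2L])
  v2 <- pop$theta_v2 * exp(eta[3L])
  phi <- list(cl = cl, v1 = v1, v2 = v2, q = pop$theta_q)
  for (fld in names(phi))
    if (!is.finite(phi[[fld]]) || phi[[fld]] <= 0)
      stop("individual parameter '", fld, "' is not a positive finite number",
           call. = FALSE)
  structure(phi, class = "individual_params")
}

#' @export
print.individual_params <- function(x, digits = 4, ...) {
  cat(sprintf("Individual PK parameters: Cl %s L/min/kg, V1 %s L/kg, V2 %s L/kg, Q %s L/min/kg\n",
              signif(x$cl, digits), signif(x$v1, digits),
              signif(x$v2, digits), signif(x$q, digits)))
  invisible(x)
}

# typical (eta = 0) clearance for a covariate set; internal fast path
typical_cl <- function(pop, cov) {
  pop$theta_cl * exp(pop$beta_ckd * cov$ckd +
                     pop$beta_creat * (cov$creatinine - pop$creat_center))
}
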