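# Closed-form disposition model and residual-error model.

# Bi-exponential two-compartment IV bolus solution, vectorised over either
# the time grid or the parameter vectors (standard R recycling).  Units:
# dose mg/kg, volumes L/kg -> concentration mg/L = ug/ml.
conc2cpt <- function(cl, v1, v2, q, dose, t) {
  k10 <- cl / v1
  k12 <- q / v1
  k21 <- q / v2
  s <- k10 + k12 + k21
  p <- k10 * k21
  disc <- sqrt(pmax(s * s - 4 * p, 0))
  alpha <- (s + disc) / 2
  beta <- (s - disc) / 2
  c0 <- dose / v1
  rep_root <- disc <= s * 1e-12
  if (any(rep_root)) {
    lam <- s / 2
    lim <- c0 * exp(-lam * t) * (1 + (k21 - lam) * t)
    if (all(rep_root)) return(lim)
    ca <- (alpha - k21) / (alpha - beta)
    cb <- (k21 - beta) / (alpha - beta)
    out <- c0 * (ca * exp(-alpha * t) + cb * exp(-beta * t))
    out[rep_root] <- lim[rep_root]
    return(out)
  }
  ca <- (alpha - k21) / (alpha - beta)
  cb <- (k21 - beta) / (alpha - beta)
  c0 * (ca * exp(-alpha * t) + cb * exp(-beta * t))
}

#' Two-compartment IV-bolus concentration
#'
#' Closed-form plasma concentration of the two-compartment disposition model
#' after an instantaneous intravenous bolus:
#' \deqn{C(t) = \frac{D}{V_1}\left[\frac{\alpha - k_{21}}{\alpha-\beta}
#'   e^{-\alpha t} + \frac{k_{21}-\beta}{\alpha-\beta} e^{-\beta t}\right]}
#' with micro constants \eqn{k_{10} = Cl/V_1}, \eqn{k_{12} = Q/V_1},
#' \eqn{k_{21} = Q/V_2}, and hybrid rate constants \eqn{\alpha > \beta > 0}
#' the roots of \eqn{x^2 - (k_{10}+k_{12}+k_{21})x + k_{10}k_{21} = 0}.
#' A repeated root (\eqn{\alpha = \beta}) is evaluated by its analytic
#' monoexponential limit, and \eqn{Q \to 0} degenerates smoothly to the
#' one-compartment solution.
#'
#' @param phi An [individual_from_effects()] parameter set (per-kg).
#' @param dose_per_kg IV bolus dose, mg/kg.
#' @param t Time(s) after dosing, min (>= 0).
#' @return Concentration(s) in µg/ml (= mg/L for per-kg dosing/volumes).
#' @examples
#' phi <- individual_from_effects(pop_model(), dog_covariates(0, 1.47))
#' two_cpt_concentration(phi, 64.7, c(0, 5, 15, 60, 90, 180))
#' @export
two_cpt_concentration <- function(phi, dose_per_kg, t) {
  stopifnot(inherits(phi, "individual_params"))
  if (!is.numeric(dose_per_kg) || length(dose_per_kg) != 1L || dose_per_kg <= 0)
    stop("'dose_per_kg' must be a positive scalar (mg/kg)", call. = FALSE)
  if (any(t < 0)) stop("times must be >= 0", call. = FALSE)
  for (fld in c("cl", "v1", "v2", "q"))
    if (!is.finite(phi[[fld]]) || phi[[fld]] < 0 ||
        (fld != "q" && phi[[fld]] == 0))
      stop("invalid parameter '", fld, "': must be positive", call. = FALSE)
  conc2cpt(phi$cl, phi$v1, phi$v2, phi$q, dose_per_kg, t)
}

#' Proportional residual standard deviation
#'
#' The residual-error model is proportional: the standard deviation of the
#' measurement error equals \code{sigma_prop} times the model-predicted
#' concentration, \eqn{g = b f}.
#'
#' @param pop A [pop_model()].
#' @param f_value Predicted concentration(s), µg/ml (>= 0).
#' @return Residual SD(s), µg/ml.
#' @examples
#' residual_sd(pop_model(), 100)  # 6.17
#' @export
residual_sd <- function(pop, f_value) {
  stopifnot(inherits(pop, "pop_model"))
  if (any(!is.finite(f_value)) || any(f_value < 0))
    stop("'f_value' must be non-negative", call. = FALSE)
  pop$sigma_prop * f_value
}
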