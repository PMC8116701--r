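# Non-compartmental clearance (Dose/AUC) and Bland-Altman agreement.

#' Non-compartmental iohexol clearance
#'
#' The comparator clearance estimate: \eqn{Cl = D / AUC_{0-\infty}} on the
#' per-kg scale (body weight cancels).  AUC to the last sample uses the
#' linear-up/log-down trapezoidal rule by default; the concentration at
#' t = 0 is log-back-extrapolated from the first two samples (standard
#' bolus-dose practice); the tail beyond the last sample is extrapolated as
#' \eqn{C_{last}/\lambda_z} with the terminal slope \eqn{\lambda_z} from a
#' log-linear regression on the last \code{n_lambda} points.
#'
#' @param times Sampling times, min (any order; sorted internally).
#' @param conc Concentrations at \code{times}, µg/ml, all > 0.
#' @param dose_per_kg Dose, mg/kg.
#' @param n_lambda Number of terminal points for the \eqn{\lambda_z}
#'   regression (default 3).
#' @param method AUC rule: \code{"linuplogdown"} (default) or
#'   \code{"linear"}.
#' @param c0 How to handle the 0-to-first-sample segment:
#'   \code{"logback"} (default; back-extrapolate C(0) from the first two
#'   samples) or \code{"first"} (treat C(0) = C(t1), i.e. a rectangle).
#' @return Object of class \code{"nca_result"} with \code{clearance}
#'   (L/min/kg), \code{clearance_ml_min_kg}, \code{auc_last},
#'   \code{auc_inf} (µg·min/ml), \code{lambda_z} (1/min), \code{c0}.
#' @examples
#' phi <- individual_from_effects(pop_model(), dog_covariates(0, 1.47))
#' y <- two_cpt_concentration(phi, 64.7, c(5, 15, 60, 90, 180))
#' nca_clearance(c(5, 15, 60, 90, 180), y, 64.7)$clearance
#' @export
nca_clearance <- function(times, conc, dose_per_kg, n_lambda = 3,
                          method = c("linuplogdown", "linear"),
                          c0 = c("logback", "first")) {
  method <- match.arg(method)
  c0 <- match.arg(c0)
  if (length(times) != length(conc))
    stop("'times' and 'conc' must have the same length", call. = FALSE)
  if (length(conc) < 3L)
    stop("at least 3 observations are required for NCA", call. = FALSE)
  if (any(conc <= 0)) stop("concentrations must be positive", call. = FALSE)
  if (any(times < 0)) stop("times must be >= 0", call. = FALSE)
  ord <- order(times)
  times <- as.numeric(times)[ord]
  conc <- as.numeric(conc)[ord]
  if (anyDuplicated(times))
    stop("duplicate sampling times", call. = FALSE)

  seg_auc <- function(t1, t2, c1, c2) {
    if (method == "linuplogdown" && c2 < c1)
      (c1 - c2) * (t2 - t1) / log(c1 / c2)
    else
      (c1 + c2) / 2 * (t2 - t1)
  }

  # 0 -> first sample; C(0) by log-back-extrapolation from the first two
  # samples when the profile is declining there
  if (times[1L] > 0) {
    if (c0 == "logback" && conc[2L] < conc[1L]) {
      sl <- (log(conc[2L]) - log(conc[1L])) / (times[2L] - times[1L])
      conc0 <- exp(log(conc[1L]) - sl * times[1L])
    } else {
      conc0 <- conc[1L]
    }
    auc <- seg_auc(0, times[1L], conc0, conc[1L])
  } else {
    conc0 <- conc[1L]
    auc <- 0
  }
  for (i in seq_len(length(times) - 1L))
    auc <- auc + seg_auc(times[i], times[i + 1L], conc[i], conc[i + 1L])

  nl <- min(n_lambda, length(conc))
  tail_idx <- seq.int(length(conc) - nl + 1L, length(conc))
  fit <- stats::lm(log(conc[tail_idx]) ~ times[tail_idx])
  lambda_z <- -unname(stats::coef(fit)[2L])
  if (!is.finite(lambda_z) || lambda_z <= 0)
    stop("extrapolation error: terminal phase is not declining (lambda_z <= 0)",
         call. = FALSE)
  auc_inf <- auc + conc[length(conc)] / lambda_z
  cl <- dose_per_kg / auc_inf
  structure(list(clearance = cl, clearance_ml_min_kg = 1000 * cl,
                 auc_last = auc, auc_inf = auc_inf, lambda_z = lambda_z,
                 c0 = conc0, n_obs = length(conc), method = method),
            class = "nca_result")
}

#' @export
print.nca_result <- function(x, digits = 4, ...) {
  cat(sprintf("NCA clearance: %s L/min/kg (%s ml/min/kg)\n",
              signif(x$clearance, digits),
              signif(x$clearance_ml_min_kg, digits)))
  cat(sprintf("  AUC(0-last) %s, AUC(0-inf) %s ug.min/ml, lambda_z %s /min\n",
              signif(x$auc_last, digits), signif(x$auc_inf, digits),
              signif(x$lambda_z, digits)))
  invisible(x)
}

#' Per-subject NCA clearance for a long-format dataset
#'
#' @param data Long-format dataset (columns \code{ID, TIME, DV, AMT}); one
#'   dose row per subject at TIME = 0.
#' @param ... Passed to [nca_clearance()].
#' @return Data frame with columns \code{ID} and \code{cl_nca} (L/min/kg).
#' @export
nca_clearance_dataset <- function(data, ...) {
  ids <- unique(data$ID)
  cl <- vapply(ids, function(id) {
    sub <- data[data$ID == id, , drop = FALSE]
    dose <- sub$AMT[!is.na(sub$AMT)][1L]
    obs <- sub[!is.na(sub$DV), , drop = FALSE]
    nca_clearance(obs$TIME, obs$DV, dose, ...)$clearance
  }, numeric(1))
  data.frame(ID = ids, cl_nca = cl, stringsAsFactors = FALSE)
}

#' Bland-Altman agreement between two clearance methods
#'
#' Paired-difference agreement statistics: bias (mean difference) and the
#' 95\% limits of agreement, bias ± 1.96 SD of the differences.
#'
#' @param a,b Equal-length paired clearance vectors (first minus second).
#' @return Object of class \code{"bland_altman"}: \code{bias},
#'   \code{loa_low}, \code{loa_high}, \code{sd_diff}, \code{n_pairs}, plus
#'   the paired \code{means} and \code{differences} for plotting.
#' @examples
#' bland_altman(c(1, 2, 3), c(1.1, 2.1, 2.9))
#' @export
bland_altman <- function(a, b) {
  if (length(a) != length(b))
    stop("pairing error: 'a' and 'b' must have the same length",
         call. = FALSE)
  if (length(a) < 2L)
    stop("at least 2 pairs are required", call. = FALSE)
  d <- a - b
  bias <- mean(d)
  sd_d <- stats::sd(d)
  structure(list(bias = bias, sd_diff = sd_d,
                 loa_low = bias - 1.96 * sd_d,
                 loa_high = bias + 1.96 * sd_d,
                 n_pairs = length(d),
                 means = (a + b) / 2, differences = d),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, digits = 4, ...) {
  cat(sprintf("Bland-Altman agreement (n = %d pairs)\n", x$n_pairs))
  cat(sprintf("  bias %s, 95%% limits of agreement [%s, %s]\n",
              signif(x$bias, digits), signif(x$loa_low, digits),
              signif(x$loa_high, digits)))
  invisible(x)
}

#' @export
plot.bland_altman <- function(x, xlab = "Mean of methods",
                              ylab = "Difference (a - b)", ...) {
  graphics::plot(x$means, x$differences, xlab = xlab, ylab = ylab, ...)
  graphics::abline(h = x$bias, col = "steelblue", lwd = 2)
  graphics::abline(h = c(x$loa_low, x$loa_high), col = "firebrick", lty = 2)
  invisible(x)
}
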