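# Limited-sampling design evaluation and ranking: the Monte-Carlo MSE
# criterion for selecting 1/2/3-point sampling schedules.

#' Enumerate candidate sampling-time combinations
#'
#' All size-k subsets of the candidate grid, in lexicographic order, for
#' each requested size.  The default grid is 30 to 180 min with a 30-min
#' step, giving the T1 (6), T2 (15) and T3 (20) candidate sets.
#'
#' @param grid Candidate times (min), strictly increasing.
#' @param sizes Design sizes to enumerate (subset of 1:3 by convention,
#'   but any sizes up to \code{length(grid)} are accepted).
#' @return List of numeric vectors, each one combination.
#' @examples
#' length(enumerate_designs(sizes = 2))  # 15
#' @export
enumerate_designs <- function(grid = seq(30, 180, by = 30), sizes = 1:3) {
  if (any(diff(grid) <= 0))
    stop("configuration error: grid must be strictly increasing",
         call. = FALSE)
  if (any(sizes < 1) || any(sizes > length(grid)))
    stop("configuration error: design sizes must be between 1 and |grid|",
         call. = FALSE)
  out <- list()
  for (k in sizes) {
    idx <- utils::combn(seq_along(grid), k, simplify = FALSE)
    out <- c(out, lapply(idx, function(i) grid[i]))
  }
  out
}

#' Evaluate one sampling design by Monte-Carlo mean squared error
#'
#' For each simulated replicate, the concentrations at the design times K
#' are handed to the MAP estimator and the squared error between the
#' estimated and the true (simulated) log-clearance random effect is
#' recorded:
#' \deqn{MSE_K = \frac{1}{n}\sum_i (\hat\eta_{Cl,i,K} - \eta^*_{Cl,i})^2.}
#' This is the average squared log-scale distance between estimated and
#' simulated clearance, combining bias and imprecision.  Non-converged
#' replicates are excluded with a warning.
#'
#' All designs for one dog should be evaluated on the same simulated
#' replicates (pass \code{profiles}), so rankings are paired comparisons.
#'
#' @param K Sampling times of the design (must be a subset of the simulated
#'   time grid).
#' @param pop,cov Population model and dog covariates (ignored when
#'   \code{profiles} is supplied).
#' @param cfg A [simulation_config()] on the full candidate grid (ignored
#'   when \code{profiles} is supplied).
#' @param profiles Optional precomputed [simulate_profiles()] output shared
#'   across designs.
#' @param full_vector If \code{TRUE}, the MSE averages the squared error
#'   over all three random-effect components rather than clearance only.
#'   The default follows the clearance-only reading of the criterion.
#' @return Object of class \code{"design_eval"}: list with \code{K},
#'   \code{mse}, \code{n_replicates}, \code{n_converged}.
#' @export
evaluate_design <- function(K, pop = NULL, cov = NULL, cfg = NULL,
                            profiles = NULL, full_vector = FALSE) {
  if (is.null(profiles)) {
    if (is.null(pop) || is.null(cov) || is.null(cfg))
      stop("either 'profiles' or all of 'pop', 'cov', 'cfg' are required",
           call. = FALSE)
    profiles <- simulate_profiles(pop, cov, cfg)
  }
  K <- sort(as.numeric(K))
  idx <- match(K, profiles$times)
  if (any(is.na(idx)))
    stop("design times must be a subset of the simulated grid", call. = FALSE)
  ctx <- ebe_context(profiles$pop, profiles$cov,
                     profiles$config$dose_per_kg, K)
  n <- nrow(profiles$conc)
  sol <- ebe_batch_cpp(profiles$conc, as.integer(idx), ctx$times, ctx$dose,
                       ctx$cl_typ, ctx$v1_typ, ctx$v2_typ, ctx$q, ctx$b,
                       unname(ctx$winv), ctx$idx, 200L, 1e-8, 1e-10)
  p <- length(ctx$idx)
  conv <- sol[, p + 2L] > 0
  n_conv <- sum(conv)
  err2 <- if (full_vector)
    rowMeans((sol[, seq_len(p), drop = FALSE] - profiles$eta)^2)
  else (sol[, 1L] - profiles$eta[, 1L])^2
  err2[!conv] <- NA_real_
  if (n_conv == 0L)
    stop("evaluation error: no replicate converged for design {",
         paste(K, collapse = ", "), "}", call. = FALSE)
  if (n_conv < n)
    warning(sprintf("design {%s}: %d of %d replicates did not converge and were excluded",
                    paste(K, collapse = ", "), n - n_conv, n), call. = FALSE)
  structure(list(K = K, mse = mean(err2, na.rm = TRUE),
                 n_replicates = n, n_converged = n_conv),
            class = "design_eval")
}

#' @export
print.design_eval <- function(x, ...) {
  cat(sprintf("Design {%s} min: MSE = %.5g x10^-3 (%d/%d replicates)\n",
              paste(x$K, collapse = ", "), 1000 * x$mse,
              x$n_converged, x$n_replicates))
  invisible(x)
}

#' Rank evaluated designs within each design size
#'
#' Sorts designs ascending by MSE within each size (number of samples).
#' Ties are broken by the earlier last sampling time, then lexicographically.
#'
#' @param evaluations List of [evaluate_design()] results.
#' @return Object of class \code{"design_ranking"}: data frame with columns
#'   \code{size, times, mse, rank, n_converged}, ordered by size then rank.
#' @export
rank_designs <- function(evaluations) {
  if (length(evaluations) < 1L)
    stop("at least one evaluation is required", call. = FALSE)
  sizes <- vapply(evaluations, function(e) length(e$K), integer(1))
  df <- data.frame(
    size = sizes,
    times = vapply(evaluations, function(e) paste(e$K, collapse = "_"),
                   character(1)),
    mse = vapply(evaluations, function(e) e$mse, numeric(1)),
    n_converged = vapply(evaluations, function(e) e$n_converged, integer(1)),
    stringsAsFactors = FALSE)
  last_time <- vapply(evaluations, function(e) max(e$K), numeric(1))
  lex <- vapply(evaluations, function(e)
    paste(sprintf("%06.1f", e$K), collapse = "_"), character(1))
  ord <- order(df$size, df$mse, last_time, lex)
  df <- df[ord, , drop = FALSE]
  df$rank <- stats::ave(df$mse, df$size, FUN = seq_along)
  rownames(df) <- NULL
  structure(df[, c("size", "times", "mse", "rank", "n_converged")],
            class = c("design_ranking", "data.frame"))
}

#' @export
print.design_ranking <- function(x, digits = 5, ...) {
  for (k in sort(unique(x$size))) {
    sub <- x[x$size == k, , drop = FALSE]
    cat(sprintf("-- %d sampling time(s) --\n", k))
    cat(sprintf("  %-14s %-12s %s\n", "times (min)", "MSE (x10^-3)", "rank"))
    for (i in seq_len(nrow(sub)))
      cat(sprintf("  %-14s %-12s %d\n", sub$times[i],
                  signif(1000 * sub$mse[i], digits), as.integer(sub$rank[i])))
  }
  invisible(x)
}

#' Best sampling times for a given dog
#'
#' Simulates one shared set of Monte-Carlo replicates on the full candidate
#' grid for the dog's covariates, evaluates every candidate design of up to
#' \code{max_samples} samples on those replicates, and ranks them by MSE.
#'
#' @param cov A [dog_covariates()].
#' @param pop A [pop_model()].
#' @param cfg A [simulation_config()] whose \code{times} are the candidate
#'   grid (default 30-180 min, step 30).
#' @param max_samples Largest design size to consider (1, 2 or 3).
#' @return A [rank_designs()] ranking.
#' @examples
#' \donttest{
#' best_times_for_dog(dog_covariates(0, 0.98), pop_model(),
#'                    simulation_config(times = seq(30, 180, 30),
#'                                      n_replicates = 200, seed = 7),
#'                    max_samples = 1)
#' }
#' @export
best_times_for_dog <- function(cov, pop,
                               cfg = simulation_config(times = seq(30, 180, 30)),
                               max_samples = 3) {
  stopifnot(max_samples >= 1)
  profiles <- simulate_profiles(pop, cov, cfg)
  designs <- enumerate_designs(cfg$times, seq_len(max_samples))
  evals <- lapply(designs, evaluate_design, profiles = profiles)
  rank_designs(evals)
}
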