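#' Profile likelihood of one circuit parameter
#'
#' Fixes the target parameter on a grid around its estimate and
#' re-optimises all remaining parameters at every grid point. A parameter
#' is practically identifiable when the profiled loss rises above the
#' confidence threshold on both sides of the estimate; a one-sided rise
#' marks practical non-identifiability in the open direction, and a
#' profile that never crosses is flat.
#'
#' For noiseless data the threshold is heuristic (5% loss inflation over
#' the best fit, plus a small absolute floor guarding against the solver
#' noise floor when the best loss is essentially zero); when `noise_sd`
#' is supplied a chi-square threshold
#' `best + noise_sd^2 * qchisq(level, 1)` is used instead.
#'
#' @param data Fitting data (see [fit_rho_circuit()]).
#' @param best_fit A converged `fit_result` from [fit_rho_circuit()].
#' @param parameter Name of the parameter to profile.
#' @param grid Optional explicit grid of parameter values; by default 21
#'   log-spaced points spanning 0.1x to 10x the estimate (clipped to the
#'   bounds).
#' @param n_grid,span Grid size and half-range factor used when `grid` is
#'   `NULL`.
#' @param noise_sd Optional per-frame noise SD of the data; switches the
#'   threshold to the chi-square form.
#' @param level Confidence level of the chi-square threshold.
#' @param loss_floor Absolute addition to the noiseless threshold
#'   (default 1e-9, the order of the integration noise floor).
#' @param maxiter LM iteration cap per grid point.
#' @return A `profile_result`: `parameter`, `grid`, `profile_loss`,
#'   `threshold`, `classification`, `failures`.
#' @export
profile_likelihood <- function(data, best_fit, parameter, grid = NULL,
                               n_grid = 21, span = 10, noise_sd = NULL,
                               level = 0.95, loss_floor = 1e-9,
                               maxiter = 150) {
  stopifnot(inherits(best_fit, "fit_result"), isTRUE(best_fit$converged))
  est <- best_fit$estimates
  if (!parameter %in% names(est))
    stop("unknown parameter: ", parameter)
  bounds <- best_fit$bounds_used
  protocol <- best_fit$protocol
  larg <- best_fit$larg_params
  variant <- best_fit$variant
  df <- as_trace_df(data, protocol)
  code <- if (variant == "WT") 0 else 1
  free <- setdiff(names(est), parameter)

  if (is.null(grid)) {
    ctr <- est[[parameter]]
    lo <- max(ctr / span, bounds$lower[[parameter]])
    hi <- min(ctr * span, bounds$upper[[parameter]])
    grid <- 10^seq(log10(lo), log10(hi), length.out = n_grid)
  }
  grid <- sort(grid)

  profile_loss <- rep(NA_real_, length(grid))
  failures <- integer(0)
  warm <- est[free]
  for (i in seq_along(grid)) {
    fixed_val <- grid[i]
    resid_fn <- function(theta_free) {
      theta <- c(theta_free, stats::setNames(fixed_val, parameter))
      o <- sim_obs_vec(theta, code, larg, protocol, df$t)
      if (is.null(o)) NULL else o - df$value
    }
    # re-optimise from both the walking warm start and the reference
    # estimates: warm chains can wander onto a worse ridge position
    cands <- Filter(Negate(is.null), lapply(
      unique(list(warm, est[free])), function(st)
        lm_fit_log(st, bounds$lower[free], bounds$upper[free],
                   resid_fn, maxiter = maxiter)))
    if (!length(cands)) {
      failures <- c(failures, i)
    } else {
      f <- cands[[which.min(vapply(cands, `[[`, 0, "loss"))]]
      profile_loss[i] <- f$loss
      warm <- stats::setNames(f$par, free)
    }
  }

  threshold <- if (!is.null(noise_sd)) {
    best_fit$loss + noise_sd^2 * stats::qchisq(level, df = 1)
  } else {
    best_fit$loss * 1.05 + loss_floor
  }
  above_lo <- any(profile_loss[grid < est[[parameter]]] > threshold,
                  na.rm = TRUE)
  above_hi <- any(profile_loss[grid > est[[parameter]]] > threshold,
                  na.rm = TRUE)
  classification <- if (above_lo && above_hi) "identifiable"
    else if (above_lo) "practically_non_identifiable_upper"
    else if (above_hi) "practically_non_identifiable_lower"
    else "flat"

  structure(list(parameter = parameter, grid = grid,
                 profile_loss = profile_loss, threshold = threshold,
                 best_loss = best_fit$loss,
                 classification = classification, failures = failures),
            class = "profile_result")
}

#' @export
print.profile_result <- function(x, ...) {
  cat("<profile_result>", x$parameter, "->", x$classification,
      sprintf("(threshold %.3g, %d grid points, %d failures)\n",
              x$threshold, length(x$grid), length(x$failures)))
  invisible(x)
}

#' Scan sensitivity of an estimate to its upper bound
#'
#' Re-fits the circuit with a sequence of upper bounds imposed on one
#' parameter and records where the estimate lands each time. Practically
#' non-identifiable parameters track the imposed bound (the optimiser
#' runs along a loss-flat ridge until the constraint stops it) while the
#' achieved loss barely changes; identifiable parameters return to the
#' same interior estimate regardless of the bound.
#'
#' The refit at each bound polishes from a small start set: the reference
#' fit's estimates (projected into the bounds), the same start with the
#' scanned parameter placed at the bound, and `n_random` fresh random
#' starts. The lowest-loss polish wins; ties at the numerical noise floor
#' are resolved toward the constrained (at-bound) candidate, which is the
#' behaviour a bounded quasi-Newton run exhibits on a flat ridge.
#'
#' @param data Fitting data.
#' @param best_fit Reference `fit_result` (its bounds are reused for all
#'   other parameters).
#' @param parameter Parameter whose upper bound is scanned.
#' @param upper_bounds Numeric vector (>= 2 values) of upper bounds.
#' @param n_random Extra random starts per bound (default 2).
#' @param seed Integer seed.
#' @param tie_tol Relative loss tolerance within which two polishes are
#'   considered equivalent (default 1e-3).
#' @param loss_floor Absolute loss tolerance added to the tie rule
#'   (default 1e-9, the integration-noise floor: differences below it are
#'   not evidence).
#' @param track_tol Estimates within this fraction of the bound count as
#'   tracking it (default 0.05).
#' @return A `bound_scan_result`: `parameter`, `upper_bounds`,
#'   `estimates`, `losses`, `tracking_flag`.
#' @export
bound_sensitivity_scan <- function(data, best_fit, parameter, upper_bounds,
                                   n_random = 2, seed = 1L,
                                   tie_tol = 1e-3, loss_floor = 1e-9,
                                   track_tol = 0.05) {
  stopifnot(inherits(best_fit, "fit_result"), length(upper_bounds) >= 2)
  upper_bounds <- sort(upper_bounds)
  est <- best_fit$estimates
  if (!parameter %in% names(est)) stop("unknown parameter: ", parameter)
  bounds <- best_fit$bounds_used
  protocol <- best_fit$protocol
  larg <- best_fit$larg_params
  variant <- best_fit$variant
  df <- as_trace_df(data, protocol)
  code <- if (variant == "WT") 0 else 1
  nm <- names(est)
  resid_fn <- function(theta)
    if (is.null(o <- sim_obs_vec(theta, code, larg, protocol, df$t)))
      NULL else o - df$value

  set.seed(seed)
  estimates <- losses <- numeric(length(upper_bounds))
  for (b in seq_along(upper_bounds)) {
    B <- upper_bounds[b]
    up <- bounds$upper[nm]
    up[[parameter]] <- B
    lo <- bounds$lower[nm]
    clip <- function(x) pmin(pmax(x, lo), up)
    warm <- clip(est)
    at_b <- warm
    at_b[[parameter]] <- B
    starts <- c(list(warm, at_b),
                lapply(seq_len(n_random), function(i)
                  stats::setNames(10^stats::runif(length(nm), log10(lo),
                                                  log10(up)), nm)))
    fits <- Filter(Negate(is.null), lapply(starts, function(st)
      lm_fit_log(st, lo, up, resid_fn)))
    if (!length(fits)) stop("all refits failed at upper bound ", B)
    if (variant == "WT")
      fits <- lapply(fits, function(f) {
        f$par <- stats::setNames(f$par, nm)
        canonicalize_wt(f, lo, up, resid_fn)
      })
    ls <- vapply(fits, `[[`, 0, "loss")
    best_loss <- min(ls)
    tied <- which(ls <= best_loss * (1 + tie_tol) + loss_floor)
    # among near-ties prefer the candidate pinned at the bound
    vals <- vapply(fits[tied], function(f)
      stats::setNames(f$par, nm)[[parameter]], 0)
    pick <- tied[which.max(vals)]
    estimates[b] <- stats::setNames(fits[[pick]]$par, nm)[[parameter]]
    losses[b] <- ls[pick]
  }
  near <- estimates >= (1 - track_tol) * upper_bounds
  consec <- any(near[-1] & near[-length(near)])
  structure(list(parameter = parameter, upper_bounds = upper_bounds,
                 estimates = estimates, losses = losses,
                 tracking_flag = consec),
            class = "bound_scan_result")
}

#' @export
print.bound_scan_result <- function(x, ...) {
  cat("<bound_scan_result>", x$parameter,
      if (x$tracking_flag) "TRACKS upper bound" else "stable", "\n")
  print(data.frame(upper_bound = x$upper_bounds,
                   estimate = signif(x$estimates, 5),
                   loss = signif(x$losses, 5)))
  invisible(x)
}
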