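#' Normalise a trace to its pre-stimulus baseline (fold change)
#'
#' Divides a trace by its mean over the baseline window, so the baseline
#' mean of the output is exactly 1. Scale-invariant: multiplying the input
#' by a constant leaves the output unchanged.
#'
#' @param trace `data.frame(t, value)` or numeric vector (then `t` must be
#'   supplied).
#' @param baseline_window Length-2 numeric pre-stimulus window (s).
#' @param t Time grid when `trace` is a bare numeric vector.
#' @return Same shape as the input, on the fold-change scale.
#' @export
fold_change_normalize <- function(trace, baseline_window = c(0, 150),
                                  t = NULL) {
  if (is.data.frame(trace)) {
    tt <- trace[[1]]
    y <- trace[[2]]
  } else {
    if (is.null(t)) stop("t is required for a bare numeric trace")
    tt <- t
    y <- trace
  }
  idx <- tt >= baseline_window[1] & tt <= baseline_window[2]
  if (!any(idx)) stop("baseline window is empty on this time grid")
  base <- mean(y[idx])
  if (!is.finite(base) || base <= 0)
    stop("non-positive baseline mean: cannot form fold change")
  out <- y / base
  if (is.data.frame(trace)) data.frame(t = tt, value = out) else out
}

# first upward crossing of `level` at or before index `ipk`, linearly
# interpolated; NA when the trace never crosses
cross_up <- function(t, y, level, ipk) {
  seg <- y[seq_len(ipk)]
  i <- which(seg >= level)[1]
  if (is.na(i)) return(NA_real_)
  if (i == 1L) return(t[1])
  t[i - 1] + (level - y[i - 1]) / (y[i] - y[i - 1]) * (t[i] - t[i - 1])
}

cross_down <- function(t, y, level, ipk) {
  n <- length(y)
  seg <- y[ipk:n]
  i <- which(seg <= level)[1]
  if (is.na(i) || i == 1L) return(if (is.na(i)) NA_real_ else t[ipk])
  j <- ipk + i - 1L
  t[j - 1] + (level - y[j - 1]) / (y[j] - y[j - 1]) * (t[j] - t[j - 1])
}

#' Observed activation/deactivation rates from a pulse-response trace
#'
#' Summarises a fold-change transient by the mean derivative over the
#' 10-90% windows of its rising and falling phases: with baseline `b`
#' (mean over the baseline window) and peak excess `A = peak - b`, the
#' 10% and 90% levels are `b + 0.1 A` and `b + 0.9 A`; crossing times are
#' linearly interpolated (first upward crossings before the peak, first
#' downward crossings after it) and the rates are the secant slopes
#' between the crossings, which for a continuous trace equal the mean
#' instantaneous derivative over each window. `k_off_obs` is reported as
#' a positive magnitude.
#'
#' @param trace Fold-change trace: `data.frame(t, value)` or numeric
#'   vector on the protocol grid.
#' @param protocol A [stimulus_protocol()]; supplies the baseline window
#'   and stimulus onset.
#' @param min_prominence Minimum peak excess over baseline required to
#'   call the transient. Default: twice the baseline SD of the trace
#'   (so any positive excess qualifies for a noiseless trace).
#' @return An `observed_kinetics` list: `k_on_obs`, `k_off_obs`,
#'   `peak_amplitude`, `t_peak`, `t10_rise`, `t90_rise`, `t90_fall`,
#'   `t10_fall`, `baseline`.
#' @export
observed_rates <- function(trace, protocol = stimulus_protocol(),
                           min_prominence = NULL) {
  df <- as_trace_df(trace, protocol)
  tt <- df$t
  y <- df$value
  bw <- protocol$baseline_window
  bidx <- tt >= bw[1] & tt <= bw[2]
  if (!any(bidx)) stop("baseline window is empty on this time grid")
  b <- mean(y[bidx])
  if (is.null(min_prominence)) {
    noise <- stats::sd(y[bidx])
    min_prominence <- if (is.finite(noise)) 2 * noise else 0
  }
  post <- which(tt >= protocol$t_start)
  if (!length(post)) stop("no samples after stimulus onset")
  ipk <- post[which.max(y[post])]
  peak <- y[ipk]
  A <- peak - b
  if (A <= min_prominence)
    stop("metric undefined: no qualifying post-stimulus peak ",
         "(excess ", signif(A, 3), " <= prominence ",
         signif(min_prominence, 3), ")")
  lv10 <- b + 0.1 * A
  lv90 <- b + 0.9 * A
  t10r <- cross_up(tt, y, lv10, ipk)
  t90r <- cross_up(tt, y, lv90, ipk)
  t90f <- cross_down(tt, y, lv90, ipk)
  t10f <- cross_down(tt, y, lv10, ipk)
  miss <- c(t10_rise = t10r, t90_rise = t90r, t90_fall = t90f,
            t10_fall = t10f)
  if (any(is.na(miss)))
    stop("metric undefined: crossing(s) not found within the trace: ",
         paste(names(miss)[is.na(miss)], collapse = ", "))
  structure(list(
    k_on_obs = (lv90 - lv10) / (t90r - t10r),
    k_off_obs = abs((lv10 - lv90) / (t10f - t90f)),
    peak_amplitude = A, t_peak = tt[ipk],
    t10_rise = t10r, t90_rise = t90r, t90_fall = t90f, t10_fall = t10f,
    baseline = b), class = "observed_kinetics")
}

#' @export
print.observed_kinetics <- function(x, ...) {
  cat(sprintf(paste0("<observed_kinetics> k_on_obs %.4g /s, k_off_obs ",
                     "%.4g /s, peak +%.4g at %g s\n"),
              x$k_on_obs, x$k_off_obs, x$peak_amplitude, x$t_peak))
  invisible(x)
}

#' Exponential decay half-life of a trace segment
#'
#' Fits `y = B exp(-k (t - t0)) + c` to a post-stimulus decay segment by
#' nonlinear least squares, with the offset `c` fixed at the supplied
#' baseline, and returns `ln(2)/k`.
#'
#' @param t,y The segment (>= 5 samples, trending downward).
#' @param baseline Fixed asymptote `c` (default 0, i.e. decay to zero;
#'   use 1 for fold-change traces).
#' @return A list: `half_life` (s), `k` (1/s), `B`, `loss`.
#' @export
decay_half_life <- function(t, y, baseline = 0) {
  stopifnot(length(t) == length(y))
  if (length(t) < 5) stop("need at least 5 samples to fit a decay")
  excess <- y - baseline
  n <- length(y)
  lead_m <- mean(excess[seq_len(ceiling(n / 3))])
  tail_m <- mean(excess[seq.int(n - ceiling(n / 3) + 1L, n)])
  if (!(lead_m > 0) || lead_m <= tail_m)
    stop("fit rejected: segment is not decaying toward the baseline")
  t0 <- t[1]
  # log-linear start where the excess is positive
  pos <- excess > 0
  if (sum(pos) >= 3) {
    sl <- stats::coef(stats::lm(log(excess[pos]) ~ I(t[pos] - t0)))
    k0 <- max(-sl[[2]], 1e-6)
    B0 <- max(exp(sl[[1]]), 1e-12)
  } else {
    k0 <- log(2) / max(diff(range(t)) / 2, 1e-6)
    B0 <- max(lead_m, 1e-12)
  }
  f <- minpack.lm::nls.lm(
    par = log10(c(B = B0, k = k0)),
    fn = function(lp) 10^lp[1] * exp(-10^lp[2] * (t - t0)) + baseline - y,
    control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14,
                                         ptol = 1e-14))
  k <- 10^f$par[[2]]
  if (!is.finite(k) || k <= 0)
    stop("fit rejected: non-positive decay constant")
  list(half_life = log(2) / k, k = k, B = 10^f$par[[1]],
       loss = f$deviance)
}
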