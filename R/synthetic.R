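#' Noise model for synthetic per-ROI biosensor traces
#'
#' Measurement heterogeneity is emulated with two components: a per-ROI
#' multiplicative response amplitude (log-normal, emulating expression-level
#' differences between cells/ROIs) and additive per-frame Gaussian noise
#' (shot-noise-like). The defaults were chosen once to resemble
#' pooled-ROI biosensor recordings: a 30% log-scale amplitude spread and
#' 0.05 fold-change units of frame noise.
#'
#' @param additive_sd Per-frame Gaussian SD (fold-change units, >= 0).
#' @param roi_scale_sd Log-scale SD of the per-ROI response amplitude
#'   (dimensionless, >= 0).
#' @param seed Optional integer seed used by consumers of the model.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(additive_sd = 0.05, roi_scale_sd = 0.3,
                        seed = NULL) {
  stopifnot(is.numeric(additive_sd), additive_sd >= 0,
            is.numeric(roi_scale_sd), roi_scale_sd >= 0)
  structure(list(additive_sd = additive_sd, roi_scale_sd = roi_scale_sd,
                 seed = seed), class = "noise_model")
}

#' Generate a noisy per-ROI trace ensemble from a model trajectory
#'
#' Each synthetic ROI trace is
#' `s_i * (observation(t) - 1) + 1 + eps_i(t)` with `s_i` log-normal
#' (meanlog 0, sdlog `roi_scale_sd`) and `eps` i.i.d. Gaussian with SD
#' `additive_sd`, mimicking the pooled single-ROI recordings around a
#' shared response shape.
#'
#' @param trajectory A `model_trajectory` (see [simulate_circuit()]).
#' @param noise A [noise_model()].
#' @param n_roi Number of ROI traces (>= 1).
#' @param condition Condition label attached to every trace
#'   (e.g. `"WT"` or `"KO"`).
#' @param compartment Compartment label (e.g. `"FA"` or `"non-FA"`).
#' @param seed Optional integer; overrides `noise$seed`.
#' @return A `trace_ensemble`: fields `t`, `traces` (n_roi x n_time),
#'   `labels` (data.frame with condition/compartment per trace) and
#'   `provenance`.
#' @export
generate_roi_ensemble <- function(trajectory, noise, n_roi = 2000,
                                  condition = "WT", compartment = "FA",
                                  seed = NULL) {
  stopifnot(inherits(trajectory, "model_trajectory"),
            inherits(noise, "noise_model"))
  if (!is.numeric(n_roi) || n_roi < 1)
    stop("n_roi must be >= 1")
  n_roi <- as.integer(n_roi)
  seed <- if (!is.null(seed)) seed else noise$seed
  if (!is.null(seed)) set.seed(seed)
  obs <- to_observation(trajectory)
  n_time <- length(obs)
  s <- if (noise$roi_scale_sd > 0) {
    stats::rlnorm(n_roi, meanlog = 0, sdlog = noise$roi_scale_sd)
  } else {
    rep(1, n_roi)
  }
  traces <- outer(s, obs - 1) + 1
  if (noise$additive_sd > 0)
    traces <- traces + matrix(stats::rnorm(n_roi * n_time, 0,
                                           noise$additive_sd),
                              n_roi, n_time)
  structure(
    list(t = trajectory$t, traces = traces,
         labels = data.frame(condition = rep(condition, n_roi),
                             compartment = rep(compartment, n_roi),
                             stringsAsFactors = FALSE),
         provenance = list(noise = noise, seed = seed,
                           params = trajectory$params_used)),
    class = "trace_ensemble")
}

#' @export
print.trace_ensemble <- function(x, ...) {
  cat("<trace_ensemble>", nrow(x$traces), "ROI traces x",
      ncol(x$traces), "frames\n")
  invisible(x)
}

#' Aggregate an ROI ensemble: fold change, median and bootstrap CI
#'
#' Each trace is first normalised to its own baseline mean (fold change).
#' The ensemble summary is the per-timepoint median across ROIs with a
#' percentile bootstrap confidence band obtained by resampling whole
#' traces.
#'
#' Traces whose baseline mean is non-positive cannot be expressed as fold
#' change; they are dropped with a warning, and an error is raised if no
#' trace survives.
#'
#' @param ensemble A `trace_ensemble`.
#' @param baseline_window Length-2 numeric, the pre-stimulus window (s).
#' @param ci_level Confidence level of the bootstrap band (default 0.99).
#' @param n_boot Bootstrap resamples (default 1000). `n_boot = 0` returns a
#'   degenerate band equal to the median.
#' @param seed Optional integer seed for the bootstrap resampling.
#' @return An `aggregate_trace`: `t`, `center`, `ci_low`, `ci_high`,
#'   `n_roi`.
#' @export
aggregate_ensemble <- function(ensemble, baseline_window = c(0, 150),
                               ci_level = 0.99, n_boot = 1000,
                               seed = NULL) {
  stopifnot(inherits(ensemble, "trace_ensemble"),
            length(baseline_window) == 2L, ci_level > 0, ci_level < 1)
  idx <- ensemble$t >= baseline_window[1] & ensemble$t <= baseline_window[2]
  if (!any(idx)) stop("baseline window not covered by the time grid")
  base <- rowMeans(ensemble$traces[, idx, drop = FALSE])
  keep <- base > 0
  if (!all(keep))
    warning(sum(!keep), " trace(s) with non-positive baseline mean excluded")
  if (!any(keep)) stop("all traces excluded: no positive baseline means")
  norm <- ensemble$traces[keep, , drop = FALSE] / base[keep]
  if (!is.null(seed)) set.seed(seed)
  res <- .Call(C_aggregate_median_ci, norm, as.integer(n_boot),
               as.numeric(ci_level))
  structure(list(t = ensemble$t, center = res[1, ],
                 ci_low = pmin(res[2, ], res[1, ]),
                 ci_high = pmax(res[3, ], res[1, ]),
                 n_roi = sum(keep)),
            class = "aggregate_trace")
}

#' @export
print.aggregate_trace <- function(x, ...) {
  cat("<aggregate_trace>", length(x$t), "frames, median over", x$n_roi,
      sprintf("ROIs; peak center %.4g\n", max(x$center)))
  invisible(x)
}

#' @export
as.data.frame.aggregate_trace <- function(x, ...) {
  data.frame(t = x$t, center = x$center, ci_low = x$ci_low,
             ci_high = x$ci_high)
}
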