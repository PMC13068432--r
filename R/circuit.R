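#' Kinetic parameters of the optogenetic GEF recruitment model
#'
#' The light-induced membrane recruitment of the LARG GEF domain is
#' described by a linear activation/deactivation model,
#' `dLARG*/dt = k_on * f_signal(t) - k_off * LARG*`.
#'
#' @param k_on Activation constant (LARG* units per second per unit input).
#' @param k_off Deactivation constant (1/s).
#' @return An object of class `larg_params`.
#' @seealso [ref_larg_params()] for the published estimates.
#' @export
larg_params <- function(k_on, k_off) {
  stopifnot(is.numeric(k_on), length(k_on) == 1L,
            is.numeric(k_off), length(k_off) == 1L)
  if (!is.finite(k_on) || !is.finite(k_off) || k_on < 0 || k_off <= 0)
    stop("k_on must be non-negative and k_off strictly positive")
  structure(list(k_on = k_on, k_off = k_off), class = "larg_params")
}

#' Published optoLARG recruitment constants
#'
#' Reference estimates of the recruitment kinetics obtained by fitting the
#' linear activation model to measured membrane-recruitment traces:
#' `k_on = 0.0123462`, `k_off = 0.0700499` (both per second). The implied
#' dissociation half-life `ln(2)/k_off` is about 9.9 s.
#'
#' @return A [larg_params()] object.
#' @export
ref_larg_params <- function() {
  larg_params(k_on = 0.0123462, k_off = 0.0700499)
}

#' Kinetic parameters of the Rho-GAP circuit
#'
#' The wild-type (`"WT"`) circuit couples Rho activation by the recruited
#' GEF to a Rho-dependent GAP (negative feedback):
#' \deqn{dGAP*/dt = v_{on}^{GAP} Rho*/(Km^{GAP} + Rho*) - k_{off}^{GAP} GAP*}
#' \deqn{dRho*/dt = V_{on}^{Rho} LARG*/(Km_{on}^{Rho} + LARG*) -
#'       V_{off}^{Rho} GAP* Rho*/(Km_{off}^{Rho} + Rho*)}
#' The knockout (`"KO"`) variant removes the Rho dependence of GAP
#' activation: `dGAP*/dt = k_on_gap - k_off_gap * GAP*`, with `v_on_gap`
#' acting as the zeroth-order activation constant (no `km_gap` is present
#' structurally; this avoids a 0/0 singularity at `Rho* = 0`).
#'
#' @param variant `"WT"` or `"KO"`.
#' @param v_on_gap GAP activation maximal rate (GAP* units/s); for `"KO"` it
#'   is the constant zeroth-order activation rate.
#' @param km_gap Michaelis constant of Rho-dependent GAP activation (Rho*
#'   units); `"WT"` only, must be absent (`NULL`) for `"KO"`.
#' @param k_off_gap First-order GAP deactivation constant (1/s).
#' @param v_on_rho Maximal Rho activation rate (Rho* units/s).
#' @param km_on_rho Michaelis constant of Rho activation (LARG* units).
#' @param v_off_rho Maximal Rho deactivation rate per unit GAP* (1/s).
#' @param km_off_rho Michaelis constant of Rho deactivation (Rho* units).
#' @return An object of class `rho_circuit_params`.
#' @seealso [ref_circuit_params()] for the published per-condition columns.
#' @export
rho_circuit_params <- function(variant = c("WT", "KO"), v_on_gap,
                               km_gap = NULL, k_off_gap, v_on_rho,
                               km_on_rho, v_off_rho, km_off_rho) {
  variant <- match.arg(variant)
  vals <- c(v_on_gap = v_on_gap, k_off_gap = k_off_gap,
            v_on_rho = v_on_rho, km_on_rho = km_on_rho,
            v_off_rho = v_off_rho, km_off_rho = km_off_rho)
  if (variant == "WT") {
    if (is.null(km_gap))
      stop("WT variant requires km_gap")
    vals <- c(vals, km_gap = km_gap)
  } else if (!is.null(km_gap)) {
    stop("km_gap is structurally absent in the KO variant; leave it NULL")
  }
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all circuit parameters must be strictly positive and finite")
  structure(c(list(variant = variant), as.list(vals)),
            class = "rho_circuit_params")
}

#' @export
print.rho_circuit_params <- function(x, ...) {
  cat("<rho_circuit_params>", x$variant, "\n")
  v <- unlist(x[circuit_param_names(x$variant)])
  print(signif(v, 6))
  invisible(x)
}

circuit_param_names <- function(variant) {
  if (variant == "WT") {
    c("v_on_gap", "km_gap", "k_off_gap", "v_on_rho", "km_on_rho",
      "v_off_rho", "km_off_rho")
  } else {
    c("v_on_gap", "k_off_gap", "v_on_rho", "km_on_rho", "v_off_rho",
      "km_off_rho")
  }
}

#' Published circuit parameter estimates per condition
#'
#' Reference parameter columns from fits of the circuit model to the
#' pooled pulse-response data, one column per experimental condition:
#' plasma membrane or focal adhesion compartment, wild type or DLC1
#' knockout. In the knockout columns the Michaelis constant of
#' Rho-dependent GAP activation converged to zero and the reduced model is
#' used, with `v_on_gap` reinterpreted as the constitutive GAP activation
#' constant.
#'
#' @param condition One of `"membrane_wt"`, `"membrane_ko"`, `"fa_wt"`,
#'   `"fa_ko"`.
#' @return A [rho_circuit_params()] object.
#' @export
ref_circuit_params <- function(condition = c("membrane_wt", "membrane_ko",
                                             "fa_wt", "fa_ko")) {
  condition <- match.arg(condition)
  switch(condition,
    membrane_wt = rho_circuit_params(
      "WT", v_on_gap = 25.2255, km_gap = 0.093982, k_off_gap = 66.0697,
      v_on_rho = 0.0061944, km_on_rho = 0.0118618, v_off_rho = 25.2258,
      km_off_rho = 60.6878),
    membrane_ko = rho_circuit_params(
      "KO", v_on_gap = 21.51569, k_off_gap = 68.84138,
      v_on_rho = 0.00997069, km_on_rho = 0.031674, v_off_rho = 21.5156,
      km_off_rho = 94.83013),
    fa_wt = rho_circuit_params(
      "WT", v_on_gap = 33.706, km_gap = 0.205939, k_off_gap = 99.9969,
      v_on_rho = 0.00457155, km_on_rho = 0.0108763, v_off_rho = 26.7483,
      km_off_rho = 76.8346),
    fa_ko = rho_circuit_params(
      "KO", v_on_gap = 15.6152, k_off_gap = 59.1818,
      v_on_rho = 0.00759578, km_on_rho = 0.0382543, v_off_rho = 15.6151,
      km_off_rho = 98.2568))
}

# ---- low-level solver ------------------------------------------------------

# Build the 16-slot parameter vector consumed by the compiled RHS.
# variant_code: 0 WT, 1 KO, 2 QSS-WT, 3 QSS-KO.
pack_params <- function(larg, circuit_vec, variant_code, protocol) {
  c(larg$k_on, larg$k_off,
    circuit_vec[["v_on_gap"]],
    if (variant_code %in% c(0, 2)) circuit_vec[["km_gap"]] else 0,
    circuit_vec[["k_off_gap"]], circuit_vec[["v_on_rho"]],
    circuit_vec[["km_on_rho"]], circuit_vec[["v_off_rho"]],
    circuit_vec[["km_off_rho"]], variant_code,
    protocol$t_start, protocol$light_duration, protocol$amplitude,
    if (protocol$input_shape == "boxcar") 0 else 1,
    protocol$decay_rate, 0)
}

# Integrate the compiled system piecewise between input breakpoints so the
# discontinuous light input never sits inside an integrator step.
solve_circuit <- function(pp, protocol, times = protocol_times(protocol),
                          rtol = 1e-8, atol = 1e-10) {
  breaks <- protocol_breaks(protocol)
  breaks <- breaks[breaks > 0 & breaks < protocol$t_end]
  edges <- sort(unique(c(0, breaks, protocol$t_end)))
  y <- c(larg = 0, gap = 0, rho = 0)
  segs <- vector("list", length(edges) - 1L)
  boxcar <- pp[14] < 0.5
  t_on <- pp[11]
  t_off <- pp[11] + pp[12]
  for (i in seq_len(length(edges) - 1L)) {
    tt <- times[times >= edges[i] & times <= edges[i + 1]]
    tt <- sort(unique(c(edges[i], tt, edges[i + 1])))
    # freeze the input shape within the segment so the integrator never
    # samples the discontinuity when it oversteps an output time
    pseg <- pp
    mid <- (edges[i] + edges[i + 1]) / 2
    if (boxcar) {
      if (mid >= t_on && mid < t_off) {
        pseg[11] <- -1e30 # always on in this segment
        pseg[12] <- 1e300
      } else {
        pseg[13] <- 0 # off
      }
    } else if (mid < t_on) {
      pseg[13] <- 0
    }
    out <- try(suppressWarnings(
      deSolve::ode(y, tt, func = "rhoflux_derivs", parms = pseg,
                   dllname = "rhoflux", initfunc = "rhoflux_init",
                   method = "lsoda", rtol = rtol, atol = atol,
                   maxsteps = 20000)), silent = TRUE)
    if (inherits(out, "try-error") || nrow(out) < length(tt) ||
        any(!is.finite(out[, -1])))
      stop("circuit_solver_error: integration failed in segment [",
           edges[i], ", ", edges[i + 1], "] s", call. = FALSE)
    y <- out[nrow(out), -1]
    segs[[i]] <- out[out[, 1] %in% times & out[, 1] < edges[i + 1], ,
                     drop = FALSE]
    if (i == length(edges) - 1L && edges[i + 1] %in% times)
      segs[[i]] <- rbind(segs[[i]], out[nrow(out), ])
  }
  res <- do.call(rbind, segs)
  states <- res[, c("larg", "gap", "rho"), drop = FALSE]
  neg_tol <- 100 * atol
  if (any(states < -neg_tol))
    stop("circuit_solver_error: negative state beyond tolerance (min ",
         signif(min(states), 3), ")", call. = FALSE)
  states[states < 0] <- 0
  list(t = res[, 1], larg = states[, "larg"], gap = states[, "gap"],
       rho = states[, "rho"])
}

make_trajectory <- function(sol, larg, circuit, protocol) {
  structure(list(t = sol$t, larg = sol$larg, gap = sol$gap, rho = sol$rho,
                 observation = 1 + sol$rho,
                 params_used = list(larg = larg, circuit = circuit),
                 protocol = protocol),
            class = "model_trajectory")
}

#' Simulate optoLARG recruitment (linear model)
#'
#' Numerically integrates the linear recruitment model
#' `dLARG*/dt = k_on f_signal(t) - k_off LARG*` with zero initial
#' condition on the protocol's sampling grid. The GAP and Rho states of the
#' returned trajectory are identically zero.
#'
#' @param params A [larg_params()] object.
#' @param protocol A [stimulus_protocol()].
#' @param rtol,atol Solver tolerances.
#' @return A `model_trajectory` (fields `t`, `larg`, `gap`, `rho`,
#'   `observation`, `params_used`, `protocol`).
#' @export
simulate_larg <- function(params, protocol, rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(params, "larg_params"),
            inherits(protocol, "stimulus_protocol"))
  dummy <- c(v_on_gap = 1, km_gap = 1, k_off_gap = 1, v_on_rho = 1e-30,
             km_on_rho = 1, v_off_rho = 1, km_off_rho = 1)
  pp <- pack_params(params, dummy, 0, protocol)
  sol <- solve_circuit(pp, protocol, rtol = rtol, atol = atol)
  sol$gap <- sol$gap * 0
  sol$rho <- sol$rho * 0
  make_trajectory(sol, params, NULL, protocol)
}

#' Closed-form recruitment trace for a boxcar protocol
#'
#' Piecewise analytic solution of the linear recruitment model under a
#' boxcar input: a saturating rise
#' `(k_on/k_off) (1 - exp(-k_off (t - t_start))) * amplitude` during the
#' light window and exponential decay after light-off.
#'
#' @inheritParams simulate_larg
#' @param t Times (s) at which to evaluate.
#' @return Numeric vector of LARG* values.
#' @export
larg_closed_form <- function(params, protocol, t = protocol_times(protocol)) {
  stopifnot(protocol$input_shape == "boxcar")
  t0 <- protocol$t_start
  t1 <- t0 + protocol$light_duration
  plateau <- params$k_on / params$k_off * protocol$amplitude
  y <- numeric(length(t))
  during <- t >= t0 & t <= t1
  after <- t > t1
  y[during] <- plateau * (1 - exp(-params$k_off * (t[during] - t0)))
  y_off <- plateau * (1 - exp(-params$k_off * (t1 - t0)))
  y[after] <- y_off * exp(-params$k_off * (t[after] - t1))
  y
}

#' Simulate the GEF-Rho-GAP circuit
#'
#' Integrates the three-species circuit (recruited GEF, active GAP, active
#' Rho) from zero initial conditions under the protocol's light input. The
#' inactive pools are treated as constant, so they never appear as states.
#' A stiff-capable solver is used throughout: GAP relaxes on a
#' `1/k_off_gap` timescale (10-20 ms for the published parameter sets)
#' against a several-hundred-second horizon.
#'
#' @param larg_params A [larg_params()] object.
#' @param circuit_params A [rho_circuit_params()] object.
#' @param protocol A [stimulus_protocol()].
#' @param rtol,atol Solver tolerances (relative / absolute). Values in
#'   `(-100 * atol, 0)` are clamped to zero after solving; larger negative
#'   states raise an error.
#' @return A `model_trajectory`; its `observation` field is the fold-change
#'   readout `1 + Rho*`.
#' @export
simulate_circuit <- function(larg_params, circuit_params, protocol,
                             rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(larg_params, "larg_params"),
            inherits(circuit_params, "rho_circuit_params"),
            inherits(protocol, "stimulus_protocol"))
  code <- if (circuit_params$variant == "WT") 0 else 1
  vec <- unlist(circuit_params[circuit_param_names(circuit_params$variant)])
  if (circuit_params$variant == "KO") vec <- c(vec, km_gap = 0)
  pp <- pack_params(larg_params, vec, code, protocol)
  sol <- solve_circuit(pp, protocol, rtol = rtol, atol = atol)
  make_trajectory(sol, larg_params, circuit_params, protocol)
}

#' Fold-change observation of a trajectory
#'
#' Maps the latent Rho* state to the biosensor readout scale. Simulations
#' start from zero activity while measured traces are normalised to a
#' baseline of 1, so the minimal consistent observation map is
#' `1 + Rho*(t)`.
#'
#' @param trajectory A `model_trajectory`.
#' @return Numeric vector, the fold-change trace on the sampling grid.
#' @export
to_observation <- function(trajectory) {
  stopifnot(inherits(trajectory, "model_trajectory"))
  if (is.null(trajectory$rho)) stop("trajectory has no rho states")
  1 + trajectory$rho
}

#' @export
print.model_trajectory <- function(x, ...) {
  cat("<model_trajectory>", length(x$t), "samples,",
      sprintf("t in [%g, %g] s; peak Rho* %.4g\n", min(x$t), max(x$t),
              max(x$rho)))
  invisible(x)
}

#' @export
as.data.frame.model_trajectory <- function(x, ...) {
  data.frame(t = x$t, larg = x$larg, gap = x$gap, rho = x$rho,
             observation = x$observation)
}
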