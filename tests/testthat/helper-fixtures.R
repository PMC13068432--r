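# shared fixtures, computed once per test run

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, fn) {
  if (!exists(name, envir = .fixtures))
    assign(name, fn(), envir = .fixtures)
  get(name, envir = .fixtures)
}

default_protocol <- function() stimulus_protocol()

noiseless_trajectory <- function(condition) {
  fixture(paste0("traj_", condition), function()
    simulate_circuit(ref_larg_params(), ref_circuit_params(condition),
                     default_protocol(), rtol = 1e-10, atol = 1e-12))
}

noiseless_trace <- function(condition) {
  traj <- noiseless_trajectory(condition)
  data.frame(t = traj$t, value = traj$observation)
}

# best WT fit to noiseless membrane data, reused across files
membrane_wt_fit <- function() {
  fixture("fit_membrane_wt", function()
    fit_rho_circuit(noiseless_trace("membrane_wt"), ref_larg_params(),
                    "WT", default_protocol(), seed = 1L))
}

relerr <- function(est, truth) abs(est - truth) / abs(truth)

match_centers <- function(detected, truth, tol = 5) {
  if (nrow(detected) == 0 || nrow(truth) == 0)
    return(list(precision = NA, recall = NA))
  cross <- outer(seq_len(nrow(detected)), seq_len(nrow(truth)),
                 Vectorize(function(i, j)
                   sqrt(sum((detected[i, ] - truth[j, ])^2))))
  list(precision = mean(apply(cross, 1, min) <= tol),
       recall = mean(apply(cross, 2, min) <= tol))
}

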