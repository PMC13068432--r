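#!/usr/bin/env Rscript
# Two-stage estimation: recruitment kinetics first, then the circuit
# parameters with the GEF profile frozen. Round-trips every condition on
# its noiseless trace, fits the noisy membrane WT median as a realism
# check, and runs the feedback-loss test (full vs reduced model on
# knockout-generated data).

suppressMessages(library(rhoflux))
dir.create("results", showWarnings = FALSE)

protocol <- stimulus_protocol()
larg_true <- ref_larg_params()
seed <- 1L

rec <- simulate_larg(larg_true, protocol, rtol = 1e-10, atol = 1e-12)
larg_fit <- fit_larg_kinetics(data.frame(t = rec$t, value = rec$larg),
                              protocol, seed = seed)
write_fit_result(larg_fit, "results/03_fit_larg.json")
cat(sprintf("recruitment fit: k_on %.7f (true %.7f), k_off %.7f (true %.7f)\n",
            larg_fit$estimates[["k_on"]], larg_true$k_on,
            larg_fit$estimates[["k_off"]], larg_true$k_off))

for (cond in c("membrane_wt", "membrane_ko", "fa_wt", "fa_ko")) {
  truth <- ref_circuit_params(cond)
  traj <- simulate_circuit(larg_true, truth, protocol,
                           rtol = 1e-10, atol = 1e-12)
  fit <- fit_rho_circuit(data.frame(t = traj$t, value = traj$observation),
                         larg_fit, truth$variant, protocol, seed = seed)
  write_fit_result(fit, sprintf("results/03_fit_%s.json", cond))
  well <- intersect(c("km_gap", "v_on_rho", "km_on_rho"),
                    names(fit$estimates))
  rel <- sapply(well, function(p)
    abs(fit$estimates[[p]] - truth[[p]]) / truth[[p]])
  cat(sprintf("%-12s loss %.2e; recovery of %s: %s\n", cond, fit$loss,
              paste(well, collapse = "/"),
              paste(sprintf("%.2f%%", 100 * rel), collapse = "/")))
}

# the feedback-loss signature: fitting the full model to data from the
# reduced circuit collapses the feedback Michaelis constant to its bound
ko_traj <- simulate_circuit(larg_true, ref_circuit_params("membrane_ko"),
                            protocol, rtol = 1e-10, atol = 1e-12)
cmp <- compare_variants(data.frame(t = ko_traj$t,
                                   value = ko_traj$observation),
                        larg_fit, protocol, seed = seed + 1L)
cat(sprintf("feedback test on KO data: km_gap -> %.2g (lower bound %.2g), preferred variant %s\n",
            cmp$wt$estimates[["km_gap"]],
            cmp$wt$bounds_used$lower[["km_gap"]], cmp$preferred))
write_fit_result(cmp$wt, "results/03_fit_wt_on_ko_data.json")

# noisy-data realism check on the membrane WT median
ens <- generate_roi_ensemble(simulate_circuit(larg_true,
        ref_circuit_params("membrane_wt"), protocol),
        noise_model(), n_roi = 2000, seed = 77)
agg <- aggregate_ensemble(ens, protocol$baseline_window, n_boot = 200,
                          seed = 78)
fit_noisy <- fit_rho_circuit(agg, larg_fit, "WT", protocol,
                             seed = seed + 2L)
write_fit_result(fit_noisy, "results/03_fit_membrane_wt_noisy.json")
truth <- ref_circuit_params("membrane_wt")
cat(sprintf("noisy membrane WT fit: km_gap %.4f (true %.4f), v_on_rho %.5f (true %.5f)\n",
            fit_noisy$estimates[["km_gap"]], truth$km_gap,
            fit_noisy$estimates[["v_on_rho"]], truth$v_on_rho))
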