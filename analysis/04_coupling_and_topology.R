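#!/usr/bin/env Rscript
# Interlayer coupling strengths and interlayer topology near the resonance
# optimum (D = 10): the inhibitory-axon coupling K_IE at fixed K_EI = 0.2,
# and the locality exponent delta of the vertex-fitness wiring.

library(fhnlayers)
dir.create("results", showWarnings = FALSE)
dp <- dynamics_params(D = 10)

sp_k <- sweep_spec(list(K_IE = seq(0.05, 0.4, by = 0.05)),
                   network_params(), dynamics_params(D = 10, K_EI = 0.2),
                   coherence_config(), n_realizations = 10,
                   base_seed = 20261006L)
r_k <- run_sweep(sp_k, verbose = TRUE)
write_sweep_result(r_k, sp_k, "results/sweep_K_IE.tsv")
tk <- trend_check(r_k, "K_IE", "increasing")
cat(sprintf("\nK_IE trend: Spearman rho = %.2f (%s); the gain is larger in the\n",
            tk$rho, if (tk$pass) "pass" else "FAIL"))
cat(sprintf("excitatory layer (T_bar_E %.2f -> %.2f) than in the inhibitory layer (%.2f -> %.2f)\n\n",
            r_k$T_bar_E[1], r_k$T_bar_E[nrow(r_k)],
            r_k$T_bar_I[1], r_k$T_bar_I[nrow(r_k)]))

sp_d <- sweep_spec(list(delta = c(0.25, 0.5, 1, 2, 4, 10)),
                   network_params(), dp, coherence_config(),
                   n_realizations = 10, base_seed = 20261007L)
r_d <- run_sweep(sp_d, verbose = TRUE)
write_sweep_result(r_d, sp_d, "results/sweep_delta.tsv")
cat(sprintf("\nT_bar at delta = 0.5: %.2f vs delta = 10: %.2f -> heterogeneous\n",
            r_d$T_bar[r_d$delta == 0.5], r_d$T_bar[r_d$delta == 10]))
cat("(scale-free-like) interlayer wiring sustains more regular activity\n")
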