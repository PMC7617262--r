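#!/usr/bin/env Rscript
# Fixed-T1 bias study: how much does assuming T1 = 2.6 s during dictionary
# T2 matching bias the estimate? Samples 20 000 fine-grid entries, matches
# them with the fixed T1, and summarises |relative bias| per (T1, B1) cell
# and over the neonatal region of interest (2 s < T1 < 3.5 s, B1rel > 0.5).

suppressMessages(library(neorelax))
dir.create("results", showWarnings = FALSE)

message("Building reduced-fidelity dictionary ...")
grid <- isochromat_grid(n_readout = 15, n_slice = 101)
fd <- interpolate_dictionary(build_dictionary(tse_protocol(), grid,
                                              pulse_model()))

message("Sampling and matching 20 000 dictionary entries ...")
bias <- estimate_fixed_t1_bias(fd, n_samples = 20000, seed = 42)
write.csv(bias$by_region, "results/03_bias_by_region.csv", row.names = FALSE)

p95 <- 100 * max_bias_in_region(bias)
mx <- 100 * max_bias_in_region(bias, statistic = "max")
message(sprintf(
  "Region 2 s < T1 < 3.5 s, B1rel > 0.5: p95 |bias| = %.2f %% (sample max %.1f %%,",
  p95, mx))
message("  the sample max is dominated by 1-ms grid quantisation at T2 < 30 ms)")
out <- 100 * quantile(abs(bias$samples$bias[bias$samples$b1 <= 0.5]), 0.95)
message(sprintf("Outside (B1rel <= 0.5) the p95 rises to %.1f %%.", out))
message("Wrote results/03_bias_by_region.csv")
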