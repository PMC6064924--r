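#!/usr/bin/env Rscript
# Solver validation against closed-form laminar solutions.
#
# 1. Steady straight channel: wall shear vs plane Poiseuille (6 eta U / h)
#    at 32/64/128 transverse cells, with the observed convergence order.
# 2. Pulsatile straight channel (alpha ~ 3.5): final-cycle wall shear
#    series vs the Womersley plane-channel oracle, driven by the same mean
#    velocity waveform through the analytic gradient transfer function.

suppressPackageStartupMessages(library(aortashear))
dir.create("results", showWarnings = FALSE)

blood <- fluid_properties()
h <- 0.00158
sp <- outlet_split(c(main = 1))

# --- steady convergence ------------------------------------------------------
tt <- seq(0, 0.1, length.out = 17L)[1:16]
cw <- fit_bezier_waveform(sampled_waveform(tt, rep(0.1, 16L), 0.1), 1L)
exact <- plane_poiseuille_wss(blood, 0.1, h)
rows <- lapply(c(32L, 64L, 128L), function(ny) {
  g <- build_channel(6 * h, h, 24L, ny, NULL)
  rec <- run_cycles(g, blood, cw, sp, n_cycles = 8L, steps_per_cycle = 200L,
                    initial = "developed")
  mid <- abs(rec$position[, 1] - 3 * h) < 0.5 * h
  d <- attr(rec, "diagnostics")
  data.frame(ny = ny, wss_sim_pa = mean(tawss(rec)[mid]), wss_exact_pa = exact,
             rel_error = abs(mean(tawss(rec)[mid]) - exact) / exact,
             max_divergence = d$max_divergence)
})
steady <- do.call(rbind, rows)
steady$order <- c(NA, -diff(log2(steady$rel_error)))
write.csv(steady, "results/validation_poiseuille.csv", row.names = FALSE)
print(steady)
cat(sprintf("observed convergence order: %.2f\n",
            -coef(lm(log2(rel_error) ~ seq_along(rel_error), steady))[[2]]))

# --- pulsatile Womersley comparison -----------------------------------------
T <- 0.1
wt <- seq(0, T, length.out = 65L)[1:64]
bw <- fit_bezier_waveform(sampled_waveform(wt, 0.04 + 0.03 * cos(2 * pi * wt / T), T), 8L)
alpha <- womersley_number(h / 2, 2 * pi / T, blood)
g <- build_channel(16 * h, h, 64L, 64L, NULL)
rec <- run_cycles(g, blood, bw, sp, n_cycles = 3L, steps_per_cycle = 1000L)
oracle <- womersley_channel_wss_series(
  channel_gradient_for_waveform(bw, h, blood, 6L), h, blood, 1000L)
mid <- abs(rec$position[, 1] - 8 * h) < 2.5 * h & rec$position[, 2] < 1e-12
sim <- colMeans(rec$tau_x[mid, , drop = FALSE])
rms <- sqrt(mean((sim - oracle$tau_pa)^2)) / sqrt(mean(oracle$tau_pa^2))
cat(sprintf("alpha = %.2f, Womersley RMS error = %.2f%%\n", alpha, 100 * rms))
write.csv(data.frame(time_s = oracle$time_s, tau_oracle_pa = oracle$tau_pa,
                     tau_solver_pa = sim),
          "results/validation_womersley_series.csv", row.names = FALSE)
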