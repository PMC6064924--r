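#!/usr/bin/env Rscript
# Inlet waveform: build the canonical murine systolic-pulse waveform
# (0.1 s cycle, 1 m/s peak), fit periodic cubic Bezier splines of
# increasing segment count, and record the fit residuals. The 10-segment
# fit is the inlet condition used by the solver runs in 02 and 03.

suppressPackageStartupMessages(library(aortashear))
dir.create("results", showWarnings = FALSE)

sw <- default_mouse_waveform(period_T = 0.1, peak = 1.0)
write_waveform_csv(sw, "results/inlet_waveform_samples.csv")

segs <- c(2L, 4L, 6L, 8L, 10L, 12L, 16L)
res <- sapply(segs, function(n) attr(fit_bezier_waveform(sw, n), "rms_residual"))
tab <- data.frame(n_segments = segs, rms_residual_m_s = res)
write.csv(tab, "results/waveform_fit_residuals.csv", row.names = FALSE)
print(tab)

bw <- fit_bezier_waveform(sw, 10L)
write_bezier_json(bw, "results/inlet_waveform_bezier.json")
gap <- abs(evaluate_waveform(bw, 0) - evaluate_waveform(bw, bw$period - 1e-12))
cat(sprintf("10-segment fit: RMS residual %.3g m/s, periodic closure gap %.2e m/s\n",
            attr(bw, "rms_residual"), gap))
cat(sprintf("peak %.3f m/s, cycle mean %.3f m/s\n",
            max(evaluate_waveform(bw, seq(0, 0.1, 1e-4))),
            mean(evaluate_waveform(bw, seq(0, 0.1, length.out = 1001)[1:1000]))))
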