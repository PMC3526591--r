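#!/usr/bin/env Rscript
# Characterize the chemoattractant gradient in the three-section chamber:
# solve the finite-difference model, compare it with the semi-infinite
# closed form over the 2 h assay window, and tabulate the membrane-gel
# interface concentration.

suppressPackageStartupMessages(library(gradchamber))
dir.create("results", showWarnings = FALSE)
dir.create("scratch", showWarnings = FALSE)

field <- solve_chamber_1d()   # default geometry, D = 2e-6 cm^2/s
write_field_csv(field, "scratch/field_full.csv")  # full grid, bulky

# interface concentration over time: the reservoir feeds the gel through a
# membrane held near C0/2
iface <- data.frame(t_s = field$t_s, c_norm = eval_field(field, 0, field$t_s))
write.csv(iface, "results/interface_series.csv", row.names = FALSE)
cat(sprintf("interface C/C0 over 0-2 h: min %.4f, max %.4f (target 0.5)\n",
            min(iface$c_norm), max(iface$c_norm)))

# closed form vs numeric at the imaged distances
g <- expand.grid(y_mm = c(2, 3, 5), t_s = seq(60, 7200, by = 60))
g$c_numeric <- eval_field(field, g$y_mm, g$t_s)
g$c_closed <- closed_form_profile(g$y_mm, g$t_s)
g$abs_diff <- abs(g$c_numeric - g$c_closed)
write.csv(g, "results/closed_vs_numeric.csv", row.names = FALSE)
cat(sprintf("max |numeric - closed form| on C/C0 scale: %.2e\n",
            max(g$abs_diff)))
sel <- g$c_closed > 0.05
cat(sprintf("max relative discrepancy where C/C0 > 0.05: %.3f%%\n",
            100 * max(g$abs_diff[sel] / g$c_closed[sel])))

# mass conservation audit of the no-flux solve
cat(sprintf("relative mass drift across the solve: %.2e\n",
            max(abs(field$mass - field$mass[1])) / field$mass[1]))
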