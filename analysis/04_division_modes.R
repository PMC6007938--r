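#!/usr/bin/env Rscript
# Can burden moments distinguish imperfect asymmetric segregation from
# perfect segregation plus symmetric differentiation/self-renewal pairs?
# Compares N = 5000, p = 0.9 asymmetric vs p = 1 with a 10% symmetric mix.
# Optional argument: a seed (default 1).

library(strandseg)

seed <- if (length(commandArgs(TRUE)) >= 1) {
  as.integer(commandArgs(TRUE)[1])
} else 1L
dir.create("results", showWarnings = FALSE)

cmp <- division_mode_comparison(n_replicates = 30, n_cells = 5000,
                                p_asym = 0.9, symmetric_fraction = 0.1,
                                mu_L = 6, n_steps = 150, seed = seed)

write.table(cmp$ci, "results/division_mode_ratio_ci.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(cmp$ratio_var_trend, "results/division_mode_ratio_var_trend.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

cat("Time-averaged variance/mean ratio (95% CI over 30 replicates):\n")
for (i in seq_len(nrow(cmp$ci))) {
  cat(sprintf("  %-14s %.2f (%.2f; %.2f)\n", cmp$ci$mode[i],
              cmp$ci$mean_ratio[i], cmp$ci$ci_low[i], cmp$ci$ci_high[i]))
}
cat("Trend of the across-replicate ratio variance over time:\n")
for (i in seq_len(nrow(cmp$ratio_var_trend))) {
  cat(sprintf("  %-14s slope %+.4f, one-sided p = %.3g\n",
              cmp$ratio_var_trend$mode[i], cmp$ratio_var_trend$var_slope[i],
              cmp$ratio_var_trend$p_one_sided[i]))
}
cat("\nThe two mechanisms share the mean trend and the average dispersion\n")
cat("ratio; only the spread of the ratio across replicate populations grows\n")
cat("with time under symmetric divisions - a (data-hungry) discriminator.\n")
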