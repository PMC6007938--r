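#!/usr/bin/env Rscript
# What happens when division-independent (background) mutations violate the
# model? Simulates true p = 0.95, mu*L = 6 with increasing background rates
# and re-infers the parameters assuming all mutations are division-linked.
# Optional argument: a seed (default 1).

library(strandseg)

seed <- if (length(commandArgs(TRUE)) >= 1) {
  as.integer(commandArgs(TRUE)[1])
} else 1L
dir.create("results", showWarnings = FALSE)

bias <- background_bias_table(backgrounds = c(0, 0.5, 1, 2),
                              p_true = 0.95, mu_L_true = 6,
                              n_cells = 2000, n_steps = 200, seed = seed)
write.table(signif(bias, 6), "results/background_bias.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

cat("Inferred parameters vs background rate (true p = 0.95, mu*L = 6):\n")
for (i in seq_len(nrow(bias))) {
  cat(sprintf("  background %.1f /region/div-time -> p_hat = %.3f, muL_hat = %.3g\n",
              bias$background[i], bias$p_hat[i], bias$muL_hat[i]))
}
cat("\nAny positive background pushes p_hat below truth, increasingly so as\n")
cat("the background grows: the published p values are therefore conservative\n")
cat("lower bounds if background mutagenesis is non-negligible.\n")
cat("Wrote results/background_bias.tsv\n")
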