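#!/usr/bin/env Rscript
# Step 3: estimate the C4 dietary fraction per two-month interval with the
# Bayesian mixing model (MCMC engine, quadrature cross-check) and document
# how the winter exemplar maps to dietary percentages across plausible
# spacing/source choices.

suppressPackageStartupMessages(library(isofodder))
obs <- read.csv("results/bimonthly_diet.csv")
src <- default_sources()
seed <- 42

mix <- run_mixing_by_group(obs, src, engine = "mcmc", seed = seed)
write.csv(mix, "results/mixing_results.csv", row.names = FALSE)
cat("Bimonthly C4 dietary fractions (posterior mean [90% CI]):\n")
for (i in seq_len(nrow(mix))) {
  cat(sprintf("  %-8s n=%d  %.3f [%.3f, %.3f]  Rhat %.3f\n",
              mix$bimonth[i], mix$n[i], mix$p_mean[i], mix$p_lo90[i],
              mix$p_hi90[i], mix$rhat_p[i]))
}

grid <- run_mixing_by_group(obs, src, engine = "grid")
cat(sprintf("\nmax |MCMC - quadrature| posterior mean: %.4f\n",
            max(abs(mix$p_mean - grid$p_mean))))

scan <- sensitivity_scan(-6, spacings = seq(13, 15, by = 0.5),
                         c3_means = seq(-26, -22, by = 1))
write.csv(scan, "results/sensitivity_scan.csv", row.names = FALSE)
in_band <- scan[scan$p_mean >= 0.44 & scan$p_mean <= 0.50, ]
cat(sprintf("\nsensitivity: winter exemplar -6 permil spans %.1f-%.1f%% C4 over %d parameterisations;\n",
            100 * min(scan$p_mean), 100 * max(scan$p_mean), nrow(scan)))
cat(sprintf("  %d parameterisation(s) fall in the 44-50%% band\n",
            nrow(in_band)))
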