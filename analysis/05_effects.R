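#!/usr/bin/env Rscript
# Posterior summaries of the six stimulation-shift parameters on the
# selected (Kahneman-Tversky) specification: means, 89%/95% credible
# intervals, Savage-Dickey Bayes factors and evidence labels.
# Writes results/effects/.

suppressPackageStartupMessages(library(rdurisk))
out <- file.path("results", "effects")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

trials_path <- file.path("results", "simulation", "trials.tsv")
if (!file.exists(trials_path))
  stop("run analysis/02_simulate.R first", call. = FALSE)
trials <- read_trials(trials_path)

fit <- fit_rdu(trials, "kahneman_tversky", "gain", mcmc_config("test"),
               seed = 12)
tab <- effect_table(fit)
print(tab, digits = 3)
write.table(tab, file.path(out, "effect_table.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

base <- do.call(rbind, lapply(c("mu_r0", "mu_gamma0", "mu_tau0"), function(p) {
  smp <- as.vector(fit$draws[, , p])
  ci <- credible_interval(smp, 0.95)
  data.frame(parameter = p, mean = mean(smp), ci95_lower = ci[1],
             ci95_upper = ci[2])
}))
cat("baseline group-level parameters:\n")
print(base, digits = 3, row.names = FALSE)
write.table(base, file.path(out, "baselines.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
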