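#!/usr/bin/env Rscript
# Re-fit the three specifications (fits are cheap at desk scale), compare
# them by LOOIC/WAIC and run the posterior predictive accuracy check on
# the winner. Writes results/comparison/.

suppressPackageStartupMessages(library(rdurisk))
out <- file.path("results", "comparison")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

trials_path <- file.path("results", "simulation", "trials.tsv")
if (!file.exists(trials_path))
  stop("run analysis/02_simulate.R first", call. = FALSE)
trials <- read_trials(trials_path)

cfg <- mcmc_config("test")
fits <- sapply(weighting_families(), function(fam)
  fit_rdu(trials, fam, "gain", cfg,
          seed = 10 + match(fam, weighting_families())),
  simplify = FALSE)

cmp <- compare_models(fits)
print(cmp)
write.table(cmp$table, file.path(out, "criteria.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

ppc <- ppc_accuracy(fits[[cmp$selected]], n_samples = 1000, seed = 4)
cat(sprintf("selected %s: PPC accuracy median %.3f, 95%% CI [%.3f, %.3f]\n",
            cmp$selected, ppc$median, ppc$ci95[1], ppc$ci95[2]))
writeLines(jsonlite::toJSON(list(selected = cmp$selected,
                                 ppc_median = ppc$median,
                                 ppc_ci95 = ppc$ci95),
                            auto_unbox = TRUE, digits = NA, pretty = TRUE),
           file.path(out, "ppc.json"))
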