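#!/usr/bin/env Rscript
# Fit the joint model to the tables written by 01_simulate.R: assemble the
# dataset, run MCMC, check convergence, and write posterior summaries, the
# run manifest and the draws needed by the LTRE step.
#
# Chain lengths here are validation-scale; pass --preset paper for the
# full protocol (4 chains, 40k adapt / 20k burn-in / 80k retained, thin 4).

library(songbirdIPM)

args <- commandArgs(trailingOnly = TRUE)
preset <- if ("--preset" %in% args) args[which(args == "--preset") + 1] else "reduced"
seed <- 20260303
out <- "results"

counts <- load_counts(file.path(out, "counts.csv"))
captures <- load_captures(file.path(out, "captures.csv"),
                          file.path(out, "stations.csv"))
captures <- filter_min_station_years(captures, 4)
ages <- load_ages(file.path(out, "ages.csv"))
covariates <- load_covariate_table(file.path(out, "covariates.csv"))
meta <- stratum_meta(read.csv(file.path(out, "strata.csv")))
dataset <- assemble_dataset(counts, captures, ages, covariates, meta)
print(dataset)

settings <- if (preset == "paper") mcmc_settings("paper") else
  mcmc_settings(chains = 2, adapt = 500, burn = 500, draws = 1000)
fit <- sample_posterior(dataset, settings, seed = seed)

conv <- convergence_check(fit)
cat(sprintf("\nmax split R-hat: %.3f (pass threshold 1.1): %s\n",
            max(conv$rhat), ifelse(attr(conv, "pass"), "PASS", "NOT CONVERGED")))

summ <- summarize_posterior(fit)
write_posterior_csv(summ, file.path(out, "posterior_summary.csv"))
write_run_manifest(fit, file.path(out, "run_manifest.json"))
saveRDS(list(fit = fit, summary = summ), file.path(out, "fit.rds"))

cat("\nPopulation trends (%/yr, posterior mean [95% CrI]):\n")
print(transform(summ$trend, mean = round(mean, 2), q2.5 = round(q2.5, 2),
                q97.5 = round(q97.5, 2))[, c("stratum", "mean", "q2.5", "q97.5")])
cat("\nMean adult apparent survival (phi0) by stratum:\n")
p <- summ$params
print(p[grep("^phi0", p$parameter), c("parameter", "mean", "q2.5", "q97.5")],
      row.names = FALSE, digits = 3)
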