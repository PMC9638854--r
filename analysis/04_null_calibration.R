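#!/usr/bin/env Rscript
# Calibration of the regional comparison under the null: when organizer and
# non-organizer regions share identical kinetics, the Kruskal-Wallis test
# on fitted half-lives should stay non-significant. 100 seeded 26-disc
# cohorts are simulated at trace level (4PL + Gaussian trace noise,
# SD 0.005) and the p-value distribution is summarised.

suppressPackageStartupMessages(library(fretkin))

kin_null <- list(region_kinetics("ORG", 0.2827, 0.6, 30, -2.3),
                 region_kinetics("NO", 0.2827, 0.6, 30, -2.3))

ps <- vapply(1:100, function(r) {
  tr <- simulate_cohort_traces(kin_null, n_discs = 26, n_frames = 130,
                               drug_time_min = 10, noise_sigma = 0.005,
                               seed = 5000 + r)
  fits <- fit_cohort(tr)
  compare_fits(fits, c("ORG", "NO"), "t_half", "kruskal")$p_value
}, 1)

dir.create("results", showWarnings = FALSE)
utils::write.csv(data.frame(run = seq_along(ps), p_value = ps),
                 "results/null_calibration.csv", row.names = FALSE)

cat(sprintf("equal-kinetics null, 100 runs: p > 0.05 in %d%% of runs\n",
            round(100 * mean(ps > 0.05))))
cat(sprintf("  p-value quartiles: %.3f / %.3f / %.3f\n",
            quantile(ps, 0.25), median(ps), quantile(ps, 0.75)))
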