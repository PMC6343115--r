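#!/usr/bin/env Rscript

# Step 4 — excess statistics with bootstrap-percentile intervals.
#
# Point estimands per outcome and subgroup: mean difference between observed
# and expected scores, ratio of the two means, standardized effect size
# (difference over the SD of the observed scores), and excess caseness for
# the distress scale. 95% intervals come from 10 000 doubly-stratified
# resamples (reference within gender, cohort within gender x group), with
# the expectation table rebuilt inside every resample so that reference
# uncertainty propagates.

library(excesscohort)
library(readr)

ref <- read_csv("results/scored_reference.csv", na = "",
                col_types = cols(id = "c", gender = "c", hscl10_case = "l",
                                 .default = "d"))
coh <- read_csv("results/eligible_cohort.csv", na = "",
                col_types = cols(id = "c", gender = "c", group = "c",
                                 hscl10_case = "l", .default = "d"))
expected <- read_csv("results/expected_values.csv", na = "",
                     col_types = cols(id = "c", outcome = "c",
                                      matched_gender = "c", .default = "d"))

estimates <- compare(coh, expected)
write_csv(estimates, "results/comparison_estimates.csv", na = "")
tot <- estimates[estimates$subgroup == "total", ]
for (i in seq_len(nrow(tot))) {
  cat(sprintf("%s: observed %.2f vs expected %.2f (ratio %.2f, diff %.2f, effect %.2f)\n",
              tot$outcome[i], tot$observed_mean[i], tot$expected_mean[i],
              tot$mean_ratio[i], tot$mean_diff[i], tot$effect_size[i]))
}
cat(sprintf("excess caseness (hscl10): %.2f observed vs %.2f expected -> %.2f\n",
            tot$observed_prop_case[1], tot$expected_prop_case[1], tot$prop_diff[1]))

ci <- run_bootstrap(coh, ref, config = bootstrap_config(
  n_resamples = 10000L, seed = 20180102L))
write_csv(ci, "results/bootstrap_ci.csv", na = "")

tot_ci <- ci[ci$subgroup == "total" & ci$estimand %in% c("mean_diff", "prop_diff"), ]
for (i in seq_len(nrow(tot_ci))) {
  cat(sprintf("%s %s: %.2f (95%% CI %.2f, %.2f)\n",
              tot_ci$outcome[i], tot_ci$estimand[i], tot_ci$point[i],
              tot_ci$ci_low[i], tot_ci$ci_high[i]))
}

ratios <- per_participant_ratios(coh, expected)
write_csv(ratios, "results/ratios.csv", na = "")
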