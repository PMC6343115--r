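#!/usr/bin/env Rscript

# Step 3 — eligibility and expected values.
#
# Participants outside the reference age range (or with undisclosed age)
# cannot be ascribed an expected score and are excluded with a logged
# reason. Every remaining participant then receives, per outcome, the mean
# score and caseness proportion of the reference cell with the same gender
# and exact age in completed years.

library(excesscohort)
library(readr)

ref <- read_csv("results/scored_reference.csv", na = "",
                col_types = cols(id = "c", gender = "c", hscl10_case = "l",
                                 .default = "d"))
coh <- read_csv("results/scored_cohort.csv", na = "",
                col_types = cols(id = "c", gender = "c", group = "c",
                                 hscl10_case = "l", .default = "d"))

elig <- filter_eligible(coh, range(ref$age))
cat(sprintf("eligible: %d of %d (%d excluded)\n",
            nrow(elig$eligible), nrow(coh), nrow(elig$exclusions)))
if (nrow(elig$exclusions) > 0) print(table(elig$exclusions$reason))

stratum_table <- build_stratum_table(ref)
cat(sprintf("stratum table: %d cells per outcome, cell sizes %d-%d\n",
            nrow(stratum_table) / 2, min(stratum_table$n), max(stratum_table$n)))

expected <- ascribe_expected(elig$eligible, stratum_table)
cat(sprintf("expected values ascribed for %d participants x %d outcomes; %d needed the age fallback\n",
            nrow(elig$eligible), length(unique(expected$outcome)),
            sum(expected$fallback_distance > 0)))

write_csv(elig$eligible, "results/eligible_cohort.csv", na = "")
write_csv(elig$exclusions, "results/exclusions.csv", na = "")
write_csv(stratum_table, "results/stratum_table.csv", na = "")
write_csv(expected, "results/expected_values.csv", na = "")
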