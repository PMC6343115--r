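#!/usr/bin/env Rscript

# Step 2 — score both instruments and check internal consistency.
#
# HSCL-10: mean of 10 items (1-4), at most one missing item tolerated,
# caseness at mean >= 1.85 (inclusive). Crisis Support Scale: mean of 4
# items (1-5), at least 3 valid. Cronbach's alpha is computed on listwise
# complete rows.

library(excesscohort)
library(readr)

read_tbl <- function(path, with_group) {
  ct <- if (with_group) {
    cols(id = "c", gender = "c", group = "c", .default = "d")
  } else {
    cols(id = "c", gender = "c", .default = "d")
  }
  read_csv(path, na = "", col_types = ct)
}

ref <- read_tbl("results/data/reference.csv", with_group = FALSE)
coh <- read_tbl("results/data/cohort.csv", with_group = TRUE)

for (def in list(hscl10(), css4())) {
  ref <- score_responses(ref, def)
  coh <- score_responses(coh, def)
  cat(sprintf("%s: alpha %.3f (reference) / %.3f (cohort); %d of %d cohort rows scoreable\n",
              def$name,
              cronbach_alpha(ref[item_columns(def)]),
              cronbach_alpha(coh[item_columns(def)]),
              sum(!is.na(coh[[paste0(def$name, "_score")]])), nrow(coh)))
}

write_csv(ref, "results/scored_reference.csv", na = "")
write_csv(coh, "results/scored_cohort.csv", na = "")
cat(sprintf("reference HSCL-10 caseness: %.3f\n",
            mean(ref$hscl10_case, na.rm = TRUE)))
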