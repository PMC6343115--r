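#!/usr/bin/env Rscript

# Step 5 — ratio dot-plots.
#
# One point per participant: the ratio between the observed and the expected
# score, panelled by gender and by exposure group, with a vertical reference
# line at 1 (parity with the reference population). With the default
# conditions the distress mass sits right of the line and the support mass
# left of it.

library(excesscohort)
library(readr)
library(ggplot2)

ratios <- read_csv("results/ratios.csv", na = "",
                   col_types = cols(id = "c", outcome = "c", gender = "c",
                                    group = "c", .default = "d"))
dir.create("results/figures", showWarnings = FALSE)

for (oc in unique(ratios$outcome)) {
  for (panel in c("gender", "group")) {
    p <- plot_ratios(ratios, oc, panel_by = panel)
    stem <- sprintf("results/figures/ratios_%s_by_%s", oc, panel)
    ggsave(paste0(stem, ".pdf"), p, width = 7, height = 3.5)
    try(suppressMessages(ggsave(paste0(stem, ".png"), p,
                                width = 7, height = 3.5, dpi = 150)),
        silent = TRUE)
    r <- ratios$ratio[ratios$outcome == oc]
    cat(sprintf("%s by %s: %d/%d participants above ratio 1 -> %s\n",
                oc, panel, sum(r > 1), length(r), paste0(stem, ".pdf")))
  }
}
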