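#!/usr/bin/env Rscript
# Step 3: plate-level statistics.
#
# Compares P301S against EV on the per-cell metrics with the study's
# test-selection logic (Shapiro-Wilk gate -> Mann-Whitney U or t-test,
# Brown-Forsythe variance check, Bonferroni m = 2), and reports effect
# ratios with Monte-Carlo standard errors against the injected factors.

suppressPackageStartupMessages(library(nucleovol))

cells <- read.csv("results/cells.csv")
layout <- read.csv("results/plate_layout.csv")

injected <- c(nuclear_volume_um3 = 1.025,
              foci_mean_area_um2 = 1.10,
              nucleolar_mean_intensity = 2.0)
rows <- list()
for (metric in names(injected)) {
  eff <- condition_effect(cells, layout, metric, "P301S", "EV")
  cmp <- compare_groups(eff$control_values, eff$condition_values, m = 2,
                        metric = metric)
  rows[[metric]] <- data.frame(
    metric = metric, injected = injected[[metric]],
    recovered_ratio = eff$ratio, se = eff$se,
    n_ev = eff$n[["control"]], n_mut = eff$n[["condition"]],
    test = cmp$test_used, p_raw = cmp$p_raw, p_adjusted = cmp$p_adjusted,
    label = cmp$label, percent_change = cmp$percent_change)
  message(sprintf("%-26s injected %.3f recovered %.3f +- %.3f  %s p_adj = %.3g %s",
                  metric, injected[[metric]], eff$ratio, eff$se,
                  cmp$test_used, cmp$p_adjusted, cmp$label))
}
comparisons <- do.call(rbind, rows)
write.csv(comparisons, "results/comparisons.csv", row.names = FALSE)
message("wrote results/comparisons.csv")
message("note: at this desk scale (~120 cells/condition) the 2.5% volume")
message("effect is within its Monte-Carlo error but not always significant;")
message("the acceptance suite runs the full 2400-cell design.")
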