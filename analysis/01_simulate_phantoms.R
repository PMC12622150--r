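#!/usr/bin/env Rscript
# Step 1: state the synthetic world.
#
# Builds the tetracycline-induced SH-SY5Y (1 h) P301S-vs-EV phantom plate at
# a desk scale (2 wells x 4 fields x 15 cells per condition; the full-scale
# run used by the acceptance suite is 6 wells x 20 fields x 20 cells) and
# writes its ground truth and plate layout. Everything downstream is
# regenerated deterministically from the same seed, so no image data needs
# to be stored.

suppressPackageStartupMessages(library(nucleovol))
dir.create("results", showWarnings = FALSE)

design <- preset_design("SH-SY5Y-1h", "P301S",
                        wells_per_condition = 2, fields_per_well = 4,
                        cells_per_field = 15, seed = 20260917)
message("conditions: ", paste(design$conditions, collapse = " vs "))
message("injected effects:")
print(design$effect_table)

plate <- make_plate_phantom(design)
write.csv(plate$truth$cells, "results/ground_truth_cells.csv",
          row.names = FALSE)
write.csv(plate$truth$foci, "results/ground_truth_foci.csv",
          row.names = FALSE)
write.csv(plate$layout, "results/plate_layout.csv", row.names = FALSE)

message(sprintf("simulated %d stacks, %d cells, %d planted foci",
                length(plate$stacks), nrow(plate$truth$cells),
                nrow(plate$truth$foci)))
tr <- plate$truth$cells
message(sprintf("true mean nuclear volume: EV %.1f um^3, P301S %.1f um^3 (ratio %.3f)",
                mean(tr$volume_um3[tr$condition == "EV"]),
                mean(tr$volume_um3[tr$condition == "P301S"]),
                mean(tr$volume_um3[tr$condition == "P301S"]) /
                  mean(tr$volume_um3[tr$condition == "EV"])))
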