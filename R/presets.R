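#' Phantom presets encoding the study's printed effect sizes
#'
#' Returns a [phantom_design()] whose effect table injects the percentage
#' changes reported for each cell model and MAPT mutation: nuclear-volume
#' expansion, nucleolar (focus) size increase, and the fold increase in
#' nucleolar marker (nP-Tau) mean intensity. Geometry, optics and noise
#' defaults are implementation choices documented in the methods vignette,
#' not reported values.
#'
#' Valid pairs: `SH-SY5Y-1h`/`SH-SY5Y-48h` with `P301S` or `S305N`; `iPSC`
#' with `P301S` or `IVS10+16`.
#'
#' @param model one of `"SH-SY5Y-1h"`, `"SH-SY5Y-48h"`, `"iPSC"`.
#' @param mutation one of `"P301S"`, `"S305N"`, `"IVS10+16"`.
#' @param ... overrides passed on to [phantom_design()] (e.g. sizes, seed).
#' @return a `phantom_design` with conditions `(control, mutation)`.
#' @export
preset_design <- function(model, mutation, ...) {
  eff <- preset_effects()
  key <- paste(model, mutation, sep = "/")
  if (!key %in% names(eff))
    stop(sprintf("unknown model/mutation pair '%s'; valid pairs: %s", key,
                 paste(names(eff), collapse = ", ")))
  e <- eff[[key]]
  control <- if (model == "iPSC") "Ctrl" else "EV"
  et <- data.frame(
    condition = mutation,
    quantity = c("nuclear_volume", "focus_area", "focus_amplitude"),
    factor = c(e["nuclear_volume"], e["focus_area"], e["focus_amplitude"]))
  args <- list(conditions = c(control, mutation), effect_table = et)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(phantom_design, args)
}

# Printed per-condition effects, as multiplicative factors vs control.
# focus_amplitude for the 48 h presets is carried over from 1 h (the study
# reports the sustained increase as "similar" without a number).
preset_effects <- function() {
  list(
    "SH-SY5Y-1h/P301S"  = c(nuclear_volume = 1.025, focus_area = 1.10,
                            focus_amplitude = 2.0),
    "SH-SY5Y-1h/S305N"  = c(nuclear_volume = 1.027, focus_area = 1.06,
                            focus_amplitude = 2.4),
    "SH-SY5Y-48h/P301S" = c(nuclear_volume = 1.15, focus_area = 1.12,
                            focus_amplitude = 2.0),
    "SH-SY5Y-48h/S305N" = c(nuclear_volume = 1.13, focus_area = 1.16,
                            focus_amplitude = 2.4),
    "iPSC/P301S"        = c(nuclear_volume = 1.52, focus_area = 1.26,
                            focus_amplitude = 1.015),
    "iPSC/IVS10+16"     = c(nuclear_volume = 1.45, focus_area = 1.35,
                            focus_amplitude = 1.04))
}

#' Design for a synthetic qPCR Ct table
#'
#' @param genes character vector of target genes.
#' @param ref_primary,ref_secondary reference (housekeeping) gene names;
#'   reference genes are drift-free across conditions by construction.
#' @param conditions condition names, first is the control.
#' @param samples_per_condition biological replicates per condition.
#' @param replicates_per_sample technical Ct replicates per (sample, gene)
#'   (>= 2).
#' @param baseline_ct named numeric vector of per-gene baseline Ct cycles,
#'   each in (0, 45); genes without an entry default to 25.
#' @param abundance_ratio data.frame `condition`, `gene`, `ratio` of true
#'   fold changes vs control (missing entries default to 1; reference genes
#'   must be 1).
#' @param ct_noise_sd Gaussian per-replicate Ct noise, cycles.
#' @param seed integer RNG seed.
#' @return object of class `qpcr_design`.
#' @export
qpcr_design <- function(genes,
                        ref_primary = "ACTB", ref_secondary = "RPS27",
                        conditions,
                        samples_per_condition = 3,
                        replicates_per_sample = 3,
                        baseline_ct = NULL,
                        abundance_ratio = NULL,
                        ct_noise_sd = 0.1,
                        seed = 1L) {
  if (replicates_per_sample < 2) stop("replicates_per_sample must be >= 2")
  if (samples_per_condition < 1) stop("samples_per_condition must be >= 1")
  if (length(conditions) < 1) stop("need at least one condition")
  all_genes <- c(genes, ref_primary, ref_secondary)
  bl <- stats::setNames(rep(25, length(all_genes)), all_genes)
  if (!is.null(baseline_ct)) bl[names(baseline_ct)] <- baseline_ct
  if (any(bl <= 0 | bl >= 45))
    stop("baseline_ct must lie in (0, 45) cycles")
  if (is.null(abundance_ratio))
    abundance_ratio <- data.frame(condition = character(), gene = character(),
                                  ratio = numeric())
  stopifnot(all(c("condition", "gene", "ratio") %in% names(abundance_ratio)))
  if (any(abundance_ratio$ratio <= 0)) stop("ratios must be > 0")
  refrows <- abundance_ratio$gene %in% c(ref_primary, ref_secondary)
  if (any(abundance_ratio$ratio[refrows] != 1))
    stop("reference genes must have ratio 1 in every condition")
  ctrlrows <- abundance_ratio$condition == conditions[1]
  if (any(abundance_ratio$ratio[ctrlrows] != 1))
    stop("control condition must have all ratios = 1")
  structure(list(genes = genes, ref_primary = ref_primary,
                 ref_secondary = ref_secondary, conditions = conditions,
                 samples_per_condition = as.integer(samples_per_condition),
                 replicates_per_sample = as.integer(replicates_per_sample),
                 baseline_ct = bl, abundance_ratio = abundance_ratio,
                 ct_noise_sd = ct_noise_sd, seed = as.integer(seed)),
            class = "qpcr_design")
}

abundance_lookup <- function(design, condition, gene) {
  ar <- design$abundance_ratio
  hit <- ar$condition == condition & ar$gene == gene
  if (any(hit)) ar$ratio[which(hit)[1]] else 1
}

#' Simulate a qPCR Ct table with known fold changes
#'
#' Ct for gene `g` in condition `c` is
#' `baseline_ct(g) - log2(ratio(c, g)) + N(0, ct_noise_sd)` per technical
#' replicate; reference genes are drift-free up to the same noise.
#'
#' @param design a [qpcr_design()].
#' @return list with `table` (data.frame sample, condition, gene, replicate,
#'   ct) and `true_fold` (data.frame condition, gene, ratio).
#' @export
make_ct_table <- function(design) {
  stopifnot(inherits(design, "qpcr_design"))
  set.seed(design$seed)
  all_genes <- c(design$genes, design$ref_primary, design$ref_secondary)
  rows <- list()
  for (cond in design$conditions) {
    for (s in seq_len(design$samples_per_condition)) {
      sample_id <- sprintf("%s_S%d", cond, s)
      for (g in all_genes) {
        mu <- design$baseline_ct[[g]] - log2(abundance_lookup(design, cond, g))
        ct <- mu + stats::rnorm(design$replicates_per_sample, 0,
                                design$ct_noise_sd)
        rows[[length(rows) + 1L]] <- data.frame(
          sample = sample_id, condition = cond, gene = g,
          replicate = seq_len(design$replicates_per_sample), ct = ct)
      }
    }
  }
  tf <- expand.grid(condition = design$conditions, gene = design$genes,
                    stringsAsFactors = FALSE)
  tf$ratio <- mapply(function(c, g) abundance_lookup(design, c, g),
                     tf$condition, tf$gene)
  list(table = do.call(rbind, rows), true_fold = tf)
}

#' qPCR presets with the study's printed rRNA fold changes
#'
#' Encodes the reported 45S/28S/18S fold increases for each model/mutation
#' as true abundance ratios, alongside MAPT transcript inductions (reported
#' qualitatively; the numeric values here are implementation assumptions,
#' with P301S > S305N/IVS10+16 as described).
#'
#' @inheritParams preset_design
#' @param ... overrides passed to [qpcr_design()].
#' @return a `qpcr_design`.
#' @export
preset_qpcr_design <- function(model, mutation, ...) {
  tab <- list(
    # model/mutation: 45S, 28S, 18S printed folds; MAPT-4R/total assumed
    "SH-SY5Y-1h/P301S"  = c(`45S` = 1.51, `28S` = 1.43, `18S` = 1.37,
                            `MAPT-4R` = 8, `MAPT-total` = 3),
    "SH-SY5Y-1h/S305N"  = c(`45S` = 2.34, `28S` = 2.45, `18S` = 1.47,
                            `MAPT-4R` = 5, `MAPT-total` = 2),
    "iPSC/P301S"        = c(`45S` = 1.60, `28S` = 2.41, `18S` = 3.83,
                            `MAPT-4R` = 3, `MAPT-total` = 2),
    "iPSC/IVS10+16"     = c(`45S` = 2.03, `28S` = 1.30, `18S` = 1.47,
                            `MAPT-4R` = 2, `MAPT-total` = 1.5))
  key <- paste(model, mutation, sep = "/")
  if (!key %in% names(tab))
    stop(sprintf("unknown model/mutation pair '%s'; valid pairs: %s", key,
                 paste(names(tab), collapse = ", ")))
  r <- tab[[key]]
  control <- if (model == "iPSC") "Ctrl" else "EV"
  ar <- data.frame(condition = mutation, gene = names(r), ratio = unname(r))
  args <- list(genes = names(r), conditions = c(control, mutation),
               abundance_ratio = ar,
               baseline_ct = c(`45S` = 12, `28S` = 10, `18S` = 9,
                               `MAPT-4R` = 26, `MAPT-total` = 24,
                               ACTB = 18, RPS27 = 20))
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(qpcr_design, args)
}
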