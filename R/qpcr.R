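#' Validate a Ct table
#'
#' A Ct table has one row per technical replicate: columns `sample`,
#' `condition`, `gene`, `replicate`, `ct`. Ct values must be finite and in
#' (0, 45] cycles (the protocol runs 45 cycles); every (sample, gene) pair
#' needs at least 2 replicates.
#'
#' @param table data.frame as above.
#' @return the table, invisibly, after validation.
#' @export
validate_ct_table <- function(table) {
  need <- c("sample", "condition", "gene", "replicate", "ct")
  missing_cols <- setdiff(need, names(table))
  if (length(missing_cols))
    stop("ct table missing columns: ", paste(missing_cols, collapse = ", "))
  if (any(!is.finite(table$ct)) || any(table$ct <= 0 | table$ct > 45))
    stop("Ct values must be finite and in (0, 45]")
  n <- stats::aggregate(ct ~ sample + gene, table, length)
  if (any(n$ct < 2))
    stop("every (sample, gene) needs >= 2 technical replicates")
  invisible(table)
}

#' Per-sample delta-Ct for a target against a reference gene
#'
#' Technical replicates are averaged per (sample, gene) first (the Livak
#' formulation), then `dCt = mean Ct(target) - mean Ct(reference)` per
#' sample.
#'
#' @param table a validated Ct table.
#' @param target,reference gene names.
#' @return data.frame: sample, condition, dct.
#' @export
delta_ct <- function(table, target, reference) {
  validate_ct_table(table)
  samples <- unique(table$sample)
  for (g in c(target, reference)) {
    missing_for <- setdiff(samples, table$sample[table$gene == g])
    if (length(missing_for))
      stop(sprintf("gene '%s' missing for sample(s): %s", g,
                   paste(missing_for, collapse = ", ")))
  }
  mt <- stats::aggregate(ct ~ sample + condition, table[table$gene == target, ],
                         mean)
  mr <- stats::aggregate(ct ~ sample, table[table$gene == reference, ], mean)
  mt$dct <- mt$ct - mr$ct[match(mt$sample, mr$sample)]
  mt[, c("sample", "condition", "dct")]
}

#' Delta-delta-Ct fold change for one condition against the control
#'
#' `ddCt = mean dCt(condition) - mean dCt(control)`;
#' `fold = 2^(-ddCt)` (amplification efficiency assumed exactly 2).
#' The p-value comes from the normality-gated test layer applied to the two
#' per-sample dCt samples (statistics are performed on dCt, not on folds).
#' Singleton conditions return the fold with a NULL p-value and a warning.
#'
#' @param dcts data.frame from [delta_ct()].
#' @param condition,control condition names present in `dcts`.
#' @param m Bonferroni family size for the comparison.
#' @return list: condition, control, delta_delta_ct, fold_change,
#'   comparison (a `comparison_result` or NULL), n per group.
#' @export
ddct_fold_change <- function(dcts, condition, control, m = 1) {
  if (!control %in% dcts$condition)
    stop(sprintf("unknown control condition '%s'", control))
  if (!condition %in% dcts$condition)
    stop(sprintf("unknown condition '%s'", condition))
  dc <- dcts$dct[dcts$condition == control]
  dm <- dcts$dct[dcts$condition == condition]
  ddct <- mean(dm) - mean(dc)
  fold <- 2^(-ddct)
  cmp <- NULL
  if (length(dc) >= 3 && length(dm) >= 3) {
    cmp <- tryCatch(compare_groups(dc, dm, m = m, metric = "dct"),
                    error = function(e) NULL)
  } else if (length(dc) >= 2 && length(dm) >= 2) {
    # too few samples for the Shapiro gate; fall back to the t-test
    cmp <- tryCatch(compare_groups(dc, dm, m = m, test = "t_test",
                                   metric = "dct"),
                    error = function(e) NULL)
  } else {
    warning("singleton condition: fold returned without a p-value")
  }
  if (is.null(cmp) && length(dc) >= 2 && length(dm) >= 2)
    warning("degenerate dCt samples: fold returned without a p-value")
  list(condition = condition, control = control, delta_delta_ct = ddct,
       fold_change = fold, comparison = cmp,
       n = c(control = length(dc), condition = length(dm)))
}

#' Full relative-quantification analysis with dual reference genes
#'
#' Computes delta-delta-Ct fold changes for each target gene and condition
#' against the control using the primary reference gene; the secondary
#' reference is used for validation only (never averaged with the primary):
#' the result is flagged concordant when
#' `|log2 fold_primary - log2 fold_secondary| <= concordance_tol`.
#'
#' @param table a Ct table.
#' @param targets target gene names.
#' @param ref_primary,ref_secondary reference genes; `ref_secondary = NULL`
#'   skips the concordance check.
#' @param control control condition.
#' @param m Bonferroni family size per comparison (default: number of
#'   non-control conditions).
#' @param concordance_tol allowed |log2 fold| discrepancy between references.
#' @return data.frame: gene, condition, delta_delta_ct, fold_change,
#'   p_value, p_adjusted, label, test_used, fold_secondary, concordant.
#' @export
ddct_analysis <- function(table, targets, ref_primary = "ACTB",
                          ref_secondary = "RPS27", control,
                          m = NULL, concordance_tol = 0.5) {
  validate_ct_table(table)
  conds <- setdiff(unique(table$condition), control)
  if (is.null(m)) m <- max(1L, length(conds))
  rows <- list()
  for (g in targets) {
    d1 <- delta_ct(table, g, ref_primary)
    d2 <- if (!is.null(ref_secondary)) delta_ct(table, g, ref_secondary)
    for (cond in conds) {
      r1 <- ddct_fold_change(d1, cond, control, m = m)
      fold2 <- NA_real_
      if (!is.null(d2)) {
        r2 <- ddct_fold_change(d2, cond, control, m = m)
        fold2 <- r2$fold_change
      }
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, condition = cond,
        delta_delta_ct = r1$delta_delta_ct,
        fold_change = r1$fold_change,
        p_value = if (!is.null(r1$comparison)) r1$comparison$p_raw else NA_real_,
        p_adjusted = if (!is.null(r1$comparison))
          r1$comparison$p_adjusted else NA_real_,
        label = if (!is.null(r1$comparison)) r1$comparison$label else NA_character_,
        test_used = if (!is.null(r1$comparison))
          r1$comparison$test_used else NA_character_,
        fold_secondary = fold2,
        concordant = if (is.na(fold2)) NA else
          abs(log2(r1$fold_change) - log2(fold2)) <= concordance_tol)
    }
  }
  do.call(rbind, rows)
}
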