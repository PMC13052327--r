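# Pearson correlations between selected protein NPX values and clinical /
# functional measures, with Fisher-z 95% confidence intervals.

#' Correlate protein NPX values with clinical measures
#'
#' Pairwise-complete Pearson correlations between each (protein, measure)
#' cell, with 95% confidence intervals via the Fisher z transform
#' (`z +/- 1.96 / sqrt(n - 3)`). Cells with fewer than `min_n` complete
#' pairs are skipped; cells where either variable is constant have an
#' undefined correlation and are returned flagged with `NA` estimates.
#'
#' @param npx an [npx_matrix()].
#' @param cohort validated cohort table carrying numeric measure columns.
#' @param proteins protein accessions to correlate.
#' @param measures names of numeric cohort columns; defaults to all numeric
#'   columns except survival bookkeeping.
#' @param groups cohort groups to pool (default older participants only).
#' @param min_n minimum complete pairs per cell.
#' @return A data.frame with `protein_id`, `measure`, `n`, `r`, `ci_low`,
#'   `ci_high`, `degenerate`.
#' @export
correlate_measures <- function(npx, cohort, proteins, measures = NULL,
                               groups = c("OC", "OP"), min_n = 4L) {
  cohort <- validate_cohort(cohort)
  sub <- cohort[cohort$group %in% groups, ]
  sub <- sub[sub$sample_id %in% rownames(npx), ]
  if (is.null(measures)) {
    skip <- c("sample_id", "group", "pair_id", "sex", "survival_time",
              "event")
    measures <- names(sub)[vapply(sub, is.numeric, logical(1L))]
    measures <- setdiff(measures, skip)
  }
  proteins <- intersect(proteins, colnames(npx))
  if (!length(proteins)) stop("no requested protein on the panel")
  if (!length(measures)) stop("no numeric measures to correlate")
  vals <- unclass(npx)[sub$sample_id, , drop = FALSE]
  rows <- list()
  for (p in proteins) {
    for (m in measures) {
      xy <- data.frame(x = vals[, p], y = sub[[m]])
      xy <- xy[complete.cases(xy) & is.finite(xy$x) & is.finite(xy$y), ]
      n <- nrow(xy)
      if (n < min_n) next
      degenerate <- sd(xy$x) == 0 || sd(xy$y) == 0
      if (degenerate) {
        r <- ci_lo <- ci_hi <- NA_real_
      } else {
        r <- cor(xy$x, xy$y)
        if (abs(r) >= 1) {          # Fisher z undefined at |r| = 1
          ci_lo <- ci_hi <- r
        } else {
          z <- atanh(r)
          hw <- qnorm(0.975) / sqrt(n - 3)
          ci_lo <- tanh(z - hw)
          ci_hi <- tanh(z + hw)
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        protein_id = p, measure = m, n = n, r = r,
        ci_low = ci_lo, ci_high = ci_hi, degenerate = degenerate,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) stop("no cell with enough complete pairs")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
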