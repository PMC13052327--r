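# Pairwise differential expression on NPX values with a Shapiro-Wilk
# normality gate: parametric t-tests where normality is tenable, Wilcoxon
# rank tests otherwise, geometric-mean fold changes and Benjamini-Hochberg
# correction across the panel.

#' Choose the per-protein test via a Shapiro-Wilk gate
#'
#' Unpaired contrasts: Shapiro-Wilk is run on each group; when the gate
#' (`both` by default) is satisfied (p >= `alpha_normality`), the
#' independent-samples t-test is used, otherwise the Wilcoxon rank-sum test.
#' Paired contrasts: the gate runs on the within-pair differences, routing
#' to the paired t-test or the Wilcoxon signed-rank test. Constant input
#' (Shapiro-Wilk undefined) falls back to the rank test with a warning.
#'
#' @param values_a,values_b numeric vectors (for paired tests, aligned by
#'   pair).
#' @param paired logical.
#' @param alpha_normality gate level (default 0.05).
#' @param gate for unpaired tests, require `"both"` groups (default) or
#'   `"any"` group to pass normality for the parametric route.
#' @return One of `"t_independent"`, `"t_paired"`, `"wilcoxon_ranksum"`,
#'   `"wilcoxon_signedrank"`.
#' @export
choose_test <- function(values_a, values_b, paired = FALSE,
                        alpha_normality = 0.05, gate = c("both", "any")) {
  gate <- match.arg(gate)
  if (paired) {
    if (length(values_a) != length(values_b))
      stop("paired groups must have equal length")
    d <- values_a - values_b
    if (length(d) < 3L) stop("need >= 3 pairs")
    if (sd(d) == 0) {
      warning("constant paired differences; routing to signed-rank test")
      return("wilcoxon_signedrank")
    }
    p <- shapiro.test(d)$p.value
    return(if (p >= alpha_normality) "t_paired" else "wilcoxon_signedrank")
  }
  if (length(values_a) < 3L || length(values_b) < 3L)
    stop("need >= 3 observations per group")
  if (sd(values_a) == 0 || sd(values_b) == 0) {
    warning("constant group; routing to rank-sum test")
    return("wilcoxon_ranksum")
  }
  pa <- shapiro.test(values_a)$p.value
  pb <- shapiro.test(values_b)$p.value
  normal <- if (gate == "both") (pa >= alpha_normality && pb >= alpha_normality)
            else (pa >= alpha_normality || pb >= alpha_normality)
  if (normal) "t_independent" else "wilcoxon_ranksum"
}

#' Geometric-mean fold change from NPX values
#'
#' NPX is log2-scale, so the linear-scale ratio of geometric means reduces
#' to `2^(mean(npx_a) - mean(npx_b))`.
#'
#' @param npx_a,npx_b numeric NPX vectors (group A over group B).
#' @return Linear fold change (> 0).
#' @export
geometric_fold_change <- function(npx_a, npx_b) {
  if (!length(npx_a) || !length(npx_b)) stop("empty group")
  if (!all(is.finite(npx_a)) || !all(is.finite(npx_b)))
    stop("non-finite NPX values")
  2^(mean(npx_a) - mean(npx_b))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Thin validated wrapper around `stats::p.adjust(method = "BH")`.
#'
#' @param p_values numeric vector in \[0, 1\].
#' @return Adjusted p-values, original order preserved.
#' @export
bh_adjust <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(p_values, method = "BH")
}

run_one_test <- function(a, b, test) {
  switch(test,
    t_independent = t.test(a, b)$p.value,
    t_paired = t.test(a, b, paired = TRUE)$p.value,
    wilcoxon_ranksum = wilcox_gated(a, b, paired = FALSE),
    wilcoxon_signedrank = wilcox_gated(a, b, paired = TRUE),
    stop("unknown test: ", test))
}

# exact p for small tie-free samples, normal approximation with continuity
# correction otherwise
wilcox_gated <- function(a, b, paired) {
  if (paired) {
    d <- a - b
    d <- d[d != 0]
    if (!length(d)) return(1)  # all pairs tied: no evidence against the null
    use_exact <- length(d) <= 25L && !anyDuplicated(abs(d))
    suppressWarnings(wilcox.test(a, b, paired = TRUE, exact = use_exact,
                                 correct = TRUE)$p.value)
  } else {
    use_exact <- length(a) <= 25L && length(b) <= 25L &&
      !anyDuplicated(c(a, b))
    suppressWarnings(wilcox.test(a, b, exact = use_exact,
                                 correct = TRUE)$p.value)
  }
}

#' Run one pairwise differential-expression comparison
#'
#' Applies the normality-gated test protein-by-protein for `group_a` vs
#' `group_b`, computes geometric-mean fold changes and BH-adjusts across the
#' full panel (m = number of proteins tested in this comparison). Paired
#' comparisons (OP vs OC via `pair_id`) use complete pairs only; pairs with
#' a missing member are dropped per protein.
#'
#' @param npx an [npx_matrix()].
#' @param cohort a validated cohort data.frame.
#' @param group_a,group_b group labels among YC/OC/OP; fold change is
#'   geomean(A)/geomean(B).
#' @param paired pair the samples via `pair_id` (requires both groups to be
#'   the paired OC/OP arms).
#' @param alpha_normality Shapiro-Wilk gate level.
#' @param alpha_fdr BH significance level.
#' @param gate see [choose_test()].
#' @return A data.frame of class `de_result` with columns `protein_id`,
#'   `assay`, `test_used`, `p_raw`, `p_adj`, `fc_linear`, `log2_fc`,
#'   `neg_log10_p_adj`, `significant`, `direction`.
#' @export
run_comparison <- function(npx, cohort, group_a, group_b, paired = FALSE,
                           alpha_normality = 0.05, alpha_fdr = 0.05,
                           gate = "both") {
  stopifnot(inherits(npx, "npx_matrix"))
  cohort <- validate_cohort(cohort)
  if (group_a == group_b) stop("groups must be disjoint")
  rows_a <- cohort$sample_id[cohort$group == group_a]
  rows_b <- cohort$sample_id[cohort$group == group_b]
  rows_a <- intersect(rows_a, rownames(npx))
  rows_b <- intersect(rows_b, rownames(npx))
  if (!length(rows_a) || !length(rows_b))
    stop("empty group after matching samples to the NPX matrix")
  if (paired) {
    sub <- cohort[cohort$sample_id %in% c(rows_a, rows_b) &
                    !is.na(cohort$pair_id), ]
    pairs <- intersect(sub$pair_id[sub$group == group_a],
                       sub$pair_id[sub$group == group_b])
    if (!length(pairs)) stop("no complete pairs for a paired comparison")
    rows_a <- sub$sample_id[match(pairs, ifelse(sub$group == group_a,
                                                sub$pair_id, NA))]
    rows_b <- sub$sample_id[match(pairs, ifelse(sub$group == group_b,
                                                sub$pair_id, NA))]
  }
  P <- ncol(npx)
  test_used <- character(P)
  p_raw <- numeric(P)
  fc <- numeric(P)
  vals <- unclass(npx)
  for (j in seq_len(P)) {
    a <- vals[rows_a, j]
    b <- vals[rows_b, j]
    if (paired) {
      ok <- is.finite(a) & is.finite(b)
      a <- a[ok]; b <- b[ok]
    } else {
      a <- a[is.finite(a)]; b <- b[is.finite(b)]
    }
    tst <- withCallingHandlers(
      choose_test(a, b, paired = paired, alpha_normality = alpha_normality,
                  gate = gate),
      warning = function(w) invokeRestart("muffleWarning"))
    test_used[j] <- tst
    p_raw[j] <- run_one_test(a, b, tst)
    fc[j] <- geometric_fold_change(a, b)
  }
  p_adj <- bh_adjust(p_raw)
  out <- data.frame(
    protein_id = colnames(npx),
    assay = unname(npx_assays(npx)),
    test_used = test_used,
    p_raw = p_raw,
    p_adj = p_adj,
    fc_linear = fc,
    log2_fc = log2(fc),
    neg_log10_p_adj = -log10(p_adj),
    significant = p_adj < alpha_fdr,
    direction = ifelse(fc > 1, "up", ifelse(fc < 1, "down", NA_character_)),
    stringsAsFactors = FALSE
  )
  attr(out, "comparison") <- list(group_a = group_a, group_b = group_b,
                                  paired = paired,
                                  alpha_normality = alpha_normality,
                                  alpha_fdr = alpha_fdr, gate = gate,
                                  n_a = length(rows_a), n_b = length(rows_b))
  class(out) <- c("de_result", "data.frame")
  out
}
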