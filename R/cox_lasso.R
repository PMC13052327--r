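# Mortality-signature extraction: L1-penalized stratified Cox regression
# (Breslow ties) fitted by IRLS + cyclic coordinate descent in compiled
# code, with unpenalized adjustment covariates, 10-fold cross-validation on
# the held-out partial-likelihood deviance (Verweij-van Houwelingen form)
# and stratified-bootstrap stability selection.

prepare_cox_data <- function(x, time, status, strata = NULL,
                             unpenalized = NULL, standardize = TRUE) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  n <- nrow(x)
  if (length(time) != n || length(status) != n)
    stop("time/status length mismatch")
  if (!all(is.finite(x)) || !all(is.finite(time)))
    stop("non-finite inputs")
  if (!all(status %in% c(0, 1))) stop("event must be 0/1")
  if (any(time <= 0)) stop("survival times must be > 0")
  if (is.null(strata)) strata <- rep("all", n)
  strata <- droplevels(factor(strata))
  if (any(tapply(status, strata, sum) < 1))
    stop("every stratum needs at least one event")
  if (!is.null(unpenalized)) {
    unpenalized <- as.matrix(unpenalized)
    if (is.null(colnames(unpenalized)))
      colnames(unpenalized) <- paste0("u", seq_len(ncol(unpenalized)))
    if (!all(is.finite(unpenalized))) stop("non-finite inputs")
  }
  center <- rep(0, ncol(x))
  scl <- rep(1, ncol(x))
  if (standardize) {
    center <- colMeans(x)
    scl <- apply(x, 2L, sd)
    if (any(scl == 0)) stop("constant penalized covariate: ",
                            paste(colnames(x)[scl == 0], collapse = ", "))
    x <- scale(x, center = center, scale = scl)
  }
  xall <- cbind(x, unpenalized)
  penalty <- c(rep(1, ncol(x)),
               rep(0, if (is.null(unpenalized)) 0 else ncol(unpenalized)))
  ord <- order(as.integer(strata), time)
  strata_sorted <- as.integer(strata)[ord]
  bounds <- cumsum(table(strata_sorted))
  str_end <- as.integer(bounds - 1L)
  str_start <- as.integer(c(0L, head(bounds, -1L)))
  list(x = xall[ord, , drop = FALSE], time = time[ord],
       status = as.numeric(status)[ord], str_start = str_start,
       str_end = str_end, penalty = penalty, order = ord,
       n = n, p = ncol(x), q = ncol(xall) - ncol(x),
       protein_names = colnames(x), var_names = colnames(xall),
       center = center, scale = scl, strata = strata)
}

#' Fit an L1-penalized stratified Cox model along a lambda path
#'
#' Maximizes the stratified Breslow partial log-likelihood minus
#' `lambda * sum(|beta_protein|)` with the adjustment covariates left
#' unpenalized, over a decreasing log-spaced lambda grid with warm starts.
#' The objective is on the `1/n`-scaled likelihood (glmnet convention), so
#' lambda values are comparable across sample sizes. Penalized covariates
#' are standardized to mean 0, sample SD 1 before penalization (so
#' coefficients are log hazard ratios per SD); `lambda_max` is the smallest
#' lambda zeroing all penalized coefficients, computed from the score at the
#' unpenalized-only fit. Convergence: max coefficient change below `tol`
#' across an outer reweighting iteration.
#'
#' @param x numeric matrix of penalized covariates (samples x proteins).
#' @param time,status follow-up times (> 0) and 0/1 event indicators.
#' @param strata baseline-hazard stratification factor (e.g. OC/OP group);
#'   `NULL` for a single stratum.
#' @param unpenalized optional matrix/vector of unpenalized covariates
#'   (e.g. a male-sex indicator).
#' @param lambda optional decreasing lambda sequence; computed when `NULL`.
#' @param nlambda,lambda_min_ratio grid length and `lambda_min/lambda_max`
#'   ratio for the automatic grid.
#' @param standardize standardize penalized covariates internally.
#' @param tol,maxit convergence tolerance and outer-iteration cap.
#' @param dfmax stop the path once more than this many penalized
#'   coefficients are active (default: half the number of events, the usual
#'   events-per-variable prudence bound); beyond that the partial
#'   likelihood approaches saturation and selection is meaningless.
#' @return An object of class `cox_lasso`: `lambda`, `beta` (variables x
#'   lambda, penalized rows first), `loglik`, `df` (nonzero penalized count
#'   per lambda), plus bookkeeping used by [cross_validate_cox()] and
#'   [kkt_max_violation()].
#' @export
fit_cox_lasso <- function(x, time, status, strata = NULL, unpenalized = NULL,
                          lambda = NULL, nlambda = 100L,
                          lambda_min_ratio = 0.01, standardize = TRUE,
                          tol = 1e-7, maxit = 100L, dfmax = NULL) {
  pd <- prepare_cox_data(x, time, status, strata, unpenalized, standardize)
  if (is.null(dfmax)) dfmax <- min(pd$p, max(5L, floor(sum(pd$status) / 2)))
  nvar <- ncol(pd$x)
  beta0 <- numeric(nvar)
  if (pd$q > 0) {
    # unpenalized-only fit: huge lambda freezes all penalized coefficients
    fit0 <- cox_lasso_path_cpp(pd$x, pd$time, pd$status, pd$str_start,
                               pd$str_end, pd$penalty, 1e30, beta0,
                               tol, maxit, dfmax)
    beta0 <- as.vector(fit0$beta)
  }
  lg <- cox_loglik_grad_cpp(pd$x, pd$time, pd$status, pd$str_start,
                            pd$str_end, beta0)
  lambda_max <- max(abs(lg$grad[pd$penalty > 0]))
  if (!is.finite(lambda_max) || lambda_max <= 0) lambda_max <- 1e-3
  grid_own <- is.null(lambda)
  if (grid_own)
    lambda <- exp(seq(log(lambda_max), log(lambda_max * lambda_min_ratio),
                      length.out = nlambda))
  lambda <- sort(lambda, decreasing = TRUE)
  res <- cox_lasso_path_cpp(pd$x, pd$time, pd$status, pd$str_start,
                            pd$str_end, pd$penalty, lambda, beta0,
                            tol, maxit, dfmax)
  beta <- res$beta
  n_fitted <- res$nlambda_fitted
  if (grid_own && n_fitted < length(lambda)) {
    # truncate the self-chosen grid at path saturation
    lambda <- lambda[seq_len(n_fitted)]
    beta <- beta[, seq_len(n_fitted), drop = FALSE]
    res$loglik <- res$loglik[seq_len(n_fitted)]
    res$iters <- res$iters[seq_len(n_fitted)]
  }
  rownames(beta) <- pd$var_names
  colnames(beta) <- signif(lambda, 6)
  structure(list(lambda = lambda, beta = beta, loglik = res$loglik,
                 iters = res$iters, n_fitted = min(n_fitted, length(lambda)),
                 df = colSums(beta[seq_len(pd$p), , drop = FALSE] != 0),
                 data = pd, tol = tol, standardize = standardize),
            class = "cox_lasso")
}

#' @export
print.cox_lasso <- function(x, ...) {
  cat(sprintf(
    "<cox_lasso> %d proteins (+%d unpenalized), %d strata, %d lambda values\n",
    x$data$p, x$data$q, length(x$data$str_start), length(x$lambda)))
  invisible(x)
}

#' Coefficients at one lambda
#'
#' @param object a `cox_lasso` fit.
#' @param s lambda value (nearest grid point used).
#' @param ... ignored.
#' @return Named coefficient vector (per-SD scale for penalized rows when
#'   the fit standardized internally).
#' @export
coef.cox_lasso <- function(object, s = min(object$lambda), ...) {
  i <- which.min(abs(object$lambda - s))
  object$beta[, i]
}

selected_at <- function(fit, s) {
  b <- coef.cox_lasso(fit, s)[seq_len(fit$data$p)]
  names(b)[b != 0]
}

#' Maximum KKT violation over the fitted path
#'
#' At a minimizer of `-(1/n) loglik + lambda * sum(pf |beta|)`, the score
#' `g_j` of the `(1/n)`-scaled log-likelihood satisfies `|g_j| <= lambda`
#' for zero penalized coefficients and `g_j = lambda * sign(beta_j)` for
#' active ones (and `g_j = 0` for unpenalized covariates). Returns the
#' largest violation of these conditions across all variables and lambda
#' values — a direct optimality certificate for the solver.
#'
#' @param fit a `cox_lasso` object.
#' @return Maximum absolute violation (scalar).
#' @export
kkt_max_violation <- function(fit) {
  pd <- fit$data
  worst <- 0
  for (i in seq_len(fit$n_fitted)) {
    lam <- fit$lambda[i]
    b <- fit$beta[, i]
    g <- cox_loglik_grad_cpp(pd$x, pd$time, pd$status, pd$str_start,
                             pd$str_end, b)$grad
    pen <- pd$penalty > 0
    viol <- c(
      pmax(abs(g[pen & b == 0]) - lam, 0),
      abs(g[pen & b != 0] - lam * sign(b[pen & b != 0])),
      abs(g[!pen])
    )
    if (length(viol)) worst <- max(worst, viol)
  }
  worst
}

make_foldid <- function(strata, status, n_folds) {
  foldid <- integer(length(status))
  cells <- interaction(strata, status, drop = TRUE)
  for (cell in levels(cells)) {
    idx <- sample(which(cells == cell))
    foldid[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  foldid
}

#' Cross-validate the penalized Cox model
#'
#' 10-fold cross-validation of the held-out partial-likelihood deviance in
#' the Verweij-van Houwelingen form: each fold's contribution is
#' `-2 * (loglik(beta_train; all data) - loglik(beta_train; training data))`,
#' which needs no risk sets within the (small) held-out fold alone. Folds
#' are stratified jointly by baseline-hazard stratum and event status so
#' every training set retains events in every stratum. Both the
#' deviance-minimizing `lambda_min` and the 1-standard-error `lambda_1se`
#' are reported, with the selected (nonzero) protein sets of the full-data
#' fit at each.
#'
#' @inheritParams fit_cox_lasso
#' @param n_folds number of folds.
#' @param seed RNG seed for the fold assignment.
#' @return An object of class `cox_cv`: `fit` (full-data `cox_lasso`),
#'   `lambda`, `cvm`, `cvsd`, `lambda_min`, `lambda_1se`, `selected`
#'   (protein sets under both rules), `foldid`.
#' @export
cross_validate_cox <- function(x, time, status, strata = NULL,
                               unpenalized = NULL, n_folds = 10L,
                               seed = 1L, lambda = NULL, nlambda = 100L,
                               lambda_min_ratio = 0.01, standardize = TRUE,
                               tol = 1e-7, maxit = 100L) {
  x <- as.matrix(x)
  if (standardize) {
    scl <- apply(x, 2L, sd)
    if (any(scl == 0)) stop("constant penalized covariate")
    x <- scale(x)  # once, so folds share the covariate scale
  }
  fit <- fit_cox_lasso(x, time, status, strata, unpenalized, lambda = lambda,
                       nlambda = nlambda, lambda_min_ratio = lambda_min_ratio,
                       standardize = FALSE, tol = tol, maxit = maxit)
  lambda <- fit$lambda
  if (is.null(strata)) strata <- rep("all", nrow(x))
  set.seed(seed)
  foldid <- make_foldid(strata, status, n_folds)
  pd_all <- prepare_cox_data(x, time, status, strata, unpenalized,
                             standardize = FALSE)
  dev <- matrix(NA_real_, n_folds, length(lambda))
  for (k in seq_len(n_folds)) {
    train <- foldid != k
    if (any(tapply(status[train], factor(strata[train]), sum, default = 0) < 1)
        || sum(status[!train]) < 1)
      stop("fold with no events; reduce n_folds")
    fit_k <- fit_cox_lasso(x[train, , drop = FALSE], time[train],
                           status[train], strata[train],
                           if (is.null(unpenalized)) NULL
                           else as.matrix(unpenalized)[train, , drop = FALSE],
                           lambda = lambda, standardize = FALSE,
                           tol = tol, maxit = maxit)
    pd_tr <- fit_k$data
    for (i in seq_along(lambda)) {
      b <- fit_k$beta[, i]
      l_all <- cox_loglik_grad_cpp(pd_all$x, pd_all$time, pd_all$status,
                                   pd_all$str_start, pd_all$str_end,
                                   b)$loglik
      l_tr <- fit_k$loglik[i]
      dev[k, i] <- -2 * (l_all - l_tr)
    }
  }
  cvm <- colMeans(dev)
  cvsd <- apply(dev, 2L, sd) / sqrt(n_folds)
  i_min <- which.min(cvm)
  lambda_min <- lambda[i_min]
  ok_1se <- which(cvm <= cvm[i_min] + cvsd[i_min])
  lambda_1se <- lambda[min(ok_1se)]  # largest lambda within 1 SE
  structure(list(fit = fit, lambda = lambda, cvm = cvm, cvsd = cvsd,
                 lambda_min = lambda_min, lambda_1se = lambda_1se,
                 selected = list(
                   lambda_min = selected_at(fit, lambda_min),
                   lambda_1se = selected_at(fit, lambda_1se)),
                 foldid = foldid, deviance_folds = dev),
            class = "cox_cv")
}

#' Bootstrap stability selection for the Cox-LASSO signature
#'
#' Repeats the full cross-validated selection on stratified bootstrap
#' resamples (each stratum resampled with replacement at its observed
#' size), and reports per-protein selection frequencies. A resample leaving
#' any stratum without events is redrawn (and counted), keeping the
#' resample count exact. Proteins selected in at least
#' `threshold * n_bootstrap` resamples form the robust set.
#'
#' @inheritParams cross_validate_cox
#' @param n_bootstrap number of bootstrap resamples.
#' @param threshold selection-frequency threshold for robustness (0.5 =
#'   the "at least half of resamples" rule; 1.0 = consistently selected).
#' @param rule `"lambda_min"` (default) or `"lambda_1se"`.
#' @return An object of class `bootstrap_stability`: `frequency` (named,
#'   per protein), `robust` (character vector), `threshold`, `rule`,
#'   `n_bootstrap`, `n_redraws`.
#' @export
bootstrap_stability <- function(x, time, status, strata = NULL,
                                unpenalized = NULL, n_bootstrap = 1000L,
                                threshold = 0.5,
                                rule = c("lambda_min", "lambda_1se"),
                                n_folds = 10L, seed = 1L, nlambda = 100L,
                                lambda_min_ratio = 0.01, tol = 1e-5,
                                maxit = 100L) {
  rule <- match.arg(rule)
  if (threshold <= 0 || threshold > 1) stop("threshold must lie in (0, 1]")
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  n <- nrow(x)
  if (is.null(strata)) strata <- rep("all", n)
  strata <- factor(strata)
  idx_by_stratum <- split(seq_len(n), strata)
  set.seed(seed)
  subseeds <- sample.int(.Machine$integer.max - 1L, n_bootstrap)
  counts <- setNames(numeric(ncol(x)), colnames(x))
  n_redraws <- 0L
  for (b in seq_len(n_bootstrap)) {
    set.seed(subseeds[b])
    attempts <- 0L
    repeat {
      idx <- unlist(lapply(idx_by_stratum, function(ii)
        sample(ii, length(ii), replace = TRUE)), use.names = FALSE)
      # >= 2 events per stratum so every CV training set keeps one
      if (all(tapply(status[idx], strata[idx], sum) >= 2)) break
      n_redraws <- n_redraws + 1L
      attempts <- attempts + 1L
      if (attempts > 1000L) stop("cannot draw a resample with events in every stratum")
    }
    cv <- cross_validate_cox(x[idx, , drop = FALSE], time[idx], status[idx],
                             strata[idx],
                             if (is.null(unpenalized)) NULL
                             else as.matrix(unpenalized)[idx, , drop = FALSE],
                             n_folds = n_folds, seed = subseeds[b],
                             nlambda = nlambda,
                             lambda_min_ratio = lambda_min_ratio,
                             tol = tol, maxit = maxit)
    sel <- cv$selected[[rule]]
    counts[sel] <- counts[sel] + 1
  }
  freq <- counts / n_bootstrap
  structure(list(frequency = freq,
                 robust = names(freq)[freq >= threshold],
                 threshold = threshold, rule = rule,
                 n_bootstrap = n_bootstrap, n_redraws = n_redraws),
            class = "bootstrap_stability")
}

#' Extract the mortality signature from a cohort
#'
#' Convenience wrapper reproducing the full signature stage on an NPX
#' matrix and cohort table: Young Controls are excluded (no events by
#' design), proteins are restricted to a candidate set (typically the APs),
#' the baseline hazard is stratified by group, sex enters unpenalized, and
#' cross-validated selection plus bootstrap stability selection are run.
#'
#' @param npx an [npx_matrix()].
#' @param cohort validated cohort table with survival columns.
#' @param proteins candidate protein accessions (e.g. the AP set).
#' @param rule,n_bootstrap,threshold,n_folds,seed,nlambda see
#'   [bootstrap_stability()].
#' @return A list with `cv` (`cox_cv`), `selected` (protein set at `rule`)
#'   and `stability` (`bootstrap_stability`, `NULL` when `n_bootstrap` = 0).
#' @export
mortality_signature <- function(npx, cohort, proteins,
                                rule = "lambda_min", n_bootstrap = 1000L,
                                threshold = 0.5, n_folds = 10L, seed = 1L,
                                nlambda = 100L) {
  cohort <- validate_cohort(cohort)
  older <- cohort[cohort$group %in% c("OC", "OP"), ]
  proteins <- intersect(proteins, colnames(npx))
  if (length(proteins) < 2L) stop("need at least 2 candidate proteins")
  xs <- unclass(npx)[older$sample_id, proteins, drop = FALSE]
  xs <- scale(xs)
  sex <- matrix(as.numeric(older$sex == "M"), ncol = 1,
                dimnames = list(NULL, "sexM"))
  cv <- cross_validate_cox(xs, older$survival_time, older$event,
                           strata = older$group, unpenalized = sex,
                           n_folds = n_folds, seed = seed, nlambda = nlambda,
                           standardize = FALSE)
  stab <- NULL
  if (n_bootstrap > 0)
    stab <- bootstrap_stability(xs, older$survival_time, older$event,
                                strata = older$group, unpenalized = sex,
                                n_bootstrap = n_bootstrap,
                                threshold = threshold, rule = rule,
                                n_folds = n_folds, seed = seed,
                                nlambda = nlambda)
  list(cv = cv, selected = cv$selected[[rule]], stability = stab)
}
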