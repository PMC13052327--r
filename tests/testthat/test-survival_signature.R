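# Penalized stratified Cox regression: optimality certificates, analytic
# and reference-implementation oracles, CV behaviour and bootstrap
# stability selection.

sim_surv <- function(n = 60L, p = 5L, beta = c(1, -0.8), seed = 1L,
                     rate = 0.1, horizon = 8) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, sprintf("P%02d", seq_len(p))))
  lp <- as.vector(x[, seq_along(beta), drop = FALSE] %*% beta)
  tt <- rexp(n, rate = rate * exp(lp))
  list(x = x, time = pmin(tt, horizon), status = as.integer(tt < horizon))
}

test_that("an infinite penalty zeroes proteins and leaves sex at its MLE", {
  d <- sim_surv(n = 50L, p = 4L, seed = 2L)
  set.seed(3)
  sex <- matrix(rbinom(50L, 1L, 0.5), ncol = 1L,
                dimnames = list(NULL, "sexM"))
  grp <- rep(c("OC", "OP"), 25L)
  fit <- fit_cox_lasso(d$x, d$time, d$status, strata = grp,
                       unpenalized = sex, lambda = c(1e6, 0.5))
  expect_true(all(fit$beta[1:4, 1] == 0))
  df <- data.frame(time = d$time, status = d$status, sexM = sex[, 1],
                   grp = grp)
  cph <- survival::coxph(
    survival::Surv(time, status) ~ sexM + survival::strata(grp),
    data = df, ties = "breslow")
  expect_equal(unname(fit$beta["sexM", 1]), unname(coef(cph)),
               tolerance = 1e-5)
})

test_that("the unpenalized coefficient solves the score equation (tiny n)", {
  # 4 subjects, one binary covariate, distinct times, lambda = 0: compare
  # with a direct maximization of the hand-coded partial likelihood
  x <- matrix(c(1, 0, 1, 0), ncol = 1, dimnames = list(NULL, "z"))
  time <- c(1, 2, 3, 4)
  status <- c(1, 1, 1, 0)
  logpl <- function(b) {
    eta <- x[, 1] * b
    risk <- exp(eta)
    sum(vapply(which(status == 1), function(i)
      eta[i] - log(sum(risk[time >= time[i]])), numeric(1)))
  }
  b_hat <- optimize(logpl, c(-5, 5), maximum = TRUE)$maximum
  fit <- fit_cox_lasso(x, time, status, lambda = c(1, 0),
                       standardize = FALSE, dfmax = 1L)
  expect_equal(unname(fit$beta["z", 2]), b_hat, tolerance = 1e-4)
})

test_that("the path matches glmnet on small single-stratum instances", {
  for (s in 1:3) {
    d <- sim_surv(n = 20L, p = 4L, beta = c(0.8, -0.5), seed = s,
                  rate = 0.2)
    fit <- fit_cox_lasso(d$x, d$time, d$status, standardize = FALSE,
                         nlambda = 25L, dfmax = 4L)
    g <- glmnet::glmnet(d$x, survival::Surv(d$time, d$status),
                        family = "cox", standardize = FALSE,
                        lambda = fit$lambda, thresh = 1e-14)
    expect_lt(max(abs(as.matrix(g$beta) -
                        fit$beta[, seq_len(fit$n_fitted)])), 1e-4)
  }
})

test_that("KKT conditions hold at every fitted lambda", {
  d <- sim_surv(n = 80L, p = 10L, beta = c(1, -0.7, 0.5), seed = 4L)
  set.seed(5)
  sex <- matrix(rbinom(80L, 1L, 0.5), ncol = 1L)
  strata <- rep(c("OC", "OP"), 40L)
  fit <- fit_cox_lasso(d$x, d$time, d$status, strata = strata,
                       unpenalized = sex)
  expect_lt(kkt_max_violation(fit), 1e-5)
})

test_that("duplicating all subjects into a second stratum leaves the fit", {
  d <- sim_surv(n = 40L, p = 4L, seed = 6L)
  f1 <- fit_cox_lasso(d$x, d$time, d$status, nlambda = 20L,
                      standardize = FALSE)
  f2 <- fit_cox_lasso(rbind(d$x, d$x), c(d$time, d$time),
                      c(d$status, d$status),
                      strata = rep(c("a", "b"), each = 40L),
                      lambda = f1$lambda, standardize = FALSE)
  expect_equal(f2$beta[, seq_len(f1$n_fitted)],
               f1$beta[, seq_len(f1$n_fitted)], tolerance = 1e-6)
})

test_that("planted hazard proteins enter the path before null proteins", {
  hits <- vapply(1:10, function(s) {
    d <- sim_surv(n = 104L, p = 10L, beta = c(0.9, 0.9, 0.9), seed = 100 + s,
                  rate = 0.05)
    fit <- fit_cox_lasso(d$x, d$time, d$status, nlambda = 50L)
    entry <- apply(fit$beta[1:10, , drop = FALSE] != 0, 1L,
                   function(r) if (any(r)) which(r)[1] else Inf)
    all(sort(entry[1:3]) <= sort(entry[4:10])[1])
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("cross-validation is deterministic and finds planted signals", {
  d <- sim_surv(n = 104L, p = 12L, beta = c(1, -1), seed = 7L, rate = 0.08)
  strata <- rep(c("OC", "OP"), each = 52L)
  cv1 <- cross_validate_cox(d$x, d$time, d$status, strata, seed = 11L,
                            nlambda = 40L)
  cv2 <- cross_validate_cox(d$x, d$time, d$status, strata, seed = 11L,
                            nlambda = 40L)
  expect_identical(cv1$cvm, cv2$cvm)
  expect_identical(cv1$foldid, cv2$foldid)
  expect_true(all(c("P01", "P02") %in% cv1$selected$lambda_min))
  # lambda_1se is the sparser rule
  expect_gte(cv1$lambda_1se, cv1$lambda_min)
})

test_that("null proteins are rarely selected at lambda_min", {
  n_sel <- vapply(1:12, function(s) {
    d <- sim_surv(n = 80L, p = 15L, beta = numeric(0), seed = 200 + s,
                  rate = 0.08)
    if (sum(d$status) < 10L) return(NA_real_)
    cv <- cross_validate_cox(d$x, d$time, d$status, seed = s, nlambda = 40L)
    length(cv$selected$lambda_min)
  }, numeric(1))
  expect_lte(median(n_sel, na.rm = TRUE), 2)
})

test_that("bootstrap stability ranks planted proteins highly", {
  d <- sim_surv(n = 104L, p = 10L, beta = c(1.2, 1.2), seed = 8L,
                rate = 0.06)
  strata <- rep(c("OC", "OP"), each = 52L)
  bs <- bootstrap_stability(d$x, d$time, d$status, strata,
                            n_bootstrap = 40L, seed = 3L, nlambda = 40L)
  expect_gte(bs$frequency[["P01"]], 0.8)
  expect_gte(bs$frequency[["P02"]], 0.8)
  expect_true(all(bs$frequency >= 0 & bs$frequency <= 1))
  # threshold = 1 keeps only proteins selected in every resample
  strict <- names(bs$frequency)[bs$frequency >= 1]
  expect_setequal(
    bootstrap_stability(d$x, d$time, d$status, strata, n_bootstrap = 40L,
                        seed = 3L, nlambda = 40L, threshold = 1)$robust,
    strict)
})

test_that("degenerate survival inputs are rejected", {
  d <- sim_surv(n = 30L, p = 3L, seed = 9L)
  expect_error(fit_cox_lasso(d$x, d$time, rep(0L, 30L)), "event")
  expect_error(fit_cox_lasso(d$x, -d$time, d$status), "> 0")
  xx <- d$x; xx[1] <- NA
  expect_error(fit_cox_lasso(xx, d$time, d$status), "finite")
})
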