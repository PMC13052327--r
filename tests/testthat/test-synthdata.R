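# The synthetic-cohort generator: configuration validation, determinism,
# planted structure, and the survival arm.

test_that("configuration invariants are enforced", {
  expect_s3_class(simulation_config(), "simulation_config")
  expect_error(simulation_config(effect_fractions = c(null = 0.5,
                                                      age_only = 0.2,
                                                      disease_only = 0.2,
                                                      both = 0.2)), "sum to 1")
  expect_error(simulation_config(n_young = 0L), "positive")
  expect_error(simulation_config(hazard_proteins = 900L), "both")
  expect_error(simulation_config(frac_skewed = 1.2), "\\[0, 1\\]")
  expect_error(simulation_config(baseline_rates = c(a = 1, b = 2)), "OC")
})

test_that("the same seed reproduces the cohort bit-for-bit", {
  cfg <- simulation_config(n_proteins = 50L, seed = 42L)
  s1 <- simulate_cohort(cfg)
  s2 <- simulate_cohort(cfg)
  expect_identical(unclass(s1$npx), unclass(s2$npx))
  expect_identical(s1$cohort, s2$cohort)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_cohort(simulation_config(n_proteins = 50L, seed = 43L))
  expect_false(identical(unclass(s1$npx), unclass(s3$npx)))
})

test_that("cohort geometry matches the emulated design", {
  cfg <- simulation_config(n_young = 20L, n_older_pairs = 52L,
                           n_proteins = 30L, seed = 1L)
  sim <- simulate_cohort(cfg)
  expect_equal(as.vector(table(sim$cohort$group)[c("YC", "OC", "OP")]),
               c(20L, 52L, 52L))
  # matched pairs share sex
  oc <- sim$cohort[sim$cohort$group == "OC", ]
  op <- sim$cohort[sim$cohort$group == "OP", ]
  expect_equal(oc$sex[match(op$pair_id, oc$pair_id)], op$sex)
  # Young Controls never die
  expect_true(all(sim$cohort$event[sim$cohort$group == "YC"] == 0L))
  # truth classes match requested fractions up to rounding
  expect_equal(as.vector(table(factor(sim$truth$class,
    c("null", "age_only", "disease_only", "both")))),
    c(21L, 3L, 3L, 3L))
})

test_that("planted shifts land where the truth table says", {
  cfg <- simulation_config(n_proteins = 200L, sigma_protein = 0.1,
                           sigma_pair = 0, frac_skewed = 0, seed = 10L)
  sim <- simulate_cohort(cfg)
  v <- unclass(sim$npx)
  g <- sim$cohort$group[match(rownames(v), sim$cohort$sample_id)]
  for (cls in c("age_only", "both")) {
    idx <- which(sim$truth$class == cls & sim$truth$sign_age == 1)[1]
    expect_gt(mean(v[g == "OC", idx]) - mean(v[g == "YC", idx]), 0.8)
  }
  idx_d <- which(sim$truth$class == "disease_only" &
                   sim$truth$sign_disease == 1)[1]
  expect_gt(mean(v[g == "OP", idx_d]) - mean(v[g == "OC", idx_d]), 0.8)
  idx_n <- which(sim$truth$class == "null")[1]
  expect_lt(abs(mean(v[g == "OP", idx_n]) - mean(v[g == "YC", idx_n])), 0.1)
})

test_that("older-patient mortality dominates older-control mortality", {
  cfg <- simulation_config(n_proteins = 20L, hazard_proteins = 0L,
                           seed = 77L)
  sim <- simulate_cohort(cfg)
  ev <- tapply(sim$cohort$event, sim$cohort$group, mean)
  expect_gt(ev[["OP"]], ev[["OC"]])
  expect_gt(ev[["OP"]], 0.3)  # ~56% expected at the default rates
  expect_lt(ev[["OC"]], 0.3)  # ~8% expected
})

test_that("AP recovery power is monotone in the planted effect sizes", {
  power_at <- function(delta) {
    hits <- vapply(1:3, function(s) {
      cfg <- simulation_config(n_proteins = 150L, delta_age = delta,
                               delta_disease = delta, seed = 500L + s)
      sim <- simulate_cohort(cfg)
      de_a <- run_comparison(sim$npx, sim$cohort, "OC", "YC")
      de_d <- run_comparison(sim$npx, sim$cohort, "OP", "OC", paired = TRUE)
      asg <- classify_proteins(de_a, de_d)
      both <- sim$truth$class == "both"
      mean(asg$category[both] == "ap")
    }, numeric(1))
    mean(hits)
  }
  p <- vapply(c(0.15, 0.5, 1.0), power_at, numeric(1))
  expect_true(all(diff(p) >= -0.02))  # non-decreasing up to MC noise
  expect_gt(p[3], p[1])
})

test_that("null survival effects leave the two protein halves exchangeable", {
  # with beta_hazard = 0 and equal baseline rates, a split by any protein
  # yields a null log-rank statistic
  set.seed(91)
  pvals <- vapply(1:60, function(s) {
    cfg <- simulation_config(n_proteins = 4L, hazard_proteins = 0L,
                             baseline_rates = c(OC = 0.05, OP = 0.05),
                             seed = 3000L + s)
    sim <- simulate_cohort(cfg)
    older <- sim$cohort[sim$cohort$group != "YC", ]
    x1 <- unclass(sim$npx)[older$sample_id, 1L]
    grp <- x1 > median(x1)
    survival::survdiff(
      survival::Surv(older$survival_time, older$event) ~ grp)$pvalue
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(pvals, "punif")$p.value), 0.01)
})

test_that("literature list simulation respects coverage and decoys", {
  cfg <- simulation_config(n_proteins = 100L, seed = 6L)
  sim <- simulate_cohort(cfg)
  lists <- simulate_literature_lists(sim$truth, coverage = 0.5,
                                     decoys = 7L, seed = 2L)
  expect_setequal(vapply(lists, `[[`, "", "source_kind"),
                  c("age", "disease", "sasp"))
  for (l in lists) {
    off_panel <- setdiff(l$members, sim$truth$protein_id)
    expect_length(off_panel, 7L)
  }
  expect_error(simulate_literature_lists(sim$truth, coverage = 1.5), "0, 1")
})

test_that("cluster simulation validates its arguments", {
  expect_error(simulate_clusters(k_true = 1L), "k_true")
  expect_error(simulate_clusters(separation = -1), "separation")
  sc <- simulate_clusters(n_proteins = 30L, k_true = 3L, seed = 1L)
  expect_equal(length(sc$truth), 30L)
  expect_equal(sort(unique(sc$truth)), 1:3)
})
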