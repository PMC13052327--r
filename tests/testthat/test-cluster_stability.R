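# Z-scoring, hierarchical clustering, scree selection, Rand index and
# subsample stability.

test_that("z-scoring uses the sample-SD convention and is idempotent", {
  v <- matrix(c(1, 2, 3, 2, 2, 2), 3, 2,
              dimnames = list(c("s1", "s2", "s3"), c("pA", "pB")))
  expect_warning(z <- zscore_proteins(npx_matrix(v)), "constant")
  expect_equal(as.vector(z[, "pA"]), c(-1, 0, 1))  # sample SD of 1:3 is 1
  npx <- tiny_npx(10L, 6L)
  z1 <- zscore_proteins(npx)
  expect_equal(colMeans(z1), setNames(rep(0, 6L), colnames(z1)),
               tolerance = 1e-12)
  expect_equal(apply(z1, 2, sd), setNames(rep(1, 6L), colnames(z1)),
               tolerance = 1e-12)
})

test_that("two separated blobs split exactly at k = 2", {
  sc <- simulate_clusters(n_proteins = 60L, k_true = 2L, separation = 3,
                          seed = 5L)
  z <- zscore_proteins(sc$npx)
  m <- hcluster_proteins(z, k = 2L)
  expect_equal(rand_index(m$labels, sc$truth[names(m$labels)]), 1)
})

test_that("auto-k recovers a planted 4-cluster proteome across seeds", {
  for (s in 1:5) {
    sc <- simulate_clusters(n_proteins = 120L, k_true = 4L, separation = 4,
                            seed = s)
    m <- hcluster_proteins(zscore_proteins(sc$npx))
    expect_equal(m$k, 4L)
    expect_equal(rand_index(m$labels, sc$truth[names(m$labels)]), 1)
  }
})

test_that("duplicated proteins always co-cluster", {
  sc <- simulate_clusters(n_proteins = 40L, k_true = 2L, separation = 3,
                          seed = 2L)
  v <- unclass(sc$npx)
  v[, 2L] <- v[, 1L] + 1e-9  # near-exact duplicate, distinct id
  m <- hcluster_proteins(zscore_proteins(npx_matrix(v)), k = 2L)
  expect_equal(m$labels[[colnames(v)[1L]]], m$labels[[colnames(v)[2L]]])
})

test_that("clustering is invariant to protein input order", {
  sc <- simulate_clusters(n_proteins = 50L, k_true = 3L, separation = 3,
                          seed = 3L)
  z <- zscore_proteins(sc$npx)
  m1 <- hcluster_proteins(z, k = 3L)
  set.seed(1)
  z2 <- z[, sample(ncol(z))]
  m2 <- hcluster_proteins(z2, k = 3L)
  expect_equal(rand_index(m1$labels, m2$labels[names(m1$labels)]), 1)
})

test_that("scree rule finds a constructed elbow and flags degeneracy", {
  # heights with a dominant jump at the merge leaving 4 groups
  heights <- c(seq(0.1, 1, length.out = 16), 9, 9.5, 10)
  expect_equal(scree_select_k(heights), 4L)
  expect_warning(k <- scree_select_k(rep(2, 10)), "degenerate")
  expect_equal(k, 2L)
  # strictly linear heights have zero second differences everywhere -> 2
  expect_equal(scree_select_k(seq_len(10)), 2L)
})

test_that("rand_index matches exhaustive pair counting", {
  expect_equal(rand_index(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  expect_equal(rand_index(c(1, 1, 2, 2), c(1, 2, 1, 2)),
               rand_brute(c(1, 1, 2, 2), c(1, 2, 1, 2)))
  set.seed(17)
  for (i in 1:200) {
    n <- sample(5:50, 1)
    a <- sample(1:4, n, replace = TRUE)
    b <- sample(1:5, n, replace = TRUE)
    expect_identical(rand_index(a, b), rand_brute(a, b))
  }
  # all-singletons vs any partition: closed form
  n <- 20L
  a <- seq_len(n)
  b <- rep(1:4, each = 5L)
  within_b <- sum(choose(table(b), 2))
  expect_equal(rand_index(a, b), (choose(n, 2) - within_b) / choose(n, 2))
  expect_error(rand_index(setNames(1:3, c("a", "b", "c")),
                          setNames(1:3, c("a", "b", "d"))), "element")
})

test_that("stability is near 1 for separated clusters and near 0 for noise", {
  sc <- simulate_clusters(n_proteins = 100L, k_true = 4L, separation = 4,
                          seed = 1L)
  z <- zscore_proteins(sc$npx)
  m <- hcluster_proteins(z)
  st <- stability_assess(z, m, n_repeats = 25L, seed = 2L)
  expect_true(all(st$summary$normalized_score >= 0.95))
  scores0 <- vapply(1:5, function(s) {
    sc0 <- simulate_clusters(n_proteins = 80L, k_true = 4L, separation = 0,
                             seed = s)
    z0 <- zscore_proteins(sc0$npx)
    m0 <- hcluster_proteins(z0, k = 4L)
    st0 <- stability_assess(z0, m0, proportions = 0.9, n_repeats = 25L,
                            seed = s)
    st0$summary$normalized_score
  }, numeric(1))
  expect_true(all(abs(scores0) <= 0.35))
  expect_lt(mean(abs(scores0)), 0.2)
})

test_that("stability assessment is reproducible under a fixed seed", {
  sc <- simulate_clusters(n_proteins = 60L, k_true = 3L, separation = 3,
                          seed = 4L)
  z <- zscore_proteins(sc$npx)
  m <- hcluster_proteins(z)
  s1 <- stability_assess(z, m, proportions = 0.9, n_repeats = 5L, seed = 9L)
  s2 <- stability_assess(z, m, proportions = 0.9, n_repeats = 5L, seed = 9L)
  expect_identical(s1, s2)
})

test_that("euclidean and manhattan clusterings largely agree", {
  sc <- simulate_clusters(n_proteins = 100L, k_true = 4L, separation = 4,
                          seed = 6L)
  z <- zscore_proteins(sc$npx)
  me <- hcluster_proteins(z, "euclidean", k = 4L)
  mm <- hcluster_proteins(z, "manhattan", k = 4L)
  expect_gte(rand_index(me$labels, mm$labels[names(me$labels)]), 0.9)
})

test_that("hypergeometric enrichment matches exact tail summation", {
  panel <- sprintf("P%05d", 1:50)
  asg <- classify_proteins(fake_de(panel, panel[1:10]),
                           fake_de(panel, panel[1:10]))  # 10 aps
  labels <- setNames(rep(c(1L, 2L), c(10L, 40L)), panel)
  model <- structure(list(labels = labels, k = 2L, distance = "euclidean"),
                     class = "cluster_model")
  enr <- enrich_categories(model, asg, categories = "ap")
  row1 <- enr[enr$cluster == 1L, ]
  # cluster 1 holds all 10 category members drawn in 10 tries: p = 1/C(50,10)
  expect_equal(row1$p_raw, 1 / choose(50, 10), tolerance = 1e-12)
  expect_equal(row1$p_raw, hyper_tail_brute(10, 10, 50, 10),
               tolerance = 1e-10)
  # zero overlap has p exactly 1
  asg2 <- classify_proteins(fake_de(panel, panel[11:20]),
                            fake_de(panel, panel[11:20]))
  enr2 <- enrich_categories(model, asg2, categories = "ap")
  expect_equal(enr2$p_raw[enr2$cluster == 1L], 1)
})
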