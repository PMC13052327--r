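# Shared builders for small in-memory fixtures; everything is generated in
# code so tests carry no data files.

# tiny NPX matrix with given dimensions, filled deterministically
tiny_npx <- function(n_samples = 4L, n_proteins = 3L, seed = 1L) {
  set.seed(seed)
  values <- matrix(rnorm(n_samples * n_proteins, mean = 5), n_samples,
                   n_proteins,
                   dimnames = list(sprintf("S%02d", seq_len(n_samples)),
                                   sprintf("P%05d", seq_len(n_proteins))))
  npx_matrix(values)
}

# cohort with nY young + nP matched OC/OP pairs, all censored by default
tiny_cohort <- function(nY = 4L, nP = 6L, events_op = 0L) {
  ids <- c(sprintf("YC%02d", seq_len(nY)), sprintf("OC%02d", seq_len(nP)),
           sprintf("OP%02d", seq_len(nP)))
  ev <- integer(nY + 2L * nP)
  if (events_op > 0)
    ev[nY + nP + seq_len(events_op)] <- 1L
  validate_cohort(data.frame(
    sample_id = ids,
    group = c(rep("YC", nY), rep("OC", nP), rep("OP", nP)),
    pair_id = c(rep(NA_character_, nY), sprintf("P%02d", seq_len(nP)),
                sprintf("P%02d", seq_len(nP))),
    sex = rep_len(c("F", "M"), nY + 2L * nP),
    survival_time = rep(7, nY + 2L * nP),
    event = ev,
    stringsAsFactors = FALSE))
}

# a de_result-shaped table where exactly `sig` proteins are significant
fake_de <- function(panel, sig, direction = "up") {
  stopifnot(all(sig %in% panel))
  is_sig <- panel %in% sig
  out <- data.frame(
    protein_id = panel,
    assay = panel,
    test_used = "t_independent",
    p_raw = ifelse(is_sig, 1e-6, 0.9),
    p_adj = ifelse(is_sig, 1e-5, 0.95),
    fc_linear = ifelse(is_sig, if (direction == "up") 2 else 0.5, 1.01),
    stringsAsFactors = FALSE)
  out$log2_fc <- log2(out$fc_linear)
  out$neg_log10_p_adj <- -log10(out$p_adj)
  out$significant <- is_sig
  out$direction <- ifelse(out$fc_linear > 1, "up", "down")
  class(out) <- c("de_result", "data.frame")
  out
}

# brute-force BH step-up, straight from the definition
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# brute-force Rand index by exhaustive pair enumeration
rand_brute <- function(a, b) {
  n <- length(a)
  agree <- 0L
  total <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      total <- total + 1L
      same_a <- a[i] == a[j]
      same_b <- b[i] == b[j]
      if (same_a == same_b) agree <- agree + 1L
    }
  }
  agree / total
}

# exact hypergeometric upper tail by log-gamma PMF summation
hyper_tail_brute <- function(k, K, N, n) {
  lo <- max(k, 0)
  hi <- min(K, n)
  if (lo > hi) return(0)
  terms <- vapply(lo:hi, function(x)
    lchoose(K, x) + lchoose(N - K, n - x) - lchoose(N, n), numeric(1))
  m <- max(terms)
  exp(m) * sum(exp(terms - m))
}
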