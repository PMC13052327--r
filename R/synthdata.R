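# Synthetic cohort generator. Emulates the study design the pipeline
# assumes: three groups (Young Controls, Older Controls, Older Patients)
# with 1:1 OC-OP matching, mostly-upregulated age and disease effects on the
# log2 NPX scale, a planted overlap ("both") protein class, pair-correlated
# noise, a skew-contaminated protein minority, and mortality driven by a
# small planted protein set through a group-stratified exponential
# proportional-hazards model. Ground-truth labels accompany every output so
# downstream recovery can be scored.

#' Simulation configuration
#'
#' Builds and validates the parameter set for [simulate_cohort()]. Defaults
#' encode the emulated study conditions: 20 Young Controls, 52 matched
#' OC-OP pairs, log2-scale shifts of 1 NPX unit for affected proteins,
#' mostly-upregulated effects (20% of age effects and 5% of disease effects
#' negative), unit residual SD, a shared OC-OP pair effect on half the
#' proteins, 20% skew-contaminated proteins, and exponential baseline
#' hazards ten-fold higher in patients than controls with 7-year
#' administrative censoring (reproducing roughly 56% vs 8% mortality).
#'
#' @param n_young number of Young Controls.
#' @param n_older_pairs number of matched OC-OP pairs.
#' @param n_proteins panel size.
#' @param effect_fractions named proportions over protein classes
#'   `c(null=, age_only=, disease_only=, both=)`; must sum to 1.
#' @param delta_age log2-scale mean shift (NPX units) added in OC and OP for
#'   age-affected proteins.
#' @param delta_disease log2-scale shift added in OP only for
#'   disease-affected proteins.
#' @param frac_downregulated length-2 proportions `c(age, disease)` of
#'   affected proteins whose shift is negative.
#' @param sigma_protein residual SD (NPX units).
#' @param sigma_pair SD of the shared OC-OP pair random effect.
#' @param frac_paired fraction of proteins carrying the pair effect.
#' @param frac_skewed fraction of proteins with skew-contaminated
#'   (centred log-normal) noise.
#' @param sigma_log log-SD of the skew contamination.
#' @param hazard_proteins number of planted mortality proteins (drawn from
#'   the `both` class).
#' @param beta_hazard log hazard ratio per SD of a planted protein.
#' @param beta_sex log hazard ratio for male sex.
#' @param baseline_rates per-stratum exponential event rates, named
#'   `c(OC=, OP=)`, in events/year.
#' @param censor_time administrative censoring horizon (years).
#' @param seed RNG seed.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_young = 20L,
                              n_older_pairs = 52L,
                              n_proteins = 1000L,
                              effect_fractions = c(null = 0.70, age_only = 0.10,
                                                   disease_only = 0.10,
                                                   both = 0.10),
                              delta_age = 1.0,
                              delta_disease = 1.0,
                              frac_downregulated = c(age = 0.20, disease = 0.05),
                              sigma_protein = 1.0,
                              sigma_pair = 0.5,
                              frac_paired = 0.5,
                              frac_skewed = 0.20,
                              sigma_log = 0.8,
                              hazard_proteins = 2L,
                              beta_hazard = 1.0,
                              beta_sex = 0.3,
                              baseline_rates = c(OC = 0.0115, OP = 0.115),
                              censor_time = 7,
                              seed = 1L) {
  cfg <- list(n_young = as.integer(n_young),
              n_older_pairs = as.integer(n_older_pairs),
              n_proteins = as.integer(n_proteins),
              effect_fractions = effect_fractions,
              delta_age = delta_age, delta_disease = delta_disease,
              frac_downregulated = frac_downregulated,
              sigma_protein = sigma_protein, sigma_pair = sigma_pair,
              frac_paired = frac_paired, frac_skewed = frac_skewed,
              sigma_log = sigma_log,
              hazard_proteins = as.integer(hazard_proteins),
              beta_hazard = beta_hazard, beta_sex = beta_sex,
              baseline_rates = baseline_rates, censor_time = censor_time,
              seed = as.integer(seed))
  ef <- cfg$effect_fractions
  if (is.null(names(ef)) ||
      !setequal(names(ef), c("null", "age_only", "disease_only", "both")))
    stop("effect_fractions must be named null/age_only/disease_only/both")
  if (any(ef < 0) || abs(sum(ef) - 1) > 1e-8)
    stop("effect_fractions must be non-negative and sum to 1")
  if (length(cfg$frac_downregulated) == 1L)
    cfg$frac_downregulated <- c(age = unname(cfg$frac_downregulated),
                                disease = unname(cfg$frac_downregulated))
  if (any(cfg$frac_downregulated < 0 | cfg$frac_downregulated > 1))
    stop("frac_downregulated must lie in [0, 1]")
  if (cfg$n_young < 1L || cfg$n_older_pairs < 1L || cfg$n_proteins < 1L)
    stop("counts must be positive")
  if (cfg$frac_paired < 0 || cfg$frac_paired > 1 ||
      cfg$frac_skewed < 0 || cfg$frac_skewed > 1)
    stop("fractions must lie in [0, 1]")
  if (is.null(names(cfg$baseline_rates)) ||
      !setequal(names(cfg$baseline_rates), c("OC", "OP")))
    stop("baseline_rates must be named c(OC=, OP=)")
  if (any(cfg$baseline_rates < 0) || cfg$censor_time <= 0)
    stop("rates must be >= 0 and censor_time > 0")
  n_both <- round(ef[["both"]] * cfg$n_proteins)
  if (cfg$hazard_proteins > n_both)
    stop("hazard_proteins exceeds the planted 'both' class size")
  structure(cfg, class = "simulation_config")
}

# integer class counts that sum exactly to n (largest-remainder rounding)
class_counts <- function(fracs, n) {
  raw <- fracs * n
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

# centred noise with unit SD from a skewed (log-normal) source
skew_noise <- function(n, sigma_log) {
  x <- rlnorm(n, meanlog = 0, sdlog = sigma_log)
  mu <- exp(sigma_log^2 / 2)
  sdv <- sqrt((exp(sigma_log^2) - 1) * exp(sigma_log^2))
  (x - mu) / sdv
}

#' Simulate a synthetic three-group cohort
#'
#' Draws an NPX matrix, cohort table and ground-truth table under the model
#' `NPX(s, p) = mu_p + delta_age * 1[s in OC, OP] (age-affected)
#' + delta_disease * 1[s in OP] (disease-affected) + pair effect + noise`,
#' with signs flipped for the configured down-regulated minority, a shared
#' pair random effect on a configurable protein fraction, and Gaussian or
#' centred log-normal noise. Survival times for older participants are drawn
#' from group-stratified exponential baselines scaled by
#' `exp(sum(beta * z_protein) + beta_sex * male)` and censored
#' administratively; Young Controls are all censored (no events).
#'
#' @param config a [simulation_config()].
#' @return A list with elements `npx` ([npx_matrix()]), `cohort`
#'   (validated cohort data.frame) and `truth` (data.frame with per-protein
#'   class, shift signs and hazard coefficient).
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "simulation_config"))
    config <- do.call(simulation_config, config)
  set.seed(config$seed)
  P <- config$n_proteins
  nY <- config$n_young
  nPair <- config$n_older_pairs
  protein_ids <- sprintf("SP%05d", seq_len(P))

  counts <- class_counts(config$effect_fractions[
    c("null", "age_only", "disease_only", "both")], P)
  classes <- rep(c("null", "age_only", "disease_only", "both"), counts)
  classes <- sample(classes)  # interleave classes over the panel

  age_affected <- classes %in% c("age_only", "both")
  dis_affected <- classes %in% c("disease_only", "both")
  sign_age <- ifelse(age_affected,
                     ifelse(runif(P) < config$frac_downregulated[["age"]],
                            -1, 1), 0)
  sign_dis <- ifelse(dis_affected,
                     ifelse(runif(P) < config$frac_downregulated[["disease"]],
                            -1, 1), 0)
  beta <- numeric(P)
  both_idx <- which(classes == "both")
  hz <- sample(both_idx, config$hazard_proteins)
  beta[hz] <- config$beta_hazard

  is_paired <- runif(P) < config$frac_paired
  is_skewed <- runif(P) < config$frac_skewed
  mu <- rnorm(P, mean = 5, sd = 1)

  sample_ids <- c(sprintf("YC%03d", seq_len(nY)),
                  sprintf("OC%03d", seq_len(nPair)),
                  sprintf("OP%03d", seq_len(nPair)))
  group <- c(rep("YC", nY), rep("OC", nPair), rep("OP", nPair))
  n <- length(sample_ids)

  values <- matrix(0, nrow = n, ncol = P,
                   dimnames = list(sample_ids, protein_ids))
  shift <- outer(as.numeric(group != "YC"), sign_age * config$delta_age) +
    outer(as.numeric(group == "OP"), sign_dis * config$delta_disease)
  values <- values + rep(mu, each = n) + shift

  # shared OC-OP pair effect for the pair-correlated protein fraction
  pair_fx <- matrix(rnorm(nPair * P, sd = config$sigma_pair), nPair, P)
  pair_fx[, !is_paired] <- 0
  oc_rows <- which(group == "OC")
  op_rows <- which(group == "OP")
  values[oc_rows, ] <- values[oc_rows, ] + pair_fx
  values[op_rows, ] <- values[op_rows, ] + pair_fx

  noise <- matrix(0, n, P)
  n_gauss <- sum(!is_skewed)
  if (n_gauss) noise[, !is_skewed] <- rnorm(n * n_gauss)
  if (any(is_skewed))
    noise[, is_skewed] <- skew_noise(n * sum(is_skewed), config$sigma_log)
  values <- values + config$sigma_protein * noise

  sex <- character(n)
  sex[group == "YC"] <- rep_len(c("F", "M"), nY)
  pair_sex <- rep_len(c("F", "M"), nPair)  # matched pairs share sex
  sex[oc_rows] <- pair_sex
  sex[op_rows] <- pair_sex
  pair_id <- rep(NA_character_, n)
  pair_id[oc_rows] <- sprintf("P%03d", seq_len(nPair))
  pair_id[op_rows] <- sprintf("P%03d", seq_len(nPair))

  # survival: stratified exponential baseline x planted-protein hazard
  time <- rep(config$censor_time, n)
  event <- integer(n)
  if (any(beta != 0) || any(config$baseline_rates > 0)) {
    older <- c(oc_rows, op_rows)
    z <- scale(values[older, beta != 0, drop = FALSE])
    lp <- if (length(older) && any(beta != 0))
      as.vector(z %*% beta[beta != 0]) else numeric(length(older))
    lp <- lp + config$beta_sex * as.numeric(sex[older] == "M")
    rate <- config$baseline_rates[ifelse(group[older] == "OC", "OC", "OP")] *
      exp(lp)
    tt <- rexp(length(older), rate = pmax(rate, 1e-12))
    event[older] <- as.integer(tt < config$censor_time)
    time[older] <- pmin(tt, config$censor_time)
  }

  cohort <- data.frame(sample_id = sample_ids, group = group,
                       pair_id = pair_id, sex = sex,
                       survival_time = time, event = event,
                       stringsAsFactors = FALSE)
  truth <- data.frame(protein_id = protein_ids, class = classes,
                      sign_age = sign_age, sign_disease = sign_dis,
                      beta_hazard = beta, paired_noise = is_paired,
                      skewed_noise = is_skewed, stringsAsFactors = FALSE)
  list(npx = npx_matrix(values), cohort = validate_cohort(cohort),
       truth = truth)
}

#' Simulate a proteome with planted co-expression clusters
#'
#' Proteins are drawn around `k_true` cluster-level mean profiles across the
#' three participant groups (each cluster's group-profile is a scaled random
#' direction of length `separation`), with unit Gaussian noise per sample.
#' Used as the fixture for clustering and stability assessment.
#'
#' @param n_proteins panel size.
#' @param k_true number of planted clusters (>= 2).
#' @param separation effect size: SD of the cluster-profile spread across
#'   samples; 0 means no structure.
#' @param n_per_group samples per participant group (length-3, YC/OC/OP).
#' @param seed RNG seed.
#' @return A list with `npx` ([npx_matrix()]) and `truth` (integer cluster
#'   membership named by protein).
#' @export
simulate_clusters <- function(n_proteins = 200L, k_true = 4L, separation = 4,
                              n_per_group = c(20L, 52L, 52L), seed = 1L) {
  if (k_true < 2L) stop("k_true must be >= 2")
  if (separation < 0) stop("separation must be >= 0")
  set.seed(seed)
  n <- sum(n_per_group)
  group <- rep(c("YC", "OC", "OP"), n_per_group)
  # Cluster centers live in the plane of group profiles with zero
  # size-weighted mean, so per-protein z-scoring preserves their geometry;
  # evenly spaced on a circle (rotated per seed) so inter-cluster distances
  # are comparable and the scree elbow sits at k_true. The basis is
  # orthonormal under the group-size-weighted inner product with unit
  # per-sample RMS, making `separation` a per-sample effect size in noise-SD
  # units, identical for every cluster.
  w <- n_per_group
  ntot <- sum(w)
  proj <- function(x) x - sum(w * x) / ntot
  v1 <- proj(c(1, 0, 0))
  v1 <- v1 / sqrt(sum(w * v1^2) / ntot)
  v2 <- proj(c(0, 1, 0))
  v2 <- v2 - v1 * sum(w * v1 * v2) / ntot
  v2 <- v2 / sqrt(sum(w * v2^2) / ntot)
  theta <- 2 * pi * seq_len(k_true) / k_true + runif(1L, 0, 2 * pi)
  centers <- separation * cbind(cos(theta), sin(theta)) %*% rbind(v1, v2)
  membership <- sort(rep_len(seq_len(k_true), n_proteins))
  membership <- sample(membership)
  gidx <- match(group, c("YC", "OC", "OP"))
  profile <- centers[, gidx, drop = FALSE]  # k_true x n
  values <- t(profile[membership, , drop = FALSE]) +
    matrix(rnorm(n * n_proteins), n, n_proteins)
  dimnames(values) <- list(
    sprintf("%s%03d", group, unlist(lapply(n_per_group, seq_len))),
    sprintf("SP%05d", seq_len(n_proteins)))
  names(membership) <- colnames(values)
  list(npx = npx_matrix(values), truth = membership)
}

#' Simulate literature protein lists from a truth table
#'
#' Builds one list per source kind covering a fixed fraction of the relevant
#' planted proteins (age: `age_only` + `both`; disease: `disease_only` +
#' `both`; sasp: `both`), plus decoy accessions absent from the panel. The
#' covered count is deterministic: `floor(coverage * K)` members drawn
#' without replacement.
#'
#' @param truth the truth table from [simulate_cohort()].
#' @param coverage proportion of relevant planted proteins included.
#' @param decoys number of off-panel decoy accessions per list.
#' @param seed RNG seed.
#' @return A named list of [literature_set()] objects.
#' @export
simulate_literature_lists <- function(truth, coverage = 0.9, decoys = 50L,
                                      seed = 1L) {
  if (coverage < 0 || coverage > 1) stop("coverage must lie in [0, 1]")
  set.seed(seed)
  relevant <- list(
    age = truth$protein_id[truth$class %in% c("age_only", "both")],
    disease = truth$protein_id[truth$class %in% c("disease_only", "both")],
    sasp = truth$protein_id[truth$class == "both"]
  )
  out <- list()
  for (kind in names(relevant)) {
    pool <- relevant[[kind]]
    k <- floor(coverage * length(pool))
    members <- if (k > 0) sample(pool, k) else character()
    if (decoys > 0)
      members <- c(members, sprintf("X%05dZ", sample.int(99999L, decoys)))
    if (length(members))
      out[[paste0("synthetic_", kind)]] <-
        literature_set(paste0("synthetic_", kind), kind, members)
  }
  out
}
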