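# Protein co-expression structure: per-protein z-scoring, complete-linkage
# agglomerative clustering of proteins, scree-based choice of the cluster
# number, subsample Rand-index stability with a random-label baseline, and
# hypergeometric enrichment of protein categories within clusters.

#' Z-score each protein across samples
#'
#' Centers and scales every protein (column) to mean 0 and sample SD 1
#' (n - 1 denominator) so each protein contributes equally to distances.
#' Constant proteins, whose SD is zero, are dropped with a warning.
#'
#' @param npx an [npx_matrix()] (samples x proteins).
#' @return A plain numeric matrix of the same orientation.
#' @export
zscore_proteins <- function(npx) {
  x <- unclass(npx)
  sds <- apply(x, 2L, sd)
  keep <- sds > 0
  if (!any(keep)) stop("all proteins are constant")
  if (!all(keep))
    warning(sprintf("dropping %d constant protein(s)", sum(!keep)))
  x <- x[, keep, drop = FALSE]
  scale(x, center = TRUE, scale = apply(x, 2L, sd))
}

#' Complete-linkage hierarchical clustering of proteins
#'
#' Proteins are the clustered objects and samples the features. Proteins
#' are ordered lexicographically by identifier before clustering so the
#' result is invariant to input column order (ties in the agglomeration are
#' then broken deterministically by that order).
#'
#' @param z standardized matrix from [zscore_proteins()] (samples x
#'   proteins).
#' @param distance `"euclidean"` (default) or `"manhattan"`.
#' @param k number of clusters, or `"auto"` to apply [scree_select_k()].
#' @param k_max upper bound for the automatic scree search.
#' @return A list of class `cluster_model`: `distance`, `hclust` (the full
#'   agglomeration), `heights`, `k`, `labels` (named integer vector),
#'   `sizes`.
#' @export
hcluster_proteins <- function(z, distance = c("euclidean", "manhattan"),
                              k = "auto", k_max = 20L) {
  distance <- match.arg(distance)
  if (ncol(z) < 2L) stop("need at least 2 proteins")
  z <- z[, order(colnames(z)), drop = FALSE]
  d <- dist(t(z), method = distance)
  hc <- hclust(d, method = "complete")
  if (identical(k, "auto")) {
    k <- scree_select_k(hc$height, k_max = k_max)
  } else {
    k <- as.integer(k)
    if (k < 2L || k > ncol(z)) stop("k out of range")
  }
  labels <- cutree(hc, k = k)
  structure(list(distance = distance, hclust = hc, heights = hc$height,
                 k = k, labels = labels,
                 sizes = as.integer(table(labels))),
            class = "cluster_model")
}

#' Scree-based cluster-number selection
#'
#' Reverses the merge-height sequence (so position j is the height at which
#' j clusters merge into j - 1) and returns the k in \[2, k_max\] with the
#' largest second difference — the elbow where heights collapse from the
#' between-cluster to the within-cluster regime. A degenerate profile (all
#' heights equal) returns 2 with a warning.
#'
#' @param heights merge heights from `hclust` (ascending).
#' @param k_max largest k considered.
#' @return Selected k (integer).
#' @export
scree_select_k <- function(heights, k_max = 20L) {
  if (length(heights) < 3L) stop("need at least 3 merges")
  s <- rev(heights)  # s[j]: height of the merge taking j+? -> j clusters
  if (diff(range(heights)) == 0) {
    warning("degenerate merge heights; returning k = 2")
    return(2L)
  }
  upper <- min(k_max, length(s) - 1L)
  ks <- 2:upper
  d2 <- s[ks - 1L] - 2 * s[ks] + s[ks + 1L]
  as.integer(ks[which.max(d2)])
}

#' Rand index between two partitions
#'
#' Classic pair-counting agreement: the fraction of element pairs on which
#' the two partitions concur (both together or both apart). Computed from
#' the contingency table in O(ab) for a x b clusters.
#'
#' @param partition_a,partition_b cluster label vectors over the same
#'   elements (matched by name when both are named, by position otherwise).
#' @return Rand index in \[0, 1\].
#' @export
rand_index <- function(partition_a, partition_b) {
  if (!is.null(names(partition_a)) && !is.null(names(partition_b))) {
    if (!setequal(names(partition_a), names(partition_b)))
      stop("partitions cover different element sets")
    partition_b <- partition_b[names(partition_a)]
  } else if (length(partition_a) != length(partition_b)) {
    stop("partitions cover different element sets")
  }
  n <- length(partition_a)
  if (n < 2L) return(1)
  tab <- table(partition_a, partition_b)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  total <- choose(n, 2)
  (total + 2 * sum_ij - sum_a - sum_b) / total
}

#' Subsample stability of a protein clustering
#'
#' For each subsampling proportion, repeatedly draws `floor(nu * P)`
#' proteins without replacement, reclusters them with the model's distance,
#' linkage and k, and scores the Rand index between the subsample partition
#' and the full-data labels restricted to the drawn proteins. Because the
#' raw Rand index scales trivially with cluster sizes, each repeat also
#' scores a random-label baseline — the full-data restricted labels randomly
#' permuted (preserving the cluster-size profile) — and the normalized
#' stability score is `(mean Rand - baseline) / (1 - baseline)`, so 0 is
#' chance-level agreement and 1 perfect reproducibility.
#'
#' @param z standardized matrix the model was fitted on.
#' @param model a `cluster_model` from [hcluster_proteins()].
#' @param proportions subsampling proportions nu.
#' @param n_repeats subsample draws per proportion.
#' @param seed RNG seed.
#' @return A list of class `stability_result`: `per_draw` (data.frame of
#'   nu, repeat, Rand, baseline draw) and `summary` (per-nu mean Rand,
#'   baseline and normalized score).
#' @export
stability_assess <- function(z, model, proportions = c(0.85, 0.90, 0.95),
                             n_repeats = 100L, seed = 1L) {
  stopifnot(inherits(model, "cluster_model"))
  set.seed(seed)
  P <- ncol(z)
  full <- model$labels
  if (!setequal(names(full), colnames(z)))
    stop("model was not fitted on this matrix")
  per <- list()
  for (nu in proportions) {
    m <- floor(nu * P)
    if (m < model$k) stop("nu * P smaller than k")
    for (r in seq_len(n_repeats)) {
      idx <- sort(sample.int(P, m))
      sub <- z[, idx, drop = FALSE]
      subm <- hcluster_proteins(sub, distance = model$distance, k = model$k)
      ref <- full[colnames(sub)]
      ri <- rand_index(subm$labels[names(ref)], ref)
      shuffled <- setNames(sample(ref), names(ref))
      base <- rand_index(shuffled, ref)
      per[[length(per) + 1L]] <- data.frame(nu = nu, rep = r, rand = ri,
                                            baseline = base)
    }
  }
  per <- do.call(rbind, per)
  summ <- do.call(rbind, lapply(split(per, per$nu), function(d) {
    mean_rand <- mean(d$rand)
    baseline <- mean(d$baseline)
    data.frame(nu = d$nu[1L], mean_rand = mean_rand, baseline = baseline,
               normalized_score = (mean_rand - baseline) / (1 - baseline))
  }))
  rownames(summ) <- NULL
  structure(list(per_draw = per, summary = summ), class = "stability_result")
}

#' Hypergeometric category enrichment per cluster
#'
#' For every (cluster, category) cell, tests over-representation of the
#' category inside the cluster against the whole panel: upper-tail
#' hypergeometric `P(X >= k)` with K category members among N panel
#' proteins and n drawn (cluster size), BH-corrected across all cells.
#'
#' @param model a `cluster_model`.
#' @param assignment a `category_assignment` over the same panel.
#' @param categories which categories to test.
#' @return A data.frame with `cluster`, `category`, `k`, `K`, `n`, `N`,
#'   `p_raw`, `p_adj`.
#' @export
enrich_categories <- function(model, assignment,
                              categories = c("chronological_only",
                                             "disease_only", "ap")) {
  labels <- model$labels
  if (!all(names(labels) %in% assignment$protein_id))
    stop("model panel not covered by the assignment")
  cat_of <- setNames(assignment$category, assignment$protein_id)[names(labels)]
  N <- length(labels)
  rows <- list()
  for (cl in sort(unique(labels))) {
    in_cl <- labels == cl
    n <- sum(in_cl)
    for (cc in categories) {
      K <- sum(cat_of == cc)
      k <- sum(in_cl & cat_of == cc)
      p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(cluster = cl, category = cc,
                                              k = k, K = K, n = n, N = N,
                                              p_raw = p)
    }
  }
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$p_raw)
  out
}
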