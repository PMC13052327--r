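# Pipeline orchestration: run every analysis stage in dependency order on
# either file inputs or a simulated cohort, writing one TSV per stage plus
# a JSON run manifest. This function is the package's end-to-end entry
# point; each stage remains individually callable.

#' Run the full analysis pipeline
#'
#' Stage order: differential expression (OC vs YC unpaired, OP vs OC
#' paired) -> AP classification -> literature overlap and novel-marker
#' calling -> clustering with stability assessment and category
#' enrichment -> over-representation analysis -> mortality signature ->
#' clinical correlates. Stages without their required inputs (e.g. ORA
#' without a gene-set collection) are skipped and recorded as such in the
#' manifest.
#'
#' @param config a named list with exactly one of:
#'   * `simulation`: arguments for [simulation_config()], or
#'   * `inputs`: list of file paths `npx` (long CSV), `cohort` (CSV),
#'     optionally `literature` (TSV), `gmt`, `mapping` (TSV with columns
#'     `uniprot`, `gene_symbol`);
#'
#'   plus optional per-stage parameter blocks `diffexp`
#'   (`alpha_normality`, `alpha_fdr`, `gate`), `cluster` (`distance`, `k`,
#'   `proportions`, `n_repeats`), `ora` (`min_size`, `max_size`),
#'   `survival` (`rule`, `n_bootstrap`, `threshold`, `n_folds`,
#'   `nlambda`), `correlates` (`measures`, `groups`), and a global `seed`.
#' @param outdir output directory (created if missing).
#' @return Invisibly, a list with the stage results and the manifest.
#' @export
run_pipeline <- function(config, outdir) {
  if (!is.null(config$simulation) && !is.null(config$inputs))
    stop("config must use exactly one of `simulation` or `inputs`")
  if (is.null(config$simulation) && is.null(config$inputs))
    stop("config must provide `simulation` or `inputs`")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  manifest <- list(package = "npxaging",
                   version = as.character(packageVersion("npxaging")),
                   seed = seed, stages = list())
  t_all <- proc.time()[["elapsed"]]
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    message(sprintf("[%s] running", name))
    out <- tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    manifest$stages[[name]] <<- list(
      seconds = round(proc.time()[["elapsed"]] - t0, 2))
    out
  }

  truth <- NULL
  lists <- NULL
  collection <- NULL
  mapping <- NULL
  if (!is.null(config$simulation)) {
    sim <- stage("simulate", {
      cfg <- do.call(simulation_config,
                     modifyList(config$simulation, list(seed = seed)))
      simulate_cohort(cfg)
    })
    npx <- sim$npx
    cohort <- sim$cohort
    truth <- sim$truth
    write_table(truth, file.path(outdir, "truth.tsv"))
    lists <- simulate_literature_lists(truth, seed = seed)
  } else {
    npx <- stage("read", read_npx_long(config$inputs$npx))
    cohort <- read_cohort(config$inputs$cohort)
    if (!is.null(config$inputs$literature))
      lists <- read_literature(config$inputs$literature)
    if (!is.null(config$inputs$gmt))
      collection <- read_gmt(config$inputs$gmt)
    if (!is.null(config$inputs$mapping))
      mapping <- as.data.frame(data.table::fread(config$inputs$mapping))
  }

  de_par <- modifyList(list(alpha_normality = 0.05, alpha_fdr = 0.05,
                            gate = "both"),
                       config$diffexp %||% list())
  de_age <- stage("diffexp_age", run_comparison(
    npx, cohort, "OC", "YC", paired = FALSE,
    alpha_normality = de_par$alpha_normality, alpha_fdr = de_par$alpha_fdr,
    gate = de_par$gate))
  de_dis <- stage("diffexp_disease", run_comparison(
    npx, cohort, "OP", "OC", paired = TRUE,
    alpha_normality = de_par$alpha_normality, alpha_fdr = de_par$alpha_fdr,
    gate = de_par$gate))
  write_table(de_age, file.path(outdir, "de_age.tsv"))
  write_table(de_dis, file.path(outdir, "de_disease.tsv"))

  assignment <- stage("classify", classify_proteins(de_age, de_dis))
  write_table(assignment, file.path(outdir, "categories.tsv"))
  manifest$venn <- attr(assignment, "venn")

  overlap <- NULL
  novel <- NULL
  if (!is.null(lists)) {
    overlap <- stage("overlap", overlap_with_literature(assignment, lists))
    novel <- novel_candidates(assignment, lists)
    write_table(overlap, file.path(outdir, "literature_overlap.tsv"))
    write_table(data.frame(protein_id = novel),
                file.path(outdir, "novel_candidates.tsv"))
  }

  cl_par <- modifyList(list(distance = "euclidean", k = "auto",
                            proportions = c(0.85, 0.90, 0.95),
                            n_repeats = 100L),
                       config$cluster %||% list())
  clust <- stage("cluster", {
    z <- zscore_proteins(npx)
    model <- hcluster_proteins(z, distance = cl_par$distance, k = cl_par$k)
    stab <- stability_assess(z, model, proportions = cl_par$proportions,
                             n_repeats = cl_par$n_repeats, seed = seed)
    enr <- enrich_categories(model, assignment)
    list(model = model, stability = stab, enrichment = enr)
  })
  write_table(data.frame(protein_id = names(clust$model$labels),
                         cluster = clust$model$labels),
              file.path(outdir, "cluster_labels.tsv"))
  write_table(clust$stability$summary, file.path(outdir, "stability.tsv"))
  write_table(clust$enrichment, file.path(outdir, "cluster_enrichment.tsv"))
  manifest$k <- clust$model$k

  ora <- NULL
  if (!is.null(collection) && !is.null(mapping)) {
    ora_par <- modifyList(list(min_size = 5L, max_size = 2000L),
                          config$ora %||% list())
    ora <- stage("ora", run_ora(
      assignment$protein_id[assignment$category == "ap"], collection,
      assignment$protein_id, mapping,
      min_size = ora_par$min_size, max_size = ora_par$max_size))
    write_table(ora, file.path(outdir, "ora.tsv"))
  }

  sig <- NULL
  aps <- assignment$protein_id[assignment$category == "ap"]
  # stratified 10-fold CV needs at least two events in each older stratum
  older_events <- tapply(cohort$event[cohort$group != "YC"],
                         cohort$group[cohort$group != "YC"], sum)
  has_events <- !is.null(cohort$event) && length(older_events) == 2L &&
    all(older_events >= 2)
  if (length(aps) >= 2L && has_events) {
    sv_par <- modifyList(list(rule = "lambda_min", n_bootstrap = 100L,
                              threshold = 0.5, n_folds = 10L,
                              nlambda = 100L),
                         config$survival %||% list())
    sig <- stage("survival", mortality_signature(
      npx, cohort, aps, rule = sv_par$rule,
      n_bootstrap = sv_par$n_bootstrap, threshold = sv_par$threshold,
      n_folds = sv_par$n_folds, seed = seed, nlambda = sv_par$nlambda))
    write_table(data.frame(protein_id = names(sig$stability$frequency),
                           frequency = sig$stability$frequency,
                           robust = names(sig$stability$frequency) %in%
                             sig$stability$robust),
                file.path(outdir, "signature_frequencies.tsv"))
    manifest$signature <- list(selected = sig$selected,
                               robust = sig$stability$robust,
                               rule = sv_par$rule)
  }

  corr <- NULL
  co_par <- modifyList(list(measures = NULL, groups = c("OC", "OP")),
                       config$correlates %||% list())
  corr_proteins <- if (!is.null(sig) && length(sig$stability$robust))
    sig$stability$robust else head(aps, 2L)
  has_measures <- length(setdiff(
    names(cohort)[vapply(cohort, is.numeric, logical(1L))],
    c("survival_time", "event"))) > 0 || !is.null(co_par$measures)
  if (length(corr_proteins) && has_measures) {
    corr <- tryCatch(
      stage("correlate", correlate_measures(
        npx, cohort, corr_proteins, measures = co_par$measures,
        groups = co_par$groups)),
      error = function(e) NULL)
    if (!is.null(corr))
      write_table(corr, file.path(outdir, "correlates.tsv"))
  }

  manifest$seconds_total <- round(proc.time()[["elapsed"]] - t_all, 2)
  manifest$outputs <- list.files(outdir, pattern = "\\.tsv$")
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(npx = npx, cohort = cohort, truth = truth,
                 de_age = de_age, de_disease = de_dis,
                 assignment = assignment, overlap = overlap, novel = novel,
                 cluster = clust, ora = ora, signature = sig,
                 correlates = corr, manifest = manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
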