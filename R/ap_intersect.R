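# Classification of panel proteins by the intersection of the two
# differential-expression contrasts, and overlap of the resulting categories
# with literature-derived protein lists keyed by UniProt accession.

strip_isoform <- function(acc) sub("-[0-9]+$", "", acc)

# one-decimal percentage, half-up (presentation convention)
round_pct <- function(count, denom) {
  if (denom == 0) return(0)
  floor(1000 * count / denom + 0.5) / 10
}

#' Classify proteins by intersecting two DE results
#'
#' A protein significant in the age-group contrast (OC vs YC) and in the
#' disease-burden contrast (OP vs OC) is a biological Aging Protein (`ap`);
#' significance in exactly one contrast yields `chronological_only` or
#' `disease_only`; neither yields `neither`. The four categories partition
#' the panel by construction.
#'
#' @param de_age,de_disease `de_result` tables covering the same panel.
#' @return A data.frame of class `category_assignment` with columns
#'   `protein_id`, `category`, `dir_age`, `dir_disease`, plus a `venn`
#'   attribute with the category counts and per-category direction tallies.
#' @export
classify_proteins <- function(de_age, de_disease) {
  if (!setequal(de_age$protein_id, de_disease$protein_id))
    stop("the two DE results must cover the same panel")
  de_disease <- de_disease[match(de_age$protein_id, de_disease$protein_id), ]
  sig_a <- de_age$significant
  sig_d <- de_disease$significant
  category <- ifelse(sig_a & sig_d, "ap",
              ifelse(sig_a, "chronological_only",
              ifelse(sig_d, "disease_only", "neither")))
  out <- data.frame(protein_id = de_age$protein_id,
                    category = category,
                    dir_age = de_age$direction,
                    dir_disease = de_disease$direction,
                    stringsAsFactors = FALSE)
  venn <- list(
    n_sig_age = sum(sig_a),
    n_sig_disease = sum(sig_d),
    ap = sum(category == "ap"),
    chronological_only = sum(category == "chronological_only"),
    disease_only = sum(category == "disease_only"),
    neither = sum(category == "neither"),
    ap_up_age = sum(category == "ap" & out$dir_age == "up", na.rm = TRUE),
    ap_down_age = sum(category == "ap" & out$dir_age == "down", na.rm = TRUE),
    ap_up_disease = sum(category == "ap" & out$dir_disease == "up",
                        na.rm = TRUE),
    ap_down_disease = sum(category == "ap" & out$dir_disease == "down",
                          na.rm = TRUE)
  )
  attr(out, "venn") <- venn
  class(out) <- c("category_assignment", "data.frame")
  out
}

lit_aggregates <- function(lists) {
  kinds <- vapply(lists, `[[`, "", "source_kind")
  agg <- lapply(split(lists, kinds), function(ls)
    unique(unlist(lapply(ls, `[[`, "members"))))
  agg[["all"]] <- unique(unlist(lapply(lists, `[[`, "members")))
  agg
}

#' Quantify category overlap with literature lists
#'
#' For every literature list, every within-source-kind aggregate (union) and
#' the grand union, reports the panel coverage (members present on the
#' panel) and, per protein category, the overlap count with two percentage
#' denominators: the category size and the list-on-panel size. Matching is
#' on UniProt accessions with isoform suffixes stripped, restricted to the
#' panel.
#'
#' @param assignment a `category_assignment` from [classify_proteins()].
#' @param lists a list of [literature_set()] objects.
#' @param panel character vector of panel UniProt accessions (defaults to
#'   the assignment's panel).
#' @return A data.frame, one row per (list or aggregate) x category, with
#'   columns `list_name`, `source_kind`, `panel_coverage`, `list_size`,
#'   `category`, `category_size`, `overlap`, `pct_of_category`,
#'   `pct_of_list_on_panel`.
#' @export
overlap_with_literature <- function(assignment, lists,
                                    panel = assignment$protein_id) {
  panel_key <- strip_isoform(panel)
  cats <- c("chronological_only", "disease_only", "ap")
  members_by_cat <- lapply(cats, function(cc)
    strip_isoform(assignment$protein_id[assignment$category == cc]))
  names(members_by_cat) <- cats

  units <- c(
    lapply(lists, function(l)
      list(name = l$name, kind = l$source_kind, members = l$members)),
    lapply(names(lit_aggregates(lists)), function(k)
      list(name = paste0("aggregate_", k), kind = k,
           members = lit_aggregates(lists)[[k]]))
  )
  rows <- lapply(units, function(u) {
    mem <- unique(strip_isoform(u$members))
    on_panel <- intersect(mem, panel_key)
    do.call(rbind, lapply(cats, function(cc) {
      ov <- length(intersect(members_by_cat[[cc]], on_panel))
      data.frame(list_name = u$name, source_kind = u$kind,
                 list_size = length(mem),
                 panel_coverage = length(on_panel),
                 category = cc,
                 category_size = length(members_by_cat[[cc]]),
                 overlap = ov,
                 pct_of_category = round_pct(ov, length(members_by_cat[[cc]])),
                 pct_of_list_on_panel = round_pct(ov, length(on_panel)),
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Novel AP candidates
#'
#' Aging Proteins absent from the union of all supplied literature lists
#' (after isoform stripping). A protein missing from every list is reported
#' novel even if some lists cover platforms lacking it; the definition is a
#' plain set difference against the grand union.
#'
#' @inheritParams overlap_with_literature
#' @return Character vector of novel AP accessions (panel spelling).
#' @export
novel_candidates <- function(assignment, lists) {
  union_all <- unique(strip_isoform(unlist(lapply(lists, `[[`, "members"))))
  aps <- assignment$protein_id[assignment$category == "ap"]
  aps[!strip_isoform(aps) %in% union_all]
}
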