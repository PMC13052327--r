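# Readers/writers for the tabular formats the pipeline touches.
# UniProt accession is the primary key everywhere; assay display names are
# decoration carried along for reporting.

#' Construct an NPX matrix
#'
#' Container for Olink-style NPX data: a samples x proteins numeric matrix of
#' log2-scale relative expression, keyed by sample identifiers (rows) and
#' UniProt accessions (columns), with optional assay display names.
#'
#' @param values numeric matrix, samples in rows, proteins in columns;
#'   rownames are sample identifiers, colnames UniProt accessions.
#' @param assays optional character vector of assay display names, named by
#'   UniProt accession (defaults to the accessions themselves).
#' @return An object of class `npx_matrix`: the matrix with an `assays`
#'   attribute.
#' @export
npx_matrix <- function(values, assays = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have sample rownames and protein colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate sample identifiers")
  if (anyDuplicated(colnames(values)))
    stop("duplicate protein identifiers")
  if (!all(is.finite(values)))
    stop("NPX values must all be finite")
  if (is.null(assays)) {
    assays <- setNames(colnames(values), colnames(values))
  } else {
    if (is.null(names(assays))) names(assays) <- colnames(values)
    assays <- assays[colnames(values)]
    assays[is.na(assays)] <- colnames(values)[is.na(assays)]
    names(assays) <- colnames(values)
  }
  structure(values, assays = assays, class = c("npx_matrix", "matrix", "array"))
}

#' @export
print.npx_matrix <- function(x, ...) {
  cat(sprintf("<npx_matrix> %d samples x %d proteins (NPX, log2 scale)\n",
              nrow(x), ncol(x)))
  invisible(x)
}

npx_assays <- function(x) attr(x, "assays")

#' Read a long-format NPX export
#'
#' Parses the Olink long CSV/TSV dialect with mandatory columns `SampleID`,
#' `UniProt`, `Assay`, `NPX` (delimiter sniffed among comma, semicolon and
#' tab; decimal point only) and pivots it to a samples x proteins
#' [npx_matrix()]. Duplicate (sample, protein) measurements are an error.
#' Rows carrying a `QC_Warning` other than `PASS` are retained with a
#' warning, mirroring panels where no sample or protein is removed on a QC
#' flag alone.
#'
#' @param path path to the long-format file.
#' @return An [npx_matrix()].
#' @export
read_npx_long <- function(path) {
  dt <- data.table::fread(path, colClasses = list(character = "SampleID"))
  need <- c("SampleID", "UniProt", "Assay", "NPX")
  missing_cols <- setdiff(need, names(dt))
  if (length(missing_cols))
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  if (!is.numeric(dt$NPX))
    stop("NPX column is not numeric")
  dup <- duplicated(dt[, c("SampleID", "UniProt")])
  if (any(dup)) {
    first <- dt[which(dup)[1L]]
    stop(sprintf("duplicate measurement for sample '%s', protein '%s'",
                 first$SampleID, first$UniProt))
  }
  if ("QC_Warning" %in% names(dt)) {
    flagged <- !is.na(dt$QC_Warning) & !(dt$QC_Warning %in% c("PASS", ""))
    if (any(flagged))
      warning(sprintf("%d QC-flagged measurement(s) retained", sum(flagged)))
  }
  wide <- data.table::dcast(dt, SampleID ~ UniProt, value.var = "NPX")
  values <- as.matrix(wide[, -1L])
  rownames(values) <- wide$SampleID
  assays <- dt$Assay[!duplicated(dt$UniProt)]
  names(assays) <- dt$UniProt[!duplicated(dt$UniProt)]
  npx_matrix(values, assays = assays)
}

#' Write an NPX matrix in the long dialect
#'
#' @param x an [npx_matrix()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_npx_long <- function(x, path) {
  assays <- npx_assays(x)
  long <- data.table::data.table(
    SampleID = rep(rownames(x), times = ncol(x)),
    UniProt = rep(colnames(x), each = nrow(x)),
    Assay = rep(unname(assays), each = nrow(x)),
    NPX = as.vector(unclass(x)[, , drop = FALSE])
  )
  data.table::fwrite(long, path)
  invisible(path)
}

#' Read / write a wide NPX table (samples x proteins TSV)
#'
#' First column `SampleID`, remaining columns UniProt accessions.
#'
#' @param path file path.
#' @rdname npx_wide
#' @export
read_npx_wide <- function(path) {
  dt <- data.table::fread(path, colClasses = list(character = "SampleID"))
  if (names(dt)[1L] != "SampleID") stop("first column must be SampleID")
  values <- as.matrix(dt[, -1L])
  rownames(values) <- dt$SampleID
  npx_matrix(values)
}

#' @param x an [npx_matrix()].
#' @rdname npx_wide
#' @export
write_npx_wide <- function(x, path) {
  dt <- data.table::data.table(SampleID = rownames(x))
  dt <- cbind(dt, data.table::as.data.table(unclass(x)))
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Validate a cohort annotation table
#'
#' Enforces the cohort-table contract: `group` in {YC, OC, OP}; each non-NA
#' `pair_id` shared by exactly one OC and one OP; Young Controls all censored
#' (`event = 0`); positive survival times where present.
#'
#' @param cohort data.frame with columns `sample_id`, `group`, `pair_id`,
#'   `sex`, `survival_time`, `event`, plus any numeric clinical measures.
#' @return The validated data.frame (invisibly usable as-is).
#' @export
validate_cohort <- function(cohort) {
  need <- c("sample_id", "group", "sex")
  miss <- setdiff(need, names(cohort))
  if (length(miss)) stop("cohort table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(cohort$sample_id)) stop("duplicate sample_id in cohort")
  if (!all(cohort$group %in% c("YC", "OC", "OP")))
    stop("group must be one of YC, OC, OP")
  if (!all(cohort$sex %in% c("F", "M")))
    stop("sex must be F or M")
  if (!is.null(cohort$pair_id)) {
    paired <- cohort[!is.na(cohort$pair_id) & cohort$pair_id != "", ]
    if (nrow(paired)) {
      tab <- table(paired$pair_id, factor(paired$group, c("YC", "OC", "OP")))
      bad <- rownames(tab)[tab[, "OC"] != 1 | tab[, "OP"] != 1 |
                             tab[, "YC"] != 0]
      if (length(bad))
        stop("pair_id not mapping to exactly one OC and one OP: ",
             paste(head(bad, 5L), collapse = ", "))
    }
  }
  if (!is.null(cohort$survival_time)) {
    st <- cohort$survival_time
    if (any(!is.na(st) & st <= 0)) stop("survival_time must be > 0")
    ev <- cohort$event
    if (any(cohort$group == "YC" & !is.na(ev) & ev != 0))
      stop("Young Controls must be event-free (event = 0)")
    if (any(!is.na(ev) & !ev %in% c(0, 1))) stop("event must be 0/1")
  }
  cohort
}

#' Read a cohort metadata CSV/TSV
#'
#' @param path file path.
#' @return A validated cohort data.frame (see [validate_cohort()]).
#' @export
read_cohort <- function(path) {
  dt <- as.data.frame(data.table::fread(
    path, colClasses = list(character = "sample_id")))
  if (!is.null(dt$pair_id)) dt$pair_id <- as.character(dt$pair_id)
  validate_cohort(dt)
}

#' @rdname read_cohort
#' @param cohort a cohort data.frame.
#' @export
write_cohort <- function(cohort, path) {
  data.table::fwrite(validate_cohort(cohort), path)
  invisible(path)
}

#' Read literature-derived protein lists
#'
#' Long TSV with columns `list_name`, `source_kind` (one of `age`, `disease`,
#' `sasp`) and `uniprot`, one member per row. Accessions are validated
#' syntactically; isoform suffixes are kept verbatim here and stripped only
#' at overlap time.
#'
#' @param path file path.
#' @return A named list of literature sets, each a list with elements
#'   `name`, `source_kind` and `members` (character vector of accessions).
#' @export
read_literature <- function(path) {
  dt <- data.table::fread(path)
  need <- c("list_name", "source_kind", "uniprot")
  miss <- setdiff(need, names(dt))
  if (length(miss)) stop("literature table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (!all(dt$source_kind %in% c("age", "disease", "sasp")))
    stop("source_kind must be one of age, disease, sasp")
  ok <- grepl("^[A-Z][A-Z0-9]{5,9}(-[0-9]+)?$", dt$uniprot)
  if (!all(ok))
    stop("syntactically invalid UniProt accession(s): ",
         paste(head(dt$uniprot[!ok], 5L), collapse = ", "))
  split_dt <- split(dt, dt$list_name)
  out <- lapply(split_dt, function(d) {
    literature_set(d$list_name[1L], d$source_kind[1L], unique(d$uniprot))
  })
  out[order(names(out))]
}

#' @rdname read_literature
#' @param name,source_kind,members components of one literature set.
#' @export
literature_set <- function(name, source_kind, members) {
  source_kind <- match.arg(source_kind, c("age", "disease", "sasp"))
  members <- unique(as.character(members))
  if (!length(members)) stop("literature set '", name, "' is empty")
  structure(list(name = name, source_kind = source_kind, members = members),
            class = "literature_set")
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then members. The description field doubles as the database tag
#' (e.g. `GO-BP`, `KEGG`, `Reactome`, `Hallmark`).
#'
#' @param path GMT file path.
#' @return A named list of gene sets, each a list with `name`, `db`
#'   (database tag) and `members`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(ln) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(parts) < 3L)
      stop("malformed GMT line (need name, description, >=1 member): ",
           substr(ln, 1L, 60L))
    list(name = parts[1L], db = parts[2L], members = unique(parts[-(1:2)]))
  })
  names(sets) <- vapply(sets, `[[`, "", "name")
  if (anyDuplicated(names(sets))) {
    # disambiguate duplicated set names across databases by tag prefix
    dup <- names(sets)[duplicated(names(sets)) |
                         duplicated(names(sets), fromLast = TRUE)]
    names(sets) <- ifelse(names(sets) %in% dup,
                          paste(vapply(sets, `[[`, "", "db"),
                                names(sets), sep = ":"),
                          names(sets))
  }
  sets
}

#' Write a result table as TSV
#'
#' @param result a data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(result, path) {
  data.table::fwrite(as.data.frame(result), path, sep = "\t")
  invisible(path)
}
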