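# Over-representation analysis of a protein set against stacked gene-set
# collections, with the measured panel as background, hypergeometric tests
# and BH correction applied once over the whole stack.

#' Over-representation analysis
#'
#' Maps query and background proteins to gene symbols, intersects every
#' gene set with the background, and tests each surviving set with an
#' upper-tail hypergeometric test (`k` query hits among `K` background set
#' members, `n` query proteins, `N` background proteins). The rich factor
#' `k / (K * n / N)` is the observed/expected hit ratio. BH correction is
#' applied once across all tested sets of the stacked collection, not per
#' database. A protein matching a set through several symbols counts once.
#'
#' @param query character vector of UniProt accessions; must be contained
#'   in `background`.
#' @param collection gene-set list from [read_gmt()] (or the same shape).
#' @param background character vector of panel UniProt accessions.
#' @param mapping data.frame with columns `uniprot`, `gene_symbol`
#'   (many-to-many allowed). Unmapped proteins are dropped and counted.
#' @param min_size,max_size set-size bounds after background intersection.
#' @return A data.frame of class `ora_result` sorted by `p_adj`, columns
#'   `set_name`, `db`, `k`, `K`, `n`, `N`, `rich_factor`, `p_raw`, `p_adj`;
#'   attribute `n_unmapped` records proteins without a symbol mapping.
#' @export
run_ora <- function(query, collection, background, mapping,
                    min_size = 5L, max_size = 2000L) {
  if (!all(query %in% background))
    stop("query must be a subset of the background")
  if (!all(c("uniprot", "gene_symbol") %in% names(mapping)))
    stop("mapping needs columns uniprot, gene_symbol")
  sym_of <- split(mapping$gene_symbol, mapping$uniprot)
  mapped <- background[background %in% names(sym_of)]
  n_unmapped <- length(background) - length(mapped)
  query <- query[query %in% mapped]
  if (!length(query)) stop("empty query after symbol mapping")
  N <- length(mapped)
  n <- length(query)
  rows <- lapply(collection, function(gs) {
    # proteins belonging to the set: any of their symbols is a member
    members <- mapped[vapply(sym_of[mapped],
                             function(s) any(s %in% gs$members), logical(1L))]
    K <- length(members)
    if (K < min_size || K > max_size) return(NULL)
    k <- length(intersect(query, members))
    data.frame(set_name = gs$name, db = gs$db, k = k, K = K, n = n, N = N,
               rich_factor = if (k == 0) 0 else k / (K * n / N),
               p_raw = phyper(k - 1, K, N - K, n, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1L))]
  if (!length(rows)) stop("no gene set within the size bounds")
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$p_raw)
  out <- out[order(out$p_adj, out$p_raw, out$set_name), ]
  rownames(out) <- NULL
  attr(out, "n_unmapped") <- n_unmapped
  class(out) <- c("ora_result", "data.frame")
  out
}

#' Top enriched pathways
#'
#' @param ora an `ora_result`.
#' @param n number of rows (default 15, the conventional report size).
#' @return The first `n` rows by adjusted p-value.
#' @export
top_pathways <- function(ora, n = 15L) utils::head(as.data.frame(ora), n)
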