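#' Tabulate module hits into per-module 2x2 tables
#'
#' For every cis-transcriptional module with at least one hit in the
#' query, builds the 2x2 contingency table of the module's gene hits in
#' the query versus the rest of the universe, at gene granularity: a gene
#' counts once however many of its promoters match. The module
#' `occurrence` is the total number of match positions summed over the
#' query genes' promoters.
#'
#' @param hits data.frame `module`, `gene`, `promoter_id`, `n_positions`.
#' @param query gene set of interest (e.g. a muscle's DEGs); must be a
#'   subset of `universe`.
#' @param universe background gene set (genes on the array with a usable
#'   promoter). Hits outside the universe are ignored.
#' @return data.frame `module`, `occurrence`, `n_target_genes`,
#'   `target_genes` (comma-separated, sorted), `a`, `b`, `c`, `d`.
#' @export
tabulate_modules <- function(hits, query, universe) {
  query <- unique(query)
  universe <- unique(universe)
  missing <- setdiff(query, universe)
  if (length(missing) > 0)
    stop(sprintf("query gene(s) absent from universe: %s",
                 paste(missing, collapse = ", ")))
  hits <- hits[hits$gene %in% universe, , drop = FALSE]
  n_query <- length(query)
  n_univ <- length(universe)

  out <- lapply(split(hits, hits$module), function(h) {
    in_query <- h$gene %in% query
    tg <- sort(unique(h$gene[in_query]))
    a <- length(tg)
    if (a == 0) return(NULL)
    c_ <- length(unique(h$gene[!in_query]))
    data.frame(module = h$module[1],
               occurrence = sum(h$n_positions[in_query]),
               n_target_genes = a,
               target_genes = paste(tg, collapse = ","),
               a = a, b = n_query - a, c = c_,
               d = n_univ - n_query - c_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(module = character(), occurrence = integer(),
                      n_target_genes = integer(), target_genes = character(),
                      a = integer(), b = integer(), c = integer(),
                      d = integer(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' One-sided Fisher's exact test for over-representation
#'
#' Upper-tail probability of the 2x2 table `(a, b; c, d)` under the
#' hypergeometric null with fixed margins: the chance of observing `a`
#' or more query hits.
#'
#' @param a query genes hit, `b` query genes not hit, `c` background
#'   (non-query) genes hit, `d` background genes not hit.
#' @param b,c,d see `a`.
#' @return the one-sided p-value (vectorized over the inputs).
#' @export
fisher_one_sided <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0)) stop("counts must be non-negative")
  stats::phyper(a - 1, a + c, b + d, a + b, lower.tail = FALSE)
}

#' Select over-represented modules
#'
#' Computes the one-sided Fisher p for each tabulated module and keeps
#' those with `p < p_cut` (strict), sorted by the number of target genes
#' (descending) and then p (ascending).
#'
#' @param enr data.frame from [tabulate_modules()], or any data.frame
#'   with columns `module`, `n_target_genes` and either `p` or the 2x2
#'   counts `a`, `b`, `c`, `d`.
#' @param p_cut selection threshold (default 0.1, strict `<`).
#' @return the retained rows, with a `p` column, re-sorted.
#' @export
select_modules <- function(enr, p_cut = 0.1) {
  if (is.null(enr$p))
    enr$p <- fisher_one_sided(enr$a, enr$b, enr$c, enr$d)
  out <- enr[enr$p < p_cut, , drop = FALSE]
  out <- out[order(-out$n_target_genes, out$p, out$module), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Modules over-represented in both lists
#'
#' @param listA,listB results of [select_modules()] at the same `p_cut`,
#'   or plain character vectors of module ids.
#' @return character vector of shared module ids.
#' @export
common_modules <- function(listA, listB) {
  ids <- function(x) if (is.character(x)) x else x$module
  intersect(ids(listA), ids(listB))
}
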