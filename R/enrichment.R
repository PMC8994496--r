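#' Term over-representation against a background universe
#'
#' One-sided hypergeometric upper-tail test per annotation term: with `N`
#' background genes of which `K` carry the term, and `n` query genes of
#' which `k` carry it, `p = P(X >= k)` for `X ~ Hypergeom(K, N - K, n)`.
#' Query genes absent from the background are dropped with a warning
#' (restriction contract). BH correction is applied within each
#' namespace; terms with `k = 0` are skipped before testing.
#'
#' @param query character vector of query genes (e.g. a DEG list).
#' @param background character vector, the gene universe (genes on the
#'   array).
#' @param annotations data.frame `gene`, `term_id`, `term_name`,
#'   `namespace`.
#' @param fdr_cut significance threshold on the BH-adjusted p (strict
#'   `<`), default 0.08.
#' @return data.frame `term_id`, `term_name`, `namespace`, `k`, `K`, `n`,
#'   `N`, `p`, `fdr`, `neg_log10_p`, `significant`, ordered by p.
#' @export
enrich <- function(query, background, annotations, fdr_cut = 0.08) {
  query <- unique(query)
  background <- unique(background)
  outside <- setdiff(query, background)
  if (length(outside) > 0) {
    warning(sprintf("%d query gene(s) absent from the background were dropped",
                    length(outside)))
    query <- intersect(query, background)
  }
  if (length(query) == 0)
    stop("empty query after restriction to the background universe")

  ann <- annotations[annotations$gene %in% background, , drop = FALSE]
  empty <- data.frame(term_id = character(), term_name = character(),
                      namespace = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(), p = numeric(),
                      fdr = numeric(), neg_log10_p = numeric(),
                      significant = logical(), stringsAsFactors = FALSE)
  if (nrow(ann) == 0) return(empty)

  N <- length(background)
  n <- length(query)
  key <- paste(ann$term_id, ann$namespace, sep = "\r")
  K_tab <- tapply(ann$gene, key, function(g) length(unique(g)))
  k_tab <- tapply(ann$gene, key, function(g) length(unique(intersect(g, query))))
  info <- ann[!duplicated(key), c("term_id", "term_name", "namespace")]
  info <- info[match(names(K_tab), key[!duplicated(key)]), ]

  out <- data.frame(info,
                    k = as.integer(k_tab), K = as.integer(K_tab),
                    n = n, N = N, row.names = NULL,
                    stringsAsFactors = FALSE)
  out <- out[out$k > 0, , drop = FALSE]
  if (nrow(out) == 0) return(empty)
  out$p <- stats::phyper(out$k - 1, out$K, out$N - out$K, out$n,
                         lower.tail = FALSE)
  out$fdr <- NA_real_
  for (ns in unique(out$namespace))
    out$fdr[out$namespace == ns] <- adjust_bh(out$p[out$namespace == ns])
  out$neg_log10_p <- -log10(out$p)
  out$significant <- out$fdr < fdr_cut
  out <- out[order(out$p, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Annotation terms significant in both result sets
#'
#' Intersects the significant terms of two enrichment results by term id
#' and attaches the per-list query gene counts.
#'
#' @param resA,resB results of [enrich()] computed at the same threshold.
#' @return data.frame `term_id`, `term_name`, `namespace`, `k_A`, `k_B`.
#' @export
common_terms <- function(resA, resB) {
  a <- resA[resA$significant, , drop = FALSE]
  b <- resB[resB$significant, , drop = FALSE]
  shared <- intersect(a$term_id, b$term_id)
  out <- a[match(shared, a$term_id),
           c("term_id", "term_name", "namespace"), drop = FALSE]
  out$k_A <- a$k[match(shared, a$term_id)]
  out$k_B <- b$k[match(shared, b$term_id)]
  rownames(out) <- NULL
  out
}
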