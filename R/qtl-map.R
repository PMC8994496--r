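#' Map genes to QTLs by strict interval containment
#'
#' A gene hits a QTL when both lie on the same chromosome and the gene
#' interval is entirely inside the QTL interval (endpoint equality
#' counts as contained; strand is ignored). A gene may hit several QTLs.
#' Both tables must use 0-based half-open coordinates (the loader
#' normalizes 1-based input). Overlap search is delegated to
#' GenomicRanges.
#'
#' @param loci data.frame `gene`, `chrom`, `start`, `end`.
#' @param qtls data.frame `qtl_id`, `chrom`, `start`, `end`, `trait`,
#'   `trait_class`.
#' @return data.frame `gene`, `qtl_id`, `trait`, `trait_class`, one row
#'   per containment, ordered by gene then qtl_id. Genes hitting no QTL
#'   are absent; their ids are attached as attribute `"unmapped"` and
#'   reported with a warning.
#' @export
map_genes_to_qtls <- function(loci, qtls) {
  if (any(loci$start >= loci$end) || any(qtls$start >= qtls$end))
    stop("inverted or empty interval")
  if (nrow(loci) == 0 || nrow(qtls) == 0) {
    out <- data.frame(gene = character(), qtl_id = character(),
                      trait = character(), trait_class = character(),
                      stringsAsFactors = FALSE)
    attr(out, "unmapped") <- loci$gene
    return(out)
  }
  # 0-based half-open -> 1-based inclusive for IRanges
  g <- GenomicRanges::GRanges(loci$chrom,
                              IRanges::IRanges(loci$start + 1, loci$end))
  q <- GenomicRanges::GRanges(qtls$chrom,
                              IRanges::IRanges(qtls$start + 1, qtls$end))
  # disjoint chromosome sets between genes and QTLs are expected, not an
  # anomaly worth a seqlevel warning
  ov <- suppressWarnings(GenomicRanges::findOverlaps(g, q, type = "within"))
  out <- data.frame(gene = loci$gene[S4Vectors::queryHits(ov)],
                    qtl_id = qtls$qtl_id[S4Vectors::subjectHits(ov)],
                    trait = qtls$trait[S4Vectors::subjectHits(ov)],
                    trait_class = qtls$trait_class[S4Vectors::subjectHits(ov)],
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene, out$qtl_id), , drop = FALSE]
  rownames(out) <- NULL
  unmapped <- setdiff(loci$gene, out$gene)
  if (length(unmapped) > 0)
    warning(sprintf("%d gene(s) not contained in any QTL", length(unmapped)))
  attr(out, "unmapped") <- unmapped
  out
}

#' Filter QTL hits to trait classes
#'
#' @param hits data.frame from [map_genes_to_qtls()].
#' @param class_set character vector of trait classes to keep (e.g.
#'   `"meat-quality"`).
#' @return the retained hits; attribute `"unique_gene_count"` gives the
#'   number of distinct genes among them.
#' @export
filter_trait_class <- function(hits, class_set) {
  out <- hits[hits$trait_class %in% class_set, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "unique_gene_count") <- length(unique(out$gene))
  out
}
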