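#' Two-set Venn partition
#'
#' Exact partition of two gene-name sets into A-only, B-only and shared
#' members. The three parts are pairwise disjoint and their union is
#' A union B.
#'
#' @param setA,setB character vectors of unique gene names.
#' @param labels length-2 character vector naming the sets.
#' @return object of class `venn_partition`: `only_A`, `only_B`, `both`
#'   (sorted), `labels`, `counts`.
#' @export
venn_partition <- function(setA, setB, labels = c("A", "B")) {
  setA <- unique(setA)
  setB <- unique(setB)
  out <- list(only_A = sort(setdiff(setA, setB)),
              only_B = sort(setdiff(setB, setA)),
              both = sort(intersect(setA, setB)),
              labels = labels)
  out$counts <- c(only_A = length(out$only_A),
                  only_B = length(out$only_B),
                  both = length(out$both))
  class(out) <- "venn_partition"
  out
}

#' @export
print.venn_partition <- function(x, ...) {
  cat(sprintf("venn: %s only = %d, %s only = %d, both = %d\n",
              x$labels[1], x$counts["only_A"],
              x$labels[2], x$counts["only_B"], x$counts["both"]))
  invisible(x)
}

#' Flag transcription regulators in a gene list
#'
#' Labels each gene `TF` (transcription factor), `TM` (transcriptional
#' modulator) or `none` according to an externally supplied dictionary.
#' The two labels are exclusive: a gene listed under both is an error.
#'
#' @param genes character vector.
#' @param tf_table data.frame `gene`, `label` with label in
#'   \{`TF`, `TM`\}; may be empty.
#' @return data.frame `gene`, `tf_flag`; attribute `"counts"` holds the
#'   per-label tally.
#' @export
flag_tfs <- function(genes, tf_table = NULL) {
  if (is.null(tf_table) || nrow(tf_table) == 0) {
    flag <- rep("none", length(genes))
  } else {
    dup <- tapply(tf_table$label, tf_table$gene,
                  function(l) length(unique(l)))
    if (any(dup > 1))
      stop(sprintf("gene(s) with conflicting TF/TM labels: %s",
                   paste(names(dup)[dup > 1], collapse = ", ")))
    flag <- tf_table$label[match(genes, tf_table$gene)]
    flag[is.na(flag)] <- "none"
  }
  out <- data.frame(gene = genes, tf_flag = flag, stringsAsFactors = FALSE)
  attr(out, "counts") <- c(TF = sum(flag == "TF"), TM = sum(flag == "TM"),
                           none = sum(flag == "none"))
  out
}

#' Integrated summary table and run report
#'
#' Combines the stage outputs into one row per (response type, gene) —
#' muscle-specific DEGs, common DEGs, common main regulators and common
#' main targets — each with its transcription-regulator flag and the
#' meat-quality QTL traits its gene is mapped to, plus a machine-readable
#' list of all headline counts.
#'
#' @param deg_lt,deg_st character vectors of DEG names per muscle.
#' @param regulators,targets character vectors of common main regulators
#'   / targets (may be empty).
#' @param modules_lt,modules_st optional module selections (data.frames
#'   from [select_modules()] or character vectors) used for the module
#'   counts.
#' @param qtl_hits optional data.frame from [map_genes_to_qtls()] (or the
#'   same columns); only rows with trait_class `"meat-quality"` feed the
#'   QTL annotations. `NULL` omits the QTL column with a warning.
#' @param tf_table optional TF/TM dictionary for [flag_tfs()].
#' @return list of class `stress_report`: `summary` (data.frame
#'   `response_type`, `gene`, `tf_flag`, `qtl_traits`) and `counts`.
#' @export
build_summary <- function(deg_lt, deg_st, regulators = character(),
                          targets = character(), modules_lt = NULL,
                          modules_st = NULL, qtl_hits = NULL,
                          tf_table = NULL) {
  vp <- venn_partition(deg_lt, deg_st, labels = c("LT", "ST"))
  part <- function(type, genes)
    data.frame(response_type = rep(type, length(genes)), gene = genes,
               stringsAsFactors = FALSE)
  rows <- rbind(
    part("LT-specific DEG", vp$only_A),
    part("ST-specific DEG", vp$only_B),
    part("Common DEG", vp$both),
    part("Common main regulator", sort(unique(regulators))),
    part("Common main target", sort(unique(targets))))
  flags <- flag_tfs(rows$gene, tf_table)
  rows$tf_flag <- flags$tf_flag

  mq_genes <- character()
  if (is.null(qtl_hits)) {
    warning("no QTL hits supplied; QTL trait column omitted")
    rows$qtl_traits <- rep(NA_character_, nrow(rows))
  } else {
    mq <- filter_trait_class(qtl_hits, "meat-quality")
    mq_genes <- unique(mq$gene)
    rows$qtl_traits <- vapply(rows$gene, function(g) {
      tr <- sort(unique(mq$trait[mq$gene == g]))
      if (length(tr) == 0) "" else paste(tr, collapse = "; ")
    }, character(1), USE.NAMES = FALSE)
  }

  common_flags <- flag_tfs(vp$both, tf_table)
  mod_ids <- function(x) {
    if (is.null(x)) return(NULL)
    if (is.character(x)) x else x$module
  }
  ml <- mod_ids(modules_lt)
  ms <- mod_ids(modules_st)
  counts <- list(
    lt_degs = length(unique(deg_lt)),
    st_degs = length(unique(deg_st)),
    lt_specific_degs = length(vp$only_A),
    st_specific_degs = length(vp$only_B),
    common_degs = length(vp$both),
    common_tfs = sum(common_flags$tf_flag == "TF"),
    lt_modules = if (is.null(ml)) NA_integer_ else length(ml),
    st_modules = if (is.null(ms)) NA_integer_ else length(ms),
    common_modules = if (is.null(ml) || is.null(ms)) NA_integer_ else
      length(common_modules(ml, ms)),
    common_regulators = length(unique(regulators)),
    common_targets = length(unique(targets)),
    meat_quality_qtl_genes = length(mq_genes))

  structure(list(summary = rows, counts = counts, venn = vp),
            class = "stress_report")
}

#' @export
print.stress_report <- function(x, ...) {
  cat("stress response report\n")
  for (n in names(x$counts))
    cat(sprintf("  %-24s %s\n", n, x$counts[[n]]))
  invisible(x)
}

#' Read a summary gene table
#'
#' Loads a TSV transcription of a study summary table: one row per
#' (response type, gene) with a transcription-regulator flag and a
#' semicolon-separated list of meat-quality QTL traits.
#'
#' @param path TSV with columns `response_type`, `gene`, `tf_flag`,
#'   `qtl_traits`.
#' @return data.frame.
#' @export
read_summary_genes <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = NULL)
  x$tf_flag[is.na(x$tf_flag) | x$tf_flag == ""] <- "none"
  x
}

#' Read a module-enrichment table
#'
#' Loads a TSV with per-module over-representation results (one muscle
#' per file): module id, one-sided Fisher p, total match-position
#' occurrence, number of target genes and the comma-separated target
#' gene list.
#'
#' @param path TSV with columns `module`, `p`, `occurrence`,
#'   `n_target_genes`, `target_genes`.
#' @return data.frame.
#' @export
read_module_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
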