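#' Write a simulated dataset to a directory of plain-text files
#'
#' Emits every pipeline input as TSV/BED/JSON: `probe_matrix.tsv`
#' (probe_id, is_control, one column per sample), `qc_flags.tsv` (same
#' shape, 0/1), `probe_map.tsv`, `design.tsv`, `module_hits.tsv`,
#' `interaction_edges.tsv`, `gene_loci.bed` (0-based half-open),
#' `qtls.tsv`, `annotations.tsv` and `ground_truth.json`. Output is a
#' pure function of the simulation object: identical (seed, config)
#' pairs write byte-identical files.
#'
#' @param sim result of [simulate_dataset()].
#' @param dir output directory, created if absent.
#' @return the directory path, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(x, f) utils::write.table(
    x, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)

  pm <- sim$probes
  mat <- data.frame(probe_id = rownames(pm$intensity),
                    is_control = as.integer(pm$is_control),
                    pm$intensity, check.names = FALSE,
                    stringsAsFactors = FALSE)
  tsv(mat, "probe_matrix.tsv")
  qc <- data.frame(probe_id = rownames(pm$intensity),
                   matrix(as.integer(pm$qc_pass), nrow(pm$qc_pass),
                          dimnames = dimnames(pm$qc_pass)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  tsv(qc, "qc_flags.tsv")
  tsv(sim$probe_map, "probe_map.tsv")
  tsv(sim$design, "design.tsv")
  tsv(sim$module_hits, "module_hits.tsv")
  tsv(sim$interaction_db$edges, "interaction_edges.tsv")
  bed <- data.frame(chrom = sim$loci$chrom,
                    start = format(sim$loci$start, scientific = FALSE,
                                   trim = TRUE),
                    end = format(sim$loci$end, scientific = FALSE,
                                 trim = TRUE),
                    name = sim$loci$gene, stringsAsFactors = FALSE)
  utils::write.table(bed, file.path(dir, "gene_loci.bed"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  qt <- sim$qtls
  qt$start <- format(qt$start, scientific = FALSE, trim = TRUE)
  qt$end <- format(qt$end, scientific = FALSE, trim = TRUE)
  tsv(qt, "qtls.tsv")
  tsv(sim$annotations, "annotations.tsv")
  truth <- sim$truth
  class(truth) <- NULL
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a probe-level intensity table
#'
#' Expects the TSV layout written by [write_simulation()]: `probe_id`,
#' `is_control`, then one intensity column per sample. An optional QC
#' table of the same shape (0/1) and a design table can be attached.
#'
#' @param matrix_file path to the intensity TSV.
#' @param qc_file optional path to the QC flag TSV.
#' @param design_file optional path to the design TSV (`sample`,
#'   `muscle`, `stress`, `diet`).
#' @return a [probe_matrix()].
#' @export
read_probe_matrix <- function(matrix_file, qc_file = NULL,
                              design_file = NULL) {
  raw <- utils::read.delim(matrix_file, check.names = FALSE,
                           stringsAsFactors = FALSE)
  intensity <- as.matrix(raw[, -(1:2), drop = FALSE])
  rownames(intensity) <- raw$probe_id
  qc <- NULL
  if (!is.null(qc_file)) {
    qraw <- utils::read.delim(qc_file, check.names = FALSE,
                              stringsAsFactors = FALSE)
    qc <- as.matrix(qraw[, -1, drop = FALSE]) > 0
    rownames(qc) <- qraw$probe_id
    qc <- qc[rownames(intensity), colnames(intensity), drop = FALSE]
  }
  design <- if (!is.null(design_file))
    utils::read.delim(design_file, stringsAsFactors = FALSE) else NULL
  probe_matrix(intensity, as.logical(raw$is_control), qc, design)
}

#' Read gene loci from a BED file
#'
#' BED is 0-based half-open and is kept in that convention internally.
#'
#' @param path BED file with columns chrom, start, end, name (gene).
#' @return data.frame `gene`, `chrom`, `start`, `end`.
#' @export
read_gene_loci <- function(path) {
  bed <- utils::read.delim(path, header = FALSE,
                           stringsAsFactors = FALSE)[, 1:4]
  names(bed) <- c("chrom", "start", "end", "gene")
  out <- bed[, c("gene", "chrom", "start", "end")]
  if (any(out$start >= out$end))
    stop("inverted or empty interval in gene loci")
  out
}

#' Read a QTL interval table
#'
#' @param path TSV with columns `qtl_id`, `chrom`, `start`, `end`,
#'   `trait`, `trait_class`.
#' @param convention coordinate convention of the file: `"bed"` (0-based
#'   half-open, the internal convention) or `"one_based"` (1-based
#'   inclusive, converted on load).
#' @return data.frame in 0-based half-open coordinates.
#' @export
read_qtl_table <- function(path, convention = c("bed", "one_based")) {
  convention <- match.arg(convention)
  qt <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (convention == "one_based") qt$start <- qt$start - 1
  if (any(qt$start >= qt$end))
    stop("inverted or empty interval in QTL table")
  qt
}
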