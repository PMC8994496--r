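#' Generate a synthetic promoter-module hit table
#'
#' Fabricates the output of a promoter-scanning step: one record per
#' (module, gene, promoter) match with a match-position count. Planted
#' modules hit their designated target sets (from the ground truth) plus a
#' low per-gene background rate; all other modules hit genes at the
#' background rate only. The table covers the whole gene universe and is
#' independent of which genes are later called differentially expressed.
#'
#' @param cfg a [sim_config()].
#' @param truth the `ground_truth` from [generate_expression()].
#' @return data.frame with columns `module`, `gene`, `promoter_id`,
#'   `n_positions` (all counts >= 1; (module, gene, promoter) unique).
#' @export
generate_module_hits <- function(cfg, truth) {
  validate_sim_config(cfg)
  set.seed(stage_seed(cfg, "modules"))
  genes <- sprintf("G%04d", seq_len(cfg$n_genes))
  planted <- names(truth$enriched_modules)
  modules <- union(planted, sprintf("M%02d", seq_len(cfg$n_modules)))

  rows <- vector("list", length(modules))
  for (i in seq_along(modules)) {
    m <- modules[i]
    hit <- genes[stats::runif(length(genes)) < cfg$module_background_rate]
    if (m %in% planted)
      hit <- union(hit, truth$enriched_modules[[m]]$genes)
    if (length(hit) == 0) next
    rows[[i]] <- data.frame(
      module = m,
      gene = hit,
      promoter_id = paste0(hit, "_pr1"),
      n_positions = 1L + stats::rpois(length(hit), 0.4),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(module = character(), gene = character(),
                      promoter_id = character(), n_positions = integer(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Generate a synthetic interaction-edge database
#'
#' Builds a directed, evidence-weighted edge list emulating a curated
#' mammalian interaction database. Planted regulators receive `Regulation`
#' edges into at least three planted DE genes with reference counts >= 3
#' and enough additional incident edges that their total relation degree
#' is >= 6 (so they survive both the per-muscle and the common-network
#' degree cut-offs). Planted targets receive incoming `Expression` edges
#' from at least three planted DE genes with reference counts >= 3 and a
#' total degree >= 6. Decoy nodes each violate exactly one admission
#' filter: a regulator decoy with reference counts of 2, a regulator decoy
#' touching a single seed, a target decoy with total degree 5, a target
#' decoy with reference counts of 2, and a target decoy reached from one
#' seed only. Reference counts on evidence edges are drawn from a shifted
#' geometric distribution (heavy-tailed, like literature-curation counts).
#'
#' @inheritParams generate_module_hits
#' @return list with components `edges` (data.frame `source`, `target`,
#'   `relation_type`, `n_references`) and `decoys` (data.frame `node`,
#'   `role`, `defect`).
#' @export
generate_interaction_db <- function(cfg, truth) {
  validate_sim_config(cfg)
  set.seed(stage_seed(cfg, "network"))
  genes <- sprintf("G%04d", seq_len(cfg$n_genes))
  seeds <- truth$de_genes$gene
  reserved <- c(seeds, truth$planted_regulators, truth$planted_targets)
  pool <- setdiff(genes, reserved)

  refs_hi <- function(n) 3L + stats::rgeom(n, 0.4)   # >= 3
  rows <- list()
  add <- function(src, dst, type, refs) {
    rows[[length(rows) + 1L]] <<- data.frame(
      source = src, target = dst, relation_type = type,
      n_references = as.integer(refs), stringsAsFactors = FALSE)
  }

  # decoy nodes are reserved before any other sampling so that padding and
  # background edges cannot accidentally raise their degree
  if (length(seeds) >= 2) {
    decoys <- data.frame(
      node = sample(pool, 5),
      role = c("regulator", "regulator", "target", "target", "target"),
      defect = c("low_refs", "single_seed", "low_degree", "low_refs",
                 "single_seed"),
      stringsAsFactors = FALSE)
    pool <- setdiff(pool, decoys$node)
  } else {
    decoys <- data.frame(node = character(), role = character(),
                         defect = character(), stringsAsFactors = FALSE)
  }

  n_seed_links <- function() min(3L, length(seeds))
  if (length(seeds) >= 2) {
    for (r in truth$planted_regulators) {
      linked <- sample(seeds, n_seed_links())
      add(r, linked, "Regulation", refs_hi(length(linked)))
      pad <- sample(pool, 3)
      add(r, pad, "Regulation", 1L + stats::rgeom(3, 0.5))
    }
    for (t in truth$planted_targets) {
      from <- sample(seeds, n_seed_links())
      add(from, t, "Expression", refs_hi(length(from)))
      pad <- sample(pool, 3)
      add(pad, t, "Expression", 1L + stats::rgeom(3, 0.5))
    }

    d <- decoys$node
    # regulator with enough seeds and degree but only 2 references per edge
    add(d[1], sample(seeds, 2), "Regulation", c(2L, 2L))
    add(d[1], sample(pool, 4), "Regulation", rep(1L, 4))
    # regulator touching one seed only, otherwise well supported
    add(d[2], sample(seeds, 1), "Regulation", 6L)
    add(d[2], sample(pool, 5), "Regulation", rep(2L, 5))
    # target with good evidence from 3 seeds but total degree 5
    add(sample(seeds, 3), d[3], "Expression", refs_hi(3))
    add(sample(pool, 2), d[3], "Expression", rep(1L, 2))
    # target with degree >= 6 but only 2 references on every seed edge
    add(sample(seeds, 3), d[4], "Expression", rep(2L, 3))
    add(sample(pool, 3), d[4], "Expression", rep(2L, 3))
    # target reached from a single seed, otherwise well supported
    add(sample(seeds, 1), d[5], "Expression", 7L)
    add(sample(pool, 5), d[5], "Expression", rep(2L, 5))
  }

  # background edges among unrelated genes
  n_bg <- 200L
  bg_src <- sample(pool, n_bg, replace = TRUE)
  bg_dst <- sample(pool, n_bg, replace = TRUE)
  keep <- bg_src != bg_dst
  add(bg_src[keep], bg_dst[keep],
      sample(c("Regulation", "Expression"), sum(keep), replace = TRUE),
      1L + stats::rgeom(sum(keep), 0.5))

  edges <- do.call(rbind, rows)
  rownames(edges) <- NULL
  list(edges = edges, decoys = decoys)
}

#' Generate synthetic gene loci and QTL intervals
#'
#' Places each gene in its own 20 kb slot on one of 29 autosomes with 200
#' kb spacing, then builds QTL intervals so that the planted QTL-spanning
#' genes are each fully contained in a meat-quality QTL while every other
#' gene is outside all QTLs or overlaps one only partially (boundary-
#' straddling decoy QTLs are planted on a sample of non-spanning genes).
#' All coordinates are 0-based half-open.
#'
#' @inheritParams generate_module_hits
#' @return list with `loci` (data.frame `gene`, `chrom`, `start`, `end`)
#'   and `qtls` (data.frame `qtl_id`, `chrom`, `start`, `end`, `trait`,
#'   `trait_class`).
#' @export
generate_loci_and_qtls <- function(cfg, truth) {
  validate_sim_config(cfg)
  set.seed(stage_seed(cfg, "loci"))
  genes <- sprintf("G%04d", seq_len(cfg$n_genes))
  i <- seq_along(genes)
  chrom <- paste0("chr", ((i - 1L) %% 29L) + 1L)
  slot <- (i - 1L) %/% 29L
  start <- 1e6 + slot * 2e5
  loci <- data.frame(gene = genes, chrom = chrom,
                     start = start, end = start + 2e4,
                     stringsAsFactors = FALSE)

  traits <- c("Shear force", "Tenderness score", "Muscle pH",
              "Juiciness", "Marbling", "Muscle compression")
  qtl <- list()
  k <- 0L
  for (g in truth$qtl_spanning_genes) {
    k <- k + 1L
    row <- loci[loci$gene == g, ]
    qtl[[k]] <- data.frame(
      qtl_id = sprintf("QTL%03d", k), chrom = row$chrom,
      start = row$start - 5e4, end = row$end + 5e4,
      trait = sample(traits, 1), trait_class = "meat-quality",
      stringsAsFactors = FALSE)
  }
  # boundary-straddling decoys: cover the gene end but not the start
  others <- setdiff(genes, truth$qtl_spanning_genes)
  for (g in sample(others, min(10L, length(others)))) {
    k <- k + 1L
    row <- loci[loci$gene == g, ]
    qtl[[k]] <- data.frame(
      qtl_id = sprintf("QTL%03d", k), chrom = row$chrom,
      start = row$start + 1e4, end = row$end + 6e4,
      trait = sample(traits, 1), trait_class = "meat-quality",
      stringsAsFactors = FALSE)
  }
  # gene-free intervals with a non-meat-quality trait class
  for (j in seq_len(5)) {
    k <- k + 1L
    qtl[[k]] <- data.frame(
      qtl_id = sprintf("QTL%03d", k), chrom = paste0("chr", j),
      start = 1e5, end = 5e5,
      trait = "Palmitic acid content", trait_class = "fatty-acid",
      stringsAsFactors = FALSE)
  }
  qtls <- do.call(rbind, qtl)
  if (is.null(qtls))
    qtls <- data.frame(qtl_id = character(), chrom = character(),
                       start = numeric(), end = numeric(),
                       trait = character(), trait_class = character(),
                       stringsAsFactors = FALSE)
  rownames(qtls) <- NULL
  list(loci = loci, qtls = qtls)
}

#' Generate a synthetic gene-to-GO annotation table
#'
#' One designated term (`T0001`, biological process) annotates every
#' planted DE gene plus a 1% background sample, so the enrichment stage
#' has a recoverable signal; the remaining terms annotate random gene
#' sets with log-normally distributed sizes across the BP and MF
#' namespaces.
#'
#' @inheritParams generate_module_hits
#' @return data.frame with columns `gene`, `term_id`, `term_name`,
#'   `namespace`.
#' @export
generate_annotations <- function(cfg, truth) {
  validate_sim_config(cfg)
  set.seed(stage_seed(cfg, "annotation"))
  genes <- sprintf("G%04d", seq_len(cfg$n_genes))
  rows <- list()
  first <- 1L
  if (nrow(truth$de_genes) > 0 && cfg$n_terms > 0) {
    bg <- genes[stats::runif(length(genes)) < 0.01]
    members <- union(truth$de_genes$gene, bg)
    rows[[1]] <- data.frame(gene = members, term_id = "T0001",
                            term_name = "planted stress response",
                            namespace = "BP", stringsAsFactors = FALSE)
    first <- 2L
  }
  if (cfg$n_terms >= first) {
    for (t in seq(first, cfg$n_terms)) {
      size <- min(length(genes), max(5L, round(stats::rlnorm(1, log(30), 0.8))))
      members <- sample(genes, size)
      rows[[t]] <- data.frame(
        gene = members, term_id = sprintf("T%04d", t),
        term_name = sprintf("random process %d", t),
        namespace = sample(c("BP", "MF"), 1), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(gene = character(), term_id = character(),
                      term_name = character(), namespace = character(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Generate every synthetic input in one call
#'
#' Convenience wrapper running all generators from one configuration.
#'
#' @param cfg a [sim_config()].
#' @return list with `probes`, `probe_map`, `design`, `truth`,
#'   `module_hits`, `interaction_db`, `loci`, `qtls`, `annotations`.
#' @export
simulate_dataset <- function(cfg) {
  expr <- generate_expression(cfg)
  geo <- generate_loci_and_qtls(cfg, expr$truth)
  c(expr,
    list(module_hits = generate_module_hits(cfg, expr$truth),
         interaction_db = generate_interaction_db(cfg, expr$truth),
         loci = geo$loci,
         qtls = geo$qtls,
         annotations = generate_annotations(cfg, expr$truth)))
}
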