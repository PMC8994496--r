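#' Probe-level intensity container
#'
#' Bundles a positive intensity matrix (probes x samples) with the
#' control-probe flag, the per-cell QC pass flag, and the sample design
#' table. This is the substrate of [qc_filter()] and [normalize_probes()].
#'
#' @param intensity numeric matrix, probes in rows (rownames = probe ids),
#'   samples in columns (colnames = sample ids). Values must be positive
#'   wherever `qc_pass` is `TRUE`.
#' @param is_control logical vector, one entry per probe.
#' @param qc_pass logical matrix of the same dimension as `intensity`, or
#'   `NULL` for all-pass.
#' @param design data.frame with columns `sample`, `muscle`, `stress`,
#'   `diet` (one row per column of `intensity`).
#' @return an object of class `probe_matrix`.
#' @export
probe_matrix <- function(intensity, is_control, qc_pass = NULL, design = NULL) {
  if (is.null(rownames(intensity)) || is.null(colnames(intensity)))
    stop("intensity must have probe rownames and sample colnames")
  if (length(is_control) != nrow(intensity))
    stop("is_control must have one entry per probe")
  if (is.null(qc_pass))
    qc_pass <- matrix(TRUE, nrow(intensity), ncol(intensity),
                      dimnames = dimnames(intensity))
  if (!identical(dim(qc_pass), dim(intensity)))
    stop("qc_pass must match the dimensions of intensity")
  bad <- qc_pass & !is.na(intensity) & intensity <= 0
  if (any(bad))
    stop("intensities must be positive where qc_pass is TRUE")
  if (!is.null(design) && !all(design$sample == colnames(intensity)))
    stop("design$sample must match the intensity column order")
  structure(list(intensity = intensity,
                 is_control = as.logical(is_control),
                 qc_pass = qc_pass,
                 design = design),
            class = "probe_matrix")
}

#' @export
print.probe_matrix <- function(x, ...) {
  cat(sprintf("probe_matrix: %d probes (%d control) x %d samples\n",
              nrow(x$intensity), sum(x$is_control), ncol(x$intensity)))
  invisible(x)
}

# Allocate per-gene probe counts drawn uniformly from the configured range,
# then nudged so they sum exactly to the number of non-control probes.
allocate_probes <- function(n_genes, range, total) {
  counts <- sample(seq(range[1], range[2]), n_genes, replace = TRUE)
  delta <- total - sum(counts)
  while (delta != 0) {
    if (delta > 0) {
      room <- which(counts < range[2])
      idx <- sample(room, min(length(room), delta))
      counts[idx] <- counts[idx] + 1L
      delta <- delta - length(idx)
    } else {
      room <- which(counts > range[1])
      idx <- sample(room, min(length(room), -delta))
      counts[idx] <- counts[idx] - 1L
      delta <- delta + length(idx)
    }
  }
  counts
}

#' Generate a synthetic probe-level expression dataset
#'
#' Simulates the full array experiment: log-normal probe intensities
#' (Gaussian on the log2 scale) with a per-array multiplicative scale
#' effect, planted signed log2 stress effects on the probes of the DE
#' genes in the stressed group of their designated muscle(s), and random
#' per-cell QC failures. Control probes receive the array effect and the
#' noise but never a biological effect, so they can be used for
#' normalization. Alongside the data, a ground-truth object records every
#' planted feature (DE genes and effects, module target sets, network
#' regulators/targets, QTL-spanning genes) for downstream recovery checks.
#' Planted regulators and targets are drawn from the non-DE gene pool:
#' they are network neighbours of the DE genes, not DE themselves.
#'
#' @param cfg a [sim_config()].
#' @return a list with components:
#'   \describe{
#'     \item{probes}{a [probe_matrix()]}
#'     \item{probe_map}{data.frame `probe_id`, `gene` (control probes are
#'       absent from the map)}
#'     \item{design}{data.frame `sample`, `animal`, `muscle`, `stress`,
#'       `diet`}
#'     \item{truth}{a `ground_truth` list: `de_genes` (data.frame `gene`,
#'       `muscle` in \{LT, ST, both\}, `lfc`), `enriched_modules` (named
#'       list of `list(genes, context)`), `planted_regulators`,
#'       `planted_targets`, `qtl_spanning_genes`}
#'   }
#' @export
generate_expression <- function(cfg) {
  validate_sim_config(cfg)
  set.seed(stage_seed(cfg, "expression"))

  n_gene_probes <- cfg$n_probes - cfg$n_control_probes
  genes <- sprintf("G%04d", seq_len(cfg$n_genes))
  counts <- allocate_probes(cfg$n_genes, cfg$probes_per_gene, n_gene_probes)
  probe_map <- data.frame(
    probe_id = sprintf("P%05d", seq_len(n_gene_probes)),
    gene = rep(genes, counts),
    stringsAsFactors = FALSE
  )
  control_ids <- sprintf("CTRL%04d", seq_len(cfg$n_control_probes))
  probe_ids <- c(probe_map$probe_id, control_ids)
  is_control <- c(rep(FALSE, n_gene_probes), rep(TRUE, cfg$n_control_probes))

  # design: each animal contributes one array per muscle
  n_animals <- 4L * cfg$n_animals_per_group
  animals <- sprintf("A%02d", seq_len(n_animals))
  stress <- rep(cfg$stress_levels, each = n_animals / 2)
  diet <- rep(rep(cfg$diet_levels, each = cfg$n_animals_per_group), times = 2)
  design <- expand.grid(animal = animals, muscle = cfg$muscles,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  design$stress <- stress[match(design$animal, animals)]
  design$diet <- diet[match(design$animal, animals)]
  design$sample <- paste(design$animal, design$muscle, sep = "_")
  design <- design[, c("sample", "animal", "muscle", "stress", "diet")]

  # planted DE genes with muscle assignment and signed log2 effect
  if (cfg$n_de_genes > 0) {
    de_gene_ids <- sample(genes, cfg$n_de_genes)
    assignment <- rep(c("LT", "ST", "both"),
                      times = cfg$de_split[c("lt_only", "st_only", "both")])
    lfc <- sample(c(-1, 1), cfg$n_de_genes, replace = TRUE) *
      stats::runif(cfg$n_de_genes, cfg$lfc_range[1], cfg$lfc_range[2])
    de_genes <- data.frame(gene = de_gene_ids, muscle = assignment,
                           lfc = lfc, stringsAsFactors = FALSE)
  } else {
    de_genes <- data.frame(gene = character(), muscle = character(),
                           lfc = numeric(), stringsAsFactors = FALSE)
  }

  # intensity: baseline + array scale + planted effect + noise, all log2
  n_samples <- nrow(design)
  mu <- stats::rnorm(cfg$n_probes, mean = 10, sd = 1.5)
  array_effect <- stats::rnorm(n_samples, 0, cfg$array_effect_sd)
  log2val <- matrix(mu, cfg$n_probes, n_samples) +
    matrix(array_effect, cfg$n_probes, n_samples, byrow = TRUE) +
    matrix(stats::rnorm(cfg$n_probes * n_samples, 0, cfg$noise_sd),
           cfg$n_probes, n_samples)
  dimnames(log2val) <- list(probe_ids, design$sample)

  if (nrow(de_genes) > 0) {
    stressed <- design$stress == "stress"
    for (i in seq_len(nrow(de_genes))) {
      rows <- which(probe_map$gene == de_genes$gene[i])
      m <- de_genes$muscle[i]
      cols <- if (m == "both") stressed else stressed & design$muscle == m
      log2val[rows, cols] <- log2val[rows, cols] + de_genes$lfc[i]
    }
  }
  intensity <- 2^log2val

  qc_pass <- matrix(stats::runif(cfg$n_probes * n_samples) >=
                      cfg$frac_probe_dropout,
                    cfg$n_probes, n_samples,
                    dimnames = dimnames(intensity))
  # every array must keep at least one usable control probe
  ctrl_rows <- which(is_control)
  for (j in seq_len(n_samples)) {
    if (!any(qc_pass[ctrl_rows, j])) qc_pass[ctrl_rows[1], j] <- TRUE
  }

  # remaining planted truth, drawn from the non-DE gene pool
  pool <- setdiff(genes, de_genes$gene)
  planted_regulators <- if (cfg$n_regulators > 0)
    sample(pool, cfg$n_regulators) else character()
  pool <- setdiff(pool, planted_regulators)
  planted_targets <- if (cfg$n_targets > 0)
    sample(pool, cfg$n_targets) else character()

  enriched_modules <- list()
  if (cfg$n_planted_modules > 0 && nrow(de_genes) > 0) {
    contexts <- rep(c("LT", "ST", "common"),
                    length.out = cfg$n_planted_modules)
    for (i in seq_len(cfg$n_planted_modules)) {
      ctx <- contexts[i]
      eligible <- switch(ctx,
        LT = de_genes$gene[de_genes$muscle %in% c("LT", "both")],
        ST = de_genes$gene[de_genes$muscle %in% c("ST", "both")],
        common = de_genes$gene[de_genes$muscle == "both"])
      size <- min(length(eligible), sample(5:12, 1))
      enriched_modules[[sprintf("M%02d", i)]] <-
        list(genes = sort(sample(eligible, size)), context = ctx)
    }
  }

  qtl_spanning <- if (cfg$n_qtl_genes > 0 && nrow(de_genes) > 0)
    sort(sample(de_genes$gene, min(cfg$n_qtl_genes, nrow(de_genes))))
  else character()

  truth <- structure(list(de_genes = de_genes,
                          enriched_modules = enriched_modules,
                          planted_regulators = sort(planted_regulators),
                          planted_targets = sort(planted_targets),
                          qtl_spanning_genes = qtl_spanning),
                     class = "ground_truth")

  list(probes = probe_matrix(intensity, is_control, qc_pass, design),
       probe_map = probe_map,
       design = design,
       truth = truth)
}
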