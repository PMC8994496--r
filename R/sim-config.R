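#' Simulation configuration
#'
#' Build and validate the configuration object driving the synthetic-data
#' generators. Defaults emulate the bovine muscle-stress array design:
#' 10,064 probes of which 1,614 are non-biological control probes, 4,210
#' genes with one to three probes each, and a 2 muscle x 2 stress-group x
#' 2 diet design with 32 animals (each animal contributes one array per
#' muscle, 16 animals per stress group).
#'
#' Differentially expressed (DE) genes are planted with a signed log2 effect
#' drawn from `lfc_range` in the stressed group of their designated
#' muscle(s); by default the split across muscles mirrors a two-muscle
#' study with a shared core response (38 LT-only, 8 ST-only, 24 common).
#'
#' @param n_probes total number of probes on the array.
#' @param n_control_probes number of control probes (no biological signal).
#' @param n_genes number of genes covered by the non-control probes.
#' @param probes_per_gene length-2 integer vector `c(min, max)`; per-gene
#'   probe counts are drawn uniformly from this range, then adjusted so the
#'   total equals `n_probes - n_control_probes`.
#' @param n_animals_per_group animals per stress x diet cell (so total
#'   animals = 4 * n_animals_per_group).
#' @param muscles,stress_levels,diet_levels factor levels of the design.
#' @param n_de_genes number of planted DE genes.
#' @param de_split named integer vector `c(lt_only=, st_only=, both=)`
#'   partitioning `n_de_genes` across muscle assignments; must sum to
#'   `n_de_genes`.
#' @param lfc_range length-2 positive vector, magnitude interval of planted
#'   log2 fold changes (sign is randomized per gene).
#' @param noise_sd standard deviation of the log2-scale measurement noise.
#' @param array_effect_sd standard deviation of the per-array log2
#'   multiplicative scale effect.
#' @param frac_probe_dropout probability that a (probe, sample) cell fails
#'   QC. Probes with any failed cell are removed during normalization, so
#'   with 64 arrays the default 0.002 retains ~88% of probes, mirroring
#'   the mild feature-level QC filtering of well-behaved arrays.
#' @param n_modules total number of cis-transcriptional modules in the
#'   synthetic hit table.
#' @param n_planted_modules number of modules planted on DE-gene target
#'   sets (<= n_modules).
#' @param module_background_rate per-gene background hit probability for
#'   every module.
#' @param n_regulators,n_targets planted network regulators / expression
#'   targets (non-DE genes wired to the planted DE genes).
#' @param n_terms number of annotation terms in the synthetic gene-to-GO
#'   table.
#' @param n_qtl_genes number of planted DE genes fully spanned by a
#'   meat-quality QTL.
#' @param seed integer master seed; every generator derives its stream from
#'   it so identical (seed, config) pairs give byte-identical outputs.
#'
#' @return an object of class `sim_config` (a validated named list).
#' @export
sim_config <- function(n_probes = 10064L,
                       n_control_probes = 1614L,
                       n_genes = 4210L,
                       probes_per_gene = c(1L, 3L),
                       n_animals_per_group = 8L,
                       muscles = c("LT", "ST"),
                       stress_levels = c("limited", "stress"),
                       diet_levels = c("control", "EP"),
                       n_de_genes = 70L,
                       de_split = c(lt_only = 38L, st_only = 8L, both = 24L),
                       lfc_range = c(1, 2),
                       noise_sd = 0.2,
                       array_effect_sd = 0.1,
                       frac_probe_dropout = 0.002,
                       n_modules = 40L,
                       n_planted_modules = 6L,
                       module_background_rate = 0.01,
                       n_regulators = 4L,
                       n_targets = 4L,
                       n_terms = 60L,
                       n_qtl_genes = 10L,
                       seed = 1L) {
  cfg <- list(
    n_probes = as.integer(n_probes),
    n_control_probes = as.integer(n_control_probes),
    n_genes = as.integer(n_genes),
    probes_per_gene = as.integer(probes_per_gene),
    n_animals_per_group = as.integer(n_animals_per_group),
    muscles = muscles,
    stress_levels = stress_levels,
    diet_levels = diet_levels,
    n_de_genes = as.integer(n_de_genes),
    de_split = de_split,
    lfc_range = as.numeric(lfc_range),
    noise_sd = as.numeric(noise_sd),
    array_effect_sd = as.numeric(array_effect_sd),
    frac_probe_dropout = as.numeric(frac_probe_dropout),
    n_modules = as.integer(n_modules),
    n_planted_modules = as.integer(n_planted_modules),
    module_background_rate = as.numeric(module_background_rate),
    n_regulators = as.integer(n_regulators),
    n_targets = as.integer(n_targets),
    n_terms = as.integer(n_terms),
    n_qtl_genes = as.integer(n_qtl_genes),
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' Validate a simulation configuration
#'
#' Errors name the offending field.
#'
#' @param cfg a `sim_config`.
#' @return `cfg`, invisibly, if valid.
#' @export
validate_sim_config <- function(cfg) {
  fail <- function(field, msg) {
    stop(sprintf("invalid sim_config: field '%s' %s", field, msg),
         call. = FALSE)
  }
  if (cfg$n_control_probes >= cfg$n_probes)
    fail("n_control_probes", "must be < n_probes")
  if (cfg$n_de_genes > cfg$n_genes)
    fail("n_de_genes", "must be <= n_genes")
  if (length(cfg$lfc_range) != 2 || cfg$lfc_range[1] <= 0 ||
      cfg$lfc_range[2] < cfg$lfc_range[1])
    fail("lfc_range", "must be an increasing interval with lower bound > 0")
  if (cfg$noise_sd <= 0)
    fail("noise_sd", "must be > 0")
  if (cfg$array_effect_sd < 0)
    fail("array_effect_sd", "must be >= 0")
  if (cfg$frac_probe_dropout < 0 || cfg$frac_probe_dropout >= 1)
    fail("frac_probe_dropout", "must be in [0, 1)")
  if (length(cfg$probes_per_gene) != 2 || cfg$probes_per_gene[1] < 1 ||
      cfg$probes_per_gene[2] < cfg$probes_per_gene[1])
    fail("probes_per_gene", "must be c(min, max) with 1 <= min <= max")
  n_gene_probes <- cfg$n_probes - cfg$n_control_probes
  if (n_gene_probes < cfg$n_genes * cfg$probes_per_gene[1] ||
      n_gene_probes > cfg$n_genes * cfg$probes_per_gene[2])
    fail("probes_per_gene",
         "range cannot allocate n_probes - n_control_probes probes over n_genes genes")
  if (sum(cfg$de_split) != cfg$n_de_genes)
    fail("de_split", "must sum to n_de_genes")
  if (cfg$n_planted_modules > cfg$n_modules)
    fail("n_planted_modules", "must be <= n_modules")
  if (cfg$n_qtl_genes > cfg$n_de_genes)
    fail("n_qtl_genes", "must be <= n_de_genes")
  invisible(cfg)
}

# Derive a reproducible sub-stream seed for one generator stage. Keeps all
# derived seeds below 2^31 - 1.
stage_seed <- function(cfg, stage) {
  offsets <- c(expression = 11L, modules = 23L, network = 37L,
               loci = 53L, annotation = 71L)
  (cfg$seed %% 1000000L) * 1000L + offsets[[stage]]
}
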