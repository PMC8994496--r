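# Scaled-down simulation configuration for fast unit tests.
small_cfg <- function(seed = 1L, ...) {
  defaults <- list(n_probes = 1200L, n_control_probes = 200L,
                   n_genes = 450L, n_de_genes = 30L,
                   de_split = c(lt_only = 15L, st_only = 5L, both = 10L),
                   n_modules = 15L, n_planted_modules = 3L,
                   n_terms = 20L, n_qtl_genes = 5L, seed = seed)
  override <- list(...)
  defaults[names(override)] <- override
  do.call(sim_config, defaults)
}

# Null configuration: no planted signal of any kind.
null_cfg <- function(seed = 1L, n_probes = 5000L) {
  sim_config(n_probes = n_probes,
             n_control_probes = as.integer(round(n_probes * 0.16)),
             n_genes = as.integer(round(n_probes * 0.42)),
             n_de_genes = 0L,
             de_split = c(lt_only = 0L, st_only = 0L, both = 0L),
             n_planted_modules = 0L, n_regulators = 0L, n_targets = 0L,
             n_qtl_genes = 0L, seed = seed)
}

extdata <- function(f) system.file("extdata", f, package = "stressnet")

# Stub network extract carrying fixed regulator/target sets (for the pure
# set-intersection operations).
stub_extract <- function(regulators, targets = character()) {
  structure(list(seeds = character(), regulators = sort(regulators),
                 targets = sort(targets),
                 edges = data.frame(), profile = "muscle"),
            class = "network_extract")
}
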