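# Shared helpers for building tiny cohorts in tests.

# small peptide library + simulated cohort with optional spikes
tiny_cohort <- function(seed = 1, n_genes = 50, peptides_per_gene = 2,
                        n_cases = 6, n_controls = 8, n_mock = 2,
                        reads_per_sample = 2e4, spike_genes = NULL, ...) {
  lib <- build_random_library(n_genes, peptides_per_gene, 30, seed = seed)
  cfg <- simulation_config(n_cases = n_cases, n_controls = n_controls,
                           n_mock = n_mock, n_genes = n_genes,
                           peptides_per_gene = peptides_per_gene,
                           reads_per_sample = reads_per_sample,
                           spike_genes = spike_genes,
                           seed = seed, ...)
  sim <- simulate_counts(cfg, lib)
  list(lib = lib, cfg = cfg, sim = sim,
       gene_counts = collapse_to_gene(sim$counts, lib))
}

# hand-built gene-level count matrix with explicit roles
manual_counts <- function(counts, roles) {
  phip_counts(counts, feature_level = "gene", roles = roles)
}

# independent loop-based reimplementation of the four hit criteria,
# gene by gene, straight from their definitions
brute_force_hits <- function(enr, config = hit_call_config()) {
  roles <- enr$roles
  cases <- names(roles)[roles == "case"]
  ctrls <- names(roles)[roles == "control"]
  out <- logical(nrow(enr$z))
  names(out) <- rownames(enr$z)
  for (g in rownames(enr$z)) {
    pos <- function(s) {
      if (config$z_inclusive) enr$z[g, s] >= config$z_threshold
      else enr$z[g, s] > config$z_threshold
    }
    pos_cases <- Filter(pos, cases)
    pos_ctrls <- Filter(pos, ctrls)
    freq_ok <- length(pos_cases) / length(cases) >= config$case_frequency_min
    control_ok <- if (config$mode == "absolute") {
      length(pos_ctrls) < config$control_positive_max
    } else {
      length(pos_ctrls) / length(ctrls) < config$control_positive_max_fraction
    }
    strong_ok <- length(pos_cases) > 0 &&
      max(enr$fc[g, pos_cases]) >= config$strong_fc_min
    dominance_ok <- !config$require_no_control_above_max_case ||
      length(pos_ctrls) == 0 ||
      max(enr$fc[g, pos_ctrls]) <= max(enr$fc[g, cases])
    out[g] <- freq_ok && control_ok && strong_ok && dominance_ok
  }
  out
}
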