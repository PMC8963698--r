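#' Run the full PhIP-Seq analysis pipeline
#'
#' Orchestrates simulate (or load) -> gene collapse -> enrichment -> hit
#' calling, plus optional control downsampling and classification, writing
#' every stage's output and a machine-readable manifest into `out_dir`.
#' Reruns with the same config and seed produce byte-identical tables.
#'
#' The config is a list (or path to a JSON file) with elements:
#' \describe{
#'   \item{seed}{integer; governs the whole run.}
#'   \item{simulation}{arguments for [simulation_config()] (its `seed` is
#'     taken from the global seed); mutually exclusive with `inputs`.}
#'   \item{inputs}{list with `counts`, `roles` (TSV paths; peptide level
#'     needs `library` FASTA too, gene level sets `feature_level = "gene"`).}
#'   \item{hit_calling}{arguments for [hit_call_config()] (optional).}
#'   \item{downsample}{list with `bins` and `reps` (optional stage).}
#'   \item{classify}{list with `n_folds`, `regularization_strength`
#'     (optional stage).}
#' }
#'
#' @param config list or path to a JSON config.
#' @param out_dir output directory (created if missing).
#' @return Invisibly, a list with the in-memory stage results (`counts`,
#'   `gene_counts`, `enrichment`, `hits`, and when configured `truth`,
#'   `downsample`, `classifier`) plus `manifest`.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (is.null(config$seed)) stop("config must define a seed")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "': ", conditionMessage(e), call. = FALSE)
    })
  }
  res <- list()
  outputs <- character(0)
  emit <- function(path) outputs <<- c(outputs, path)

  if (!is.null(config$simulation)) {
    sim_stage <- stage("simulate", {
      sc <- do.call(simulation_config,
                    c(config$simulation[setdiff(names(config$simulation), "seed")],
                      list(seed = config$seed)))
      lib <- build_random_library(sc$n_genes, sc$peptides_per_gene,
                                  seed = config$seed)
      sim <- simulate_counts(sc, lib)
      list(lib = lib, counts = sim$counts, truth = sim$truth)
    })
    res$library <- sim_stage$lib
    res$counts <- sim_stage$counts
    res$truth <- sim_stage$truth
    emit(write_library_fasta(res$library, file.path(out_dir, "library.fasta"),
                             file.path(out_dir, "gene_map.tsv")))
    emit(file.path(out_dir, "gene_map.tsv"))
    emit(write_counts_tsv(res$counts, file.path(out_dir, "counts_peptide.tsv"),
                          file.path(out_dir, "roles.tsv")))
    emit(file.path(out_dir, "roles.tsv"))
    emit(write_tsv(res$truth, file.path(out_dir, "truth.tsv")))
    res$gene_counts <- stage("collapse", collapse_to_gene(res$counts, res$library))
  } else if (!is.null(config$inputs)) {
    inp <- config$inputs
    for (p in unlist(inp)) {
      if (!file.exists(p)) stop("pipeline stage 'load': input file not found: ", p)
    }
    if (!is.null(inp$library)) {
      res$library <- stage("load", read_library_fasta(inp$library))
      res$counts <- stage("load", read_counts_tsv(inp$counts, inp$roles, "peptide"))
      res$gene_counts <- stage("collapse", collapse_to_gene(res$counts, res$library))
    } else {
      res$gene_counts <- stage("load", read_counts_tsv(inp$counts, inp$roles, "gene"))
    }
  } else {
    stop("config must define either 'simulation' or 'inputs'")
  }

  emit(write_counts_tsv(res$gene_counts, file.path(out_dir, "counts_gene.tsv"),
                        file.path(out_dir, "roles_gene.tsv")))
  emit(file.path(out_dir, "roles_gene.tsv"))

  res$enrichment <- stage("enrich", compute_enrichment(res$gene_counts))
  for (p in write_enrichment_tsv(res$enrichment,
                                 file.path(out_dir, "enrichment"))) emit(p)

  hc <- do.call(hit_call_config, as.list(config$hit_calling))
  res$hits <- stage("call-hits", call_hits(res$enrichment, hc))
  emit(write_hits_tsv(res$hits, file.path(out_dir, "hits.tsv")))

  if (!is.null(config$downsample)) {
    res$downsample <- stage("downsample", downsample_controls(
      res$gene_counts, bins = unlist(config$downsample$bins),
      reps = config$downsample$reps %||% 10, config = hc, seed = config$seed))
    emit(write_hits_tsv(res$downsample, file.path(out_dir, "downsample.tsv")))
    emit(file.path(out_dir, "downsample_summary.tsv"))
  }

  if (!is.null(config$classify)) {
    res$classifier <- stage("classify", {
      feats <- rpk_transform(res$gene_counts)
      roles <- res$gene_counts$roles
      keep <- names(roles)[roles %in% c("case", "control")]
      fit_logistic_cv(feats[, keep, drop = FALSE], roles[keep],
                      n_folds = config$classify$n_folds %||% 5,
                      regularization_strength =
                        config$classify$regularization_strength %||% 1.0,
                      seed = config$seed)
    })
    for (p in write_classifier_outputs(res$classifier,
                                       file.path(out_dir, "classifier"))) emit(p)
  }

  manifest <- list(
    package = "phipseqr",
    version = as.character(utils::packageVersion("phipseqr")),
    seed = config$seed,
    hit_calling = unclass(hc),
    outputs = as.list(stats::setNames(
      unname(tools::md5sum(outputs)), basename(outputs))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  res$manifest <- manifest
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate the packaged demo cohort (fixtures)
#'
#' Builds a small but structurally complete synthetic cohort — 200 genes
#' tiled by 4 peptides across 40 samples (16 cases, 20 controls, 4 mock-IPs)
#' with 5 disease-shared antigens spiked at 30-44% case frequency and an
#' expected fold change of 60 — and writes library FASTA, count/role/truth
#' TSVs into `dir`. Fully deterministic in `seed`, so fixtures are
#' regenerated rather than shipped.
#'
#' Private reactivity in the demo uses multipliers capped below the
#' strong-positive fold-change threshold, so the demo's hit table is exactly
#' its spiked antigens; the cohort-level analyses elsewhere use the
#' generator's stronger default range, under which private reactivities can
#' and do masquerade as apparent hits.
#'
#' @param seed integer seed.
#' @param dir output directory (created if missing).
#' @return Invisibly, a list with `library`, `counts` (peptide level),
#'   `gene_counts`, `truth`, `spike_genes`, and the written `paths`.
#' @export
make_fixtures <- function(seed = 1, dir = tempfile("phip_fixtures_")) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  lib <- build_random_library(200, 4, 49, seed = seed)
  base_cfg <- simulation_config(n_cases = 16, n_controls = 20, n_mock = 4,
                                n_genes = 200, peptides_per_gene = 4,
                                reads_per_sample = 1e5, dispersion = 3000,
                                private_reactivity_rate = 1,
                                private_multiplier_range = c(5, 40),
                                seed = seed)
  freqs <- seq(0.30, 0.44, length.out = 5)
  spikes <- data.frame(
    gene = sprintf("GENE%04d", 1:5),
    case_frequency = freqs,
    multiplier = spike_multiplier_for_fc(base_cfg, rep(60, 5),
                                         case_frequency = freqs))
  cfg <- simulation_config(n_cases = 16, n_controls = 20, n_mock = 4,
                           n_genes = 200, peptides_per_gene = 4,
                           reads_per_sample = 1e5, dispersion = 3000,
                           private_reactivity_rate = 1,
                           private_multiplier_range = c(5, 40),
                           spike_genes = spikes,
                           seed = seed)
  sim <- simulate_counts(cfg, lib)
  paths <- c(
    library = file.path(dir, "library.fasta"),
    gene_map = file.path(dir, "gene_map.tsv"),
    counts = file.path(dir, "counts_peptide.tsv"),
    roles = file.path(dir, "roles.tsv"),
    truth = file.path(dir, "truth.tsv"))
  write_library_fasta(lib, paths["library"], paths["gene_map"])
  write_counts_tsv(sim$counts, paths["counts"], paths["roles"])
  write_tsv(sim$truth, paths["truth"])
  invisible(list(library = lib, counts = sim$counts,
                 gene_counts = collapse_to_gene(sim$counts, lib),
                 truth = sim$truth, spike_genes = spikes, paths = paths))
}
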