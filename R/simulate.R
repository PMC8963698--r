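#' Simulation configuration
#'
#' Parameters of the synthetic PhIP-Seq cohort generator. The generator is
#' compositional: every sample is a multinomial draw from per-sample peptide
#' frequencies derived from one shared background composition, because the
#' downstream statistics (percent of reads, fold change over mock-IP) are
#' themselves compositional.
#'
#' @param n_cases,n_controls,n_mock numbers of disease, control and bead-only
#'   (mock-IP) samples; `n_mock >= 1` is required downstream.
#' @param n_genes,peptides_per_gene library shape used when the config is
#'   asked to build its own library.
#' @param reads_per_sample mean sequencing depth per sample; actual totals
#'   are Poisson around this mean when `poisson_depth = TRUE`, exactly this
#'   value otherwise.
#' @param spike_genes `data.frame(gene, case_frequency, multiplier)` of
#'   disease-shared antigens: each spike gene's peptide frequencies are
#'   multiplied by `multiplier` (> 1) in `round(case_frequency * n_cases)`
#'   cases (round-half-up, sampled without replacement).
#' @param private_reactivity_rate expected number of privately autoreactive
#'   genes per serum sample (cases AND controls; Poisson-distributed). This
#'   models the patient-specific reactivity spectrum seen in real cohorts
#'   regardless of disease status.
#' @param private_multiplier_range length-2 numeric, uniform range (> 1) of
#'   private enrichment multipliers.
#' @param dispersion concentration of the per-sample Dirichlet perturbation
#'   of the background composition; larger = less sample-to-sample noise,
#'   `Inf` = none.
#' @param poisson_depth logical, see `reads_per_sample`.
#' @param seed integer; fixes all randomness of the simulation.
#' @return A list of class `sim_config`.
#' @export
simulation_config <- function(n_cases = 10, n_controls = 20, n_mock = 4,
                              n_genes = 200, peptides_per_gene = 4,
                              reads_per_sample = 1e5,
                              spike_genes = NULL,
                              private_reactivity_rate = 2,
                              private_multiplier_range = c(5, 200),
                              dispersion = 800,
                              poisson_depth = TRUE,
                              seed = 1) {
  if (any(c(n_cases, n_controls, n_mock, n_genes, peptides_per_gene,
            reads_per_sample) < 0)) {
    stop("all counts must be >= 0")
  }
  if (!is.null(spike_genes)) {
    spike_genes <- as.data.frame(spike_genes)  # accepts JSON column lists too
    stopifnot(all(c("gene", "case_frequency", "multiplier") %in% names(spike_genes)))
    if (any(spike_genes$case_frequency < 0 | spike_genes$case_frequency > 1)) {
      stop("spike case_frequency must be in [0, 1]")
    }
    if (any(spike_genes$multiplier <= 1)) stop("spike multipliers must be > 1")
  }
  if (private_reactivity_rate < 0) stop("private_reactivity_rate must be >= 0")
  stopifnot(length(private_multiplier_range) == 2,
            private_multiplier_range[1] > 1,
            diff(private_multiplier_range) >= 0)
  if (dispersion <= 0) stop("dispersion must be > 0 (Inf allowed)")
  structure(list(n_cases = n_cases, n_controls = n_controls, n_mock = n_mock,
                 n_genes = n_genes, peptides_per_gene = peptides_per_gene,
                 reads_per_sample = reads_per_sample, spike_genes = spike_genes,
                 private_reactivity_rate = private_reactivity_rate,
                 private_multiplier_range = private_multiplier_range,
                 dispersion = dispersion, poisson_depth = poisson_depth,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a PhIP-Seq cohort count matrix with ground truth
#'
#' Generative model: (1) one background peptide composition is drawn from a
#' symmetric Dirichlet (library representation is never uniform); (2) mock-IP
#' samples are multinomial draws from that background; (3) every serum sample
#' (case or control) perturbs the background with per-sample Dirichlet noise
#' at concentration `dispersion`, then a Poisson(`private_reactivity_rate`)
#' number of private genes have all their peptide frequencies multiplied by a
#' value drawn uniformly from `private_multiplier_range`; (4) each spike gene
#' is additionally multiplied by its `multiplier` in a without-replacement
#' sample of `round(case_frequency * n_cases)` cases; frequencies are
#' renormalized and counts drawn multinomially. All of (3) and (4) are
#' recorded in the truth table.
#'
#' @param config a [simulation_config()].
#' @param library a [peptide_library()]; must contain every spike gene.
#' @return A list with elements `counts` (peptide-level [phip_counts()]) and
#'   `truth` (data.frame `sample_id`, `gene`, `multiplier`, `kind` in
#'   \{private, spike\}; the spike design is attached as attribute
#'   `spike_design`).
#' @examples
#' lib <- build_random_library(20, 2, 30, seed = 1)
#' sim <- simulate_counts(simulation_config(n_genes = 20, peptides_per_gene = 2,
#'                                          seed = 2), lib)
#' colSums(sim$counts$counts)[1:3]
#' @export
simulate_counts <- function(config, library) {
  stopifnot(inherits(config, "sim_config"))
  validate_peptide_library(library)
  genes <- unique(library$gene)
  if (!is.null(config$spike_genes)) {
    absent <- setdiff(config$spike_genes$gene, genes)
    if (length(absent) > 0) {
      stop("spike gene(s) absent from library: ", paste(absent, collapse = ", "))
    }
    if (length(genes) < nrow(config$spike_genes)) {
      stop("library has fewer genes than spike_genes")
    }
  }
  if (config$n_mock < 1) stop("n_mock must be >= 1 (mock-IP defines the background)")

  P <- nrow(library)
  gene_of <- library$gene
  case_ids <- if (config$n_cases > 0) sprintf("case%03d", seq_len(config$n_cases)) else character(0)
  ctrl_ids <- if (config$n_controls > 0) sprintf("control%03d", seq_len(config$n_controls)) else character(0)
  mock_ids <- sprintf("mock%02d", seq_len(config$n_mock))
  serum_ids <- c(case_ids, ctrl_ids)

  res <- with_seed(config$seed, {
    base <- rgamma(P, shape = 1)
    base <- base / sum(base)

    # per-serum-sample frequency perturbation
    freq <- matrix(base, nrow = P, ncol = length(serum_ids),
                   dimnames = list(library$peptide_id, serum_ids))
    if (is.finite(config$dispersion)) {
      for (j in seq_along(serum_ids)) {
        g <- rgamma(P, shape = config$dispersion * base)
        if (sum(g) == 0) g <- base  # pathological tiny-dispersion guard
        freq[, j] <- g / sum(g)
      }
    }

    truth <- list()
    if (config$private_reactivity_rate > 0 && length(serum_ids) > 0) {
      for (j in seq_along(serum_ids)) {
        k <- min(rpois(1, config$private_reactivity_rate), length(genes))
        if (k > 0) {
          gs <- sample(genes, k)
          mult <- runif(k, config$private_multiplier_range[1],
                        config$private_multiplier_range[2])
          for (i in seq_len(k)) {
            sel <- gene_of == gs[i]
            freq[sel, j] <- freq[sel, j] * mult[i]
          }
          truth[[length(truth) + 1L]] <- data.frame(
            sample_id = serum_ids[j], gene = gs, multiplier = mult,
            kind = "private", stringsAsFactors = FALSE)
        }
      }
    }

    if (!is.null(config$spike_genes) && config$n_cases > 0) {
      for (i in seq_len(nrow(config$spike_genes))) {
        sg <- config$spike_genes[i, ]
        k <- round_half_up(sg$case_frequency * config$n_cases)
        if (k > 0) {
          chosen <- sample(case_ids, k)
          sel <- gene_of == sg$gene
          for (s in chosen) freq[sel, s] <- freq[sel, s] * sg$multiplier
          truth[[length(truth) + 1L]] <- data.frame(
            sample_id = chosen, gene = sg$gene, multiplier = sg$multiplier,
            kind = "spike", stringsAsFactors = FALSE)
        }
      }
    }

    freq <- sweep(freq, 2, colSums(freq), "/")

    all_ids <- c(serum_ids, mock_ids)
    counts <- matrix(0, nrow = P, ncol = length(all_ids),
                     dimnames = list(library$peptide_id, all_ids))
    depth <- function() {
      if (config$poisson_depth) rpois(1, config$reads_per_sample)
      else config$reads_per_sample
    }
    for (j in seq_along(serum_ids)) {
      counts[, serum_ids[j]] <- rmultinom(1, depth(), freq[, j])
    }
    for (m in mock_ids) counts[, m] <- rmultinom(1, depth(), base)

    list(counts = counts, truth = truth)
  })

  roles <- c(stats::setNames(rep("case", length(case_ids)), case_ids),
             stats::setNames(rep("control", length(ctrl_ids)), ctrl_ids),
             stats::setNames(rep("mock_ip", length(mock_ids)), mock_ids))
  truth <- if (length(res$truth) > 0) {
    do.call(rbind, res$truth)
  } else {
    data.frame(sample_id = character(0), gene = character(0),
               multiplier = numeric(0), kind = character(0),
               stringsAsFactors = FALSE)
  }
  rownames(truth) <- NULL
  attr(truth, "spike_design") <- config$spike_genes
  list(counts = phip_counts(res$counts, feature_level = "peptide", roles = roles),
       truth = truth)
}

#' Expected fold change of a spiked gene, and its inverse
#'
#' The generator is compositional: multiplying one gene's frequencies by `m`
#' also inflates the sample's total, so the realized fold change over mock-IP
#' is smaller than `m`. Plugging expected values into the renormalization,
#' a spiked case's fold change for gene `i` is approximately
#' `FC_i = m_i / ((1 - p + M + S_i) + m_i * p)` with `p = 1/n_genes` the
#' expected background share of one gene,
#' `M = private_reactivity_rate * (mean(private_multiplier_range) - 1) / n_genes`
#' the expected compositional mass of private reactivities, and
#' `S_i = sum_{j != i} case_frequency_j * (m_j - 1) * p` the expected mass of
#' other spikes co-occurring in the same case. `expected_spike_fc()` evaluates
#' this for a config's spike design; `spike_multiplier_for_fc()` inverts it,
#' solving the coupled system by fixed-point iteration to give multipliers
#' that target desired expected fold changes (each `target_fc` must stay
#' below `n_genes`, the compositional ceiling).
#'
#' @param config a [simulation_config()]; for `expected_spike_fc` it must
#'   carry `spike_genes`.
#' @param target_fc desired expected fold change(s) over mock-IP.
#' @param case_frequency planned case frequency per spike (recycled); used
#'   for the co-spike mass term.
#' @return `expected_spike_fc`: expected fold change per spike gene;
#'   `spike_multiplier_for_fc`: required multiplier per target.
#' @export
expected_spike_fc <- function(config) {
  stopifnot(inherits(config, "sim_config"), !is.null(config$spike_genes))
  sg <- config$spike_genes
  p <- 1 / config$n_genes
  M <- config$private_reactivity_rate *
    (mean(config$private_multiplier_range) - 1) / config$n_genes
  co <- sum(sg$case_frequency * (sg$multiplier - 1)) * p -
    sg$case_frequency * (sg$multiplier - 1) * p
  stats::setNames(sg$multiplier / ((1 - p + M + co) + sg$multiplier * p),
                  sg$gene)
}

#' @rdname expected_spike_fc
#' @export
spike_multiplier_for_fc <- function(config, target_fc, case_frequency = 0) {
  stopifnot(inherits(config, "sim_config"))
  p <- 1 / config$n_genes
  if (any(target_fc * p >= 1)) {
    stop("target_fc must be below the compositional ceiling n_genes")
  }
  f <- rep_len(case_frequency, length(target_fc))
  # the coupled system m_i = FC_i (1 - p + M + S_i) / (1 - FC_i p) with
  # S_i = sum_{j!=i} f_j (m_j - 1) p is affine in m; it has a positive
  # solution only when the total spike mass feedback stays below 1
  gain <- sum(f * p * target_fc / (1 - target_fc * p))
  if (gain >= 1) {
    stop("spike design is compositionally infeasible: requested total ",
         "enrichment mass feeds back on itself (gain ", round(gain, 2),
         " >= 1); lower target_fc, case frequencies, or use more genes")
  }
  M <- config$private_reactivity_rate *
    (mean(config$private_multiplier_range) - 1) / config$n_genes
  m <- target_fc  # starting point; geometric convergence at rate `gain`
  for (it in 1:200) {
    co <- sum(f * (m - 1)) * p - f * (m - 1) * p
    m_new <- target_fc * (1 - p + M + co) / (1 - target_fc * p)
    if (max(abs(m_new - m)) < 1e-10) { m <- m_new; break }
    m <- m_new
  }
  stopifnot(all(is.finite(m)), all(m > 1))
  m
}

# Fixed reverse-translation codon table: for each amino acid, the first codon
# in the standard genetic code's conventional TTT..GGG enumeration.
preferred_codons <- function() {
  gc <- Biostrings::GENETIC_CODE
  gc <- gc[gc != "*"]
  tapply(names(gc), gc, function(x) x[1])
}

reverse_translate <- function(aa) {
  tab <- preferred_codons()
  vapply(strsplit(aa, "", fixed = TRUE),
         function(ch) paste0(tab[ch], collapse = ""), "")
}

#' Emit synthetic sequencing reads for a peptide-level count matrix
#'
#' For every (peptide, sample) cell, exactly `count` reads are written whose
#' nucleotide sequence is the fixed-codon reverse translation of that
#' peptide's prefix, so counting the reads back recovers the matrix exactly.
#' Read names are `<sample_id>:<serial>`; Phred qualities are constant (Q40).
#'
#' @param matrix a peptide-level [phip_counts()].
#' @param library the [peptide_library()].
#' @param fastq output path; `.gz` suffix triggers gzip compression.
#' @param read_length read length in nucleotides; must be a multiple of 3 and
#'   at most 3x the shortest peptide.
#' @param seed seed for shuffling read order within the file.
#' @return `fastq`, invisibly.
#' @export
simulate_reads <- function(matrix, library, fastq, read_length = 48, seed = 1) {
  stopifnot(inherits(matrix, "phip_counts"))
  if (matrix$feature_level != "peptide") stop("counts must be at peptide level")
  validate_peptide_library(library)
  if (read_length %% 3 != 0) stop("read_length must be a multiple of 3")
  aa_len <- read_length / 3
  if (aa_len > min(nchar(library$sequence))) {
    stop("read_length exceeds 3x the shortest peptide length")
  }
  miss <- setdiff(rownames(matrix$counts), library$peptide_id)
  if (length(miss) > 0) stop("peptide id(s) absent from library: ", miss[1])

  prefix_nt <- reverse_translate(substr(
    library$sequence[match(rownames(matrix$counts), library$peptide_id)],
    1, aa_len))
  names(prefix_nt) <- rownames(matrix$counts)

  seqs <- character(0)
  samp <- character(0)
  for (s in colnames(matrix$counts)) {
    cnt <- matrix$counts[, s]
    nz <- cnt > 0
    if (any(nz)) {
      seqs <- c(seqs, rep(prefix_nt[nz], times = cnt[nz]))
      samp <- c(samp, rep(s, sum(cnt[nz])))
    }
  }
  if (length(seqs) > 0) {
    ord <- with_seed(seed, sample.int(length(seqs)))
    seqs <- seqs[ord]
    samp <- samp[ord]
  }
  dna <- Biostrings::DNAStringSet(seqs)
  names(dna) <- sprintf("%s:%07d", samp, seq_along(seqs))
  qual <- Biostrings::PhredQuality(
    vapply(Biostrings::width(dna), function(w) strrep("I", w), ""))
  reads <- Biostrings::QualityScaledDNAStringSet(dna, qual)
  Biostrings::writeQualityScaledXStringSet(reads, fastq,
                                           compress = grepl("\\.gz$", fastq))
  invisible(fastq)
}
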