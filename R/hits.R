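#' Hit-calling configuration
#'
#' Thresholds for calling shared candidate antigens. A sample is *positive*
#' for a gene when its Z-score reaches `z_threshold` (inclusive by default;
#' set `z_inclusive = FALSE` for a strict `>`). A gene is a hit when all four
#' criteria hold: (a) at least `case_frequency_min` of cases are positive;
#' (b) positive controls stay below the control cap; (c) at least one
#' positive case reaches `strong_fc_min` fold change over mock-IP; (d) no
#' positive control's fold change exceeds the highest case fold change.
#'
#' The control cap has two readings, both in use for real cohorts: an
#' absolute count (`mode = "absolute"`: fewer than `control_positive_max`
#' positive controls, default fewer than 2 — suited to small cohorts) or a
#' fraction (`mode = "fraction"`: positive in less than
#' `control_positive_max_fraction` of controls, default 2% — suited to
#' cohorts of hundreds). Exactly one mode is active.
#'
#' @param z_threshold Z-score defining a positive sample (default 10).
#' @param case_frequency_min minimum fraction of positive cases (default
#'   0.10; 0.04 admits rarer shared antigens at some specificity cost).
#' @param control_positive_max absolute cap: hit requires strictly fewer
#'   positive controls than this (default 2).
#' @param control_positive_max_fraction fractional cap (default 0.02).
#' @param mode `"absolute"` or `"fraction"`.
#' @param strong_fc_min minimum fold change of the strongest positive case
#'   (default 50).
#' @param require_no_control_above_max_case enforce criterion (d)?
#' @param dominance_all_controls if `TRUE`, criterion (d) compares the
#'   maximum fold change over *all* controls (not just positive ones) to the
#'   maximum case fold change.
#' @param z_inclusive positive means `z >= z_threshold` (default) rather
#'   than `z > z_threshold`.
#' @return A list of class `hit_config`.
#' @export
hit_call_config <- function(z_threshold = 10, case_frequency_min = 0.10,
                            control_positive_max = 2,
                            control_positive_max_fraction = 0.02,
                            mode = c("absolute", "fraction"),
                            strong_fc_min = 50,
                            require_no_control_above_max_case = TRUE,
                            dominance_all_controls = FALSE,
                            z_inclusive = TRUE) {
  mode <- match.arg(mode)
  if (any(c(z_threshold, case_frequency_min, control_positive_max,
            control_positive_max_fraction, strong_fc_min) <= 0)) {
    stop("all thresholds must be > 0")
  }
  structure(list(z_threshold = z_threshold,
                 case_frequency_min = case_frequency_min,
                 control_positive_max = control_positive_max,
                 control_positive_max_fraction = control_positive_max_fraction,
                 mode = mode, strong_fc_min = strong_fc_min,
                 require_no_control_above_max_case = require_no_control_above_max_case,
                 dominance_all_controls = dominance_all_controls,
                 z_inclusive = z_inclusive),
            class = "hit_config")
}

row_max <- function(m) {
  if (ncol(m) == 0) return(rep(-Inf, nrow(m)))
  do.call(pmax, c(asplit(m, 2), na.rm = TRUE))
}

#' Call shared candidate antigen hits
#'
#' Applies the four hit criteria of [hit_call_config()] gene by gene to the
#' cohort's Z-scores and fold changes. Genes with a degenerate (zero
#' variance) control distribution are still evaluated — their infinite
#' Z-scores simply count as positive — but carry the `degenerate_sd` flag so
#' they can be audited.
#'
#' @param enr a [compute_enrichment()] result.
#' @param config a [hit_call_config()].
#' @return A `data.frame` of class `hit_table`, one row per gene:
#'   positive-sample tallies, max fold changes, the four criterion flags
#'   (`freq_ok`, `control_ok`, `strong_ok`, `dominance_ok`), `degenerate_sd`,
#'   and `is_hit` (the conjunction of the four flags).
#' @export
call_hits <- function(enr, config = hit_call_config()) {
  stopifnot(inherits(enr, "phip_enrichment"), inherits(config, "hit_config"))
  roles <- enr$roles
  cases <- intersect(colnames(enr$z), names(roles)[roles == "case"])
  ctrls <- intersect(colnames(enr$z), names(roles)[roles == "control"])
  if (length(cases) < 1) stop("at least one case sample is required")
  if (length(ctrls) < 3) stop("at least 3 control samples are required")

  pos <- if (config$z_inclusive) enr$z >= config$z_threshold
         else enr$z > config$z_threshold
  pos_case <- pos[, cases, drop = FALSE]
  pos_ctrl <- pos[, ctrls, drop = FALSE]
  fc_case <- enr$fc[, cases, drop = FALSE]
  fc_ctrl <- enr$fc[, ctrls, drop = FALSE]

  case_positive_count <- rowSums(pos_case)
  control_positive_count <- rowSums(pos_ctrl)
  case_positive_fraction <- case_positive_count / length(cases)
  max_case_fc <- row_max(fc_case)
  max_control_fc <- row_max(fc_ctrl)

  fc_pos_case <- fc_case
  fc_pos_case[!pos_case] <- -Inf
  max_positive_case_fc <- row_max(fc_pos_case)

  fc_pos_ctrl <- fc_ctrl
  fc_pos_ctrl[!pos_ctrl] <- -Inf
  max_positive_control_fc <- row_max(fc_pos_ctrl)

  freq_ok <- case_positive_fraction >= config$case_frequency_min
  control_ok <- if (config$mode == "absolute") {
    control_positive_count < config$control_positive_max
  } else {
    control_positive_count / length(ctrls) < config$control_positive_max_fraction
  }
  strong_ok <- max_positive_case_fc >= config$strong_fc_min
  dominance_ref <- if (config$dominance_all_controls) max_control_fc
                   else max_positive_control_fc
  dominance_ok <- if (config$require_no_control_above_max_case) {
    dominance_ref <= max_case_fc
  } else rep(TRUE, nrow(enr$z))

  out <- data.frame(
    gene = rownames(enr$z),
    case_positive_count = case_positive_count,
    case_positive_fraction = case_positive_fraction,
    control_positive_count = control_positive_count,
    max_case_fc = max_case_fc,
    max_control_fc = max_control_fc,
    freq_ok = freq_ok, control_ok = control_ok,
    strong_ok = strong_ok, dominance_ok = dominance_ok,
    degenerate_sd = unname(enr$degenerate[rownames(enr$z)]),
    is_hit = freq_ok & control_ok & strong_ok & dominance_ok,
    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("hit_table", "data.frame")
  out
}

# enrichment restricted to the given case/control samples, with z recomputed
# against only those controls (fc and pct are per-sample, so unchanged)
enrichment_subset <- function(enr, cases, ctrls) {
  keep <- c(cases, ctrls)
  roles <- enr$roles[keep]
  fc <- enr$fc[, keep, drop = FALSE]
  z <- z_scores(fc, roles)
  structure(list(pct = enr$pct[, keep, drop = FALSE], fc = fc,
                 z = `attr<-`(z, "degenerate", NULL),
                 mock_mean_pct = enr$mock_mean_pct,
                 degenerate = attr(z, "degenerate"), roles = roles),
            class = "phip_enrichment")
}

#' Control-cohort downsampling analysis
#'
#' Quantifies how the apparent-hit count depends on control cohort size:
#' for each bin size, repeatedly samples that many controls without
#' replacement, recomputes every case's Z-scores against *only* the
#' subsampled controls (and each subsampled control against the others),
#' re-calls hits, and records the hit count. Small control cohorts
#' systematically inflate the apparent-hit count, because private control
#' reactivities that would disqualify a gene are simply not observed.
#'
#' @param counts a gene-level [phip_counts()] (cases, controls, mock-IPs).
#' @param bins integer vector of control cohort sizes (each >= 3 and at most
#'   the number of controls available).
#' @param reps replicates per bin (default 10).
#' @param config a [hit_call_config()].
#' @param seed seed for the control subsampling.
#' @return A list of class `downsample_result`: `per_rep`
#'   (`data.frame(bin, rep, n_hits)`), `summary` (`data.frame(bin,
#'   mean_hits)`), `bins`, `reps`, `seed`.
#' @export
downsample_controls <- function(counts, bins, reps = 10,
                                config = hit_call_config(), seed = 1) {
  stopifnot(inherits(counts, "phip_counts"))
  enr <- compute_enrichment(counts)
  roles <- counts$roles
  cases <- names(roles)[roles == "case"]
  ctrls <- names(roles)[roles == "control"]
  if (any(bins > length(ctrls))) stop("bin size exceeds the number of controls")
  if (any(bins < 3)) stop("bin sizes must be >= 3 (Z-scores need 3 controls)")
  if (reps < 1) stop("reps must be >= 1")

  subsets <- with_seed(seed, {
    lapply(bins, function(b) lapply(seq_len(reps), function(r) sample(ctrls, b)))
  })
  per_rep <- do.call(rbind, lapply(seq_along(bins), function(i) {
    n_hits <- vapply(seq_len(reps), function(r) {
      sub <- enrichment_subset(enr, cases, subsets[[i]][[r]])
      sum(call_hits(sub, config)$is_hit)
    }, integer(1))
    data.frame(bin = bins[i], rep = seq_len(reps), n_hits = n_hits)
  }))
  summary <- stats::aggregate(n_hits ~ bin, per_rep, mean)
  names(summary) <- c("bin", "mean_hits")
  structure(list(per_rep = per_rep, summary = summary,
                 bins = bins, reps = reps, seed = as.integer(seed)),
            class = "downsample_result")
}

#' @export
print.downsample_result <- function(x, ...) {
  cat("downsample_result (mean apparent hits per control bin):\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Write hit / downsampling tables as TSV
#'
#' @param x a `hit_table` or `downsample_result`.
#' @param path output TSV (for `downsample_result`, the per-replicate table;
#'   a `<path>_summary.tsv` companion holds the per-bin means).
#' @return `path`, invisibly.
#' @export
write_hits_tsv <- function(x, path) {
  if (inherits(x, "downsample_result")) {
    write_tsv(x$per_rep, path)
    write_tsv(x$summary, paste0(sub("\\.tsv$", "", path), "_summary.tsv"))
  } else {
    write_tsv(as.data.frame(x), path)
  }
  invisible(path)
}
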