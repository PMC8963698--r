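#' Percent-of-total normalization with pseudocount
#'
#' Adds a pseudocount of 0.5 reads to every gene, then converts each sample's
#' counts to percentages of its (pseudocounted) total. The pseudocount keeps
#' every percentage strictly positive, so downstream fold changes are always
#' defined. Applied identically to case, control and mock-IP samples.
#'
#' @param matrix a gene-level [phip_counts()].
#' @param pseudocount reads added to every gene (default 0.5).
#' @return Numeric matrix of percentages, genes x samples; each column sums
#'   to 100.
#' @export
normalize_pct <- function(matrix, pseudocount = 0.5) {
  stopifnot(inherits(matrix, "phip_counts"))
  if (matrix$feature_level != "gene") stop("normalize_pct expects gene-level counts")
  if (nrow(matrix$counts) == 0) stop("sample with zero genes")
  x <- matrix$counts + pseudocount
  sweep(x, 2, colSums(x), "/") * 100
}

#' Fold change over mock-IP
#'
#' For every gene, divides each serum sample's read percentage by the mean
#' percentage across the mock-IP (bead-only) samples. Computed for all
#' non-mock samples; the per-gene mock mean is attached as attribute
#' `mock_mean_pct`. The pseudocount in [normalize_pct()] guarantees a
#' strictly positive mock mean.
#'
#' @param pct percentage matrix from [normalize_pct()] (all samples).
#' @param roles named role vector covering the columns of `pct`.
#' @return Fold-change matrix, genes x non-mock samples, attribute
#'   `mock_mean_pct`.
#' @export
fold_change <- function(pct, roles) {
  roles <- check_roles(roles, colnames(pct))
  mock <- names(roles)[roles == "mock_ip"]
  if (length(mock) < 1) stop("at least one mock_ip sample is required")
  mock_mean <- rowMeans(pct[, mock, drop = FALSE])
  stopifnot(all(mock_mean > 0))  # guaranteed by the pseudocount
  keep <- setdiff(colnames(pct), mock)
  fc <- pct[, keep, drop = FALSE] / mock_mean
  attr(fc, "mock_mean_pct") <- mock_mean
  fc
}

# mean and sample (n-1) sd of each row of a matrix
row_mean_sd <- function(m) {
  n <- ncol(m)
  mu <- rowMeans(m)
  ss <- rowSums((m - mu)^2)
  list(mean = mu, sd = sqrt(ss / (n - 1)))
}

z_from <- function(x, mu, sdev) {
  z <- (x - mu) / sdev
  deg <- sdev == 0
  if (any(deg)) {
    xd <- x[deg]
    z[deg] <- ifelse(xd > mu[deg], Inf, 0)
  }
  z
}

#' Cohort Z-scores of fold changes
#'
#' Standardizes each gene's fold change against the control cohort's
#' fold-change distribution for that gene: case (and antibody-control)
#' samples are scored against all controls; each control is scored against
#' all *other* controls (leave-one-out), so no sample contributes to its own
#' reference distribution. The sample (n-1) standard deviation is used.
#'
#' Genes whose reference sd is zero for any scored sample are flagged
#' degenerate; their z is `Inf` where the fold change exceeds the reference
#' mean and 0 otherwise, so the hit caller can still evaluate them while
#' reporting the flag (a zero-variance gene usually signals a library design
#' problem rather than biology).
#'
#' @param fc fold-change matrix from [fold_change()].
#' @param roles named role vector covering the columns of `fc`.
#' @return Z-score matrix (same shape as `fc`), attribute `degenerate`:
#'   named logical per gene.
#' @export
z_scores <- function(fc, roles) {
  roles <- check_roles(roles, colnames(fc))
  ctrl <- names(roles)[roles == "control"]
  if (length(ctrl) < 3) stop("at least 3 control samples are required")
  others <- setdiff(colnames(fc), ctrl)

  z <- matrix(NA_real_, nrow(fc), ncol(fc), dimnames = dimnames(fc))
  cm <- fc[, ctrl, drop = FALSE]
  st <- row_mean_sd(cm)
  degenerate <- st$sd == 0
  for (s in others) z[, s] <- z_from(fc[, s], st$mean, st$sd)

  # leave-one-out for controls: mean/sd over the other n-1 controls
  n <- length(ctrl)
  S <- rowSums(cm)
  SS <- rowSums(cm^2)
  for (s in ctrl) {
    x <- cm[, s]
    mu <- (S - x) / (n - 1)
    var_loo <- pmax((SS - x^2 - (n - 1) * mu^2) / (n - 2), 0)
    sd_loo <- sqrt(var_loo)
    degenerate <- degenerate | sd_loo == 0
    z[, s] <- z_from(x, mu, sd_loo)
  }
  attr(z, "degenerate") <- stats::setNames(degenerate, rownames(fc))
  z
}

#' Full enrichment statistics for a gene-level count matrix
#'
#' Convenience wrapper chaining [normalize_pct()], [fold_change()] and
#' [z_scores()].
#'
#' @param matrix a gene-level [phip_counts()].
#' @return A list of class `phip_enrichment`: `pct` (all samples), `fc` and
#'   `z` (non-mock samples), `mock_mean_pct`, `degenerate`, `roles`.
#' @examples
#' lib <- build_random_library(20, 2, 30, seed = 1)
#' sim <- simulate_counts(simulation_config(n_genes = 20, peptides_per_gene = 2,
#'                                          seed = 2), lib)
#' enr <- compute_enrichment(collapse_to_gene(sim$counts, lib))
#' summary(as.vector(enr$z))
#' @export
compute_enrichment <- function(matrix) {
  pct <- normalize_pct(matrix)
  fc <- fold_change(pct, matrix$roles)
  z <- z_scores(fc, matrix$roles)
  structure(list(pct = pct, fc = `attr<-`(fc, "mock_mean_pct", NULL),
                 z = `attr<-`(z, "degenerate", NULL),
                 mock_mean_pct = attr(fc, "mock_mean_pct"),
                 degenerate = attr(z, "degenerate"),
                 roles = matrix$roles),
            class = "phip_enrichment")
}

#' @export
print.phip_enrichment <- function(x, ...) {
  cat(sprintf("phip_enrichment: %d genes x %d scored samples (max |z| = %.1f)\n",
              nrow(x$z), ncol(x$z), max(abs(x$z[is.finite(x$z)]))))
  invisible(x)
}

#' Write enrichment matrices as wide TSVs
#'
#' Writes `<prefix>_pct.tsv`, `<prefix>_fc.tsv` and `<prefix>_z.tsv`
#' (genes x samples, first column `gene`).
#'
#' @param enr a [compute_enrichment()] result.
#' @param prefix output path prefix.
#' @return The three paths, invisibly.
#' @export
write_enrichment_tsv <- function(enr, prefix) {
  stopifnot(inherits(enr, "phip_enrichment"))
  paths <- character(3)
  for (i in seq_along(c("pct", "fc", "z"))) {
    nm <- c("pct", "fc", "z")[i]
    m <- enr[[nm]]
    paths[i] <- paste0(prefix, "_", nm, ".tsv")
    write_tsv(data.frame(gene = rownames(m), m, check.names = FALSE), paths[i])
  }
  invisible(paths)
}
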