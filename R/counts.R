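#' Count matrix constructor
#'
#' Container for a feature (peptide or gene) by sample matrix of non-negative
#' integer read counts, with a role for every sample. At least one `mock_ip`
#' (bead-only) sample is required by downstream fold-change computation, so
#' its absence is reported there, not here.
#'
#' @param counts integer matrix, features x samples, with dimnames.
#' @param feature_level `"peptide"` or `"gene"`.
#' @param roles named character vector mapping every sample id to one of
#'   [sample_roles()].
#' @return A list of class `phip_counts` with elements `counts`,
#'   `feature_level`, `roles`.
#' @export
phip_counts <- function(counts, feature_level = c("peptide", "gene"), roles) {
  feature_level <- match.arg(feature_level)
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must have feature rownames and sample colnames")
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  storage.mode(counts) <- "double"  # keeps totals exact past .Machine$integer.max
  roles <- check_roles(roles, colnames(counts))
  structure(list(counts = counts, feature_level = feature_level, roles = roles),
            class = "phip_counts")
}

#' @export
print.phip_counts <- function(x, ...) {
  cat(sprintf("phip_counts: %d %ss x %d samples (%s)\n",
              nrow(x$counts), x$feature_level, ncol(x$counts),
              paste(sprintf("%s=%d", names(table(x$roles)), table(x$roles)),
                    collapse = ", ")))
  invisible(x)
}

samples_with_role <- function(x, role) names(x$roles)[x$roles == role]

#' Collapse a peptide-level count matrix to gene level
#'
#' Gene counts are the sums of all peptide counts mapping to that gene, so
#' per-sample totals are conserved exactly.
#'
#' @param matrix a peptide-level [phip_counts()].
#' @param library the [peptide_library()] defining the peptide-to-gene map.
#' @return A gene-level `phip_counts`.
#' @export
collapse_to_gene <- function(matrix, library) {
  stopifnot(inherits(matrix, "phip_counts"))
  if (matrix$feature_level != "peptide") {
    stop("collapse_to_gene expects a peptide-level matrix")
  }
  unknown <- setdiff(rownames(matrix$counts), library$peptide_id)
  if (length(unknown) > 0) {
    stop("peptide id(s) absent from library: ",
         paste(head(unknown, 5), collapse = ", "))
  }
  gene <- library$gene[match(rownames(matrix$counts), library$peptide_id)]
  collapsed <- rowsum(matrix$counts, group = gene)
  phip_counts(collapsed[sort(rownames(collapsed)), , drop = FALSE],
              feature_level = "gene", roles = matrix$roles)
}

#' Write / read a count matrix as TSV (+ roles TSV)
#'
#' The counts TSV has a first column `feature` then one column per sample;
#' roles live in a two-column TSV (`sample_id`, `role`).
#'
#' @param x a [phip_counts()].
#' @param counts_tsv,roles_tsv file paths.
#' @param feature_level feature level to assume when reading.
#' @return Path (writers, invisibly); a `phip_counts` (reader).
#' @export
write_counts_tsv <- function(x, counts_tsv, roles_tsv) {
  stopifnot(inherits(x, "phip_counts"))
  df <- data.frame(feature = rownames(x$counts), x$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, counts_tsv)
  write_tsv(data.frame(sample_id = names(x$roles), role = unname(x$roles)),
            roles_tsv)
  invisible(counts_tsv)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(counts_tsv, roles_tsv,
                            feature_level = c("peptide", "gene")) {
  feature_level <- match.arg(feature_level)
  df <- read_tsv(counts_tsv)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  rdf <- read_tsv(roles_tsv)
  roles <- stats::setNames(rdf$role, rdf$sample_id)
  phip_counts(m, feature_level = feature_level, roles = roles)
}
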