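#' Read-to-peptide matching policy
#'
#' Reads are translated in frame 1 (forward strand) and matched to library
#' peptides at the amino-acid level. `exact_prefix` requires the translated
#' read to equal a prefix of the peptide; `kmer` assigns a read to the
#' peptide sharing the most amino-acid k-mers, provided at least
#' `min_matching_kmers` match. Ties (several best peptides) drop the read,
#' which is tallied as ambiguous rather than double-counted.
#'
#' @param mode `"exact_prefix"` or `"kmer"`.
#' @param k k-mer size in amino acids (kmer mode; >= 5).
#' @param min_matching_kmers minimum shared k-mers for an assignment (>= 1).
#' @return A list of class `match_policy`.
#' @export
match_policy <- function(mode = c("exact_prefix", "kmer"), k = 7,
                         min_matching_kmers = 1) {
  mode <- match.arg(mode)
  if (mode == "kmer" && k < 5) stop("k must be >= 5 in kmer mode")
  if (min_matching_kmers < 1) stop("min_matching_kmers must be >= 1")
  structure(list(mode = mode, k = as.integer(k),
                 min_matching_kmers = as.integer(min_matching_kmers)),
            class = "match_policy")
}

# Validate FASTQ structure line by line so malformed records can be reported
# with their record index (Biostrings' parser error does not carry one).
validate_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4 != 0) {
    stop("malformed FASTQ: truncated record at record index ",
         length(lines) %/% 4 + 1)
  }
  n <- length(lines) / 4
  for (i in seq_len(n)) {
    b <- lines[(i - 1) * 4 + 1:4]
    if (!startsWith(b[1], "@") || !startsWith(b[3], "+") ||
        nchar(b[2]) != nchar(b[4])) {
      stop("malformed FASTQ record at record index ", i)
    }
  }
  invisible(n)
}

aa_kmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  unique(substring(seq, 1:(n - k + 1), k:n))
}

#' Count translated reads against a peptide library
#'
#' Each read is translated in frame 1 (trailing partial codons dropped) and
#' assigned to at most one peptide under the given [match_policy()]. Reads
#' matching no peptide (including any read containing a stop codon, which can
#' never equal a library peptide) are tallied as unassigned; reads matching
#' several peptides equally well are dropped and tallied as ambiguous. The
#' sample of origin is taken from the read name prefix before the first `:`
#' (the convention written by [simulate_reads()]).
#'
#' @param fastq path to a FASTQ file (optionally gzipped).
#' @param library a [peptide_library()].
#' @param policy a [match_policy()].
#' @param roles optional named role vector for the samples found in the file;
#'   defaults to `"control"` for every sample.
#' @return A peptide-level [phip_counts()] covering every library peptide
#'   (zero-filled), with an attached `read_log` attribute:
#'   `c(n_reads, n_assigned, n_unassigned, n_ambiguous)`.
#' @export
count_reads <- function(fastq, library, policy = match_policy(), roles = NULL) {
  validate_peptide_library(library)
  stopifnot(inherits(policy, "match_policy"))
  validate_fastq(fastq)
  reads <- Biostrings::readDNAStringSet(fastq, format = "fastq")

  sample_of <- sub(":.*$", "", names(reads))
  samples <- unique(sample_of)
  counts <- matrix(0, nrow = nrow(library), ncol = length(samples),
                   dimnames = list(library$peptide_id, samples))
  n_unassigned <- 0L
  n_ambiguous <- 0L

  if (length(reads) > 0) {
    trimmed <- Biostrings::subseq(reads, 1,
                                  (Biostrings::width(reads) %/% 3) * 3)
    aa <- as.character(Biostrings::translate(trimmed, if.fuzzy.codon = "X"))

    assigned <- rep(NA_integer_, length(aa))  # peptide row index per read
    if (policy$mode == "exact_prefix") {
      for (L in unique(nchar(aa))) {
        sel <- which(nchar(aa) == L)
        if (L == 0 || L > max(nchar(library$sequence))) next
        pref <- substr(library$sequence, 1, L)
        pref[nchar(library$sequence) < L] <- NA
        hits <- match(aa[sel], pref)
        # a prefix shared by several peptides is ambiguous: drop those reads
        dup_pref <- pref[!is.na(pref)][duplicated(pref[!is.na(pref)])]
        amb <- !is.na(hits) & aa[sel] %in% dup_pref
        n_ambiguous <- n_ambiguous + sum(amb)
        hits[amb] <- NA
        assigned[sel] <- hits
      }
    } else {
      kmer_index <- new.env(parent = emptyenv())
      for (i in seq_len(nrow(library))) {
        for (km in aa_kmers(library$sequence[i], policy$k)) {
          assign(km, c(if (exists(km, kmer_index)) get(km, kmer_index),
                       i), kmer_index)
        }
      }
      for (r in seq_along(aa)) {
        kms <- aa_kmers(aa[r], policy$k)
        cand <- unlist(lapply(kms, function(km)
          if (exists(km, kmer_index)) get(km, kmer_index)))
        if (is.null(cand)) next
        tab <- table(cand)
        best <- max(tab)
        if (best < policy$min_matching_kmers) next
        top <- as.integer(names(tab)[tab == best])
        if (length(top) > 1) n_ambiguous <- n_ambiguous + 1L
        else assigned[r] <- top
      }
    }
    n_unassigned <- sum(is.na(assigned)) - n_ambiguous
    ok <- !is.na(assigned)
    if (any(ok)) {
      tab <- table(factor(assigned[ok], levels = seq_len(nrow(library))),
                   factor(sample_of[ok], levels = samples))
      counts <- counts + unclass(tab)
    }
  }

  if (is.null(roles)) {
    roles <- stats::setNames(rep("control", length(samples)), samples)
  }
  out <- phip_counts(counts, feature_level = "peptide", roles = roles)
  attr(out, "read_log") <- c(n_reads = length(reads),
                             n_assigned = length(reads) - n_unassigned - n_ambiguous,
                             n_unassigned = n_unassigned,
                             n_ambiguous = n_ambiguous)
  out
}
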