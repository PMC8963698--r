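#' Peptide library constructor
#'
#' A peptide library describes the displayed peptide set: each row is one
#' peptide tile with its parent gene, amino-acid sequence, and 0-based tile
#' start within the parent protein. Genes are typically tiled by several
#' overlapping or adjacent peptides.
#'
#' @param peptide_id character, unique peptide identifiers.
#' @param gene character, parent gene symbol per peptide.
#' @param sequence character, amino-acid sequences (20 standard residues).
#' @param tile_start integer, 0-based offset of the tile in the parent
#'   protein; tiles of one gene must have distinct starts.
#' @return A `data.frame` of class `peptide_library` with columns
#'   `peptide_id`, `gene`, `sequence`, `tile_start`.
#' @export
peptide_library <- function(peptide_id, gene, sequence, tile_start) {
  lib <- data.frame(peptide_id = as.character(peptide_id),
                    gene = as.character(gene),
                    sequence = as.character(sequence),
                    tile_start = as.integer(tile_start),
                    stringsAsFactors = FALSE)
  validate_peptide_library(lib)
  class(lib) <- c("peptide_library", "data.frame")
  lib
}

AA_ALPHABET20 <- c("A","C","D","E","F","G","H","I","K","L",
                   "M","N","P","Q","R","S","T","V","W","Y")

validate_peptide_library <- function(lib) {
  stopifnot(is.data.frame(lib),
            all(c("peptide_id", "gene", "sequence", "tile_start") %in% names(lib)))
  if (nrow(lib) == 0) stop("peptide library is empty")
  if (anyDuplicated(lib$peptide_id)) stop("peptide_ids must be unique")
  if (any(nchar(lib$sequence) == 0)) stop("sequences must be non-empty")
  chars <- unique(unlist(strsplit(lib$sequence, "", fixed = TRUE)))
  bad <- setdiff(chars, AA_ALPHABET20)
  if (length(bad) > 0) {
    stop("non-standard amino acid(s) in sequences: ", paste(bad, collapse = ""))
  }
  dup_tiles <- any(vapply(split(lib$tile_start, lib$gene),
                          anyDuplicated, integer(1)) > 0)
  if (dup_tiles) stop("tiles of a gene must have distinct tile_start values")
  invisible(lib)
}

#' @export
print.peptide_library <- function(x, ...) {
  cat(sprintf("peptide_library: %d peptides, %d genes, tile length %s aa\n",
              nrow(x), length(unique(x$gene)),
              paste(range(nchar(x$sequence)), collapse = "-")))
  invisible(x)
}

#' Build a random tiled peptide library
#'
#' Generates `n_genes` synthetic genes, each tiled by `peptides_per_gene`
#' non-overlapping random peptides of `peptide_length` amino acids. Used as
#' the substrate for cohort simulation; sequences are uniform over the 20
#' standard residues, so tiles are unique with overwhelming probability at
#' conventional tile lengths.
#'
#' @param n_genes number of genes (>= 1).
#' @param peptides_per_gene tiles per gene (>= 1).
#' @param peptide_length tile length in amino acids (>= 1); 49 aa is the
#'   conventional tile size for proteome-wide display libraries.
#' @param seed integer seed; fixes the library completely.
#' @return A [peptide_library()].
#' @examples
#' lib <- build_random_library(10, 4, 49, seed = 1)
#' table(lib$gene)
#' @export
build_random_library <- function(n_genes, peptides_per_gene, peptide_length = 49,
                                 seed = 1) {
  if (any(c(n_genes, peptides_per_gene, peptide_length) < 1)) {
    stop("n_genes, peptides_per_gene and peptide_length must all be >= 1")
  }
  n_pep <- n_genes * peptides_per_gene
  seqs <- with_seed(seed, {
    mat <- matrix(sample(AA_ALPHABET20, n_pep * peptide_length, replace = TRUE),
                  nrow = n_pep)
    apply(mat, 1, paste0, collapse = "")
  })
  gene <- rep(sprintf("GENE%04d", seq_len(n_genes)), each = peptides_per_gene)
  tile <- rep(seq_len(peptides_per_gene) - 1L, times = n_genes)
  peptide_library(
    peptide_id = sprintf("%s_t%02d", gene, tile),
    gene = gene,
    sequence = seqs,
    tile_start = tile * peptide_length
  )
}

#' Write / read a peptide library as FASTA (+ gene map TSV)
#'
#' FASTA headers are `peptide_id|gene|tile_start`; the companion TSV has
#' columns `peptide_id`, `gene`.
#'
#' @param library a [peptide_library()].
#' @param fasta path of the FASTA file.
#' @param gene_map optional path of the peptide-to-gene map TSV; defaults to
#'   `fasta` with extension `_gene_map.tsv`.
#' @return `fasta`, invisibly (writer); a `peptide_library` (reader).
#' @export
write_library_fasta <- function(library, fasta, gene_map = NULL) {
  validate_peptide_library(library)
  aa <- Biostrings::AAStringSet(library$sequence)
  names(aa) <- sprintf("%s|%s|%d", library$peptide_id, library$gene,
                       library$tile_start)
  Biostrings::writeXStringSet(aa, fasta)
  if (is.null(gene_map)) {
    gene_map <- paste0(sub("\\.(fa|fasta)$", "", fasta), "_gene_map.tsv")
  }
  write_tsv(library[, c("peptide_id", "gene")], gene_map)
  invisible(fasta)
}

#' @rdname write_library_fasta
#' @export
read_library_fasta <- function(fasta) {
  aa <- Biostrings::readAAStringSet(fasta)
  parts <- strsplit(names(aa), "|", fixed = TRUE)
  if (any(lengths(parts) != 3)) {
    stop("FASTA headers must be 'peptide_id|gene|tile_start'")
  }
  peptide_library(
    peptide_id = vapply(parts, `[`, "", 1),
    gene = vapply(parts, `[`, "", 2),
    sequence = as.character(aa),
    tile_start = as.integer(vapply(parts, `[`, "", 3))
  )
}
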