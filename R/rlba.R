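#' Radioligand binding assay plate
#'
#' One row per well: sample wells (serum), blank wells (no serum) and
#' positive-control wells (commercial antibody), each with its
#' counts-per-million (cpm) scintillation readout.
#'
#' @param well_id unique well identifiers.
#' @param sample_id sample identifier (empty string allowed for blanks and
#'   positive controls).
#' @param role `"sample"`, `"blank"` or `"positive_control"`.
#' @param cpm non-negative scintillation counts per million.
#' @return A `data.frame` of class `rlba_plate`.
#' @export
rlba_plate <- function(well_id, sample_id, role, cpm) {
  plate <- data.frame(well_id = as.character(well_id),
                      sample_id = as.character(sample_id),
                      role = as.character(role),
                      cpm = as.numeric(cpm), stringsAsFactors = FALSE)
  if (anyDuplicated(plate$well_id)) stop("well_ids must be unique")
  bad <- setdiff(plate$role, c("sample", "blank", "positive_control"))
  if (length(bad) > 0) stop("unknown well role(s): ", paste(bad, collapse = ", "))
  if (sum(plate$role == "blank") < 1) stop("at least one blank well is required")
  if (sum(plate$role == "positive_control") < 1) {
    stop("at least one positive_control well is required")
  }
  if (any(plate$cpm < 0)) stop("cpm must be non-negative")
  class(plate) <- c("rlba_plate", "data.frame")
  plate
}

#' Antibody index from a radioligand binding assay plate
#'
#' Normalizes each sample's scintillation signal between the plate blanks
#' and the positive-control antibody:
#' `index = (sample - mean blank) / (positive control - mean blank)`,
#' so a blank-level sample scores 0 and a positive-control-level sample
#' scores 1. Replicate sample wells are averaged before the formula, as is
#' the positive control when several wells are present. No positivity
#' threshold is applied; antigen-specific cutoffs are set by the caller.
#'
#' @param plate an [rlba_plate()].
#' @return Named numeric vector, one antibody index per sample.
#' @examples
#' p <- rlba_plate(c("A1", "A2", "A3"), c("s1", "", ""),
#'                 c("sample", "blank", "positive_control"),
#'                 c(5000, 500, 5500))
#' antibody_index(p)  # (5000 - 500) / (5500 - 500) = 0.9
#' @export
antibody_index <- function(plate) {
  stopifnot(inherits(plate, "rlba_plate"))
  blank <- mean(plate$cpm[plate$role == "blank"])
  pos <- mean(plate$cpm[plate$role == "positive_control"])
  if (pos <= blank) {
    stop("assay failure: positive control cpm (", pos,
         ") does not exceed mean blank (", blank, ")")
  }
  s <- plate[plate$role == "sample", ]
  if (nrow(s) == 0) return(stats::setNames(numeric(0), character(0)))
  per_sample <- tapply(s$cpm, s$sample_id, mean)
  idx <- (per_sample - blank) / (pos - blank)
  stats::setNames(as.numeric(idx), names(per_sample))
}

#' Read / write RLBA plate TSVs
#'
#' Plate TSV columns: `well_id`, `sample_id`, `role`, `cpm`. The index
#' writer emits `sample_id`, `antibody_index`.
#'
#' @param path TSV path.
#' @param idx named index vector from [antibody_index()].
#' @return An `rlba_plate` (reader); `path` invisibly (writer).
#' @export
read_rlba_tsv <- function(path) {
  df <- read_tsv(path, colClasses = c(sample_id = "character"))
  df$sample_id[is.na(df$sample_id)] <- ""
  rlba_plate(df$well_id, df$sample_id, df$role, df$cpm)
}

#' @rdname read_rlba_tsv
#' @export
write_index_tsv <- function(idx, path) {
  write_tsv(data.frame(sample_id = names(idx), antibody_index = unname(idx)),
            path)
  invisible(path)
}
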