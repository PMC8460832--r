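#' Tissue group labels
#'
#' The five tissue groups used throughout the pipeline: benign prostate
#' control (`C`), non-aggressive primary tumor (`NAG`, Gleason 6), aggressive
#' primary tumor (`AG`, Gleason >= 7), castration-naive metastasis (`Nmet`)
#' and castration-resistant metastasis under androgen deprivation (`M`).
#'
#' @format Character vector of length 5.
#' @export
TISSUE_GROUPS <- c("C", "NAG", "AG", "Nmet", "M")

# log2 matrix out of either a plain matrix or a norm_matrix object
.as_log2 <- function(x) {
  if (inherits(x, "norm_matrix")) x$log2 else x
}

#' Round half away from zero
#'
#' Rounds with ties going away from zero (so 0.25 -> 0.3 at one decimal),
#' matching the usual reporting convention for percentages, rather than the
#' round-half-even rule of [round()].
#'
#' @param x Numeric vector.
#' @param digits Number of decimal digits (default 1).
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# per-biological-sample view of run-level metadata
.sample_info <- function(metadata) {
  info <- unique(metadata[, c("sample_id", "group", "cohort")])
  if (anyDuplicated(info$sample_id)) {
    bad <- info$sample_id[duplicated(info$sample_id)]
    stop("inconsistent group/cohort annotation for sample(s): ",
         paste(unique(bad), collapse = ", "))
  }
  rownames(info) <- NULL
  info
}

.stop_if_missing_group <- function(metadata, group) {
  if (!group %in% metadata$group) {
    stop("group '", group, "' has no samples in the metadata", call. = FALSE)
  }
}
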