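#' NPY surrogate peptide sequences
#'
#' Tryptic surrogate peptides of neuropeptide Y: the intact NPY(1-36) form,
#' the DPP4-cleaved NPY(3-36) form (two N-terminal residues removed) and the
#' shared C-terminal peptide used as a total-substrate reference.
#'
#' @format Character scalars.
#' @export
NPY_INTACT <- "YPSKPDNPGEDAPAEDMAR"

#' @rdname NPY_INTACT
#' @export
NPY_CLEAVED <- "SKPDNPGEDAPAEDMAR"

#' @rdname NPY_INTACT
#' @export
NPY_CTERM <- "HYINLITRQR"

#' Validate a protein abundance matrix
#'
#' Checks the container contract: a numeric matrix with unique protein row
#' names and unique run column names, all present values non-negative, and
#' at least one present value per protein. Missing values are `NA`
#' (an empty cell on disk), never zero: zeros count as measured.
#'
#' @param x Numeric matrix, proteins x runs.
#' @return `x` invisibly.
#' @export
validate_abundance <- function(x) {
  if (!is.matrix(x) || !is.numeric(x)) stop("abundance must be a numeric matrix")
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop("abundance matrix needs protein row names and run column names")
  }
  if (anyDuplicated(rownames(x))) {
    stop("duplicated protein id(s): ",
         paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", "))
  }
  if (anyDuplicated(colnames(x))) {
    stop("duplicated run id(s): ",
         paste(unique(colnames(x)[duplicated(colnames(x))]), collapse = ", "))
  }
  neg <- which(x < 0, arr.ind = TRUE)
  if (nrow(neg)) {
    stop("negative intensity at protein '", rownames(x)[neg[1, 1]],
         "', run '", colnames(x)[neg[1, 2]], "'")
  }
  empty <- rowSums(!is.na(x)) == 0
  if (any(empty)) {
    stop("protein(s) with no quantified value: ",
         paste(utils::head(rownames(x)[empty], 5), collapse = ", "))
  }
  invisible(x)
}

#' Read / write an abundance matrix as tab-separated text
#'
#' First column holds the protein id, the header row the run ids; an empty
#' cell is a missing value. Writing then reading reproduces the values to
#' decimal-text fidelity (15 significant digits).
#'
#' @param path File path.
#' @param x Validated abundance matrix.
#' @return `read_abundance()` returns the validated matrix;
#'   `write_abundance()` returns `path` invisibly.
#' @export
read_abundance <- function(path) {
  nf <- utils::count.fields(path, sep = "\t", quote = "", blank.lines.skip = FALSE)
  if (length(unique(nf)) != 1) {
    stop("ragged rows in '", path, "' (line ",
         which(nf != nf[1])[1], " has ", nf[which(nf != nf[1])[1]],
         " fields, expected ", nf[1], ")")
  }
  df <- utils::read.delim(path, check.names = FALSE, colClasses = "character",
                          na.strings = "")
  ids <- df[[1]]
  vals <- df[, -1, drop = FALSE]
  x <- as.matrix(vals)
  suppressWarnings(storage.mode(x) <- "double")
  bad <- which(is.na(x) & !is.na(as.matrix(vals)), arr.ind = TRUE)
  if (nrow(bad)) {
    stop("non-numeric value at protein '", ids[bad[1, 1]], "', run '",
         colnames(vals)[bad[1, 2]], "'")
  }
  rownames(x) <- ids
  validate_abundance(x)
  x
}

#' @rdname read_abundance
#' @export
write_abundance <- function(x, path) {
  validate_abundance(x)
  chr <- format(x, digits = 15, trim = TRUE, scientific = FALSE)
  chr[is.na(x)] <- NA  # format() would print the string "NA"
  df <- data.frame(protein_id = rownames(x), chr,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Validate run-level sample metadata
#'
#' Requires columns `run_id`, `sample_id`, `group`, `cohort`, `replicate`;
#' groups restricted to [TISSUE_GROUPS]; run ids unique. When an abundance
#' matrix is supplied, every matrix run id must appear exactly once.
#'
#' @param metadata Data frame of run annotations.
#' @param x Optional abundance matrix to join against.
#' @return `metadata` invisibly.
#' @export
validate_metadata <- function(metadata, x = NULL) {
  need <- c("run_id", "sample_id", "group", "cohort", "replicate")
  miss <- setdiff(need, names(metadata))
  if (length(miss)) stop("metadata lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(metadata$run_id)) {
    stop("duplicated run id(s) in metadata: ",
         paste(unique(metadata$run_id[duplicated(metadata$run_id)]), collapse = ", "))
  }
  badg <- setdiff(unique(metadata$group), TISSUE_GROUPS)
  if (length(badg)) {
    stop("unknown group label(s): ", paste(badg, collapse = ", "),
         " (allowed: ", paste(TISSUE_GROUPS, collapse = ", "), ")")
  }
  if (any(metadata$replicate < 1)) stop("replicate index must be >= 1")
  if (!is.null(x)) {
    unmatched <- setdiff(colnames(x), metadata$run_id)
    if (length(unmatched)) {
      stop("matrix run(s) absent from metadata: ",
           paste(utils::head(unmatched, 5), collapse = ", "))
    }
  }
  invisible(metadata)
}

#' Read / write run-level metadata as tab-separated text
#'
#' @param path File path.
#' @param metadata Validated metadata data frame.
#' @return `read_metadata()` returns the validated data frame.
#' @export
read_metadata <- function(path) {
  md <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  md$run_id <- as.character(md$run_id)
  md$sample_id <- as.character(md$sample_id)
  validate_metadata(md)
  md
}

#' @rdname read_metadata
#' @export
write_metadata <- function(metadata, path) {
  validate_metadata(metadata)
  utils::write.table(metadata, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Validate a peptide quantification table
#'
#' Columns `peptide_sequence` (upper-case amino acids), `protein_id`,
#' `run_id`, `intensity` (>= 0); each (peptide, run) pair unique.
#'
#' @param peptides Data frame.
#' @return `peptides`, invisibly validated.
#' @export
validate_peptides <- function(peptides) {
  need <- c("peptide_sequence", "protein_id", "run_id", "intensity")
  miss <- setdiff(need, names(peptides))
  if (length(miss)) stop("peptide table lacks column(s): ", paste(miss, collapse = ", "))
  bad <- !grepl("^[A-Z]+$", peptides$peptide_sequence)
  if (any(bad)) {
    stop("invalid peptide sequence(s): ",
         paste(utils::head(unique(peptides$peptide_sequence[bad]), 3), collapse = ", "))
  }
  if (any(!is.na(peptides$intensity) & peptides$intensity < 0)) {
    stop("negative peptide intensity")
  }
  key <- paste(peptides$peptide_sequence, peptides$run_id)
  if (anyDuplicated(key)) {
    stop("duplicated (peptide, run) pair(s): ",
         paste(utils::head(unique(key[duplicated(key)]), 3), collapse = "; "))
  }
  invisible(peptides)
}

#' Read / write a peptide table as tab-separated text
#'
#' @param path File path.
#' @param peptides Validated peptide table.
#' @export
read_peptides <- function(path) {
  p <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  p$run_id <- as.character(p$run_id)
  validate_peptides(p)
  p
}

#' @rdname read_peptides
#' @export
write_peptides <- function(peptides, path) {
  validate_peptides(peptides)
  utils::write.table(peptides, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Define a substrate cleavage assay
#'
#' A cleavage assay pairs the intact substrate surrogate peptide with its
#' protease-cleaved form (the intact sequence minus its first
#' `truncation_length` residues — two for a dipeptidyl peptidase such as
#' DPP4) and, optionally, a reference peptide measuring total substrate.
#'
#' @param enzyme_protein_id Protein id of the protease (e.g. `"DPP4"`).
#' @param intact_sequence,cleaved_sequence Upper-case amino-acid strings.
#' @param reference_sequence Optional reference (total-substrate) peptide.
#' @param truncation_length Number of N-terminal residues removed by the
#'   protease (default 2).
#' @return A validated object of class `cleavage_assay`.
#' @examples
#' cleavage_assay("DPP4", NPY_INTACT, NPY_CLEAVED, NPY_CTERM)
#' @export
cleavage_assay <- function(enzyme_protein_id, intact_sequence, cleaved_sequence,
                           reference_sequence = NULL, truncation_length = 2) {
  assay <- structure(list(
    enzyme_protein_id = enzyme_protein_id,
    intact_sequence = toupper(intact_sequence),
    cleaved_sequence = toupper(cleaved_sequence),
    reference_sequence = if (!is.null(reference_sequence)) toupper(reference_sequence),
    truncation_length = as.integer(truncation_length)
  ), class = "cleavage_assay")
  validate_assay(assay)
}

#' Validate a cleavage assay
#'
#' Confirms that the cleaved sequence equals the intact sequence with its
#' first `truncation_length` residues removed.
#'
#' @param assay A `cleavage_assay` object.
#' @return The normalized assay.
#' @export
validate_assay <- function(assay) {
  stopifnot(inherits(assay, "cleavage_assay"))
  for (f in c("intact_sequence", "cleaved_sequence")) {
    if (!nzchar(assay[[f]]) || !grepl("^[A-Z]+$", assay[[f]])) {
      stop(f, " must be a non-empty amino-acid string")
    }
  }
  tl <- assay$truncation_length
  if (tl < 1 || tl >= nchar(assay$intact_sequence)) {
    stop("truncation_length must be in [1, nchar(intact) - 1]")
  }
  expected <- substr(assay$intact_sequence, tl + 1, nchar(assay$intact_sequence))
  if (!identical(assay$cleaved_sequence, expected)) {
    stop("cleaved sequence does not match the truncated intact sequence; ",
         "expected suffix '", expected, "', got '", assay$cleaved_sequence, "'")
  }
  assay
}

#' Read / write a cleavage assay as JSON
#'
#' @param path File path.
#' @param assay A validated `cleavage_assay`.
#' @export
read_assay <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  cleavage_assay(raw$enzyme_protein_id, raw$intact_sequence,
                 raw$cleaved_sequence, raw$reference_sequence,
                 if (is.null(raw$truncation_length)) 2 else raw$truncation_length)
}

#' @rdname read_assay
#' @export
write_assay <- function(assay, path) {
  validate_assay(assay)
  jsonlite::write_json(unclass(assay), path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' The NPY / DPP4 cleavage assay
#'
#' Convenience constructor for the neuropeptide-Y assay: DPP4 removes the
#' N-terminal dipeptide of NPY(1-36), so the cleaved surrogate peptide is the
#' intact one minus its first two residues, and the shared C-terminal peptide
#' serves as the total-substrate reference.
#'
#' @return A `cleavage_assay`.
#' @export
npy_dpp4_assay <- function() {
  cleavage_assay("DPP4", NPY_INTACT, NPY_CLEAVED, NPY_CTERM, 2L)
}
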