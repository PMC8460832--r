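#' Cleaved/intact substrate peptide ratios per sample
#'
#' For each biological sample, computes the protease-activity readout
#' `ratio = cleaved / intact` from the assay's substrate peptides, after
#' averaging replicate runs on the linear scale (ratio of means, the default;
#' `average = "after"` takes the mean of per-run ratios instead). The ratio
#' is undefined (`NA`, never 0) when the intact peptide is missing or zero;
#' `log2_ratio` is defined only when both intensities are positive. Samples
#' with an undefined ratio are excluded from downstream statistics; the
#' exclusion count is attached as attribute `n_excluded`.
#'
#' @param peptides Peptide table (see [validate_peptides()]).
#' @param assay A validated [cleavage_assay()].
#' @param metadata Run-level metadata.
#' @param average `"before"` (ratio of replicate means, default) or
#'   `"after"` (mean of per-run ratios).
#' @return Data frame of class `activity_result`: `sample_id`, `group`,
#'   `intact`, `cleaved`, `reference`, `ratio`, `log2_ratio`.
#' @export
compute_ratios <- function(peptides, assay, metadata,
                           average = c("before", "after")) {
  average <- match.arg(average)
  validate_peptides(peptides)
  validate_assay(assay)
  validate_metadata(metadata)

  seqs <- c(intact = assay$intact_sequence, cleaved = assay$cleaved_sequence)
  if (!any(peptides$peptide_sequence %in% seqs)) {
    stop("assay peptides not found in the table (",
         paste(seqs, collapse = ", "), ")")
  }
  if (!is.null(assay$reference_sequence)) {
    seqs <- c(seqs, reference = assay$reference_sequence)
  }

  info <- .sample_info(metadata)
  per_sample <- function(seq) {
    rows <- peptides[peptides$peptide_sequence == seq, ]
    sm <- metadata$sample_id[match(rows$run_id, metadata$run_id)]
    v <- tapply(rows$intensity, factor(sm, levels = info$sample_id),
                mean, na.rm = TRUE)
    as.numeric(v)
  }

  intact <- per_sample(seqs[["intact"]])
  cleaved <- per_sample(seqs[["cleaved"]])
  reference <- if ("reference" %in% names(seqs)) per_sample(seqs[["reference"]])
               else rep(NA_real_, nrow(info))

  if (average == "before") {
    ratio <- ifelse(!is.na(intact) & intact > 0 & !is.na(cleaved),
                    cleaved / intact, NA_real_)
  } else {
    ratio <- vapply(info$sample_id, function(s) {
      runs <- metadata$run_id[metadata$sample_id == s]
      ri <- peptides$intensity[peptides$peptide_sequence == seqs[["intact"]] &
                                 peptides$run_id %in% runs]
      rc <- peptides$intensity[peptides$peptide_sequence == seqs[["cleaved"]] &
                                 peptides$run_id %in% runs]
      k <- min(length(ri), length(rc))
      ok <- seq_len(k)[!is.na(ri[seq_len(k)]) & !is.na(rc[seq_len(k)]) &
                         ri[seq_len(k)] > 0]
      if (!length(ok)) NA_real_ else mean(rc[ok] / ri[ok])
    }, numeric(1))
  }

  out <- data.frame(
    sample_id = info$sample_id, group = info$group,
    intact = intact, cleaved = cleaved, reference = reference,
    ratio = ratio,
    log2_ratio = ifelse(!is.na(ratio) & ratio > 0, log2(ratio), NA_real_),
    stringsAsFactors = FALSE
  )
  attr(out, "n_excluded") <- sum(is.na(out$ratio))
  attr(out, "enzyme") <- assay$enzyme_protein_id
  class(out) <- c("activity_result", "data.frame")
  out
}

#' Correlate protease abundance with substrate cleavage ratio
#'
#' Pearson correlation between the per-sample enzyme log2 abundance and the
#' log2 cleaved/intact ratio (or the linear-scale quantities with
#' `scale = "linear"`), with a two-sided p-value from the t transform of r.
#'
#' @param ratios Output of [compute_ratios()].
#' @param x Sample-level `norm_matrix` or log2 matrix containing the enzyme.
#' @param enzyme_id Protein id of the enzyme, default the assay's.
#' @param scale `"log"` (default) or `"linear"`.
#' @return List with `enzyme`, `pearson_r`, `p_value`, `n_samples`.
#' @export
correlate_with_enzyme <- function(ratios, x, enzyme_id = attr(ratios, "enzyme"),
                                  scale = c("log", "linear")) {
  scale <- match.arg(scale)
  m <- .as_log2(x)
  if (!enzyme_id %in% rownames(m)) {
    stop("enzyme '", enzyme_id, "' not in the abundance matrix")
  }
  enz <- m[enzyme_id, ][ratios$sample_id]
  if (scale == "log") {
    a <- enz; b <- ratios$log2_ratio
  } else {
    a <- 2^enz; b <- ratios$ratio
  }
  ok <- !is.na(a) & !is.na(b)
  n <- sum(ok)
  if (n < 3) stop("fewer than 3 samples with both enzyme abundance and ratio")
  r <- stats::cor(a[ok], b[ok])
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(enzyme = enzyme_id, pearson_r = r,
       p_value = 2 * stats::pt(abs(t), n - 2, lower.tail = FALSE),
       n_samples = n)
}

#' Compare cleavage ratios (and total substrate) between groups
#'
#' Student's t-test (pooled variance) of the per-sample log2 cleaved/intact
#' ratio between two tissue groups, plus the analogous comparison of the
#' log2 reference-peptide intensity (total substrate) when available.
#'
#' @param ratios Output of [compute_ratios()].
#' @param group_a,group_b Group labels (defaults AG, NAG).
#' @return List with elements `ratio` and `total` (the latter `NULL` without
#'   a reference peptide), each holding `mean_log2_a`, `mean_log2_b`,
#'   `difference`, `t_statistic`, `p_value`, `n_a`, `n_b`.
#' @export
compare_ratio_groups <- function(ratios, group_a = "AG", group_b = "NAG") {
  cmp <- function(v) {
    a <- v[ratios$group == group_a]; a <- a[!is.na(a)]
    b <- v[ratios$group == group_b]; b <- b[!is.na(b)]
    if (length(a) < 2 || length(b) < 2) {
      stop("need >= 2 defined values per group (", group_a, ": ", length(a),
           ", ", group_b, ": ", length(b), ")")
    }
    if (stats::sd(c(a - mean(a), b - mean(b))) == 0) {
      tt <- list(statistic = c(t = 0), p.value = 1)
    } else {
      tt <- stats::t.test(a, b, var.equal = TRUE)
    }
    list(mean_log2_a = mean(a), mean_log2_b = mean(b),
         difference = mean(a) - mean(b),
         t_statistic = unname(tt$statistic), p_value = tt$p.value,
         n_a = length(a), n_b = length(b))
  }
  total <- NULL
  if (any(!is.na(ratios$reference))) {
    lref <- ifelse(!is.na(ratios$reference) & ratios$reference > 0,
                   log2(ratios$reference), NA_real_)
    total <- cmp(lref)
  }
  list(ratio = cmp(ratios$log2_ratio), total = total,
       group_a = group_a, group_b = group_b)
}
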