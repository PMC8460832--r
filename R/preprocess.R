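#' Normalize an abundance matrix to a reference run
#'
#' Every run is rescaled so that, over the proteins it shares with the
#' reference run, the median of the scaled abundance ratios to the reference
#' is exactly 1 (i.e. every run is assumed to have a median relative
#' expression of 1 against the reference); the output holds the log2 of the
#' scaled ratios. The reference run's own log2 ratios are therefore all 0.
#' Proteins not quantified in the reference have no ratio and stay missing in
#' every run; zero intensities are treated as measured but yield no finite
#' log2 ratio and become missing in the output.
#'
#' @param x Abundance matrix (proteins x runs, linear scale, `NA` missing).
#' @param reference Column (run) id of the reference sample, default
#'   `"AG1"`.
#' @return An object of class `norm_matrix`: a list with `log2` (matrix of
#'   log2 ratios), `scale_factors` (named per-run multipliers) and
#'   `reference`.
#' @examples
#' x <- matrix(c(2, 4, 8, 4, 8, 16), 3, dimnames = list(paste0("P", 1:3),
#'             c("AG1", "S2")))
#' normalize_to_reference(x, "AG1")$log2
#' @export
normalize_to_reference <- function(x, reference = "AG1") {
  validate_abundance(x)
  if (!reference %in% colnames(x)) {
    stop("reference run '", reference, "' not found in the matrix")
  }
  ref <- x[, reference]
  usable_ref <- !is.na(ref) & ref > 0
  ratios <- x / ref
  ratios[!usable_ref, ] <- NA

  sf <- vapply(colnames(x), function(s) {
    r <- ratios[, s]
    r <- r[!is.na(r) & r > 0]
    if (!length(r)) {
      stop("run '", s, "' shares no positive quantified protein with the reference")
    }
    1 / stats::median(r)
  }, numeric(1))

  scaled <- sweep(ratios, 2, sf, `*`)
  scaled[!is.na(scaled) & scaled <= 0] <- NA  # zero intensity: no finite log2
  structure(list(log2 = log2(scaled), scale_factors = sf, reference = reference),
            class = "norm_matrix")
}

#' @export
print.norm_matrix <- function(x, ...) {
  cat("Normalized log2-ratio matrix: ", nrow(x$log2), " proteins x ",
      ncol(x$log2), " columns (reference: ", x$reference, ")\n", sep = "")
  invisible(x)
}

#' @export
as.matrix.norm_matrix <- function(x, ...) x$log2

#' Collapse replicate runs to biological samples
#'
#' Replicate runs of the same biological sample are averaged on the log2
#' scale (mean of the present values; missing only if missing in every
#' replicate). Columns of the result are biological sample ids in order of
#' first appearance in the metadata.
#'
#' @param norm A `norm_matrix` from [normalize_to_reference()] (or a plain
#'   log2 matrix).
#' @param metadata Run-level metadata; every column of `norm` must appear.
#' @return A `norm_matrix` with one column per biological sample.
#' @export
average_replicates <- function(norm, metadata) {
  m <- .as_log2(norm)
  validate_metadata(metadata)
  idx <- match(colnames(m), metadata$run_id)
  if (anyNA(idx)) {
    stop("run(s) absent from metadata: ",
         paste(utils::head(colnames(m)[is.na(idx)], 5), collapse = ", "))
  }
  samples <- unique(metadata$sample_id[idx])
  out <- matrix(NA_real_, nrow(m), length(samples),
                dimnames = list(rownames(m), samples))
  for (s in samples) {
    cols <- m[, idx %in% which(metadata$sample_id == s), drop = FALSE]
    v <- rowMeans(cols, na.rm = TRUE)
    v[!is.finite(v)] <- NA_real_
    out[, s] <- v
  }
  ref_sample <- if (inherits(norm, "norm_matrix") &&
                    norm$reference %in% metadata$run_id) {
    metadata$sample_id[metadata$run_id == norm$reference]
  }
  structure(list(log2 = out, scale_factors = NULL,
                 reference = if (is.null(ref_sample)) NA_character_ else ref_sample),
            class = "norm_matrix")
}

#' Correlation between replicate runs
#'
#' Pearson correlation of log2 values over co-quantified proteins, computed
#' per replicate pair, summarized as the mean across pairs. Used as a
#' reproducibility score of the quantification workflow.
#'
#' @param norm `norm_matrix` or log2 matrix at run level.
#' @param metadata Run-level metadata.
#' @param min_shared Minimum number of co-present proteins per pair
#'   (default 3); pairs below it, or without variation (such as the
#'   reference run, whose normalized ratios are identically 0), get `NA`
#'   and are dropped from the mean.
#' @return List with `mean_correlation` and a data frame `pairs`
#'   (`sample_id`, `r`, `n_shared`).
#' @export
replicate_correlation <- function(norm, metadata, min_shared = 3) {
  m <- .as_log2(norm)
  validate_metadata(metadata)
  md <- metadata[metadata$run_id %in% colnames(m), ]
  reps <- split(md$run_id, md$sample_id)
  reps <- reps[vapply(reps, length, 1L) >= 2]
  if (!length(reps)) stop("no replicated samples in the matrix")
  pairs <- do.call(rbind, lapply(names(reps), function(s) {
    runs <- reps[[s]]
    cmb <- utils::combn(runs, 2)
    do.call(rbind, lapply(seq_len(ncol(cmb)), function(j) {
      a <- m[, cmb[1, j]]; b <- m[, cmb[2, j]]
      ok <- !is.na(a) & !is.na(b)
      # degenerate pairs (no variation, e.g. the reference run whose ratios
      # are all 0) have no defined correlation and drop out of the mean
      r <- if (sum(ok) >= min_shared &&
               stats::sd(a[ok]) > 0 && stats::sd(b[ok]) > 0) {
        stats::cor(a[ok], b[ok])
      } else NA_real_
      data.frame(sample_id = s, r = r, n_shared = sum(ok))
    }))
  }))
  list(mean_correlation = mean(pairs$r, na.rm = TRUE), pairs = pairs)
}

# linear-scale CV of a replicate pair, vectorized over proteins:
# sd of two values is |a - b| / sqrt(2)
.pair_cv <- function(a, b) (abs(a - b) / sqrt(2)) / ((a + b) / 2)

#' Reliability filter from biological vs technical coefficients of variation
#'
#' For every protein, the biological CV (SD / |mean| across replicate-averaged
#' biological samples) is compared against the technical CV estimated from
#' duplicate runs. The technical CV is computed per tissue group as the
#' root-mean-square over that group's replicate pairs of the pair-level CV,
#' and the maximum across groups is used. A protein is retained when its
#' biological CV is at least this maximum technical CV — variation across
#' patients no smaller than the measurement noise. Proteins quantified in
#' fewer than `min_samples` biological samples yield no biological CV and
#' are dropped as non-computable; proteins with no computable technical CV
#' (never seen in a complete replicate pair) are retained for lack of
#' evidence against them.
#'
#' By default CVs are taken on the linear scale (`2^log2` of the normalized
#' ratios), the standard definition; `cv_scale = "log2"` computes SD/|mean|
#' on the log2 ratios directly (unstable when the mean ratio is near 0, kept
#' as an alternative reading).
#'
#' @param norm Run-level `norm_matrix` from [normalize_to_reference()].
#' @param metadata Run-level metadata.
#' @param cv_scale `"linear"` (default) or `"log2"`.
#' @param tech_aggregate How a group's replicate-pair CVs are pooled:
#'   `"rms"` (default, pools pair variances) or `"mean"`.
#' @param min_samples Minimum biological samples for a biological CV
#'   (default 3).
#' @return Data frame with one row per protein: `protein_id`,
#'   `biological_cv`, one `tech_cv_<group>` column per group with replicate
#'   pairs, `max_technical_cv`, `n_samples`, `computable`, `retained`.
#' @export
cv_filter <- function(norm, metadata, cv_scale = c("linear", "log2"),
                      tech_aggregate = c("rms", "mean"), min_samples = 3) {
  cv_scale <- match.arg(cv_scale)
  tech_aggregate <- match.arg(tech_aggregate)
  m_run <- .as_log2(norm)
  validate_metadata(metadata)

  to_scale <- function(v) if (cv_scale == "linear") 2^v else v

  # biological CV on replicate-averaged samples
  m_sam <- .as_log2(average_replicates(norm, metadata))
  vs <- to_scale(m_sam)
  n_obs <- rowSums(!is.na(vs))
  mu <- rowMeans(vs, na.rm = TRUE)
  sd_ <- apply(vs, 1, stats::sd, na.rm = TRUE)
  bio <- ifelse(n_obs >= min_samples & abs(mu) > 0, sd_ / abs(mu), NA_real_)

  # technical CV per group from duplicate runs
  md <- metadata[metadata$run_id %in% colnames(m_run), ]
  reps <- split(md, md$sample_id)
  reps <- reps[vapply(reps, nrow, 1L) >= 2]
  tech <- list()
  for (g in unique(md$group)) {
    pair_cvs <- NULL
    for (s in names(reps)) {
      rd <- reps[[s]]
      if (rd$group[1] != g) next
      runs <- rd$run_id[1:2]
      a <- to_scale(m_run[, runs[1]]); b <- to_scale(m_run[, runs[2]])
      cvp <- ifelse(!is.na(a) & !is.na(b) & (a + b) > 0, .pair_cv(a, b), NA_real_)
      pair_cvs <- cbind(pair_cvs, cvp)
    }
    if (is.null(pair_cvs)) next
    tech[[g]] <- apply(pair_cvs, 1, function(v) {
      v <- v[!is.na(v)]
      if (!length(v)) return(NA_real_)
      if (tech_aggregate == "rms") sqrt(mean(v^2)) else mean(v)
    })
  }
  if (!length(tech)) stop("no replicate pairs available in any group")

  tech_mat <- do.call(cbind, tech)
  max_tech <- apply(tech_mat, 1, function(v) {
    if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE)
  })

  out <- data.frame(protein_id = rownames(m_run), biological_cv = bio,
                    stringsAsFactors = FALSE)
  for (g in names(tech)) out[[paste0("tech_cv_", g)]] <- tech[[g]]
  out$max_technical_cv <- max_tech
  out$n_samples <- n_obs
  out$computable <- !is.na(bio)
  out$retained <- out$computable & (is.na(max_tech) | bio >= max_tech)
  rownames(out) <- NULL
  out
}

#' Apply a CV-filter result to a matrix
#'
#' @param norm `norm_matrix` or matrix.
#' @param records Output of [cv_filter()].
#' @return The input restricted to retained proteins (same class).
#' @export
apply_cv_filter <- function(norm, records) {
  keep <- records$protein_id[records$retained]
  if (inherits(norm, "norm_matrix")) {
    norm$log2 <- norm$log2[rownames(norm$log2) %in% keep, , drop = FALSE]
    norm
  } else {
    norm[rownames(norm) %in% keep, , drop = FALSE]
  }
}
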