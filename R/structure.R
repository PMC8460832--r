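# row variances with NA handling (sample variance, n - 1 denominator)
.row_vars <- function(m) {
  n <- rowSums(!is.na(m))
  mu <- rowMeans(m, na.rm = TRUE)
  ss <- rowSums((m - mu)^2, na.rm = TRUE)
  ifelse(n >= 2, ss / (n - 1), NA_real_)
}

#' Select the most variant proteins
#'
#' The `k` proteins with the largest sample variance (n - 1 denominator) of
#' log2 values across columns; ties broken deterministically by protein id.
#' Proteins with fewer than two present values have no variance and are
#' never selected.
#'
#' @param x `norm_matrix` or log2 matrix.
#' @param k Number of proteins, default 500.
#' @return Character vector of selected protein ids.
#' @export
select_top_variance <- function(x, k = 500) {
  m <- .as_log2(x)
  v <- .row_vars(m)
  ok <- which(!is.na(v))
  if (k > length(ok)) {
    stop("k = ", k, " exceeds the ", length(ok),
         " proteins with a computable variance")
  }
  ord <- ok[order(-v[ok], rownames(m)[ok])]
  rownames(m)[ord[seq_len(k)]]
}

#' Z-score matrix rows
#'
#' Per-protein standardization: (x - row mean) / row SD, with missing values
#' excluded from the statistics and left missing. Rows with zero or
#' undefined SD are dropped with a warning.
#'
#' @param x `norm_matrix` or log2 matrix.
#' @return Z-scored matrix (each row has mean 0, sample SD 1).
#' @export
zscore_rows <- function(x) {
  m <- .as_log2(x)
  v <- .row_vars(m)
  bad <- is.na(v) | v == 0
  if (any(bad)) {
    warning(sum(bad), " constant or unquantifiable row(s) excluded from Z-scoring")
    m <- m[!bad, , drop = FALSE]
    v <- v[!bad]
  }
  (m - rowMeans(m, na.rm = TRUE)) / sqrt(v)
}

#' Hierarchical clustering of proteins and samples
#'
#' Ward-linkage agglomerative clustering on Euclidean distances
#' (`hclust(method = "ward.D2")`, the Ward criterion on a Euclidean distance
#' matrix), applied to the protein rows and, optionally, the sample columns
#' of a Z-scored matrix. Missing Z-values are imputed as 0 — the row mean —
#' for the distance computation only. Flat protein clusters are obtained by
#' cutting the protein tree at `n_clusters`.
#'
#' @param z Z-scored matrix from [zscore_rows()].
#' @param n_clusters Number of flat protein clusters, default 4.
#' @param cluster_samples Also cluster the sample columns (default `TRUE`).
#' @return List of class `clustering_result` with `protein_hclust`,
#'   `sample_hclust` (or `NULL`), `protein_clusters` (named integer vector)
#'   and `n_clusters`.
#' @export
hierarchical_structure <- function(z, n_clusters = 4, cluster_samples = TRUE) {
  z <- .as_log2(z)
  if (nrow(z) < 2) stop("need at least 2 rows to cluster")
  if (n_clusters > nrow(z)) stop("n_clusters exceeds the number of proteins")
  z0 <- z
  z0[is.na(z0)] <- 0
  ph <- stats::hclust(stats::dist(z0, method = "euclidean"), method = "ward.D2")
  sh <- if (cluster_samples && ncol(z0) >= 2) {
    stats::hclust(stats::dist(t(z0), method = "euclidean"), method = "ward.D2")
  }
  structure(list(protein_hclust = ph, sample_hclust = sh,
                 protein_clusters = stats::cutree(ph, k = n_clusters),
                 n_clusters = n_clusters),
            class = "clustering_result")
}

#' Principal component analysis of samples
#'
#' Samples are treated as observations and proteins as variables; the
#' decomposition is the SVD of the column-centered sample-by-protein matrix
#' ([stats::prcomp()], no scaling). Missing values are imputed as 0 before
#' the decomposition, which on a Z-scored input is the protein mean.
#'
#' @param x Matrix (proteins x samples), typically Z-scored.
#' @return List with `scores` (samples x components), `explained_variance`
#'   (component variances, non-increasing, summing to the total variance of
#'   the centered matrix), `prop_variance`, and the `prcomp` fit.
#' @export
pca_samples <- function(x) {
  m <- .as_log2(x)
  m[is.na(m)] <- 0
  sm <- t(m)
  if (all(apply(sm, 2, stats::var) == 0)) stop("matrix is constant; PCA undefined")
  fit <- stats::prcomp(sm, center = TRUE, scale. = FALSE)
  ev <- fit$sdev^2
  list(scores = fit$x, explained_variance = ev, prop_variance = ev / sum(ev),
       fit = fit)
}
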