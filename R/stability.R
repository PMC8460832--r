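#' Rank p-values, smallest first
#'
#' Ascending ranks with average-rank ties: the smallest p-value gets rank 1.
#'
#' @param p Finite numeric vector.
#' @return Numeric ranks.
#' @examples
#' rank_by_pvalue(c(0.2, 0.1, 0.3))  # 2 1 3
#' @export
rank_by_pvalue <- function(p) {
  if (any(!is.finite(p))) stop("p-values must be finite")
  rank(p, ties.method = "average")
}

# rank with undefined p-values placed jointly last at their average rank,
# so that ranks always sum to m(m+1)/2
.rank_na_last <- function(p) {
  r <- rank(p, ties.method = "average", na.last = "keep")
  k <- sum(!is.na(p))
  m <- length(p)
  r[is.na(r)] <- (k + 1 + m) / 2
  r
}

#' Permutation rank-stability test for subtype-associated proteins
#'
#' Assesses how robust each protein's differential-expression rank between
#' two tissue groups is against group-label shuffling. The observed
#' AG-vs-NAG (by default) per-protein t-test p-values are ranked (rank 1 =
#' smallest). Then, for each of `n_permutations` iterations, the group
#' labels are shuffled uniformly over the combined samples (group sizes
#' preserved), p-values are recomputed and re-ranked. A protein is called
#' stable when its observed rank lies below the `percentile`-th percentile
#' of its own permuted rank distribution — it ranks better than it ever
#' plausibly does under a broken group structure.
#'
#' Only proteins testable in the observed analysis enter the ranking (m =
#' number of tested proteins). Within a permutation, proteins that become
#' untestable are assigned the average of the remaining worst ranks, so each
#' iteration's ranks sum to m(m+1)/2 exactly.
#'
#' @param x Sample-level `norm_matrix` or log2 matrix.
#' @param metadata Run-level metadata.
#' @param group_a,group_b Group labels (defaults AG and NAG).
#' @param n_permutations Number of label shuffles, default 500.
#' @param percentile Stability percentile of the permuted rank distribution,
#'   default 5.
#' @param seed Mandatory integer seed; fixed seed gives identical results.
#' @param var_equal Passed to the t-test core.
#' @param jackknife If `TRUE`, also computes leave-one-sample-out observed
#'   average ranks as a resampling diagnostic of the unpermuted analysis.
#' @return List of class `stability_result`:
#'   \describe{
#'     \item{results}{data frame `protein_id`, `observed_p`,
#'       `observed_rank`, `mean_permuted_rank`, `rank_threshold`
#'       (the percentile cut), `stable`.}
#'     \item{permuted_ranks}{m x B matrix of per-iteration ranks.}
#'     \item{curve}{average observed and permuted rank over the top-n
#'       proteins (n = 1..m), ordered by observed rank — the data behind the
#'       rank-stability plot.}
#'     \item{jackknife_rank}{per-protein mean leave-one-out rank, or `NULL`.}
#'     \item{n_permutations, percentile, seed}{the parameters used.}
#'   }
#' @export
permutation_stability <- function(x, metadata, group_a = "AG", group_b = "NAG",
                                  n_permutations = 500, percentile = 5,
                                  seed, var_equal = TRUE, jackknife = FALSE) {
  if (missing(seed)) stop("a seed is required for the permutation test")
  if (n_permutations < 1) stop("n_permutations must be >= 1")
  m <- .as_log2(x)
  info <- .sample_info(metadata)
  .stop_if_missing_group(info, group_a)
  .stop_if_missing_group(info, group_b)
  cols_a <- intersect(colnames(m), info$sample_id[info$group == group_a])
  cols_b <- intersect(colnames(m), info$sample_id[info$group == group_b])
  if (length(cols_a) < 2 || length(cols_b) < 2) {
    stop("each group needs at least 2 samples in the matrix")
  }
  na_ <- length(cols_a)
  comb <- m[, c(cols_a, cols_b), drop = FALSE]
  n <- ncol(comb)

  obs <- .row_t_core(comb[, seq_len(na_), drop = FALSE],
                     comb[, (na_ + 1):n, drop = FALSE], var_equal = var_equal)
  tested <- obs$tested
  if (sum(tested) < 2) stop("fewer than 2 testable proteins")
  comb <- comb[tested, , drop = FALSE]
  p_obs <- obs$p_value[tested]
  observed_rank <- rank_by_pvalue(p_obs)
  mm <- nrow(comb)

  perm <- withr::with_seed(seed, {
    pr <- matrix(NA_real_, mm, n_permutations)
    for (b in seq_len(n_permutations)) {
      idx <- sample.int(n)
      pb <- .row_t_core(comb[, idx[seq_len(na_)], drop = FALSE],
                        comb[, idx[(na_ + 1):n], drop = FALSE],
                        var_equal = var_equal)$p_value
      pr[, b] <- .rank_na_last(pb)
    }
    pr
  })

  threshold <- apply(perm, 1, stats::quantile, probs = percentile / 100,
                     names = FALSE)
  results <- data.frame(
    protein_id = rownames(comb),
    observed_p = p_obs,
    observed_rank = observed_rank,
    mean_permuted_rank = rowMeans(perm),
    rank_threshold = threshold,
    stable = observed_rank < threshold,
    stringsAsFactors = FALSE
  )

  ord <- order(results$observed_rank)
  curve <- data.frame(
    n_proteins = seq_len(mm),
    avg_observed_rank = cumsum(sort(results$observed_rank)) / seq_len(mm),
    avg_permuted_rank = cumsum(results$mean_permuted_rank[ord]) / seq_len(mm)
  )

  jk <- NULL
  if (jackknife) {
    jk_ranks <- matrix(NA_real_, mm, n)
    for (i in seq_len(n)) {
      keep <- setdiff(seq_len(n), i)
      ia <- intersect(keep, seq_len(na_)); ib <- setdiff(keep, seq_len(na_))
      pj <- .row_t_core(comb[, ia, drop = FALSE], comb[, ib, drop = FALSE],
                        var_equal = var_equal)$p_value
      jk_ranks[, i] <- .rank_na_last(pj)
    }
    jk <- rowMeans(jk_ranks)
  }

  structure(list(results = results, permuted_ranks = perm, curve = curve,
                 jackknife_rank = jk, n_permutations = n_permutations,
                 percentile = percentile, seed = seed,
                 group_a = group_a, group_b = group_b),
            class = "stability_result")
}

#' @export
print.stability_result <- function(x, ...) {
  cat("Permutation rank-stability test (", x$group_a, " vs ", x$group_b,
      "): ", nrow(x$results), " proteins, B = ", x$n_permutations,
      ", ", sum(x$results$stable), " stable at the ", x$percentile,
      "th percentile\n", sep = "")
  invisible(x)
}
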