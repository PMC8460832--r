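# Vectorized two-sample t-test over matrix rows with NA handling.
# Returns a data frame; rows with < 2 present values in either group are
# flagged tested = FALSE with NA statistics.
.row_t_core <- function(xa, xb, var_equal = TRUE) {
  na <- rowSums(!is.na(xa)); nb <- rowSums(!is.na(xb))
  ma <- rowMeans(xa, na.rm = TRUE); mb <- rowMeans(xb, na.rm = TRUE)
  ssa <- rowSums((xa - ma)^2, na.rm = TRUE)
  ssb <- rowSums((xb - mb)^2, na.rm = TRUE)
  tested <- na >= 2 & nb >= 2
  diff <- ma - mb
  if (var_equal) {
    df <- na + nb - 2
    sp2 <- (ssa + ssb) / df
    se <- sqrt(sp2 * (1 / na + 1 / nb))
  } else {
    va <- ssa / (na - 1); vb <- ssb / (nb - 1)
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      (va^2 / (na^2 * (na - 1)) + vb^2 / (nb^2 * (nb - 1)))
  }
  t <- diff / se
  # zero pooled variance: identical values give t = 0, p = 1; a nonzero
  # difference with zero variance is infinitely significant
  degenerate <- tested & !is.na(se) & se == 0
  t[degenerate] <- ifelse(diff[degenerate] == 0, 0, sign(diff[degenerate]) * Inf)
  p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  p[degenerate & diff == 0] <- 1
  t[!tested] <- NA_real_; p[!tested] <- NA_real_; df[!tested] <- NA_real_
  ma[na == 0] <- NA_real_; mb[nb == 0] <- NA_real_
  data.frame(n_a = na, n_b = nb, mean_log2_a = ma, mean_log2_b = mb,
             t_statistic = t, df = df, p_value = p, tested = tested)
}

#' Row-wise two-sample t-test between tissue groups
#'
#' Two-sided Student's t-test (pooled variance by default, Welch optional)
#' on log2 values, computed for every protein between two groups of
#' biological samples. Proteins with fewer than two present values in either
#' group are flagged `tested = FALSE` and carry `NA` statistics; they are
#' excluded from any subsequent multiple-testing correction.
#'
#' @param x Sample-level `norm_matrix` (or log2 matrix) whose columns are
#'   biological sample ids.
#' @param metadata Run-level metadata (collapsed internally per sample).
#' @param group_a,group_b Tissue group labels; `group_a` may also be a vector
#'   of labels pooled into one side of the contrast (e.g. all tumor groups).
#' @param var_equal Pooled-variance Student's t (default `TRUE`); `FALSE`
#'   gives Welch's test.
#' @return Data frame with `protein_id`, group sizes, group means,
#'   `log2_fold_change` (mean A - mean B), `fold_change`
#'   (`2^log2_fold_change`), `t_statistic`, `df`, `p_value`, `tested`.
#' @export
row_t_test <- function(x, metadata, group_a, group_b, var_equal = TRUE) {
  m <- .as_log2(x)
  info <- .sample_info(metadata)
  for (g in c(group_a, group_b)) .stop_if_missing_group(info, g)
  cols_a <- intersect(colnames(m), info$sample_id[info$group %in% group_a])
  cols_b <- intersect(colnames(m), info$sample_id[info$group %in% group_b])
  if (!length(cols_a) || !length(cols_b)) {
    stop("contrast group(s) have no columns in the matrix")
  }
  res <- .row_t_core(m[, cols_a, drop = FALSE], m[, cols_b, drop = FALSE],
                     var_equal = var_equal)
  res$log2_fold_change <- res$mean_log2_a - res$mean_log2_b
  res$fold_change <- 2^res$log2_fold_change
  cbind(protein_id = rownames(m), res,
        group_a = paste(group_a, collapse = "+"),
        group_b = paste(group_b, collapse = "+"),
        stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment. `NA` entries (untested proteins)
#' are excluded before adjustment — they do not count towards the number of
#' tests — and stay `NA` in the output.
#'
#' @param p Numeric vector of p-values in \[0, 1\] (`NA` allowed).
#' @return Adjusted p-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(p))
  out[ok] <- stats::p.adjust(p[ok], method = "BH")
  out
}

#' Classify differential-expression results under a threshold regime
#'
#' Two regimes mirror the two contrasts of the analysis:
#' \describe{
#'   \item{`tumor_vs_control`}{significant when BH-adjusted p < 0.01 and
#'     fold change >= 2 (up) or <= 1/2 (down); used for the pooled
#'     tumors-versus-control volcano.}
#'   \item{`subtype`}{significant when raw p < 0.05 and fold change >= 1.5
#'     (up) or <= 1/1.5 (down); the relaxed regime for the small AG-vs-NAG
#'     comparison.}
#' }
#' Both fold-change cuts are inclusive (>= / <=), the p-value cuts strict.
#' BH adjustment is applied within the tested set of the given results.
#'
#' @param results Output of [row_t_test()].
#' @param regime `"tumor_vs_control"` or `"subtype"`.
#' @return `results` with added columns `adjusted_p`, `call`
#'   (`"up"`, `"down"`, `"not_significant"`, `NA` if untested) and `regime`.
#' @export
classify_differential <- function(results,
                                  regime = c("tumor_vs_control", "subtype")) {
  regime <- match.arg(regime)
  results$adjusted_p <- bh_adjust(results$p_value)
  fc <- results$fold_change
  if (regime == "tumor_vs_control") {
    sig <- results$adjusted_p < 0.01
    up <- sig & fc >= 2
    down <- sig & fc <= 1 / 2
  } else {
    sig <- results$p_value < 0.05
    up <- sig & fc >= 1.5
    down <- sig & fc <= 1 / 1.5
  }
  call <- ifelse(up, "up", ifelse(down, "down", "not_significant"))
  call[!results$tested] <- NA_character_
  results$call <- call
  results$regime <- regime
  results
}

#' Differential expression for a named contrast
#'
#' Convenience wrapper running [row_t_test()] plus [classify_differential()]
#' for the two contrasts of the analysis: pooled tumors (NAG, AG, Nmet, M)
#' versus benign controls under the strict regime, or AG versus NAG under
#' the subtype regime.
#'
#' @param x Sample-level `norm_matrix` or log2 matrix.
#' @param metadata Run-level metadata.
#' @param contrast `"tumor_vs_control"` or `"ag_vs_nag"`.
#' @param var_equal Passed to [row_t_test()].
#' @return Classified results data frame (see [classify_differential()]).
#' @export
differential_expression <- function(x, metadata,
                                    contrast = c("tumor_vs_control", "ag_vs_nag"),
                                    var_equal = TRUE) {
  contrast <- match.arg(contrast)
  info <- .sample_info(metadata)
  if (contrast == "tumor_vs_control") {
    tumor <- intersect(c("NAG", "AG", "Nmet", "M"), unique(info$group))
    if (!length(tumor)) stop("no tumor groups in the metadata")
    res <- row_t_test(x, metadata, tumor, "C", var_equal = var_equal)
    classify_differential(res, "tumor_vs_control")
  } else {
    res <- row_t_test(x, metadata, "AG", "NAG", var_equal = var_equal)
    classify_differential(res, "subtype")
  }
}
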