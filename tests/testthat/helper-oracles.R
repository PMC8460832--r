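`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent brute-force oracles used to cross-check the implementation.
# These deliberately use naive loops / closed forms, never the package's own
# code paths.

# Benjamini-Hochberg step-up: adj_i = min_{j : p_j >= p_i over sorted order}
# of m * p_(j) / j, capped at 1.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[i] <- min(1, min(m * ps[i:m] / (i:m)))
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# From-scratch CV filter on a run-level log2 matrix + metadata, mirroring the
# documented rule with plain loops.
oracle_cv_filter <- function(log2_run, metadata, cv_scale = "linear",
                             min_samples = 3) {
  tr <- function(v) if (cv_scale == "linear") 2^v else v
  samples <- unique(metadata$sample_id)
  # replicate-averaged sample matrix (log2 mean of present values)
  sm <- sapply(samples, function(s) {
    runs <- metadata$run_id[metadata$sample_id == s]
    apply(log2_run[, runs, drop = FALSE], 1, function(v) {
      v <- v[!is.na(v)]
      if (length(v)) mean(v) else NA_real_
    })
  })
  retained <- logical(nrow(log2_run))
  for (i in seq_len(nrow(log2_run))) {
    v <- tr(sm[i, ])
    v <- v[!is.na(v)]
    if (length(v) < min_samples || mean(v) == 0) {
      retained[i] <- FALSE
      next
    }
    bio <- sd(v) / abs(mean(v))
    group_cvs <- c()
    for (g in unique(metadata$group)) {
      pair_sq <- c()
      for (s in samples) {
        runs <- metadata$run_id[metadata$sample_id == s & metadata$group == g]
        if (length(runs) < 2) next
        a <- tr(log2_run[i, runs[1]]); b <- tr(log2_run[i, runs[2]])
        if (is.na(a) || is.na(b) || (a + b) <= 0) next
        pair_sq <- c(pair_sq, (sd(c(a, b)) / mean(c(a, b)))^2)
      }
      if (length(pair_sq)) group_cvs <- c(group_cvs, sqrt(mean(pair_sq)))
    }
    retained[i] <- if (length(group_cvs)) bio >= max(group_cvs) else TRUE
  }
  rownames(log2_run)[retained]
}

# mean silhouette width of a 2-D embedding under given labels
mean_silhouette <- function(coords, labels) {
  d <- as.matrix(dist(coords))
  n <- nrow(coords)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    a <- mean(d[i, own & seq_len(n) != i])
    b <- min(vapply(unique(labels[!own]), function(g) {
      mean(d[i, labels == g])
    }, numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# small random abundance fixture with replicate runs and missingness
random_fixture <- function(seed, n_proteins = 30, miss = 0.08) {
  set.seed(seed)
  cfg <- sim_config(
    group_sizes = c(C = 3L, NAG = 3L, AG = 3L, Nmet = 3L, M = 3L),
    n_proteins = n_proteins, n_replicated_samples = 8,
    protease_panel = character(0),
    miss_intercept = qlogis(miss) + 0.5 * 20, miss_slope = -0.5,
    seed = seed
  )
  simulate_cohort(cfg)
}
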