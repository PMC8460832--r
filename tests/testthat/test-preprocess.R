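toy_matrix <- function(vals, proteins = NULL, runs = NULL) {
  m <- as.matrix(vals)
  dimnames(m) <- list(proteins %||% paste0("P", seq_len(nrow(m))),
                      runs %||% paste0("S", seq_len(ncol(m))))
  m
}

test_that("normalization removes pure per-sample scaling", {
  # every sample equal to the reference: factors 1, ratios 0
  x <- toy_matrix(cbind(c(2, 4, 8), c(2, 4, 8), c(2, 4, 8)),
                  runs = c("AG1", "S2", "S3"))
  n <- normalize_to_reference(x, "AG1")
  expect_equal(unname(n$scale_factors), rep(1, 3))
  expect_true(all(n$log2 == 0))

  # a sample at exactly 2x the reference: factor 1/2, ratios 0
  x2 <- x; x2[, "S2"] <- 2 * x2[, "S2"]
  n2 <- normalize_to_reference(x2, "AG1")
  expect_equal(unname(n2$scale_factors[["S2"]]), 0.5)
  expect_equal(unname(n2$log2[, "S2"]), rep(0, 3))
})

test_that("a 3-protein toy reproduces the hand-computed log2 ratios", {
  # ratios to reference 1, 2, 4 -> median 2 -> factor 1/2 -> log2 -1, 0, 1
  x <- toy_matrix(cbind(c(10, 10, 10), c(10, 20, 40)), runs = c("REF", "S"))
  n <- normalize_to_reference(x, "REF")
  expect_equal(unname(n$scale_factors[["S"]]), 0.5)
  expect_equal(unname(n$log2[, "S"]), c(-1, 0, 1))
})

test_that("normalization is scale-invariant and idempotent", {
  co <- random_fixture(3)
  x <- co$abundance
  n1 <- normalize_to_reference(x, "AG1")
  # multiplying any sample's raw column by a positive constant changes nothing
  x2 <- x
  x2[, "NAG2"] <- x2[, "NAG2"] * 37.5
  n2 <- normalize_to_reference(x2, "AG1")
  expect_lt(max(abs(n1$log2 - n2$log2), na.rm = TRUE), 1e-10)
  # the reference run's own median log2 ratio is exactly 0
  expect_identical(median(n1$log2[, "AG1"], na.rm = TRUE), 0)
  # renormalizing the already-normalized matrix gives factors 1
  # (restricted to proteins with a ratio, i.e. quantified in the reference)
  lin <- 2^n1$log2[rowSums(!is.na(n1$log2)) > 0, ]
  renorm <- normalize_to_reference(lin, "AG1")
  expect_lt(max(abs(renorm$scale_factors - 1)), 1e-12)
  # missing stays missing (including proteins unquantified in the reference)
  mask <- is.na(x)
  mask[is.na(x[, "AG1"]), ] <- TRUE
  expect_true(all(is.na(n1$log2[mask])))
})

test_that("normalization needs shared proteins with the reference", {
  x <- toy_matrix(cbind(c(1, NA), c(NA, 5)), runs = c("REF", "S1"))
  expect_error(normalize_to_reference(x, "REF"), "S1")
  expect_error(normalize_to_reference(x, "nope"), "not found")
})

test_that("replicate averaging is a missing-tolerant mean", {
  x <- toy_matrix(cbind(c(1, 2, NA), c(3, NA, NA), c(5, 6, 7)),
                  runs = c("A1", "A1_rep2", "B1"))
  md <- data.frame(run_id = c("A1", "A1_rep2", "B1"),
                   sample_id = c("A1", "A1", "B1"),
                   group = c("AG", "AG", "NAG"), cohort = "discovery",
                   replicate = c(1, 2, 1))
  avg <- average_replicates(structure(list(log2 = x, reference = "A1"),
                                      class = "norm_matrix"), md)
  expect_equal(unname(avg$log2[, "A1"]), c(2, 2, NA))  # mean, single, all-NA
  expect_equal(unname(avg$log2[, "B1"]), c(5, 6, 7))   # singleton unchanged
})

test_that("replicate correlation is 1 for identical runs and tracks noise", {
  co <- random_fixture(4)
  norm <- normalize_to_reference(co$abundance, "AG1")
  rc <- replicate_correlation(norm, co$metadata)
  expect_true(rc$mean_correlation > 0 && rc$mean_correlation <= 1)

  # identical replicates: correlation exactly 1
  x <- toy_matrix(cbind(c(1, 2, 3, 4), c(1, 2, 3, 4)), runs = c("A1", "A1_rep2"))
  md <- data.frame(run_id = colnames(x), sample_id = "A1", group = "AG",
                   cohort = "discovery", replicate = 1:2)
  rc1 <- replicate_correlation(structure(list(log2 = x, reference = "A1"),
                                         class = "norm_matrix"), md)
  expect_equal(rc1$mean_correlation, 1)

  # correlation decreases monotonically with the technical CV
  rs <- vapply(c(0.05, 0.3, 1.0), function(cv) {
    cfg <- sim_config(group_sizes = c(C = 4L, NAG = 4L, AG = 4L,
                                      Nmet = 4L, M = 4L),
                      n_proteins = 400, n_replicated_samples = 10,
                      protease_panel = character(0), technical_cv = cv,
                      miss_intercept = -20, seed = 42)
    co <- simulate_cohort(cfg)
    replicate_correlation(normalize_to_reference(co$abundance, "AG1"),
                          co$metadata)$mean_correlation
  }, numeric(1))
  expect_true(all(diff(rs) < 0))

  md0 <- md; md0$sample_id <- c("A1", "A2"); md0$replicate <- c(1, 1)
  expect_error(replicate_correlation(
    structure(list(log2 = x, reference = "A1"), class = "norm_matrix"), md0),
    "no replicated samples")
})

test_that("CV filter keeps boundary cases by the >= rule", {
  # constant everywhere: biological CV 0, technical CV 0, retained (0 >= 0)
  x <- toy_matrix(matrix(3, 2, 6),
                  runs = c("A1", "A1_rep2", "B1", "B1_rep2", "C1", "D1"))
  md <- data.frame(
    run_id = colnames(x), sample_id = c("A1", "A1", "B1", "B1", "C1", "D1"),
    group = c("AG", "AG", "NAG", "NAG", "C", "M"), cohort = "discovery",
    replicate = c(1, 2, 1, 2, 1, 1))
  norm <- structure(list(log2 = x, reference = "A1"), class = "norm_matrix")
  rec <- cv_filter(norm, md)
  expect_equal(rec$biological_cv, c(0, 0))
  expect_equal(rec$max_technical_cv, c(0, 0))
  expect_true(all(rec$retained))

  # constant across samples but noisy within replicates: removed
  x2 <- x
  x2[1, "A1"] <- 3.4; x2[1, "A1_rep2"] <- 2.6
  rec2 <- cv_filter(structure(list(log2 = x2, reference = "A1"),
                              class = "norm_matrix"), md)
  expect_gt(rec2$max_technical_cv[1], rec2$biological_cv[1])
  expect_false(rec2$retained[1])
  expect_true(rec2$retained[2])
})

test_that("CV filter matches the brute-force oracle on random fixtures", {
  for (seed in 1:6) {
    co <- random_fixture(seed, n_proteins = 50)
    norm <- normalize_to_reference(co$abundance, "AG1")
    for (scale in c("linear", "log2")) {
      rec <- cv_filter(norm, co$metadata, cv_scale = scale)
      kept <- rec$protein_id[rec$retained]
      expect_identical(sort(kept),
                       sort(oracle_cv_filter(norm$log2, co$metadata, scale)))
    }
  }
})

test_that("proteins quantified in too few samples are non-computable", {
  co <- random_fixture(7, n_proteins = 20)
  x <- co$abundance
  x[1, ] <- NA
  x[1, c("AG1", "NAG1")] <- c(100, 200)  # 2 samples < min_samples
  norm <- normalize_to_reference(x, "AG1")
  rec <- cv_filter(norm, co$metadata)
  expect_false(rec$computable[1])
  expect_false(rec$retained[1])
  filt <- apply_cv_filter(norm, rec)
  expect_false(rec$protein_id[1] %in% rownames(filt$log2))
})
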