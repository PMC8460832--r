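make_two_group <- function(vals_a, vals_b, n_prot = 1) {
  m <- matrix(c(vals_a, vals_b), n_prot, length(vals_a) + length(vals_b),
              byrow = TRUE)
  dimnames(m) <- list(paste0("P", seq_len(n_prot)),
                      c(paste0("AG", seq_along(vals_a)),
                        paste0("NAG", seq_along(vals_b))))
  md <- data.frame(run_id = colnames(m), sample_id = colnames(m),
                   group = rep(c("AG", "NAG"), c(length(vals_a), length(vals_b))),
                   cohort = "discovery", replicate = 1)
  list(m = m, md = md)
}

test_that("the pooled t-test reproduces the closed-form textbook case", {
  tg <- make_two_group(c(1, 2, 3), c(4, 5, 6))
  de <- row_t_test(tg$m, tg$md, "AG", "NAG")
  # pooled sp2 = 1, se = sqrt(2/3), t = -3/se
  expect_equal(de$t_statistic, -3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(de$df, 4)
  expect_equal(de$p_value, 2 * pt(-3 / sqrt(2 / 3), 4), tolerance = 1e-12)
  expect_equal(de$log2_fold_change, -3)
  expect_equal(de$fold_change, 2^-3)
})

test_that("identical groups give t = 0 and p = 1, even at zero variance", {
  tg <- make_two_group(c(1, 2, 3), c(1, 2, 3))
  de <- row_t_test(tg$m, tg$md, "AG", "NAG")
  expect_equal(de$t_statistic, 0)
  expect_equal(de$p_value, 1)
  tg0 <- make_two_group(c(5, 5), c(5, 5))
  de0 <- row_t_test(tg0$m, tg0$md, "AG", "NAG")
  expect_equal(de0$t_statistic, 0)
  expect_equal(de0$p_value, 1)
})

test_that("row-wise t matches stats::t.test over random matrices with NAs", {
  set.seed(31)
  for (rep in 1:3) {
    m <- matrix(rnorm(40 * 14), 40, 14,
                dimnames = list(sprintf("P%02d", 1:40),
                                c(paste0("AG", 1:6), paste0("NAG", 1:8))))
    m[sample(length(m), 60)] <- NA
    md <- data.frame(run_id = colnames(m), sample_id = colnames(m),
                     group = rep(c("AG", "NAG"), c(6, 8)),
                     cohort = "discovery", replicate = 1)
    for (ve in c(TRUE, FALSE)) {
      de <- row_t_test(m, md, "AG", "NAG", var_equal = ve)
      for (i in seq_len(nrow(m))) {
        a <- m[i, 1:6]; b <- m[i, 7:14]
        if (sum(!is.na(a)) < 2 || sum(!is.na(b)) < 2) {
          expect_false(de$tested[i])
          expect_true(is.na(de$p_value[i]))
        } else {
          ref <- t.test(a, b, var.equal = ve)
          expect_equal(de$t_statistic[i], unname(ref$statistic),
                       tolerance = 1e-10)
          expect_equal(de$p_value[i], ref$p.value, tolerance = 1e-10)
          expect_equal(de$df[i], unname(ref$parameter), tolerance = 1e-10)
        }
      }
    }
  }
})

test_that("swapping the groups negates the fold change and keeps p", {
  co <- random_fixture(9, n_proteins = 40)
  norm <- average_replicates(normalize_to_reference(co$abundance, "AG1"),
                             co$metadata)
  ab <- row_t_test(norm, co$metadata, "AG", "NAG")
  ba <- row_t_test(norm, co$metadata, "NAG", "AG")
  expect_equal(ab$log2_fold_change, -ba$log2_fold_change)
  expect_equal(ab$p_value, ba$p_value)
})

test_that("an all-missing group is flagged and kept out of the adjustment", {
  m <- rbind(P1 = c(1, 2, 3, NA, NA, NA),
             P2 = c(2, 2.5, 3.5, 9, 9.5, 8))
  colnames(m) <- c(paste0("AG", 1:3), paste0("NAG", 1:3))
  md <- data.frame(run_id = colnames(m), sample_id = colnames(m),
                   group = rep(c("AG", "NAG"), each = 3),
                   cohort = "discovery", replicate = 1)
  de <- row_t_test(m, md, "AG", "NAG")
  expect_false(de$tested[1])
  expect_true(de$tested[2])
  cls <- classify_differential(de, "subtype")
  expect_true(is.na(cls$adjusted_p[1]))
  expect_true(is.na(cls$call[1]))
  # m = 1 for the single tested protein: adjusted equals raw
  expect_equal(cls$adjusted_p[2], de$p_value[2])
})

test_that("BH adjustment equals the step-up oracle", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(17)
  for (i in 1:50) {
    p <- runif(sample(1:200, 1))
    expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-12)
  }
  # monotone in the raw p-values
  p <- runif(100)
  adj <- bh_adjust(p)
  expect_true(all(diff(adj[order(p)]) >= 0))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("classification thresholds sit exactly on the stated boundaries", {
  res <- data.frame(protein_id = c("a", "b", "c", "d"),
                    p_value = c(0.001, 0.05, 0.003, 0.04),
                    fold_change = c(2, 1.6, 1 / 2, 1.49),
                    tested = TRUE)
  res$log2_fold_change <- log2(res$fold_change)
  # tumor regime: FC >= 2 inclusive, adjusted p < 0.01 strict
  cls <- classify_differential(res, "tumor_vs_control")
  expect_equal(cls$call[1], ifelse(cls$adjusted_p[1] < 0.01, "up",
                                   "not_significant"))
  # direct boundary probes with controlled adjusted p
  one <- data.frame(protein_id = "x", p_value = 0.009, fold_change = 2,
                    log2_fold_change = 1, tested = TRUE)
  expect_equal(classify_differential(one, "tumor_vs_control")$call, "up")
  one$fold_change <- 0.5; one$log2_fold_change <- -1
  expect_equal(classify_differential(one, "tumor_vs_control")$call, "down")
  # subtype regime: p < 0.05 strict, so p = 0.05 exactly is not significant
  two <- data.frame(protein_id = "y", p_value = 0.05, fold_change = 3,
                    log2_fold_change = log2(3), tested = TRUE)
  expect_equal(classify_differential(two, "subtype")$call, "not_significant")
  two$p_value <- 0.049
  expect_equal(classify_differential(two, "subtype")$call, "up")
  expect_error(classify_differential(two, "bogus"))
})

test_that("planted >= 2-fold proteins are recalled with controlled FDR", {
  planted <- data.frame(
    protein_id = sprintf("PROT%05d", 1:50),
    group = "C",
    log2_shift = rep(c(2, -2), 25)
  )
  cfg <- sim_config(n_proteins = 1500, protease_panel = character(0),
                    planted_effects = planted, biological_log2_sd = 0.35,
                    miss_intercept = -20, seed = 61)
  co <- simulate_cohort(cfg)
  norm <- average_replicates(normalize_to_reference(co$abundance, "AG1"),
                             co$metadata)
  de <- differential_expression(norm, co$metadata, "tumor_vs_control")
  called <- de$protein_id[de$call %in% c("up", "down") & de$tested]
  recall <- mean(planted$protein_id %in% called)
  fdr <- if (length(called)) mean(!called %in% planted$protein_id) else 0
  expect_gte(recall, 0.95)
  expect_lte(fdr, 0.05)
  # planted direction: shifted up in C means tumors-vs-control calls it down
  down_ids <- de$protein_id[de$call == "down" & de$tested]
  expect_true(all(planted$protein_id[planted$log2_shift > 0] %in% down_ids))
})
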