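test_that("TMM factors: identical and rescaled columns are library-size invariant", {
  v <- matrix(rep(c(5, 10, 20, 40, 80), 4), 5, 4,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:4)))
  e <- expression_matrix(v, "mRNA", "raw")
  expect_equal(unname(tmm_factors(e)), rep(1, 4))

  v2 <- v; v2[, 2] <- 2 * v[, 1]
  f <- tmm_factors(expression_matrix(v2, "mRNA", "raw"))
  expect_equal(unname(f), rep(1, 4))
})

test_that("TMM factors match a literal transcription of the definition", {
  for (seed in 1:5) {
    counts <- rand_counts(20, 4, seed = seed, lambda = 50)
    # heterogeneous depths + a few zeros so trimming and exclusion engage
    counts[, 2] <- counts[, 2] * 3L
    counts[cbind(c(1, 5, 9), c(1, 2, 3))] <- 0L
    e <- expression_matrix(counts + 0, "mRNA", "raw")
    expect_equal(unname(tmm_factors(e)), tmm_oracle(counts),
                 tolerance = 1e-8)
  }
})

test_that("TMM factors have geometric mean 1 and resist global rescaling", {
  counts <- rand_counts(50, 6, seed = 11, lambda = 200)
  e <- expression_matrix(counts + 0, "mRNA", "raw")
  f <- tmm_factors(e)
  expect_equal(exp(mean(log(f))), 1, tolerance = 1e-12)
  e2 <- e; e2$values <- e$values * 37
  expect_equal(tmm_factors(e2), f, tolerance = 1e-12)

  bad <- e; bad$values[, 2] <- 0
  expect_error(tmm_factors(bad), "all-zero")
  one <- e; one$values <- one$values[, 1, drop = FALSE]
  expect_error(tmm_factors(one), "2 samples")
  expect_error(tmm_factors(log_transform(e)), "raw")
})

test_that("normalization equalizes depth-driven differences", {
  counts <- rand_counts(100, 4, seed = 3, lambda = 100)
  counts[, 3] <- counts[, 3] * 4L
  e <- expression_matrix(counts + 0, "mRNA", "raw")
  nrm <- normalize_tmm(e)
  expect_identical(nrm$scale, "normalized")
  cs <- colSums(nrm$values)
  expect_lt(max(cs) / min(cs), 1.1)
})

test_that("log transform maps counts as stated and inverts exactly", {
  v <- matrix(c(0, 3, 7, 15), 2, 2,
              dimnames = list(c("a", "b"), c("s1", "s2")))
  e <- expression_matrix(v, "mRNA", "raw")
  le <- log_transform(e, 2, 1)
  expect_equal(le$values, matrix(c(0, 2, 3, 4), 2, 2,
                                 dimnames = dimnames(v)))
  expect_identical(le$scale, "log")
  back <- inverse_log_transform(le)
  expect_equal(back$values, v, tolerance = 1e-12)

  neg <- expression_matrix(v - 1, "mRNA", "log")
  expect_error(log_transform(neg), "nonnegative|already")
})

test_that("paired t statistics match the textbook oracle and BH the step-up oracle", {
  n_pat <- 10
  d <- mk_design(n_pat)
  set.seed(5)
  v <- matrix(rnorm(100 * 2 * n_pat), 100, 2 * n_pat,
              dimnames = list(paste0("g", 1:100), d$sample_id))
  tab <- paired_ttest(mk_log_expr(v), d)
  for (i in c(1, 17, 100)) {
    tt <- t.test(v[i, d$status == 1], v[i, d$status == 0], paired = TRUE)
    expect_equal(tab$t_stat[i], unname(tt$statistic), tolerance = 1e-12)
    expect_equal(tab$p_value[i], tt$p.value, tolerance = 1e-12)
  }
  expect_equal(tab$fdr, bh_stepup_oracle(tab$p_value), tolerance = 1e-12)
})

test_that("BH adjustment equals brute-force step-up on random p-vectors", {
  set.seed(8)
  for (i in 1:200) {
    p <- runif(sample(3:80, 1))^sample(1:3, 1)
    expect_equal(stats::p.adjust(p, "BH"), bh_stepup_oracle(p),
                 tolerance = 1e-14)
  }
})

test_that("label swap negates t and preserves p; zero-variance rows are flagged", {
  n_pat <- 8
  d <- mk_design(n_pat)
  set.seed(6)
  v <- matrix(rnorm(20 * 16), 20, 16, dimnames = list(paste0("g", 1:20),
                                                      d$sample_id))
  # feature with constant nonzero difference: sd(d) == 0
  v[1, d$status == 1] <- 5
  v[1, d$status == 0] <- 4
  swapped <- paired_design(d$sample_id, d$patient_id, 1L - d$status)
  t1 <- paired_ttest(mk_log_expr(v), d)
  t2 <- paired_ttest(mk_log_expr(v), swapped)
  expect_equal(t2$t_stat[-1], -t1$t_stat[-1], tolerance = 1e-12)
  expect_equal(t2$p_value, t1$p_value, tolerance = 1e-12)
  expect_true(t1$degenerate[1])
  expect_equal(t1$p_value[1], 1)
  expect_false(t1$passes[1])
  expect_false("g1" %in% select_significant(t1, 1))
})

test_that("p-values are uniform under the global null", {
  n_pat <- 10
  d <- mk_design(n_pat)
  set.seed(7)
  v <- matrix(rnorm(5000 * 2 * n_pat), 5000, 2 * n_pat,
              dimnames = list(paste0("g", 1:5000), d$sample_id))
  tab <- paired_ttest(mk_log_expr(v), d)
  expect_gt(stats::ks.test(tab$p_value, "punif")$p.value, 0.01)
})

test_that("fold changes come from raw medians, with zero-median sentinel", {
  n_pat <- 5
  d <- mk_design(n_pat)
  raw <- matrix(c(rep(c(8, 2), each = n_pat),   # fc = 4
                  rep(c(3, 0), each = n_pat),   # normal median 0 -> Inf
                  rep(c(2, 2), each = n_pat)),  # fc = 1
                3, 2 * n_pat, byrow = TRUE,
                dimnames = list(c("up", "inf", "flat"), d$sample_id))
  e_raw <- expression_matrix(raw, "mRNA", "raw")
  tab <- paired_ttest(log_transform(e_raw), d, raw_expr = e_raw)
  expect_equal(tab$fold_change, c(4, Inf, 1))
  expect_identical(tab$fc_undefined, c(FALSE, TRUE, FALSE))
})

test_that("significance selection is strict, ordered, idempotent, monotone", {
  tab <- structure(data.frame(
    feature_id = c("a", "b", "c", "d"),
    t_stat = 1:4, p_value = c(0.001, 0.01, 0.02, 0.1),
    fdr = c(0.01, 0.049, 0.05, 0.2),
    fold_change = 1, passes = NA, degenerate = FALSE, fc_undefined = FALSE),
    class = c("him_diff", "data.frame"))
  expect_identical(select_significant(tab, 0.05), c("a", "b"))
  expect_identical(select_significant(tab[0, ], 0.05), character(0))
  expect_identical(sort(select_significant(tab, 1.0)), c("a", "b", "c", "d"))
  # monotone in threshold
  th <- c(0.01, 0.05, 0.1, 0.5, 1)
  sets <- lapply(th, select_significant, table = tab)
  for (i in seq_along(th)[-1])
    expect_true(all(sets[[i - 1]] %in% sets[[i]]))
})

test_that("sparse features are dropped by missing fraction, fills are explicit", {
  v <- rand_counts(5, 20, seed = 9) + 0
  v[1, 1:19] <- NA   # 95% missing
  v[2, 1] <- NA      # 5% missing
  e <- expression_matrix(v, "miRNA", "raw", allow_missing = TRUE)
  expect_error(drop_sparse_features(e, 0.9), "zero-fill")
  out <- drop_sparse_features(e, 0.9, fill = "zero")
  expect_false("f1" %in% feature_ids(out))
  expect_equal(out$values["f2", "s1"], 0)

  full <- expression_matrix(rand_counts(4, 6, seed = 2) + 0, "miRNA", "raw")
  expect_identical(drop_sparse_features(full, 0.9)$values, full$values)
  # threshold 0: any missing cell is fatal to its feature
  out0 <- drop_sparse_features(e, 0)
  expect_identical(feature_ids(out0), c("f3", "f4", "f5"))
  all_na <- expression_matrix(matrix(NA_real_, 2, 2,
      dimnames = list(c("a", "b"), c("s1", "s2"))), "miRNA", "raw",
      allow_missing = TRUE)
  expect_error(drop_sparse_features(all_na, 0.5), "all features")
})

test_that("dependence diagnostic: copies give r = 1, null data matches theory", {
  n_pat <- 30
  d <- mk_design(n_pat)
  set.seed(10)
  v <- matrix(rnorm(200 * 2 * n_pat), 200, 2 * n_pat,
              dimnames = list(paste0("g", 1:200), d$sample_id))
  # feature 1: normal is an exact copy of tumor
  v[1, d$status == 0] <- v[1, d$status == 1][match(
    d$patient_id[d$status == 0], d$patient_id[d$status == 1])]
  # feature 2: constant tumor vector -> degenerate
  v[2, d$status == 1] <- 3
  rep <- dependence_report(mk_log_expr(v), d, threshold = 0.3)
  expect_equal(rep$table$r[1], 1)
  expect_true(rep$table$degenerate[2])
  expect_equal(rep$table$r[2], 0)

  # direct recomputation
  r_direct <- cor(v[3, d$status == 1][order(d$patient_id[d$status == 1])],
                  v[3, d$status == 0][order(d$patient_id[d$status == 0])])
  expect_equal(rep$table$r[3], r_direct, tolerance = 1e-12)

  # null expectation: |r| < 0.3 with probability from the t transform
  tcrit <- 0.3 * sqrt(n_pat - 2) / sqrt(1 - 0.3^2)
  p_theory <- 2 * stats::pt(tcrit, n_pat - 2) - 1
  ok <- !rep$table$degenerate & rep$table$r != 1
  expect_lt(abs(mean(abs(rep$table$r[ok]) < 0.3) - p_theory),
            4 * sqrt(p_theory * (1 - p_theory) / sum(ok)))
  # threshold 1 captures every non-degenerate feature with |r| < 1
  v2 <- v[-(1:2), , drop = FALSE]
  expect_equal(dependence_report(mk_log_expr(v2), d, 1)$fraction_below, 1)
})
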