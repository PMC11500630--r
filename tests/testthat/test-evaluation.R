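pair_from <- function(orig_df, imp_df, mask_cells, scales, exclude = integer(0)) {
  orig <- mixed_data(orig_df, scales)
  imp <- mixed_data(imp_df, scales)
  amp_df <- orig_df
  for (r in seq_len(nrow(mask_cells)))
    amp_df[mask_cells[r, 1], mask_cells[r, 2]] <- NA
  mask <- build_mask(mixed_data(amp_df, scales))
  evaluation_pair(imp, orig, mask, exclude_rows = exclude)
}

test_that("precision measures are zero for a truth oracle and match hand values", {
  orig <- data.frame(a = c(100, 2, 3, 4), b = c(10, 20, 30, 40))
  cells <- rbind(c(1, 1), c(3, 1), c(2, 2), c(4, 2))
  sc <- c("continuous", "continuous")
  perfect <- pair_from(orig, orig, cells, sc)
  expect_identical(mape(perfect), 0)
  expect_identical(nrmse(perfect), 0)
  expect_identical(msecor(perfect), 0)

  imp <- orig; imp$a[1] <- 110   # 10% off on a single scored cell
  p1 <- pair_from(orig, imp, cbind(1, 1), sc)
  expect_equal(mape(p1), 10)

  imp2 <- orig; imp2$a[1] <- 110; imp2$b[3] <- 39  # errors 10% and 30%
  orig2 <- orig; orig2$b[3] <- 30
  p2 <- pair_from(orig2, imp2, rbind(c(1, 1), c(3, 2)), sc)
  expect_equal(mape(p2), 20)
})

test_that("nrmse matches the hand-computed toy and flags degenerate variances", {
  # one column, originals (1, 3) at the scored cells, imputations (2, 2)
  orig <- data.frame(y = c(1, 3, 5), x = c(0, 0.5, 1))
  imp <- orig; imp$y[1:2] <- 2
  p <- pair_from(orig, imp, cbind(1:2, 1), c("continuous", "continuous"))
  expect_equal(nrmse(p), sqrt(0.5), tolerance = 1e-12)  # ~0.7071

  # imputing the scored-cell mean scores the same ~0.71: mean imputation
  # lands near the poor-performance regime around 1
  imp_mean <- orig; imp_mean$y[1:2] <- mean(c(1, 3))
  p_mean <- pair_from(orig, imp_mean, cbind(1:2, 1), c("continuous", "continuous"))
  expect_equal(nrmse(p_mean), sqrt(0.5), tolerance = 1e-12)

  single <- pair_from(orig, imp, cbind(1, 1), c("continuous", "continuous"))
  expect_error(nrmse(single), "single scored cell")
})

test_that("msecor follows the Frobenius form and ignores variable order", {
  set.seed(1)
  base <- MASS::mvrnorm(200, c(0, 0), matrix(c(1, 0.5, 0.5, 1), 2),
                        empirical = TRUE)
  target <- MASS::mvrnorm(200, c(0, 0), matrix(c(1, 0.3, 0.3, 1), 2),
                          empirical = TRUE)
  sc <- c("continuous", "continuous")
  orig <- as.data.frame(base); names(orig) <- c("a", "b")
  imp <- as.data.frame(target); names(imp) <- c("a", "b")
  p <- pair_from(orig, imp, cbind(1, 1), sc)
  expect_equal(msecor(p), sqrt(2 * 0.04), tolerance = 1e-10)  # ~0.2828
  expect_equal(msecor(p, form = "double_sum"), 0)  # D-1 = 1 leaves only the diagonal

  # permuting the variables leaves the norm form unchanged
  p_perm <- pair_from(orig[, 2:1], imp[, 2:1], cbind(1, 1), sc)
  expect_equal(msecor(p_perm), msecor(p))
})

test_that("false classification rate counts mismatched categories", {
  sc <- c("categorical", "continuous")
  orig <- data.frame(g = factor(c("a", "b", "a", "b"), levels = c("a", "b", "c")),
                     x = 1:4 + 0.5)
  cells <- cbind(1:4, 1)
  expect_identical(false_classification_rate(pair_from(orig, orig, cells, sc)), 0)
  imp <- orig; imp$g[2] <- "c"
  expect_equal(false_classification_rate(pair_from(orig, imp, cells, sc)), 25)
  allwrong <- orig; allwrong$g <- factor(c("c", "c", "c", "c"), levels = c("a", "b", "c"))
  expect_equal(false_classification_rate(pair_from(orig, allwrong, cells, sc)), 100)
})

test_that("scores depend only on the scored cells", {
  sc <- c("continuous", "continuous")
  orig <- data.frame(a = c(1, 2, 3, 4), b = c(5, 6, 7, 8))
  imp <- orig; imp$a[2] <- 2.5
  cells <- cbind(2, 1)
  m1 <- mape(pair_from(orig, imp, cells, sc))
  # perturb a never-missing cell identically in both inputs
  orig2 <- orig; orig2$b[4] <- 80
  imp2 <- imp; imp2$b[4] <- 80
  expect_identical(mape(pair_from(orig2, imp2, cells, sc)), m1)
  expect_identical(nrmse(pair_from(orig2, imp2, rbind(cells, c(3, 1)), sc)),
                   nrmse(pair_from(orig, imp, rbind(cells, c(3, 1)), sc)))
})

test_that("loading differences are sign-aligned and entry-wise relative", {
  B <- matrix(c(0.5, 0.5), 1, 2)
  B_imp <- matrix(c(0.55, 0.45), 1, 2)
  expect_equal(loading_rel_diff(B, B_imp), 10)
  expect_identical(loading_rel_diff(B, B), 0)
  expect_identical(loading_rel_diff(B, -B), 0)  # global sign flip aligns away
  Bz <- matrix(c(0, 1, 1, 1), 2, 2)
  expect_warning(loading_rel_diff(Bz, Bz), "zero")
})

test_that("estimator summaries satisfy rmse^2 = variance + bias^2", {
  expect_identical(unname(estimator_summary(c(2, 2, 2), theta = 2)), c(0, 0, 0))
  sm <- estimator_summary(c(1, 3), theta = 2)
  expect_equal(unname(sm), c(0, 1, 1))
  set.seed(4)
  for (case in 1:20) {
    est <- stats::rnorm(10); th <- stats::rnorm(1)
    sm <- estimator_summary(est, theta = th)
    expect_equal(sm[["rmse"]]^2, sm[["variance"]] + sm[["bias"]]^2, tolerance = 1e-12)
    shifted <- estimator_summary(est + 0.7, theta = th)
    expect_equal(shifted[["bias"]], sm[["bias"]] + 0.7)
    expect_equal(shifted[["variance"]], sm[["variance"]])
  }
})

test_that("coverage is the fraction of intervals containing theta", {
  r1 <- estimator_replicates(1:3, lower = c(0, 1, 2), upper = c(4, 5, 6), theta = 2.5)
  expect_identical(coverage_rate(r1), 1)
  r2 <- estimator_replicates(rep(0, 100), lower = c(rep(-1, 95), rep(5, 5)),
                             upper = c(rep(1, 95), rep(6, 5)), theta = 0)
  expect_identical(coverage_rate(r2), 0.95)
  r3 <- estimator_replicates(1:2, lower = c(5, 5), upper = c(6, 6), theta = 0)
  expect_identical(coverage_rate(r3), 0)
  expect_error(estimator_replicates(1, lower = 2, upper = 1, theta = 0), "lower")
})

test_that("rubin pooling combines within and between variance as stated", {
  same <- rubin_pool(c(2, 2, 2), c(1.5, 1.5, 1.5))
  expect_identical(same$between, 0)
  expect_identical(same$total_var, 1.5)

  p <- rubin_pool(c(1, 2, 3), c(1, 1, 1))
  expect_identical(p$estimate, 2)
  expect_identical(p$between, 1)
  expect_equal(p$total_var, 7 / 3, tolerance = 1e-12)
  expect_equal(p$df, 2 * (1 + 1 / (4 / 3))^2)
  expect_gte(p$total_var, p$within)

  single <- rubin_pool(5, 0.25, df_single = 10)
  expect_equal(single$lower, 5 - stats::qt(0.975, 10) * 0.5)
  expect_error(rubin_pool(numeric(0), numeric(0)), "no estimates")
})

test_that("accuracy and F1 follow the confusion-count formulas", {
  expect_identical(unname(f1_accuracy(3, 4, 0, 0)), c(1, 1))
  expect_equal(f1_accuracy(1, 0, 1, 1)[["f1"]], 0.5)
  expect_equal(f1_accuracy(8, 0, 2, 4)[["f1"]], 16 / 22)
  expect_equal(f1_accuracy(8, 1, 2, 4)[["accuracy"]], 9 / 15)
  expect_error(f1_accuracy(0, 5, 0, 0), "undefined")
})
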