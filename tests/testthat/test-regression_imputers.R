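test_that("the posterior coefficient draw collapses without noise and centres on beta_hat", {
  md <- line_md(n = 20)
  X <- matrix(md$data$x, ncol = 1)
  y <- md$data$y
  d <- bayes_regression_draw(X, y, seed = 1)
  expect_equal(unname(d$beta_star), c(1, 2), tolerance = 1e-10)
  expect_identical(d$sigma_star, 0)

  set.seed(2)
  yn <- y + stats::rnorm(20, sd = 0.5)
  d1 <- bayes_regression_draw(X, yn, seed = 7)
  expect_identical(d1$beta_star, bayes_regression_draw(X, yn, seed = 7)$beta_star)

  # mean of the slope draw over many seeds approaches the estimate
  slopes <- vapply(1:10000, function(s) bayes_regression_draw(X, yn, seed = s)$beta_star[2], 0)
  mc_se <- stats::sd(slopes) / 100
  expect_lt(abs(mean(slopes) - d1$beta_hat[2]), 4 * mc_se)

  expect_error(bayes_regression_draw(cbind(X, X), yn, seed = 1), "rank")
})

test_that("midas_kappa reproduces the printed worked values", {
  expect_identical(round(midas_kappa(0.9, 1e-4)), 10)
  expect_identical(midas_kappa(0), 0)
  expect_equal(midas_kappa(0.5, 0), 50^(3 / 8))
  expect_error(midas_kappa(1, 0), "undefined")
})

test_that("midas_probs weights donors as omega * d^-kappa with the zero-distance limit", {
  expect_equal(midas_probs(c(1, 1, 1), c(2, 2, 2), 3), rep(1 / 3, 3))
  expect_equal(midas_probs(c(1, 2), c(1, 1), 1), c(2 / 3, 1 / 3))
  expect_equal(midas_probs(c(1, 2), c(3, 5), 0), c(3 / 8, 5 / 8))
  expect_equal(midas_probs(c(0, 1, 0), c(1, 1, 1), 2), c(0.5, 0, 0.5))
  expect_error(midas_probs(c(1, 2), c(0, 0), 1), "zero")

  # invariance: rescaling all distances by c > 0 leaves probabilities unchanged
  set.seed(3)
  for (case in 1:50) {
    d <- stats::rexp(5) + 0.01; w <- stats::rpois(5, 2) + 1; k <- stats::runif(1, 0, 5)
    p1 <- midas_probs(d, w, k)
    expect_equal(sum(p1), 1, tolerance = 1e-12)
    expect_equal(p1, midas_probs(3.7 * d, w, k), tolerance = 1e-12)
  }
})

test_that("midastouch donor frequencies follow the stated probabilities", {
  d <- c(1, 2, 4); w <- c(2, 1, 1); k <- 1.5
  p <- midas_probs(d, w, k)
  draws <- impbench:::with_local_seed(10,
    vapply(1:10000, function(i) impbench:::midas_draw(d, w, k), 0L))
  freq <- tabulate(draws, 3) / 10000
  se <- sqrt(p * (1 - p) / 10000)
  expect_true(all(abs(freq - p) <= 3 * se))
})

test_that("pmm copies observed values and matches a brute-force donor search", {
  const <- mixed_data(data.frame(x = 1:6, y = c(7, 7, 7, 7, 7, NA)),
                      c("count", "continuous"))
  out <- pmm_impute(const, m = 2, k_donors = 3, seed = 1)
  expect_true(all(vapply(out$completions, function(cp) cp$data$data$y[6] == 7, TRUE)))

  md <- gaussian_md(n = 50, p = 2, seed = 4)
  amp <- ampute_mcar(md, 0.2, seed = 5)
  out2 <- pmm_impute(amp$data, amp$mask, m = 3, seed = 6)
  for (cp in out2$completions) {
    expect_true(check_preservation(amp$data, cp))
    for (j in 1:2) {
      obs <- amp$data$data[[j]][amp$mask$entries[, j] == 0L]
      expect_true(all(cp$data$data[[j]][amp$mask$entries[, j] == 1L] %in% obs))
    }
  }

  # noise-free y = 2x with k_donors = 1: the imputed value is the observed y
  # of the donor with the nearest prediction (type-2 scores are monotone in x)
  x <- c(0, 1, 2, 3, 4, 5, 6, 2.6)
  y <- 2 * x; y[8] <- NA
  md8 <- mixed_data(data.frame(x = x, y = y), c("continuous", "continuous"))
  got <- pmm_impute(md8, m = 1, k_donors = 1, seed = 2)$completions[[1]]$data$data$y[8]
  expect_equal(got, 2 * 3)  # donor x = 3 is nearest in prediction space
  expect_error(pmm_impute(md8, m = 1, k_donors = 10, seed = 1), "donors")
})

test_that("midastouch imputations stay in the observed support; ties fall to the omega coin", {
  md <- gaussian_md(n = 40, p = 2, seed = 14)
  amp <- ampute_mcar(md, 0.15, seed = 15)
  out <- midastouch_impute(amp$data, amp$mask, m = 3, seed = 16)
  for (cp in out$completions) {
    expect_true(check_preservation(amp$data, cp))
    for (j in 1:2) {
      obs <- amp$data$data[[j]][amp$mask$entries[, j] == 0L]
      expect_true(all(cp$data$data[[j]][amp$mask$entries[, j] == 1L] %in% obs))
    }
  }

  # identical predictor rows -> equal distances -> either donor can be drawn
  df <- data.frame(x = c(1, 1, 1), y = c(0, 10, NA))
  mdt <- mixed_data(df, c("continuous", "continuous"))
  vals <- vapply(1:200, function(s)
    midastouch_impute(mdt, m = 1, seed = s)$completions[[1]]$data$data$y[3], 0)
  expect_setequal(unique(vals), c(0, 10))
})

test_that("robust continuous fits equal least squares on clean data but resist leverage", {
  md <- line_md(n = 40)
  X <- matrix(md$data$x, ncol = 1)
  fit <- robust_fit(X, md$data$y, "continuous")
  expect_equal(unname(fit$coefficients), c(1, 2), tolerance = 1e-8)

  set.seed(20)
  y <- 1 + 2 * md$data$x + stats::rnorm(40, sd = 0.2)
  Xc <- X; yc <- y
  bad <- 1:4                               # 10% gross leverage points
  Xc[bad, 1] <- 50; yc[bad] <- -100
  ls_slope <- stats::coef(stats::lm(yc ~ Xc))[2]
  rob <- robust_fit(Xc, yc, "continuous")
  expect_lt(abs(rob$coefficients[2] - 2), abs(ls_slope - 2))
  expect_lt(mean(rob$weights[bad]), 0.5)   # the planted points are downweighted
})

test_that("the semicontinuous fit separates the spike from the continuous part", {
  set.seed(21)
  n <- 100
  x <- stats::rnorm(n)
  spike <- stats::runif(n) < 0.4
  y <- ifelse(spike, 0, 5 + 3 * x + stats::rnorm(n, sd = 0.1))
  # make spike membership predictable from x2
  x2 <- ifelse(spike, -2, 2) + stats::rnorm(n, sd = 0.3)
  X <- cbind(x, x2)
  fit <- robust_fit(X, y, "semicontinuous")
  pred <- predict(fit, X)
  expect_gt(mean((pred == 0) == spike), 0.95)
  expect_equal(pred[!spike], 5 + 3 * x[!spike], tolerance = 0.5)
})

test_that("binary, categorical and count families predict their scales", {
  set.seed(22)
  n <- 120
  x <- stats::rnorm(n)
  g <- factor(ifelse(x + stats::rnorm(n, sd = 0.3) > 0, "yes", "no"))
  bf <- robust_fit(matrix(x, ncol = 1), g, "binary")
  expect_gt(mean(predict(bf, matrix(x, ncol = 1)) == g), 0.8)

  y3 <- factor(cut(x + stats::rnorm(n, sd = 0.3), c(-Inf, -0.5, 0.5, Inf),
                   labels = c("lo", "mid", "hi")))
  cf <- robust_fit(matrix(x, ncol = 1), y3, "categorical")
  expect_gt(mean(predict(cf, matrix(x, ncol = 1)) == y3), 0.6)

  mu <- exp(1 + 0.5 * x)
  k <- stats::rpois(n, mu)
  pf <- robust_fit(matrix(x, ncol = 1), k, "count")
  pred <- predict(pf, matrix(x, ncol = 1))
  expect_true(all(pred >= 0 & pred %% 1 == 0))
  expect_gt(stats::cor(pred, k), 0.5)
})

test_that("irmi recovers exact linear structure and reports its iterations", {
  md0 <- line_md(n = 40)
  done <- irmi_impute(md0, seed = 1)
  expect_identical(attr(done, "iterations"), 0L)
  expect_identical(done$data$data, md0$data)

  md <- line_md(n = 40, miss = 1:8)
  out <- irmi_impute(md, noise = FALSE, seed = 2)
  truth <- 1 + 2 * md$data$x[1:8]
  expect_equal(out$data$data$y[1:8], truth, tolerance = 1e-6)
  expect_true(attr(out, "converged"))
  expect_gte(attr(out, "iterations"), 1L)
})

test_that("robust irmi resists leverage outliers where the least-squares variant fails", {
  n <- 60
  x <- seq(0, 10, length.out = n)
  y <- 1 + 2 * x
  df <- data.frame(x = x, y = y)
  df$y[1:10] <- NA                       # held-out cells to impute
  df$x[51:55] <- 60; df$y[51:55] <- -200 # gross leverage points, fully observed
  md <- mixed_data(df, c("continuous", "continuous"))
  truth <- 1 + 2 * x[1:10]

  clean <- mixed_data(data.frame(x = x, y = replace(1 + 2 * x, 1:10, NA)),
                      c("continuous", "continuous"))
  err_clean <- max(abs(irmi_impute(clean, noise = FALSE, seed = 3)$data$data$y[1:10] - truth))

  rob <- irmi_impute(md, noise = FALSE, seed = 3)
  ols <- suppressWarnings(irmi_impute(md, robust = FALSE, noise = FALSE, seed = 3))
  err_rob <- max(abs(rob$data$data$y[1:10] - truth))
  err_ols <- max(abs(ols$data$data$y[1:10] - truth))
  bound <- 10 * max(err_clean, 1e-4)
  expect_lt(err_rob, bound)
  expect_gt(err_ols, bound)
})

test_that("irmi multiple imputation varies imputed cells but not observed ones", {
  spec <- income_sim_spec()
  d <- simulate_income(spec, seed = 30)
  amp <- ampute_mar(d, "INCOME", "AGE", 0.3, seed = 31)
  out <- irmi_impute(amp$data, amp$mask, multiple = 3, seed = 32)
  expect_s3_class(out, "mi_set")
  v1 <- out$completions[[1]]$data$data$INCOME
  v2 <- out$completions[[2]]$data$data$INCOME
  mis <- amp$mask$entries[, "INCOME"] == 1L
  expect_true(all(v1[!mis] == v2[!mis]))
  expect_gt(mean(v1[mis] != v2[mis]), 0.9)
})
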