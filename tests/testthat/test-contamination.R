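test_that("income samples have the population moments and are seed-deterministic", {
  spec <- income_sim_spec()
  d <- simulate_income(spec, seed = 42)
  expect_identical(dim(d), c(200L, 2L))
  sigma <- income_covariance(spec)
  se <- sqrt(diag(sigma) / spec$n)
  expect_lt(abs(mean(d$data$AGE) - 40), 4 * se[1])
  expect_lt(abs(mean(d$data$INCOME) - 1500), 4 * se[2])

  expect_identical(simulate_income(spec, seed = 42)$data, d$data)
  single <- simulate_income(income_sim_spec(n = 1), seed = 7)
  expect_identical(nrow(single$data), 1L)
  expect_true(all(is.finite(unlist(single$data))))
})

test_that("the three covariance readings assemble as declared", {
  raw <- income_covariance(income_sim_spec())
  expect_equal(unname(raw), matrix(c(10, 44, 44, 300), 2))
  sq <- income_covariance(income_sim_spec(cov_reading = "elementwise_square"))
  expect_equal(unname(sq), matrix(c(100, 1936, 1936, 90000), 2))
  mm <- income_covariance(income_sim_spec(cov_reading = "matrix_square"))
  expect_equal(unname(mm), matrix(c(10, 44, 44, 300), 2) %*% matrix(c(10, 44, 44, 300), 2))
  expect_error(income_sim_spec(s_age = 1, cross = 44), "positive definite")
})

test_that("leverage outliers sit at mean +/- 0.8 diag(Sigma) and spare other rows", {
  spec <- income_sim_spec(cov_reading = "elementwise_square",
                          outlier_placement = "spread")
  d <- simulate_income(spec, seed = 5)

  k0 <- inject_leverage_outliers(d, 0, spec, seed = 1)
  expect_identical(k0$data$data, d$data)
  expect_length(k0$flags$outlier_rows, 0)

  # with Sigma = [[100, 1936], [1936, 90000]] the four centers are
  # (40 +/- 80, 1500 +/- 72000); each outlier lands near one of them
  big <- inject_leverage_outliers(d, 150, spec, seed = 2)
  rows <- big$flags$outlier_rows
  vals <- big$data$data[rows, ]
  centers_age <- c(-40, 120)
  centers_inc <- c(-70500, 73500)
  d_age <- pmin(abs(vals$AGE - centers_age[1]), abs(vals$AGE - centers_age[2]))
  d_inc <- pmin(abs(vals$INCOME - centers_inc[1]), abs(vals$INCOME - centers_inc[2]))
  expect_lt(max(d_age / sqrt(100 / 5)), 5)       # within 5 cluster SDs
  expect_lt(max(d_inc / sqrt(90000 / 5)), 5)
  # both signs occur under spread placement
  expect_setequal(unique(sign(vals$AGE - 40)), c(-1, 1))

  full <- inject_leverage_outliers(d, 80, income_sim_spec(), seed = 3)
  expect_length(full$flags$outlier_rows, 80)
  untouched <- setdiff(seq_len(200), full$flags$outlier_rows)
  expect_identical(full$data$data[untouched, ], d$data[untouched, ])
  expect_error(inject_leverage_outliers(d, 201, spec, 1), "more outliers")
})

test_that("cluster placement puts all of a draw's outliers in one corner", {
  spec <- income_sim_spec()  # default cluster placement
  d <- simulate_income(spec, seed = 9)
  inj <- inject_leverage_outliers(d, 50, spec, seed = 4)
  vals <- inj$data$data[inj$flags$outlier_rows, ]
  expect_identical(length(unique(sign(vals$AGE - 40))), 1L)
  expect_identical(length(unique(sign(vals$INCOME - 1500))), 1L)
})

test_that("energy draws follow the lognormal generating model", {
  noiseless <- energy_sim_spec(noise_var = 0, n = 2000)
  d <- simulate_energy(noiseless, seed = 11)
  with(d$data, {
    expect_equal(energy[type == "0"], exp(2 - 0.1 * log(runtime[type == "0"])),
                 tolerance = 1e-12)
    expect_equal(energy[type == "1"], exp(3 - 0.1 * log(runtime[type == "1"])),
                 tolerance = 1e-12)
  })
  # E[log runtime] = log(100) - gamma ~ 4.028 for Exp(1/100)
  big <- simulate_energy(energy_sim_spec(n = 1e5), seed = 12)
  expect_equal(mean(log(big$data$runtime)), log(100) + digamma(1),
               tolerance = 4 * pi / sqrt(6) / sqrt(1e5) * 3)
  expect_gt(min(big$data$energy), 0)
})

test_that("misclassification flips are an involution and spare the energy column", {
  d <- simulate_energy(energy_sim_spec(), seed = 3)
  k0 <- inject_misclassifications(d, 0, seed = 1)
  expect_identical(k0$data$data, d$data)

  all_flip <- inject_misclassifications(d, 200, seed = 2)
  expect_true(all(all_flip$data$data$type != d$data$type))
  back <- inject_misclassifications(all_flip$data, 200, seed = 5)
  expect_identical(as.character(back$data$data$type), as.character(d$data$type))

  some <- inject_misclassifications(d, 40, seed = 4)
  expect_length(some$flags$misclassified_rows, 40)
  expect_identical(some$data$data$energy, d$data$energy)
  expect_error(inject_misclassifications(d, 201), "more rows")
})

test_that("MCD flagging catches a gross outlier and is deterministic", {
  x <- impbench:::with_local_seed(8, MASS::mvrnorm(50, c(0, 0), diag(2)))
  x <- rbind(x, c(100, 100))
  md <- mixed_data(as.data.frame(x) |> stats::setNames(c("a", "b")),
                   c("continuous", "continuous"))
  res <- flag_outliers_mcd(md)
  expect_true(res$flagged[51])
  # brute-force check against classical estimates on the clean part
  d2 <- stats::mahalanobis(x, colMeans(x[1:50, ]), stats::cov(x[1:50, ]))
  expect_gt(d2[51], stats::qchisq(0.99, 1))
  expect_identical(flag_outliers_mcd(md)$flagged, res$flagged)
  expect_true(all(res$flagged == (res$distances^2 > res$cutoff), na.rm = TRUE))
})

test_that("MCD flagged fraction of clean Gaussian data approaches 1 - prob", {
  md <- gaussian_md(n = 1e4, p = 2, rho = 0.5, seed = 21)
  res <- flag_outliers_mcd(md, prob = 0.99, df = 2)  # df = D calibration
  expect_lt(abs(mean(res$flagged) - 0.01), 0.02)
})

test_that("MCAR amputation removes exact counts and honours protection", {
  md <- gaussian_md(n = 100, p = 3, seed = 5)
  amp <- ampute_mcar(md, 0.1, seed = 1)
  expect_identical(unname(amp$mask$per_column), rep(10, 3))

  zero <- ampute_mcar(md, 0, seed = 1)
  expect_true(all(zero$mask$entries == 0L))

  prot <- ampute_mcar(md, 0.1, protected = 1:5, seed = 2)
  expect_true(all(prot$mask$entries[1:5, ] == 0L))
  expect_identical(unname(prot$mask$per_column), rep(round(0.1 * 95), 3))
  expect_error(ampute_mcar(md, 0.5, protected = 1:100), "protected")
})

test_that("rank-MAR amputation hits exact counts and prefers high driver values", {
  spec <- income_sim_spec()
  d <- simulate_income(spec, seed = 31)
  amp <- ampute_mar(d, "INCOME", "AGE", 0.3, seed = 1)
  expect_identical(sum(amp$mask$entries[, "INCOME"]), 60L)
  expect_identical(sum(amp$mask$entries[, "AGE"]), 0L)
  expect_true(all(amp$mask$entries[1:5, "AGE"] == 0L))

  # over replications, missingness in the top driver decile beats the bottom
  md <- mixed_data(data.frame(x = 1:100, y = rnorm(100)),
                   c("continuous", "continuous"))
  top <- bot <- 0
  for (r in 1:2000) {
    m <- ampute_mar(md, "y", "x", 0.2, seed = r)$mask$entries[, "y"]
    top <- top + sum(m[91:100]); bot <- bot + sum(m[1:10])
  }
  expect_gt(top, bot * 2)

  const <- mixed_data(data.frame(x = rep(1, 50), y = rnorm(50)),
                      c("continuous", "continuous"))
  expect_warning(ampute_mar(const, "y", "x", 0.2, seed = 1), "constant")
})

test_that("a constant driver degrades rank-MAR to uniform missingness", {
  const <- mixed_data(data.frame(x = rep(1, 40), y = rnorm(40)),
                      c("continuous", "continuous"))
  counts <- numeric(40)
  for (r in 1:2000) {
    m <- suppressWarnings(ampute_mar(const, "y", "x", 0.25, seed = r))
    counts <- counts + m$mask$entries[, "y"]
  }
  # chi-square goodness of fit against uniform cell selection
  expect_gt(stats::chisq.test(counts)$p.value, 0.01)
})
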