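#' Specification of the bivariate age/income study population
#'
#' Parameters of the bivariate Gaussian (AGE, INCOME) population from which
#' the outlier study samples: mean vector (40, 1500), a 2 x 2 scatter matrix
#' assembled from `(s_age, s_income, cross)`, a 30% MAR missing rate in
#' INCOME, and the placement rule for high-leverage outliers (mean shifted by
#' `0.8 *` the covariance diagonal, scatter shrunk to 1/5).
#'
#' The printed source for the scatter matrix is typographically ambiguous,
#' so the construction is selectable:
#' \describe{
#'   \item{`"raw"`}{(default) the printed entries are the covariances:
#'     `Sigma = [[s_age, cross], [cross, s_income]]`. This is the reading
#'     under which the four outlier positions have moderate leverage and
#'     extreme income deviations, so that every non-robust imputer —
#'     including donor-distance methods — is visibly disturbed.}
#'   \item{`"elementwise_square"`}{`Sigma = [[s_age^2, cross^2], [cross^2,
#'     s_income^2]]`.}
#'   \item{`"matrix_square"`}{`Sigma = M %*% M` with
#'     `M = [[s_age, cross], [cross, s_income]]`.}
#' }
#'
#' @param mean_age,mean_income population means (40, 1500)
#' @param s_age,s_income,cross the three printed scatter parameters (10, 300, 44)
#' @param cov_reading how to assemble the covariance matrix, see Details
#' @param n sample size per replicate (200)
#' @param missing_rate fraction of eligible INCOME cells set missing (0.30)
#' @param outlier_shift_factor multiple of the covariance diagonal added or
#'   subtracted from the mean to place an outlier position (0.8)
#' @param outlier_variance_ratio scatter of the outlier clusters relative to
#'   the population scatter (1/5)
#' @param outlier_placement `"cluster"` (default) places all of a
#'   replicate's outliers at one of the four corner positions, chosen
#'   uniformly per draw — a contamination cluster whose direction varies
#'   across replicates, the reading under which even a few outliers
#'   systematically distort the non-robust imputation models;
#'   `"spread"` instead assigns every outlier its own uniformly chosen
#'   corner, so the four corners partially cancel within a replicate
#' @return an object of class `income_sim_spec`
#' @examples
#' spec <- income_sim_spec()
#' income_covariance(spec)
#' @export
income_sim_spec <- function(mean_age = 40, mean_income = 1500,
                            s_age = 10, s_income = 300, cross = 44,
                            cov_reading = c("raw", "elementwise_square", "matrix_square"),
                            n = 200, missing_rate = 0.30,
                            outlier_shift_factor = 0.8,
                            outlier_variance_ratio = 1 / 5,
                            outlier_placement = c("cluster", "spread")) {
  cov_reading <- match.arg(cov_reading)
  outlier_placement <- match.arg(outlier_placement)
  stopifnot(n >= 1, missing_rate >= 0, missing_rate < 1,
            outlier_variance_ratio > 0)
  spec <- structure(list(mean = c(AGE = mean_age, INCOME = mean_income),
                         s_age = s_age, s_income = s_income, cross = cross,
                         cov_reading = cov_reading, n = as.integer(n),
                         missing_rate = missing_rate,
                         outlier_shift_factor = outlier_shift_factor,
                         outlier_variance_ratio = outlier_variance_ratio,
                         outlier_placement = outlier_placement),
                    class = "income_sim_spec")
  income_covariance(spec)  # validates positive definiteness
  spec
}

#' @rdname income_sim_spec
#' @param spec an `income_sim_spec`
#' @export
income_covariance <- function(spec) {
  m <- matrix(c(spec$s_age, spec$cross, spec$cross, spec$s_income), 2, 2)
  sigma <- switch(spec$cov_reading,
                  raw = m,
                  elementwise_square = m^2,
                  matrix_square = m %*% m)
  dimnames(sigma) <- list(c("AGE", "INCOME"), c("AGE", "INCOME"))
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0))
    stop("assembled covariance matrix is not positive definite")
  sigma
}

#' Specification of the energy-consumption study population
#'
#' Parameters of the misclassification study's generating model: energy is
#' lognormal in the runtime with a binary machine-type effect,
#' `energy = exp(2 + I(type = 1) - 0.1 * log(runtime) + eps)`,
#' `type ~ Bin(p = 0.4)`, `runtime ~ Exp(rate = 1/100)`,
#' `eps ~ N(0, 0.1)`. The noise enters inside the exponent (a multiplicative
#' lognormal error), so the energy/runtime relationship is linear after
#' taking logs of both variables, which is how the study imputes it.
#'
#' @param intercept linear-predictor intercept (2)
#' @param type_effect effect added when `type == 1` (1)
#' @param runtime_coeff coefficient of `log(runtime)` (-0.1)
#' @param type_prob binomial probability of type 1 (0.4)
#' @param runtime_rate exponential rate of the runtime (1/100)
#' @param noise_var variance of the Gaussian noise in the exponent (0.1);
#'   0 disables the noise
#' @param n sample size per replicate (200)
#' @param missing_rate fraction of eligible energy cells set missing (0.30)
#' @return an object of class `energy_sim_spec`
#' @export
energy_sim_spec <- function(intercept = 2, type_effect = 1, runtime_coeff = -0.1,
                            type_prob = 0.4, runtime_rate = 1 / 100,
                            noise_var = 0.1, n = 200, missing_rate = 0.30) {
  stopifnot(runtime_rate > 0, type_prob > 0, type_prob < 1, noise_var >= 0,
            n >= 1, missing_rate >= 0, missing_rate < 1)
  structure(list(intercept = intercept, type_effect = type_effect,
                 runtime_coeff = runtime_coeff, type_prob = type_prob,
                 runtime_rate = runtime_rate, noise_var = noise_var,
                 n = as.integer(n), missing_rate = missing_rate),
            class = "energy_sim_spec")
}

#' Rows flagged as contaminated
#'
#' Bookkeeping container for the row indices that were replaced by outliers
#' and/or had their type label flipped.
#'
#' @param outlier_rows,misclassified_rows integer row indices
#' @return an object of class `contamination_flags`
#' @export
contamination_flags <- function(outlier_rows = integer(0),
                                misclassified_rows = integer(0)) {
  structure(list(outlier_rows = sort(unique(as.integer(outlier_rows))),
                 misclassified_rows = sort(unique(as.integer(misclassified_rows)))),
            class = "contamination_flags")
}

#' @rdname contamination_flags
#' @param flags a `contamination_flags` object (or `NULL`)
#' @export
contaminated_rows <- function(flags) {
  if (is.null(flags)) return(integer(0))
  sort(unique(c(flags$outlier_rows, flags$misclassified_rows)))
}

#' Draw a sample from the age/income population
#'
#' @param spec an [income_sim_spec]
#' @param seed integer seed; the draw is a pure function of `(spec, seed)`
#' @return a [mixed_data] with continuous columns `AGE` and `INCOME`
#' @export
simulate_income <- function(spec = income_sim_spec(), seed = NULL) {
  stopifnot(inherits(spec, "income_sim_spec"))
  sigma <- income_covariance(spec)
  x <- with_local_seed(seed, MASS::mvrnorm(spec$n, spec$mean, sigma))
  if (spec$n == 1L) x <- matrix(x, nrow = 1)
  mixed_data(data.frame(AGE = x[, 1], INCOME = x[, 2]),
             scales = c(AGE = "continuous", INCOME = "continuous"))
}

#' Replace rows by high-leverage outliers
#'
#' Replaces `k` uniformly chosen rows by draws centred at one of the four
#' positions `mean +/- outlier_shift_factor * diag(Sigma)` with scatter
#' `Sigma * outlier_variance_ratio`. The corner signs are chosen uniformly —
#' once per replicate (`outlier_placement = "cluster"`, the default) or
#' independently per outlier (`"spread"`), see [income_sim_spec].
#' Non-selected rows are left bit-identical.
#'
#' @param data a [mixed_data] with the spec's `AGE`/`INCOME` columns
#' @param k number of rows to replace (`0 <= k <= n`)
#' @param spec the [income_sim_spec] that generated `data`
#' @param seed integer seed
#' @return a list with elements `data` (contaminated copy) and `flags`
#'   (a [contamination_flags] recording the replaced rows)
#' @export
inject_leverage_outliers <- function(data, k, spec = income_sim_spec(), seed = NULL) {
  stopifnot(inherits(data, "mixed_data"),
            all(c("AGE", "INCOME") %in% names(data$data)))
  n <- nrow(data$data)
  if (k > n) stop("cannot place more outliers than rows")
  if (k == 0L)
    return(list(data = data, flags = contamination_flags()))
  sigma <- income_covariance(spec)
  shift <- spec$outlier_shift_factor * diag(sigma)
  out <- with_local_seed(seed, {
    rows <- sample.int(n, k)
    signs <- if (identical(spec$outlier_placement, "spread"))
      matrix(sample(c(-1, 1), 2L * k, replace = TRUE), ncol = 2L)
    else
      matrix(rep(sample(c(-1, 1), 2L, replace = TRUE), each = k), ncol = 2L)
    noise <- MASS::mvrnorm(k, c(0, 0), sigma * spec$outlier_variance_ratio)
    if (k == 1L) noise <- matrix(noise, nrow = 1)
    vals <- sweep(signs, 2L, shift, `*`) + noise
    vals <- sweep(vals, 2L, spec$mean, `+`)
    list(rows = rows, vals = vals)
  })
  df <- data$data
  df[out$rows, c("AGE", "INCOME")] <- out$vals
  list(data = set_values(data, df),
       flags = contamination_flags(outlier_rows = out$rows))
}

#' Draw a sample of the energy-consumption model
#'
#' @param spec an [energy_sim_spec]
#' @param seed integer seed
#' @return a [mixed_data] with columns `type` (binary, levels "0"/"1"),
#'   `runtime` (continuous, positive) and `energy` (continuous, positive)
#' @export
simulate_energy <- function(spec = energy_sim_spec(), seed = NULL) {
  stopifnot(inherits(spec, "energy_sim_spec"))
  sim <- with_local_seed(seed, {
    type <- stats::rbinom(spec$n, 1L, spec$type_prob)
    runtime <- stats::rexp(spec$n, rate = spec$runtime_rate)
    eps <- if (spec$noise_var > 0) stats::rnorm(spec$n, 0, sqrt(spec$noise_var)) else 0
    list(type = type, runtime = runtime, eps = eps)
  })
  energy <- exp(spec$intercept + spec$type_effect * (sim$type == 1L) +
                  spec$runtime_coeff * log(sim$runtime) + sim$eps)
  mixed_data(data.frame(type = factor(sim$type, levels = c("0", "1")),
                        runtime = sim$runtime, energy = energy),
             scales = c(type = "binary", runtime = "continuous",
                        energy = "continuous"))
}

#' Flip the type label of randomly chosen rows
#'
#' `k` distinct rows chosen uniformly get the two levels of the binary
#' `column` swapped; applying the same flip twice restores the input.
#'
#' @param data a [mixed_data] with a binary column
#' @param k number of rows to misclassify
#' @param seed integer seed
#' @param column name of the binary column (default `"type"`)
#' @return a list with elements `data` and `flags`
#' @export
inject_misclassifications <- function(data, k, seed = NULL, column = "type") {
  stopifnot(inherits(data, "mixed_data"),
            column %in% names(data$data),
            data$scales[[column]] == "binary")
  n <- nrow(data$data)
  if (k > n) stop("cannot misclassify more rows than exist")
  if (k == 0L)
    return(list(data = data, flags = contamination_flags()))
  rows <- with_local_seed(seed, sample.int(n, k))
  df <- data$data
  lev <- levels(df[[column]])
  cur <- df[[column]][rows]
  df[[column]][rows] <- factor(ifelse(cur == lev[1L], lev[2L], lev[1L]), levels = lev)
  list(data = set_values(data, df),
       flags = contamination_flags(misclassified_rows = rows))
}

#' Robust outlier flagging via MCD Mahalanobis distances
#'
#' Computes robust Mahalanobis distances of the continuous columns from the
#' minimum covariance determinant (MCD) location and scatter, and flags rows
#' whose squared distance exceeds the chi-squared quantile at probability
#' `prob`. Following the study protocol the default degrees of freedom are
#' the number of continuous variables minus one (`df = D - 1`); pass
#' `df = D` for the textbook calibration under which the flagged fraction of
#' clean Gaussian data approaches `1 - prob`.
#'
#' The MCD subset search is stochastic; a fixed internal `seed` makes the
#' flagging deterministic (identical inputs give identical flags).
#'
#' @param data a [mixed_data]; rows with missing continuous cells get an
#'   `NA` distance and are never flagged
#' @param prob chi-squared cutoff probability (default 0.99)
#' @param df degrees of freedom of the cutoff; default `D - 1`
#' @param seed seed for the MCD subset search
#' @return an object of class `robust_distance_result` with elements
#'   `distances` (robust Mahalanobis distances), `cutoff` (chi-squared
#'   quantile for the squared distance), `flagged`, `center`, `scatter`,
#'   `df`, `prob`
#' @export
flag_outliers_mcd <- function(data, prob = 0.99, df = NULL, seed = 1L) {
  stopifnot(inherits(data, "mixed_data"), prob > 0, prob < 1)
  cont <- names(data$scales)[data$scales == "continuous"]
  if (length(cont) < 2L) stop("need at least two continuous columns for MCD flagging")
  x <- as.matrix(data$data[cont])
  complete <- stats::complete.cases(x)
  if (sum(complete) < ncol(x) + 1L)
    stop("too few complete rows to fit the MCD estimator")
  fit <- with_local_seed(seed, MASS::cov.rob(x[complete, , drop = FALSE], method = "mcd"))
  d2 <- rep(NA_real_, nrow(x))
  d2[complete] <- stats::mahalanobis(x[complete, , drop = FALSE], fit$center, fit$cov)
  if (is.null(df)) df <- length(cont) - 1L
  cutoff <- stats::qchisq(prob, df = df)
  flagged <- !is.na(d2) & d2 > cutoff
  structure(list(distances = sqrt(d2), cutoff = cutoff, flagged = flagged,
                 center = fit$center, scatter = fit$cov, df = df, prob = prob),
            class = "robust_distance_result")
}

#' @export
print.robust_distance_result <- function(x, ...) {
  cat(sprintf("robust_distance_result: %d/%d rows flagged (cutoff chi2 = %.3f, df = %d, prob = %.3f)\n",
              sum(x$flagged), length(x$flagged), x$cutoff, x$df, x$prob))
  invisible(x)
}

amputation_counts <- function(rate, n_eligible) {
  k <- round_half_up(rate * n_eligible)
  if (rate > 0 && k < 1L)
    warning("amputation rate too small to remove any cell")
  k
}

#' Ampute cells completely at random (MCAR)
#'
#' Per column, exactly `round(rate * n_eligible)` cells among the
#' non-protected rows are set missing, uniformly without replacement
#' (rounding half up). Protected rows — typically the flagged outliers — are
#' never amputed.
#'
#' @param data a [mixed_data]
#' @param rate fraction of eligible cells to remove per column
#' @param protected integer row indices that must stay fully observed
#' @param seed integer seed
#' @param columns columns to ampute (default: all)
#' @return a list with elements `data` (the amputed copy) and `mask`
#'   (its [build_mask])
#' @export
ampute_mcar <- function(data, rate, protected = integer(0), seed = NULL,
                        columns = NULL) {
  stopifnot(inherits(data, "mixed_data"), rate >= 0, rate < 1)
  n <- nrow(data$data)
  columns <- columns %||% names(data$data)
  eligible <- setdiff(seq_len(n), protected)
  if (!length(eligible) && rate > 0)
    stop("all rows are protected; nothing can be amputed")
  df <- with_local_seed(seed, {
    df <- data$data
    for (cl in columns) {
      k <- amputation_counts(rate, length(eligible))
      if (k > 0L) df[[cl]][sample(eligible, k)] <- NA
    }
    df
  })
  out <- set_values(data, df)
  list(data = out, mask = build_mask(out))
}

#' Ampute one column at random given another (monotone MAR)
#'
#' Removes exactly `round(rate * n_eligible)` cells of `target` among
#' non-protected rows, sampled without replacement with selection weight
#' proportional to the rank of the fully observed `driver` column — the
#' higher the driver value, the more likely the target is missing. A
#' constant driver degrades to MCAR with a warning.
#'
#' @param data a [mixed_data]
#' @param target column to ampute
#' @param driver fully observed column whose rank drives the missingness
#' @param rate fraction of eligible target cells to remove
#' @param protected integer row indices never amputed
#' @param seed integer seed
#' @return a list with elements `data` and `mask`
#' @export
ampute_mar <- function(data, target, driver, rate, protected = integer(0),
                       seed = NULL) {
  stopifnot(inherits(data, "mixed_data"),
            target %in% names(data$data), driver %in% names(data$data),
            target != driver, rate >= 0, rate < 1)
  drv <- data$data[[driver]]
  if (anyNA(drv)) stop("the MAR driver column must be fully observed")
  n <- nrow(data$data)
  eligible <- setdiff(seq_len(n), protected)
  if (!length(eligible) && rate > 0)
    stop("all rows are protected; nothing can be amputed")
  w <- rank(as.numeric(drv[eligible]), ties.method = "average")
  if (length(unique(w)) == 1L) {
    warning("constant MAR driver; mechanism degrades to MCAR")
    w <- rep(1, length(eligible))
  }
  k <- amputation_counts(rate, length(eligible))
  df <- data$data
  if (k > 0L) {
    rows <- with_local_seed(seed, sample(eligible, k, prob = w))
    df[[target]][rows] <- NA
  }
  out <- set_values(data, df)
  list(data = out, mask = build_mask(out))
}
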