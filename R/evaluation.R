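#' Pair an imputed dataset with its ground truth for scoring
#'
#' Bundles the completed data, the original (fully known) data, the mask of
#' scored cells and an optional set of excluded rows (typically the flagged
#' outliers, which should not enter any precision score).
#'
#' @param imputed a [completed_data] or fully observed [mixed_data]
#' @param original the ground-truth [mixed_data]
#' @param mask the [build_mask] marking which cells are scored
#' @param exclude_rows integer row indices dropped from all scoring
#' @return an object of class `evaluation_pair`
#' @export
evaluation_pair <- function(imputed, original, mask = NULL,
                            exclude_rows = integer(0)) {
  imp <- if (inherits(imputed, "completed_data")) imputed$data else imputed
  stopifnot(inherits(imp, "mixed_data"), inherits(original, "mixed_data"))
  if (is.null(mask)) {
    mask <- if (inherits(imputed, "completed_data")) imputed$source_mask
            else stop("a mask is required when `imputed` is not a completed_data")
  }
  if (!all(dim(imp$data) == dim(original$data)) ||
      !identical(imp$scales, original$scales))
    stop("imputed and original data must share shape and schema")
  validate_mask(mask, original)
  structure(list(imputed = imp, original = original, mask = mask,
                 exclude_rows = sort(unique(as.integer(exclude_rows)))),
            class = "evaluation_pair")
}

scored_cells <- function(pair, scales_wanted) {
  ent <- pair$mask$entries
  if (length(pair$exclude_rows)) ent[pair$exclude_rows, ] <- 0L
  cols <- which(pair$original$scales %in% scales_wanted)
  cells <- which(ent[, cols, drop = FALSE] == 1L, arr.ind = TRUE)
  if (nrow(cells)) cells[, 2L] <- cols[cells[, 2L]]
  cells
}

#' Mean absolute percentage error of imputed cells
#'
#' `100 *` the mean over the scored continuous cells of
#' `|imputed - original| / |original|`. Requires every scored original cell
#' to be nonzero (set `skip_zero = TRUE` to drop zero cells instead).
#'
#' @param pair an [evaluation_pair]
#' @param skip_zero drop scored cells whose original value is 0 instead of
#'   signalling an error
#' @return percentage (0 for perfect imputation)
#' @export
mape <- function(pair, skip_zero = FALSE) {
  cells <- scored_cells(pair, "continuous")
  if (!nrow(cells)) stop("no scored continuous cells")
  orig <- mapply(function(i, j) pair$original$data[i, j], cells[, 1L], cells[, 2L])
  imp <- mapply(function(i, j) pair$imputed$data[i, j], cells[, 1L], cells[, 2L])
  zero <- orig == 0
  if (any(zero)) {
    if (!skip_zero) stop("scored original cell equals zero; MAPE undefined")
    orig <- orig[!zero]; imp <- imp[!zero]
  }
  100 * mean(abs(imp - orig) / abs(orig))
}

#' Normalized root mean squared error of imputed cells
#'
#' The square root of the mean over scored continuous cells of
#' `(imputed - original)^2 / s2_j`, where `s2_j` is the variance of the
#' original values at the scored cells of column j (divisor: number of
#' scored cells in the column minus one). Near 0 for good imputations and
#' around 1 in the regime of mean imputation.
#'
#' @param pair an [evaluation_pair]
#' @return a nonnegative number
#' @export
nrmse <- function(pair) {
  cells <- scored_cells(pair, "continuous")
  if (!nrow(cells)) stop("no scored continuous cells")
  ratios <- numeric(0)
  for (j in unique(cells[, 2L])) {
    rows <- cells[cells[, 2L] == j, 1L]
    if (length(rows) < 2L)
      stop(sprintf("column '%s' has a single scored cell; its variance is undefined",
                   names(pair$original$data)[j]))
    orig <- pair$original$data[rows, j]
    imp <- pair$imputed$data[rows, j]
    s2 <- stats::var(orig)
    if (s2 <= 0)
      stop(sprintf("zero variance of the original values in column '%s'",
                   names(pair$original$data)[j]))
    ratios <- c(ratios, (imp - orig)^2 / s2)
  }
  sqrt(mean(ratios))
}

#' Distortion of the correlation structure (MSECOR)
#'
#' Compares the correlation matrix of the original continuous variables
#' with the one after imputation: the Frobenius norm of their difference
#' divided by `D - 1` (D continuous variables). Excluded rows (outliers)
#' are dropped from both matrices. `form = "double_sum"` instead computes
#' the alternative index-limited double-sum variant
#' `sum_{i,j=1}^{D-1} (r_ij - r~_ij)^2 / (D-1)^2`.
#'
#' @param pair an [evaluation_pair]
#' @param form `"norm"` (default) or `"double_sum"`
#' @return a nonnegative number, 0 when the correlation structure is intact
#' @export
msecor <- function(pair, form = c("norm", "double_sum")) {
  form <- match.arg(form)
  cols <- which(pair$original$scales == "continuous")
  if (length(cols) < 2L) stop("MSECOR needs at least two continuous variables")
  rows <- setdiff(seq_len(nrow(pair$original$data)), pair$exclude_rows)
  xo <- as.matrix(pair$original$data[rows, cols])
  xi <- as.matrix(pair$imputed$data[rows, cols])
  if (any(apply(xo, 2L, stats::sd) == 0) || any(apply(xi, 2L, stats::sd) == 0))
    stop("constant column after exclusion; correlation undefined")
  R <- stats::cor(xo)
  Rt <- stats::cor(xi)
  D <- length(cols)
  if (form == "norm") {
    sqrt(sum((R - Rt)^2)) / (D - 1)
  } else {
    idx <- seq_len(D - 1L)
    sum((R[idx, idx] - Rt[idx, idx])^2) / (D - 1)^2
  }
}

#' False classification rate of imputed categorical cells
#'
#' `100 *` the fraction of scored binary/categorical cells whose imputed
#' category differs from the original one.
#'
#' @param pair an [evaluation_pair]
#' @return percentage in `[0, 100]`
#' @export
false_classification_rate <- function(pair) {
  cells <- scored_cells(pair, c("binary", "categorical"))
  if (!nrow(cells)) stop("no scored categorical cells")
  wrong <- mapply(function(i, j)
    as.character(pair$imputed$data[i, j]) != as.character(pair$original$data[i, j]),
    cells[, 1L], cells[, 2L])
  100 * mean(wrong)
}

#' Relative difference of principal-component loadings
#'
#' Entry-wise relative difference (in percent) between the p x 2 loadings
#' of the complete data and the loadings after insertion and imputation of
#' missing values: `100 / (2p) * sum |b - b_imp| / |b|`. Each column of
#' `B_imp` is first sign-aligned with the corresponding column of `B`
#' (principal-axis signs are arbitrary). Zero entries of `B` are excluded
#' with a warning.
#'
#' @param B,B_imp p x 2 loading matrices
#' @return percentage
#' @export
loading_rel_diff <- function(B, B_imp) {
  B <- as.matrix(B); B_imp <- as.matrix(B_imp)
  stopifnot(all(dim(B) == dim(B_imp)), ncol(B) == 2L)
  for (jj in 1:2) {
    if (sum(B[, jj] * B_imp[, jj]) < 0) B_imp[, jj] <- -B_imp[, jj]
  }
  nz <- B != 0
  if (!any(nz)) stop("all-zero loading matrix")
  if (any(!nz)) warning("zero loading entries excluded from the relative difference")
  p <- nrow(B)
  100 / (2 * p) * sum(abs(B[nz] - B_imp[nz]) / abs(B[nz]))
}

#' Replicated point estimates with confidence intervals
#'
#' Container for per-replicate estimates of a known target parameter and
#' their confidence intervals, feeding bias/variance/RMSE and coverage.
#'
#' @param estimates per-replicate point estimates
#' @param lower,upper per-replicate interval bounds (optional, needed for
#'   coverage)
#' @param theta the true parameter value
#' @param level nominal confidence level (default 0.95)
#' @return an object of class `estimator_replicates`
#' @export
estimator_replicates <- function(estimates, lower = NULL, upper = NULL,
                                 theta, level = 0.95) {
  stopifnot(length(estimates) >= 1L)
  if (!is.null(lower)) {
    stopifnot(length(lower) == length(estimates),
              length(upper) == length(estimates))
    bad <- !is.na(lower) & !is.na(upper) & lower > upper
    if (any(bad)) stop("intervals must satisfy lower <= upper")
  }
  structure(list(estimates = estimates, lower = lower, upper = upper,
                 theta = theta, level = level),
            class = "estimator_replicates")
}

#' Bias, variance and RMSE of replicated estimates
#'
#' `bias = mean(estimates) - theta`; `variance` is the mean squared
#' deviation from the replicate mean (divisor R, the number of
#' replicates); `rmse = sqrt(variance + bias^2)`.
#'
#' @param reps an [estimator_replicates] (or a numeric vector of estimates,
#'   with `theta` supplied)
#' @param theta true parameter (ignored when `reps` carries one)
#' @return named numeric vector `c(bias, variance, rmse)`
#' @export
estimator_summary <- function(reps, theta = NULL) {
  if (inherits(reps, "estimator_replicates")) {
    est <- reps$estimates; theta <- reps$theta
  } else est <- as.numeric(reps)
  stopifnot(!is.null(theta))
  bias <- mean(est) - theta
  variance <- mean((est - mean(est))^2)
  c(bias = bias, variance = variance, rmse = sqrt(variance + bias^2))
}

#' Coverage rate of replicated confidence intervals
#'
#' Fraction of replicates whose interval contains the true parameter; at a
#' nominal 95% level a well-calibrated procedure gives 0.95.
#'
#' @param reps an [estimator_replicates] with intervals
#' @return fraction in `[0, 1]`
#' @export
coverage_rate <- function(reps) {
  stopifnot(inherits(reps, "estimator_replicates"), !is.null(reps$lower))
  mean(reps$lower <= reps$theta & reps$theta <= reps$upper)
}

#' Rubin's rules for pooling multiple-imputation estimates
#'
#' Pools m per-copy estimates and their within-imputation variances:
#' `Qbar = mean(estimates)`, `W = mean(within)`, `B` = between-copy
#' variance (divisor m-1), total variance `T = W + (1 + 1/m) B`, and the
#' interval `Qbar +/- t_nu sqrt(T)` with
#' `nu = (m - 1)(1 + W / ((1 + 1/m) B))^2`. With m = 1 (or B = 0) the
#' single-analysis t-interval on `df_single` degrees of freedom is
#' returned.
#'
#' @param estimates per-copy point estimates
#' @param within per-copy within-imputation variances of the estimate
#' @param level nominal confidence level (default 0.95)
#' @param df_single degrees of freedom for the m = 1 / B = 0 fallback
#'   (default `Inf`, a normal interval)
#' @return list with `estimate`, `within`, `between`, `total_var`, `df`,
#'   `lower`, `upper`, `level`, `m`
#' @export
rubin_pool <- function(estimates, within, level = 0.95, df_single = Inf) {
  m <- length(estimates)
  if (m == 0L) stop("no estimates to pool")
  stopifnot(length(within) == m)
  Q <- mean(estimates)
  W <- mean(within)
  if (m == 1L) {
    Tt <- W; B <- 0; nu <- df_single
  } else {
    B <- stats::var(estimates)
    Tt <- W + (1 + 1 / m) * B
    nu <- if (B > 0) (m - 1) * (1 + W / ((1 + 1 / m) * B))^2 else df_single
  }
  half <- stats::qt(1 - (1 - level) / 2, df = nu) * sqrt(Tt)
  list(estimate = Q, within = W, between = B, total_var = Tt, df = nu,
       lower = Q - half, upper = Q + half, level = level, m = m)
}

#' Accuracy and F1 from a binary confusion table
#'
#' `accuracy = (TP + TN) / (TP + TN + FP + FN)`;
#' `F1 = 2 TP / (2 TP + FP + FN)`.
#'
#' @param tp,tn,fp,fn nonnegative confusion counts
#' @return named numeric vector `c(accuracy, f1)`
#' @export
f1_accuracy <- function(tp, tn, fp, fn) {
  stopifnot(tp >= 0, tn >= 0, fp >= 0, fn >= 0)
  total <- tp + tn + fp + fn
  if (total == 0) stop("empty confusion table")
  f1_den <- 2 * tp + fp + fn
  if (f1_den == 0) stop("F1 undefined: no positives predicted or present")
  c(accuracy = (tp + tn) / total, f1 = 2 * tp / f1_den)
}
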