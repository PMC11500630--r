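#' Distance-importance exponent of midastouch
#'
#' `kappa(R2) = (50 * R2 / (1 + delta - R2))^(3/8)`, the exponent that
#' converts prediction distances into donor probabilities: the better the
#' donor model fits (larger R-squared of the donors' regression), the more
#' the closest donors dominate. At `R2` around 0.9 the exponent is about 10.
#'
#' @param R2 coefficient of determination of the donor model, in `[0, 1]`
#' @param delta small guard constant (default `1e-4`); must be positive
#'   when `R2 = 1`
#' @return a nonnegative number
#' @examples
#' midas_kappa(0.9)      # about 10
#' midas_kappa(0.5, 0)   # 50^(3/8)
#' @export
midas_kappa <- function(R2, delta = 1e-4) {
  stopifnot(R2 >= 0, R2 <= 1, delta >= 0)
  if (delta == 0 && R2 >= 1)
    stop("kappa is undefined at R2 = 1 with delta = 0")
  (50 * R2 / (1 + delta - R2))^(3 / 8)
}

#' Donor probabilities from distances and bootstrap weights
#'
#' Probability of donor i imputing a given recipient:
#' `omega_i * d_i^(-kappa)` normalized over the donor pool, where `omega`
#' are the donors' bootstrap frequencies. Donors at distance exactly zero
#' absorb all mass, split equally among themselves (the `d -> 0` limit).
#'
#' @param distances nonnegative donor-recipient distances
#' @param omegas nonnegative donor weights with positive sum
#' @param kappa nonnegative distance-importance exponent
#' @return a probability vector summing to 1
#' @export
midas_probs <- function(distances, omegas, kappa) {
  stopifnot(length(distances) == length(omegas),
            all(distances >= 0), all(omegas >= 0), kappa >= 0)
  if (sum(omegas) <= 0) stop("all donor weights are zero")
  if (kappa > 0 && any(distances == 0)) {
    pr <- as.numeric(distances == 0)
    return(pr / sum(pr))
  }
  mass <- omegas * distances^(-kappa)
  mass / sum(mass)
}

# one donor index drawn according to the midastouch probabilities
midas_draw <- function(distances, omegas, kappa) {
  pr <- midas_probs(distances, omegas, kappa)
  sample.int(length(pr), 1L, prob = pr)
}

#' Midastouch imputation (distance-weighted donor sampling)
#'
#' A predictive-mean-matching variant in which every observed case can act
#' as donor. Per imputation and per target variable: a bootstrap resample
#' of the donor rows is drawn (an approximate Bayesian bootstrap — donors
#' absent from the resample get weight zero); the donor model is fitted on
#' the resample and both donors and recipients are scored with it (type-2
#' matching); the distance-importance exponent comes from [midas_kappa]
#' applied to the donor model's R-squared; each recipient then receives the
#' observed value of one donor sampled with probability proportional to
#' `omega_i * d_ij^(-kappa)` ([midas_probs]). Binary/categorical targets
#' fall back to logistic/polytomous matching as in [pmm_impute].
#'
#' @param data a [mixed_data]
#' @param mask its [build_mask]
#' @param m number of imputed copies (default 5)
#' @param delta guard constant passed to [midas_kappa]
#' @param seed integer seed
#' @return an [mi_set] of `m` completions
#' @export
midastouch_impute <- function(data, mask = build_mask(data), m = 5L,
                              delta = 1e-4, seed = NULL) {
  stopifnot(m >= 1L)
  numeric_step <- function(X, y, Xmis) {
    n_obs <- length(y)
    if (stats::sd(y) == 0) return(rep(y[1L], nrow(Xmis)))
    # R-squared of the donor model on the full donor pool
    q <- qr(cbind(1, X))
    beta_obs <- qr.coef(q, y)
    beta_obs[is.na(beta_obs)] <- 0
    ss_res <- sum((y - drop(cbind(1, X) %*% beta_obs))^2)
    ss_tot <- sum((y - mean(y))^2)
    if (ss_tot <= 0) stop("degenerate donor model: R-squared undefined")
    R2 <- max(0, min(1, 1 - ss_res / ss_tot))
    kap <- midas_kappa(R2, delta)
    # approximate Bayesian bootstrap: resample donors, weight by frequency
    boot <- sample.int(n_obs, replace = TRUE)
    omega <- tabulate(boot, nbins = n_obs)
    Xb <- X[boot, , drop = FALSE]
    keep <- full_rank_columns(Xb, seq_len(length(boot)))
    beta_star <- qr.coef(qr(cbind(1, Xb[, keep, drop = FALSE])), y[boot])
    beta_star[is.na(beta_star)] <- 0
    yhat_obs <- predict_linear(beta_star, X[, keep, drop = FALSE])
    yhat_mis <- predict_linear(beta_star, Xmis[, keep, drop = FALSE])
    vapply(seq_len(nrow(Xmis)), function(r) {
      d <- abs(yhat_obs - yhat_mis[r])
      y[midas_draw(d, omega, kap)]
    }, 0)
  }
  categorical_step <- function(X, y, Xmis) categorical_pmm_step(X, y, Xmis, 5L)
  chained_impute(data, mask, m = m, seed = seed, method = "midastouch",
                 numeric_step = numeric_step,
                 categorical_step = categorical_step,
                 min_donors = 2L)
}
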