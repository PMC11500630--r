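#' Predictive mean matching (type-2 matching)
#'
#' Multiple imputation by Bayesian-regression predictive mean matching. Per
#' imputation and per target variable, one posterior draw of the regression
#' coefficients is taken ([bayes_regression_draw]); donors and recipients
#' are both scored with the drawn coefficients (type-2 matching, distances
#' in the response space); for each missing cell the `k_donors` observed
#' rows with the closest predictions are located and the observed value of
#' one of them, chosen uniformly, is copied. Binary/categorical targets use
#' logistic/polytomous regression with matching on predicted class
#' probabilities. Multivariate missingness is handled by the
#' chained-equations loop.
#'
#' @param data a [mixed_data]
#' @param mask its [build_mask]
#' @param m number of imputed copies (default 5)
#' @param k_donors size of the donor candidate set (default 5)
#' @param seed integer seed
#' @return an [mi_set] of `m` completions
#' @export
pmm_impute <- function(data, mask = build_mask(data), m = 5L, k_donors = 5L,
                       seed = NULL) {
  stopifnot(m >= 1L, k_donors >= 1L)
  numeric_step <- function(X, y, Xmis) {
    n_obs <- length(y)
    if (n_obs < k_donors)
      stop(sprintf("only %d donors available but k_donors = %d", n_obs, k_donors))
    if (stats::sd(y) == 0) return(rep(y[1L], nrow(Xmis)))
    draw <- bayes_regression_draw(X, y, seed = NULL)
    yhat_obs <- predict_linear(draw$beta_star, X)
    yhat_mis <- predict_linear(draw$beta_star, Xmis)
    out <- numeric(nrow(Xmis))
    for (r in seq_len(nrow(Xmis))) {
      nb <- order(abs(yhat_obs - yhat_mis[r]), seq_len(n_obs))[seq_len(k_donors)]
      out[r] <- y[nb[sample.int(k_donors, 1L)]]
    }
    out
  }
  categorical_step <- function(X, y, Xmis) categorical_pmm_step(X, y, Xmis, k_donors)
  chained_impute(data, mask, m = m, seed = seed, method = "pmm",
                 numeric_step = numeric_step,
                 categorical_step = categorical_step,
                 min_donors = k_donors)
}
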