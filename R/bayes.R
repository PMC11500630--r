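#' Posterior draw of regression coefficients
#'
#' Fits ordinary least squares of `y` on `X` (an intercept is added
#' internally) and takes one random draw from the posterior of the
#' coefficients under the standard noninformative prior: the residual
#' variance is drawn from its scaled inverse chi-squared posterior and the
#' coefficients from a multivariate normal centred at the least-squares
#' estimate with covariance `sigma*^2 (X'X)^-1`. With a perfect (noise-free)
#' fit the posterior is degenerate and the draw equals the estimate.
#'
#' @param X numeric predictor matrix (no intercept column)
#' @param y numeric response
#' @param seed integer seed; the draw is deterministic given `(X, y, seed)`
#' @return an object of class `bayes_draw` with elements `beta_hat`,
#'   `beta_star`, `sigma_hat`, `sigma_star` and `xtx_inv`
#' @export
bayes_regression_draw <- function(X, y, seed = NULL) {
  X <- as.matrix(X)
  n <- length(y)
  Xi <- cbind("(Intercept)" = 1, X)
  p1 <- ncol(Xi)
  if (n <= p1)
    stop("need more observed rows than coefficients for a posterior draw")
  q <- qr(Xi)
  if (q$rank < p1)
    stop("rank-deficient design; drop collinear predictors before the draw")
  beta_hat <- qr.coef(q, y)
  res <- y - Xi %*% beta_hat
  df <- n - p1
  ss <- sum(res^2)
  sigma_hat <- sqrt(ss / df)
  xtx_inv <- chol2inv(qr.R(q))
  dimnames(xtx_inv) <- list(colnames(Xi), colnames(Xi))
  if (sigma_hat < 1e-10 * max(1, sqrt(mean(y^2)))) {
    beta_star <- beta_hat
    sigma_star <- 0
  } else {
    draw <- with_local_seed(seed, {
      s2 <- ss / stats::rchisq(1L, df)
      z <- stats::rnorm(p1)
      list(s2 = s2, z = z)
    })
    sigma_star <- sqrt(draw$s2)
    beta_star <- beta_hat + sigma_star * drop(t(chol(xtx_inv)) %*% draw$z)
  }
  structure(list(beta_hat = beta_hat, beta_star = beta_star,
                 sigma_hat = sigma_hat, sigma_star = sigma_star,
                 xtx_inv = xtx_inv),
            class = "bayes_draw")
}

predict_linear <- function(beta, X) drop(cbind(1, as.matrix(X)) %*% beta)
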