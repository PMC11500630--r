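#' Scale-appropriate (robust) regression fit for one response
#'
#' The per-variable model behind iterative robust model-based imputation.
#' The model family follows the declared response scale:
#' \describe{
#'   \item{continuous}{bounded-influence MM regression (bisquare loss, 95%
#'     Gaussian efficiency, high-breakdown S initialization) via
#'     [MASS::rlm]; returns coefficients, a robust residual scale and the
#'     final observation weights. With `robust = FALSE`, least squares.}
#'   \item{binary}{logistic regression.}
#'   \item{categorical}{polytomous (multinomial) regression.}
#'   \item{count}{Poisson regression with log link; with `robust = TRUE`
#'     iteratively Huber-downweighted on Pearson residuals.}
#'   \item{semicontinuous}{two stages: a logistic model for spike versus
#'     non-spike, then a robust continuous fit on the non-spike part.}
#' }
#' When the least-squares residual scale is numerically zero the data are
#' fitted exactly and the least-squares solution is returned unchanged (no
#' downweighting is needed or possible).
#'
#' @param X numeric predictor matrix (no intercept column; factors already
#'   dummy-coded, collinear columns already dropped)
#' @param y response: numeric for continuous/semicontinuous/count, a factor
#'   for binary/categorical
#' @param family one of `"continuous"`, `"binary"`, `"categorical"`,
#'   `"semicontinuous"`, `"count"`
#' @param robust use the robust variant where one exists (default `TRUE`)
#' @param spike the semi-continuous spike value (default 0)
#' @return an object of class `robust_fit` with elements `family`,
#'   `coefficients` (where meaningful), `scale` (robust residual scale),
#'   `weights` and the fitted components needed for prediction
#' @export
robust_fit <- function(X, y, family = c("continuous", "binary", "categorical",
                                        "semicontinuous", "count"),
                       robust = TRUE, spike = 0) {
  family <- match.arg(family)
  X <- as.matrix(X)
  n <- NROW(X)
  if (n == 0L) n <- length(y)
  fit <- switch(family,
    continuous = fit_continuous(X, y, robust),
    binary = fit_binary(X, y),
    categorical = fit_categorical(X, y),
    count = fit_count(X, y, robust),
    semicontinuous = fit_semicontinuous(X, y, robust, spike))
  fit$family <- family
  class(fit) <- "robust_fit"
  fit
}

fit_continuous <- function(X, y, robust) {
  n <- length(y)
  Xi <- cbind("(Intercept)" = 1, X)
  if (n <= ncol(Xi)) stop("need more observations than coefficients")
  ls <- stats::lm.fit(Xi, y)
  dfree <- max(1L, n - ls$rank)
  sig <- sqrt(sum(ls$residuals^2) / dfree)
  co <- ls$coefficients
  co[is.na(co)] <- 0
  exact <- sig < 1e-10 * max(1, sqrt(mean(y^2)))
  if (!robust || exact) {
    return(list(coefficients = co, scale = if (exact) 0 else sig,
                weights = rep(1, n), robust = FALSE))
  }
  dtr <- data.frame(.y = y, X, check.names = TRUE)
  valid <- function(f) !is.null(f) && all(is.finite(stats::coef(f))) &&
    is.finite(f$s) && f$s > 1e-300
  rf <- tryCatch(
    suppressWarnings(MASS::rlm(.y ~ ., data = dtr, method = "MM", maxit = 100)),
    error = function(e) NULL)
  if (!valid(rf)) rf <- NULL
  if (is.null(rf)) {
    # the S-scale degenerates when the data majority fits exactly; fall back
    # to a high-breakdown LTS start
    lt <- tryCatch(suppressWarnings(MASS::lqs(.y ~ ., data = dtr, method = "lts")),
                   error = function(e) NULL)
    if (!is.null(lt)) {
      res <- y - stats::fitted(lt)
      s <- stats::mad(res)
      tol <- 1e-8 * max(1, sqrt(mean(y^2)))
      if (s < tol) {
        return(list(coefficients = stats::coef(lt), scale = 0,
                    weights = as.numeric(abs(res) <= tol * 10), robust = TRUE))
      }
      rf <- tryCatch(
        suppressWarnings(MASS::rlm(.y ~ ., data = dtr, psi = MASS::psi.bisquare,
                                   init = "lts", maxit = 100)),
        error = function(e) NULL)
      if (!valid(rf)) rf <- NULL
    }
  }
  if (is.null(rf)) {
    rf <- tryCatch(
      suppressWarnings(MASS::rlm(.y ~ ., data = dtr, psi = MASS::psi.huber, maxit = 100)),
      error = function(e) NULL)
    if (!valid(rf)) rf <- NULL
  }
  if (is.null(rf))
    return(list(coefficients = co, scale = sig, weights = rep(1, n), robust = FALSE))
  list(coefficients = stats::coef(rf), scale = rf$s,
       weights = pmin(1, pmax(0, rf$w)), robust = TRUE)
}

fit_binary <- function(X, y, w = NULL) {
  stopifnot(is.factor(y), nlevels(y) == 2L)
  n <- length(y)
  Xi <- cbind(1, X)
  y01 <- as.numeric(y == levels(y)[2L])
  gf <- tryCatch(
    suppressWarnings(stats::glm.fit(Xi, y01, weights = w,
                                    family = stats::binomial())),
    error = function(e) NULL)
  beta <- if (is.null(gf)) c(stats::qlogis(pmin(pmax(mean(y01), 1e-6), 1 - 1e-6)),
                             rep(0, ncol(X)))
          else { b <- gf$coefficients; b[is.na(b)] <- 0; b }
  list(coefficients = beta, levels = levels(y), scale = NA_real_,
       weights = rep(1, n))
}

fit_categorical <- function(X, y) {
  stopifnot(is.factor(y))
  if (nlevels(droplevels(y)) < 2L) {
    # one observed class: predict it with certainty
    return(list(constant_class = as.character(y[1L]), levels = levels(y),
                scale = NA_real_, weights = rep(1, length(y))))
  }
  dtr <- data.frame(.y = y, X, check.names = TRUE)
  mfit <- nnet::multinom(.y ~ ., data = dtr, trace = FALSE, maxit = 200)
  list(multinom = mfit, levels = levels(y), scale = NA_real_,
       weights = rep(1, length(y)))
}

fit_count <- function(X, y, robust) {
  n <- length(y)
  Xi <- cbind(1, X)
  w <- rep(1, n)
  beta <- NULL
  iters <- if (robust) 15L else 1L
  for (it in seq_len(iters)) {
    gf <- suppressWarnings(stats::glm.fit(Xi, y, weights = w,
                                          family = stats::poisson()))
    beta <- gf$coefficients
    beta[is.na(beta)] <- 0
    if (!robust) break
    mu <- pmax(exp(drop(Xi %*% beta)), 1e-8)
    r <- (y - mu) / sqrt(mu)
    s <- stats::mad(r, center = 0)
    if (!is.finite(s) || s < 1e-8) break
    w_new <- MASS::psi.huber(r / s, k = 1.345)
    if (max(abs(w_new - w)) < 1e-6) { w <- w_new; break }
    w <- w_new
  }
  list(coefficients = beta, scale = NA_real_, weights = w, robust = robust)
}

fit_semicontinuous <- function(X, y, robust, spike) {
  n <- length(y)
  nonspike <- y != spike
  ind <- factor(ifelse(nonspike, "nonspike", "spike"),
                levels = c("spike", "nonspike"))
  stage1 <- if (length(unique(ind)) < 2L) {
    list(constant = as.character(ind[1L]))
  } else {
    fit_binary(X, ind)
  }
  stage2 <- if (sum(nonspike) > ncol(X) + 1L) {
    fit_continuous(X[nonspike, , drop = FALSE], y[nonspike], robust)
  } else if (any(nonspike)) {
    list(coefficients = c(stats::median(y[nonspike]), rep(0, ncol(X))),
         scale = stats::mad(y[nonspike]), weights = NULL, robust = FALSE)
  } else {
    NULL
  }
  list(stage1 = stage1, stage2 = stage2, spike = spike,
       scale = if (is.null(stage2)) 0 else stage2$scale,
       weights = rep(1, n))
}

#' Predictions from a [robust_fit]
#'
#' @param object a `robust_fit`
#' @param X predictor matrix of the rows to predict (same columns as fitted)
#' @param stochastic if `TRUE`, draw from the fitted conditional
#'   distribution (residual noise for continuous responses, class sampling
#'   for categorical ones) instead of returning the central prediction
#' @param noise_inflation multiplier applied to the continuous residual
#'   scale when `stochastic = TRUE`
#' @param ... unused
#' @return numeric vector or factor of predictions
#' @export
predict.robust_fit <- function(object, X, stochastic = FALSE,
                               noise_inflation = 1, ...) {
  X <- as.matrix(X)
  nr <- nrow(X)
  switch(object$family,
    continuous = {
      mu <- predict_linear(object$coefficients, X)
      if (stochastic && object$scale > 0)
        mu <- mu + stats::rnorm(nr, 0, object$scale * noise_inflation)
      mu
    },
    count = {
      mu <- pmax(exp(predict_linear(object$coefficients, X)), 1e-8)
      if (stochastic) stats::rpois(nr, mu) else round_half_up(mu)
    },
    binary = {
      p <- stats::plogis(predict_linear(object$coefficients, X))
      lev <- object$levels
      cls <- if (stochastic) ifelse(stats::runif(nr) < p, lev[2L], lev[1L])
             else ifelse(p >= 0.5, lev[2L], lev[1L])
      factor(cls, levels = lev)
    },
    categorical = {
      lev <- object$levels
      if (!is.null(object$constant_class))
        return(factor(rep(object$constant_class, nr), levels = lev))
      newd <- data.frame(X, check.names = TRUE)
      pr <- stats::predict(object$multinom, newdata = newd, type = "probs")
      if (is.null(dim(pr))) pr <- matrix(pr, nrow = nr)
      cls <- apply(pr, 1L, function(p) {
        p <- pmax(p, 0)
        lv <- colnames(pr) %||% levels(droplevels(factor(lev)))
        if (stochastic) sample(lv, 1L, prob = p + 1e-12) else lv[which.max(p)]
      })
      factor(cls, levels = lev)
    },
    semicontinuous = {
      p_non <- if (!is.null(object$stage1$constant)) {
        rep(as.numeric(object$stage1$constant == "nonspike"), nr)
      } else {
        stats::plogis(predict_linear(object$stage1$coefficients, X))
      }
      use_cont <- if (stochastic) stats::runif(nr) < p_non else p_non >= 0.5
      out <- rep(object$spike, nr)
      if (any(use_cont) && !is.null(object$stage2)) {
        mu <- predict_linear(object$stage2$coefficients, X[use_cont, , drop = FALSE])
        if (stochastic && isTRUE(object$stage2$scale > 0))
          mu <- mu + stats::rnorm(sum(use_cont), 0,
                                  object$stage2$scale * noise_inflation)
        out[use_cont] <- mu
      }
      out
    })
}
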