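#' Iterative random-forest imputation
#'
#' Mean/mode initialization followed by chained random-forest regression:
#' per sweep, each incomplete variable is re-fitted on all remaining
#' variables over its observed rows and its missing cells are replaced by
#' the forest predictions. Variables are processed in ascending order of
#' missing count. The sweep repeats until the imputed values stabilize —
#' for a continuous variable the summed squared change divided by the
#' summed square of the current values, for a categorical variable the
#' fraction of changed cells, each below `delta` — or until `maxit` sweeps.
#' Within one call the forest seed per variable is held fixed across sweeps
#' so stabilization is well defined.
#'
#' @param data a [mixed_data]
#' @param mask its [build_mask]
#' @param trees trees per forest (default 100)
#' @param delta convergence constant (default `1e-3`)
#' @param maxit maximum sweeps (default 10)
#' @param seed integer seed
#' @return a [completed_data] with attributes `iterations`, `converged`
#'   and `conv_stats` (the per-sweep stabilization statistics)
#' @export
forest_impute <- function(data, mask = build_mask(data), trees = 100L,
                          delta = 1e-3, maxit = 10L, seed = NULL) {
  validate_mask(mask, data)
  stopifnot(trees >= 1L, delta > 0, maxit >= 1L)
  mis_cols <- which(mask$per_column > 0L)
  if (!length(mis_cols)) {
    cp <- completed_data(data, mask, method = "forest", seed = seed)
    attr(cp, "iterations") <- 0L
    attr(cp, "converged") <- TRUE
    return(cp)
  }
  ord <- mis_cols[order(mask$per_column[mis_cols])]
  seed0 <- seed %||% 0L
  df <- impute_mean(data, mask)$data$data

  conv_stats <- NULL
  converged <- FALSE
  it <- 0L
  while (it < maxit && !converged) {
    it <- it + 1L
    stat <- stats::setNames(numeric(length(ord)), names(data$data)[ord])
    for (idx in seq_along(ord)) {
      j <- ord[idx]
      target <- names(data$data)[j]
      obs_rows <- which(mask$entries[, j] == 0L)
      mis_rows <- which(mask$entries[, j] == 1L)
      y <- data$data[[target]][obs_rows]
      pred <- if ((is.factor(y) && nlevels(droplevels(y)) < 2L) ||
                  (!is.factor(y) && stats::sd(y) == 0)) {
        rep(y[1L], length(mis_rows))  # constant column: nothing to learn
      } else {
        xcols <- setdiff(names(df), target)
        # probability forests + deterministic argmax for factors: majority
        # voting breaks ties nondeterministically
        fit <- ranger::ranger(x = df[obs_rows, xcols, drop = FALSE], y = y,
                              num.trees = trees, num.threads = 1L,
                              probability = is.factor(y),
                              seed = derive_seed(seed0, "forest", j))
        pr <- stats::predict(fit, data = df[mis_rows, xcols, drop = FALSE],
                             num.threads = 1L)$predictions
        if (is.factor(y))
          factor(colnames(pr)[max.col(pr, ties.method = "first")],
                 levels = levels(y))
        else pr
      }
      old <- df[[target]][mis_rows]
      stat[idx] <- if (is_numeric_col(data, j)) {
        num <- sum((as.numeric(pred) - as.numeric(old))^2)
        den <- sum(as.numeric(pred)^2)
        if (den > 0) num / den else num
      } else {
        mean(as.character(pred) != as.character(old))
      }
      df[[target]][mis_rows] <- if (data$scales[[j]] == "count")
        round_half_up(as.numeric(pred)) else pred
    }
    conv_stats <- rbind(conv_stats, stat)
    converged <- all(stat < delta)
  }
  rownames(conv_stats) <- NULL
  cp <- completed_data(set_values(data, df), mask, method = "forest", seed = seed)
  attr(cp, "iterations") <- it
  attr(cp, "converged") <- converged
  attr(cp, "conv_stats") <- conv_stats
  cp
}

#' Bootstrap boosted-tree imputation with predictive mean matching
#'
#' Per imputed copy: missing cells are initialized simply; the incomplete
#' variables are processed in ascending order of missing count; for each, a
#' gradient-boosted tree model is fitted on a bootstrap resample of the
#' rows observed in the target, all rows are scored, and every missing cell
#' is imputed by predictive mean matching — copying the observed value of
#' one of the `k` donors with the closest prediction (categorical targets
#' are matched on their predicted class-probability vectors by Euclidean
#' distance). Independent bootstraps per copy carry the model uncertainty.
#'
#' @param data a [mixed_data]
#' @param mask its [build_mask]
#' @param m number of imputed copies (default 5)
#' @param rounds boosting rounds (default 100)
#' @param eta learning rate (default 0.1)
#' @param k donors in the matching set (default 5)
#' @param seed integer seed
#' @return an [mi_set] of `m` completions
#' @export
boosted_impute <- function(data, mask = build_mask(data), m = 5L,
                           rounds = 100L, eta = 0.1, k = 5L, seed = NULL) {
  validate_mask(mask, data)
  stopifnot(m >= 1L, rounds >= 1L, k >= 1L)
  mis_cols <- which(mask$per_column > 0L)
  if (!length(mis_cols)) {
    cp <- completed_data(data, mask, method = "boost", seed = seed)
    return(mi_set(rep(list(cp), m)))
  }
  ord <- mis_cols[order(mask$per_column[mis_cols])]
  seed0 <- seed %||% 0L
  df_init <- impute_mean(data, mask)$data$data

  one_copy <- function(copy) {
    copy_seed <- derive_seed(seed0, "boost", copy)
    df <- with_local_seed(copy_seed, {
      df <- df_init
      for (idx in seq_along(ord)) {
        j <- ord[idx]
        target <- names(data$data)[j]
        obs_rows <- which(mask$entries[, j] == 0L)
        mis_rows <- which(mask$entries[, j] == 1L)
        y <- data$data[[target]][obs_rows]
        if (length(obs_rows) < k)
          stop(sprintf("column '%s' has fewer donors than k = %d", target, k))
        if ((is.factor(y) && nlevels(droplevels(y)) < 2L) ||
            (!is.factor(y) && stats::sd(y) == 0)) {
          df[[target]][mis_rows] <- y[1L]
          next
        }
        X <- build_design(df, exclude = target)
        boot <- sample.int(length(obs_rows), replace = TRUE)
        Xb <- X[obs_rows[boot], , drop = FALSE]
        xgb_seed <- derive_seed(copy_seed, "xgb", j)
        if (is.factor(y)) {
          yb <- droplevels(y[boot])
          probs <- if (nlevels(yb) < 2L) {
            # degenerate resample: fall back to the donor class frequencies
            fr <- as.numeric(table(y)) / length(y)
            matrix(fr, nrow(X), length(fr), byrow = TRUE)
          } else {
            bst <- xgboost::xgboost(Xb, yb, nrounds = rounds,
                                    learning_rate = eta, max_depth = 6,
                                    nthreads = 1L, seed = xgb_seed, verbosity = 0)
            pr <- stats::predict(bst, X, type = "response")
            if (is.matrix(pr)) pr else cbind(1 - pr, pr)
          }
          p_obs <- probs[obs_rows, , drop = FALSE]
          for (r in mis_rows) {
            d <- sqrt(rowSums((p_obs -
              matrix(probs[r, ], nrow(p_obs), ncol(probs), byrow = TRUE))^2))
            nb <- order(d, seq_along(obs_rows))[seq_len(min(k, length(obs_rows)))]
            df[[target]][r] <- y[nb[sample.int(length(nb), 1L)]]
          }
        } else {
          bst <- xgboost::xgboost(Xb, y[boot], nrounds = rounds,
                                  learning_rate = eta, max_depth = 6,
                                  nthreads = 1L, seed = xgb_seed, verbosity = 0)
          pred <- stats::predict(bst, X)
          p_obs <- pred[obs_rows]
          for (r in mis_rows) {
            nb <- order(abs(p_obs - pred[r]), seq_along(obs_rows))[seq_len(min(k, length(obs_rows)))]
            val <- y[nb[sample.int(length(nb), 1L)]]
            df[[target]][r] <- if (data$scales[[j]] == "count") round_half_up(val) else val
          }
        }
      }
      df
    })
    completed_data(set_values(data, df), mask, method = "boost", seed = copy_seed)
  }
  mi_set(lapply(seq_len(m), one_copy))
}
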