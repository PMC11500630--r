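#' Iterative robust model-based imputation (IRMI)
#'
#' Chained-equations imputation for mixed-scale data in which every
#' per-variable regression is robust, so that outliers in predictors or
#' response cannot drag the imputations away from the bulk of the data.
#'
#' The algorithm: (1) initialize missing cells by k-nearest-neighbour
#' imputation; (2) sort the variables by decreasing number of missing
#' cells; (3) cycle over the incomplete variables, regressing the observed
#' part of each on all remaining variables with the scale-appropriate
#' (robust) model ([robust_fit]) and re-imputing its missing part by the
#' model prediction; (4) stop when for every variable the summed squared
#' change of the imputed values falls below `delta_conv` (categorical
#' variables: the fraction of changed cells), or after `maxit` sweeps;
#' (5) one final stochastic sweep replaces each imputed cell by the model
#' prediction plus a residual draw with robust scale inflated by
#' `sqrt(1 + n_mis/n)`, which widens the imputation spread with the number
#' of missing responses. With `multiple > 1` the stochastic sweep is rerun
#' with fresh noise per copy, giving a multiple-imputation set that carries
#' the imputation uncertainty.
#'
#' The robust fits use resampling-based initialization; within one call the
#' resampling seed per variable is held fixed across sweeps so that the
#' iteration is a deterministic fixed-point map and the stopping rule is
#' well defined.
#'
#' @param data a [mixed_data]
#' @param mask its [build_mask]
#' @param robust use robust per-variable fits (`FALSE` gives the
#'   least-squares variant, useful only for comparison)
#' @param noise run the final stochastic sweep (default `TRUE`); with
#'   `FALSE` the deterministic model predictions are returned
#' @param multiple number of imputed copies (default 1; requires `noise`)
#' @param delta_conv convergence constant (default `1e-4`)
#' @param maxit maximum number of sweeps (default 10)
#' @param seed integer seed
#' @param init_k neighbours for the kNN initialization (default 5)
#' @param step_selection stepwise AIC model selection per variable; accepted
#'   for interface compatibility but not implemented (all remaining
#'   variables are always used)
#' @return a [completed_data] (`multiple = 1`) or [mi_set], with attributes
#'   `iterations`, `converged` and `conv_stats`
#' @export
irmi_impute <- function(data, mask = build_mask(data), robust = TRUE,
                        noise = TRUE, multiple = 1L, delta_conv = 1e-4,
                        maxit = 10L, seed = NULL, init_k = 5L,
                        step_selection = FALSE) {
  validate_mask(mask, data)
  stopifnot(multiple >= 1L, maxit >= 1L, delta_conv > 0)
  if (step_selection)
    warning("stepwise model selection is not implemented; using all remaining variables")
  if (multiple > 1L && !noise)
    stop("multiple imputation needs the stochastic sweep (noise = TRUE)")
  mis_cols <- which(mask$per_column > 0L)
  method_tag <- if (robust) "irmi" else "irmi_ols"
  if (!length(mis_cols)) {
    cp <- completed_data(data, mask, method = method_tag, seed = seed)
    attr(cp, "iterations") <- 0L
    attr(cp, "converged") <- TRUE
    if (multiple > 1L) return(mi_set(rep(list(cp), multiple)))
    return(cp)
  }
  ord <- mis_cols[order(-mask$per_column[mis_cols])]
  names_ord <- names(data$data)[ord]
  n <- nrow(data$data)
  seed0 <- seed %||% 0L

  df <- impute_knn(data, mask, k = init_k)$data$data

  fits <- designs <- stats::setNames(vector("list", length(ord)), names_ord)
  conv_stats <- NULL
  converged <- FALSE
  it <- 0L
  while (it < maxit && !converged) {
    it <- it + 1L
    stat <- stats::setNames(numeric(length(ord)), names_ord)
    for (idx in seq_along(ord)) {
      j <- ord[idx]
      target <- names(data$data)[j]
      obs_rows <- which(mask$entries[, j] == 0L)
      mis_rows <- which(mask$entries[, j] == 1L)
      X <- build_design(df, exclude = target)
      keep <- full_rank_columns(X, obs_rows)
      X <- X[, keep, drop = FALSE]
      fit <- with_local_seed(derive_seed(seed0, "irmi_fit", j),
        robust_fit(X[obs_rows, , drop = FALSE], data$data[[target]][obs_rows],
                   family = data$scales[[j]], robust = robust,
                   spike = if (data$scales[[j]] == "semicontinuous") data$spike[[target]] else 0))
      pred <- stats::predict(fit, X[mis_rows, , drop = FALSE])
      old <- df[[target]][mis_rows]
      stat[idx] <- if (is_numeric_col(data, j)) sum((as.numeric(pred) - as.numeric(old))^2)
                   else mean(as.character(pred) != as.character(old))
      df[[target]][mis_rows] <- pred
      fits[[target]] <- fit
      designs[[target]] <- keep
    }
    conv_stats <- rbind(conv_stats, stat)
    converged <- all(stat < delta_conv)
  }
  rownames(conv_stats) <- NULL
  if (!converged)
    warning(sprintf("IRMI did not stabilize within %d sweeps; returning the last iterate", maxit))

  finish <- function(dfc, copy_seed) {
    if (noise) {
      dfc <- with_local_seed(copy_seed, {
        for (idx in seq_along(ord)) {
          j <- ord[idx]
          target <- names(data$data)[j]
          mis_rows <- which(mask$entries[, j] == 1L)
          X <- build_design(dfc, exclude = target)
          X <- X[, designs[[target]], drop = FALSE]
          infl <- sqrt(1 + length(mis_rows) / n)
          dfc[[target]][mis_rows] <- stats::predict(
            fits[[target]], X[mis_rows, , drop = FALSE],
            stochastic = TRUE, noise_inflation = infl)
        }
        dfc
      })
    }
    cp <- completed_data(set_values(data, dfc), mask, method = method_tag,
                         seed = copy_seed)
    attr(cp, "iterations") <- it
    attr(cp, "converged") <- converged
    attr(cp, "conv_stats") <- conv_stats
    cp
  }

  if (multiple == 1L) return(finish(df, seed))
  mi_set(lapply(seq_len(multiple), function(cc)
    finish(df, derive_seed(seed0, "irmi_copy", cc))))
}
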