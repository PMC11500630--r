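# Chained-equations driver shared by the PMM and midastouch imputers.
#
# With missingness in a single variable the loop reduces to one univariate
# pass. With multivariate missingness the missing cells are initialized by
# column medians/modes and the variables are cycled in ascending order of
# missing count for a fixed number of cycles (the usual fully-conditional-
# specification convention), re-imputing each variable from the current
# completion of the others.

chained_impute <- function(data, mask, m, seed, method,
                           numeric_step, categorical_step,
                           cycles = 5L, min_donors = 1L) {
  validate_mask(mask, data)
  df0 <- data$data
  mis_cols <- which(mask$per_column > 0L)
  if (!length(mis_cols)) {
    cp <- completed_data(data, mask, method = method, seed = seed)
    return(mi_set(rep(list(cp), m)))
  }
  for (j in mis_cols) {
    n_don <- sum(!is.na(df0[[j]]))
    if (n_don < min_donors)
      stop(sprintf("column '%s' has %d donors; %d required", names(df0)[j], n_don, min_donors))
  }
  ord <- mis_cols[order(mask$per_column[mis_cols])]
  n_cycles <- if (length(mis_cols) == 1L) 1L else cycles

  completions <- vector("list", m)
  for (copy in seq_len(m)) {
    copy_seed <- if (is.null(seed)) NULL else derive_seed(seed, "chain", copy)
    df <- with_local_seed(copy_seed, {
      df <- df0
      for (j in mis_cols) {   # starting values for the cycling
        mis <- is.na(df[[j]])
        obs <- df[[j]][!mis]
        df[[j]][mis] <- if (is_numeric_col(data, j)) stats::median(obs)
                        else factor(stat_mode(obs), levels = levels(df[[j]]))
      }
      for (cyc in seq_len(n_cycles)) {
        for (j in ord) {
          target <- names(df0)[j]
          obs_rows <- which(mask$entries[, j] == 0L)
          mis_rows <- which(mask$entries[, j] == 1L)
          X <- build_design(df, exclude = target)
          keep <- full_rank_columns(X, obs_rows)
          X <- X[, keep, drop = FALSE]
          y <- df0[[j]][obs_rows]
          imputed <- if (is_numeric_col(data, j)) {
            numeric_step(X[obs_rows, , drop = FALSE], y,
                         X[mis_rows, , drop = FALSE])
          } else {
            categorical_step(X[obs_rows, , drop = FALSE], y,
                             X[mis_rows, , drop = FALSE])
          }
          df[[j]][mis_rows] <- imputed
        }
      }
      df
    })
    completions[[copy]] <- completed_data(set_values(data, df), mask,
                                          method = method, seed = copy_seed)
  }
  mi_set(completions)
}

# Donor matching for categorical/binary targets, shared by PMM and
# midastouch: a logistic (binary) or polytomous (multi-category) model is
# fitted on a bootstrap resample of the donors (model uncertainty), both
# donors and recipients are scored with it, and each recipient copies the
# observed category of one of the k donors with the closest predicted class
# probabilities.
categorical_pmm_step <- function(X, y, Xmis, k_donors = 5L) {
  n_obs <- length(y)
  lev <- levels(y)
  boot <- sample.int(n_obs, replace = TRUE)
  probs_all <- tryCatch({
    if (length(lev) == 2L) {
      Xi <- cbind(1, X)
      fit <- suppressWarnings(stats::glm.fit(Xi[boot, , drop = FALSE],
                                             as.numeric(y[boot] == lev[2L]),
                                             family = stats::binomial()))
      beta <- fit$coefficients
      beta[is.na(beta)] <- 0
      p <- stats::plogis(drop(cbind(1, rbind(X, Xmis)) %*% beta))
      cbind(1 - p, p)
    } else {
      dtr <- data.frame(.y = y[boot], X[boot, , drop = FALSE], check.names = TRUE)
      fit <- nnet::multinom(.y ~ ., data = dtr, trace = FALSE, maxit = 200)
      newd <- data.frame(rbind(X, Xmis), check.names = TRUE)
      pr <- stats::predict(fit, newdata = newd, type = "probs")
      if (is.null(dim(pr))) pr <- cbind(1 - pr, pr)
      pr
    }
  }, error = function(e) {
    # degenerate resample (e.g. one class): fall back to the class frequencies
    fr <- as.numeric(table(factor(y[boot], levels = lev))) / n_obs
    matrix(fr, nrow = n_obs + nrow(Xmis), ncol = length(lev), byrow = TRUE)
  })
  p_obs <- probs_all[seq_len(n_obs), , drop = FALSE]
  p_mis <- probs_all[-seq_len(n_obs), , drop = FALSE]
  k <- min(k_donors, n_obs)
  out <- y[rep(1L, nrow(Xmis))]
  for (r in seq_len(nrow(Xmis))) {
    d <- sqrt(rowSums((p_obs - matrix(p_mis[r, ], n_obs, ncol(p_obs), byrow = TRUE))^2))
    nb <- order(d, seq_len(n_obs))[seq_len(k)]
    out[r] <- y[nb[sample.int(k, 1L)]]
  }
  out
}
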