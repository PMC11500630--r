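#' Mean / median / mode imputation
#'
#' Replaces every missing numeric cell by the chosen column statistic of the
#' observed cells and every missing binary/categorical cell by the observed
#' mode. A benchmark method only: it ignores all between-variable structure.
#'
#' @param data a [mixed_data]
#' @param mask its [build_mask] (recomputed by default)
#' @param statistic `"mean"`, `"median"` or `"mode"` for numeric columns;
#'   categorical columns always receive the mode
#' @return a [completed_data]
#' @export
impute_mean <- function(data, mask = build_mask(data),
                        statistic = c("mean", "median", "mode")) {
  statistic <- match.arg(statistic)
  validate_mask(mask, data)
  df <- data$data
  for (j in seq_along(df)) {
    mis <- is.na(df[[j]])
    if (!any(mis)) next
    obs <- df[[j]][!mis]
    if (!length(obs)) stop(sprintf("column '%s' is fully missing", names(df)[j]))
    fill <- if (is_numeric_col(data, j)) {
      v <- switch(statistic, mean = mean(obs), median = stats::median(obs),
                  mode = as.numeric(stat_mode(obs)))
      if (data$scales[[j]] == "count") round_half_up(v) else v
    } else {
      factor(stat_mode(obs), levels = levels(df[[j]]))
    }
    df[[j]][mis] <- fill
  }
  completed_data(set_values(data, df), mask, method = paste0(statistic, "_imputation"))
}

#' Random hotdeck imputation
#'
#' Each missing cell receives the value of a donor row drawn uniformly from
#' the rows observed in that variable (simple random hotdeck, no sorting or
#' domain variables).
#'
#' @param data a [mixed_data]
#' @param mask its [build_mask]
#' @param seed integer seed
#' @return a [completed_data]
#' @export
impute_hotdeck <- function(data, mask = build_mask(data), seed = NULL) {
  validate_mask(mask, data)
  df <- with_local_seed(seed, {
    df <- data$data
    for (j in seq_along(df)) {
      mis <- which(is.na(df[[j]]))
      if (!length(mis)) next
      donors <- which(!is.na(df[[j]]))
      if (!length(donors)) stop(sprintf("no donors for column '%s'", names(df)[j]))
      df[[j]][mis] <- df[[j]][donors[sample.int(length(donors), length(mis), replace = TRUE)]]
    }
    df
  })
  completed_data(set_values(data, df), mask, method = "hotdeck", seed = seed)
}

#' k-nearest-neighbour imputation with Gower distance
#'
#' For every row with missing cells, the `k` rows observed in the target
#' variable with the smallest Gower distance (computed over the commonly
#' observed variables) are located; numeric targets are imputed by the
#' donors' median, categorical targets by their most frequent category.
#' Ties at the k-th distance are broken toward the lexicographically
#' smallest row ids, and mode ties toward the smallest category label, so
#' the imputation is deterministic. A recipient row that shares no observed
#' variable with any donor (e.g. a fully missing row) has no defined Gower
#' distance; such cells fall back to the column median/mode with a warning.
#'
#' @param data a [mixed_data]
#' @param mask its [build_mask]
#' @param k number of neighbours (default 5)
#' @param seed unused (the method is deterministic); kept so all imputers
#'   share a signature
#' @param weights optional Gower variable weights, see [gower_context]
#' @return a [completed_data]
#' @export
impute_knn <- function(data, mask = build_mask(data), k = 5L, seed = NULL,
                       weights = NULL) {
  validate_mask(mask, data)
  stopifnot(k >= 1L)
  ctx <- gower_context(data, weights)
  df <- data$data
  out <- df
  recipients <- which(rowSums(mask$entries) > 0L)
  for (i in recipients) {
    d <- gower_to_all(data, i, ctx)
    for (j in which(mask$entries[i, ] == 1L)) {
      pool <- which(!is.na(df[[j]]))
      if (!length(pool))
        stop(sprintf("no donor for column '%s'", names(df)[j]))
      pool <- pool[!is.na(d[pool])]
      if (!length(pool)) {
        warning(sprintf(
          "row %d shares no observed variable with any donor of '%s'; falling back to the column median/mode",
          i, names(df)[j]))
        obs <- df[[j]][!is.na(df[[j]])]
        out[[j]][i] <- if (is_numeric_col(data, j)) {
          v <- stats::median(obs)
          if (data$scales[[j]] == "count") round_half_up(v) else v
        } else factor(stat_mode(obs), levels = levels(df[[j]]))
        next
      }
      ord <- pool[order(d[pool], data$row_ids[pool])]
      nb <- ord[seq_len(min(k, length(ord)))]
      vals <- df[[j]][nb]
      out[[j]][i] <- if (is_numeric_col(data, j)) {
        v <- stats::median(vals)
        if (data$scales[[j]] == "count") round_half_up(v) else v
      } else {
        factor(stat_mode(vals), levels = levels(df[[j]]))
      }
    }
  }
  completed_data(set_values(data, out), mask, method = "knn", seed = seed)
}
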