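#' Gower distance context
#'
#' Precomputes what the Gower dissimilarity needs: the observed ranges
#' (max - min) of the numeric-scale columns of a dataset and the per-variable
#' weights. Ranges are taken over the observed values of the full input
#' dataset — not per donor pool — so distances are stable under amputation.
#' Constant columns contribute dissimilarity 0.
#'
#' @param data a [mixed_data]
#' @param weights optional nonnegative per-variable weights (default equal);
#'   may be named by column
#' @return an object of class `gower_context`
#' @export
gower_context <- function(data, weights = NULL) {
  stopifnot(inherits(data, "mixed_data"))
  p <- ncol(data$data)
  if (is.null(weights)) weights <- rep(1, p)
  if (!is.null(names(weights))) weights <- weights[names(data$data)]
  stopifnot(length(weights) == p, all(weights >= 0), any(weights > 0))
  ranges <- vapply(seq_len(p), function(j) {
    if (!is_numeric_col(data, j)) return(NA_real_)
    v <- data$data[[j]]
    v <- v[!is.na(v)]
    if (!length(v)) return(NA_real_)
    diff(range(v))
  }, 0)
  structure(list(scales = data$scales, ranges = stats::setNames(ranges, names(data$data)),
                 weights = stats::setNames(weights, names(data$data))),
            class = "gower_context")
}

#' Gower dissimilarity between two rows
#'
#' The weighted mean of per-variable dissimilarities over the variables
#' observed in *both* rows: `|a - b| / range` for numeric scales
#' (continuous, semi-continuous, count) and 0/1 disagreement for
#' binary/categorical scales. Symmetric, bounded in `[0, 1]`, and zero iff
#' all commonly observed variables agree.
#'
#' @param row_a,row_b one-row data frames (or list-like rows) conforming to
#'   the context's schema
#' @param ctx a [gower_context]
#' @return a number in `[0, 1]`
#' @examples
#' md <- mixed_data(data.frame(x = c(2, 7, 12)), scales = "continuous")
#' ctx <- gower_context(md)
#' gower_distance(md$data[1, , drop = FALSE], md$data[2, , drop = FALSE], ctx)
#' @export
gower_distance <- function(row_a, row_b, ctx) {
  stopifnot(inherits(ctx, "gower_context"))
  vars <- names(ctx$scales)
  num <- dem <- 0
  for (v in vars) {
    a <- row_a[[v]]
    b <- row_b[[v]]
    if (is.na(a) || is.na(b)) next
    w <- ctx$weights[[v]]
    d <- if (ctx$scales[[v]] %in% numeric_scales) {
      rg <- ctx$ranges[[v]]
      if (is.na(rg) || rg == 0) 0 else min(abs(as.numeric(a) - as.numeric(b)) / rg, 1)
    } else {
      as.numeric(as.character(a) != as.character(b))
    }
    num <- num + w * d
    dem <- dem + w
  }
  if (dem == 0)
    stop("Gower distance undefined: no commonly observed variable")
  num / dem
}

# Vectorized Gower distances from one recipient row to every row of a dataset.
# Rows sharing no observed variable with the recipient get distance NA.
gower_to_all <- function(data, recipient_row, ctx) {
  df <- data$data
  n <- nrow(df)
  num <- dem <- numeric(n)
  for (v in names(ctx$scales)) {
    a <- df[recipient_row, v]
    if (is.na(a)) next
    col <- df[[v]]
    ok <- !is.na(col)
    w <- ctx$weights[[v]]
    if (ctx$scales[[v]] %in% numeric_scales) {
      rg <- ctx$ranges[[v]]
      d <- if (is.na(rg) || rg == 0) rep(0, n) else pmin(abs(col - as.numeric(a)) / rg, 1)
    } else {
      d <- as.numeric(as.character(col) != as.character(a))
    }
    num[ok] <- num[ok] + w * d[ok]
    dem[ok] <- dem[ok] + w
  }
  ifelse(dem > 0, num / dem, NA_real_)
}
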