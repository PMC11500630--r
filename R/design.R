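# Design-matrix plumbing shared by the model-based imputers.

# Numeric design matrix (no intercept column) from the columns of `df`
# other than `exclude`, dummy-coding factors. `df` must be complete.
build_design <- function(df, exclude = character(0)) {
  keep <- setdiff(names(df), exclude)
  if (!length(keep)) return(matrix(numeric(0), nrow(df), 0))
  cols <- lapply(keep, function(nm) {
    v <- df[[nm]]
    if (is.factor(v)) {
      lev <- levels(v)
      if (length(lev) < 2L) return(NULL)
      m <- vapply(lev[-1L], function(l) as.numeric(v == l), numeric(length(v)))
      m <- matrix(m, nrow = length(v))
      colnames(m) <- paste(nm, lev[-1L], sep = ".")
      m
    } else {
      matrix(as.numeric(v), ncol = 1, dimnames = list(NULL, nm))
    }
  })
  do.call(cbind, cols[!vapply(cols, is.null, TRUE)])
}

# Drop columns of X until the fit rows give a full-rank design (intercept
# included). Returns the indices of the kept columns.
full_rank_columns <- function(X, rows) {
  if (ncol(X) == 0L) return(integer(0))
  Xi <- cbind(1, X[rows, , drop = FALSE])
  q <- qr(Xi)
  keep <- sort(q$pivot[seq_len(q$rank)])
  setdiff(keep, 1L) - 1L
}
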