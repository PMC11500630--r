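#' @keywords internal
"_PACKAGE"

MEASUREMENT_SCALES <- c("continuous", "semicontinuous", "binary", "categorical", "count")

numeric_scales <- c("continuous", "semicontinuous", "count")

#' Mixed-type dataset with per-column scale declarations
#'
#' The universal input container of the package: a rectangular table in which
#' every column carries a declared measurement scale (continuous,
#' semi-continuous, binary, categorical or count). Binary and categorical
#' columns are stored as factors whose levels are the declared category
#' labels; semi-continuous columns additionally declare the constant spike
#' value (usually zero) at which their point mass sits.
#'
#' @param values data frame of cell values. `NA` is the missing sentinel.
#'   Character columns declared binary/categorical are converted to factors.
#' @param scales character vector of scales, one per column, each one of
#'   `"continuous"`, `"semicontinuous"`, `"binary"`, `"categorical"`,
#'   `"count"`. May be named by column.
#' @param spike named numeric vector of spike values for semi-continuous
#'   columns; defaults to 0 for each.
#' @param row_ids optional unique row labels; defaults to `"1"..."n"`.
#' @return An object of class `mixed_data` with elements `data`, `scales`,
#'   `spike` and `row_ids`.
#' @examples
#' md <- mixed_data(
#'   data.frame(age = c(31, 45, NA), group = c("a", "b", "a")),
#'   scales = c(age = "continuous", group = "binary")
#' )
#' n_missing(md)
#' @export
mixed_data <- function(values, scales, spike = NULL, row_ids = NULL) {
  if (!is.data.frame(values)) values <- as.data.frame(values)
  if (nrow(values) < 1L || ncol(values) < 1L)
    stop("a mixed_data table needs at least one row and one column")
  if (!is.null(names(scales)) && all(names(scales) != "")) {
    if (!setequal(names(scales), names(values)))
      stop("names of `scales` do not match the columns of `values`")
    scales <- scales[names(values)]
  }
  if (length(scales) != ncol(values))
    stop("need one scale per column")
  scales <- match.arg(as.character(scales), MEASUREMENT_SCALES, several.ok = TRUE)
  names(scales) <- names(values)

  for (j in seq_along(values)) {
    sc <- scales[[j]]
    col <- values[[j]]
    if (sc %in% numeric_scales) {
      if (!is.numeric(col)) stop(sprintf("column '%s' declared %s must be numeric", names(values)[j], sc))
      if (sc == "count" && any(col[!is.na(col)] %% 1 != 0))
        stop(sprintf("count column '%s' contains non-integer values", names(values)[j]))
    } else {
      if (!is.factor(col)) col <- factor(col)
      nlev <- nlevels(col)
      if (sc == "binary" && nlev != 2L)
        stop(sprintf("binary column '%s' must declare exactly 2 categories, has %d", names(values)[j], nlev))
      if (sc == "categorical" && nlev < 2L)
        stop(sprintf("categorical column '%s' must declare at least 2 categories", names(values)[j]))
      values[[j]] <- col
    }
  }

  semis <- names(scales)[scales == "semicontinuous"]
  sp <- stats::setNames(rep(0, length(semis)), semis)
  if (!is.null(spike)) {
    bad <- setdiff(names(spike), semis)
    if (length(bad)) stop("spike values given for non-semicontinuous columns: ", paste(bad, collapse = ", "))
    sp[names(spike)] <- spike
  }

  if (is.null(row_ids)) row_ids <- as.character(seq_len(nrow(values)))
  row_ids <- as.character(row_ids)
  if (anyDuplicated(row_ids)) stop("row_ids must be unique")
  if (length(row_ids) != nrow(values)) stop("row_ids length must equal the number of rows")
  rownames(values) <- NULL

  structure(list(data = values, scales = scales, spike = sp, row_ids = row_ids),
            class = "mixed_data")
}

#' @export
print.mixed_data <- function(x, ...) {
  cat(sprintf("mixed_data: %d rows x %d columns\n", nrow(x$data), ncol(x$data)))
  cat("scales:", paste(sprintf("%s(%s)", names(x$scales), x$scales), collapse = ", "), "\n")
  nm <- sum(is.na(x$data))
  cat(sprintf("missing cells: %d\n", nm))
  invisible(x)
}

#' @export
dim.mixed_data <- function(x) dim(x$data)

#' Number of missing cells in a mixed dataset
#' @param data a [mixed_data] object
#' @return integer count of missing cells
#' @export
n_missing <- function(data) sum(is.na(data$data))

is_numeric_col <- function(data, j) data$scales[[j]] %in% numeric_scales

#' Missingness indicator mask
#'
#' Builds the indicator matrix with entries 1 exactly where a cell is
#' missing, together with the per-column missing counts. The operation is
#' idempotent and free of side effects.
#'
#' @param data a [mixed_data] object
#' @return An object of class `missing_mask`: a list with `entries` (an
#'   n x p 0/1 integer matrix) and `per_column` (named column sums).
#' @export
build_mask <- function(data) {
  stopifnot(inherits(data, "mixed_data"))
  entries <- matrix(0L, nrow(data$data), ncol(data$data),
                    dimnames = list(NULL, names(data$data)))
  entries[as.matrix(is.na(data$data))] <- 1L
  structure(list(entries = entries, per_column = colSums(entries)),
            class = "missing_mask")
}

#' @export
print.missing_mask <- function(x, ...) {
  cat(sprintf("missing_mask: %d x %d, %d missing cells\n",
              nrow(x$entries), ncol(x$entries), sum(x$entries)))
  print(x$per_column)
  invisible(x)
}

validate_mask <- function(mask, data = NULL) {
  stopifnot(inherits(mask, "missing_mask"))
  if (!identical(unname(colSums(mask$entries)), unname(mask$per_column)))
    stop("mask per-column counts disagree with its entries")
  if (!is.null(data) && !all(dim(mask$entries) == dim(data$data)))
    stop("mask shape does not match the dataset")
  invisible(mask)
}

#' Completed (imputed) dataset
#'
#' Wraps a fully observed copy of a dataset together with the mask that says
#' which cells were filled, the imputing method's tag and the seed used.
#'
#' @param data a [mixed_data] object with no missing cells
#' @param source_mask the [build_mask] of the dataset before imputation
#' @param method character tag of the imputation method
#' @param seed integer seed used by the imputer (or `NULL`)
#' @return an object of class `completed_data`
#' @export
completed_data <- function(data, source_mask, method = "unknown", seed = NULL) {
  stopifnot(inherits(data, "mixed_data"))
  validate_mask(source_mask, data)
  if (n_missing(data) > 0L)
    stop("a completed dataset may not contain missing cells")
  structure(list(data = data, source_mask = source_mask,
                 method = method, seed = seed),
            class = "completed_data")
}

#' @export
print.completed_data <- function(x, ...) {
  cat(sprintf("completed_data (%s): %d x %d, %d cells imputed\n",
              x$method, nrow(x$data$data), ncol(x$data$data),
              sum(x$source_mask$entries)))
  invisible(x)
}

#' Multiple-imputation set
#'
#' An ordered collection of `m` completed copies of the same dataset, all
#' sharing schema, shape and source mask.
#'
#' @param completions list of [completed_data] objects
#' @return an object of class `mi_set` with elements `completions` and `m`
#' @export
mi_set <- function(completions) {
  stopifnot(length(completions) >= 1L,
            all(vapply(completions, inherits, TRUE, "completed_data")))
  ref <- completions[[1L]]
  for (cp in completions[-1L]) {
    if (!identical(cp$data$scales, ref$data$scales) ||
        !all(dim(cp$data$data) == dim(ref$data$data)) ||
        !identical(cp$source_mask$entries, ref$source_mask$entries))
      stop("all completions must share schema, shape and source mask")
  }
  structure(list(completions = completions, m = length(completions)),
            class = "mi_set")
}

#' @export
print.mi_set <- function(x, ...) {
  cat(sprintf("mi_set: m = %d completions (%s)\n", x$m, x$completions[[1L]]$method))
  invisible(x)
}

#' Check that imputation preserved the observed cells
#'
#' `TRUE` iff every cell that was observed in `original` is unchanged in
#' `completed` and no missing sentinel remains.
#'
#' @param original the [mixed_data] before imputation
#' @param completed a [completed_data] or fully observed [mixed_data]
#' @return logical scalar
#' @export
check_preservation <- function(original, completed) {
  stopifnot(inherits(original, "mixed_data"))
  comp <- if (inherits(completed, "completed_data")) completed$data else completed
  stopifnot(inherits(comp, "mixed_data"))
  if (!all(dim(original$data) == dim(comp$data)) ||
      !identical(original$scales, comp$scales))
    stop("shape or schema mismatch between original and completed data")
  if (anyNA(comp$data)) return(FALSE)
  for (j in seq_along(original$data)) {
    obs <- !is.na(original$data[[j]])
    a <- original$data[[j]][obs]
    b <- comp$data[[j]][obs]
    if (is.factor(a)) { a <- as.character(a); b <- as.character(b) }
    else { a <- as.numeric(a); b <- as.numeric(b) }  # integer vs double storage
    if (!identical(a, b)) return(FALSE)
  }
  TRUE
}

# replace the values of a mixed_data object (keeping schema), re-validating factors
set_values <- function(data, new_values) {
  mixed_data(new_values, data$scales, spike = data$spike, row_ids = data$row_ids)
}

## ---------------------------------------------------------------- file I/O

#' Read and write mixed datasets as CSV plus a schema file
#'
#' Datasets travel as RFC-4180 CSV (UTF-8). Both the empty field and the
#' literal `NA` parse as the missing sentinel; writing emits empty fields.
#' The scale declaration travels separately as a YAML (or JSON) file mapping
#' column name to `scale`, optional `categories` and optional `spike`.
#' Numeric cells are written with 17 significant digits so that a
#' write/read round trip reproduces the values exactly.
#'
#' @param file path of the CSV file
#' @param schema path of the schema YAML/JSON file, or an already-parsed
#'   schema list
#' @param data a [mixed_data] object
#' @return `read_mixed_csv` returns a [mixed_data]; the writers return the
#'   file path invisibly.
#' @export
read_mixed_csv <- function(file, schema) {
  if (is.character(schema)) schema <- read_schema(schema)
  df <- utils::read.csv(file, na.strings = c("", "NA"), check.names = FALSE,
                        colClasses = "character", fileEncoding = "UTF-8")
  if (!setequal(names(df), names(schema)))
    stop("CSV columns do not match the schema")
  df <- df[names(schema)]
  scales <- vapply(schema, function(s) s$scale, "")
  spike <- NULL
  for (nm in names(schema)) {
    s <- schema[[nm]]
    if (s$scale %in% numeric_scales) {
      v <- as.numeric(df[[nm]])
      # counts are integral by invariant; store them as integers
      if (s$scale == "count" && all(is.na(v) | abs(v) < .Machine$integer.max))
        v <- as.integer(v)
      df[[nm]] <- v
    } else {
      if (is.null(s$categories)) stop(sprintf("column '%s' needs declared categories", nm))
      df[[nm]] <- factor(df[[nm]], levels = as.character(s$categories))
    }
    if (s$scale == "semicontinuous")
      spike <- c(spike, stats::setNames(s$spike %||% 0, nm))
  }
  mixed_data(df, scales, spike = spike)
}

#' @rdname read_mixed_csv
#' @export
write_mixed_csv <- function(data, file) {
  stopifnot(inherits(data, "mixed_data"))
  out <- data$data
  for (j in seq_along(out)) {
    col <- out[[j]]
    out[[j]] <- ifelse(is.na(col), "",
                       if (is.numeric(col)) sprintf("%.17g", col) else as.character(col))
  }
  utils::write.csv(out, file, row.names = FALSE, quote = TRUE, na = "",
                   fileEncoding = "UTF-8")
  invisible(file)
}

#' @rdname read_mixed_csv
#' @export
read_schema <- function(file) {
  txt <- paste(readLines(file, warn = FALSE, encoding = "UTF-8"), collapse = "\n")
  schema <- if (grepl("\\.json$", file, ignore.case = TRUE))
    jsonlite::fromJSON(txt, simplifyVector = FALSE)
  else
    yaml::yaml.load(txt)
  for (nm in names(schema)) {
    if (is.character(schema[[nm]]) && length(schema[[nm]]) == 1L)
      schema[[nm]] <- list(scale = schema[[nm]])
    schema[[nm]]$scale <- match.arg(schema[[nm]]$scale, MEASUREMENT_SCALES)
  }
  schema
}

#' @rdname read_mixed_csv
#' @export
write_schema <- function(data, file) {
  stopifnot(inherits(data, "mixed_data"))
  schema <- lapply(names(data$scales), function(nm) {
    sc <- data$scales[[nm]]
    entry <- list(scale = sc)
    if (!sc %in% numeric_scales) entry$categories <- levels(data$data[[nm]])
    if (sc == "semicontinuous") entry$spike <- unname(data$spike[[nm]])
    entry
  })
  names(schema) <- names(data$scales)
  writeLines(yaml::as.yaml(schema), file, useBytes = TRUE)
  invisible(file)
}
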