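# internal helpers shared across modules

# round-half-up, used wherever an exact missing-cell count is derived from a rate
round_half_up <- function(x) floor(x + 0.5)

# Run `expr` under `seed` without disturbing the caller's RNG stream.
# seed = NULL runs the expression as-is.
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Deterministic sub-seed derivation; keeps every derived seed < 2^31.
# All arithmetic stays below 2^53 so doubles are exact.
derive_seed <- function(base, ...) {
  parts <- list(...)
  s <- as.numeric(base) %% 2147483587
  for (p in parts) {
    v <- if (is.character(p)) sum(utf8ToInt(p) * seq_along(utf8ToInt(p))) else as.numeric(p)
    s <- (s * 69069 + v * 7919 + 1) %% 2147483587
  }
  as.integer(s + 1)
}

# most frequent value; ties broken by the smallest label
stat_mode <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) stop("cannot take the mode of an all-missing vector")
  tab <- table(as.character(x))
  winners <- names(tab)[tab == max(tab)]
  sort(winners)[1L]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
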