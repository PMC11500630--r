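# fixtures built in code; all randomness under fixed seeds

toy_mixed <- function() {
  mixed_data(
    data.frame(x = c(1.5, 2.0, NA, 4.5),
               g = factor(c("a", NA, "b", "a"), levels = c("a", "b")),
               k = c(0L, 3L, 1L, NA)),
    scales = c(x = "continuous", g = "binary", k = "count"))
}

# correlated Gaussian dataset with p continuous columns
gaussian_md <- function(n = 100, p = 3, rho = 0.8, seed = 1) {
  sigma <- matrix(rho, p, p); diag(sigma) <- 1
  x <- impbench:::with_local_seed(seed, MASS::mvrnorm(n, rep(0, p), sigma))
  df <- as.data.frame(x)
  names(df) <- paste0("v", seq_len(p))
  mixed_data(df, scales = rep("continuous", p))
}

# straight-line dataset y = a + b x with optional missing y cells
line_md <- function(n = 30, a = 1, b = 2, miss = integer(0), seed = 3) {
  x <- impbench:::with_local_seed(seed, stats::runif(n, 0, 10))
  y <- a + b * x
  y[miss] <- NA
  mixed_data(data.frame(x = x, y = y), scales = c("continuous", "continuous"))
}
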