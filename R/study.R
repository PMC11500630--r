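#' Configuration of a simulation study
#'
#' Declarative description of one benchmarking experiment: which setting,
#' which imputation methods, the contamination grid, the number of
#' replicates and multiple-imputation copies, and the base seed from which
#' every replicate seed is derived. Within a replicate all methods consume
#' identical simulated data and identical masks (common random numbers), so
#' method contrasts are paired; each method's own randomness is driven by a
#' seed derived from (base seed, replicate, contamination, method).
#'
#' @param setting one of `"income_outliers"`, `"energy_misclassification"`,
#'   `"precision"`, `"classification"`
#' @param methods character vector of method names; any of
#'   `"complete_case"`, `"mean"`, `"median"`, `"hotdeck"`, `"knn"`,
#'   `"pmm"`, `"midastouch"`, `"irmi"`, `"irmi_single"`, `"irmi_ols"`,
#'   `"forest"`, `"boost"`, and — in the precision/classification settings —
#'   `"oracle"` (copies the truth) and `"none"` (no amputation baseline)
#' @param contamination integer grid of outlier / misclassification counts
#' @param replications number of replicates (the full-scale studies use
#'   1000; reduced replication is supported throughout)
#' @param m multiple-imputation copies for the methods that produce them
#' @param seed base seed
#' @param level nominal confidence level
#' @param mcar_rate per-variable MCAR rate of the precision and
#'   classification settings (default 0.10)
#' @param income_spec an [income_sim_spec] (outlier setting)
#' @param energy_spec an [energy_sim_spec] (misclassification setting)
#' @param complete_case_adjusted use the MAR-consistent regression
#'   estimator for the complete-case baseline instead of the plain mean
#'   (default `FALSE`, the plain mean)
#' @param train_fraction training fraction of the classification split
#' @return an object of class `study_config`
#' @export
study_config <- function(setting = c("income_outliers", "energy_misclassification",
                                     "precision", "classification"),
                         methods, contamination = 0L, replications = 100L,
                         m = 5L, seed = 1L, level = 0.95, mcar_rate = 0.10,
                         income_spec = income_sim_spec(),
                         energy_spec = energy_sim_spec(),
                         complete_case_adjusted = FALSE,
                         train_fraction = 0.7) {
  setting <- match.arg(setting)
  stopifnot(length(methods) >= 1L, replications >= 1L, m >= 1L,
            all(contamination >= 0), level > 0, level < 1)
  structure(list(setting = setting, methods = methods,
                 contamination = as.integer(contamination),
                 replications = as.integer(replications), m = as.integer(m),
                 seed = as.integer(seed), level = level,
                 mcar_rate = mcar_rate, income_spec = income_spec,
                 energy_spec = energy_spec,
                 complete_case_adjusted = complete_case_adjusted,
                 train_fraction = train_fraction),
            class = "study_config")
}

MI_METHODS <- c("pmm", "midastouch", "irmi", "irmi_ols", "boost")

# Impute with a named method; returns a list of completed_data copies.
study_impute <- function(method, data, mask, m, seed) {
  switch(method,
    mean = list(impute_mean(data, mask, "mean")),
    median = list(impute_mean(data, mask, "median")),
    hotdeck = list(impute_hotdeck(data, mask, seed = seed)),
    knn = list(impute_knn(data, mask)),
    pmm = pmm_impute(data, mask, m = m, seed = seed)$completions,
    midastouch = midastouch_impute(data, mask, m = m, seed = seed)$completions,
    irmi = {
      out <- irmi_impute(data, mask, multiple = m, seed = seed)
      if (inherits(out, "mi_set")) out$completions else list(out)
    },
    irmi_single = list(irmi_impute(data, mask, multiple = 1L, seed = seed)),
    irmi_ols = {
      out <- irmi_impute(data, mask, robust = FALSE, multiple = m, seed = seed)
      if (inherits(out, "mi_set")) out$completions else list(out)
    },
    forest = list(forest_impute(data, mask, seed = seed)),
    boost = boosted_impute(data, mask, m = m, seed = seed)$completions,
    stop(sprintf("unknown imputation method '%s'", method))
  )
}

t_interval <- function(x, level) {
  n <- length(x)
  se <- stats::sd(x) / sqrt(n)
  half <- stats::qt(1 - (1 - level) / 2, df = n - 1) * se
  list(estimate = mean(x), lower = mean(x) - half, upper = mean(x) + half)
}

# Point estimate and interval for the mean of `target` over `est_rows`,
# given the amputed data, for one method.
estimate_mean_interval <- function(method, data, mask, target, est_rows,
                                   config, seed, cc_driver = NULL) {
  level <- config$level
  if (method == "complete_case") {
    y <- data$data[[target]][est_rows]
    obs <- !is.na(y)
    if (config$complete_case_adjusted && !is.null(cc_driver)) {
      x <- data$data[[cc_driver]][est_rows]
      fit <- stats::lm(y[obs] ~ x[obs])
      b <- stats::coef(fit)
      mu <- b[1L] + b[2L] * mean(x)
      V <- stats::vcov(fit)
      cvec <- c(1, mean(x))
      se2 <- drop(t(cvec) %*% V %*% cvec) + b[2L]^2 * stats::var(x) / length(x)
      half <- stats::qt(1 - (1 - level) / 2, df = sum(obs) - 2) * sqrt(se2)
      return(list(estimate = unname(mu), lower = unname(mu - half),
                  upper = unname(mu + half)))
    }
    return(t_interval(y[obs], level))
  }
  copies <- study_impute(method, data, mask, config$m, seed)
  vals <- lapply(copies, function(cp) cp$data$data[[target]][est_rows])
  if (length(copies) > 1L) {
    ests <- vapply(vals, mean, 0)
    withins <- vapply(vals, function(v) stats::var(v) / length(v), 0)
    pooled <- rubin_pool(ests, withins, level = level,
                         df_single = length(est_rows) - 1L)
    list(estimate = pooled$estimate, lower = pooled$lower, upper = pooled$upper)
  } else {
    t_interval(vals[[1L]], level)
  }
}

study_result <- function(replicates, config, theta = NA_real_) {
  res <- structure(list(replicates = replicates, config = config,
                        theta = theta),
                   class = "study_result")
  res$summary <- summarize_study(res)
  res
}

#' Aggregate a study's per-replicate table
#'
#' Recomputes the per-cell aggregates (bias, variance, RMSE and coverage
#' for estimator studies; medians for metric studies) from the full
#' per-replicate table, so every printed aggregate can be audited against
#' the raw rows.
#'
#' @param result a `study_result`
#' @return a data frame of aggregates
#' @export
summarize_study <- function(result) {
  reps <- result$replicates
  if (all(c("estimate", "lower", "upper") %in% names(reps))) {
    cells <- unique(reps[c("method", "contamination")])
    out <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
      sub <- reps[reps$method == cells$method[i] &
                    reps$contamination == cells$contamination[i], ]
      er <- estimator_replicates(sub$estimate, sub$lower, sub$upper,
                                 theta = result$theta,
                                 level = result$config$level)
      sm <- estimator_summary(er)
      data.frame(method = cells$method[i], contamination = cells$contamination[i],
                 bias = sm[["bias"]], variance = sm[["variance"]],
                 rmse = sm[["rmse"]], coverage = coverage_rate(er))
    }))
    rownames(out) <- NULL
    return(out)
  }
  if ("metric" %in% names(reps)) {
    agg <- stats::aggregate(value ~ method + metric, data = reps,
                            FUN = function(v) stats::median(v, na.rm = TRUE))
    names(agg)[names(agg) == "value"] <- "median"
    return(agg)
  }
  agg <- stats::aggregate(cbind(accuracy, f1) ~ method, data = reps, FUN = stats::median)
  names(agg)[-1L] <- paste0("median_", names(agg)[-1L])
  agg
}

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf("study_result (%s): %d replicates, methods: %s\n",
              x$config$setting, x$config$replications,
              paste(x$config$methods, collapse = ", ")))
  print(x$summary)
  invisible(x)
}

#' Outlier study on the age/income population
#'
#' Per replicate and contamination count k: draw n = 200 from the bivariate
#' age/income population, replace k rows by four-corner leverage outliers,
#' ampute 30% of INCOME among the non-outlier rows by rank-MAR on AGE
#' (outlier rows are never amputed), impute with each method, and estimate
#' the mean of INCOME with a nominal-level confidence interval — Rubin
#' pooling for the multiple-imputation methods, a t-interval otherwise, and
#' the observed-cases mean for the complete-case baseline. The outliers
#' disturb only the imputation: the estimate is computed over the
#' non-contaminated rows, whose true population mean is the target.
#'
#' @param config a [study_config] with `setting = "income_outliers"`
#' @return a `study_result` with the per-replicate table and the
#'   (recomputable) bias/variance/RMSE/coverage aggregates
#' @export
run_outlier_study <- function(config) {
  stopifnot(inherits(config, "study_config"),
            config$setting == "income_outliers")
  spec <- config$income_spec
  theta <- unname(spec$mean["INCOME"])
  n <- spec$n
  if (any(config$contamination > n)) stop("contamination grid exceeds the sample size")
  rows <- list()
  for (r in seq_len(config$replications)) {
    d0 <- simulate_income(spec, seed = derive_seed(config$seed, "data", r))
    for (k in config$contamination) {
      inj <- inject_leverage_outliers(d0, k, spec,
                                      seed = derive_seed(config$seed, "outl", r, k))
      protected <- inj$flags$outlier_rows
      amp <- ampute_mar(inj$data, target = "INCOME", driver = "AGE",
                        rate = spec$missing_rate, protected = protected,
                        seed = derive_seed(config$seed, "amp", r, k))
      est_rows <- setdiff(seq_len(n), protected)
      for (mi in seq_along(config$methods)) {
        meth <- config$methods[mi]
        est <- estimate_mean_interval(meth, amp$data, amp$mask, "INCOME",
                                      est_rows, config,
                                      seed = derive_seed(config$seed, "imp", r, k, mi),
                                      cc_driver = "AGE")
        rows[[length(rows) + 1L]] <- data.frame(
          method = meth, contamination = k, replicate = r,
          estimate = est$estimate, lower = est$lower, upper = est$upper)
      }
    }
  }
  study_result(do.call(rbind, rows), config, theta = theta)
}

#' True type-1 group mean of log energy under the generating model
#'
#' Closed form of the target parameter of the misclassification study:
#' `intercept + type_effect + runtime_coeff * E[log runtime]` with
#' `E[log runtime] = log(1/rate) - gamma` (gamma: Euler-Mascheroni).
#'
#' @param spec an [energy_sim_spec]
#' @return the population group mean of log energy for type-1 machines
#' @export
energy_group_mean <- function(spec = energy_sim_spec()) {
  e_log_runtime <- log(1 / spec$runtime_rate) + digamma(1)  # digamma(1) = -gamma
  spec$intercept + spec$type_effect + spec$runtime_coeff * e_log_runtime
}

#' Misclassification study on the energy-consumption model
#'
#' Per replicate and misclassification count k: simulate the
#' energy-consumption data, flip the type of k rows, take logs of energy
#' and runtime (the relationship is lognormal), ampute 30% of log energy
#' among the non-misclassified rows by rank-MAR on runtime, impute with
#' each method, and estimate the group mean of log energy of the machines
#' whose *true* type is 1, with its nominal-level interval. The
#' misclassifications disturb only the imputation models.
#'
#' @param config a [study_config] with `setting = "energy_misclassification"`
#' @return a `study_result`
#' @export
run_misclassification_study <- function(config) {
  stopifnot(inherits(config, "study_config"),
            config$setting == "energy_misclassification")
  spec <- config$energy_spec
  theta <- energy_group_mean(spec)
  n <- spec$n
  if (any(config$contamination > n)) stop("contamination grid exceeds the sample size")
  rows <- list()
  for (r in seq_len(config$replications)) {
    d0 <- simulate_energy(spec, seed = derive_seed(config$seed, "data", r))
    true_type <- d0$data$type
    for (k in config$contamination) {
      inj <- inject_misclassifications(d0, k,
                                       seed = derive_seed(config$seed, "mis", r, k))
      df <- inj$data$data
      df$runtime <- log(df$runtime)
      df$energy <- log(df$energy)
      dlog <- set_values(inj$data, df)
      protected <- inj$flags$misclassified_rows
      amp <- ampute_mar(dlog, target = "energy", driver = "runtime",
                        rate = spec$missing_rate, protected = protected,
                        seed = derive_seed(config$seed, "amp", r, k))
      est_rows <- which(true_type == "1")
      for (mi in seq_along(config$methods)) {
        meth <- config$methods[mi]
        est <- estimate_mean_interval(meth, amp$data, amp$mask, "energy",
                                      est_rows, config,
                                      seed = derive_seed(config$seed, "imp", r, k, mi),
                                      cc_driver = "runtime")
        rows[[length(rows) + 1L]] <- data.frame(
          method = meth, contamination = k, replicate = r,
          estimate = est$estimate, lower = est$lower, upper = est$upper)
      }
    }
  }
  study_result(do.call(rbind, rows), config, theta = theta)
}

#' Precision study on a complete dataset
#'
#' Per replicate: flag outliers robustly (MCD), ampute 10% of every
#' variable completely at random while protecting the flagged rows, impute
#' with each method, and score MAPE, NRMSE, MSECOR and the false
#' classification rate against the known truth (flagged rows excluded from
#' all scores). The special methods `"oracle"` (copies the truth) and the
#' usual imputers are allowed; multiple-imputation methods contribute their
#' first completion.
#'
#' @param config a [study_config] with `setting = "precision"`
#' @param dataset a complete [mixed_data]
#' @return a `study_result` with a long per-replicate metric table
#' @export
run_precision_study <- function(config, dataset) {
  stopifnot(inherits(config, "study_config"), config$setting == "precision",
            inherits(dataset, "mixed_data"))
  if (n_missing(dataset) > 0L)
    stop("the precision study needs a complete dataset")
  n_cont <- sum(dataset$scales == "continuous")
  flags <- if (n_cont >= 2L) flag_outliers_mcd(dataset) else NULL
  protected <- if (is.null(flags)) integer(0) else which(flags$flagged)
  has_zero <- any(vapply(which(dataset$scales == "continuous"),
                         function(j) any(dataset$data[[j]] == 0, na.rm = TRUE), TRUE))
  rows <- list()
  for (r in seq_len(config$replications)) {
    amp <- ampute_mcar(dataset, config$mcar_rate, protected = protected,
                       seed = derive_seed(config$seed, "amp", r))
    for (mi in seq_along(config$methods)) {
      meth <- config$methods[mi]
      completed <- if (meth == "oracle") {
        completed_data(dataset, amp$mask, method = "oracle")
      } else {
        study_impute(meth, amp$data, amp$mask, config$m,
                     seed = derive_seed(config$seed, "imp", r, mi))[[1L]]
      }
      pair <- evaluation_pair(completed, dataset, amp$mask,
                              exclude_rows = protected)
      vals <- c(
        mape = tryCatch(mape(pair, skip_zero = has_zero), error = function(e) NA_real_),
        nrmse = tryCatch(nrmse(pair), error = function(e) NA_real_),
        msecor = tryCatch(msecor(pair), error = function(e) NA_real_),
        fc = tryCatch(false_classification_rate(pair), error = function(e) NA_real_))
      rows[[length(rows) + 1L]] <- data.frame(
        method = meth, replicate = r, metric = names(vals), value = unname(vals))
    }
  }
  study_result(do.call(rbind, rows), config)
}

#' Classification-context study
#'
#' Per replicate: split the complete dataset into a stratified train/test
#' partition, set 10% of every training feature missing completely at
#' random, impute with each method (the complete-case baseline drops
#' incomplete training rows; `"none"` trains on the untouched data), train
#' a random-forest classifier on the training set and score accuracy and
#' F1 on the untouched test set. The first level of the label is the
#' positive class.
#'
#' @param config a [study_config] with `setting = "classification"`
#' @param dataset a complete [mixed_data] containing the label column
#' @param label_column name of the categorical/binary label column
#' @param trees trees of the random-forest classifier (default 100)
#' @return a `study_result` with per-replicate accuracy and F1 rows
#' @export
run_classification_study <- function(config, dataset, label_column, trees = 100L) {
  stopifnot(inherits(config, "study_config"),
            config$setting == "classification",
            label_column %in% names(dataset$data))
  if (n_missing(dataset) > 0L) stop("the classification study needs complete data")
  lab <- dataset$data[[label_column]]
  if (!is.factor(lab) || nlevels(droplevels(lab)) < 2L)
    stop("the label column must carry at least two observed classes")
  pos <- levels(lab)[1L]
  n <- nrow(dataset$data)
  feature_cols <- setdiff(names(dataset$data), label_column)
  rows <- list()
  for (r in seq_len(config$replications)) {
    split_seed <- derive_seed(config$seed, "split", r)
    train_idx <- with_local_seed(split_seed, {
      unlist(lapply(split(seq_len(n), lab), function(ix)
        sample(ix, max(1L, round_half_up(config$train_fraction * length(ix))))))
    })
    test_idx <- setdiff(seq_len(n), train_idx)
    train_df <- dataset$data[train_idx, , drop = FALSE]
    rownames(train_df) <- NULL
    train_md <- mixed_data(train_df, dataset$scales, spike = dataset$spike)
    amp <- ampute_mcar(train_md, config$mcar_rate,
                       seed = derive_seed(config$seed, "amp", r),
                       columns = feature_cols)
    for (mi in seq_along(config$methods)) {
      meth <- config$methods[mi]
      fit_df <- if (meth == "none") {
        train_md$data
      } else if (meth == "complete_case") {
        cc <- stats::complete.cases(amp$data$data)
        if (!any(cc)) stop("complete-case analysis removed every training row")
        amp$data$data[cc, , drop = FALSE]
      } else if (meth == "oracle") {
        train_md$data
      } else {
        study_impute(meth, amp$data, amp$mask, config$m,
                     seed = derive_seed(config$seed, "imp", r, mi))[[1L]]$data$data
      }
      rf_seed <- derive_seed(config$seed, "rf", r, mi)
      # probability forest + deterministic argmax: majority-vote tie-breaking
      # is not reproducible across calls
      fit <- ranger::ranger(x = fit_df[feature_cols], y = fit_df[[label_column]],
                            num.trees = trees, num.threads = 1L,
                            probability = TRUE, seed = rf_seed)
      pr <- stats::predict(fit, data = dataset$data[test_idx, feature_cols, drop = FALSE],
                           num.threads = 1L)$predictions
      pred <- factor(colnames(pr)[max.col(pr, ties.method = "first")],
                     levels = levels(lab))
      truth <- lab[test_idx]
      tp <- sum(pred == pos & truth == pos)
      tn <- sum(pred != pos & truth != pos)
      fp <- sum(pred == pos & truth != pos)
      fn <- sum(pred != pos & truth == pos)
      sc <- f1_accuracy(tp, tn, fp, fn)
      rows[[length(rows) + 1L]] <- data.frame(
        method = meth, replicate = r,
        accuracy = sc[["accuracy"]], f1 = sc[["f1"]])
    }
  }
  study_result(do.call(rbind, rows), config)
}
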