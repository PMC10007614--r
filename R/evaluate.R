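# Evaluation protocol: fixed 8:2 split, repeated reseeded training
# iterations with 5-fold CV for model selection, and the R2 / RMSE / RPD
# metric set with per-day prediction summaries.

#' Evaluation protocol
#'
#' @param test_fraction Held-out fraction (default 0.2, an 8:2 split).
#' @param k_folds Cross-validation folds used for model selection within
#'   the training set (default 5).
#' @param n_repeats Independent reseeded prediction iterations (default 5).
#' @param seed Integer seed; fixes the split and the per-repeat seeds.
#' @param group_split If `TRUE`, split by shrimp rather than by sample
#'   (leakage study switch; the standard protocol splits samples).
#' @return A list of class `sors_protocol`.
#' @export
eval_protocol <- function(test_fraction = 0.2, k_folds = 5L,
                          n_repeats = 5L, seed = 1L, group_split = FALSE) {
  if (test_fraction <= 0 || test_fraction >= 1) {
    abort("`test_fraction` must lie in (0, 1)", class = "sors_config_error")
  }
  if (k_folds < 2L) abort("`k_folds` must be >= 2",
                          class = "sors_config_error")
  structure(list(test_fraction = test_fraction, k_folds = as.integer(k_folds),
                 n_repeats = as.integer(n_repeats), seed = as.integer(seed),
                 group_split = isTRUE(group_split)),
            class = "sors_protocol")
}

#' Split samples into training and test sets
#'
#' Seeded random partition; the test set holds `round(test_fraction * n)`
#' samples (140 of 700 under the default design).
#'
#' @param n_samples Total sample count (>= 5).
#' @param protocol An [eval_protocol()].
#' @return A list with integer index vectors `train` and `test` (disjoint,
#'   exhaustive).
#' @export
split_dataset <- function(n_samples, protocol = eval_protocol()) {
  if (n_samples < 5L) abort("need at least 5 samples",
                            class = "sors_input_error")
  rs <- .Random.seed_swap(protocol$seed)
  on.exit(.Random.seed_restore(rs))
  n_test <- round(protocol$test_fraction * n_samples)
  test <- sort(sample.int(n_samples, n_test))
  list(train = setdiff(seq_len(n_samples), test), test = test)
}

#' Regression metrics: R-squared, RMSE, residual prediction deviation
#'
#' `metric_r2` is `1 - SSE/SST` (SST about the mean of the truth),
#' `metric_rmse` the root mean squared error, and `metric_rpd` the sample
#' standard deviation (n - 1 denominator) of the truth divided by the
#' RMSE. A perfect prediction has RMSE 0 and an infinite RPD; constant
#' truth makes R-squared and RPD undefined and raises an error.
#'
#' @param truth,pred Equal-length numeric vectors (length >= 2).
#' @return A single numeric value.
#' @export
metric_r2 <- function(truth, pred) {
  check_metric_args(truth, pred, need_varying = TRUE)
  1 - sum((truth - pred)^2) / sum((truth - mean(truth))^2)
}

#' @rdname metric_r2
#' @export
metric_rmse <- function(truth, pred) {
  check_metric_args(truth, pred)
  sqrt(mean((truth - pred)^2))
}

#' @rdname metric_r2
#' @export
metric_rpd <- function(truth, pred) {
  check_metric_args(truth, pred, need_varying = TRUE)
  rmse <- metric_rmse(truth, pred)
  if (rmse == 0) return(Inf)
  sd(truth) / rmse
}

check_metric_args <- function(truth, pred, need_varying = FALSE) {
  if (length(truth) != length(pred) || length(truth) < 2L) {
    abort("`truth` and `pred` must have equal length >= 2",
          class = "sors_input_error")
  }
  if (need_varying && sd(truth) == 0) {
    abort("metric undefined for constant truth",
          class = "sors_metric_error")
  }
  invisible(TRUE)
}

# Box-plot statistics of predictions grouped by true day: quartiles,
# 1.5*IQR whiskers clamped to the data, and outlier count.
per_day_box_stats <- function(truth, pred) {
  purrr::map_dfr(sort(unique(truth)), function(d) {
    p <- pred[truth == d]
    q1 <- quantile(p, 0.25, names = FALSE)
    q3 <- quantile(p, 0.75, names = FALSE)
    iqr <- q3 - q1
    lower <- min(p[p >= q1 - 1.5 * iqr])
    upper <- max(p[p <= q3 + 1.5 * iqr])
    tibble(day = d, q1 = q1, median = median(p), q3 = q3,
           lower = lower, upper = upper,
           n_outliers = sum(p < lower | p > upper))
  })
}

# Train one model entry on the training samples and predict the test set.
# `model` is either a sors_model_spec (deep variant) or a baseline kind
# string; baselines first select their optimal offset on the training set.
fit_and_predict <- function(model, X, y, idx, protocol, repeat_seed) {
  if (inherits(model, "sors_model_spec")) {
    spec <- model
    spec$seed <- as.integer(spec$seed + repeat_seed)
    fitm <- fit(build_model(spec),
                X[idx$train, , , drop = FALSE], y[idx$train])
    list(pred = predict(fitm, X[idx$test, , , drop = FALSE]),
         detail = list(final_mse = fitm$final_mse))
  } else {
    sel <- select_optimal_offset(X[idx$train, , , drop = FALSE],
                                 y[idx$train], method = "cv_r2",
                                 seed = repeat_seed)
    tr <- spectra_at_offset(X[idx$train, , , drop = FALSE],
                            sel$offset_index)
    te <- spectra_at_offset(X[idx$test, , , drop = FALSE],
                            sel$offset_index)
    b <- fit_baseline(model, tr, y[idx$train], seed = repeat_seed)
    list(pred = predict(b, te),
         detail = list(offset_index = sel$offset_index))
  }
}

#' Run the full evaluation protocol over a set of models
#'
#' Fixes one seeded 8:2 train/test split, then performs `n_repeats`
#' independent reseeded iterations: each repeat re-runs model selection
#' (cross-validated hyperparameters for the baselines, reseeded weight
#' initialisation and shuffling for the deep variants) on the training
#' set, refits, and predicts the fixed test set. Metrics are reported per
#' repeat with their mean and standard deviation across repeats, along
#' with per-day box-plot summaries of the pooled predictions.
#'
#' @param processed A processed tibble (from [preprocess_dataset()] /
#'   [simulate_processed_dataset()]) or an `n x bands x offsets` array
#'   with labels supplied via `labels`.
#' @param models Named list; each element a [model_spec()] or one of
#'   `"plsr"`, `"svr"`, `"et"`.
#' @param protocol An [eval_protocol()].
#' @param labels Storage-day labels (unneeded for processed tibbles).
#' @return A `sors_eval` object: `metrics` (per model x repeat),
#'   `summary` (mean and sd per model), `predictions` (model, repeat,
#'   sample, truth, prediction), `box` (per model x day), `split`.
#' @export
run_experiment <- function(processed, models, protocol = eval_protocol(),
                           labels = NULL) {
  if (is.data.frame(processed)) {
    labels <- processed$day
    X <- as_model_input(processed)
    ids <- processed$sample_id
  } else {
    X <- processed
    ids <- as.character(seq_len(dim(X)[1]))
  }
  if (length(unique(labels)) < 2L) {
    abort("labels are constant; evaluation undefined",
          class = "sors_input_error")
  }
  if (is.null(names(models)) || any(names(models) == "")) {
    abort("`models` must be a fully named list", class = "sors_input_error")
  }
  idx <- split_dataset(dim(X)[1], protocol)
  truth <- labels[idx$test]
  preds <- list(); mets <- list()
  for (r in seq_len(protocol$n_repeats)) {
    repeat_seed <- protocol$seed + 1000L * r
    for (nm in names(models)) {
      res <- fit_and_predict(models[[nm]], X, labels, idx, protocol,
                             repeat_seed)
      preds[[length(preds) + 1L]] <- tibble(
        model = nm, iteration = r, sample_id = ids[idx$test],
        truth = truth, prediction = res$pred)
      mets[[length(mets) + 1L]] <- tibble(
        model = nm, iteration = r,
        r2 = metric_r2(truth, res$pred),
        rmse = metric_rmse(truth, res$pred),
        rpd = metric_rpd(truth, res$pred))
    }
  }
  metrics <- dplyr::bind_rows(mets)
  predictions <- dplyr::bind_rows(preds)
  summary <- metrics |>
    dplyr::group_by(.data$model) |>
    dplyr::summarise(dplyr::across(
      c("r2", "rmse", "rpd"),
      list(mean = mean,
           sd = function(v) if (length(v) < 2L) 0 else sd(v))),
      .groups = "drop")
  box <- predictions |>
    dplyr::group_by(.data$model) |>
    dplyr::group_modify(function(d, g) per_day_box_stats(d$truth,
                                                         d$prediction)) |>
    dplyr::ungroup()
  structure(list(metrics = metrics, summary = summary,
                 predictions = predictions, box = box,
                 split = idx, protocol = protocol),
            class = "sors_eval")
}

#' @export
print.sors_eval <- function(x, ...) {
  cat(sprintf("<sors_eval> %d model(s), %d iteration(s), %d test samples\n",
              length(unique(x$metrics$model)), x$protocol$n_repeats,
              length(x$split$test)))
  print(as.data.frame(x$summary), row.names = FALSE, digits = 3)
  invisible(x)
}

#' @export
tidy.sors_eval <- function(x, ...) x$metrics

#' @export
glance.sors_eval <- function(x, ...) x$summary

#' Box plot of predicted versus true storage day
#'
#' @param object A `sors_eval`.
#' @param ... Unused.
#' @return A ggplot: pooled predicted storage day by true day, one facet
#'   per model.
#' @export
autoplot.sors_eval <- function(object, ...) {
  ggplot2::ggplot(object$predictions,
                  ggplot2::aes(x = factor(.data$truth), y = .data$prediction)) +
    ggplot2::geom_boxplot(fill = "#a6bddb") +
    ggplot2::geom_abline(slope = 1, intercept = 0,
                         linetype = "dashed", colour = "grey40") +
    ggplot2::facet_wrap(~model) +
    ggplot2::labs(x = "true storage day", y = "predicted storage day") +
    ggplot2::theme_minimal()
}
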