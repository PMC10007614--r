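# Chemometric baselines operating on the spectrum of a single (optimal)
# offset distance: PLSR, radial-kernel SVR and extremely randomized trees.

#' Extract the single-offset spectra from processed samples
#'
#' @param x An `n x bands x offsets` array or processed tibble.
#' @param offset_index Offset column to use (1-based).
#' @return An `n x bands` matrix with band names `b1..bK`.
#' @export
spectra_at_offset <- function(x, offset_index) {
  if (is.data.frame(x)) x <- as_model_input(x)
  stopifnot(length(dim(x)) == 3L,
            offset_index >= 1L, offset_index <= dim(x)[3])
  s <- matrix(x[, , offset_index], nrow = dim(x)[1])
  colnames(s) <- paste0("b", seq_len(ncol(s)))
  s
}

seeded_folds <- function(n, k, seed) {
  rs <- .Random.seed_swap(seed)
  on.exit(.Random.seed_restore(rs))
  sample(rep_len(seq_len(k), n))
}

# 5-fold CV curve of PLSR over 1..ncomp_max components; returns mean CV
# R-squared per component count. One pls fit per fold: predictions for all
# component counts come from the same fit.
plsr_cv_r2 <- function(spectra, labels, ncomp_max, k = 5L, seed = 1L) {
  n <- nrow(spectra)
  folds <- seeded_folds(n, k, seed)
  sse <- matrix(0, k, ncomp_max)
  sst <- numeric(k)
  for (f in seq_len(k)) {
    tr <- folds != f
    fitp <- mixOmics::pls(spectra[tr, , drop = FALSE], labels[tr],
                          ncomp = ncomp_max, mode = "regression")
    pr <- predict(fitp, spectra[!tr, , drop = FALSE])$predict[, 1L, ]
    pr <- matrix(pr, ncol = ncomp_max)
    sse[f, ] <- colSums((pr - labels[!tr])^2)
    sst[f] <- sum((labels[!tr] - mean(labels[tr]))^2)
  }
  1 - colSums(sse) / sum(sst)
}

#' Fit a single-offset chemometric baseline
#'
#' * `plsr`: partial least squares regression; the component count (1 up
#'   to `ncomp_max`) is chosen by 5-fold cross-validated R-squared.
#' * `svr`: eps-regression SVM with radial kernel; cost and kernel width
#'   are grid-searched by 5-fold cross-validation.
#' * `et`: extremely randomized trees (500 trees, no bootstrap, random
#'   split points), seeded.
#'
#' @param kind One of `"plsr"`, `"svr"`, `"et"`.
#' @param spectra `n x bands` matrix (one offset column's spectra).
#' @param labels Numeric storage-day labels (n >= 10).
#' @param seed Integer seed for fold assignment / tree randomness.
#' @param ncomp_max Maximum PLSR components considered (default 20).
#' @return An object of class `sors_baseline` supporting [predict()].
#' @export
fit_baseline <- function(kind = c("plsr", "svr", "et"), spectra, labels,
                         seed = 1L, ncomp_max = 20L) {
  kind <- match.arg(kind)
  n <- nrow(spectra)
  if (n < 10L) abort("need at least 10 training samples",
                     class = "sors_input_error")
  if (length(unique(labels)) < 2L) {
    abort("labels are constant; nothing to regress",
          class = "sors_input_error")
  }
  if (is.null(colnames(spectra))) {
    colnames(spectra) <- paste0("b", seq_len(ncol(spectra)))
  }
  out <- list(kind = kind, seed = seed, bands = colnames(spectra))
  if (kind == "plsr") {
    ncomp_max <- min(ncomp_max, n - ceiling(n / 5) - 1L, ncol(spectra))
    cv <- plsr_cv_r2(spectra, labels, ncomp_max, seed = seed)
    out$ncomp <- which.max(cv)
    out$cv_r2 <- cv
    out$fit <- mixOmics::pls(spectra, labels, ncomp = out$ncomp,
                             mode = "regression")
  } else if (kind == "svr") {
    p <- ncol(spectra)
    grid <- expand.grid(cost = c(1, 10, 100, 1000),
                        gamma = c(0.25, 0.5, 1, 2, 5) / p)
    folds <- seeded_folds(n, 5L, seed)
    rmse <- vapply(seq_len(nrow(grid)), function(g) {
      errs <- vapply(1:5, function(f) {
        tr <- folds != f
        m <- e1071::svm(spectra[tr, , drop = FALSE], labels[tr],
                        type = "eps-regression", kernel = "radial",
                        cost = grid$cost[g], gamma = grid$gamma[g])
        sqrt(mean((predict(m, spectra[!tr, , drop = FALSE]) - labels[!tr])^2))
      }, numeric(1))
      mean(errs)
    }, numeric(1))
    best <- grid[which.min(rmse), ]
    out$tuning <- cbind(grid, rmse = rmse)
    out$fit <- e1071::svm(spectra, labels, type = "eps-regression",
                          kernel = "radial", cost = best$cost,
                          gamma = best$gamma)
  } else {
    df <- as.data.frame(spectra)
    df$.day <- labels
    out$fit <- ranger::ranger(
      dependent.variable.name = ".day", data = df,
      num.trees = 500L, splitrule = "extratrees", num.random.splits = 1L,
      replace = FALSE, sample.fraction = 1, min.node.size = 5L,
      seed = seed)
  }
  class(out) <- "sors_baseline"
  out
}

#' @export
predict.sors_baseline <- function(object, newdata, ...) {
  if (is.null(colnames(newdata))) colnames(newdata) <- object$bands
  switch(object$kind,
         plsr = as.numeric(predict(object$fit, newdata)$predict[, 1L,
                                                                object$ncomp]),
         svr = as.numeric(predict(object$fit, newdata)),
         et = as.numeric(predict(object$fit,
                                 as.data.frame(newdata))$predictions))
}

#' @export
print.sors_baseline <- function(x, ...) {
  cat(sprintf("<sors_baseline: %s>%s\n", x$kind,
              if (x$kind == "plsr") sprintf(" %d components", x$ncomp) else ""))
  invisible(x)
}

#' Select the optimal spatial offset distance
#'
#' Conventional single-offset chemometrics needs the one offset whose
#' spectrum best reflects the subsurface layer. Two criteria are offered:
#'
#' * `cv_r2` (default): for each offset column, fit the PLSR baseline on
#'   that column's spectra under 5-fold cross-validation and pick the
#'   offset maximising the best mean CV R-squared.
#' * `contrast_ratio`: pick the offset maximising the mean ratio of the
#'   baseline-subtracted 1269 cm^-1 peak amplitude to the local
#'   fluorescence background.
#'
#' Ties break toward the smaller offset.
#'
#' @param x An `n x bands x offsets` array or processed tibble.
#' @param labels Storage-day labels (must not be constant for `cv_r2`).
#' @param method `"cv_r2"` or `"contrast_ratio"`.
#' @param band_centers_cm1 Band centers, needed for `contrast_ratio`
#'   (taken from the tibble's first sample when available).
#' @param seed Seed for the CV folds.
#' @return A `sors_offset_selection`: list with `offset_index` (1-based
#'   column), `method` and `criterion` (tibble: offset_index, value).
#' @export
select_optimal_offset <- function(x, labels,
                                  method = c("cv_r2", "contrast_ratio"),
                                  band_centers_cm1 = NULL, seed = 1L) {
  method <- match.arg(method)
  if (is.data.frame(x)) {
    if (is.null(band_centers_cm1)) {
      band_centers_cm1 <- x$spectra[[1]]$band_centers_cm1
    }
    x <- as_model_input(x)
  }
  n_off <- dim(x)[3]
  if (n_off < 1L) abort("no offsets", class = "sors_input_error")
  if (n_off == 1L) {
    return(structure(list(offset_index = 1L, method = method,
                          criterion = tibble(offset_index = 1L, value = NA_real_)),
                     class = "sors_offset_selection"))
  }
  if (method == "cv_r2") {
    if (length(unique(labels)) < 2L) {
      abort("labels are constant; offset selection undefined",
            class = "sors_input_error")
    }
    vals <- vapply(seq_len(n_off), function(k) {
      s <- spectra_at_offset(x, k)
      ncomp_max <- min(20L, nrow(s) - ceiling(nrow(s) / 5) - 1L, ncol(s))
      max(plsr_cv_r2(s, labels, ncomp_max, seed = seed))
    }, numeric(1))
  } else {
    if (is.null(band_centers_cm1)) {
      abort("`band_centers_cm1` required for contrast_ratio",
            class = "sors_input_error")
    }
    i0 <- which.min(abs(band_centers_cm1 - 1269))
    w <- max(1L, round(40 / mean(diff(band_centers_cm1))))
    lo <- max(1L, i0 - w); hi <- min(length(band_centers_cm1), i0 + w)
    vals <- vapply(seq_len(n_off), function(k) {
      s <- spectra_at_offset(x, k)
      bg <- (s[, lo] + s[, hi]) / 2
      mean((s[, i0] - bg) / pmax(bg, 1e-12))
    }, numeric(1))
  }
  best <- which(vals >= max(vals) - 1e-12)[1]  # ties -> smaller offset
  structure(list(offset_index = best, method = method,
                 criterion = tibble(offset_index = seq_len(n_off),
                                    value = vals)),
            class = "sors_offset_selection")
}

#' @export
print.sors_offset_selection <- function(x, ...) {
  cat(sprintf("<sors_offset_selection> method %s -> offset column %d\n",
              x$method, x$offset_index))
  invisible(x)
}
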