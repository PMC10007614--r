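# Attention-based LSTM regressor for waveband-sequence inputs.
#
# Architecture (default spec): the 200-waveband sequence of 11-dimensional
# offset profiles runs through an LSTM (21 units, tanh) returning the full
# hidden sequence; a many-to-one attention block scores every hidden state
# against the last one through a bias-free linear map, softmax-normalises
# the scores over the 200 steps, forms the context as the weighted sum of
# hidden states, concatenates [context; last state] and projects it
# bias-free with tanh to the 50-unit attention vector; a 10-unit ReLU
# fully connected layer and a linear unit produce the storage-day
# prediction. Implemented directly with batched matrix operations
# (no external deep-learning framework); gradients are exact
# backpropagation-through-time, checked against numerical differentiation
# in the test suite.

#' Model specification for the attention-based LSTM
#'
#' @param n_bands Sequence length m, the waveband count (default 200).
#' @param n_offsets Features per step, the offset count (default 11).
#' @param lstm_units LSTM hidden units (default 21, tanh activation).
#' @param attention_units Width of the attention vector (default 50).
#' @param fc_units Fully connected units (default 10, ReLU).
#' @param epochs Training epochs; every batch is seen once per epoch
#'   (default 1000).
#' @param optimizer `"sgd"` (plain gradient descent, the default) or
#'   `"adam"` (adaptive switch).
#' @param learning_rate Step size (default 1e-3).
#' @param batch_size Minibatch size (default 32).
#' @param lr_decay_epochs Epochs at which the learning rate is multiplied
#'   by `lr_decay_factor` (default none: constant rate).
#' @param lr_decay_factor Multiplicative step-decay factor (default 0.3).
#' @param clip_norm Global gradient-norm clipping threshold, the standard
#'   stabiliser for recurrent nets (default 5; `Inf` disables).
#' @param ablation Character subset of `c("lstm", "attention", "fc")`
#'   naming layers to remove (see [ablate()]).
#' @param seed Integer seed for weight initialisation and batch shuffling.
#' @return A list of class `sors_model_spec`.
#' @export
model_spec <- function(n_bands = 200L, n_offsets = 11L,
                       lstm_units = 21L, attention_units = 50L,
                       fc_units = 10L, epochs = 1000L,
                       optimizer = c("sgd", "adam"),
                       learning_rate = 1e-3, batch_size = 32L,
                       lr_decay_epochs = integer(0), lr_decay_factor = 0.3,
                       clip_norm = 5, ablation = character(0), seed = 1L) {
  optimizer <- match.arg(optimizer)
  if (!all(ablation %in% c("lstm", "attention", "fc"))) {
    abort("`ablation` must be a subset of {lstm, attention, fc}",
          class = "sors_spec_error")
  }
  spec <- list(n_bands = as.integer(n_bands),
               n_offsets = as.integer(n_offsets),
               lstm_units = as.integer(lstm_units),
               attention_units = as.integer(attention_units),
               fc_units = as.integer(fc_units),
               epochs = as.integer(epochs), optimizer = optimizer,
               learning_rate = learning_rate,
               batch_size = as.integer(batch_size),
               lr_decay_epochs = as.integer(lr_decay_epochs),
               lr_decay_factor = lr_decay_factor,
               clip_norm = clip_norm,
               ablation = unique(ablation), seed = as.integer(seed))
  with(spec, if (any(c(n_bands, n_offsets, lstm_units, attention_units,
                       fc_units, epochs, batch_size) < 1L)) {
    abort("all sizes must be positive", class = "sors_spec_error")
  })
  class(spec) <- "sors_model_spec"
  spec
}

#' Remove layers from a model specification
#'
#' Mirrors the structural ablation study: each named layer is deleted and
#' adjacent shapes are reconciled. Without the LSTM, attention operates
#' directly on the raw per-waveband offset profiles (hidden size becomes
#' `n_offsets`). Without attention, the representation is the last LSTM
#' state (or, with the LSTM also removed, the flattened input). Without
#' the fully connected layer, the representation feeds the linear output
#' unit directly.
#'
#' @param spec A [model_spec()].
#' @param drop Character subset of `c("lstm", "attention", "fc")`.
#' @return The modified spec.
#' @export
ablate <- function(spec, drop = character(0)) {
  stopifnot(inherits(spec, "sors_model_spec"))
  if (!all(drop %in% c("lstm", "attention", "fc"))) {
    abort("`drop` must be a subset of {lstm, attention, fc}",
          class = "sors_spec_error")
  }
  spec$ablation <- unique(c(spec$ablation, drop))
  spec
}

has_layer <- function(spec, layer) !(layer %in% spec$ablation)

# Hidden size seen by the attention block (LSTM units, or raw feature
# count when the LSTM is ablated).
attention_input_dim <- function(spec) {
  if (has_layer(spec, "lstm")) spec$lstm_units else spec$n_offsets
}

# Width of the representation feeding the FC/output head.
representation_dim <- function(spec) {
  if (has_layer(spec, "attention")) {
    spec$attention_units
  } else if (has_layer(spec, "lstm")) {
    spec$lstm_units
  } else {
    spec$n_bands * spec$n_offsets  # flatten fallback
  }
}

glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(runif(nr * nc, -lim, lim), nr, nc)
}

#' Build an attention-based LSTM model
#'
#' Initialises all trainable parameters (seeded) and tabulates the exact
#' per-layer trainable parameter counts: for the default spec these are
#' LSTM `4 * ((11 + 21) * 21 + 21) = 2772`, attention
#' `21^2 + 42 * 50 = 2541`, FC `50 * 10 + 10 = 510` and output
#' `10 * 1 + 1 = 11`.
#'
#' @param spec A [model_spec()].
#' @return An object of class `sors_lstm` with elements `spec`, `params`
#'   (named list of weight matrices), `layers` (tibble: layer, units,
#'   output_shape, parameters) and `fitted = FALSE`.
#' @export
build_model <- function(spec = model_spec()) {
  stopifnot(inherits(spec, "sors_model_spec"))
  rs <- .Random.seed_swap(spec$seed)
  on.exit(.Random.seed_restore(rs))
  f <- spec$n_offsets; m <- spec$n_bands
  H <- spec$lstm_units; A <- spec$attention_units
  params <- list()
  layers <- list()
  if (has_layer(spec, "lstm")) {
    params$W <- glorot(f, 4L * H)
    params$U <- glorot(H, 4L * H)
    b <- rep(0, 4L * H)
    b[(H + 1L):(2L * H)] <- 1  # forget-gate bias
    params$b <- b
    layers$lstm <- tibble(layer = "LSTM", units = H,
                          output_shape = sprintf("%d x %d", m, H),
                          parameters = 4L * ((f + H) * H + H))
  }
  if (has_layer(spec, "attention")) {
    Ha <- attention_input_dim(spec)
    params$Wa <- glorot(Ha, Ha)
    params$Wv <- glorot(2L * Ha, A)
    layers$attention <- tibble(layer = "Attention", units = A,
                               output_shape = as.character(A),
                               parameters = Ha * Ha + 2L * Ha * A)
  }
  rep_dim <- representation_dim(spec)
  if (has_layer(spec, "fc")) {
    params$Wf <- glorot(rep_dim, spec$fc_units)
    params$bf <- rep(0, spec$fc_units)
    layers$fc <- tibble(layer = "FC", units = spec$fc_units,
                        output_shape = as.character(spec$fc_units),
                        parameters = rep_dim * spec$fc_units + spec$fc_units)
    out_in <- spec$fc_units
  } else {
    out_in <- rep_dim
  }
  params$Wo <- glorot(out_in, 1L)
  params$bo <- 0
  layers$output <- tibble(layer = "Output", units = 1L,
                          output_shape = "1",
                          parameters = out_in + 1L)
  structure(list(spec = spec, params = params,
                 layers = dplyr::bind_rows(layers), fitted = FALSE),
            class = "sors_lstm")
}

#' @export
print.sors_lstm <- function(x, ...) {
  cat(sprintf("<sors_lstm>%s %s\n",
              if (length(x$spec$ablation))
                paste0(" (ablated: ", paste(x$spec$ablation, collapse = ","), ")")
              else "",
              if (x$fitted) "fitted" else "untrained"))
  print(as.data.frame(x$layers), row.names = FALSE)
  cat(sprintf("  total trainable parameters: %d\n", sum(x$layers$parameters)))
  invisible(x)
}

# ---- forward / backward core (batched) ------------------------------------

sigmoid <- function(x) 1 / (1 + exp(-x))

# Batched attention: hs = list of m matrices (B x H), h_last = B x H.
attention_forward_batch <- function(hs, h_last, Wa, Wv) {
  m <- length(hs)
  B <- nrow(h_last)
  P <- lapply(hs, function(h) h %*% Wa)
  e <- vapply(P, function(p) rowSums(p * h_last), numeric(B))
  e <- matrix(e, B, m)                       # B x m scores
  e <- e - apply(e, 1L, max)
  a <- exp(e); a <- a / rowSums(a)           # softmax over steps
  context <- matrix(0, B, ncol(h_last))
  for (t in seq_len(m)) context <- context + a[, t] * hs[[t]]
  concat <- cbind(context, h_last)
  u <- concat %*% Wv
  v <- tanh(u)
  list(weights = a, context = context, concat = concat, v = v, P = P)
}

#' Many-to-one attention forward pass
#'
#' Scores every hidden state against the last one through the bias-free
#' projection `Wa` (`e_t = <h_t Wa, h_last>`), softmax-normalises the
#' scores over the sequence, forms the context vector as the weighted sum
#' of hidden states and returns the attention vector
#' `tanh([context; h_last] Wv)`. The weights are nonnegative and sum to 1.
#'
#' @param hidden_states `m x H` matrix of hidden states (one row per
#'   sequence step).
#' @param last_state Length-`H` vector, the final hidden state.
#' @param Wa `H x H` score projection (bias-free).
#' @param Wv `2H x A` output projection (bias-free).
#' @return A list with `weights` (length `m`, sums to 1), `context`
#'   (length `H`) and `attention_vector` (length `A`).
#' @export
attention_forward <- function(hidden_states, last_state, Wa, Wv) {
  stopifnot(is.matrix(hidden_states),
            ncol(hidden_states) == length(last_state),
            nrow(Wa) == ncol(hidden_states),
            nrow(Wv) == 2L * ncol(hidden_states))
  hs <- lapply(seq_len(nrow(hidden_states)),
               function(t) matrix(hidden_states[t, ], 1L))
  out <- attention_forward_batch(hs, matrix(last_state, 1L), Wa, Wv)
  list(weights = as.numeric(out$weights),
       context = as.numeric(out$context),
       attention_vector = as.numeric(out$v))
}

# Full forward pass. X: B x m x f array. Returns prediction and cache.
nn_forward <- function(params, X, spec) {
  B <- dim(X)[1]; m <- dim(X)[2]
  xs <- lapply(seq_len(m), function(t) matrix(X[, t, ], nrow = B))
  cache <- list(xs = xs, B = B)
  if (has_layer(spec, "lstm")) {
    H <- spec$lstm_units
    h <- matrix(0, B, H); cc <- matrix(0, B, H)
    hs <- vector("list", m)
    gates <- vector("list", m)
    for (t in seq_len(m)) {
      z <- xs[[t]] %*% params$W + h %*% params$U +
        matrix(params$b, B, 4L * H, byrow = TRUE)
      i <- sigmoid(z[, 1:H, drop = FALSE])
      fg <- sigmoid(z[, (H + 1L):(2L * H), drop = FALSE])
      g <- tanh(z[, (2L * H + 1L):(3L * H), drop = FALSE])
      o <- sigmoid(z[, (3L * H + 1L):(4L * H), drop = FALSE])
      c_prev <- cc
      cc <- fg * cc + i * g
      tc <- tanh(cc)
      h <- o * tc
      hs[[t]] <- h
      gates[[t]] <- list(i = i, f = fg, g = g, o = o,
                         c = cc, c_prev = c_prev, tc = tc)
    }
    cache$hs <- hs; cache$gates <- gates
  } else {
    cache$hs <- xs
  }
  h_last <- cache$hs[[m]]
  if (has_layer(spec, "attention")) {
    att <- attention_forward_batch(cache$hs, h_last, params$Wa, params$Wv)
    cache$att <- att
    rep_ <- att$v
  } else if (has_layer(spec, "lstm")) {
    rep_ <- h_last
  } else {
    rep_ <- matrix(X, nrow = B)  # flatten fallback
  }
  cache$rep <- rep_
  if (has_layer(spec, "fc")) {
    q <- rep_ %*% params$Wf + matrix(params$bf, B, spec$fc_units, byrow = TRUE)
    r <- pmax(q, 0)
    cache$q <- q; cache$r <- r
  } else {
    r <- rep_
  }
  cache$pred <- as.numeric(r %*% params$Wo + params$bo)
  cache
}

# Exact gradients of the mean-squared-error loss w.r.t. every parameter.
nn_backward <- function(params, cache, y, spec) {
  B <- cache$B
  m <- length(cache$hs)
  grads <- lapply(params, function(p) p * 0)
  dpred <- matrix(2 * (cache$pred - y) / B, B, 1L)
  r <- if (has_layer(spec, "fc")) cache$r else cache$rep
  grads$Wo <- crossprod(r, dpred)
  grads$bo <- sum(dpred)
  dr <- dpred %*% t(params$Wo)
  if (has_layer(spec, "fc")) {
    dq <- dr * (cache$q > 0)
    grads$Wf <- crossprod(cache$rep, dq)
    grads$bf <- colSums(dq)
    drep <- dq %*% t(params$Wf)
  } else {
    drep <- dr
  }
  hs <- cache$hs
  dh_ext <- NULL
  if (has_layer(spec, "attention")) {
    att <- cache$att
    H <- ncol(hs[[1]])
    du <- drep * (1 - att$v^2)
    grads$Wv <- crossprod(att$concat, du)
    dconcat <- du %*% t(params$Wv)
    dctx <- dconcat[, 1:H, drop = FALSE]
    dh_last <- dconcat[, (H + 1L):(2L * H), drop = FALSE]
    a <- att$weights
    da <- vapply(hs, function(h) rowSums(dctx * h), numeric(B))
    da <- matrix(da, B, m)
    de <- a * (da - rowSums(a * da))         # softmax backward
    hWt <- hs[[m]] %*% t(params$Wa)          # d e_t / d h_t, per row
    dh_ext <- vector("list", m)
    dWa <- matrix(0, H, H)
    for (t in seq_len(m)) {
      det <- de[, t]
      dh_ext[[t]] <- a[, t] * dctx + det * hWt
      dh_last <- dh_last + det * att$P[[t]]
      dWa <- dWa + crossprod(hs[[t]], det * hs[[m]])
    }
    grads$Wa <- dWa
    dh_ext[[m]] <- dh_ext[[m]] + dh_last
  } else if (has_layer(spec, "lstm")) {
    dh_ext <- vector("list", m)
    zero <- matrix(0, B, spec$lstm_units)
    for (t in seq_len(m)) dh_ext[[t]] <- zero
    dh_ext[[m]] <- drep
  }
  if (has_layer(spec, "lstm")) {
    H <- spec$lstm_units
    dW <- grads$W; dU <- grads$U; db <- grads$b
    dh_next <- matrix(0, B, H); dc_next <- matrix(0, B, H)
    for (t in rev(seq_len(m))) {
      gt <- cache$gates[[t]]
      dh <- dh_ext[[t]] + dh_next
      do_ <- dh * gt$tc
      dc <- dc_next + dh * gt$o * (1 - gt$tc^2)
      di <- dc * gt$g
      dg <- dc * gt$i
      df <- dc * gt$c_prev
      dz <- cbind(di * gt$i * (1 - gt$i),
                  df * gt$f * (1 - gt$f),
                  dg * (1 - gt$g^2),
                  do_ * gt$o * (1 - gt$o))
      dW <- dW + crossprod(cache$xs[[t]], dz)
      h_prev <- if (t > 1L) cache$hs[[t - 1L]] else matrix(0, B, H)
      dU <- dU + crossprod(h_prev, dz)
      db <- db + colSums(dz)
      dh_next <- dz %*% t(params$U)
      dc_next <- dc * gt$f
    }
    grads$W <- dW; grads$U <- dU; grads$b <- db
  }
  grads
}

# ---- training --------------------------------------------------------------

make_optimizer <- function(kind, params) {
  if (kind == "sgd") {
    list(step = function(params, grads, state, lr) {
      list(params = purrr::map2(params, grads, function(p, g) p - lr * g),
           state = state)
    }, state = list())
  } else {
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    state <- list(m = lapply(params, function(p) p * 0),
                  v = lapply(params, function(p) p * 0), t = 0)
    list(step = function(params, grads, state, lr) {
      state$t <- state$t + 1
      state$m <- purrr::map2(state$m, grads, function(m, g) b1 * m + (1 - b1) * g)
      state$v <- purrr::map2(state$v, grads, function(v, g) b2 * v + (1 - b2) * g^2)
      mh <- lapply(state$m, function(m) m / (1 - b1^state$t))
      vh <- lapply(state$v, function(v) v / (1 - b2^state$t))
      params <- purrr::pmap(list(params, mh, vh),
                            function(p, m, v) p - lr * m / (sqrt(v) + eps))
      list(params = params, state = state)
    }, state = state)
  }
}

#' Train the attention-based LSTM
#'
#' Minimises the mean squared error of the storage-day prediction by
#' (stochastic) gradient descent with exact backpropagation through time.
#' Inputs are standardised per (waveband, offset) cell and labels are
#' standardised, using training-set statistics stored in the fitted model;
#' the reported loss history is on the original day scale.
#'
#' @param object An unfitted `sors_lstm` from [build_model()].
#' @param x Model input: an `n x bands x offsets` array (see
#'   [as_model_input()]) or a processed-dataset tibble with a `spectra`
#'   column.
#' @param y Numeric storage-day labels (taken from `x` when it is a
#'   processed tibble).
#' @param ... Unused.
#' @return The fitted `sors_lstm`, with `loss_history` (tibble: epoch,
#'   mse) and `final_mse`.
#' @export
fit.sors_lstm <- function(object, x, y = NULL, ...) {
  if (is.data.frame(x)) {
    if (is.null(y)) y <- x$day
    x <- as_model_input(x)
  }
  stopifnot(length(dim(x)) == 3L, dim(x)[1] == length(y))
  spec <- object$spec
  if (dim(x)[2] != spec$n_bands || dim(x)[3] != spec$n_offsets) {
    abort(sprintf("input is %d x %d per sample; spec expects %d x %d",
                  dim(x)[2], dim(x)[3], spec$n_bands, spec$n_offsets),
          class = "sors_contract_error")
  }
  n <- dim(x)[1]
  mu <- apply(x, c(2L, 3L), mean)
  sg <- pmax(apply(x, c(2L, 3L), sd), 1e-8)
  Xs <- sweep(sweep(x, c(2L, 3L), mu, "-"), c(2L, 3L), sg, "/")
  y_mu <- mean(y); y_sd <- max(sd(y), 1e-8)
  ys <- (y - y_mu) / y_sd

  rs <- .Random.seed_swap(spec$seed + 1L)
  on.exit(.Random.seed_restore(rs))
  params <- object$params
  opt <- make_optimizer(spec$optimizer, params)
  state <- opt$state
  history <- numeric(spec$epochs)
  for (ep in seq_len(spec$epochs)) {
    lr <- spec$learning_rate *
      spec$lr_decay_factor^sum(ep > spec$lr_decay_epochs)
    idx <- sample.int(n)
    starts <- seq(1L, n, by = spec$batch_size)
    ep_sse <- 0
    for (s in starts) {
      b <- idx[s:min(s + spec$batch_size - 1L, n)]
      Xb <- Xs[b, , , drop = FALSE]
      cache <- nn_forward(params, Xb, spec)
      res <- cache$pred - ys[b]
      ep_sse <- ep_sse + sum(res^2)
      grads <- nn_backward(params, cache, ys[b], spec)
      if (is.finite(spec$clip_norm)) {
        gn <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
        if (gn > spec$clip_norm) {
          grads <- lapply(grads, function(g) g * (spec$clip_norm / gn))
        }
      }
      stepped <- opt$step(params, grads, state, lr)
      params <- stepped$params; state <- stepped$state
    }
    history[ep] <- (ep_sse / n) * y_sd^2
    if (!is.finite(history[ep])) {
      abort(sprintf("training diverged (non-finite loss) at epoch %d", ep),
            class = "sors_training_error")
    }
  }
  object$params <- params
  object$scaling <- list(mu = mu, sd = sg, y_mu = y_mu, y_sd = y_sd)
  object$loss_history <- tibble(epoch = seq_len(spec$epochs), mse = history)
  object$final_mse <- history[length(history)]
  object$fitted <- TRUE
  object
}

#' @importFrom generics fit
#' @export
generics::fit

#' Predict storage days for processed samples
#'
#' @param object A fitted `sors_lstm`.
#' @param newdata An `n x bands x offsets` array or processed tibble.
#' @param ... Unused.
#' @return Numeric vector of predicted (continuous) storage days.
#' @export
predict.sors_lstm <- function(object, newdata, ...) {
  if (!isTRUE(object$fitted)) {
    abort("model has not been trained", class = "sors_state_error")
  }
  if (is.data.frame(newdata)) newdata <- as_model_input(newdata)
  if (length(dim(newdata)) == 2L) {
    newdata <- array(newdata, dim = c(1L, dim(newdata)))
  }
  sc <- object$scaling
  Xs <- sweep(sweep(newdata, c(2L, 3L), sc$mu, "-"), c(2L, 3L), sc$sd, "/")
  pred <- nn_forward(object$params, Xs, object$spec)$pred
  pred * sc$y_sd + sc$y_mu
}

#' Attention weights assigned to each waveband
#'
#' @param object A fitted `sors_lstm` with an attention layer.
#' @param newdata Processed samples (array or tibble).
#' @return A matrix `n x bands` of softmax attention weights (rows sum
#'   to 1).
#' @export
attention_weights <- function(object, newdata) {
  if (!isTRUE(object$fitted)) {
    abort("model has not been trained", class = "sors_state_error")
  }
  if (!has_layer(object$spec, "attention")) {
    abort("model has no attention layer", class = "sors_state_error")
  }
  if (is.data.frame(newdata)) newdata <- as_model_input(newdata)
  sc <- object$scaling
  Xs <- sweep(sweep(newdata, c(2L, 3L), sc$mu, "-"), c(2L, 3L), sc$sd, "/")
  nn_forward(object$params, Xs, object$spec)$att$weights
}

#' @export
tidy.sors_lstm <- function(x, ...) x$layers

#' @export
glance.sors_lstm <- function(x, ...) {
  tibble(fitted = x$fitted,
         total_parameters = sum(x$layers$parameters),
         epochs = if (x$fitted) x$spec$epochs else NA_integer_,
         final_mse = if (x$fitted) x$final_mse else NA_real_,
         optimizer = x$spec$optimizer,
         ablation = paste(x$spec$ablation, collapse = ","))
}

#' Plot the training loss history
#'
#' @param object A fitted `sors_lstm`.
#' @param ... Unused.
#' @return A ggplot of epoch versus training MSE (log scale).
#' @export
autoplot.sors_lstm <- function(object, ...) {
  if (!isTRUE(object$fitted)) {
    abort("model has not been trained", class = "sors_state_error")
  }
  ggplot2::ggplot(object$loss_history,
                  ggplot2::aes(x = .data$epoch, y = .data$mse)) +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "epoch", y = "training MSE (days^2)",
                  title = "Attention-LSTM training loss") +
    ggplot2::theme_minimal()
}
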