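test_that("default architecture reproduces the published parameter counts", {
  m <- build_model(model_spec())
  counts <- setNames(m$layers$parameters, m$layers$layer)
  expect_identical(counts[["LSTM"]], 2772L)
  expect_identical(counts[["Attention"]], 2541L)
  expect_identical(counts[["FC"]], 510L)
  expect_identical(counts[["Output"]], 11L)
  expect_identical(m$layers$output_shape, c("200 x 21", "50", "10", "1"))
  # closed-form cross-checks
  expect_identical(counts[["LSTM"]], 4L * ((11L + 21L) * 21L + 21L))
  expect_identical(counts[["Attention"]], 21L * 21L + 42L * 50L)
})

test_that("toy and ablated architectures match closed-form counts", {
  toy <- build_model(model_spec(n_bands = 3, n_offsets = 1, lstm_units = 1))
  expect_identical(toy$layers$parameters[1], 4L * ((1L + 1L) * 1L + 1L))  # 12

  flat <- build_model(ablate(model_spec(), c("lstm", "attention")))
  expect_identical(flat$layers$layer, c("FC", "Output"))
  expect_identical(flat$layers$parameters, c(2200L * 10L + 10L, 11L))

  no_fc <- build_model(ablate(model_spec(), "fc"))
  expect_identical(tail(no_fc$layers$parameters, 1), 50L + 1L)

  no_lstm <- build_model(ablate(model_spec(), "lstm"))
  att_row <- no_lstm$layers[no_lstm$layers$layer == "Attention", ]
  expect_identical(att_row$parameters, 11L * 11L + 22L * 50L)

  expect_identical(ablate(model_spec())$ablation, character(0))
  expect_error(ablate(model_spec(), "conv"), class = "sors_spec_error")
})

test_that("attention weights are uniform for constant scores and concentrated in the limit", {
  m <- 8; H <- 2
  hs <- cbind(rnorm(m), rep(0, m))     # all states orthogonal to last_state
  last <- c(0, 1)
  Wa <- diag(H)
  Wv <- matrix(rnorm(2 * H * 3), 2 * H, 3)
  out <- attention_forward(hs, last, Wa, Wv)
  expect_equal(out$weights, rep(1 / m, m))
  expect_equal(out$context, colMeans(hs))
  expect_equal(sum(out$weights), 1)

  hs2 <- matrix(rnorm(m * H, 0, 0.01), m, H)
  hs2[3, ] <- c(50, 50)                # dominates the score against itself
  out2 <- attention_forward(hs2, hs2[3, ], Wa, Wv)
  expect_gt(out2$weights[3], 0.999)
  expect_equal(out2$context, hs2[3, ], tolerance = 1e-2)
})

test_that("attention matches a step-by-step brute-force oracle", {
  set.seed(77)
  for (case in 1:100) {
    m <- sample(2:6, 1); H <- sample(2:4, 1); A <- sample(2:6, 1)
    hs <- matrix(rnorm(m * H), m, H)
    last <- hs[m, ]
    Wa <- matrix(rnorm(H * H), H, H)
    Wv <- matrix(rnorm(2 * H * A), 2 * H, A)
    out <- attention_forward(hs, last, Wa, Wv)
    e <- vapply(seq_len(m), function(t) sum((hs[t, ] %*% Wa) * last),
                numeric(1))
    a <- exp(e - max(e)); a <- a / sum(a)
    ctx <- as.numeric(t(hs) %*% a)
    v <- as.numeric(tanh(c(ctx, last) %*% Wv))
    expect_equal(out$weights, a)
    expect_equal(out$context, ctx)
    expect_equal(out$attention_vector, v)
    expect_equal(sum(out$weights), 1, tolerance = 1e-6)
  }
})

test_that("analytic gradients match numerical differentiation for every variant", {
  variants <- list(character(0), "fc", "attention", "lstm",
                   c("lstm", "attention"))
  set.seed(12)
  X <- array(rnorm(2 * 5 * 3), c(2, 5, 3))
  y <- c(0.7, -1.1)
  for (ab in variants) {
    spec <- model_spec(n_bands = 5, n_offsets = 3, lstm_units = 4,
                       attention_units = 6, fc_units = 3,
                       ablation = ab, seed = 3)
    mod <- build_model(spec)
    cache <- sorsfresh:::nn_forward(mod$params, X, spec)
    g <- sorsfresh:::nn_backward(mod$params, cache, y, spec)
    loss <- function(p) {
      mean((sorsfresh:::nn_forward(p, X, spec)$pred - y)^2)
    }
    for (nm in names(mod$params)) {
      k <- sample(length(mod$params[[nm]]), 1)
      eps <- 1e-6
      up <- mod$params; up[[nm]][k] <- up[[nm]][k] + eps
      dn <- mod$params; dn[[nm]][k] <- dn[[nm]][k] - eps
      num <- (loss(up) - loss(dn)) / (2 * eps)
      expect_equal(g[[nm]][k], num, tolerance = 1e-4)
    }
  }
})

test_that("constant labels are fitted to near-zero loss", {
  set.seed(5)
  X <- array(rnorm(24 * 20 * 4), c(24, 20, 4))
  spec <- model_spec(n_bands = 20, n_offsets = 4, lstm_units = 6,
                     attention_units = 8, fc_units = 4, epochs = 40,
                     optimizer = "adam", learning_rate = 5e-3, seed = 2)
  fitm <- fit(build_model(spec), X, rep(3, 24))
  expect_lt(fitm$final_mse, 1e-3)
  expect_identical(nrow(fitm$loss_history), 40L)
  expect_equal(unname(predict(fitm, X)), rep(3, 24), tolerance = 0.1)
})

test_that("training reduces the loss below the label variance; permuted labels do not generalise", {
  proc <- small_processed()
  X <- as_model_input(proc)
  y <- proc$day
  spec <- model_spec(epochs = 30, optimizer = "adam", learning_rate = 3e-3,
                     seed = 4)
  fitm <- fit(build_model(spec), X, y)
  expect_lt(fitm$final_mse, var(y))

  idx <- split_dataset(length(y), eval_protocol(seed = 3))
  set.seed(31)
  y_perm <- sample(y[idx$train])
  fperm <- fit(build_model(spec), X[idx$train, , , drop = FALSE], y_perm)
  r2 <- metric_r2(y[idx$test], predict(fperm, X[idx$test, , , drop = FALSE]))
  expect_lt(r2, 0.3)
})

test_that("prediction is stateless and batch-invariant", {
  proc <- small_processed()
  X <- as_model_input(proc)
  spec <- model_spec(epochs = 5, optimizer = "adam", seed = 9)
  expect_error(predict(build_model(spec), X), class = "sors_state_error")
  fitm <- fit(build_model(spec), X, proc$day)
  batch <- predict(fitm, X[1:6, , , drop = FALSE])
  single <- vapply(1:6, function(i) {
    predict(fitm, X[i, , , drop = FALSE])
  }, numeric(1))
  expect_equal(single, batch)
  expect_length(predict(fitm, X[1, , , drop = FALSE]), 1)
  # determinism under identical seeds
  fit2 <- fit(build_model(spec), X, proc$day)
  expect_identical(predict(fit2, X), predict(fitm, X))
})

test_that("a noiseless strongly-signalled campaign is predicted with R2 >= 0.9", {
  cfg <- clean_sim_config(n_shrimp = 8, seed = 55)
  proc <- simulate_processed_dataset(
    cfg, preprocess_config(n_bands_out = 50))
  spec <- model_spec(n_bands = 50, epochs = 80, optimizer = "adam",
                     learning_rate = 3e-3, seed = 6)
  idx <- split_dataset(nrow(proc), eval_protocol(seed = 2))
  X <- as_model_input(proc)
  fitm <- fit(build_model(spec), X[idx$train, , , drop = FALSE],
              proc$day[idx$train])
  r2 <- metric_r2(proc$day[idx$test],
                  predict(fitm, X[idx$test, , , drop = FALSE]))
  expect_gte(r2, 0.9)
})

test_that("attention weights sum to one for arbitrary inputs", {
  proc <- small_processed()
  X <- as_model_input(proc)
  spec <- model_spec(epochs = 3, optimizer = "adam", seed = 13)
  fitm <- fit(build_model(spec), X[1:20, , , drop = FALSE], proc$day[1:20])
  w <- attention_weights(fitm, X[1:10, , , drop = FALSE])
  expect_identical(dim(w), c(10L, 200L))
  expect_equal(rowSums(w), rep(1, 10), tolerance = 1e-6)
  expect_true(all(w >= 0))
})

test_that("tidy and glance summarise architecture and fit", {
  m <- build_model(model_spec())
  expect_identical(tidy(m)$parameters, c(2772L, 2541L, 510L, 11L))
  g <- glance(m)
  expect_identical(g$total_parameters, 2772L + 2541L + 510L + 11L)
  expect_false(g$fitted)
})
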