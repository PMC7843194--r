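test_that("sigmoid matches its closed form and symmetry", {
  expect_identical(sigmoid(0), 0.5)
  for (a in c(-3, -1, 0, 1, 3))
    expect_equal(sigmoid(a) + sigmoid(-a), 1, tolerance = 1e-15)
  expect_equal(sigmoid(2), 1 / (1 + exp(-2)), tolerance = 1e-15)
  x <- matrix(seq(-5, 5, length.out = 12), 3)
  expect_true(all(sigmoid(x) > 0 & sigmoid(x) < 1))
  expect_true(all(diff(sigmoid(seq(-4, 4, by = 0.5))) > 0))
})

test_that("masking corruption zeroes the expected fraction", {
  x <- matrix(runif(100) + 1, 10, 10)
  expect_identical(corrupt(x, 0, seed = 1), x)
  expect_true(all(corrupt(x, 1, seed = 1) == 0))
  big <- matrix(1, 100, 100)
  zeroed <- mean(corrupt(big, 0.5, seed = 42) == 0)
  expect_lt(abs(zeroed - 0.5), 3 * sqrt(0.25 / 1e4))  # 3 binomial SDs
  expect_identical(corrupt(big, 0.5, seed = 7), corrupt(big, 0.5, seed = 7))
})

test_that("encode and decode match the hand matrix-product oracle", {
  ae <- eegsdae:::new_dae(W = matrix(0, 2, 3), b = rep(0, 2),
                          W_dec = matrix(0, 3, 2), b_dec = rep(0, 3))
  x <- matrix(rnorm(9), 3)
  expect_true(all(encode(ae, x) == 0.5))
  expect_true(all(decode(ae, matrix(0, 2, 3)) == 0.5))

  set.seed(3)
  W <- matrix(rnorm(6), 3, 2); b <- rnorm(3)
  Wd <- matrix(rnorm(6), 2, 3); bd <- rnorm(2)
  ae2 <- eegsdae:::new_dae(W, b, Wd, bd)
  x2 <- matrix(rnorm(8), 2, 4)
  manual <- matrix(0, 3, 4)
  for (j in 1:4) for (i in 1:3)
    manual[i, j] <- 1 / (1 + exp(-(sum(W[i, ] * x2[, j]) + b[i])))
  expect_equal(encode(ae2, x2), manual, tolerance = 1e-14, ignore_attr = TRUE)
  y <- encode(ae2, x2)
  manual_z <- matrix(0, 2, 4)
  for (j in 1:4) for (i in 1:2)
    manual_z[i, j] <- 1 / (1 + exp(-(sum(Wd[i, ] * y[, j]) + bd[i])))
  expect_equal(decode(ae2, y), manual_z, tolerance = 1e-14, ignore_attr = TRUE)
  expect_error(encode(ae2, matrix(0, 3, 2)), "dimension")
})

test_that("zero learning rate leaves the autoencoder at its initialisation", {
  x <- matrix(runif(5 * 300), 5, 300)
  cfg <- train_config(learning_rate = 0, seed = 9, minibatch = 50, epochs = 3)
  ae <- suppressWarnings(train_autoencoder(x, 3, cfg))
  init <- eegsdae:::with_seed(9L, eegsdae:::init_dae(5L, 3L))
  expect_identical(ae$W, init$W)
  expect_identical(ae$W_dec, init$W_dec)
  expect_equal(ae$loss_history[1], ae$loss_history[length(ae$loss_history)])
})

test_that("a constant 0.5 input is reconstructed to high precision", {
  x <- matrix(0.5, 4, 400)
  cfg <- train_config(corruption_fraction = 0, learning_rate = 1,
                      minibatch = 100, epochs = 60, seed = 2)
  ae <- train_autoencoder(x, 2, cfg)
  expect_lt(ae$final_mse, 1e-3)
})

test_that("the reference training configuration runs on a 12-channel recording", {
  x <- eegsdae:::with_seed(5L, matrix(runif(12 * 1200), 12, 1200))
  cfg <- train_config()                   # corruption 0.5, lr 1, batch 200, 8 epochs
  expect_identical(cfg$corruption_fraction, 0.5)
  expect_identical(cfg$learning_rate, 1)
  expect_identical(cfg$minibatch, 200L)
  expect_identical(cfg$epochs, 8L)
  ae <- train_autoencoder(x, 8, cfg)
  expect_true(is.finite(ae$final_mse))
  expect_true(isTRUE(ae$trained))
})

test_that("stacked training respects dimensions and rejects m > n", {
  x <- eegsdae:::with_seed(1L, matrix(rnorm(16 * 800), 16, 800))
  model <- stack_train(x, 8, 3, train_config(seed = 4))
  expect_identical(nrow(model$stages[[1]]$W), 8L)
  expect_identical(nrow(model$stages[[2]]$W), 3L)
  expect_identical(ncol(model$stages[[2]]$W), 8L)
  expect_error(stack_train(x, 3, 8, train_config()), "must be <=")

  degenerate <- suppressWarnings(
    stack_train(matrix(rnorm(2 * 300), 2, 300), 1, 1, train_config(seed = 1)))
  expect_identical(degenerate$n, 1L)
  expect_identical(degenerate$m, 1L)
})

test_that("training is bit-identical under a fixed seed and loss decreases", {
  x <- eegsdae:::with_seed(8L, matrix(rnorm(9 * 1500), 9, 1500))
  m1 <- stack_train(x, 6, 2, train_config(seed = 13))
  m2 <- stack_train(x, 6, 2, train_config(seed = 13))
  expect_identical(m1$stages[[1]]$W, m2$stages[[1]]$W)
  expect_identical(m1$stages[[2]]$W_dec, m2$stages[[2]]$W_dec)
  expect_identical(m1$err1, m2$err1)
  h <- m1$stages[[1]]$loss_history
  expect_lt(h[length(h)], h[1])
})

test_that("hidden activations and reconstructions stay inside (0, 1)", {
  for (seed in 1:3) {
    x <- eegsdae:::with_seed(seed, matrix(rnorm(6 * 500, sd = 30), 6, 500))
    model <- stack_train(x, 4, 2, train_config(seed = seed, epochs = 2))
    xs <- eegsdae:::sdae_scale(model, x)
    y1 <- encode(model$stages[[1]], xs)
    y2 <- encode(model$stages[[2]], y1)
    z <- decode(model$stages[[1]], y1)
    expect_true(all(y1 > 0 & y1 < 1))
    expect_true(all(y2 > 0 & y2 < 1))
    expect_true(all(z > 0 & z < 1))
  }
})

test_that("extract_feature is the mean of the deepest hidden series", {
  x <- eegsdae:::with_seed(2L, matrix(rnorm(7 * 600), 7, 600))
  model <- stack_train(x, 5, 3, train_config(seed = 3, epochs = 2))
  y2 <- encode(model$stages[[2]],
               encode(model$stages[[1]], eegsdae:::sdae_scale(model, x)))
  manual <- (y2[1, ] + y2[2, ] + y2[3, ]) / 3
  expect_equal(extract_feature(model, x), manual, tolerance = 1e-14)

  model1 <- stack_train(x, 5, 1, train_config(seed = 3, epochs = 2))
  y2_single <- encode(model1$stages[[2]],
                      encode(model1$stages[[1]], eegsdae:::sdae_scale(model1, x)))
  expect_equal(extract_feature(model1, x), as.numeric(y2_single[1, ]),
               tolerance = 1e-14)
  expect_error(extract_feature(model, x[1:3, ]), "channel count")
})

test_that("models survive a JSON save/load round-trip", {
  x <- eegsdae:::with_seed(4L, matrix(rnorm(6 * 400), 6, 400))
  model <- stack_train(x, 4, 2, train_config(seed = 5, epochs = 2))
  path <- tempfile(fileext = ".json")
  save_sdae(model, path)
  back <- load_sdae(path)
  expect_equal(back$stages[[1]]$W, model$stages[[1]]$W, tolerance = 1e-12)
  expect_equal(back$scaler$lo, unname(model$scaler$lo), tolerance = 1e-12)
  expect_equal(extract_feature(back, x), extract_feature(model, x),
               tolerance = 1e-10)
})
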