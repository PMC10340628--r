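test_that("the 1D-CNN+LSTM layer inventory matches the stated sequence", {
  m <- nn_init(build_cnn1d_lstm(), 1)
  inv <- nn_layers(m)
  types <- inv$type[inv$type != "relu"]
  expect_equal(types, c("conv1d", "maxpool1d", "conv1d", "maxpool1d",
                        "lstm", "lstm", "dropout", "dense"))
  convs <- m$layers[vapply(m$layers, function(l) l$type == "conv1d", logical(1))]
  expect_equal(vapply(convs, `[[`, integer(1), "out_ch"), c(16L, 32L))
  lstms <- m$layers[vapply(m$layers, function(l) l$type == "lstm", logical(1))]
  expect_equal(vapply(lstms, `[[`, integer(1), "hidden"), c(64L, 64L))
  expect_equal(m$output_shape, 2L)
})

test_that("temporal max pooling halves the sequence length (floor) at each stage", {
  m <- nn_init(build_cnn1d_lstm(), 1)
  shp <- lapply(m$layers, `[[`, "out_shape")
  types <- vapply(m$layers, `[[`, character(1), "type")
  pre_pool <- which(types == "maxpool1d")
  for (i in pre_pool) {
    expect_equal(shp[[i]][1], shp[[i - 1]][1] %/% 2L)
  }
})

test_that("per-chunk class probabilities are valid distributions", {
  set.seed(31)
  m <- nn_init(build_cnn1d_lstm(list(input_len = 400, k1 = 8, s1 = 2, k2 = 4,
                                     s2 = 2)), 2)
  p <- nn_predict_probs(m, array(rnorm(400 * 5), c(400, 1, 5)))
  expect_true(all(p >= 0))
  expect_equal(colSums(p), rep(1, 5), tolerance = 1e-6)

  m2 <- nn_init(build_resnet2d(), 3)
  p2 <- nn_predict_probs(m2, array(rnorm(128 * 63 * 2), c(128, 63, 1, 2)))
  expect_equal(colSums(p2), rep(1, 2), tolerance = 1e-6)
})

test_that("the residual encoder emits 64-dimensional chunk embeddings", {
  m <- nn_init(build_resnet2d(), 1)
  e <- nn_embed(m, array(rnorm(128 * 63 * 3), c(128, 63, 1, 3)))
  expect_equal(dim(e), c(64L, 3L))
  expect_equal(m$embedding_dim, 64L)
  widths <- vapply(m$layers[vapply(m$layers, function(l) l$type == "resblock",
                                   logical(1))], `[[`, integer(1), "out_ch")
  expect_equal(widths, c(16L, 16L, 32L, 32L, 64L, 64L))
  expect_error(nn_forward(m, array(rnorm(100), c(10, 10, 1, 1))))
})

test_that("zeroing the residual branch reduces a block to the identity", {
  set.seed(32)
  lay <- pdvoice:::.layer_init(pdvoice:::layer_resblock(8L, stride = 1L),
                               c(6L, 5L, 8L))
  # zero the second conv and its batch-norm scale so F(x) = 0
  lay$params$conv2$W[] <- 0
  lay$params$bn2$gamma[] <- 0
  x <- array(abs(rnorm(6 * 5 * 8 * 2)), c(6, 5, 8, 2)) # positive so final ReLU is inert
  out <- pdvoice:::.resblock_fwd(lay, x, training = FALSE)
  expect_equal(out$y, x, tolerance = 1e-12)
})

test_that("positive-scaling invariance holds through a zero-bias homogeneous stem", {
  set.seed(33)
  m <- nn_init(build_resnet2d(), 5)
  x <- array(rnorm(128 * 63 * 3), c(128, 63, 1, 3))
  p1 <- nn_predict_probs(m, x)
  p2 <- nn_predict_probs(m, 2 * x)
  # batch-norm standardizes scale away entirely in eval... instead check the
  # ordering of the raw stem convolution, which is positively homogeneous
  stem <- m$layers[[1]]
  y1 <- pdvoice:::.conv2d_fwd(list(W = stem$params$W, b = numeric(16)), x,
                              stem$kh, stem$kw, stem$sh, stem$sw, stem$ph, stem$pw)$y
  y2 <- pdvoice:::.conv2d_fwd(list(W = stem$params$W, b = numeric(16)), 2 * x,
                              stem$kh, stem$kw, stem$sh, stem$sw, stem$ph, stem$pw)$y
  expect_equal(y2, 2 * y1, tolerance = 1e-9)
  expect_identical(order(y1[, , 1, 1]), order(y2[, , 1, 1]))
})

test_that("the pretrained adapter mean-pools frames deterministically", {
  const_embedder <- structure(list(
    name = "const", dim = 3,
    frame_embeddings = function(samples, rate) {
      matrix(rep(c(1, 2, 3), each = 5), 5, 3)
    }), class = "pretrained_embedder")
  rec <- audio_recording(rnorm(8000), 8000)
  expect_equal(pretrained_embed(rec, const_embedder), c(1, 2, 3))

  two_row <- structure(list(
    name = "tworow", dim = 2,
    frame_embeddings = function(samples, rate) rbind(c(1, 0), c(0, 1))),
    class = "pretrained_embedder")
  expect_equal(pretrained_embed(rec, two_row), c(0.5, 0.5))

  empty <- structure(list(name = "empty", dim = 2,
                          frame_embeddings = function(samples, rate) {
                            matrix(0, 0, 2)
                          }), class = "pretrained_embedder")
  expect_error(pretrained_embed(rec, empty), "no frames")

  stub <- stub_embedder(dim = 32)
  v1 <- pretrained_embed(rec, stub)
  v2 <- pretrained_embed(rec, stub)
  expect_identical(v1, v2)
  expect_length(v1, 32)
})

test_that("speaker scores average chunk scores", {
  expect_equal(speaker_score(c(0.2, 0.8)), 0.5)
  expect_equal(speaker_score(0.7), 0.7)
  set.seed(34)
  s <- stats::runif(7)
  total <- 0
  for (v in s) total <- total + v
  expect_equal(speaker_score(s), total / 7, tolerance = 1e-12)
  expect_error(speaker_score(numeric(0)), "no chunk scores")
  expect_error(speaker_score(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("training both speech models on a fixed synthetic set is reproducible", {
  set.seed(35)
  n <- 12
  x1 <- array(rnorm(400 * n), c(400, 1, n))
  y <- rep(c(0L, 1L), n / 2)
  x1[, , y == 1] <- x1[, , y == 1] + 1
  tr <- list(x = x1[, , 1:8, drop = FALSE], y = y[1:8])
  va <- list(x = x1[, , 9:12, drop = FALSE], y = y[9:12])
  cfg <- train_config(epochs = 3, patience = 2, dropout_grid = 0.2,
                      l2_grid = 1e-4, seed = 7)
  m <- build_cnn1d_lstm(list(input_len = 400, k1 = 8, s1 = 2, k2 = 4, s2 = 2))
  f1 <- train_deep(m, tr, va, cfg)
  f2 <- train_deep(m, tr, va, cfg)
  expect_equal(f1$history$train_loss, f2$history$train_loss, tolerance = 1e-6)
  expect_identical(nn_get_params(f1$model), nn_get_params(f2$model))

  x2 <- array(rnorm(128 * 63 * 6), c(128, 63, 1, 6))
  y2 <- rep(c(0L, 1L), 3)
  tr2 <- list(x = x2[, , , 1:4, drop = FALSE], y = y2[1:4])
  va2 <- list(x = x2[, , , 5:6, drop = FALSE], y = y2[5:6])
  cfg2 <- train_config(epochs = 2, patience = 1, dropout_grid = 0.2,
                       l2_grid = 1e-4, seed = 8)
  g1 <- train_deep(build_resnet2d(), tr2, va2, cfg2)
  g2 <- train_deep(build_resnet2d(), tr2, va2, cfg2)
  expect_equal(g1$history$train_loss, g2$history$train_loss, tolerance = 1e-6)
})
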