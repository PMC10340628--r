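test_that("mean pooling averages embeddings exactly", {
  expect_equal(mean_pool(list(c(0, 2), c(2, 0))), c(1, 1))
  expect_equal(mean_pool(list(c(3, 4, 5))), c(3, 4, 5))
  set.seed(301)
  vs <- lapply(1:100, function(i) rnorm(6))
  acc <- numeric(6)
  for (v in vs) acc <- acc + v
  expect_equal(mean_pool(vs), acc / 100, tolerance = 1e-9)
  expect_error(mean_pool(list()), "no embeddings")
  expect_error(mean_pool(list(1:2, 1:3)), "unequal")
})

test_that("early fusion concatenates and records slices", {
  s <- rnorm(768)
  l <- rnorm(192)
  fv <- early_fuse(s, l)
  expect_length(fv, 960)
  expect_equal(as.numeric(fv[attr(fv, "parts")$speech]), s)
  expect_equal(as.numeric(fv[attr(fv, "parts")$language]), l)
  fz <- early_fuse(s, numeric(192))
  expect_equal(as.numeric(fz[1:768]), s)
  expect_error(early_fuse(c(1, NA), l), "finite")
})

test_that("feature scaling uses only the statistics it was fitted on", {
  set.seed(302)
  Xtrain <- matrix(rnorm(20 * 4, mean = 3, sd = 2), 20, 4)
  Xtest <- matrix(rnorm(5 * 4, mean = -10, sd = 9), 5, 4)
  sc <- fit_scaler(Xtrain)
  Zte <- apply_scaler(Xtest, sc)
  # recomputation: transform must equal (x - train_mean) / train_sd exactly,
  # i.e. no test-fold statistic enters
  manual <- sweep(sweep(Xtest, 2, colMeans(Xtrain)), 2,
                  apply(Xtrain, 2, sd), `/`)
  expect_equal(Zte, manual, tolerance = 1e-12)
  ztr <- apply_scaler(Xtrain, sc)
  expect_equal(colMeans(ztr), numeric(4), tolerance = 1e-12)
})

test_that("K = 1 supervectors equal the closed-form mean and population variance", {
  set.seed(303)
  X <- matrix(rnorm(40 * 3, mean = 2), 40, 3)
  sv <- gmm_supervector(X, K = 1)
  expect_length(sv, 6)
  expect_equal(as.numeric(sv[1:3]), colMeans(X), tolerance = 1e-6)
  expect_equal(as.numeric(sv[4:6]),
               colMeans(sweep(X, 2, colMeans(X))^2), tolerance = 1e-6)
})

test_that("supervector length is 2 K d and small samples are rejected", {
  set.seed(304)
  X <- matrix(rnorm(200 * 64), 200, 64)
  sv <- gmm_supervector(X, K = 8, seed = 2)
  expect_length(sv, 2 * 8 * 64)
  expect_true(all(sv[(8 * 64 + 1):(2 * 8 * 64)] >= 1e-6))
  expect_error(gmm_supervector(X[1:5, ], K = 8), "smaller K")
})

test_that("EM recovers well-separated mixture parameters", {
  set.seed(305)
  X <- rbind(matrix(rnorm(500, 0, 1), 250, 2),
             matrix(rnorm(500, 10, 1), 250, 2))
  fit <- gmm_fit_diag(X, K = 2, seed = 11)
  expect_equal(as.numeric(fit$means[1, ]), c(0, 0), tolerance = 0.2)
  expect_equal(as.numeric(fit$means[2, ]), c(10, 10), tolerance = 0.2)
  # log-likelihood is non-decreasing (asserted internally too)
  expect_true(all(diff(fit$loglik) >= -1e-6 * (abs(fit$loglik[-1]) + 1)))
  # responsibilities assign >= 99% of points to the nearer true component
  R <- gmm_responsibilities(fit, X)
  nearer <- ifelse(rowSums(X) < 10, 1, 2)
  hard <- max.col(R)
  expect_gte(mean(hard == nearer), 0.99)
})

test_that("supervectors are invariant to the order of input embeddings", {
  set.seed(306)
  X <- rbind(matrix(rnorm(100, 0, 1), 50, 2), matrix(rnorm(100, 6, 1), 50, 2))
  sv1 <- gmm_supervector(X, K = 2, seed = 9)
  sv2 <- gmm_supervector(X[sample(100), ], K = 2, seed = 9)
  expect_equal(as.numeric(sv1), as.numeric(sv2), tolerance = 1e-4)
})

test_that("the EM log-likelihood agrees with an independent mixture fitter", {
  skip_if_not_installed("mclust")
  suppressMessages(library(mclust))
  set.seed(307)
  X <- rbind(matrix(rnorm(300, 0, 1), 150, 2), matrix(rnorm(300, 5, 1), 150, 2))
  fit <- gmm_fit_diag(X, K = 2, seed = 4)
  mc <- mclust::Mclust(X, G = 2, modelNames = "VVI", verbose = FALSE)
  # both should reach essentially the same optimum on well-separated data
  expect_equal(tail(fit$loglik, 1), mc$loglik, tolerance = 1e-2)
  expect_equal(fit$means[order(fit$means[, 1]), ],
               t(mc$parameters$mean)[order(mc$parameters$mean[1, ]), ],
               tolerance = 0.05, ignore_attr = TRUE)
})

test_that("late fusion produces validated 2-vectors", {
  fv <- late_fuse(0.9, 0.3)
  expect_equal(as.numeric(fv), c(0.9, 0.3))
  expect_length(fv, 2)
  fe <- late_fuse(0.4, 0.4)
  expect_equal(as.numeric(fe), c(0.4, 0.4))
  expect_error(late_fuse(1.2, 0.5), "\\[0, 1\\]")
})

test_that("an SVM on separable 2-D late-fusion scores fits the training set", {
  set.seed(308)
  n <- 30
  y <- rep(c(0L, 1L), each = n / 2)
  speech <- ifelse(y == 1, runif(n, 0.7, 0.95), runif(n, 0.05, 0.3))
  lang <- ifelse(y == 1, runif(n, 0.6, 0.9), runif(n, 0.1, 0.4))
  X <- t(mapply(late_fuse, speech, lang))
  r <- svm_fit_predict(X, y, X, seed = 5)
  expect_equal(as.integer(r$scores >= 0.5), y)
})

test_that("joint fusion ignores the supervector slice when its head weights are zero", {
  set.seed(309)
  mj <- build_ngram_cnn(d = 6, filters = 4, sv_dim = 10, seed = 13)
  mt <- build_ngram_cnn(d = 6, filters = 4, seed = 13)
  # same conv filters; text head = joint head restricted to the language slice
  mt$params$conv <- mj$params$conv
  mt$params$head$W <- mj$params$head$W[, 1:12]
  mt$params$head$b <- mj$params$head$b
  M <- matrix(rnorm(42), 7, 6)
  out_j <- joint_forward(M, numeric(10), mj)
  out_t <- ngram_cnn_forward(M, mt)
  expect_equal(out_j$probs, out_t$probs, tolerance = 1e-12)
  # determinism
  expect_identical(joint_forward(M, rnorm(10), mj)$language_embedding,
                   out_j$language_embedding)
  expect_error(joint_forward(M, numeric(3), mj), "supervector")
})

test_that("joint-fusion training reaches the text-CNN filters (nonzero gradient)", {
  set.seed(310)
  m <- build_ngram_cnn(d = 4, filters = 3, sv_dim = 5, seed = 21)
  M <- matrix(rnorm(20), 5, 4)
  sv <- rnorm(5)
  batch <- list(M = list(M), sv = list(sv), y = 1L)
  g <- nn_loss_grads(m, batch, training = FALSE)$grads
  # conv-filter gradient block is nonzero, and matches finite differences
  n_conv <- length(unlist(m$params$conv))
  expect_gt(max(abs(g[seq_len(n_conv)])), 0)
  th <- pdvoice::nn_get_params(m)
  i <- which.max(abs(g[seq_len(n_conv)]))
  f <- function(v) {
    th2 <- th; th2[i] <- v
    m2 <- pdvoice::nn_set_params(m, th2)
    -log(max(joint_forward(M, sv, m2)$probs[2], 1e-12))
  }
  e <- 1e-5
  fd <- (f(th[i] + e) - f(th[i] - e)) / (2 * e)
  expect_equal(fd, g[i], tolerance = 1e-5)
})
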