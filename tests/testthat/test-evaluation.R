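test_that("fold plans partition speakers with balanced, stratified folds", {
  man <- tibble::tibble(speaker_id = sprintf("s%02d", 1:40),
                        label = rep(c("PD", "HC"), each = 20))
  plan <- speaker_folds(man, k = 10, seed = 3)
  expect_setequal(plan$speaker_id, man$speaker_id)
  expect_true(all(table(plan$fold) == 4))
  expect_true(all(table(plan$fold, plan$label) == 2))
  # partition: train/test intersection empty for every fold
  for (f in 1:10) {
    expect_length(intersect(plan$speaker_id[plan$fold == f],
                            plan$speaker_id[plan$fold != f]), 0)
  }
  expect_error(speaker_folds(man[1:5, ], k = 10), "fewer speakers")
})

test_that("fold plans are seed-deterministic and seed-sensitive", {
  man <- tibble::tibble(speaker_id = sprintf("s%02d", 1:33),
                        label = rep_len(c("PD", "HC"), 33))
  p1 <- speaker_folds(man, k = 10, seed = 5)
  p2 <- speaker_folds(man, k = 10, seed = 5)
  expect_identical(p1$fold, p2$fold)
  p3 <- speaker_folds(man, k = 10, seed = 6)
  expect_false(identical(p1$fold, p3$fold))
  # uneven cohort still balanced within 1
  expect_lte(diff(range(table(p1$fold))), 1)
})

test_that("the SVM grid spans the printed decade sets", {
  cfg <- svm_config()
  expect_length(cfg$C_grid, 6)
  expect_length(cfg$gamma_grid, 7)
  expect_equal(length(cfg$C_grid) * length(cfg$gamma_grid), 42)
  expect_equal(min(cfg$C_grid), 0.001)
  expect_equal(max(cfg$C_grid), 100)
  expect_equal(min(cfg$gamma_grid), 0.0001)
  expect_equal(max(cfg$gamma_grid), 100)
})

test_that("the SVM separates separable blobs and selects grid members", {
  set.seed(401)
  n <- 40
  y <- rep(c(0L, 1L), each = n / 2)
  X <- cbind(rnorm(n, ifelse(y == 1, 3, -3), 0.5),
             rnorm(n, ifelse(y == 1, 3, -3), 0.5))
  r <- svm_fit_predict(X, y, X, seed = 2)
  expect_true(r$params$C %in% svm_config()$C_grid)
  expect_true(r$params$gamma %in% svm_config()$gamma_grid)
  expect_equal(as.integer(r$train_scores >= 0.5), y)
  expect_equal(as.integer(r$scores >= 0.5), y)
  expect_error(svm_fit_predict(X, rep(1L, n), X), "single class")
})

test_that("metrics follow confusion-matrix arithmetic with PD positive", {
  # TP=4, TN=4, FP=1, FN=1
  scores <- c(rep(0.9, 4), 0.1, rep(0.1, 4), 0.9)
  labels <- c(rep("PD", 5), rep("HC", 5))
  m <- compute_metrics(scores, labels)
  expect_equal(m$accuracy, 80)
  expect_equal(m$sensitivity, 80)
  expect_equal(m$specificity, 80)
  expect_equal(m$f1, 80)

  perfect <- compute_metrics(c(1, 1, 0, 0), c("PD", "PD", "HC", "HC"))
  expect_true(all(unlist(perfect) == 100))

  # all scores at threshold: the >= tie rule calls everything PD
  tie <- compute_metrics(rep(0.5, 6), rep(c("PD", "HC"), 3))
  expect_equal(tie$sensitivity, 100)
  expect_equal(tie$specificity, 0)

  expect_error(compute_metrics(c(0.2, 0.9), c("PD", "PD")), "single class")
})

test_that("metric identities hold against independent recomputation", {
  set.seed(402)
  scores <- stats::runif(60)
  y <- rbinom(60, 1, 0.5)
  if (length(unique(y)) == 1) y[1] <- 1 - y[1]
  m <- compute_metrics(scores, y)
  pred <- as.integer(scores >= 0.5)
  expect_equal(m$accuracy, 100 * mean(pred == y), tolerance = 1e-12)
  prec <- sum(pred == 1 & y == 1) / sum(pred == 1)
  rec <- sum(pred == 1 & y == 1) / sum(y == 1)
  expect_equal(m$f1, 100 * 2 * prec * rec / (prec + rec), tolerance = 1e-12)
})

test_that("early stopping halts 1 + patience epochs after a frozen optimum", {
  set.seed(403)
  M <- lapply(1:6, function(i) matrix(rnorm(12), 3, 4))
  y <- rep(c(0L, 1L), 3)
  tr <- list(M = M[1:4], y = y[1:4])
  va <- list(M = M[5:6], y = y[5:6])
  model <- build_ngram_cnn(d = 4, filters = 2, dropout = 0)
  # lr = 0 freezes the model, so the validation loss never improves
  cfg <- train_config(epochs = 200, patience = 40, lr = 0,
                      dropout_grid = 0, l2_grid = 0, seed = 1)
  fit <- train_deep(model, tr, va, cfg)
  expect_equal(fit$epochs_run, 41L)
  cfg2 <- train_config(epochs = 30, patience = 10, lr = 0,
                       dropout_grid = 0, l2_grid = 0, seed = 1)
  expect_equal(train_deep(model, tr, va, cfg2)$epochs_run, 11L)
  expect_error(train_deep(model, tr, list(M = list(), y = integer(0)), cfg),
               "empty validation")
})

test_that("training a toy separable set reaches high training accuracy", {
  set.seed(404)
  n <- 24
  y <- rep(c(0L, 1L), n / 2)
  M <- lapply(seq_len(n), function(i) {
    matrix(rnorm(8 * 4, mean = ifelse(y[i] == 1, 1.5, -1.5)), 8, 4)
  })
  tr <- list(M = M[1:16], y = y[1:16])
  va <- list(M = M[17:24], y = y[17:24])
  cfg <- train_config(epochs = 60, patience = 15, batch_size = 4,
                      dropout_grid = 0.2, l2_grid = 1e-4, seed = 2)
  fit <- train_deep(build_ngram_cnn(d = 4, filters = 8), tr, va, cfg)
  train_acc <- mean(as.integer(nn_predict(fit$model, tr) >= 0.5) == tr$y)
  expect_gte(train_acc, 0.95)
})

test_that("hyper-parameter grids are searched by validation loss", {
  set.seed(405)
  n <- 12
  y <- rep(c(0L, 1L), n / 2)
  M <- lapply(seq_len(n), function(i) {
    matrix(rnorm(6 * 4, mean = ifelse(y[i] == 1, 1, -1)), 6, 4)
  })
  cfg <- train_config(epochs = 5, patience = 3, dropout_grid = c(0.2, 0.6),
                      l2_grid = c(1e-4, 5e-3), seed = 3)
  fit <- train_deep(build_ngram_cnn(d = 4, filters = 4),
                    list(M = M[1:8], y = y[1:8]),
                    list(M = M[9:12], y = y[9:12]), cfg)
  expect_true(fit$chosen$dropout %in% c(0.2, 0.6))
  expect_true(fit$chosen$l2 %in% c(1e-4, 5e-3))
})

test_that("cross-validated reports have coherent structure and aggregates", {
  coh <- small_cohort()
  rep <- run_experiment(coh, "text_functionals_svm", k = 4, seed = 9,
                        opts = fast_opts())
  expect_s3_class(rep, "cv_report")
  td <- tidy(rep)
  expect_equal(nrow(td), 4)
  expect_equal(sum(td$n_test), 16)
  expect_true(all(td$accuracy >= 0 & td$accuracy <= 100))
  # aggregate equals independent recomputation from the fold list
  expect_equal(rep$aggregate$mean[rep$aggregate$metric == "accuracy"],
               mean(td$accuracy), tolerance = 1e-12)
  expect_equal(rep$aggregate$sd[rep$aggregate$metric == "f1"],
               stats::sd(td$f1), tolerance = 1e-12)
  g <- glance(rep)
  expect_equal(g$accuracy_mean, mean(td$accuracy))
  expect_equal(nrow(rep$scores), 16)
  expect_true(all(rep$scores$score >= 0 & rep$scores$score <= 1))
  p <- autoplot(rep)
  expect_s3_class(p, "ggplot")
})

test_that("reports export to JSON and CSV", {
  coh <- small_cohort()
  rep <- run_experiment(coh, "text_functionals_svm", k = 4, seed = 9,
                        opts = fast_opts())
  d <- withr::local_tempdir()
  export_report(rep, d)
  expect_true(file.exists(file.path(d, "report.json")))
  j <- jsonlite::fromJSON(file.path(d, "report.json"))
  expect_equal(j$branch, "text_functionals_svm")
  sc <- utils::read.csv(file.path(d, "scores.csv"))
  expect_equal(nrow(sc), 16)
})

test_that("no test-fold speaker feeds scalers, grids or early stopping", {
  coh <- small_cohort()
  for (br in c("speech_pretrained_svm", "text_ngram_cnn", "fusion_joint")) {
    rep <- run_experiment(coh, br, k = 4, seed = 11, opts = fast_opts())
    for (prov in rep$provenance) {
      expect_length(intersect(prov$test_speakers, prov$train_speakers), 0)
      if (!is.null(prov$scaler_speakers)) {
        expect_length(intersect(prov$test_speakers, prov$scaler_speakers), 0)
      }
      if (!is.null(prov$grid_speakers)) {
        expect_length(intersect(prov$test_speakers, prov$grid_speakers), 0)
      }
      if (!is.null(prov$val_speakers)) {
        expect_length(intersect(prov$test_speakers, prov$val_speakers), 0)
        expect_true(all(prov$val_speakers %in% prov$train_speakers))
      }
    }
  }
})

test_that("experiments are reproducible under a fixed seed", {
  coh <- small_cohort()
  r1 <- run_experiment(coh, "text_ngram_cnn", k = 4, seed = 13, opts = fast_opts())
  r2 <- run_experiment(coh, "text_ngram_cnn", k = 4, seed = 13, opts = fast_opts())
  expect_identical(r1$scores$score, r2$scores$score)
  expect_identical(r1$per_fold, r2$per_fold)
})
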