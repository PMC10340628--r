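.mix_seed <- function(seed, salt) {
  as.integer((as.numeric(seed) * 131 + salt * 7919) %% 2147483647)
}

# Shuffle a vector without base sample()'s length-1 integer surprise.
.shuffle <- function(x) x[sample.int(length(x))]

#' Speaker-independent stratified fold plan
#'
#' Partitions speakers (never samples) into `k` folds, stratified by
#' label: every speaker lands in exactly one fold, fold sizes differ by at
#' most one, and each class is spread as evenly as possible across folds.
#'
#' @param x A `cohort`, a fold-plan-compatible data frame with
#'   `speaker_id` and `label` columns, or a manifest.
#' @param k Number of folds (default 10).
#' @param seed Shuffling seed; the same seed reproduces the same plan.
#' @return A `fold_plan` tibble with columns `speaker_id`, `label`,
#'   `fold`.
#' @export
speaker_folds <- function(x, k = 10L, seed = 1L) {
  if (inherits(x, "cohort")) x <- x$manifest
  stopifnot(all(c("speaker_id", "label") %in% names(x)))
  n <- nrow(x)
  if (n < k) stop("fewer speakers (", n, ") than folds (", k, ")")
  fold_sizes <- integer(k)
  assign <- stats::setNames(integer(n), x$speaker_id)
  .with_seed(.mix_seed(seed, 1L), {
    for (lab in unique(x$label)) {
      spk <- .shuffle(x$speaker_id[x$label == lab])
      for (s in spk) {
        f <- which.min(fold_sizes)
        assign[s] <- f
        fold_sizes[f] <- fold_sizes[f] + 1L
      }
    }
  })
  out <- tibble::tibble(speaker_id = x$speaker_id, label = x$label,
                        fold = as.integer(assign[x$speaker_id]))
  structure(out, k = k, seed = seed, class = c("fold_plan", class(out)))
}

#' RBF-SVM grid-search configuration
#'
#' The candidate grids are the printed decade sets
#' `C in {0.001, 0.01, ..., 100}` and `gamma in {0.0001, ..., 100}`
#' (6 x 7 = 42 pairs).
#'
#' @param C_grid,gamma_grid Candidate values.
#' @param inner_k Inner cross-validation folds for model selection
#'   (default 5), run on training data only.
#' @return An `svm_config` list.
#' @export
svm_config <- function(C_grid = c(0.001, 0.01, 0.1, 1, 10, 100),
                       gamma_grid = c(0.0001, 0.001, 0.01, 0.1, 1, 10, 100),
                       inner_k = 5L) {
  structure(list(C_grid = C_grid, gamma_grid = gamma_grid, inner_k = inner_k),
            class = "svm_config")
}

# Platt-style sigmoid calibration of decision values, with target smoothing.
.platt_fit <- function(f, y) {
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  t <- ifelse(y == 1, (n1 + 1) / (n1 + 2), 1 / (n0 + 2))
  obj <- function(par) {
    p <- 1 / (1 + exp(par[1] * f + par[2]))
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -sum(t * log(p) + (1 - t) * log(1 - p))
  }
  fit <- stats::optim(c(-1, 0), obj, method = "BFGS")
  fit$par
}

.platt_apply <- function(f, par) 1 / (1 + exp(par[1] * f + par[2]))

.svm_decision <- function(fit, X) {
  pr <- stats::predict(fit, X, decision.values = TRUE)
  as.numeric(attr(pr, "decision.values"))
}

#' Fit an RBF-SVM with leak-free grid search and return calibrated scores
#'
#' Hyper-parameters are selected by inner stratified cross-validation on
#' the training rows only (mean accuracy; ties broken by smaller `C`,
#' then smaller `gamma`). The selected model is refitted on all training
#' rows and its decision values are mapped to `[0, 1]` through a
#' Platt-style logistic calibration fitted on training decision values.
#'
#' @param X_train,X_test Feature matrices (standardize upstream with
#'   training statistics).
#' @param y_train Integer labels, 0 = HC, 1 = PD (both classes required).
#' @param cfg An [svm_config()].
#' @param seed Seed for the inner fold shuffling.
#' @return List with `scores` (test PD probabilities), `train_scores`,
#'   `params` (chosen `C`, `gamma`), `inner_acc`, and `predict_fn`.
#' @export
svm_fit_predict <- function(X_train, y_train, X_test, cfg = svm_config(),
                            seed = 1L) {
  X_train <- as.matrix(X_train)
  X_test <- as.matrix(X_test)
  y_train <- as.integer(y_train)
  if (length(unique(y_train)) < 2) {
    stop("training data contain a single class; cannot fit a classifier")
  }
  yf <- factor(y_train, levels = c(0, 1))
  n <- nrow(X_train)
  ik <- min(cfg$inner_k, n)
  inner <- .with_seed(.mix_seed(seed, 2L), {
    fold <- integer(n)
    for (cl in c(0L, 1L)) {
      idx <- .shuffle(which(y_train == cl))
      fold[idx] <- rep_len(seq_len(ik), length(idx))
    }
    fold
  })
  best <- list(acc = -Inf, C = NA, gamma = NA)
  for (C in cfg$C_grid) {
    for (g in cfg$gamma_grid) {
      correct <- 0L
      for (f in seq_len(ik)) {
        tr <- inner != f
        te <- inner == f
        if (sum(te) == 0 || sum(tr) == 0) next
        if (length(unique(y_train[tr])) < 2) {
          maj <- as.integer(mean(y_train[tr]) >= 0.5)
          correct <- correct + sum(y_train[te] == maj)
          next
        }
        m <- e1071::svm(X_train[tr, , drop = FALSE], yf[tr],
                        kernel = "radial", cost = C, gamma = g, scale = FALSE)
        pr <- stats::predict(m, X_train[te, , drop = FALSE])
        correct <- correct + sum(as.integer(as.character(pr)) == y_train[te])
      }
      acc <- correct / n
      if (acc > best$acc) best <- list(acc = acc, C = C, gamma = g)
    }
  }
  fit <- e1071::svm(X_train, yf, kernel = "radial", cost = best$C,
                    gamma = best$gamma, scale = FALSE)
  f_train <- .svm_decision(fit, X_train)
  # standardize decision values so the calibration is well-conditioned even
  # for heavily regularized models with near-zero margins
  f_scale <- stats::sd(f_train)
  if (!is.finite(f_scale) || f_scale == 0) f_scale <- 1
  platt <- .platt_fit(f_train / f_scale, y_train)
  predict_fn <- function(Xnew) {
    .platt_apply(.svm_decision(fit, as.matrix(Xnew)) / f_scale, platt)
  }
  list(scores = if (nrow(X_test) > 0) predict_fn(X_test) else numeric(0),
       train_scores = .platt_apply(f_train / f_scale, platt),
       params = list(C = best$C, gamma = best$gamma),
       inner_acc = best$acc,
       predict_fn = predict_fn)
}

#' Classification metrics from scores
#'
#' PD is the positive class: sensitivity is PD recall and specificity is
#' HC recall. Scores at or above the threshold are called PD (documented
#' tie rule). Values are percentages.
#'
#' @param scores PD probabilities in `[0, 1]`.
#' @param labels `"PD"`/`"HC"` character, or 0/1 integers (1 = PD).
#' @param threshold Decision threshold (default 0.5).
#' @return A tibble with `accuracy`, `sensitivity`, `specificity`, `f1`.
#' @export
compute_metrics <- function(scores, labels, threshold = 0.5) {
  stopifnot(all(scores >= 0 & scores <= 1))
  y <- if (is.character(labels) || is.factor(labels)) {
    as.integer(as.character(labels) == "PD")
  } else {
    as.integer(labels)
  }
  if (length(unique(y)) < 2) {
    stop("labels contain a single class; sensitivity/specificity undefined")
  }
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & y == 1)
  tn <- sum(pred == 0 & y == 0)
  fp <- sum(pred == 1 & y == 0)
  fn <- sum(pred == 0 & y == 1)
  tibble::tibble(
    accuracy = 100 * (tp + tn) / length(y),
    sensitivity = 100 * tp / (tp + fn),
    specificity = 100 * tn / (tn + fp),
    f1 = 100 * 2 * tp / (2 * tp + fp + fn)
  )
}

#' Options controlling a cross-validated experiment
#'
#' @param chunks_per_speaker Training chunks subsampled (evenly spaced)
#'   per speaker for the deep speech models; test speakers are always
#'   scored on all their chunks.
#' @param embedder_d Toy word-embedder dimension (default 8).
#' @param filters n-gram CNN filters per kernel width (default 64).
#' @param gmm_K Gaussians per speaker supervector (default 8, as in the
#'   reported joint-fusion configuration).
#' @param adapter_dim Stub pretrained-embedder dimension (default 768).
#' @param val_frac Fraction of training speakers carved out as the
#'   early-stopping validation set (default 0.2).
#' @param epochs,patience,batch_size,lr,dropout,l2 Desk-scale training
#'   regimen for the deep branches; pass vectors for `dropout`/`l2` to
#'   grid-search them by validation loss.
#' @param epochs_speech Epoch cap for the chunk-level speech models,
#'   whose per-epoch cost is much higher than the text models' (default
#'   6; early stopping applies within it).
#' @param crossfit_k Folds used to cross-fit training-speaker scores in
#'   late fusion (default 3).
#' @return An `experiment_opts` list.
#' @export
experiment_opts <- function(chunks_per_speaker = 6L, embedder_d = 8L,
                            filters = 64L, gmm_K = 8L, adapter_dim = 768L,
                            val_frac = 0.2, epochs = 30L, patience = 8L,
                            batch_size = 32L, lr = 1e-3, dropout = 0.2,
                            l2 = 1e-4, epochs_speech = 6L, crossfit_k = 3L) {
  structure(as.list(environment()), class = "experiment_opts")
}

.exp_train_cfg <- function(opts, seed, epochs = opts$epochs) {
  train_config(epochs = epochs, patience = min(opts$patience, epochs - 1L),
               lr = opts$lr, batch_size = opts$batch_size,
               dropout_grid = opts$dropout, l2_grid = opts$l2, seed = seed)
}

# Stratified train/validation speaker split within a training fold.
.val_split <- function(speakers, labels, frac, seed) {
  .with_seed(seed, {
    val <- character(0)
    for (lab in unique(labels)) {
      spk <- .shuffle(speakers[labels == lab])
      n_val <- max(1L, round(frac * length(spk)))
      val <- c(val, spk[seq_len(n_val)])
    }
    list(train = setdiff(speakers, val), val = val)
  })
}

.even_subsample <- function(n, k) unique(round(seq(1, n, length.out = min(n, k))))

# ---------------------------------------------------------------------------
# Per-branch feature preparation (per-speaker, fold-independent)
# ---------------------------------------------------------------------------

.prep_mels <- function(cohort) {
  lapply(cohort$recordings, function(rec) {
    rec <- preprocess_recording(rec, rec$rate)
    ch <- segment_chunks(rec)
    mels <- lapply(ch$samples, mel_spectrogram, rate = rec$rate,
                   expected_samples = round(rec$rate * 0.5))
    ms <- standardize_mels(mels)
    arr <- array(0, c(nrow(ms[[1]]), ncol(ms[[1]]), 1L, length(ms)))
    for (i in seq_along(ms)) arr[, , 1, i] <- unclass(ms[[i]])
    arr
  })
}

.prep_raw_chunks <- function(cohort) {
  lapply(cohort$recordings, function(rec) {
    rec <- preprocess_recording(rec, rec$rate)
    ch <- segment_chunks(rec)
    arr <- array(0, c(length(ch$samples[[1]]), 1L, nrow(ch)))
    for (i in seq_len(nrow(ch))) arr[, 1, i] <- ch$samples[[i]]
    arr
  })
}

.chunk_dataset <- function(feats, speakers, labels01, per_speaker = NULL) {
  xs <- list(); ys <- integer(0)
  for (i in seq_along(speakers)) {
    a <- feats[[speakers[i]]]
    nc <- dim(a)[length(dim(a))]
    keep <- if (is.null(per_speaker)) seq_len(nc) else .even_subsample(nc, per_speaker)
    xs[[i]] <- .subset_last(a, keep)
    ys <- c(ys, rep(labels01[i], length(keep)))
  }
  nd <- length(dim(xs[[1]]))
  x <- array(0, c(dim(xs[[1]])[-nd], length(ys)))
  pos <- 0L
  for (a in xs) {
    nc <- dim(a)[nd]
    if (nd == 4) x[, , , pos + seq_len(nc)] <- a else x[, , pos + seq_len(nc)] <- a
    pos <- pos + nc
  }
  list(x = x, y = ys)
}

# ---------------------------------------------------------------------------
# run_experiment
# ---------------------------------------------------------------------------

#' Run a speaker-independent cross-validated experiment
#'
#' Trains and evaluates one branch of the pipeline under stratified
#' speaker-independent k-fold cross-validation. Every statistic that
#' could leak information (feature standardization, SVM grid search,
#' early stopping, per-speaker GMMs) is computed from training-fold
#' speakers only; the provenance of each is recorded in the report and
#' asserted in the test suite.
#'
#' Branches:
#' \describe{
#'   \item{`speech_resnet2d`}{residual 2D-CNN on log-mel chunks; speaker
#'     score = mean chunk probability.}
#'   \item{`speech_cnn1d_lstm`}{1D-CNN+LSTM on raw waveform chunks.}
#'   \item{`speech_pretrained_svm`}{pretrained-adapter recording vectors
#'     (temporal mean) + RBF-SVM.}
#'   \item{`text_functionals_svm`}{4-functional vectors + RBF-SVM.}
#'   \item{`text_ngram_cnn`}{multi-kernel n-gram CNN on embedding
#'     matrices.}
#'   \item{`fusion_early`}{adapter speech vector concatenated with the
#'     fold-trained language embedding, per-part standardized, + SVM.}
#'   \item{`fusion_joint`}{n-gram CNN with the speaker's GMM supervector
#'     concatenated before the head, trained end to end.}
#'   \item{`fusion_late`}{2-D `[speech_score, language_score]` + SVM,
#'     with cross-fitted training scores.}
#' }
#'
#' @param cohort A `cohort` from [gen_cohort()] (or a compatible list of
#'   recordings/transcripts/manifest).
#' @param branch Branch name, see above.
#' @param k Number of outer folds (default 10).
#' @param seed Master seed; all fold, initialization, and shuffling seeds
#'   derive from it.
#' @param opts An [experiment_opts()].
#' @return A `cv_report`; see [tidy.cv_report()], [glance.cv_report()],
#'   [autoplot.cv_report()].
#' @export
run_experiment <- function(cohort, branch = c("speech_resnet2d",
                                              "speech_cnn1d_lstm",
                                              "speech_pretrained_svm",
                                              "text_functionals_svm",
                                              "text_ngram_cnn",
                                              "fusion_early", "fusion_joint",
                                              "fusion_late"),
                           k = 10L, seed = 1L, opts = experiment_opts()) {
  branch <- match.arg(branch)
  man <- cohort$manifest
  plan <- speaker_folds(man, k = k, seed = seed)
  labels01 <- stats::setNames(as.integer(man$label == "PD"), man$speaker_id)

  needs_mels <- branch == "speech_resnet2d"
  needs_raw <- branch == "speech_cnn1d_lstm"
  needs_text <- branch %in% c("text_functionals_svm", "text_ngram_cnn",
                              "fusion_early", "fusion_joint", "fusion_late")
  needs_adapter <- branch %in% c("speech_pretrained_svm", "fusion_early",
                                 "fusion_late")
  needs_frames <- branch == "fusion_joint"

  embedder <- if (needs_text) toy_embedder(cohort_vocab(), d = opts$embedder_d,
                                           seed = 42L)
  adapter <- if (needs_adapter || needs_frames) stub_embedder(dim = opts$adapter_dim)

  feats <- list()
  if (needs_mels) feats$mels <- .prep_mels(cohort)
  if (needs_raw) feats$raw <- .prep_raw_chunks(cohort)
  if (needs_text) {
    feats$M <- lapply(cohort$transcripts, embed_transcript, embedder = embedder)
  }
  if (needs_adapter) {
    feats$avec <- t(vapply(cohort$recordings, pretrained_embed,
                           numeric(adapter$dim), embedder = adapter))
  }
  if (needs_frames) {
    feats$sv <- purrr::imap(cohort$recordings, function(rec, id) {
      fr <- frame_embeddings(rec, adapter)
      gmm_supervector(fr, K = opts$gmm_K,
                      seed = .mix_seed(seed, 500L + .string_hash(id) %% 1000L))
    })
  }

  fold_results <- vector("list", k)
  score_rows <- vector("list", k)
  provenance <- vector("list", k)

  for (f in seq_len(k)) {
    fseed <- .mix_seed(seed, 10L + f)
    test_spk <- plan$speaker_id[plan$fold == f]
    train_all <- plan$speaker_id[plan$fold != f]
    res <- .run_fold(branch, feats, labels01, train_all, test_spk,
                     fseed, opts)
    test_scores <- res$scores
    prov <- res$provenance
    prov$test_speakers <- test_spk
    prov$train_speakers <- train_all
    provenance[[f]] <- prov
    m <- compute_metrics(test_scores, labels01[test_spk])
    fold_results[[f]] <- dplyr::mutate(m, fold = f, n_test = length(test_spk),
                                       .before = 1)
    score_rows[[f]] <- tibble::tibble(
      fold = f, speaker_id = test_spk,
      label = ifelse(labels01[test_spk] == 1L, "PD", "HC"),
      score = unname(test_scores),
      pred = ifelse(test_scores >= 0.5, "PD", "HC")
    )
  }

  per_fold <- dplyr::bind_rows(fold_results)
  metrics <- c("accuracy", "sensitivity", "specificity", "f1")
  aggregate <- tibble::tibble(
    metric = metrics,
    mean = unname(vapply(metrics, function(m) mean(per_fold[[m]]), numeric(1))),
    sd = unname(vapply(metrics, function(m) stats::sd(per_fold[[m]]), numeric(1)))
  )
  structure(list(branch = branch, per_fold = per_fold,
                 scores = dplyr::bind_rows(score_rows),
                 aggregate = aggregate, fold_plan = plan,
                 provenance = provenance,
                 config = list(k = k, seed = seed, opts = opts)),
            class = "cv_report")
}

# One outer fold of one branch. Returns test-speaker scores (named) and
# the provenance of every training-data-derived statistic.
.run_fold <- function(branch, feats, labels01, train_all, test_spk, fseed, opts) {
  prov <- list()
  ytr <- labels01[train_all]

  svm_branch <- function(X) {
    scaler <- fit_scaler(X[train_all, , drop = FALSE])
    prov$scaler_speakers <<- train_all
    prov$grid_speakers <<- train_all
    Xs <- apply_scaler(X, scaler)
    r <- svm_fit_predict(Xs[train_all, , drop = FALSE], ytr,
                         Xs[test_spk, , drop = FALSE], seed = fseed)
    stats::setNames(r$scores, test_spk)
  }

  deep_split <- function() {
    sp <- .val_split(train_all, ifelse(ytr == 1, "PD", "HC"),
                     opts$val_frac, .mix_seed(fseed, 3L))
    prov$val_speakers <<- sp$val
    prov$early_stop_speakers <<- sp$val
    sp
  }

  scores <- switch(branch,
    speech_resnet2d = ,
    speech_cnn1d_lstm = {
      fx <- if (branch == "speech_resnet2d") feats$mels else feats$raw
      sp <- deep_split()
      tr <- .chunk_dataset(fx, sp$train, labels01[sp$train], opts$chunks_per_speaker)
      va <- .chunk_dataset(fx, sp$val, labels01[sp$val], opts$chunks_per_speaker)
      model <- if (branch == "speech_resnet2d") build_resnet2d() else build_cnn1d_lstm()
      cfg <- .exp_train_cfg(opts, fseed, epochs = opts$epochs_speech)
      fit <- train_deep(model, tr, va, cfg)
      vapply(test_spk, function(s) {
        a <- fx[[s]]
        probs <- nn_predict(fit$model, list(x = a, y = integer(dim(a)[length(dim(a))])))
        speaker_score(probs)
      }, numeric(1))
    },
    speech_pretrained_svm = svm_branch(feats$avec),
    text_functionals_svm = {
      X <- t(vapply(feats$M, functional_vector,
                    numeric(4L * ncol(feats$M[[1]]))))
      svm_branch(X)
    },
    text_ngram_cnn = {
      sp <- deep_split()
      model <- build_ngram_cnn(d = ncol(feats$M[[1]]), filters = opts$filters)
      cfg <- .exp_train_cfg(opts, fseed)
      fit <- train_deep(model,
                        list(M = feats$M[sp$train], y = labels01[sp$train]),
                        list(M = feats$M[sp$val], y = labels01[sp$val]), cfg)
      s <- nn_predict(fit$model, list(M = feats$M[test_spk],
                                      y = labels01[test_spk]))
      stats::setNames(s, test_spk)
    },
    fusion_early = {
      sp <- deep_split()
      model <- build_ngram_cnn(d = ncol(feats$M[[1]]), filters = opts$filters)
      cfg <- .exp_train_cfg(opts, fseed)
      fit <- train_deep(model,
                        list(M = feats$M[sp$train], y = labels01[sp$train]),
                        list(M = feats$M[sp$val], y = labels01[sp$val]), cfg)
      all_spk <- c(train_all, test_spk)
      lang <- t(vapply(all_spk, function(s) {
        ngram_cnn_forward(feats$M[[s]], fit$model)$language_embedding
      }, numeric(model$language_embedding_dim)))
      fused <- cbind(feats$avec[all_spk, , drop = FALSE], lang)
      rownames(fused) <- all_spk
      prov$fusion_parts <- list(speech = seq_len(ncol(feats$avec)),
                                language = ncol(feats$avec) + seq_len(ncol(lang)))
      svm_branch(fused)
    },
    fusion_joint = {
      sp <- deep_split()
      sv_mat <- t(vapply(names(feats$sv), function(s) as.numeric(feats$sv[[s]]),
                         numeric(length(feats$sv[[1]]))))
      scaler <- fit_scaler(sv_mat[train_all, , drop = FALSE])
      prov$scaler_speakers <- train_all
      prov$gmm_scope <- "per_speaker"
      svs <- apply_scaler(sv_mat, scaler)
      sv_list <- stats::setNames(lapply(rownames(svs), function(s) svs[s, ]),
                                 rownames(svs))
      model <- build_ngram_cnn(d = ncol(feats$M[[1]]), filters = opts$filters,
                               sv_dim = ncol(svs))
      cfg <- .exp_train_cfg(opts, fseed)
      fit <- train_deep(model,
                        list(M = feats$M[sp$train], sv = sv_list[sp$train],
                             y = labels01[sp$train]),
                        list(M = feats$M[sp$val], sv = sv_list[sp$val],
                             y = labels01[sp$val]), cfg)
      s <- nn_predict(fit$model, list(M = feats$M[test_spk],
                                      sv = sv_list[test_spk],
                                      y = labels01[test_spk]))
      stats::setNames(s, test_spk)
    },
    fusion_late = {
      # Speech scores: adapter vectors + SVM; language scores: n-gram CNN.
      # Training-fold scores are 5-fold cross-fitted so the fusion SVM never
      # sees resubstitution scores; test scores come from models trained on
      # the full training fold.
      prov$scaler_speakers <- train_all
      prov$grid_speakers <- train_all
      cfg <- .exp_train_cfg(opts, fseed)

      speech_scaler <- fit_scaler(feats$avec[train_all, , drop = FALSE])
      As <- apply_scaler(feats$avec, speech_scaler)
      sp_fit <- svm_fit_predict(As[train_all, , drop = FALSE], ytr,
                                As[test_spk, , drop = FALSE], seed = fseed)
      speech_test <- sp_fit$scores

      spl <- deep_split()
      lg_model <- build_ngram_cnn(d = ncol(feats$M[[1]]), filters = opts$filters)
      lg_fit <- train_deep(lg_model,
                           list(M = feats$M[spl$train], y = labels01[spl$train]),
                           list(M = feats$M[spl$val], y = labels01[spl$val]), cfg)
      lang_test <- nn_predict(lg_fit$model, list(M = feats$M[test_spk],
                                                 y = labels01[test_spk]))

      xk <- opts$crossfit_k
      xfold <- .with_seed(.mix_seed(fseed, 4L), {
        fold <- integer(length(train_all))
        for (cl in c(0L, 1L)) {
          idx <- .shuffle(which(ytr == cl))
          fold[idx] <- rep_len(seq_len(xk), length(idx))
        }
        fold
      })
      speech_train <- numeric(length(train_all))
      lang_train <- numeric(length(train_all))
      for (xf in seq_len(xk)) {
        in_spk <- train_all[xfold != xf]
        out_spk <- train_all[xfold == xf]
        if (length(out_spk) == 0) next
        scl <- fit_scaler(feats$avec[in_spk, , drop = FALSE])
        Ai <- apply_scaler(feats$avec, scl)
        rs <- svm_fit_predict(Ai[in_spk, , drop = FALSE], labels01[in_spk],
                              Ai[out_spk, , drop = FALSE],
                              seed = .mix_seed(fseed, 40L + xf))
        speech_train[xfold == xf] <- rs$scores
        spi <- .val_split(in_spk, ifelse(labels01[in_spk] == 1, "PD", "HC"),
                          opts$val_frac, .mix_seed(fseed, 60L + xf))
        lfit <- train_deep(lg_model,
                           list(M = feats$M[spi$train], y = labels01[spi$train]),
                           list(M = feats$M[spi$val], y = labels01[spi$val]),
                           .exp_train_cfg(opts, .mix_seed(fseed, 80L + xf)))
        lang_train[xfold == xf] <- nn_predict(lfit$model,
                                              list(M = feats$M[out_spk],
                                                   y = labels01[out_spk]))
      }
      fuse_tr <- t(mapply(late_fuse, speech_train, lang_train))
      fuse_te <- t(mapply(late_fuse, speech_test, lang_test))
      scaler <- fit_scaler(fuse_tr)
      r <- svm_fit_predict(apply_scaler(fuse_tr, scaler), ytr,
                           apply_scaler(fuse_te, scaler),
                           seed = .mix_seed(fseed, 5L))
      stats::setNames(r$scores, test_spk)
    }
  )
  list(scores = scores, provenance = prov)
}
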