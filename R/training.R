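#' Deep-model training configuration
#'
#' Defaults mirror the study regimen: up to 200 epochs of Adam on the
#' cross-entropy loss, early stopping with patience 40 on validation loss,
#' and hyper-parameter grids for dropout (0.2, 0.4, 0.6) and L2 weight
#' decay (0.0001, 0.005, 0.001). Experiments on small synthetic cohorts
#' typically override `epochs` and collapse the grids to single values for
#' runtime (see the vignette).
#'
#' @param epochs Maximum epochs (default 200).
#' @param patience Early-stopping patience in epochs (default 40).
#' @param lr Adam learning rate (default 1e-3).
#' @param batch_size Mini-batch size (default 32).
#' @param dropout_grid Candidate dropout rates.
#' @param l2_grid Candidate L2 penalties.
#' @param seed Training seed (initialization, shuffling, dropout masks).
#' @return A `train_config` list.
#' @export
train_config <- function(epochs = 200L, patience = 40L, lr = 1e-3,
                         batch_size = 32L,
                         dropout_grid = c(0.2, 0.4, 0.6),
                         l2_grid = c(0.0001, 0.005, 0.001),
                         seed = 1L) {
  stopifnot(patience < epochs, length(dropout_grid) > 0, length(l2_grid) > 0)
  structure(list(epochs = epochs, patience = patience, lr = lr,
                 batch_size = batch_size, dropout_grid = dropout_grid,
                 l2_grid = l2_grid, seed = seed),
            class = "train_config")
}

# ---------------------------------------------------------------------------
# Generic dataset handling
# ---------------------------------------------------------------------------

.subset_last <- function(x, idx) {
  d <- dim(x)
  switch(as.character(length(d)),
         "2" = x[, idx, drop = FALSE],
         "3" = x[, , idx, drop = FALSE],
         "4" = x[, , , idx, drop = FALSE],
         stop("unsupported array rank"))
}

.data_n <- function(data) length(data$y)

.data_subset <- function(data, idx) {
  out <- data
  if (!is.null(data$x)) out$x <- .subset_last(data$x, idx)
  if (!is.null(data$M)) out$M <- data$M[idx]
  if (!is.null(data$sv)) out$sv <- data$sv[idx]
  out$y <- data$y[idx]
  out
}

# ---------------------------------------------------------------------------
# Per-kind loss/grad/predict methods
# ---------------------------------------------------------------------------

#' Loss and flattened gradients on a mini-batch
#'
#' Developer-level entry point used by the training loop and by gradient
#' tests.
#'
#' @param model An `nn_model`.
#' @param batch Dataset list (see [train_deep()]).
#' @param training Forward in training mode (batch statistics, dropout).
#' @return List with `loss`, `grads` (flat vector aligned with
#'   [nn_get_params()]), and the possibly state-updated `model`.
#' @export
nn_loss_grads <- function(model, batch, training = TRUE) UseMethod("nn_loss_grads")

#' @export
nn_loss_grads.seq_nn <- function(model, batch, training = TRUE) {
  fw <- nn_forward(model, batch$x, training = training)
  ls <- softmax_xent(fw$out, batch$y)
  bw <- nn_backward(fw$model, fw$caches, ls$dlogits)
  list(loss = ls$loss, grads = .flat_grads(bw$grads), model = fw$model)
}

#' @export
nn_loss_grads.ngram_cnn <- function(model, batch, training = TRUE) {
  n <- length(batch$y)
  gacc <- NULL
  loss <- 0
  for (i in seq_len(n)) {
    fw <- .ngram_fwd_one(model, batch$M[[i]],
                         sv = if (!is.null(batch$sv)) as.numeric(batch$sv[[i]]) else NULL,
                         training = training)
    y <- batch$y[i]
    loss <- loss - log(max(fw$probs[y + 1L], 1e-12))
    dz <- fw$probs
    dz[y + 1L] <- dz[y + 1L] - 1
    g <- unlist(.ngram_bwd_one(model, fw, dz), use.names = FALSE)
    gacc <- if (is.null(gacc)) g else gacc + g
  }
  list(loss = loss / n, grads = gacc / n, model = model)
}

#' Get or set a model's parameters as one flat numeric vector
#'
#' @param model An `nn_model`.
#' @return `nn_get_params()` returns the flattened parameter vector;
#'   `nn_set_params()` returns the model with parameters replaced.
#' @export
nn_get_params <- function(model) UseMethod("nn_get_params")
#' @export
nn_get_params.seq_nn <- function(model) .flat_params(model)
#' @export
nn_get_params.ngram_cnn <- function(model) unlist(model$params, use.names = FALSE)

#' @rdname nn_get_params
#' @param vec Replacement parameter vector from [nn_get_params()].
#' @export
nn_set_params <- function(model, vec) UseMethod("nn_set_params")
#' @export
nn_set_params.seq_nn <- function(model, vec) .set_flat_params(model, vec)
#' @export
nn_set_params.ngram_cnn <- function(model, vec) {
  pos <- 0L
  rec <- function(p) {
    if (is.list(p)) return(lapply(p, rec))
    n <- length(p)
    out <- vec[(pos + 1L):(pos + n)]
    pos <<- pos + n
    if (!is.null(dim(p))) dim(out) <- dim(p)
    out
  }
  model$params <- rec(model$params)
  model
}

nn_l2_mask <- function(model) UseMethod("nn_l2_mask")
#' @export
nn_l2_mask.seq_nn <- function(model) .l2_mask(model)
#' @export
nn_l2_mask.ngram_cnn <- function(model) {
  rec <- function(p, nm) {
    if (is.list(p)) {
      return(unlist(mapply(rec, p, names(p), SIMPLIFY = FALSE), use.names = FALSE))
    }
    rep(if (identical(nm, "W")) 1 else 0, length(p))
  }
  unlist(mapply(rec, model$params, names(model$params), SIMPLIFY = FALSE),
         use.names = FALSE)
}

nn_reinit <- function(model, seed) UseMethod("nn_reinit")
#' @export
nn_reinit.seq_nn <- function(model, seed) nn_init(model, seed)
#' @export
nn_reinit.ngram_cnn <- function(model, seed) {
  build_ngram_cnn(d = model$d, filters = model$filters, widths = model$widths,
                  dropout = model$dropout, sv_dim = model$sv_dim, seed = seed)
}

nn_set_dropout <- function(model, p) UseMethod("nn_set_dropout")
#' @export
nn_set_dropout.seq_nn <- function(model, p) {
  for (i in seq_along(model$layers)) {
    if (model$layers[[i]]$type == "dropout") model$layers[[i]]$p <- p
  }
  model
}
#' @export
nn_set_dropout.ngram_cnn <- function(model, p) { model$dropout <- p; model }

#' Predicted PD probability for every observation in a dataset
#'
#' Evaluation-mode forward pass (running batch-norm statistics, no
#' dropout).
#'
#' @param model A trained `nn_model`.
#' @param data Dataset list: `x` + `y` for array models, `M` (+ `sv`) +
#'   `y` for text/joint models.
#' @return Numeric vector of class-PD probabilities.
#' @export
nn_predict <- function(model, data) UseMethod("nn_predict")

#' @export
nn_predict.seq_nn <- function(model, data) {
  n <- .data_n(data)
  out <- numeric(n)
  for (start in seq(1, n, by = 128)) {
    idx <- start:min(start + 127, n)
    p <- nn_predict_probs(model, .subset_last(data$x, idx))
    out[idx] <- p[2, ]
  }
  out
}

#' @export
nn_predict.ngram_cnn <- function(model, data) {
  vapply(seq_len(.data_n(data)), function(i) {
    fw <- .ngram_fwd_one(model, data$M[[i]],
                         sv = if (!is.null(data$sv)) as.numeric(data$sv[[i]]) else NULL,
                         training = FALSE)
    fw$probs[2]
  }, numeric(1))
}

.eval_loss <- function(model, data) {
  n <- .data_n(data)
  p <- nn_predict(model, data)
  p1 <- ifelse(data$y == 1L, p, 1 - p)
  -mean(log(pmax(p1, 1e-12)))
}

# ---------------------------------------------------------------------------
# Training loop
# ---------------------------------------------------------------------------

.train_once <- function(model, train, val, cfg, l2) {
  set.seed(cfg$seed)
  model <- nn_reinit(model, seed = cfg$seed)
  theta <- nn_get_params(model)
  mask <- nn_l2_mask(model)
  ad <- .adam_init(length(theta))
  n <- .data_n(train)
  best_val <- Inf
  best_model <- model
  no_improve <- 0L
  history <- vector("list", cfg$epochs)
  epochs_run <- 0L
  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    tr_loss <- 0
    nb <- 0L
    for (start in seq(1, n, by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
      batch <- .data_subset(train, idx)
      lg <- nn_loss_grads(model, batch, training = TRUE)
      model <- lg$model
      g <- lg$grads + l2 * mask * theta
      upd <- .adam_step(theta, g, ad, lr = cfg$lr)
      theta <- upd$theta
      ad <- upd$st
      model <- nn_set_params(model, theta)
      tr_loss <- tr_loss + lg$loss
      nb <- nb + 1L
    }
    val_loss <- .eval_loss(model, val)
    history[[epoch]] <- tibble::tibble(epoch = epoch,
                                       train_loss = tr_loss / nb,
                                       val_loss = val_loss)
    epochs_run <- epoch
    if (val_loss < best_val) {
      best_val <- val_loss
      best_model <- model
      no_improve <- 0L
    } else {
      no_improve <- no_improve + 1L
      if (no_improve >= cfg$patience) break
    }
  }
  list(model = best_model, best_val = best_val,
       history = dplyr::bind_rows(history[seq_len(epochs_run)]),
       epochs_run = epochs_run)
}

#' Train a deep model with Adam, early stopping and grid search
#'
#' Trains on the cross-entropy loss for at most `cfg$epochs` epochs,
#' stopping once the validation loss has not improved for `cfg$patience`
#' consecutive epochs, and returns the parameters of the best-validation
#' epoch. When the dropout/L2 grids contain more than one value, each
#' combination is trained from the same seed and the combination with the
#' lowest validation loss is kept. Train and validation sets must come
#' from disjoint speaker sets; the caller is responsible for the split.
#'
#' @param model An `nn_model` (array-based or n-gram/joint CNN).
#' @param train,val Dataset lists (`x`/`M`/`sv` + `y` with labels 0 = HC,
#'   1 = PD). `val` must be non-empty.
#' @param cfg A [train_config()].
#' @return A `trained_model`: list with `model`, `history` (per-epoch
#'   losses of the selected combination), `best_val`, `epochs_run`, and
#'   `chosen` (dropout and L2 actually used).
#' @export
train_deep <- function(model, train, val, cfg = train_config()) {
  if (is.null(val$y) || length(val$y) == 0) stop("empty validation set")
  best <- NULL
  for (dr in cfg$dropout_grid) {
    for (l2 in cfg$l2_grid) {
      m <- nn_set_dropout(model, dr)
      fit <- .train_once(m, train, val, cfg, l2)
      if (is.null(best) || fit$best_val < best$best_val) {
        best <- fit
        best$chosen <- list(dropout = dr, l2 = l2)
      }
    }
  }
  structure(best, class = "trained_model")
}

#' @export
print.trained_model <- function(x, ...) {
  cat(sprintf("<trained_model> %s: %d epochs run, best val loss %.4f (dropout %.2f, l2 %g)\n",
              paste(class(x$model)[1]), x$epochs_run, x$best_val,
              x$chosen$dropout, x$chosen$l2))
  invisible(x)
}
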