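#' Mean-pool a set of embeddings
#'
#' The speaker-level speech representation is the arithmetic mean of the
#' per-segment embeddings.
#'
#' @param embeddings A list of equal-length numeric vectors, or a matrix
#'   with one embedding per row.
#' @return The mean vector.
#' @export
mean_pool <- function(embeddings) {
  if (is.list(embeddings)) {
    if (length(embeddings) == 0) stop("no embeddings to pool")
    dims <- unique(lengths(embeddings))
    if (length(dims) != 1) stop("embeddings have unequal dimensions")
    embeddings <- do.call(rbind, embeddings)
  }
  if (!is.matrix(embeddings) || nrow(embeddings) == 0) {
    stop("no embeddings to pool")
  }
  colMeans(embeddings)
}

#' Early fusion: concatenate modality vectors
#'
#' Concatenates the speech and language vectors into one feature vector,
#' recording the slice boundaries. Standardization against the
#' speech/language scale mismatch is applied downstream with
#' training-fold statistics (see [fit_scaler()]).
#'
#' @param speech_vec Numeric speech representation.
#' @param lang_vec Numeric language representation.
#' @return A `fusion_vector`: the concatenation with a `parts` attribute
#'   naming the `speech` and `language` index slices.
#' @export
early_fuse <- function(speech_vec, lang_vec) {
  if (!all(is.finite(speech_vec)) || !all(is.finite(lang_vec))) {
    stop("fusion inputs must be finite")
  }
  v <- c(speech_vec, lang_vec)
  structure(v,
            parts = list(speech = seq_along(speech_vec),
                         language = length(speech_vec) + seq_along(lang_vec)),
            class = "fusion_vector")
}

#' Late fusion: bi-modal score vector
#'
#' @param speech_score Speaker-level speech score in `[0, 1]`.
#' @param lang_score Speaker-level language score in `[0, 1]`.
#' @return A 2-element `fusion_vector` `[speech_score, lang_score]`.
#' @export
late_fuse <- function(speech_score, lang_score) {
  if (speech_score < 0 || speech_score > 1 || lang_score < 0 || lang_score > 1) {
    stop("scores must lie in [0, 1]")
  }
  structure(c(speech = speech_score, language = lang_score),
            parts = list(speech = 1L, language = 2L),
            class = "fusion_vector")
}

#' Per-feature standardization statistics
#'
#' @param X Numeric matrix (rows = observations). In cross-validated use,
#'   only training-fold rows may be passed here.
#' @return A `feature_scaler` with `mean` and `sd` (zero spreads replaced
#'   by 1 so constant features pass through centered).
#' @export
fit_scaler <- function(X) {
  mu <- colMeans(X)
  sds <- apply(X, 2, stats::sd)
  sds[sds == 0 | !is.finite(sds)] <- 1
  structure(list(mean = mu, sd = sds), class = "feature_scaler")
}

#' @rdname fit_scaler
#' @param scaler A `feature_scaler` fitted on training data.
#' @export
apply_scaler <- function(X, scaler) {
  sweep(sweep(X, 2, scaler$mean), 2, scaler$sd, `/`)
}

# ---------------------------------------------------------------------------
# Diagonal-covariance GMM by EM
# ---------------------------------------------------------------------------

# log N(x | mu_k, diag(var_k)) for all points and components: (n, K)
.gmm_logdens <- function(X, means, vars) {
  n <- nrow(X); K <- nrow(means); d <- ncol(X)
  out <- matrix(0, n, K)
  for (k in seq_len(K)) {
    q <- sweep(X, 2, means[k, ])^2
    out[, k] <- -0.5 * (d * log(2 * pi) + sum(log(vars[k, ])) +
                          rowSums(sweep(q, 2, vars[k, ], `/`)))
  }
  out
}

.logsumexp_rows <- function(L) {
  m <- apply(L, 1, max)
  m + log(rowSums(exp(L - m)))
}

#' Fit a diagonal-covariance Gaussian mixture by EM
#'
#' K-means initialization (seeded), expectation-maximization with a
#' variance floor, and a deterministic component ordering (ascending first
#' mean coordinate, ties by the second). The log-likelihood is checked to
#' be non-decreasing at every iteration.
#'
#' @param X Numeric matrix, one observation per row (`nrow(X) >= K`).
#' @param K Number of mixture components.
#' @param seed Seed for the k-means initialization.
#' @param var_floor Lower bound on every variance entry (default 1e-6).
#' @param max_iter Maximum EM iterations (default 200).
#' @param tol Stop when the log-likelihood gain falls below this (default 1e-6).
#' @return A `diag_gmm`: list with `means` (`K x d`), `vars` (`K x d`),
#'   `weights`, `loglik` (trace over iterations), `K`, `d`.
#' @export
gmm_fit_diag <- function(X, K, seed = 1L, var_floor = 1e-6, max_iter = 200L,
                         tol = 1e-6) {
  X <- as.matrix(X)
  n <- nrow(X); d <- ncol(X)
  if (n < K) {
    stop("only ", n, " embeddings for K=", K,
         " components; use a smaller K")
  }
  if (K == 1L) {
    mu <- matrix(colMeans(X), 1, d)
    v <- matrix(pmax(colMeans(sweep(X, 2, mu[1, ])^2), var_floor), 1, d)
    ll <- sum(.gmm_logdens(X, mu, v))
    return(structure(list(means = mu, vars = v, weights = 1,
                          loglik = ll, K = 1L, d = d),
                     class = "diag_gmm"))
  }
  km <- .with_seed(seed, tryCatch(
    stats::kmeans(X, centers = K, nstart = 1, iter.max = 50),
    error = function(e) NULL
  ))
  if (!is.null(km)) {
    means <- km$centers
    assign <- km$cluster
  } else {
    # degenerate data (fewer distinct points than K): spread along first axis
    ord <- order(X[, 1])
    pick <- ord[round(seq(1, n, length.out = K))]
    means <- X[pick, , drop = FALSE]
    assign <- apply(X, 1, function(x) which.min(colSums((t(means) - x)^2)))
  }
  vars <- matrix(0, K, d)
  w <- numeric(K)
  for (k in seq_len(K)) {
    Xi <- X[assign == k, , drop = FALSE]
    w[k] <- max(nrow(Xi), 1) / n
    if (nrow(Xi) > 0) {
      vars[k, ] <- pmax(colMeans(sweep(Xi, 2, means[k, ])^2), var_floor)
    } else {
      vars[k, ] <- pmax(apply(X, 2, stats::var), var_floor)
    }
  }
  w <- w / sum(w)
  loglik <- numeric(0)
  prev <- -Inf
  for (it in seq_len(max_iter)) {
    L <- sweep(.gmm_logdens(X, means, vars), 2, log(w), `+`)
    lse <- .logsumexp_rows(L)
    ll <- sum(lse)
    if (length(loglik) > 0 && ll < prev - 1e-6 * (abs(prev) + 1)) {
      stop("EM log-likelihood decreased (", prev, " -> ", ll, ")")
    }
    loglik <- c(loglik, ll)
    R <- exp(L - lse)
    Nk <- pmax(colSums(R), 1e-10)
    means <- sweep(crossprod(R, X), 1, Nk, `/`)
    EX2 <- sweep(crossprod(R, X^2), 1, Nk, `/`)
    vars <- pmax(EX2 - means^2, var_floor)
    w <- Nk / n
    if (ll - prev < tol && it > 1) { prev <- ll; break }
    prev <- ll
  }
  ord <- order(means[, 1], if (d >= 2) means[, 2] else means[, 1])
  structure(list(means = means[ord, , drop = FALSE],
                 vars = vars[ord, , drop = FALSE],
                 weights = w[ord], loglik = loglik, K = K, d = d),
            class = "diag_gmm")
}

#' Component responsibilities under a fitted mixture
#'
#' @param fit A `diag_gmm`.
#' @param X Matrix of observations.
#' @return Matrix `n x K` of posterior component probabilities.
#' @export
gmm_responsibilities <- function(fit, X) {
  X <- as.matrix(X)
  L <- sweep(.gmm_logdens(X, fit$means, fit$vars), 2, log(fit$weights), `+`)
  exp(L - .logsumexp_rows(L))
}

#' GMM supervector of a set of chunk embeddings
#'
#' Fits a per-speaker diagonal-covariance GMM to the speaker's chunk (or
#' frame) embeddings and stacks the component means followed by the
#' diagonal covariances: `[mu_1 .. mu_K | diagSigma_1 .. diagSigma_K]`,
#' a vector of length `2 K d`. Components are ordered deterministically
#' so the supervector layout is stable across refits. With `K = 1` this
#' reduces to the sample mean and population variance per dimension.
#'
#' @param embeddings Matrix (`n x d`) or list of `d`-vectors, `n >= K`.
#' @param K Number of Gaussians (the study considered 2, 4 and 8).
#' @param seed Seed for the k-means initialization.
#' @param ... Passed to [gmm_fit_diag()].
#' @return A numeric vector of class `gmm_supervector` with attributes
#'   `K`, `d` and the fitted `gmm`.
#' @export
gmm_supervector <- function(embeddings, K, seed = 1L, ...) {
  if (is.list(embeddings)) embeddings <- do.call(rbind, embeddings)
  fit <- gmm_fit_diag(embeddings, K, seed = seed, ...)
  v <- c(as.vector(t(fit$means)), as.vector(t(fit$vars)))
  structure(v, K = fit$K, d = fit$d, gmm = fit, class = "gmm_supervector")
}

#' Joint-fusion forward pass
#'
#' Runs the text n-gram CNN to its language embedding, concatenates the
#' speaker's fixed GMM supervector just before the fully connected layer,
#' and returns the 2-class probabilities. During training (see
#' [train_deep()]) the loss gradient reaches the text-CNN filters; the
#' supervector is an input, not a learned quantity.
#'
#' @param M An `embedding_matrix` for the speaker's transliteration.
#' @param sv The speaker's `gmm_supervector` (or numeric vector of length
#'   `model$sv_dim`).
#' @param model A [build_ngram_cnn()] model built with `sv_dim > 0`.
#' @return List with `probs` (2-vector) and `language_embedding`.
#' @export
joint_forward <- function(M, sv, model) {
  stopifnot(inherits(model, "joint_cnn"))
  fw <- .ngram_fwd_one(model, M, sv = as.numeric(sv), training = FALSE)
  list(probs = fw$probs, language_embedding = fw$embedding)
}
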