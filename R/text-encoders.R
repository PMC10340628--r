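#' Tokenize a transliteration
#'
#' Lowercases, strips punctuation, and splits on whitespace. Transcripts
#' in this pipeline come from spontaneous-speech transliterations, so no
#' sentence structure is assumed.
#'
#' @param text Character scalar.
#' @return Character vector of tokens.
#' @export
tokenize_text <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  x <- tolower(text)
  x <- gsub("[[:punct:]]+", " ", x)
  tok <- strsplit(trimws(x), "[[:space:]]+")[[1]]
  tok[nzchar(tok)]
}

#' Construct a transliteration
#'
#' @param tokens Character vector of tokens (or raw text, which is
#'   tokenized with [tokenize_text()]).
#' @param speaker_id Speaker identifier.
#' @param label `"PD"`, `"HC"`, or `NA`.
#' @return An object of class `transliteration` with `tokens`,
#'   `speaker_id`, `label`, `n_words`.
#' @export
transliteration <- function(tokens, speaker_id = "unknown", label = NA_character_) {
  if (length(tokens) == 1 && grepl("[[:space:]]", tokens)) {
    tokens <- tokenize_text(tokens)
  }
  if (length(tokens) < 1) stop("transliteration must contain at least one token")
  if (!is.na(label)) label <- match.arg(label, c("PD", "HC"))
  structure(list(tokens = as.character(tokens), speaker_id = as.character(speaker_id),
                 label = label, n_words = length(tokens)),
            class = "transliteration")
}

# ---------------------------------------------------------------------------
# Word embedders
# ---------------------------------------------------------------------------

# Deterministic 31-bit string hash (used to seed out-of-vocabulary vectors).
.string_hash <- function(s) {
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  as.integer(h)
}

# Evaluate expr under a temporary RNG seed, restoring the caller's stream.
.with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Deterministic vector for an out-of-vocabulary token
#'
#' Seeded by a hash of the token, so the same token always maps to the
#' same vector across runs and sessions.
#'
#' @param token Character scalar.
#' @param d Embedding dimension.
#' @return Numeric vector of length `d` with norm about 1.
#' @export
oov_vector <- function(token, d) {
  v <- .with_seed(.string_hash(token), stats::rnorm(d))
  v / sqrt(sum(v^2))
}

#' Construct a context-independent word embedder from a lookup table
#'
#' @param table Named list or a matrix with row names = tokens, giving one
#'   `d`-vector per token.
#' @param name Embedder name.
#' @return An object of class `word_embedder` whose out-of-vocabulary
#'   tokens map to deterministic hash-seeded vectors.
#' @export
table_embedder <- function(table, name = "table") {
  if (is.matrix(table)) {
    toks <- rownames(table)
    table <- stats::setNames(lapply(seq_len(nrow(table)), function(i) table[i, ]), toks)
  }
  d <- length(table[[1]])
  env <- list2env(table, hash = TRUE)
  structure(list(name = name, dim = d, contextual = FALSE,
                 lookup = function(token) {
                   if (exists(token, envir = env, inherits = FALSE)) {
                     get(token, envir = env)
                   } else {
                     oov_vector(token, d)
                   }
                 }),
            class = "word_embedder")
}

#' Load a word2vec text-format embedding table
#'
#' Reads the plain-text format: an optional `"<n> <d>"` header line, then
#' one line per token: the token followed by `d` floats.
#'
#' @param path Path to the embedding file.
#' @param name Embedder name (default the file name).
#' @return A `word_embedder`.
#' @export
load_word2vec <- function(path, name = basename(path)) {
  lines <- readLines(path, warn = FALSE)
  first <- strsplit(trimws(lines[1]), "[[:space:]]+")[[1]]
  if (length(first) == 2 && !anyNA(suppressWarnings(as.numeric(first)))) {
    lines <- lines[-1]
  }
  parts <- strsplit(trimws(lines), "[[:space:]]+")
  toks <- vapply(parts, `[[`, character(1), 1)
  vecs <- lapply(parts, function(p) as.numeric(p[-1]))
  d <- unique(lengths(vecs))
  if (length(d) != 1) stop("inconsistent embedding dimensions in ", path)
  table_embedder(stats::setNames(vecs, toks), name = name)
}

#' Toy contextual word embedder
#'
#' A deterministic stand-in for transformer-style context-dependent
#' embedders: each token's vector is its base (context-independent) vector
#' averaged with the base vectors of its neighbors within a window, so the
#' same token can receive different rows in different contexts.
#'
#' @param base A context-independent `word_embedder`.
#' @param window Neighbor window half-width (default 1).
#' @return A contextual `word_embedder`.
#' @export
contextual_toy_embedder <- function(base, window = 1L) {
  stopifnot(inherits(base, "word_embedder"), !isTRUE(base$contextual))
  structure(list(name = paste0(base$name, "-ctx"), dim = base$dim,
                 contextual = TRUE,
                 embed_seq = function(tokens) {
                   B <- t(vapply(tokens, base$lookup, numeric(base$dim)))
                   n <- length(tokens)
                   out <- B
                   for (i in seq_len(n)) {
                     lo <- max(1, i - window)
                     hi <- min(n, i + window)
                     out[i, ] <- colMeans(B[lo:hi, , drop = FALSE])
                   }
                   out
                 }),
            class = "word_embedder")
}

#' Embedding matrix of a transliteration
#'
#' Builds the `n x d` matrix `M` with one row per token, in order. For
#' context-independent embedders repeated tokens receive identical rows;
#' out-of-vocabulary tokens receive deterministic hash-seeded vectors.
#'
#' @param transcript A [transliteration()] (or character vector of tokens).
#' @param embedder A `word_embedder`.
#' @return A matrix of class `embedding_matrix` (`n x d`) with attributes
#'   `embedder_name`, `speaker_id`, `label`.
#' @export
embed_transcript <- function(transcript, embedder) {
  if (is.character(transcript)) transcript <- transliteration(transcript)
  stopifnot(inherits(transcript, "transliteration"),
            inherits(embedder, "word_embedder"))
  tokens <- transcript$tokens
  if (length(tokens) == 0) stop("empty token list")
  M <- if (isTRUE(embedder$contextual)) {
    embedder$embed_seq(tokens)
  } else {
    t(vapply(tokens, embedder$lookup, numeric(embedder$dim)))
  }
  rownames(M) <- NULL
  structure(M, class = c("embedding_matrix", class(M)),
            embedder_name = embedder$name,
            speaker_id = transcript$speaker_id, label = transcript$label)
}

#' Statistical-functional representation of an embedding matrix
#'
#' Stacks, per embedding dimension, the mean, population standard
#' deviation, skewness and (raw, non-excess) kurtosis of the token
#' vectors: a vector of length `4 d` ordered `[means | stds | skews |
#' kurts]`. Dimensions with zero variance yield skewness 0 and kurtosis 0
#' so degenerate inputs cannot propagate NaN.
#'
#' @param M An `embedding_matrix` (or any `n x d` matrix, `n >= 1`).
#' @return Numeric vector of length `4 * ncol(M)`.
#' @export
functional_vector <- function(M) {
  M <- unclass(M)
  stopifnot(is.matrix(M), nrow(M) >= 1)
  n <- nrow(M)
  mu <- colMeans(M)
  Xc <- sweep(M, 2, mu)
  m2 <- colMeans(Xc^2)
  m3 <- colMeans(Xc^3)
  m4 <- colMeans(Xc^4)
  sds <- sqrt(m2)
  skew <- ifelse(m2 > 0, m3 / m2^1.5, 0)
  kurt <- ifelse(m2 > 0, m4 / m2^2, 0)
  c(mu, sds, skew, kurt)
}

# ---------------------------------------------------------------------------
# n-gram CNN
# ---------------------------------------------------------------------------

#' Build the multi-kernel n-gram CNN for embedding matrices
#'
#' One-dimensional convolution over token positions with kernels spanning
#' the full embedding dimension: widths 2, 3 and 4 map bi-gram, tri-gram
#' and four-gram relations. Each filter's activations are max-pooled over
#' positions; the concatenation of all pooled filters is the language
#' embedding, and a fully connected layer with softmax makes the decision.
#'
#' @param d Embedding dimension of the word embedder.
#' @param filters Filters per kernel width (default 64).
#' @param widths Kernel widths (default `c(2, 3, 4)`).
#' @param dropout Dropout rate on the language embedding during training.
#' @param sv_dim Optional dimension of a supervector concatenated before
#'   the head (used by joint fusion; default 0).
#' @param seed Initialization seed.
#' @return An object of class `ngram_cnn` (with class `joint_cnn` when
#'   `sv_dim > 0`); `language_embedding_dim = length(widths) * filters`.
#' @export
build_ngram_cnn <- function(d, filters = 64L, widths = c(2L, 3L, 4L),
                            dropout = 0.2, sv_dim = 0L, seed = 1L) {
  stopifnot(d >= 1, filters >= 1, all(widths >= 1))
  emb_dim <- length(widths) * filters
  params <- .with_seed(seed, {
    conv <- lapply(widths, function(w) {
      fan_in <- w * d
      list(W = .he_mat(fan_in, filters, fan_in), b = numeric(filters))
    })
    names(conv) <- paste0("w", widths)
    head_in <- emb_dim + sv_dim
    list(conv = conv,
         head = list(W = .he_mat(2L, head_in, head_in), b = numeric(2)))
  })
  structure(list(params = params, d = d, filters = filters, widths = widths,
                 dropout = dropout, sv_dim = sv_dim,
                 language_embedding_dim = emb_dim, init_seed = seed),
            class = c(if (sv_dim > 0) "joint_cnn", "ngram_cnn", "nn_model"))
}

#' Kernel shapes of an n-gram CNN
#'
#' @param model An `ngram_cnn`.
#' @return List of `c(width, d)` pairs, one per kernel width.
#' @export
ngram_kernel_shapes <- function(model) {
  lapply(model$widths, function(w) c(w, model$d))
}

# Zero-row padding so inputs shorter than the widest kernel stay valid.
.pad_rows <- function(M, min_rows) {
  if (nrow(M) >= min_rows) return(M)
  rbind(M, matrix(0, min_rows - nrow(M), ncol(M)))
}

# Single-sample forward pass. Returns activations needed for backprop.
.ngram_fwd_one <- function(model, M, sv = NULL, training = FALSE,
                           drop_mask = NULL) {
  M <- unclass(M)
  if (ncol(M) != model$d) {
    stop("embedding dimension mismatch: model expects d=", model$d,
         ", matrix has d=", ncol(M))
  }
  M <- .pad_rows(M, max(model$widths))
  n <- nrow(M)
  per_w <- vector("list", length(model$widths))
  pooled <- numeric(0)
  for (wi in seq_along(model$widths)) {
    w <- model$widths[wi]
    npos <- n - w + 1L
    idx <- as.vector(outer(seq_len(w), seq_len(npos) - 1L, `+`))
    # Patch layout: rows of M t..t+w-1 flattened column-major (w fastest,
    # then embedding dim), matching the kernel layout in params$conv.
    P <- matrix(M[idx, , drop = FALSE], w, npos * ncol(M))
    dim(P) <- c(w, npos, ncol(M))
    P <- matrix(aperm(P, c(1, 3, 2)), w * ncol(M), npos)
    cw <- model$params$conv[[wi]]
    act_pre <- crossprod(cw$W, P) + cw$b # (filters, npos)
    act <- pmax(act_pre, 0)
    amax <- max.col(act, ties.method = "first")
    pool <- act[cbind(seq_len(model$filters), amax)]
    per_w[[wi]] <- list(P = P, act_pre = act_pre, amax = amax, npos = npos)
    pooled <- c(pooled, pool)
  }
  embedding <- pooled
  feat <- embedding
  if (training && model$dropout > 0) {
    if (is.null(drop_mask)) {
      drop_mask <- (stats::runif(length(feat)) >= model$dropout) / (1 - model$dropout)
    }
    feat <- feat * drop_mask
  }
  if (model$sv_dim > 0) {
    if (is.null(sv) || length(sv) != model$sv_dim) {
      stop("supervector of length ", model$sv_dim, " required, got ",
           length(sv %||% numeric(0)))
    }
    feat <- c(feat, sv)
  }
  z <- as.vector(model$params$head$W %*% feat) + model$params$head$b
  zs <- z - max(z)
  p <- exp(zs) / sum(exp(zs))
  list(probs = p, logits = z, embedding = embedding, feat = feat,
       per_w = per_w, drop_mask = if (training && model$dropout > 0) drop_mask else NULL)
}

.ngram_bwd_one <- function(model, fw, dz) {
  gh_W <- dz %*% t(fw$feat)
  gh_b <- dz
  emb_dim <- model$language_embedding_dim
  dfeat <- as.vector(crossprod(model$params$head$W, dz))
  demb <- dfeat[seq_len(emb_dim)]
  if (!is.null(fw$drop_mask)) demb <- demb * fw$drop_mask
  gconv <- vector("list", length(model$widths))
  off <- 0L
  for (wi in seq_along(model$widths)) {
    pw <- fw$per_w[[wi]]
    dpool <- demb[off + seq_len(model$filters)]
    off <- off + model$filters
    dact <- matrix(0, model$filters, pw$npos)
    dact[cbind(seq_len(model$filters), pw$amax)] <- dpool
    dact <- dact * (pw$act_pre > 0)
    gconv[[wi]] <- list(W = pw$P %*% t(dact), b = rowSums(dact))
  }
  names(gconv) <- names(model$params$conv)
  list(conv = gconv, head = list(W = gh_W, b = gh_b))
}

#' Forward pass of the n-gram CNN
#'
#' Valid 1-D convolution over token positions for each kernel width
#' (inputs shorter than the widest kernel are zero-row padded), ReLU,
#' per-filter max pooling, concatenation into the language embedding, and
#' a fully connected softmax head.
#'
#' @param M An `embedding_matrix` (`n x d`).
#' @param model An [build_ngram_cnn()] model with `sv_dim = 0`.
#' @return List with `language_embedding` (length `widths * filters`) and
#'   `probs` (2-vector, entry 2 = PD probability).
#' @export
ngram_cnn_forward <- function(M, model) {
  stopifnot(inherits(model, "ngram_cnn"))
  if (model$sv_dim > 0) stop("model expects a supervector; use joint_forward()")
  fw <- .ngram_fwd_one(model, M, training = FALSE)
  list(language_embedding = fw$embedding, probs = fw$probs)
}
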