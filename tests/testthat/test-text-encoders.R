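toy8 <- toy_embedder(cohort_vocab(), d = 8, seed = 42)

test_that("embedding matrices have one row per token in order", {
  tr <- transliteration(c("ta01", "tb02", "ta01", "fw03", "zzz"), "s1", "PD")
  M <- embed_transcript(tr, toy8)
  expect_equal(dim(M), c(5L, 8L))
  # repeated token under a context-independent embedder: identical rows
  expect_identical(M[1, ], M[3, ])
  expect_error(transliteration(character(0)), "at least one token")
})

test_that("out-of-vocabulary tokens map to reproducible hash-seeded vectors", {
  v1 <- oov_vector("nuncaantes", 8)
  v2 <- oov_vector("nuncaantes", 8)
  expect_identical(v1, v2)
  expect_false(identical(v1, oov_vector("otracosa", 8)))
  # embedding through the table embedder uses the same deterministic path
  M1 <- embed_transcript(transliteration(c("zzqq", "ta01")), toy8)
  M2 <- embed_transcript(transliteration(c("zzqq", "ta01")), toy8)
  expect_identical(M1, M2)
  expect_equal(M1[1, ], oov_vector("zzqq", 8))
})

test_that("tokenization lowercases, strips punctuation and splits", {
  expect_equal(tokenize_text("Hola, mundo!  BUEN dia."),
               c("hola", "mundo", "buen", "dia"))
})

test_that("contextual toy embedder varies rows with context", {
  ctx <- contextual_toy_embedder(toy8, window = 1)
  Ma <- embed_transcript(transliteration(c("ta01", "ta02", "ta03")), ctx)
  Mb <- embed_transcript(transliteration(c("tb01", "ta02", "tb02")), ctx)
  expect_false(isTRUE(all.equal(Ma[2, ], Mb[2, ])))
  # deterministic
  expect_identical(Ma, embed_transcript(transliteration(c("ta01", "ta02", "ta03")), ctx))
})

test_that("functional vectors match closed-form and loop-oracle moments", {
  # constant matrix: means = v, all spreads zero
  v <- c(1, -2, 3)
  Mc <- matrix(rep(v, each = 4), 4, 3)
  fv <- functional_vector(Mc)
  expect_equal(fv, c(v, rep(0, 9)))

  # single column 1,2,3: population std sqrt(2/3), skewness 0, raw kurtosis 1.5
  f1 <- functional_vector(matrix(c(1, 2, 3), 3, 1))
  expect_equal(f1[1], 2)
  expect_equal(f1[2], sqrt(2 / 3), tolerance = 1e-9)
  expect_equal(f1[2], 0.8165, tolerance = 1e-4)
  expect_equal(f1[3], 0)
  expect_equal(f1[4], 1.5)

  # length is 4d
  M300 <- matrix(rnorm(5 * 300), 5, 300)
  expect_length(functional_vector(M300), 1200)

  set.seed(201)
  for (i in 1:20) {
    nr <- sample(2:9, 1); nc <- sample(2:5, 1)
    M <- matrix(rnorm(nr * nc), nr, nc)
    expect_equal(functional_vector(M), oracle_functionals(M), tolerance = 1e-9)
  }
})

test_that("functional moments agree with e1071's estimators where defined", {
  set.seed(202)
  M <- matrix(rnorm(50 * 3), 50, 3)
  fv <- functional_vector(M)
  d <- ncol(M)
  for (j in seq_len(d)) {
    expect_equal(fv[2 * d + j], e1071::skewness(M[, j], type = 1), tolerance = 1e-9)
    expect_equal(fv[3 * d + j], e1071::kurtosis(M[, j], type = 1) + 3, tolerance = 1e-9)
  }
})

test_that("the n-gram CNN uses kernels spanning the embedding dimension", {
  m <- build_ngram_cnn(d = 8, filters = 64)
  expect_equal(ngram_kernel_shapes(m), list(c(2, 8), c(3, 8), c(4, 8)))
  expect_equal(m$language_embedding_dim, 192L)
  # parameter count: conv filters + head
  expected <- sum(vapply(c(2, 3, 4), function(w) 64 * (w * 8 + 1), numeric(1))) +
    2 * 192 + 2
  expect_equal(length(pdvoice::nn_get_params(m)), expected)
  expect_error(ngram_cnn_forward(matrix(0, 3, 5), m), "dimension mismatch")
})

test_that("one filter per width yields a 3-dimensional language embedding", {
  m <- build_ngram_cnn(d = 4, filters = 1, seed = 3)
  M <- matrix(rnorm(24), 6, 4)
  out <- ngram_cnn_forward(M, m)
  expect_length(out$language_embedding, 3)
  expect_equal(sum(out$probs), 1, tolerance = 1e-9)
  expect_true(all(out$probs >= 0))
})

test_that("width-2 filter activations match a hand-computed sliding dot product", {
  m <- build_ngram_cnn(d = 2, filters = 1, widths = 2L, seed = 5)
  W <- matrix(c(1, -1, 0.5, 2), 2, 2) # kernel rows = positions, cols = dims
  m$params$conv$w2$W <- matrix(as.vector(W), 4, 1)
  m$params$conv$w2$b <- 0
  M <- rbind(c(1, 0), c(0, 1), c(2, -1))
  a1 <- sum(W * M[1:2, ])
  a2 <- sum(W * M[2:3, ])
  out <- ngram_cnn_forward(M, m)
  expect_equal(out$language_embedding, max(0, max(a1, a2)), tolerance = 1e-12)
})

test_that("inputs shorter than the widest kernel are zero-row padded", {
  m <- build_ngram_cnn(d = 3, filters = 2, seed = 6)
  M <- matrix(rnorm(6), 2, 3)
  out <- ngram_cnn_forward(M, m)
  expect_true(all(is.finite(out$language_embedding)))
  expect_equal(sum(out$probs), 1, tolerance = 1e-9)
})

test_that("pooled activations are sensitive to token order", {
  set.seed(203)
  m <- build_ngram_cnn(d = 6, filters = 8, seed = 7)
  changed <- 0L
  for (i in 1:10) {
    M <- matrix(rnorm(8 * 6), 8, 6)
    e1 <- ngram_cnn_forward(M, m)$language_embedding
    e2 <- ngram_cnn_forward(M[sample(8), ], m)$language_embedding
    if (!isTRUE(all.equal(e1, e2))) changed <- changed + 1L
  }
  expect_gte(changed, 9L)
  # but identical rows are permutation-invariant
  Mc <- matrix(rep(rnorm(6), each = 5), 5, 6)
  expect_equal(ngram_cnn_forward(Mc, m)$language_embedding,
               ngram_cnn_forward(Mc[c(3, 1, 5, 2, 4), ], m)$language_embedding)
})

test_that("per-filter max pooling is invariant to pattern position away from edges", {
  set.seed(204)
  m <- build_ngram_cnn(d = 4, filters = 5, seed = 8)
  pattern <- matrix(rnorm(4 * 4, sd = 3), 4, 4)
  embed_at <- function(offset, n = 12) {
    M <- matrix(0, n, 4)
    M[offset + 1:4, ] <- pattern
    ngram_cnn_forward(M, m)$language_embedding
  }
  # with zero background, activations come from windows touching the pattern;
  # shifts that keep every partial window inside the sequence leave each
  # filter's max unchanged
  e <- lapply(3:5, embed_at)
  for (i in 2:3) expect_equal(e[[i]], e[[1]], tolerance = 1e-9)
})

test_that("word2vec text tables load with and without header", {
  p <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("2 3", "hola 1 0 0.5", "dia 0 1 -0.5"), p)
  emb <- load_word2vec(p)
  expect_equal(emb$dim, 3)
  M <- embed_transcript(transliteration(c("hola", "dia")), emb)
  expect_equal(unclass(M), rbind(c(1, 0, 0.5), c(0, 1, -0.5)),
               ignore_attr = TRUE)
  p2 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("hola 1 0", "dia 0 1"), p2)
  expect_equal(load_word2vec(p2)$dim, 2)
})
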