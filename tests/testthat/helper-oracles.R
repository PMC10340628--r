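# Independent brute-force oracles used to validate the vectorized
# implementations. These deliberately use explicit loops and share no code
# with the package internals.

# Valid cross-correlation conv1d: out[j, t] = b[j] + sum_c sum_u w[j,c,u] x[c, t+u-1]
oracle_conv1d <- function(x, weights, bias) {
  Cout <- dim(weights)[1]; Cin <- dim(weights)[2]; k <- dim(weights)[3]
  L <- ncol(x)
  Lp <- L - k + 1
  out <- matrix(0, Cout, Lp)
  for (j in seq_len(Cout)) {
    for (t in seq_len(Lp)) {
      acc <- bias[j]
      for (cc in seq_len(Cin)) {
        for (u in seq_len(k)) {
          acc <- acc + weights[j, cc, u] * x[cc, t + u - 1]
        }
      }
      out[j, t] <- acc
    }
  }
  out
}

# Literal flipped-kernel 2D convolution, valid region:
# G[m, n] = sum_j sum_k H[j, k] * I[m - j, n - k], indices arranged so the
# kernel anchor spans the valid output grid.
oracle_conv2d <- function(I, H) {
  kh <- nrow(H); kw <- ncol(H)
  OH <- nrow(I) - kh + 1; OW <- ncol(I) - kw + 1
  G <- matrix(0, OH, OW)
  for (m in seq_len(OH)) {
    for (n in seq_len(OW)) {
      acc <- 0
      for (j in seq_len(kh)) {
        for (k in seq_len(kw)) {
          acc <- acc + H[j, k] * I[m + kh - j, n + kw - k]
        }
      }
      G[m, n] <- acc
    }
  }
  G
}

# Scalar LSTM cell following the gate equations one operation at a time.
oracle_lstm_scalar <- function(x, h_prev, c_prev, wf_h, wf_x, bf, wi_h, wi_x, bi,
                               wc_h, wc_x, bc, wo_h, wo_x, bo) {
  sg <- function(z) 1 / (1 + exp(-z))
  f <- sg(wf_h * h_prev + wf_x * x + bf)
  i <- sg(wi_h * h_prev + wi_x * x + bi)
  ctil <- tanh(wc_h * h_prev + wc_x * x + bc)
  cc <- f * c_prev + i * ctil
  o <- sg(wo_h * h_prev + wo_x * x + bo)
  list(h = o * tanh(cc), c = cc)
}

# Loop-based column moments (population), raw kurtosis.
oracle_functionals <- function(M) {
  d <- ncol(M); n <- nrow(M)
  mu <- st <- sk <- ku <- numeric(d)
  for (j in seq_len(d)) {
    v <- M[, j]
    m <- sum(v) / n
    m2 <- sum((v - m)^2) / n
    m3 <- sum((v - m)^3) / n
    m4 <- sum((v - m)^4) / n
    mu[j] <- m
    st[j] <- sqrt(m2)
    sk[j] <- if (m2 > 0) m3 / m2^1.5 else 0
    ku[j] <- if (m2 > 0) m4 / m2^2 else 0
  }
  c(mu, st, sk, ku)
}

# Zero-crossing-based jitter estimator: coefficient of variation of the
# intervals between upward zero crossings of the (band-limited) waveform.
oracle_jitter_cv <- function(samples) {
  s <- sign(samples)
  ups <- which(diff(s) > 0)
  iv <- diff(ups)
  iv <- iv[iv > 8] # discard sub-millisecond spurious crossings
  stats::sd(iv) / mean(iv)
}

# Cached expensive fixtures shared across test files (built in code).
.fixture_env <- new.env(parent = emptyenv())

get_fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

small_cohort <- function() {
  get_fixture("small_cohort", function() {
    gen_cohort(cohort_spec(n_pd = 8, n_hc = 8, duration_s = 3, seed = 77))
  })
}

default_cohort <- function() {
  get_fixture("default_cohort", function() gen_cohort(cohort_spec()))
}

fast_opts <- function(...) {
  experiment_opts(epochs = 12L, patience = 4L, epochs_speech = 3L,
                  chunks_per_speaker = 4L, adapter_dim = 64L, gmm_K = 2L, ...)
}
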