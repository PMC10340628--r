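## Minimal neural-network core: forward/backward layers on R arrays with
## BLAS-backed im2col convolutions, an LSTM with truncated-free BPTT, Adam,
## and an early-stopping training loop. Tensor layouts (column-major):
##   2D feature maps: (H, W, C, N); 1D sequences: (L, C, N); vectors: (D, N).

`%||%` <- function(a, b) if (is.null(a)) b else a

.sigmoid <- function(x) 1 / (1 + exp(-x))

# ---------------------------------------------------------------------------
# Equation-level operations (exposed, oracle-tested)
# ---------------------------------------------------------------------------

#' Specification of a 1D convolution layer
#'
#' @param weights Array `C_out x C_in x kernel_size`.
#' @param bias Numeric vector of length `C_out`.
#' @return A `conv1d_spec` object.
#' @export
conv1d_spec <- function(weights, bias = numeric(dim(weights)[1])) {
  stopifnot(length(dim(weights)) == 3, length(bias) == dim(weights)[1])
  structure(list(weights = weights, bias = bias,
                 out_channels = dim(weights)[1], in_channels = dim(weights)[2],
                 kernel_size = dim(weights)[3]),
            class = "conv1d_spec")
}

#' Apply a 1D convolution (valid cross-correlation)
#'
#' Each output channel is its bias plus the sum over input channels of the
#' valid cross-correlation of the channel with its kernel; the output
#' length is `L - kernel_size + 1`.
#'
#' @param x Input matrix `C_in x L`.
#' @param spec A [conv1d_spec()].
#' @return Matrix `C_out x (L - kernel_size + 1)`.
#' @export
conv1d_apply <- function(x, spec) {
  stopifnot(inherits(spec, "conv1d_spec"))
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  if (nrow(x) != spec$in_channels) {
    stop("input has ", nrow(x), " channels but spec declares ", spec$in_channels)
  }
  k <- spec$kernel_size
  L <- ncol(x)
  if (L < k) stop("sequence length ", L, " shorter than kernel size ", k)
  Lp <- L - k + 1L
  # patch columns: x[, t:(t+k-1)] flattened column-major (C_in fastest)
  idx <- as.vector(outer(seq_len(k) - 1L, seq_len(Lp), `+`))
  P <- matrix(x[, idx], nrow(x) * k, Lp)
  W <- matrix(aperm(spec$weights, c(2, 3, 1)), spec$in_channels * k,
              spec$out_channels)
  t(crossprod(P, W)) + spec$bias
}

#' Apply a 2D convolution as a flipped-kernel sum
#'
#' True convolution `G[m,n] = sum_{j,k} H[j,k] I[m-j, n-k]` restricted to
#' the valid region, i.e. cross-correlation with the 180-degree-rotated
#' kernel. Learned layers in this package use cross-correlation (the
#' framework convention); the two coincide up to a kernel flip.
#'
#' @param I Input matrix (single-channel image).
#' @param H Kernel matrix, strictly smaller than `I` in both dimensions
#'   (equal size is permitted and yields a 1 x 1 output).
#' @return The valid-region feature map, a matrix of size
#'   `(nrow(I)-nrow(H)+1) x (ncol(I)-ncol(H)+1)`.
#' @export
conv2d_apply <- function(I, H) {
  stopifnot(is.matrix(I), is.matrix(H))
  if (nrow(H) > nrow(I) || ncol(H) > ncol(I)) {
    stop("kernel (", nrow(H), "x", ncol(H), ") must not exceed image (",
         nrow(I), "x", ncol(I), ")")
  }
  Hf <- H[rev(seq_len(nrow(H))), rev(seq_len(ncol(H))), drop = FALSE]
  OH <- nrow(I) - nrow(H) + 1L
  OW <- ncol(I) - ncol(H) + 1L
  G <- matrix(0, OH, OW)
  for (j in seq_len(nrow(H))) {
    for (k in seq_len(ncol(H))) {
      G <- G + Hf[j, k] * I[j:(j + OH - 1L), k:(k + OW - 1L), drop = FALSE]
    }
  }
  G
}

#' One LSTM cell update
#'
#' Computes the forget, input and output gates with the logistic function,
#' the candidate cell state with `tanh`, and returns the updated hidden and
#' cell states:
#' `c_t = f_t * c_{t-1} + i_t * c~`, `h_t = o_t * tanh(c_t)`,
#' all gates acting on the concatenation `[h_{t-1}, x_t]`.
#'
#' @param x_t Input vector at time `t`.
#' @param state List with hidden vector `h` and cell vector `c`.
#' @param weights List with matrices `W_f`, `W_i`, `W_c`, `W_o` (each
#'   `H x (H + length(x_t))`) and bias vectors `b_f`, `b_i`, `b_c`, `b_o`.
#' @return Updated state: list with `h`, `c`, and the gate activations
#'   `f`, `i`, `o`, `c_tilde`.
#' @export
lstm_step <- function(x_t, state, weights) {
  if (!all(is.finite(x_t)) || !all(is.finite(state$h)) || !all(is.finite(state$c))) {
    stop("non-finite inputs to lstm_step")
  }
  z <- c(state$h, x_t)
  f <- .sigmoid(as.vector(weights$W_f %*% z) + weights$b_f)
  i <- .sigmoid(as.vector(weights$W_i %*% z) + weights$b_i)
  c_tilde <- tanh(as.vector(weights$W_c %*% z) + weights$b_c)
  o <- .sigmoid(as.vector(weights$W_o %*% z) + weights$b_o)
  c_new <- f * state$c + i * c_tilde
  h_new <- o * tanh(c_new)
  list(h = h_new, c = c_new, f = f, i = i, o = o, c_tilde = c_tilde)
}

# ---------------------------------------------------------------------------
# Layer constructors
# ---------------------------------------------------------------------------

.layer <- function(type, ...) structure(list(type = type, ...), class = "nn_layer")

layer_conv2d <- function(out_ch, kh = 3, kw = 3, sh = 1, sw = 1,
                         ph = (kh - 1) %/% 2, pw = (kw - 1) %/% 2) {
  .layer("conv2d", out_ch = out_ch, kh = kh, kw = kw, sh = sh, sw = sw,
         ph = ph, pw = pw)
}
layer_conv1d <- function(out_ch, k = 3, s = 1) {
  .layer("conv1d", out_ch = out_ch, k = k, s = s)
}
layer_bn <- function() .layer("bn")
layer_relu <- function() .layer("relu")
layer_maxpool2d <- function() .layer("maxpool2d")
layer_maxpool1d <- function() .layer("maxpool1d")
layer_gap2d <- function(tag = NULL) .layer("gap2d", tag = tag)
layer_flatten <- function() .layer("flatten")
layer_dense <- function(out) .layer("dense", out = out)
layer_dropout <- function(p) .layer("dropout", p = p)
layer_lstm <- function(hidden, return_seq = FALSE) {
  .layer("lstm", hidden = hidden, return_seq = return_seq)
}
layer_resblock <- function(out_ch, stride = 1) {
  .layer("resblock", out_ch = out_ch, stride = stride)
}

# ---------------------------------------------------------------------------
# Initialization (He for conv/dense; uniform for LSTM)
# ---------------------------------------------------------------------------

.he_mat <- function(nr, nc, fan_in) matrix(stats::rnorm(nr * nc, 0, sqrt(2 / fan_in)), nr, nc)

.layer_init <- function(layer, in_shape) {
  switch(layer$type,
    conv2d = {
      C <- in_shape[3]
      fan_in <- layer$kh * layer$kw * C
      layer$in_ch <- C
      layer$params <- list(W = .he_mat(fan_in, layer$out_ch, fan_in),
                           b = numeric(layer$out_ch))
      OH <- (in_shape[1] + 2 * layer$ph - layer$kh) %/% layer$sh + 1L
      OW <- (in_shape[2] + 2 * layer$pw - layer$kw) %/% layer$sw + 1L
      layer$out_shape <- c(OH, OW, layer$out_ch)
      layer
    },
    conv1d = {
      C <- in_shape[2]
      fan_in <- layer$k * C
      layer$in_ch <- C
      layer$params <- list(W = .he_mat(fan_in, layer$out_ch, fan_in),
                           b = numeric(layer$out_ch))
      layer$out_shape <- c((in_shape[1] - layer$k) %/% layer$s + 1L, layer$out_ch)
      layer
    },
    bn = {
      C <- in_shape[length(in_shape)]
      layer$params <- list(gamma = rep(1, C), beta = numeric(C))
      layer$state <- list(mean = numeric(C), var = rep(1, C), momentum = 0.1)
      layer$out_shape <- in_shape
      layer
    },
    relu = { layer$out_shape <- in_shape; layer },
    maxpool2d = {
      layer$out_shape <- c(in_shape[1] %/% 2L, in_shape[2] %/% 2L, in_shape[3])
      layer
    },
    maxpool1d = {
      layer$out_shape <- c(in_shape[1] %/% 2L, in_shape[2])
      layer
    },
    gap2d = { layer$out_shape <- in_shape[3]; layer },
    flatten = { layer$out_shape <- prod(in_shape); layer },
    dense = {
      din <- prod(in_shape)
      layer$params <- list(W = .he_mat(layer$out, din, din), b = numeric(layer$out))
      layer$out_shape <- layer$out
      layer
    },
    dropout = { layer$out_shape <- in_shape; layer },
    lstm = {
      Cin <- in_shape[2]
      H <- layer$hidden
      r <- 1 / sqrt(H)
      layer$params <- list(
        W = matrix(stats::runif(4 * H * (Cin + H), -r, r), 4 * H, Cin + H),
        b = numeric(4 * H)
      )
      layer$in_ch <- Cin
      layer$out_shape <- if (layer$return_seq) c(in_shape[1], H) else H
      layer
    },
    resblock = {
      C <- in_shape[3]
      s <- layer$stride
      oc <- layer$out_ch
      mk_conv <- function(kh, kw, cin, cout) {
        fan_in <- kh * kw * cin
        list(W = .he_mat(fan_in, cout, fan_in), b = numeric(cout))
      }
      mk_bn <- function(cout) list(gamma = rep(1, cout), beta = numeric(cout))
      layer$in_ch <- C
      layer$params <- list(
        conv1 = mk_conv(3, 3, C, oc), bn1 = mk_bn(oc),
        conv2 = mk_conv(3, 3, oc, oc), bn2 = mk_bn(oc)
      )
      layer$project <- (s != 1 || C != oc)
      if (layer$project) {
        layer$params$proj <- mk_conv(1, 1, C, oc)
        layer$params$bnp <- mk_bn(oc)
      }
      layer$state <- list(
        bn1 = list(mean = numeric(oc), var = rep(1, oc), momentum = 0.1),
        bn2 = list(mean = numeric(oc), var = rep(1, oc), momentum = 0.1),
        bnp = list(mean = numeric(oc), var = rep(1, oc), momentum = 0.1)
      )
      OH <- (in_shape[1] - 1L) %/% s + 1L
      OW <- (in_shape[2] - 1L) %/% s + 1L
      layer$out_shape <- c(OH, OW, oc)
      layer
    },
    stop("unknown layer type: ", layer$type)
  )
}

#' Initialize the parameters of a sequential model
#'
#' @param model An `nn_model` (see the model builders).
#' @param seed Integer seed; initialization is fully reproducible.
#' @return The model with parameters allocated and output shapes recorded.
#' @export
nn_init <- function(model, seed = 1) {
  set.seed(seed)
  shape <- model$input_shape
  for (i in seq_along(model$layers)) {
    model$layers[[i]] <- .layer_init(model$layers[[i]], shape)
    shape <- model$layers[[i]]$out_shape
  }
  model$output_shape <- shape
  model$init_seed <- seed
  model
}

# ---------------------------------------------------------------------------
# im2col helpers
# ---------------------------------------------------------------------------

.im2col_idx <- function(Hp, Wp, C, kh, kw, sh, sw) {
  OH <- (Hp - kh) %/% sh + 1L
  OW <- (Wp - kw) %/% sw + 1L
  off <- as.vector(outer(seq_len(kh), (seq_len(kw) - 1L) * Hp, `+`))
  off_c <- as.vector(outer(off, (seq_len(C) - 1L) * (Hp * Wp), `+`))
  orig <- as.vector(outer((seq_len(OH) - 1L) * sh, (seq_len(OW) - 1L) * sw * Hp, `+`))
  list(idx = outer(off_c, orig, `+`), OH = OH, OW = OW)
}

.pad2d <- function(x, ph, pw) {
  if (ph == 0 && pw == 0) return(x)
  d <- dim(x)
  xp <- array(0, c(d[1] + 2 * ph, d[2] + 2 * pw, d[3], d[4]))
  xp[ph + seq_len(d[1]), pw + seq_len(d[2]), , ] <- x
  xp
}

.conv2d_fwd <- function(params, x, kh, kw, sh, sw, ph, pw) {
  xp <- .pad2d(x, ph, pw)
  d <- dim(xp)
  N <- d[4]
  ic <- .im2col_idx(d[1], d[2], d[3], kh, kw, sh, sw)
  Xm <- matrix(xp, d[1] * d[2] * d[3], N)
  P <- Xm[as.vector(ic$idx), , drop = FALSE]
  dim(P) <- c(nrow(ic$idx), ncol(ic$idx) * N)
  Y <- crossprod(params$W, P) + params$b
  dim(Y) <- c(ncol(params$W), ic$OH, ic$OW, N)
  list(y = aperm(Y, c(2, 3, 1, 4)),
       cache = list(P = P, ic = ic, dpad = d, ph = ph, pw = pw,
                    in_dim = dim(x)))
}

.conv2d_bwd <- function(params, dy, cache) {
  ic <- cache$ic
  Cout <- ncol(params$W)
  N <- dim(dy)[4]
  dYm <- matrix(aperm(dy, c(3, 1, 2, 4)), Cout)
  gW <- cache$P %*% t(dYm)
  gb <- rowSums(dYm)
  dP <- params$W %*% dYm
  dim(dP) <- c(nrow(ic$idx) * ncol(ic$idx), N)
  g <- as.vector(ic$idx)
  acc <- rowsum(dP, g)
  dXm <- matrix(0, prod(cache$dpad[1:3]), N)
  dXm[as.integer(rownames(acc)), ] <- acc
  dXp <- array(dXm, cache$dpad)
  d0 <- cache$in_dim
  dx <- dXp[cache$ph + seq_len(d0[1]), cache$pw + seq_len(d0[2]), , , drop = FALSE]
  dim(dx) <- d0
  list(dx = dx, grads = list(W = gW, b = gb))
}

.conv1d_fwd <- function(params, x, k, s) {
  d <- dim(x) # (L, C, N)
  Lp <- (d[1] - k) %/% s + 1L
  off <- as.vector(outer(seq_len(k), (seq_len(d[2]) - 1L) * d[1], `+`))
  orig <- (seq_len(Lp) - 1L) * s
  idx <- outer(off, orig, `+`)
  Xm <- matrix(x, d[1] * d[2], d[3])
  P <- Xm[as.vector(idx), , drop = FALSE]
  dim(P) <- c(nrow(idx), Lp * d[3])
  Y <- crossprod(params$W, P) + params$b
  dim(Y) <- c(ncol(params$W), Lp, d[3])
  list(y = aperm(Y, c(2, 1, 3)),
       cache = list(P = P, idx = idx, in_dim = d, Lp = Lp))
}

.conv1d_bwd <- function(params, dy, cache) {
  d <- cache$in_dim
  Cout <- ncol(params$W)
  dYm <- matrix(aperm(dy, c(2, 1, 3)), Cout)
  gW <- cache$P %*% t(dYm)
  gb <- rowSums(dYm)
  dP <- params$W %*% dYm
  dim(dP) <- c(nrow(cache$idx) * ncol(cache$idx), d[3])
  acc <- rowsum(dP, as.vector(cache$idx))
  dXm <- matrix(0, d[1] * d[2], d[3])
  dXm[as.integer(rownames(acc)), ] <- acc
  list(dx = array(dXm, d), grads = list(W = gW, b = gb))
}

# Batch norm over all axes except the channel axis (assumed last-but-one for
# feature maps, i.e. arrays (H,W,C,N) or (L,C,N), or rows of (C,N) matrices).
.bn_moments_mat <- function(x) {
  d <- dim(x)
  nd <- length(d)
  if (nd == 4) {
    xm <- matrix(aperm(x, c(1, 2, 4, 3)), ncol = d[3])
  } else if (nd == 3) {
    xm <- matrix(aperm(x, c(1, 3, 2)), ncol = d[2])
  } else {
    xm <- t(x)
  }
  xm
}

.bn_unmat <- function(xm, d) {
  nd <- length(d)
  if (nd == 4) {
    aperm(array(xm, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
  } else if (nd == 3) {
    aperm(array(xm, c(d[1], d[3], d[2])), c(1, 3, 2))
  } else {
    t(xm)
  }
}

.bn_fwd <- function(params, state, x, training, eps = 1e-5) {
  d <- dim(x)
  xm <- .bn_moments_mat(x)
  if (training) {
    mu <- colMeans(xm)
    v <- colMeans(xm^2) - mu^2
    state$mean <- (1 - state$momentum) * state$mean + state$momentum * mu
    state$var <- (1 - state$momentum) * state$var + state$momentum * v
  } else {
    mu <- state$mean
    v <- state$var
  }
  inv <- 1 / sqrt(v + eps)
  xhat <- sweep(sweep(xm, 2, mu), 2, inv, `*`)
  ym <- sweep(sweep(xhat, 2, params$gamma, `*`), 2, params$beta, `+`)
  list(y = .bn_unmat(ym, d), state = state,
       cache = list(xhat = xhat, inv = inv, d = d))
}

.bn_bwd <- function(params, dy, cache) {
  dym <- .bn_moments_mat(dy)
  xhat <- cache$xhat
  ggamma <- colSums(dym * xhat)
  gbeta <- colSums(dym)
  m <- nrow(dym)
  t1 <- sweep(dym, 2, colMeans(dym))
  t2 <- sweep(xhat, 2, colMeans(dym * xhat), `*`)
  dxm <- sweep(t1 - t2, 2, params$gamma * cache$inv, `*`)
  list(dx = .bn_unmat(dxm, cache$d), grads = list(gamma = ggamma, beta = gbeta))
}

.maxpool2d_fwd <- function(x) {
  d <- dim(x)
  H2 <- d[1] %/% 2L
  W2 <- d[2] %/% 2L
  ri <- seq_len(2L * H2)
  ci <- seq_len(2L * W2)
  xs <- x[ri, ci, , , drop = FALSE]
  a <- list(
    xs[seq(1, 2 * H2, 2), seq(1, 2 * W2, 2), , , drop = FALSE],
    xs[seq(2, 2 * H2, 2), seq(1, 2 * W2, 2), , , drop = FALSE],
    xs[seq(1, 2 * H2, 2), seq(2, 2 * W2, 2), , , drop = FALSE],
    xs[seq(2, 2 * H2, 2), seq(2, 2 * W2, 2), , , drop = FALSE]
  )
  y <- pmax(a[[1]], a[[2]], a[[3]], a[[4]])
  list(y = y, cache = list(a = a, y = y, d = d, H2 = H2, W2 = W2))
}

.maxpool2d_bwd <- function(dy, cache) {
  d <- cache$d
  dx <- array(0, d)
  taken <- array(FALSE, dim(cache$y))
  rows <- list(seq(1, 2 * cache$H2, 2), seq(2, 2 * cache$H2, 2))
  cols <- list(seq(1, 2 * cache$W2, 2), seq(2, 2 * cache$W2, 2))
  sel <- list(c(1, 1), c(2, 1), c(1, 2), c(2, 2))
  for (q in 1:4) {
    mk <- (cache$a[[q]] == cache$y) & !taken
    taken <- taken | mk
    sub <- array(0, dim(cache$y))
    sub[mk] <- dy[mk]
    dx[rows[[sel[[q]][1]]], cols[[sel[[q]][2]]], , ] <- sub
  }
  dx
}

.maxpool1d_fwd <- function(x) {
  d <- dim(x)
  L2 <- d[1] %/% 2L
  xs <- x[seq_len(2L * L2), , , drop = FALSE]
  a1 <- xs[seq(1, 2 * L2, 2), , , drop = FALSE]
  a2 <- xs[seq(2, 2 * L2, 2), , , drop = FALSE]
  y <- pmax(a1, a2)
  list(y = y, cache = list(a1 = a1, a2 = a2, y = y, d = d, L2 = L2))
}

.maxpool1d_bwd <- function(dy, cache) {
  dx <- array(0, cache$d)
  m1 <- cache$a1 == cache$y
  s1 <- array(0, dim(cache$y)); s1[m1] <- dy[m1]
  m2 <- (cache$a2 == cache$y) & !m1
  s2 <- array(0, dim(cache$y)); s2[m2] <- dy[m2]
  dx[seq(1, 2 * cache$L2, 2), , ] <- s1
  dx[seq(2, 2 * cache$L2, 2), , ] <- s2
  dx
}

.lstm_fwd <- function(params, x, hidden, return_seq) {
  d <- dim(x) # (L, C, N)
  L <- d[1]; C <- d[2]; N <- d[3]
  H <- hidden
  h <- matrix(0, H, N)
  cc <- matrix(0, H, N)
  steps <- vector("list", L)
  Y <- if (return_seq) array(0, c(L, H, N)) else NULL
  for (t in seq_len(L)) {
    xt <- matrix(x[t, , ], C, N)
    comb <- rbind(h, xt)
    z <- params$W %*% comb + params$b
    i <- .sigmoid(z[seq_len(H), , drop = FALSE])
    f <- .sigmoid(z[H + seq_len(H), , drop = FALSE])
    g <- tanh(z[2 * H + seq_len(H), , drop = FALSE])
    o <- .sigmoid(z[3 * H + seq_len(H), , drop = FALSE])
    c_prev <- cc
    cc <- f * c_prev + i * g
    tc <- tanh(cc)
    h_prev <- h
    h <- o * tc
    steps[[t]] <- list(i = i, f = f, g = g, o = o, c_prev = c_prev, tc = tc,
                       h_prev = h_prev, xt = xt)
    if (return_seq) Y[t, , ] <- h
  }
  list(y = if (return_seq) Y else h,
       cache = list(steps = steps, d = d, H = H, return_seq = return_seq))
}

.lstm_bwd <- function(params, dy, cache) {
  d <- cache$d
  L <- d[1]; C <- d[2]; N <- d[3]
  H <- cache$H
  gW <- matrix(0, nrow(params$W), ncol(params$W))
  gb <- numeric(length(params$b))
  dh_next <- matrix(0, H, N)
  dc_next <- matrix(0, H, N)
  dx <- array(0, d)
  for (t in rev(seq_len(L))) {
    st <- cache$steps[[t]]
    dh <- dh_next
    if (cache$return_seq) {
      dh <- dh + matrix(dy[t, , ], H, N)
    } else if (t == L) {
      dh <- dh + dy
    }
    do <- dh * st$tc
    dc <- dc_next + dh * st$o * (1 - st$tc^2)
    di <- dc * st$g
    dg <- dc * st$i
    df <- dc * st$c_prev
    dc_next <- dc * st$f
    dz <- rbind(di * st$i * (1 - st$i),
                df * st$f * (1 - st$f),
                dg * (1 - st$g^2),
                do * st$o * (1 - st$o))
    comb <- rbind(st$h_prev, st$xt)
    gW <- gW + dz %*% t(comb)
    gb <- gb + rowSums(dz)
    dcomb <- crossprod(params$W, dz)
    dh_next <- dcomb[seq_len(H), , drop = FALSE]
    dx[t, , ] <- dcomb[H + seq_len(C), , drop = FALSE]
  }
  list(dx = dx, grads = list(W = gW, b = gb))
}

.resblock_fwd <- function(layer, x, training) {
  p <- layer$params
  s <- layer$stride
  c1 <- .conv2d_fwd(p$conv1, x, 3, 3, s, s, 1, 1)
  b1 <- .bn_fwd(p$bn1, layer$state$bn1, c1$y, training)
  r1 <- pmax(b1$y, 0)
  c2 <- .conv2d_fwd(p$conv2, r1, 3, 3, 1, 1, 1, 1)
  b2 <- .bn_fwd(p$bn2, layer$state$bn2, c2$y, training)
  if (layer$project) {
    cp <- .conv2d_fwd(p$proj, x, 1, 1, s, s, 0, 0)
    bp <- .bn_fwd(p$bnp, layer$state$bnp, cp$y, training)
    skip <- bp$y
  } else {
    cp <- NULL; bp <- NULL
    skip <- x
  }
  pre <- b2$y + skip
  y <- pmax(pre, 0)
  layer$state$bn1 <- b1$state
  layer$state$bn2 <- b2$state
  if (layer$project) layer$state$bnp <- bp$state
  list(y = y, layer = layer,
       cache = list(c1 = c1$cache, b1 = b1$cache, r1pre = b1$y,
                    c2 = c2$cache, b2 = b2$cache,
                    cp = if (layer$project) cp$cache else NULL,
                    bp = if (layer$project) bp$cache else NULL,
                    pre = pre))
}

.resblock_bwd <- function(layer, dy, cache) {
  p <- layer$params
  dpre <- dy * (cache$pre > 0)
  # main branch
  db2 <- .bn_bwd(p$bn2, dpre, cache$b2)
  dc2 <- .conv2d_bwd(p$conv2, db2$dx, cache$c2)
  dr1 <- dc2$dx * (cache$r1pre > 0)
  db1 <- .bn_bwd(p$bn1, dr1, cache$b1)
  dc1 <- .conv2d_bwd(p$conv1, db1$dx, cache$c1)
  dx <- dc1$dx
  grads <- list(conv1 = dc1$grads, bn1 = db1$grads,
                conv2 = dc2$grads, bn2 = db2$grads)
  if (layer$project) {
    dbp <- .bn_bwd(p$bnp, dpre, cache$bp)
    dcp <- .conv2d_bwd(p$proj, dbp$dx, cache$cp)
    dx <- dx + dcp$dx
    grads$proj <- dcp$grads
    grads$bnp <- dbp$grads
  } else {
    dx <- dx + dpre
  }
  list(dx = dx, grads = grads)
}

# ---------------------------------------------------------------------------
# Sequential forward / backward
# ---------------------------------------------------------------------------

.fwd_layer <- function(layer, x, training) {
  switch(layer$type,
    conv2d = {
      r <- .conv2d_fwd(layer$params, x, layer$kh, layer$kw, layer$sh,
                       layer$sw, layer$ph, layer$pw)
      list(y = r$y, cache = r$cache, layer = layer)
    },
    conv1d = {
      r <- .conv1d_fwd(layer$params, x, layer$k, layer$s)
      list(y = r$y, cache = r$cache, layer = layer)
    },
    bn = {
      r <- .bn_fwd(layer$params, layer$state, x, training)
      layer$state <- r$state
      list(y = r$y, cache = r$cache, layer = layer)
    },
    relu = list(y = pmax(x, 0), cache = list(x = x), layer = layer),
    maxpool2d = { r <- .maxpool2d_fwd(x); list(y = r$y, cache = r$cache, layer = layer) },
    maxpool1d = { r <- .maxpool1d_fwd(x); list(y = r$y, cache = r$cache, layer = layer) },
    gap2d = {
      d <- dim(x)
      y <- matrix(colMeans(matrix(x, d[1] * d[2], d[3] * d[4])), d[3], d[4])
      list(y = y, cache = list(d = d), layer = layer)
    },
    flatten = {
      d <- dim(x)
      y <- x
      dim(y) <- c(prod(d[-length(d)]), d[length(d)])
      list(y = y, cache = list(d = d), layer = layer)
    },
    dense = {
      y <- layer$params$W %*% x + layer$params$b
      list(y = y, cache = list(x = x), layer = layer)
    },
    dropout = {
      if (training && layer$p > 0) {
        mask <- (stats::runif(length(x)) >= layer$p) / (1 - layer$p)
        dim(mask) <- dim(x)
        list(y = x * mask, cache = list(mask = mask), layer = layer)
      } else {
        list(y = x, cache = list(mask = NULL), layer = layer)
      }
    },
    lstm = {
      r <- .lstm_fwd(layer$params, x, layer$hidden, layer$return_seq)
      list(y = r$y, cache = r$cache, layer = layer)
    },
    resblock = {
      r <- .resblock_fwd(layer, x, training)
      list(y = r$y, cache = r$cache, layer = r$layer)
    },
    stop("unknown layer type: ", layer$type)
  )
}

.bwd_layer <- function(layer, dy, cache) {
  switch(layer$type,
    conv2d = .conv2d_bwd(layer$params, dy, cache),
    conv1d = .conv1d_bwd(layer$params, dy, cache),
    bn = .bn_bwd(layer$params, dy, cache),
    relu = list(dx = dy * (cache$x > 0), grads = list()),
    maxpool2d = list(dx = .maxpool2d_bwd(dy, cache), grads = list()),
    maxpool1d = list(dx = .maxpool1d_bwd(dy, cache), grads = list()),
    gap2d = {
      d <- cache$d
      list(dx = array(rep(as.vector(dy) / (d[1] * d[2]), each = d[1] * d[2]), d),
           grads = list())
    },
    flatten = { dim(dy) <- cache$d; list(dx = dy, grads = list()) },
    dense = list(dx = crossprod(layer$params$W, dy),
                 grads = list(W = dy %*% t(cache$x), b = rowSums(dy))),
    dropout = {
      if (is.null(cache$mask)) list(dx = dy, grads = list())
      else list(dx = dy * cache$mask, grads = list())
    },
    lstm = .lstm_bwd(layer$params, dy, cache),
    resblock = .resblock_bwd(layer, dy, cache),
    stop("unknown layer type: ", layer$type)
  )
}

#' Run a sequential model forward
#'
#' @param model Initialized `nn_model`.
#' @param x Input batch array whose last dimension indexes observations.
#' @param training Use batch statistics and dropout (`TRUE`) or running
#'   statistics and identity dropout (`FALSE`).
#' @return List with `out` (final activations), `caches`, the (possibly
#'   state-updated) `model`, and `embedding` captured at the layer tagged
#'   `"embedding"`, if any.
#' @keywords internal
nn_forward <- function(model, x, training = FALSE) {
  if (!is.null(model$input_shape)) {
    d <- dim(x)
    exp_d <- model$input_shape
    if (length(d) != length(exp_d) + 1L || !all(d[-length(d)] == exp_d)) {
      stop("input shape mismatch: expected ", paste(exp_d, collapse = "x"),
           " (x N), got ", paste(d, collapse = "x"))
    }
  }
  caches <- vector("list", length(model$layers))
  embedding <- NULL
  for (i in seq_along(model$layers)) {
    r <- .fwd_layer(model$layers[[i]], x, training)
    x <- r$y
    caches[[i]] <- r$cache
    model$layers[[i]] <- r$layer
    if (identical(model$layers[[i]]$tag, "embedding")) embedding <- x
  }
  list(out = x, caches = caches, model = model, embedding = embedding)
}

nn_backward <- function(model, caches, dout) {
  grads <- vector("list", length(model$layers))
  dy <- dout
  for (i in rev(seq_along(model$layers))) {
    r <- .bwd_layer(model$layers[[i]], dy, caches[[i]])
    grads[[i]] <- r$grads
    dy <- r$dx
  }
  list(dx = dy, grads = grads)
}

#' Softmax cross-entropy loss and gradient
#'
#' @param logits Matrix `n_classes x N`.
#' @param y Integer class labels in `0:(n_classes-1)`.
#' @return List with `loss` (mean negative log-likelihood), `probs`, and
#'   `dlogits` (gradient of the mean loss).
#' @keywords internal
softmax_xent <- function(logits, y) {
  z <- sweep(logits, 2, apply(logits, 2, max))
  e <- exp(z)
  p <- sweep(e, 2, colSums(e), `/`)
  N <- ncol(logits)
  ll <- log(pmax(p[cbind(y + 1L, seq_len(N))], 1e-12))
  onehot <- matrix(0, nrow(logits), N)
  onehot[cbind(y + 1L, seq_len(N))] <- 1
  list(loss = -mean(ll), probs = p, dlogits = (p - onehot) / N)
}

# ---------------------------------------------------------------------------
# Flat parameter access and Adam
# ---------------------------------------------------------------------------

.model_params <- function(model) lapply(model$layers, function(l) l$params %||% list())

.flat_params <- function(model) unlist(.model_params(model), use.names = FALSE)

.set_flat_params <- function(model, vec) {
  pos <- 0L
  assign_rec <- function(p) {
    if (is.list(p)) return(lapply(p, assign_rec))
    n <- length(p)
    out <- vec[(pos + 1L):(pos + n)]
    pos <<- pos + n
    if (!is.null(dim(p))) dim(out) <- dim(p)
    out
  }
  for (i in seq_along(model$layers)) {
    if (!is.null(model$layers[[i]]$params)) {
      model$layers[[i]]$params <- assign_rec(model$layers[[i]]$params)
    }
  }
  model
}

.flat_grads <- function(grads) unlist(grads, use.names = FALSE)

# Mask of entries subject to L2 weight decay (weight matrices named "W",
# not biases or batch-norm scales).
.l2_mask <- function(model) {
  rec <- function(p, nm) {
    if (is.list(p)) {
      if (length(p) == 0) return(numeric(0))
      return(unlist(mapply(rec, p, names(p), SIMPLIFY = FALSE), use.names = FALSE))
    }
    rep(if (identical(nm, "W")) 1 else 0, length(p))
  }
  unlist(lapply(.model_params(model), rec, nm = ""), use.names = FALSE)
}

.adam_init <- function(n) list(m = numeric(n), v = numeric(n), t = 0L)

.adam_step <- function(theta, grad, st, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  st$t <- st$t + 1L
  st$m <- beta1 * st$m + (1 - beta1) * grad
  st$v <- beta2 * st$v + (1 - beta2) * grad^2
  mhat <- st$m / (1 - beta1^st$t)
  vhat <- st$v / (1 - beta2^st$t)
  list(theta = theta - lr * mhat / (sqrt(vhat) + eps), st = st)
}
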