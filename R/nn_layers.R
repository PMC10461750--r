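#' @name nn_layers
#' @title Layer primitives with hand-derived backward passes
#' @description
#' Minimal double-precision layer set backing the convolutional LSTM-UNet:
#' 3x3 convolution (im2col, zero padding), batch normalization with
#' statistics pooled over a stack of frames, ReLU, 2x2 max pooling, bilinear
#' x2 upsampling, and the ConvLSTM cell. Tensors are H x W x C arrays;
#' multi-frame activations are lists of such arrays. Every `*_bwd` is the
#' exact adjoint of its `*_fwd` (validated against finite differences in the
#' test suite).
#' @keywords internal
NULL

conv_init <- function(k, cin, cout, scale = sqrt(2 / (k * k * cin))) {
  list(W = matrix(rnorm(k * k * cin * cout, 0, scale), k * k * cin, cout),
       b = numeric(cout))
}

conv_fwd <- function(x, prm, k = 3L) {
  cpp_conv2d_fwd(x, prm$W, prm$b, k)
}

conv_bwd <- function(x, prm, gy, k = 3L) {
  cpp_conv2d_bwd(x, prm$W, gy, k)
}

# Trainable scale/shift; running statistics live in a separate buffer list
# so the optimizer never touches them.
bn_init <- function(c) list(gamma = rep(1, c), beta = numeric(c))
bn_buf_init <- function(c) list(run_mean = numeric(c), run_var = rep(1, c))

# Stack a list of H x W x C arrays into an (n*H*W) x C matrix.
bn_stack <- function(xs) {
  C <- dim(xs[[1]])[3]
  do.call(rbind, lapply(xs, function(a) matrix(a, ncol = C)))
}

bn_unstack <- function(M, xs) {
  C <- dim(xs[[1]])[3]
  n_per <- vapply(xs, function(a) prod(dim(a)[1:2]), 0)
  off <- c(0, cumsum(n_per))
  lapply(seq_along(xs), function(i) {
    array(M[(off[i] + 1):off[i + 1], ], dim = dim(xs[[i]]))
  })
}

bn_fwd <- function(xs, prm, buf, training = TRUE, momentum = 0.1,
                   eps = 1e-5) {
  single <- !is.list(xs)
  if (single) xs <- list(xs)
  X <- bn_stack(xs)
  n <- nrow(X)
  rep_c <- function(a) rep.int(a, rep.int(n, length(a)))  # col-major recycling
  if (training) {
    mu <- colMeans(X)
    v <- colMeans((X - rep_c(mu))^2)       # biased variance, as in training
  } else {
    mu <- buf$run_mean
    v <- buf$run_var
  }
  xhat <- (X - rep_c(mu)) * rep_c(1 / sqrt(v + eps))
  Y <- xhat * rep_c(prm$gamma) + rep_c(prm$beta)
  ys <- bn_unstack(Y, xs)
  if (training) {
    buf$run_mean <- (1 - momentum) * buf$run_mean + momentum * mu
    buf$run_var <- (1 - momentum) * buf$run_var + momentum * v
  }
  list(y = if (single) ys[[1]] else ys,
       cache = list(xhat = xhat, mu = mu, v = v, eps = eps, xs = xs,
                    single = single),
       buf = buf)
}

bn_bwd <- function(gy, prm, cache) {
  gys <- if (cache$single) list(gy) else gy
  G <- bn_stack(gys)
  xhat <- cache$xhat
  m <- nrow(G)
  dgamma <- colSums(G * xhat)
  dbeta <- colSums(G)
  inv_sd <- 1 / sqrt(cache$v + cache$eps)
  rep_c <- function(a) rep.int(a, rep.int(m, length(a)))
  dxhat <- G * rep_c(prm$gamma)
  ## dX = inv_sd/m * (m*dxhat - sum(dxhat) - xhat * sum(dxhat*xhat))
  dX <- (m * dxhat - rep_c(colSums(dxhat)) -
           xhat * rep_c(colSums(dxhat * xhat))) * rep_c(inv_sd / m)
  gxs <- bn_unstack(dX, cache$xs)
  list(gx = if (cache$single) gxs[[1]] else gxs,
       dgamma = dgamma, dbeta = dbeta)
}

relu_fwd <- function(x) { x[x < 0] <- 0; x }
relu_bwd <- function(x, gy) gy * (x > 0)

sigmoid <- function(x) 1 / (1 + exp(-x))

concat_c <- function(a, b) {
  d <- dim(a)
  array(c(a, b), dim = c(d[1], d[2], d[3] + dim(b)[3]))
}

split_c <- function(x, c1) {
  d <- dim(x)
  list(x[, , seq_len(c1), drop = FALSE],
       x[, , (c1 + 1):d[3], drop = FALSE])
}

lstm_init <- function(k, cx, L) {
  prm <- conv_init(k, cx + L, 4 * L, scale = sqrt(1 / (k * k * (cx + L))))
  prm$b[seq_len(L)] <- 1       # forget-gate bias
  prm
}

# One ConvLSTM step. z = conv([x, h_prev]) splits into (f, i, o, g):
# c_new = f*c_prev + i*g ; h_new = o * tanh(c_new).
lstm_fwd <- function(x, h_prev, c_prev, prm, L, k = 3L) {
  xc <- concat_c(x, h_prev)
  z <- conv_fwd(xc, prm, k)
  f <- sigmoid(z[, , 1:L, drop = FALSE])
  i <- sigmoid(z[, , (L + 1):(2 * L), drop = FALSE])
  o <- sigmoid(z[, , (2 * L + 1):(3 * L), drop = FALSE])
  g <- tanh(z[, , (3 * L + 1):(4 * L), drop = FALSE])
  c_new <- f * c_prev + i * g
  tc <- tanh(c_new)
  h_new <- o * tc
  list(h = h_new, c = c_new,
       cache = list(xc = xc, f = f, i = i, o = o, g = g,
                    c_prev = c_prev, tc = tc))
}

lstm_bwd <- function(gh, gc, prm, cache, L, k = 3L) {
  with(cache, {
    do <- gh * tc
    gc_total <- gc + gh * o * (1 - tc^2)
    df <- gc_total * c_prev
    di <- gc_total * g
    dg <- gc_total * i
    gc_prev <- gc_total * f
    dz <- array(0, dim = c(dim(f)[1], dim(f)[2], 4 * L))
    dz[, , 1:L] <- df * f * (1 - f)
    dz[, , (L + 1):(2 * L)] <- di * i * (1 - i)
    dz[, , (2 * L + 1):(3 * L)] <- do * o * (1 - o)
    dz[, , (3 * L + 1):(4 * L)] <- dg * (1 - g^2)
    cb <- conv_bwd(xc, prm, dz, k)
    sp <- split_c(cb$gx, dim(xc)[3] - L)
    list(gx = sp[[1]], gh_prev = sp[[2]], gc_prev = gc_prev,
         gW = cb$gW, gb = cb$gb)
  })
}

# --- nested parameter-list helpers (flatten for the Adam optimizer) -------

flatten_params <- function(p) {
  if (is.numeric(p)) return(as.numeric(p))
  unlist(lapply(p, flatten_params), use.names = FALSE)
}

# Fill the numeric leaves of skeleton `p` from `vec`, preserving dims.
unflatten_params <- function(p, vec, pos = 1L) {
  fill <- function(node) {
    if (is.numeric(node)) {
      n <- length(node)
      out <- vec[pos:(pos + n - 1L)]
      pos <<- pos + n
      if (!is.null(dim(node))) dim(out) <- dim(node)
      return(out)
    }
    lapply(node, fill)
  }
  fill(p)
}

zero_params <- function(p) {
  if (is.numeric(p)) return(p * 0)
  lapply(p, zero_params)
}

add_params <- function(a, b) {
  if (is.numeric(a)) return(a + b)
  mapply(add_params, a, b, SIMPLIFY = FALSE)
}
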