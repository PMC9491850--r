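# Building blocks of the 1-D deep residual shrinkage network: convolution,
# batch normalization, soft thresholding with thresholds learned by a
# squeeze-and-excitation subnetwork, and the residual shrinkage unit.
# Feature maps are [batch, channel, length] arrays; every forward has a
# matching analytic backward (verified against numerical gradients in the
# test suite).

#' Soft thresholding (shrinkage) operator
#'
#' Zeroes values in `[-tau, tau]` and moves the rest toward zero by `tau`:
#' `y = x - tau` for `x > tau`, `0` for `|x| <= tau`, `x + tau` for
#' `x < -tau`. The core denoising step of the residual shrinkage unit.
#'
#' @param x Numeric vector/array.
#' @param tau Threshold(s) `>= 0`, recycled against `x`.
#' @return Shrunk values, same shape as `x`.
#' @export
soft_threshold <- function(x, tau) {
  if (any(tau < 0)) abort("tau must be >= 0.")
  sign(x) * pmax(abs(x) - tau, 0)
}

#' Derivative of soft thresholding with respect to its input
#'
#' Equals 1 where `|x| > tau` and 0 where `|x| <= tau`, so gradients passed
#' through the shrinkage layer are never amplified.
#'
#' @inheritParams soft_threshold
#' @return 0/1 values, same shape as `x`.
#' @export
soft_threshold_grad <- function(x, tau) {
  if (any(tau < 0)) abort("tau must be >= 0.")
  as.numeric(abs(x) > tau)
}

#' Squeeze step of the SE attention subnetwork
#'
#' Global average pooling: one descriptor per channel, the mean of that
#' channel's feature map.
#'
#' @param feature_map `[channel, length]` matrix or `[batch, channel,
#'   length]` array.
#' @return Per-channel means: a vector, or a `[batch, channel]` matrix.
#' @export
senet_squeeze <- function(feature_map) {
  if (is.matrix(feature_map)) rowMeans(feature_map)
  else if (length(dim(feature_map)) == 3) gap3(feature_map)
  else abort("feature_map must be [channel, length] or [batch, channel, length].")
}

# --- internal array helpers -------------------------------------------------

# mean over the length axis of a [B, C, L] array -> [B, C]
gap3 <- function(x) {
  d <- dim(x)
  matrix(colMeans(aperm(x, c(3, 1, 2)), dims = 1), d[1], d[2])
}

as_bcl <- function(x) {
  if (length(dim(x)) == 3) x
  else if (is.matrix(x)) array(x, c(1, dim(x)))   # [C, L] -> batch of 1
  else abort("expected a [batch, channel, length] array or [channel, length] matrix.")
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# --- 1-D convolution --------------------------------------------------------

conv1d_init <- function(kernel, c_in, c_out, scale = NULL) {
  if (is.null(scale)) scale <- sqrt(2 / (kernel * c_in))
  list(W = array(rnorm(kernel * c_in * c_out, sd = scale),
                 c(kernel, c_in, c_out)),
       b = numeric(c_out))
}

conv1d_forward <- function(x, par, stride = 1) {
  d <- dim(x); B <- d[1]; Cin <- d[2]; L <- d[3]
  k <- dim(par$W)[1]; Cout <- dim(par$W)[3]
  p <- (k - 1L) %/% 2L
  Lout <- (L + 2L * p - k) %/% stride + 1L
  xp <- array(0, c(B, Cin, L + 2L * p))
  xp[, , p + seq_len(L)] <- x
  cols <- array(0, c(B, Cin, k, Lout))
  for (t in seq_len(k)) {
    cols[, , t, ] <- xp[, , (seq_len(Lout) - 1L) * stride + t]
  }
  xmat <- aperm(cols, c(1, 4, 2, 3))        # [B, Lout, Cin, k]
  dim(xmat) <- c(B * Lout, Cin * k)
  wmat <- aperm(par$W, c(2, 1, 3))          # [Cin, k, Cout]
  dim(wmat) <- c(Cin * k, Cout)
  y <- xmat %*% wmat
  y <- sweep(y, 2, par$b, `+`)
  dim(y) <- c(B, Lout, Cout)
  y <- aperm(y, c(1, 3, 2))                 # [B, Cout, Lout]
  list(out = y,
       cache = list(xmat = xmat, wmat = wmat, dims = d, k = k, p = p,
                    stride = stride, Lout = Lout))
}

conv1d_backward <- function(dy, cache) {
  d <- cache$dims; B <- d[1]; Cin <- d[2]; L <- d[3]
  k <- cache$k; p <- cache$p; stride <- cache$stride; Lout <- cache$Lout
  Cout <- ncol(cache$wmat)
  dymat <- aperm(dy, c(1, 3, 2))
  dim(dymat) <- c(B * Lout, Cout)
  db <- colSums(dymat)
  dwmat <- crossprod(cache$xmat, dymat)     # [Cin*k, Cout]
  dW <- array(dwmat, c(Cin, k, Cout))
  dW <- aperm(dW, c(2, 1, 3))               # [k, Cin, Cout]
  dxmat <- dymat %*% t(cache$wmat)          # [B*Lout, Cin*k]
  dim(dxmat) <- c(B, Lout, Cin, k)
  dcols <- aperm(dxmat, c(1, 3, 4, 2))      # [B, Cin, k, Lout]
  dxp <- array(0, c(B, Cin, L + 2L * p))
  for (t in seq_len(k)) {
    idx <- (seq_len(Lout) - 1L) * stride + t
    dxp[, , idx] <- dxp[, , idx] + dcols[, , t, ]
  }
  list(dx = dxp[, , p + seq_len(L), drop = FALSE],
       dW = dW, db = db)
}

# --- batch normalization ----------------------------------------------------
# Works on [B, C, L] arrays (stats over batch and length) and on [B, C]
# matrices (stats over batch). `buf` holds running mean/var for inference.

bn_init <- function(c_out) {
  list(par = list(g = rep(1, c_out), b = numeric(c_out)),
       buf = list(mean = numeric(c_out), var = rep(1, c_out)))
}

bn_forward <- function(x, par, buf, training, eps = 1e-5, momentum = 0.1) {
  is3 <- length(dim(x)) == 3
  xm <- if (is3) aperm(x, c(1, 3, 2)) else x       # channels last
  dm <- dim(xm)
  xm <- matrix(xm, ncol = dm[length(dm)])
  if (training) {
    mu <- colMeans(xm)
    v <- colMeans(xm^2) - mu^2
    buf$mean <- (1 - momentum) * buf$mean + momentum * mu
    buf$var <- (1 - momentum) * buf$var + momentum * v
  } else {
    mu <- buf$mean
    v <- buf$var
  }
  ivar <- 1 / sqrt(v + eps)
  xhat <- sweep(sweep(xm, 2, mu), 2, ivar, `*`)
  y <- sweep(sweep(xhat, 2, par$g, `*`), 2, par$b, `+`)
  reshape_back <- function(m) {
    if (is3) {
      dim(m) <- dm
      aperm(m, c(1, 3, 2))
    } else m
  }
  list(out = reshape_back(y), buf = buf,
       cache = list(xhat = xhat, ivar = ivar, g = par$g, is3 = is3, dm = dm,
                    training = training, reshape_back = reshape_back))
}

bn_backward <- function(dy, cache) {
  dym <- if (cache$is3) aperm(dy, c(1, 3, 2)) else dy
  dym <- matrix(dym, ncol = length(cache$g))
  xhat <- cache$xhat
  dg <- colSums(dym * xhat)
  db <- colSums(dym)
  dxhat <- sweep(dym, 2, cache$g, `*`)
  if (cache$training) {
    dx <- sweep(
      dxhat -
        matrix(colMeans(dxhat), nrow(dxhat), ncol(dxhat), byrow = TRUE) -
        xhat * matrix(colMeans(dxhat * xhat), nrow(dxhat), ncol(dxhat),
                      byrow = TRUE),
      2, cache$ivar, `*`)
  } else {
    dx <- sweep(dxhat, 2, cache$ivar, `*`)
  }
  list(dx = cache$reshape_back(dx), dg = dg, db = db)
}

relu_forward <- function(x) list(out = pmax(x, 0), cache = x > 0)
relu_backward <- function(dy, cache) dy * cache

dense_init <- function(c_in, c_out, scale = NULL) {
  if (is.null(scale)) scale <- sqrt(2 / c_in)
  list(W = matrix(rnorm(c_in * c_out, sd = scale), c_in, c_out),
       b = numeric(c_out))
}

dense_forward <- function(x, par) {
  list(out = sweep(x %*% par$W, 2, par$b, `+`), cache = list(x = x, W = par$W))
}

dense_backward <- function(dy, cache) {
  list(dx = dy %*% t(cache$W), dW = crossprod(cache$x, dy), db = colSums(dy))
}

# --- threshold subnetwork + shrinkage ---------------------------------------

subnet_init <- function(c_out, mode) {
  n_alpha <- if (mode == "channel_shared") 1L else c_out
  c(dense_init(c_out, c_out), list(bn = bn_init(c_out)),
    stats::setNames(dense_init(c_out, n_alpha, scale = 0.01), c("W2", "b2")))
}

subnet_forward <- function(m, sub, training) {
  f1 <- dense_forward(m, list(W = sub$W, b = sub$b))
  bn <- bn_forward(f1$out, sub$bn$par, sub$bn$buf, training)
  rl <- relu_forward(bn$out)
  f2 <- dense_forward(rl$out, list(W = sub$W2, b = sub$b2))
  alpha <- sigmoid(f2$out)                 # [B, C] or [B, 1]
  sub$bn$buf <- bn$buf
  list(alpha = alpha, sub = sub,
       cache = list(f1 = f1$cache, bn = bn$cache, rl = rl$cache,
                    f2 = f2$cache, alpha = alpha))
}

subnet_backward <- function(dalpha, cache) {
  dpre <- dalpha * cache$alpha * (1 - cache$alpha)
  g2 <- dense_backward(dpre, cache$f2)
  drl <- relu_backward(g2$dx, cache$rl)
  gbn <- bn_backward(drl, cache$bn)
  g1 <- dense_backward(gbn$dx, cache$f1)
  list(dm = g1$dx,
       grads = list(W = g1$dW, b = g1$db,
                    bn = list(par = list(g = gbn$dg, b = gbn$db)),
                    W2 = g2$dW, b2 = g2$db))
}

#' Learn per-channel soft thresholds from a feature map
#'
#' Implements the adaptive threshold of the residual shrinkage unit:
#' `tau_c = alpha_c * mean(|feature_map_c|)` where `alpha_c` in `(0, 1)` is
#' the sigmoid output of the attention subnetwork (global pool of the
#' absolute feature map, dense, batch norm, ReLU, dense, sigmoid). Because
#' `alpha < 1`, every threshold is positive yet strictly below the
#' channel's mean absolute activation. `channel_shared` subnetworks emit a
#' single `alpha` used for all channels.
#'
#' @param feature_map `[batch, channel, length]` array (a `[channel,
#'   length]` matrix is treated as one sample).
#' @param subnet Subnetwork parameters, e.g. from an [new_rsbu_unit()]
#'   element `$sub`, plus a `$mode` entry.
#' @return `[batch, channel]` matrix of thresholds.
#' @export
learn_threshold <- function(feature_map, subnet) {
  x <- as_bcl(feature_map)
  m <- gap3(abs(x))
  sf <- subnet_forward(m, subnet, training = FALSE)
  alpha <- sf$alpha
  if (ncol(alpha) == 1L && ncol(m) > 1L) {
    alpha <- matrix(alpha, nrow(m), ncol(m))
  }
  alpha * m
}

# Shrinkage with subnetwork-learned thresholds; full backward through both
# the direct path and the threshold path (tau depends on |r| via the pool
# and the subnetwork).
shrink_forward <- function(r, sub, training, enabled = TRUE) {
  d <- dim(r); B <- d[1]; C <- d[2]; L <- d[3]
  if (!enabled) {
    return(list(out = r, sub = sub, cache = list(enabled = FALSE)))
  }
  m <- gap3(abs(r))
  sf <- subnet_forward(m, sub, training)
  alpha <- sf$alpha
  shared <- ncol(alpha) == 1L
  alpha_full <- if (shared) matrix(alpha, B, C) else alpha
  tau <- alpha_full * m
  tau_bc <- array(tau, c(B, C, L))
  sgn <- sign(r)
  mask <- abs(r) > tau_bc
  out <- sgn * pmax(abs(r) - tau_bc, 0)
  list(out = out, sub = sf$sub,
       cache = list(enabled = TRUE, r = r, sgn = sgn, mask = mask, m = m,
                    alpha = alpha, alpha_full = alpha_full, shared = shared,
                    subcache = sf$cache, dims = d))
}

shrink_backward <- function(dy, cache) {
  if (!cache$enabled) return(list(dr = dy, grads = NULL))
  d <- cache$dims; B <- d[1]; C <- d[2]; L <- d[3]
  dr <- dy * cache$mask
  # d tau: sum over length of -sign(r) * dy on the active set
  dtau <- matrix(rowSums(array(-dy * cache$sgn * cache$mask, c(B, C, L)),
                         dims = 2), B, C)
  dalpha_full <- dtau * cache$m
  dm_tau <- dtau * cache$alpha_full
  dalpha <- if (cache$shared) matrix(rowSums(dalpha_full), B, 1)
            else dalpha_full
  sb <- subnet_backward(dalpha, cache$subcache)
  dm <- dm_tau + sb$dm
  # m = mean over length of |r|
  dabs <- array(dm / L, c(B, C, L))
  dr <- dr + dabs * cache$sgn
  list(dr = dr, grads = sb$grads)
}

# --- residual shrinkage building unit ---------------------------------------

#' Create a residual shrinkage building unit
#'
#' Two-layer convolutional residual branch (conv, batch norm, ReLU, conv,
#' batch norm) whose output is soft-thresholded with thresholds learned by
#' an SE-style subnetwork, then added to the shortcut. A 1x1 convolution
#' `Ws` transforms the shortcut when channel count or stride changes shape.
#'
#' @param c_in,c_out Input/output channel counts.
#' @param kernel Convolution kernel size (taps).
#' @param stride Stride of the first convolution.
#' @param mode `"channel_wise"` (one threshold per channel) or
#'   `"channel_shared"` (a single threshold for all channels).
#' @param init `"he"` random initialization or `"zero"` (zero residual
#'   branch, which makes the unit an identity on matching shapes).
#' @return An `rsbu_unit` parameter list.
#' @export
new_rsbu_unit <- function(c_in, c_out, kernel = 3, stride = 1,
                          mode = c("channel_wise", "channel_shared"),
                          init = c("he", "zero")) {
  mode <- match.arg(mode)
  init <- match.arg(init)
  scale <- if (init == "zero") 0 else NULL
  unit <- list(
    conv1 = conv1d_init(kernel, c_in, c_out, scale = scale),
    bn1 = bn_init(c_out),
    conv2 = conv1d_init(kernel, c_out, c_out, scale = scale),
    bn2 = bn_init(c_out),
    sub = subnet_init(c_out, mode),
    mode = mode, stride = stride, c_in = c_in, c_out = c_out,
    kernel = kernel
  )
  if (init == "zero") {
    unit$sub$W <- unit$sub$W * 0
    unit$sub$W2 <- unit$sub$W2 * 0
  }
  if (stride != 1 || c_in != c_out) {
    unit$shortcut <- conv1d_init(1, c_in, c_out)
  }
  class(unit) <- "rsbu_unit"
  unit
}

rsbu_forward <- function(x, unit, training, shrinkage = TRUE) {
  c1 <- conv1d_forward(x, unit$conv1, stride = unit$stride)
  b1 <- bn_forward(c1$out, unit$bn1$par, unit$bn1$buf, training)
  r1 <- relu_forward(b1$out)
  c2 <- conv1d_forward(r1$out, unit$conv2, stride = 1)
  b2 <- bn_forward(c2$out, unit$bn2$par, unit$bn2$buf, training)
  sh <- shrink_forward(b2$out, unit$sub, training, enabled = shrinkage)
  if (!is.null(unit$shortcut)) {
    sc <- conv1d_forward(x, unit$shortcut, stride = unit$stride)
    shortcut_out <- sc$out
    sc_cache <- sc$cache
  } else {
    shortcut_out <- x
    sc_cache <- NULL
  }
  unit$bn1$buf <- b1$buf
  unit$bn2$buf <- b2$buf
  unit$sub <- sh$sub
  list(out = shortcut_out + sh$out, unit = unit,
       cache = list(c1 = c1$cache, b1 = b1$cache, r1 = r1$cache,
                    c2 = c2$cache, b2 = b2$cache, sh = sh$cache,
                    sc = sc_cache))
}

rsbu_backward <- function(dy, cache, unit) {
  g <- list()
  sh <- shrink_backward(dy, cache$sh)
  gb2 <- bn_backward(sh$dr, cache$b2)
  gc2 <- conv1d_backward(gb2$dx, cache$c2)
  gr1 <- relu_backward(gc2$dx, cache$r1)
  gb1 <- bn_backward(gr1, cache$b1)
  gc1 <- conv1d_backward(gb1$dx, cache$c1)
  dx <- gc1$dx
  if (!is.null(cache$sc)) {
    gsc <- conv1d_backward(dy, cache$sc)
    dx <- dx + gsc$dx
    g$shortcut <- list(W = gsc$dW, b = gsc$db)
  } else {
    dx <- dx + dy
  }
  g$conv1 <- list(W = gc1$dW, b = gc1$db)
  g$bn1 <- list(par = list(g = gb1$dg, b = gb1$db))
  g$conv2 <- list(W = gc2$dW, b = gc2$db)
  g$bn2 <- list(par = list(g = gb2$dg, b = gb2$db))
  g$sub <- sh$grads
  list(dx = dx, grads = g)
}

#' Forward pass of a residual shrinkage unit
#'
#' `y = shortcut(x) + shrink(residual_branch(x))` in inference mode (batch
#' norm uses running statistics). With the residual branch and subnetwork
#' zeroed and matching shapes, the unit is an identity map.
#'
#' @param x `[batch, channel, length]` array (or `[channel, length]`
#'   matrix, treated as one sample).
#' @param unit An [new_rsbu_unit()].
#' @return Output array `[batch, c_out, length/stride]`.
#' @export
residual_block_forward <- function(x, unit) {
  x <- as_bcl(x)
  rsbu_forward(x, unit, training = FALSE)$out
}
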