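# DRSN building blocks: shrinkage operator, SE squeeze, threshold learning,
# residual unit, and full analytic backprop vs numerical gradients.

test_that("soft thresholding shrinks toward zero with a dead zone", {
  expect_equal(soft_threshold(2.0, 0.5), 1.5)
  expect_equal(soft_threshold(0.3, 0.5), 0)
  expect_equal(soft_threshold(-2.0, 0.5), -1.5)
  expect_equal(soft_threshold(c(-1, -0.2, 0, 0.2, 1), 0.25),
               c(-0.75, 0, 0, 0, 0.75))
  expect_error(soft_threshold(1, -0.1), "tau")
  # contraction: elementwise |shrink(v)| <= |v| for any tau >= 0
  set.seed(41)
  for (tau in c(0, 0.1, 1, 10)) {
    v <- rnorm(200)
    expect_true(all(abs(soft_threshold(v, tau)) <= abs(v)))
    expect_lte(sum(abs(soft_threshold(v, tau))), sum(abs(v)))
  }
})

test_that("shrinkage derivative is the 0/1 indicator of the active set", {
  expect_equal(soft_threshold_grad(2, 0.5), 1)
  expect_equal(soft_threshold_grad(0.1, 0.5), 0)
  expect_equal(soft_threshold_grad(-0.5, 0.5), 0)
  x <- seq(-5, 5, length.out = 1e4)
  tau <- 0.8
  g <- soft_threshold_grad(x, tau)
  expect_true(all(g %in% c(0, 1)))
  expect_equal(g, as.numeric(abs(x) > tau))
  # finite differences away from the kinks
  keep <- abs(abs(x) - tau) > 1e-3
  h <- 1e-4
  fd <- (soft_threshold(x + h, tau) - soft_threshold(x - h, tau)) / (2 * h)
  expect_equal(g[keep], fd[keep], tolerance = 1e-8)
})

test_that("SE squeeze is the per-channel mean", {
  expect_equal(senet_squeeze(matrix(3, 2, 7)), c(3, 3))
  expect_equal(senet_squeeze(matrix(c(1, 2), 2, 1)), c(1, 2))
  set.seed(42)
  x <- array(rnorm(3 * 4 * 6), c(3, 4, 6))
  z <- senet_squeeze(x)
  for (b in 1:3) for (c in 1:4) {
    acc <- 0
    for (l in 1:6) acc <- acc + x[b, c, l]
    expect_equal(z[b, c], acc / 6)
  }
})

test_that("learned thresholds obey the positivity and magnitude constraints", {
  unit <- with_fixed_rng(43, new_rsbu_unit(3, 3, init = "zero"))
  # zeroed subnetwork: sigmoid(0) = 0.5, so tau = 0.5 * mean|x|
  fm <- array(2 * sign(rnorm(2 * 3 * 8)), c(2, 3, 8))
  tau <- learn_threshold(fm, c(unit$sub, mode = unit$mode))
  expect_equal(tau, matrix(1, 2, 3), tolerance = 1e-12, ignore_attr = TRUE)
  # all-zero map gives tau = 0 and an identity unit output
  z <- array(0, c(1, 3, 8))
  expect_equal(learn_threshold(z, c(unit$sub, mode = unit$mode)),
               matrix(0, 1, 3), ignore_attr = TRUE)
  # random subnetwork: 0 < tau < mean|x| always (sigmoid in (0,1))
  unit2 <- with_fixed_rng(44, new_rsbu_unit(3, 3))
  fm2 <- array(rnorm(4 * 3 * 8), c(4, 3, 8))
  tau2 <- learn_threshold(fm2, c(unit2$sub, mode = unit2$mode))
  m <- semgforce:::gap3(abs(fm2))
  expect_true(all(tau2 > 0 & tau2 < m))
})

test_that("channel_shared mode uses one alpha across channels", {
  unit <- with_fixed_rng(45, new_rsbu_unit(4, 4, mode = "channel_shared"))
  fm <- array(rnorm(2 * 4 * 8), c(2, 4, 8))
  tau <- learn_threshold(fm, c(unit$sub, mode = unit$mode))
  m <- semgforce:::gap3(abs(fm))
  alpha <- tau / m
  expect_equal(alpha[, 1], alpha[, 2], tolerance = 1e-12)
  expect_equal(alpha[, 1], alpha[, 4], tolerance = 1e-12)
})

test_that("zeroed residual branch makes the unit an identity on matching shapes", {
  unit <- with_fixed_rng(46, new_rsbu_unit(4, 4, init = "zero"))
  x <- array(rnorm(3 * 4 * 10), c(3, 4, 10))
  expect_equal(residual_block_forward(x, unit), x, tolerance = 1e-12)
})

test_that("unit output shape follows channels and stride", {
  unit <- with_fixed_rng(47, new_rsbu_unit(3, 8, stride = 2))
  x <- array(rnorm(2 * 3 * 12), c(2, 3, 12))
  expect_equal(dim(residual_block_forward(x, unit)), c(2, 8, 6))
})

test_that("unit forward equals a hand-unrolled layer composition", {
  unit <- with_fixed_rng(48, new_rsbu_unit(1, 2, kernel = 3, stride = 1))
  x <- array(seq(-0.7, 0.7, length.out = 8), c(1, 1, 8))
  out <- residual_block_forward(x, unit)

  # independent step-by-step recomputation with explicit loops
  conv_ref <- function(xv, W, b, stride = 1) {
    # xv: [C_in, L]; W: [k, C_in, C_out]
    k <- dim(W)[1]; cin <- dim(W)[2]; cout <- dim(W)[3]
    L <- ncol(xv); p <- (k - 1) %/% 2
    xp <- cbind(matrix(0, cin, p), xv, matrix(0, cin, p))
    Lout <- (L + 2 * p - k) %/% stride + 1
    y <- matrix(0, cout, Lout)
    for (co in 1:cout) for (j in 1:Lout) {
      acc <- b[co]
      for (ci in 1:cin) for (t in 1:k) {
        acc <- acc + W[t, ci, co] * xp[ci, (j - 1) * stride + t]
      }
      y[co, j] <- acc
    }
    y
  }
  bn_ref <- function(y, par, buf) {
    # inference mode: running stats
    sweep(sweep(sweep(sweep(y, 1, buf$mean), 1, sqrt(buf$var + 1e-5), `/`),
                1, par$g, `*`), 1, par$b, `+`)
  }
  xm <- x[1, , , drop = TRUE]
  xm <- matrix(xm, 1, 8)
  h <- conv_ref(xm, unit$conv1$W, unit$conv1$b)
  h <- bn_ref(h, unit$bn1$par, unit$bn1$buf)
  h <- pmax(h, 0)
  h <- conv_ref(h, unit$conv2$W, unit$conv2$b)
  r <- bn_ref(h, unit$bn2$par, unit$bn2$buf)
  # threshold subnetwork on the pooled |r|
  m <- rowMeans(abs(r))
  h1 <- drop(m %*% unit$sub$W) + unit$sub$b
  h1 <- (h1 - unit$sub$bn$buf$mean) / sqrt(unit$sub$bn$buf$var + 1e-5) *
    unit$sub$bn$par$g + unit$sub$bn$par$b
  h1 <- pmax(h1, 0)
  alpha <- 1 / (1 + exp(-(drop(h1 %*% unit$sub$W2) + unit$sub$b2)))
  tau <- alpha * m
  shrunk <- sign(r) * pmax(abs(r) - tau, 0)
  shortcut <- conv_ref(xm, unit$shortcut$W, unit$shortcut$b)
  expected <- shortcut + shrunk
  expect_equal(out[1, , ], expected, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("analytic gradients match central finite differences", {
  cfg <- drsn_config(n_units = 2, channels = c(4, 6), epochs = 0, seed = 7)
  set.seed(7)
  B <- 4; C <- 3; L <- 8
  x <- array(rnorm(B * C * L), c(B, C, L))
  y <- rnorm(B)
  net <- semgforce:::drsn_init(cfg, c_in = C)
  loss_fn <- function(nt) {
    fw <- semgforce:::net_forward(nt, x, cfg, training = TRUE)
    mean((fw$out - y)^2)
  }
  fw <- semgforce:::net_forward(net, x, cfg, training = TRUE)
  grads <- semgforce:::net_backward(2 * (fw$out - y) / B, fw$cache, net, cfg)

  relerr <- c()
  h <- 1e-5
  probe <- function(path) {
    leaf <- net
    gleaf <- grads
    for (k in path) {
      leaf <- leaf[[k]]
      gleaf <- gleaf[[k]]
    }
    idx <- unique(round(seq(1, length(leaf), length.out = min(3, length(leaf)))))
    for (i in idx) {
      set_leaf <- function(tree, p, val) {
        if (length(p) == 1) {
          tree[[p[[1]]]] <- val
          return(tree)
        }
        tree[[p[[1]]]] <- set_leaf(tree[[p[[1]]]], p[-1], val)
        tree
      }
      lp <- leaf; lp[i] <- lp[i] + h
      lm <- leaf; lm[i] <- lm[i] - h
      num <- (loss_fn(set_leaf(net, path, lp)) -
                loss_fn(set_leaf(net, path, lm))) / (2 * h)
      relerr <<- c(relerr,
                   abs(num - gleaf[i]) / max(1e-8, abs(num) + abs(gleaf[i])))
    }
  }
  paths <- list(
    list("stem", "W"), list("stem", "b"), list("stem", "bn", "par", "g"),
    list("units", 1L, "conv1", "W"), list("units", 1L, "bn1", "par", "b"),
    list("units", 1L, "conv2", "W"), list("units", 1L, "sub", "W"),
    list("units", 1L, "sub", "W2"), list("units", 1L, "sub", "b2"),
    list("units", 2L, "conv1", "W"), list("units", 2L, "shortcut", "W"),
    list("units", 2L, "sub", "W"), list("units", 2L, "bn2", "par", "g"),
    list("head", "W"), list("head", "b")
  )
  for (p in paths) probe(p)
  expect_gt(length(relerr), 30)
  # a couple of probes may straddle a shrinkage kink; the bulk must agree
  expect_lt(median(relerr), 1e-7)
  expect_lt(sort(relerr)[ceiling(0.9 * length(relerr))], 1e-4)
})
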