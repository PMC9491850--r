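# Dimensionality reduction: linear PCA baseline and Gaussian-kernel KPCA.

test_that("pca_fit matches the prcomp oracle up to component sign", {
  set.seed(21)
  for (i in 1:3) {
    x <- matrix(rnorm(30 * 6), 30, 6)
    model <- pca_fit(x, 4)
    ours <- pca_project(model, x)
    oracle <- prcomp(x, center = TRUE, scale. = FALSE)$x[, 1:4]
    for (j in 1:4) {
      expect_lt(min(max(abs(ours[, j] - oracle[, j])),
                    max(abs(ours[, j] + oracle[, j]))), 1e-8)
    }
    expect_equal(model$axes %*% t(model$axes), diag(4), tolerance = 1e-10)
  }
})

test_that("pca degenerate and edge cases behave", {
  # points on a line through the centroid: one component carries everything
  t <- seq(-1, 1, length.out = 11)
  x <- cbind(2 * t, -t, 3 * t) + 5
  model <- pca_fit(x, 3)
  expect_gt(model$eigenvalues[1] / sum(model$eigenvalues), 1 - 1e-12)
  # projecting the mean sample gives zero scores
  expect_equal(pca_project(model, colMeans(x)), rep(0, 3),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(pca_fit(x, 0), "positive")
  expect_error(pca_fit(x, 9), "min")
})

test_that("gaussian kernel has closed form, symmetry, and PSD kernel matrix", {
  expect_equal(gaussian_kernel(c(1, 2), c(1, 2), 3), 1)
  expect_equal(gaussian_kernel(c(0, 0), c(1, 1), 0.5), exp(-1))
  expect_error(gaussian_kernel(1, 1, 0), "gamma")
  expect_error(gaussian_kernel(1, c(1, 2), 1), "dimensions")
  set.seed(22)
  x <- matrix(rnorm(10 * 3), 10, 3)
  K <- outer(seq_len(10), seq_len(10),
             Vectorize(function(i, j) gaussian_kernel(x[i, ], x[j, ], 0.7)))
  expect_equal(K, t(K))
  expect_gt(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values),
            -1e-10)
})

test_that("linear-kernel KPCA reproduces PCA projections up to sign", {
  set.seed(23)
  for (i in 1:5) {
    x <- matrix(rnorm(20 * 8), 20, 8)
    km <- kpca_fit(x, kernel = "linear", xi_threshold = 1)
    pm <- pca_fit(x, 8)
    sk <- kpca_project(km, x, n_components = 8)
    sp <- pca_project(pm, x)
    for (j in 1:8) {
      expect_lt(min(max(abs(sk[, j] - sp[, j])),
                    max(abs(sk[, j] + sp[, j]))), 1e-8)
    }
  }
})

test_that("kpca agrees with the kernlab oracle up to sign and scale", {
  set.seed(24)
  x <- matrix(rnorm(30 * 5), 30, 5)
  g <- 0.3
  ours <- kpca_project(kpca_fit(x, gamma = g, xi_threshold = 1), x,
                       n_components = 4)
  oracle <- kernlab::rotated(kernlab::kpca(x, kernel = "rbfdot",
                                           kpar = list(sigma = g),
                                           features = 4))
  for (j in 1:4) {
    expect_gt(abs(cor(ours[, j], oracle[, j])), 1 - 1e-8)
  }
})

test_that("kpca centering statistics make training scores zero-mean", {
  set.seed(25)
  x <- matrix(rnorm(25 * 4), 25, 4)
  km <- kpca_fit(x, gamma = 0.5, xi_threshold = 1)
  scores <- kpca_project(km, x, n_components = ncol(km$alphas))
  expect_lt(max(abs(colMeans(scores))), 1e-10)
  # projecting a training row reproduces its training score
  expect_equal(kpca_project(km, x[7, ]),
               drop(scores[7, seq_len(km$P)]), tolerance = 1e-12)
})

test_that("kpca projections are invariant to a constant shift of all samples", {
  set.seed(26)
  x <- matrix(rnorm(15 * 3), 15, 3)
  shift <- matrix(rep(c(5, -2, 8), each = 15), 15, 3)
  for (kern in c("gaussian", "linear")) {
    g <- if (kern == "gaussian") 0.4 else NULL
    k1 <- kpca_fit(x, gamma = g, xi_threshold = 1, kernel = kern)
    k2 <- kpca_fit(x + shift, gamma = g, xi_threshold = 1, kernel = kern)
    s1 <- kpca_project(k1, x[3, ])
    s2 <- kpca_project(k2, x[3, ] + shift[3, ])
    expect_equal(abs(s1), abs(s2), tolerance = 1e-8)
  }
})

test_that("contribution rates and component selection follow the eigenvalues", {
  expect_equal(contribution_rates(c(3, 1)), c(0.75, 0.25))
  expect_equal(contribution_rates(rep(2, 5)), rep(0.2, 5))
  expect_equal(cumulative_contribution(c(5, 3, 2), 3), 1)
  expect_error(contribution_rates(c(0, 0)), "zero")
  expect_error(contribution_rates(c(-1, 2)), "non-negative")

  set.seed(27)
  x <- matrix(rnorm(12 * 3), 12, 3)
  km <- kpca_fit(x, gamma = 0.5, xi_threshold = 1)
  # eigenvalues sorted non-increasing and clipped at zero
  expect_true(all(diff(km$eigenvalues) <= 1e-12))
  expect_true(all(km$eigenvalues >= 0))
  # xi = 1 keeps every non-zero component
  expect_equal(km$P, ncol(km$alphas))
  expect_equal(sum(km$contributions), 1)
  # P is the smallest count reaching the cutoff
  km2 <- kpca_fit(x, gamma = 0.5, xi_threshold = 0.6)
  expect_gte(cumulative_contribution(km2$eigenvalues, km2$P), 0.6)
  if (km2$P > 1) {
    expect_lt(cumulative_contribution(km2$eigenvalues, km2$P - 1), 0.6)
  }
})

test_that("degenerate all-identical input errors by name", {
  x <- matrix(1, 6, 3)
  expect_error(kpca_fit(x, gamma = 1), "degenerate")
})

test_that("kpca save/load/project round trip is bit-identical", {
  set.seed(28)
  x <- matrix(rnorm(20 * 4), 20, 4)
  km <- kpca_fit(x)
  path <- withr::local_tempfile(fileext = ".rds")
  kpca_save(km, path)
  km2 <- kpca_load(path)
  xnew <- matrix(rnorm(3 * 4), 3, 4)
  expect_identical(kpca_project(km, xnew), kpca_project(km2, xnew))
})
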