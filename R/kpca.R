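# Kernel PCA with a Gaussian kernel: double-centered kernel matrix,
# eigendecomposition, coefficient vectors normalized so the feature-space
# components have unit norm, and component selection by cumulative
# contribution rate.

#' Gaussian (RBF) kernel between two vectors
#'
#' @param x,y Equal-length numeric vectors.
#' @param gamma Inverse-width parameter, `> 0`.
#' @return `exp(-gamma * ||x - y||^2)`, in `(0, 1]`.
#' @export
gaussian_kernel <- function(x, y, gamma) {
  if (gamma <= 0) abort("gamma must be positive.")
  if (length(x) != length(y)) abort("x and y must have equal dimensions.")
  exp(-gamma * sum((x - y)^2))
}

# Pairwise squared Euclidean distances, rows of a vs rows of b.
sqdist <- function(a, b) {
  an <- rowSums(a^2)
  bn <- rowSums(b^2)
  d2 <- outer(an, bn, `+`) - 2 * tcrossprod(a, b)
  pmax(d2, 0)
}

kernel_matrix <- function(a, b, gamma, kernel) {
  if (kernel == "linear") tcrossprod(a, b) else exp(-gamma * sqdist(a, b))
}

#' Median-heuristic kernel bandwidth
#'
#' `gamma = 1 / median(pairwise squared distances)` over the positive
#' pairwise distances of the sample, the standard data-driven default when
#' no bandwidth is prescribed.
#'
#' @param x Sample matrix, rows are observations.
#' @return Positive scalar `gamma`.
#' @export
median_gamma <- function(x) {
  d2 <- sqdist(as.matrix(x), as.matrix(x))
  d2 <- d2[upper.tri(d2)]
  d2 <- d2[d2 > 0]
  if (length(d2) == 0) abort("all samples identical; bandwidth undefined.")
  1 / median(d2)
}

#' Contribution rate of each component
#'
#' Each eigenvalue's share of the total eigenvalue sum.
#'
#' @param eigenvalues Non-negative eigenvalues (not all zero).
#' @return Vector summing to 1.
#' @export
contribution_rates <- function(eigenvalues) {
  if (any(eigenvalues < -1e-12 * max(abs(eigenvalues)))) {
    abort("eigenvalues must be non-negative.")
  }
  eigenvalues <- pmax(eigenvalues, 0)
  s <- sum(eigenvalues)
  if (s == 0) abort("all eigenvalues are zero.")
  eigenvalues / s
}

#' Cumulative contribution of the leading components
#'
#' @inheritParams contribution_rates
#' @param p Number of leading components.
#' @return Cumulative contribution in `[0, 1]`, non-decreasing in `p`.
#' @export
cumulative_contribution <- function(eigenvalues, p) {
  stopifnot(p >= 1, p <= length(eigenvalues))
  sum(contribution_rates(eigenvalues)[seq_len(p)])
}

#' Fit kernel principal component analysis
#'
#' Builds the kernel matrix, double-centers it in feature space
#' (`K~ = K - 1K - K1 + 1K1`), eigendecomposes, scales each eigenvector by
#' `1/sqrt(lambda)` so the feature-space components have unit norm, and
#' retains the smallest component count whose cumulative contribution rate
#' reaches `xi_threshold`.
#'
#' @param x Training matrix, samples in rows (`n >= 2`).
#' @param gamma Gaussian-kernel inverse width; `NULL` uses the median
#'   heuristic ([median_gamma()]).
#' @param xi_threshold Cumulative contribution cutoff in `(0, 1]`.
#' @param kernel `"gaussian"` (default) or `"linear"` (the linear kernel
#'   reproduces ordinary PCA and is used for cross-checks).
#' @param center Double-center the kernel matrix in feature space (the
#'   default, and required for unbiased projections of raw windows).
#'   `center = FALSE` eigendecomposes the raw kernel matrix, i.e. takes the
#'   input as already centered in feature space.
#' @return A `kpca_model` with training data, centering statistics,
#'   eigenvalues (non-increasing, clipped at 0), coefficient matrix
#'   `alphas` (one column per non-zero component), contribution rates, and
#'   the retained count `P`.
#' @export
kpca_fit <- function(x, gamma = NULL, xi_threshold = 0.85,
                     kernel = c("gaussian", "linear"), center = TRUE) {
  kernel <- match.arg(kernel)
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 2) abort("need at least two samples.")
  if (xi_threshold <= 0 || xi_threshold > 1) {
    abort("xi_threshold must lie in (0, 1].")
  }
  if (kernel == "gaussian" && is.null(gamma)) gamma <- median_gamma(x)
  if (kernel == "gaussian" && gamma <= 0) abort("gamma must be positive.")

  K <- kernel_matrix(x, x, gamma, kernel)
  if (center) {
    row_means <- rowMeans(K)
    grand_mean <- mean(K)
    Kc <- K - outer(row_means, rep(1, n)) - outer(rep(1, n), row_means) +
      grand_mean
  } else {
    row_means <- numeric(n)
    grand_mean <- 0
    Kc <- K
  }

  eg <- eigen(Kc, symmetric = TRUE)
  lambda <- pmax(eg$values, 0)
  nz <- which(lambda > max(lambda) * 1e-12)
  if (length(nz) == 0 || max(lambda) <= 0) {
    abort("degenerate input: all samples identical (centered kernel matrix has rank 0).")
  }
  alphas <- eg$vectors[, nz, drop = FALSE]
  alphas <- sweep(alphas, 2, sqrt(lambda[nz]), `/`)
  for (i in seq_len(ncol(alphas))) {
    j <- which.max(abs(alphas[, i]))
    if (alphas[j, i] < 0) alphas[, i] <- -alphas[, i]
  }

  cont <- numeric(n)
  cont[nz] <- lambda[nz] / sum(lambda[nz])
  P <- which(cumsum(cont) >= xi_threshold - 1e-12)[1]

  structure(list(
    x_train = x, gamma = gamma, kernel = kernel,
    eigenvalues = lambda, alphas = alphas,
    contributions = cont, P = P, xi_threshold = xi_threshold,
    center = center, kernel_row_means = row_means, grand_mean = grand_mean,
    version = "1"
  ), class = "kpca_model")
}

#' Project samples onto kernel principal components
#'
#' Applies the training centering statistics to the test kernel vector and
#' returns the leading component scores.
#'
#' @param model A [kpca_fit()] result.
#' @param x Numeric vector (one sample) or matrix (samples in rows) with
#'   the training dimensionality.
#' @param n_components How many scores to return; defaults to the model's
#'   retained count `P`.
#' @return Score matrix (n x n_components), or a vector for one sample.
#' @export
kpca_project <- function(model, x, n_components = model$P) {
  single <- is.null(dim(x))
  x <- matrix(x, ncol = ncol(model$x_train), byrow = FALSE)
  n_components <- min(n_components, ncol(model$alphas))
  k <- kernel_matrix(x, model$x_train, model$gamma, model$kernel)
  kc <- if (isFALSE(model$center)) k else
    k - outer(rep(1, nrow(k)), model$kernel_row_means) -
      rowMeans(k) + model$grand_mean
  scores <- kc %*% model$alphas[, seq_len(n_components), drop = FALSE]
  if (single) drop(scores) else scores
}

#' @export
print.kpca_model <- function(x, ...) {
  cat(sprintf(
    "<kpca_model> %s kernel, n = %d, P = %d (cumulative contribution %.3f at xi = %.2f)\n",
    x$kernel, nrow(x$x_train), x$P,
    cumulative_contribution(x$eigenvalues, x$P), x$xi_threshold
  ))
  invisible(x)
}

#' @export
tidy.kpca_model <- function(x, ...) {
  tibble(
    component = seq_along(x$eigenvalues),
    eigenvalue = x$eigenvalues,
    contribution = x$contributions,
    cumulative = cumsum(x$contributions),
    retained = seq_along(x$eigenvalues) <= x$P
  )
}

#' @export
glance.kpca_model <- function(x, ...) {
  tibble(
    n = nrow(x$x_train), gamma = x$gamma, P = x$P,
    xi_threshold = x$xi_threshold,
    cumulative_at_P = cumulative_contribution(x$eigenvalues, x$P)
  )
}

#' Save / load a fitted KPCA model
#'
#' Single-file persistence; `kpca_save()` then [kpca_load()] followed by
#' [kpca_project()] reproduces projections bit-identically.
#'
#' @param model A `kpca_model`.
#' @param path File path.
#' @export
kpca_save <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname kpca_save
#' @export
kpca_load <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "kpca_model"))
  model
}
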