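# Linear PCA baseline: covariance eigendecomposition with explicit
# centering statistics, the linear counterpart of the kernel reducer.

#' Fit linear principal component analysis
#'
#' Centers each variable, eigendecomposes the covariance matrix, and keeps
#' the top `k` axes. Component signs are fixed so the largest-magnitude
#' loading of each axis is positive.
#'
#' @param x Numeric matrix, samples in rows.
#' @param k Number of components to retain (`1 <= k <= min(n, d)`).
#' @return A `pca_model`: `mean`, `axes` (k x d, orthonormal rows),
#'   `eigenvalues`, `k`.
#' @export
pca_fit <- function(x, k) {
  x <- as.matrix(x)
  if (k <= 0) abort("k must be a positive integer.")
  if (k > min(dim(x))) abort("k exceeds min(n, d).")
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu)
  cv <- crossprod(xc) / nrow(x)
  eg <- eigen(cv, symmetric = TRUE)
  axes <- t(eg$vectors[, seq_len(k), drop = FALSE])
  for (i in seq_len(k)) {
    j <- which.max(abs(axes[i, ]))
    if (axes[i, j] < 0) axes[i, ] <- -axes[i, ]
  }
  structure(list(mean = mu, axes = axes,
                 eigenvalues = pmax(eg$values, 0), k = k),
            class = "pca_model")
}

#' Project samples onto fitted principal axes
#'
#' @param model A [pca_fit()] result.
#' @param x Numeric vector (one sample) or matrix (samples in rows).
#' @return Score matrix (n x k), or a k-vector for a single sample.
#' @export
pca_project <- function(model, x) {
  single <- is.null(dim(x))
  x <- matrix(x, ncol = length(model$mean), byrow = FALSE)
  scores <- sweep(x, 2, model$mean) %*% t(model$axes)
  if (single) drop(scores) else scores
}

#' @export
tidy.pca_model <- function(x, ...) {
  ev <- x$eigenvalues
  tibble(
    component = seq_along(ev),
    eigenvalue = ev,
    contribution = contribution_rates(ev),
    cumulative = cumsum(contribution_rates(ev)),
    retained = seq_along(ev) <= x$k
  )
}
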