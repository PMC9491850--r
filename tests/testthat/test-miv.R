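# Mean Impact Value computation, selection, and contribution tables.

test_that("closed-form MIV of a linear model", {
  lin <- function(x) 3 * x[, 1] + x[, 2]
  x <- matrix(1, 10, 2)
  rep <- compute_miv(lin, x, perturbation = 0.1)
  # 2 * p * coef * mean(x): c(0.6, 0.2)
  expect_equal(unname(rep$miv), c(0.6, 0.2), tolerance = 1e-10)
  expect_equal(unname(rep$abs_normalized), c(0.75, 0.25), tolerance = 1e-10)
  expect_equal(rep$ranking, c(1L, 2L))
})

test_that("zero coefficients, zero perturbation, degenerate predictors", {
  lin <- function(x) 2 * x[, 1] + 0 * x[, 2]
  set.seed(51)
  x <- matrix(rnorm(20), 10, 2)
  rep <- compute_miv(lin, x, perturbation = 0.1)
  expect_equal(unname(rep$miv[2]), 0)

  expect_warning(rep0 <- compute_miv(lin, x, perturbation = 0),
                 "insensitive")
  expect_true(all(rep0$iv_per_sample == 0))
  expect_true(all(rep0$miv == 0))

  expect_warning(repc <- compute_miv(function(x) rep(7, nrow(x)), x),
                 "insensitive")
  expect_true(repc$degenerate)
  expect_length(select_variables(repc), 0)
  expect_error(compute_miv(lin, x, perturbation = -0.1), "perturbation")
})

test_that("MIV is linear in the perturbation for a linear model", {
  set.seed(52)
  x <- matrix(rnorm(60), 20, 3)
  lin <- function(x) x %*% c(2, -1, 0.5)
  m1 <- compute_miv(lin, x, perturbation = 0.05)$miv
  m2 <- compute_miv(lin, x, perturbation = 0.10)$miv
  expect_equal(2 * m1, m2, tolerance = 1e-10)
})

test_that("variable selection takes the smallest prefix reaching the cutoff", {
  fake <- function(abs_norm, cutoff) {
    iv <- matrix(rep(abs_norm, each = 4), 4)
    rep <- compute_miv(function(x) as.vector(x %*% abs_norm / 0.2),
                       matrix(1, 4, length(abs_norm)), cutoff = cutoff)
    rep
  }
  rep <- fake(c(0.6, 0.25, 0.1, 0.05), cutoff = 0.9)
  expect_equal(rep$abs_normalized, c(0.6, 0.25, 0.1, 0.05),
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(select_variables(rep), c(1L, 2L, 3L))
  # single dominant variable
  rep1 <- compute_miv(function(x) 5 * x[, 1], matrix(1, 5, 1))
  expect_equal(select_variables(rep1), 1L)
  # cutoff 1 selects every variable with non-zero impact
  lin <- function(x) x %*% c(1, 0, 3)
  rep2 <- compute_miv(lin, matrix(1, 5, 3), cutoff = 1)
  expect_setequal(select_variables(rep2), c(1L, 3L))
  # selected is always a prefix of the ranking
  expect_equal(rep$selected, rep$ranking[seq_along(rep$selected)])
})

test_that("contribution table rows sum to one and track channel order", {
  mk_report <- function(miv, labels) {
    iv <- matrix(rep(miv, each = 6), 6, dimnames = list(NULL, labels))
    semgforce:::new_miv_report(iv, 0.1, 0.9, labels)
  }
  r1 <- mk_report(c(0.5, 0.3, 0.2), c("a", "b", "c"))
  r2 <- mk_report(c(0.2, 0.5, 0.3), c("a", "b", "c"))
  tab <- muscle_contribution_table(list(t1 = r1, t2 = r2))
  expect_equal(rowSums(tab[, -1]), c(1, 1), ignore_attr = TRUE)
  expect_equal(names(tab), c("task", "a", "b", "c"))
  expect_equal(names(tab[, -1])[apply(tab[, -1], 1, which.max)], c("a", "b"))
  # permuting the variables permutes the columns identically
  r1p <- mk_report(c(0.2, 0.5, 0.3), c("c", "a", "b"))
  tabp <- muscle_contribution_table(list(t1 = r1p))
  expect_equal(tabp$a, 0.5)
  expect_equal(tabp$c, 0.2)
})

test_that("tidied report orders variables by rank", {
  lin <- function(x) x %*% c(1, 4, 2)
  rep <- compute_miv(lin, matrix(1, 6, 3), labels = c("x", "y", "z"))
  td <- tidy(rep)
  expect_equal(td$variable, c("y", "z", "x"))
  expect_equal(td$rank, 1:3)
  expect_true(all(td$selected[1:2]))
})
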