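test_that("standardize centers and scales with the 1/N convention", {
  z <- standardize(cbind(a = c(1, 2, 3), b = c(10, 0, 5)))
  expect_equal(colMeans(z), c(a = 0, b = 0))
  expect_equal(colMeans(z^2), c(a = 1, b = 1))
  expect_equal(standardize(z), z, tolerance = 1e-12)
  expect_error(standardize(cbind(a = c(1, 2), b = c(3, 3))),
               "zero variance: b")
})

test_that("matrix roots satisfy their defining identities", {
  expect_equal(matrix_inv_sqrt(diag(2)), diag(2))
  expect_equal(matrix_inv_sqrt(diag(c(4, 9))), diag(c(1 / 2, 1 / 3)))
  set.seed(11)
  M <- random_corr(5)
  R <- matrix_inv_sqrt(M)
  expect_equal(R %*% M %*% R, diag(5), tolerance = 1e-10)
  Q <- matrix_sqrt(M)
  expect_equal(Q %*% Q, M, tolerance = 1e-10)
  expect_true(isSymmetric(R))
  expect_error(matrix_inv_sqrt(matrix(c(1, 2, 2, 1), 2)),
               "not positive-definite")
})

test_that("maxvar recovers the generating weights from the exact population matrix", {
  for (m in c(1L, 4L)) {
    p <- population_sigma(m)
    sol <- maxvar_weights(p$sigma, p$spec)
    for (nm in names(p$population$weights))
      expect_equal(sol$weights[[nm]],
                   p$population$weights[[nm]],
                   tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("singleton blocks get weight one and composite correlation equals the indicator correlation", {
  spec <- composite_spec(list(c1 = "a", c2 = "b"))
  S <- matrix(c(1, 0.42, 0.42, 1), 2, dimnames = list(c("a", "b"), c("a", "b")))
  sol <- maxvar_weights(S, spec)
  expect_equal(sol$weights$c1, 1, ignore_attr = TRUE)
  expect_equal(sol$weights$c2, 1, ignore_attr = TRUE)
  cc <- composite_correlations(S, sol$weights, spec)
  expect_equal(cc["c1", "c2"], 0.42)
})

test_that("with two blocks the composite correlation is the first canonical correlation", {
  set.seed(7)
  for (rep in 1:5) {
    inst <- random_instance(2, kj = c(3, 2))
    sol <- maxvar_weights(inst$S, inst$spec)
    cc <- composite_correlations(inst$S, sol$weights, inst$spec)
    idx <- lapply(inst$spec$blocks, function(b) match(b, inst$spec$indicators))
    expect_equal(abs(cc["c1", "c2"]),
                 oracle_canonical_corr(inst$S, idx[[1]], idx[[2]]),
                 tolerance = 1e-8)
    # attained objective for two blocks is 1 + canonical correlation
    expect_equal(sol$eigenvalue,
                 1 + oracle_canonical_corr(inst$S, idx[[1]], idx[[2]]),
                 tolerance = 1e-8)
  }
})

test_that("maxvar objective matches a constrained numeric optimizer", {
  set.seed(123)
  for (rep in 1:8) {
    inst <- random_instance(sample(2:3, 1))
    sol <- maxvar_weights(inst$S, inst$spec)
    expect_equal(sol$eigenvalue,
                 oracle_maxvar_objective(inst$S, inst$spec),
                 tolerance = 1e-6)
  }
})

test_that("estimated weights satisfy the unit-variance constraint on any input", {
  set.seed(99)
  for (rep in 1:10) {
    inst <- random_instance(sample(2:3, 1))
    sol <- maxvar_weights(inst$S, inst$spec)
    for (nm in names(inst$spec$blocks)) {
      i <- match(inst$spec$blocks[[nm]], inst$spec$indicators)
      expect_equal(composite_variance(sol$weights[[nm]],
                                      inst$S[i, i, drop = FALSE]),
                   1, tolerance = 1e-10)
    }
  }
})

test_that("composite scores behave as linear combinations with unit variance", {
  spec <- composite_spec(list(c1 = "a", c2 = c("b", "c")))
  set.seed(5)
  x <- matrix(rnorm(300), 100, 3, dimnames = list(NULL, c("a", "b", "c")))
  z <- standardize(x)
  S <- crossprod(z) / nrow(z)
  sol <- maxvar_weights(S, spec)
  sc <- composite_scores(z, sol$weights, spec)
  expect_equal(sc[, "c1"], z[, "a"] * sign(sol$weights$c1[1]))
  # score variance equals the quadratic form exactly (algebraic identity)
  expect_equal(mean(sc[, "c2"]^2),
               composite_variance(sol$weights$c2, S[2:3, 2:3]),
               tolerance = 1e-12)
  expect_equal(unname(colMeans(sc^2)), c(1, 1), tolerance = 1e-10)
})

test_that("population weights give unit score variance in large samples", {
  x <- draw_sample(population_sigma(1)$sigma, 10000, seed = 31)
  w <- list(c1 = c(0.6, 0.2, 0.4), c2 = c(0.4, 0.2, 0.6))
  sc <- composite_scores(x, w, model1_spec())
  expect_equal(unname(apply(sc, 2, function(s) mean(s^2))), c(1, 1),
               tolerance = 0.05)
})

test_that("fitting the exact population matrix reproduces it (perfect-fit fixed point)", {
  for (m in c(1L, 4L)) {
    p <- population_sigma(m)
    fit <- cca(p$sigma, p$spec)
    expect_equal(fit$sigma_hat, p$sigma, tolerance = 1e-10,
                 ignore_attr = TRUE)
    expect_equal(max(abs(fit$residuals)), 0, tolerance = 1e-10)
  }
  fit1 <- cca(population_sigma(1)$sigma, model1_spec())
  expect_equal(fit1$loadings$c1, c(0.9, 0.7, 0.8), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(fit1$composite_corr["c1", "c2"], 0.3, tolerance = 1e-8)
})

test_that("estimates are equivariant under indicator permutation within blocks", {
  set.seed(17)
  x <- draw_sample(population_sigma(1)$sigma, 150, seed = 8)
  spec <- model1_spec()
  perm_spec <- composite_spec(list(c1 = c("x13", "x11", "x12"),
                                   c2 = c("x22", "x23", "x21")))
  f1 <- cca(x, spec)
  f2 <- cca(x[, perm_spec$indicators], perm_spec)
  expect_equal(f2$weights$c1[c("x11", "x12", "x13")],
               f1$weights$c1, tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(f2$composite_corr, f1$composite_corr, tolerance = 1e-10)
  ord <- spec$indicators
  expect_equal(f2$sigma_hat[ord, ord], f1$sigma_hat, tolerance = 1e-10)
})

test_that("sampled composite correlations concentrate around the population value", {
  x <- draw_sample(population_sigma(1)$sigma, 500, seed = 12)
  fit <- cca(x, model1_spec())
  se <- (1 - 0.3^2) / sqrt(500)
  expect_lt(abs(fit$composite_corr["c1", "c2"] - 0.3), 3 * se)
})

test_that("cca validates its inputs", {
  spec <- model1_spec()
  x <- draw_sample(population_sigma(1)$sigma, 100, seed = 1)
  expect_error(cca(x[, 1:5], spec), "lacks column")
  xna <- x; xna[3, 2] <- NA
  expect_error(cca(xna, spec), "missing values")
  expect_error(cca(x[1:5, ], spec), "more observations")
  solo <- composite_spec(list(c = c("x11", "x12", "x13")))
  expect_error(cca(x[, 1:3], solo), "under-identified")
})

test_that("coef, fitted, residuals and predict expose the fit", {
  x <- draw_sample(population_sigma(1)$sigma, 200, seed = 21)
  fit <- cca(x, model1_spec())
  w <- coef(fit)
  expect_named(w, c("x11", "x12", "x13", "x21", "x22", "x23"))
  lam <- coef(fit, "loadings")
  expect_equal(unname(lam[1:3]),
               unname(drop(fit$sample_corr[1:3, 1:3] %*% fit$weights$c1)),
               tolerance = 1e-12)
  expect_equal(fitted(fit) + residuals(fit), fit$sample_corr,
               ignore_attr = TRUE)
  expect_equal(predict(fit), fit$scores)
  sc2 <- predict(fit, newdata = x[1:50, ])
  expect_equal(dim(sc2), c(50L, 2L))
})
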