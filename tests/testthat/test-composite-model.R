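test_that("composite loadings are the intra-block matrix times the weights", {
  Sjj <- equicorr(3, 0.5)
  expect_equal(composite_loadings(c(0.6, 0.2, 0.4), Sjj), c(0.9, 0.7, 0.8))
  expect_equal(composite_loadings(c(0.4, 0.2, 0.6), Sjj), c(0.8, 0.7, 0.9))
  expect_equal(composite_loadings(1, matrix(1, 1, 1)), 1)
  expect_error(composite_loadings(c(1, 1), Sjj), "does not match")
})

test_that("composite variance is the quadratic form of weights and intra-block matrix", {
  expect_equal(composite_variance(c(0.6, 0.2, 0.4), equicorr(3, 0.5)), 1)
  expect_equal(composite_variance(1, matrix(1, 1, 1)), 1)
  expect_equal(composite_variance(c(0.5, 0.5), diag(2)), 0.5)
})

test_that("rescale_weights normalizes to unit composite variance, preserving direction", {
  Sjj <- equicorr(3, 0.5)
  expect_equal(rescale_weights(c(1.2, 0.4, 0.8), Sjj), c(0.6, 0.2, 0.4))
  w <- c(0.6, 0.2, 0.4)
  expect_identical(rescale_weights(w, Sjj), w / sqrt(composite_variance(w, Sjj)))
  expect_equal(rescale_weights(w, Sjj), w, tolerance = 1e-12)
  expect_error(rescale_weights(c(0, 0, 0), Sjj), "degenerate")
})

test_that("model-implied matrix has unconstrained diagonal blocks and rank-one off blocks", {
  pop <- population_sigma(1)$population
  sig <- pop$sigma
  expect_equal(sig["x11", "x21"], 0.3 * 0.9 * 0.8)
  expect_equal(sig[1:3, 1:3], unname(equicorr(3, 0.5)),
               ignore_attr = TRUE)
  expect_true(isSymmetric(unname(sig)))
  expect_equal(unname(diag(sig)), rep(1, 6))
})

test_that("a single-block model reproduces its intra-block matrix exactly", {
  spec <- composite_spec(list(c1 = c("a", "b", "c")))
  Sjj <- equicorr(3, 0.4)
  w <- rescale_weights(c(1, 1, 1), Sjj)
  pop <- composite_population(spec, weights = list(c1 = w),
                              composite_corr = matrix(1, 1, 1),
                              intra_block_corr = list(c1 = Sjj))
  expect_equal(unname(pop$sigma), Sjj, ignore_attr = TRUE)
})

test_that("every 2x2 minor of every inter-block submatrix vanishes", {
  set.seed(42)
  for (rep in 1:10) {
    J <- sample(2:3, 1)
    kj <- sample(2:3, J, replace = TRUE)
    inst <- random_instance(J, kj)
    intra <- lapply(names(inst$spec$blocks), function(nm) {
      i <- match(inst$spec$blocks[[nm]], inst$spec$indicators)
      inst$S[i, i, drop = FALSE]
    })
    names(intra) <- names(inst$spec$blocks)
    w <- lapply(names(intra), function(nm)
      rescale_weights(runif(nrow(intra[[nm]]), 0.2, 1), intra[[nm]]))
    names(w) <- names(intra)
    cc <- equicorr(J, 0.3)
    pop <- composite_population(inst$spec, w, cc, intra)
    bidx <- lapply(inst$spec$blocks, function(b)
      match(b, inst$spec$indicators))
    for (j in seq_len(J - 1)) for (l in seq(j + 1, J)) {
      blk <- pop$sigma[bidx[[j]], bidx[[l]], drop = FALSE]
      for (r1 in seq_len(nrow(blk) - 1)) for (r2 in seq(r1 + 1, nrow(blk)))
        for (c1 in seq_len(ncol(blk) - 1)) for (c2 in seq(c1 + 1, ncol(blk)))
          expect_equal(blk[r1, c1] * blk[r2, c2] -
                         blk[r1, c2] * blk[r2, c1], 0, tolerance = 1e-12)
    }
  }
})

test_that("free variables spread their composite correlations through the loadings", {
  spec <- composite_spec(list(c = c("x1", "x2")), free = c("y", "z"))
  Sjj <- matrix(c(1, 0.3, 0.3, 1), 2)
  w <- rescale_weights(c(0.5, 0.5), Sjj)
  lam <- composite_loadings(w, Sjj)
  fv <- rbind(y = c(0.4, 1, 0.2),   # corr with composite, y, z
              z = c(0.6, 0.2, 1))
  pop <- composite_population(spec, weights = list(c = w),
                              composite_corr = matrix(1, 1, 1),
                              intra_block_corr = list(c = Sjj),
                              free_var_corr = fv)
  expect_equal(pop$sigma["x1", "y"], 0.4 * lam[1])
  expect_equal(pop$sigma["x2", "z"], 0.6 * lam[2])
  expect_equal(pop$sigma["y", "z"], 0.2)
})

test_that("non-positive-definite inputs are rejected naming the failing condition", {
  spec <- model1_spec()
  Sjj <- equicorr(3, 0.5)
  w <- list(c1 = c(0.6, 0.2, 0.4), c2 = c(0.4, 0.2, 0.6))
  bad_cc <- matrix(c(1, 1.2, 1.2, 1), 2)
  expect_error(
    composite_population(spec, w, bad_cc, list(c1 = Sjj, c2 = Sjj)),
    "composite-level correlation matrix is not positive-definite")
  bad_intra <- equicorr(3, -0.9)
  wb <- rescale_weights(c(1, 1, 4), bad_intra)
  expect_error(
    composite_population(spec, list(c1 = wb, c2 = c(0.4, 0.2, 0.6)),
                         matrix(c(1, 0.3, 0.3, 1), 2),
                         list(c1 = bad_intra, c2 = Sjj)),
    "intra-block matrix of 'c1'")
})

test_that("population construction enforces unit composite variance", {
  spec <- model1_spec()
  Sjj <- equicorr(3, 0.5)
  expect_error(
    composite_population(spec,
                         list(c1 = c(1, 1, 1), c2 = c(0.4, 0.2, 0.6)),
                         matrix(c(1, 0.3, 0.3, 1), 2),
                         list(c1 = Sjj, c2 = Sjj)),
    "composite variance")
})

test_that("all bundled population models have unit composite variances", {
  for (m in c(1L, 4L)) {
    pop <- population_sigma(m)$population
    for (nm in names(pop$weights))
      expect_equal(composite_variance(pop$weights[[nm]],
                                      pop$intra_block_corr[[nm]]),
                   1, tolerance = 1e-12)
  }
})

test_that("specification validation catches duplicates and empty blocks", {
  expect_error(composite_spec(list(c1 = c("a", "b"), c2 = c("b", "c"))),
               "more than once")
  expect_error(composite_spec(list(c1 = c("a"), c2 = character())),
               "at least one indicator")
  expect_error(composite_spec(list(c1 = "a"), free = "a"), "more than once")
  spec <- composite_spec(list(c("a", "b")))
  expect_identical(names(spec$blocks), "c1")
})
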