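test_that("all three measures vanish exactly at a perfect fit and only there", {
  S <- population_sigma(1)$sigma
  expect_equal(distance_euclidean(S, S), 0)
  expect_equal(distance_geodesic(S, S), 0, tolerance = 1e-12)
  expect_equal(srmr(S, S), 0)
  off <- S
  off["x11", "x21"] <- off["x21", "x11"] <- S["x11", "x21"] + 0.05
  expect_gt(distance_euclidean(S, off), 0)
  expect_gt(distance_geodesic(S, off), 0)
  expect_gt(srmr(S, off), 0)
})

test_that("squared Euclidean distance matches hand computations and is degree-2 homogeneous", {
  S <- matrix(c(1, 0.5, 0.5, 1), 2)
  Sh <- matrix(c(1, 0.3, 0.3, 1), 2)
  expect_equal(distance_euclidean(S, Sh), 0.04)
  delta <- S - Sh
  expect_equal(distance_euclidean(S, S - 2 * delta),
               4 * distance_euclidean(S, Sh))
  expect_error(distance_euclidean(S, diag(3)), "equal dimension")
})

test_that("geodesic distance matches closed forms", {
  set.seed(2)
  S <- random_corr(4)
  expect_equal(distance_geodesic(S, exp(1) * S), sqrt(2), tolerance = 1e-10)
  expect_equal(distance_geodesic(diag(c(2, 1)), diag(2)),
               abs(log(0.5)) / sqrt(2), tolerance = 1e-12)
})

test_that("geodesic distance is symmetric in its arguments", {
  set.seed(3)
  for (rep in 1:5) {
    A <- random_corr(4)
    B <- random_corr(4)
    expect_equal(distance_geodesic(A, B), distance_geodesic(B, A),
                 tolerance = 1e-9)
  }
})

test_that("SRMR averages squared standardized residuals over the lower triangle", {
  S <- matrix(c(1, 0.5, 0.5, 1), 2)
  Sh <- matrix(c(1, 0.3, 0.3, 1), 2)
  expect_equal(srmr(S, Sh), sqrt(2 * 0.04 / 6))
  # identity on correlation-scale matrices:
  # srmr^2 * K(K+1)/2 = sum of squared lower-triangle residuals
  set.seed(4)
  A <- random_corr(5)
  B <- random_corr(5)
  K <- 5
  expect_equal(srmr(A, B)^2 * K * (K + 1) / 2,
               sum(((A - B)[lower.tri(A, diag = TRUE)])^2),
               tolerance = 1e-12)
  bad <- A; bad[1, 1] <- -1
  expect_error(srmr(bad, B), "non-positive diagonal")
})

test_that("on unit-diagonal matrices dL and SRMR are monotone transforms of each other", {
  set.seed(6)
  vals <- t(replicate(20, {
    A <- random_corr(4)
    B <- random_corr(4)
    c(distance_euclidean(A, B), srmr(A, B))
  }))
  expect_equal(order(vals[, 1]), order(vals[, 2]))
  # exact algebraic relation: dL = srmr^2 * K(K+1)/2 when diagonals match
  expect_equal(vals[, 1], vals[, 2]^2 * 4 * 5 / 2, tolerance = 1e-10)
})

test_that("NFI compares the model discrepancy to the uncorrelated baseline", {
  S <- population_sigma(1)$sigma
  expect_equal(nfi(S, S), 1)
  expect_equal(nfi(S, diag(6)), 0)
  # crafted half-discrepancy case under the Euclidean option
  S2 <- matrix(c(1, 0.4, 0.4, 1), 2)
  sh_off <- 0.4 - sqrt(0.08)
  Sh <- matrix(c(1, sh_off, sh_off, 1), 2)
  expect_equal(nfi(S2, Sh, discrepancy = "euclidean"), 0.5)
  expect_error(nfi(diag(3), diag(3)), "undefined")
})

test_that("RMS_theta averages only cross-block residuals", {
  spec <- composite_spec(list(c1 = c("x1", "x2"), c2 = "x3"))
  S <- diag(3)
  dimnames(S) <- list(c("x1", "x2", "x3"), c("x1", "x2", "x3"))
  Sh <- S
  S["x1", "x3"] <- S["x3", "x1"] <- 0.3    # one cross-block residual
  S["x1", "x2"] <- S["x2", "x1"] <- 0.9    # within-block: ignored
  expect_equal(rms_theta(S, Sh, spec), 0.3 / sqrt(2))
  expect_equal(rms_theta(Sh, Sh, spec), 0)
  solo <- composite_spec(list(c = c("x1", "x2", "x3")))
  expect_error(rms_theta(S, Sh, solo), "no cross-block")
})

test_that("a misspecified population leaves a strictly positive RMS_theta", {
  p5 <- population_sigma(5)
  fit <- cca(p5$sigma, p5$spec)
  expect_gt(rms_theta(p5$sigma, fit$sigma_hat, p5$spec), 0.001)
  p4 <- population_sigma(4)
  fit4 <- cca(p4$sigma, p4$spec)
  expect_equal(rms_theta(p4$sigma, fit4$sigma_hat, p4$spec), 0,
               tolerance = 1e-10)
})

test_that("the Bollen-Stine transform imposes the fitted matrix exactly", {
  x <- draw_sample(population_sigma(1)$sigma, 250, seed = 14)
  fit <- cca(x, model1_spec())
  xs <- bollen_stine_transform(fit$data, fit$sample_corr, fit$sigma_hat)
  expect_equal(crossprod(xs) / nrow(xs), fit$sigma_hat,
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(unname(colMeans(xs)), rep(0, 6), tolerance = 1e-12)
  # identity transform at perfect fit
  xid <- bollen_stine_transform(fit$data, fit$sample_corr, fit$sample_corr)
  expect_equal(xid, fit$data, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("summary.cca reports discrepancies and fit indices", {
  x <- draw_sample(population_sigma(1)$sigma, 200, seed = 22)
  fit <- cca(x, model1_spec())
  s <- summary(fit)
  expect_s3_class(s, "summary.cca")
  expect_equal(s$measures$d_L,
               distance_euclidean(fit$sample_corr, fit$sigma_hat))
  expect_true(s$indices$nfi <= 1)
  expect_output(print(s), "NFI")
})
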