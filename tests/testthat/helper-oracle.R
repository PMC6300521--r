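# Independent oracles and random instance generators for the test suite.

# Random positive-definite correlation matrix of dimension k.
random_corr <- function(k, n = 5 * k + 20) {
  x <- matrix(rnorm(n * k), n, k)
  stats::cov2cor(crossprod(x) / n)
}

# Random composite-model instance: J blocks of sizes kj, a random PD
# indicator correlation matrix partitioned accordingly.
random_instance <- function(J = 2, kj = NULL) {
  if (is.null(kj)) kj <- sample(1:3, J, replace = TRUE)
  names_by_block <- lapply(seq_len(J), function(j)
    paste0("b", j, "v", seq_len(kj[j])))
  spec <- composite_spec(stats::setNames(names_by_block,
                                         paste0("c", seq_len(J))))
  S <- random_corr(sum(kj))
  dimnames(S) <- list(spec$indicators, spec$indicators)
  list(spec = spec, S = S, kj = kj)
}

# Brute-force maxvar oracle: maximize the largest eigenvalue of the
# composite correlation matrix over block weights under the
# unit-composite-variance constraints, by multi-start Nelder-Mead on the
# unconstrained parametrization (weights renormalized inside the
# objective). Independent of the closed-form eigen solution.
oracle_maxvar_objective <- function(S, spec, starts = 8) {
  bidx <- lapply(spec$blocks, function(b) match(b, spec$indicators))
  kj <- lengths(bidx)
  objective <- function(par) {
    w <- split(par, rep(seq_along(kj), kj))
    cc <- diag(length(kj))
    for (j in seq_along(w)) {
      Sjj <- S[bidx[[j]], bidx[[j]], drop = FALSE]
      v <- drop(crossprod(w[[j]], Sjj %*% w[[j]]))
      if (v < 1e-12) return(1e6)
      w[[j]] <- w[[j]] / sqrt(v)
    }
    for (j in seq_along(w)) for (l in seq_along(w)) if (j < l) {
      r <- drop(crossprod(w[[j]],
                          S[bidx[[j]], bidx[[l]], drop = FALSE] %*% w[[l]]))
      cc[j, l] <- cc[l, j] <- r
    }
    -max(eigen(cc, symmetric = TRUE, only.values = TRUE)$values)
  }
  best <- -Inf
  for (s in seq_len(starts)) {
    par0 <- rnorm(sum(kj))
    opt <- stats::optim(par0, objective, method = "Nelder-Mead",
                        control = list(maxit = 5000, reltol = 1e-14))
    # polish
    opt <- stats::optim(opt$par, objective, method = "Nelder-Mead",
                        control = list(maxit = 5000, reltol = 1e-14))
    best <- max(best, -opt$value)
  }
  best
}

# First canonical correlation between two blocks, from the population
# matrix (closed form, independent of the maxvar code path).
oracle_canonical_corr <- function(S, idx1, idx2) {
  S11 <- S[idx1, idx1, drop = FALSE]
  S22 <- S[idx2, idx2, drop = FALSE]
  S12 <- S[idx1, idx2, drop = FALSE]
  m <- solve(S11, S12) %*% solve(S22, t(S12))
  sqrt(max(Re(eigen(m)$values)))
}

model1_spec <- function() {
  composite_spec(list(c1 = c("x11", "x12", "x13"),
                      c2 = c("x21", "x22", "x23")))
}

equicorr <- function(k, r) {
  m <- matrix(r, k, k)
  diag(m) <- 1
  m
}
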