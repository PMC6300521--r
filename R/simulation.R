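#' Benchmark population models for the fit test
#'
#' A catalogue of five population indicator correlation matrices used to
#' study the type-I error and power of the bootstrap fit test. Models 1
#' and 4 satisfy the rank-one constraints of the composite model they are
#' fitted with (correct specification); models 2, 3 and 5 violate them.
#'
#' \describe{
#'   \item{model 1}{two composites of three indicators each, all
#'     intra-block correlations 0.5, weights (0.6, 0.2, 0.4) and
#'     (0.4, 0.2, 0.6), composite correlation 0.3.}
#'   \item{model 2}{confounded indicators: the model-1 matrix with the rows
#'     and columns of x13 and x21 interchanged, emulating two indicators
#'     assigned to the wrong composite.}
#'   \item{model 3}{unexplained correlation: the model-1 matrix with the
#'     (x13, x21) entry replaced by \code{unexplained_cor}, which must
#'     exceed the model-implied value 0.192. No default is supplied; the
#'     bundled Monte Carlo study passes 0.4.}
#'   \item{model 4}{three composites of three indicators, weights
#'     (0.6, 0.4, 0.2), (0.3, 0.5, 0.6), (0.4, 0.5, 0.5) and composite
#'     correlations rho12 = 0.3, rho13 = 0.5, rho23 = 0.4. The intra-block
#'     matrices are reconstructed (see Details).}
#'   \item{model 5}{the model-4 matrix with the (x13, x21) entry set to
#'     0.25 (model-implied value 0.084), a weak violation.}
#' }
#'
#' @details The intra-block correlation matrices of models 4-5 are a
#' synthetic reconstruction, not canonical: block 1 is equicorrelated at
#' 0.5, block 2 has correlations (x21,x22) = (x21,x23) = 1/11 and
#' (x22,x23) = 0.4, and block 3 is equicorrelated at 0.34/1.3. They are
#' pinned down by requiring unit composite variance in every block and a
#' model-implied (x13, x21) correlation of exactly 0.084; pass
#' \code{intra_block_corr} to use different matrices (unit composite
#' variance is enforced).
#'
#' @param model integer 1 to 5.
#' @param unexplained_cor replacement correlation for the (x13, x21) entry
#'   (required for model 3; fixed at 0.25 for model 5).
#' @param intra_block_corr optional named list of intra-block correlation
#'   matrices overriding the defaults (models 4-5).
#' @return an object of class \code{"cca_population"}: list with
#'   \code{sigma} (the population correlation matrix), \code{spec} (the
#'   composite model used for estimation), \code{model} and
#'   \code{misspecification} (\code{"none"}, \code{"confounded_indicators"}
#'   or \code{"unexplained_correlation"}); for models 1 and 4 also
#'   \code{population}, the underlying [composite_population()].
#' @examples
#' pop <- population_sigma(1)
#' pop$sigma["x11", "x21"]  # 0.216
#' population_sigma(5)$sigma["x13", "x21"]  # 0.25
#' @export
population_sigma <- function(model, unexplained_cor = NULL,
                             intra_block_corr = NULL) {
  if (!model %in% 1:5) stop("'model' must be 1, 2, 3, 4 or 5")
  if (model <= 3) {
    spec <- composite_spec(list(c1 = c("x11", "x12", "x13"),
                                c2 = c("x21", "x22", "x23")))
    Sjj <- matrix(0.5, 3, 3); diag(Sjj) <- 1
    pop <- composite_population(
      spec,
      weights = list(c1 = c(0.6, 0.2, 0.4), c2 = c(0.4, 0.2, 0.6)),
      composite_corr = matrix(c(1, 0.3, 0.3, 1), 2),
      intra_block_corr = list(c1 = Sjj, c2 = Sjj))
  } else {
    spec <- composite_spec(list(c1 = c("x11", "x12", "x13"),
                                c2 = c("x21", "x22", "x23"),
                                c3 = c("x31", "x32", "x33")))
    if (is.null(intra_block_corr)) {
      S1 <- matrix(0.5, 3, 3); diag(S1) <- 1
      s <- 1 / 11
      S2 <- matrix(c(1, s, s, s, 1, 0.4, s, 0.4, 1), 3, 3)
      t3 <- 0.34 / 1.3
      S3 <- matrix(t3, 3, 3); diag(S3) <- 1
      intra_block_corr <- list(c1 = S1, c2 = S2, c3 = S3)
    }
    pop <- composite_population(
      spec,
      weights = list(c1 = c(0.6, 0.4, 0.2), c2 = c(0.3, 0.5, 0.6),
                     c3 = c(0.4, 0.5, 0.5)),
      composite_corr = matrix(c(1, 0.3, 0.5,
                                0.3, 1, 0.4,
                                0.5, 0.4, 1), 3),
      intra_block_corr = intra_block_corr)
  }
  sigma <- pop$sigma
  misspec <- "none"
  perturb <- NULL
  if (model == 2) {
    ord <- c("x11", "x12", "x21", "x13", "x22", "x23")
    swapped <- sigma[ord, ord]
    # relabel in the original order: the estimated spec still assigns
    # x13 to block 1 and x21 to block 2, but the data-generating roles
    # of the two indicators are interchanged
    dimnames(swapped) <- dimnames(sigma)
    sigma <- swapped
    misspec <- "confounded_indicators"
  } else if (model == 3) {
    if (is.null(unexplained_cor))
      stop("model 3 needs an explicit 'unexplained_cor' ",
           "(must exceed the model-implied value 0.192)")
    implied <- sigma["x13", "x21"]
    if (unexplained_cor <= implied)
      stop("'unexplained_cor' (", unexplained_cor,
           ") must exceed the model-implied value ",
           format(implied), " to induce misfit")
    sigma["x13", "x21"] <- sigma["x21", "x13"] <- unexplained_cor
    misspec <- "unexplained_correlation"
    perturb <- c(x13_x21 = unexplained_cor)
  } else if (model == 5) {
    sigma["x13", "x21"] <- sigma["x21", "x13"] <- 0.25
    misspec <- "unexplained_correlation"
    perturb <- c(x13_x21 = 0.25)
  }
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= pd_tol * max(ev))
    stop("perturbed population matrix is not positive-definite ",
         "(smallest eigenvalue ", format(min(ev), digits = 4), ")")
  structure(list(sigma = sigma, spec = spec, model = as.integer(model),
                 misspecification = misspec, perturbation = perturb,
                 population = if (model %in% c(1L, 4L)) pop),
            class = "cca_population")
}

#' @export
print.cca_population <- function(x, ...) {
  cat("Population model ", x$model, " (", x$misspecification, "), K = ",
      nrow(x$sigma), "\n", sep = "")
  invisible(x)
}

#' Draw a standardized multivariate-normal sample
#'
#' Draws n observations from the zero-mean multivariate normal
#' distribution with the given covariance matrix and standardizes the
#' result (mean 0, variance 1 per column, 1/N convention).
#'
#' @param sigma positive-definite covariance matrix (or a
#'   \code{"cca_population"} object).
#' @param n number of observations; must exceed the number of variables.
#' @param seed optional integer seed.
#' @return n x K standardized data matrix with \code{sigma}'s column names.
#' @export
draw_sample <- function(sigma, n, seed = NULL) {
  if (inherits(sigma, "cca_population")) sigma <- sigma$sigma
  if (n <= ncol(sigma))
    stop("n (", n, ") must exceed the number of variables (",
         ncol(sigma), ")")
  if (!is.null(seed)) set.seed(seed)
  x <- MASS::mvrnorm(n, mu = rep(0, ncol(sigma)), Sigma = sigma)
  colnames(x) <- colnames(sigma)
  standardize(x)
}

#' Binomial confidence band around a nominal rejection rate
#'
#' Normal-approximation (Wald) binomial interval
#' \eqn{p \pm z \sqrt{p(1-p)/reps}} around a nominal rate, clipped to
#' [0, 1]. Used to shade the band within which a Monte Carlo rejection
#' rate is consistent with the nominal significance level.
#'
#' @param rate nominal rate (e.g. the significance level alpha).
#' @param reps number of Monte Carlo replications.
#' @param level coverage of the band (default 0.95).
#' @return named vector \code{c(lower, upper)}.
#' @examples
#' rejection_band(0.05, 10000)
#' @export
rejection_band <- function(rate, reps, level = 0.95) {
  if (reps <= 0) stop("'reps' must be positive")
  if (rate < 0 || rate > 1) stop("'rate' must be in [0, 1]")
  z <- stats::qnorm(1 - (1 - level) / 2)
  half <- z * sqrt(rate * (1 - rate) / reps)
  c(lower = max(0, rate - half), upper = min(1, rate + half))
}

#' Monte Carlo study of the bootstrap fit test
#'
#' For every combination of population model, sample size and significance
#' level, draws \code{reps} datasets, runs the bootstrap fit test on each,
#' and tabulates the rejection rate per discrepancy measure together with
#' the binomial band around the nominal level. Under correctly specified
#' models (1 and 4) the rejection rate estimates the type-I error; under
#' misspecified models (2, 3, 5) it estimates power.
#'
#' Each (model, n) cell receives its own deterministic RNG substream
#' derived from \code{seed}, and within a cell each replication has its
#' own seed, so results are identical for any \code{workers} count and any
#' subset of cells can be reproduced in isolation.
#'
#' @param models integer vector from 1:5.
#' @param n_grid vector of sample sizes (full-scale default
#'   \code{seq(50, 1450, by = 100)} is usually thinned for desk use).
#' @param alphas significance levels.
#' @param reps Monte Carlo replications per cell (default 300; 10000 for a
#'   full-scale run).
#' @param B bootstrap resamples per test (default 200).
#' @param seed master seed.
#' @param workers parallel workers (forked; results do not depend on it).
#' @param measures discrepancy measures to track.
#' @param model3_cor unexplained correlation used when model 3 is run
#'   (default 0.4; see [population_sigma()]).
#' @return an object of classes \code{"cca_sim"} and \code{"data.frame"}:
#'   one row per (model, n, alpha, measure) with columns \code{rate},
#'   \code{reps}, \code{lower}, \code{upper} (band around the nominal
#'   alpha), and \code{failed} (replications whose test aborted). The
#'   per-replication rejection decisions are kept in
#'   \code{attr(, "decisions")}.
#' @examples
#' \donttest{
#' rs <- run_study(models = 1, n_grid = 100, alphas = 0.05,
#'                 reps = 20, B = 50, seed = 1)
#' rs
#' }
#' @export
run_study <- function(models = 1:5, n_grid = seq(50, 1450, by = 100),
                      alphas = c(0.01, 0.05, 0.10), reps = 300, B = 200,
                      seed = 1, workers = 1,
                      measures = c("dL", "dG", "srmr"),
                      model3_cor = 0.4) {
  if (reps < 1) stop("'reps' must be at least 1")
  measures <- match.arg(measures, several.ok = TRUE)
  pops <- lapply(models, function(m)
    if (m == 3) population_sigma(3, unexplained_cor = model3_cor)
    else population_sigma(m))
  names(pops) <- as.character(models)
  cells <- expand.grid(model = models, n = n_grid,
                       KEEP.OUT.ATTRS = FALSE)
  rows <- list()
  dec_store <- list()
  for (ci in seq_len(nrow(cells))) {
    m <- cells$model[ci]
    n <- cells$n[ci]
    pop <- pops[[as.character(m)]]
    cell_seed <- cell_stream_seed(seed, m, n)
    rep_seeds <- substream_seeds(cell_seed, reps)
    one_rep <- function(r) {
      x <- draw_sample(pop$sigma, n, seed = rep_seeds[r])
      tst <- tryCatch(
        cca_boot_test(x, pop$spec, B = B, alpha = min(alphas),
                      measures = measures, seed = rep_seeds[r] + 1L),
        error = function(e) NULL)
      if (is.null(tst)) return(rep(NA_real_, length(measures)))
      tst$p_values[measures]
    }
    pvals <- if (workers > 1)
      do.call(rbind, parallel::mclapply(seq_len(reps), one_rep,
                                        mc.cores = workers))
    else do.call(rbind, lapply(seq_len(reps), one_rep))
    failed <- sum(is.na(pvals[, 1]))
    if (failed > 0.05 * reps)
      warning("cell model=", m, " n=", n, ": ", failed, " of ", reps,
              " replications failed")
    # decision: observed discrepancy above the empirical (1 - a) critical
    # value; on the b/B lattice this is p <= a for integer B * a
    for (a in alphas) for (mm in measures) {
      p <- pvals[, match(mm, measures)]
      rate <- mean(p[!is.na(p)] <= a)
      band <- rejection_band(a, reps - failed)
      rows[[length(rows) + 1L]] <- data.frame(
        model = m, n = n, alpha = a, measure = mm, rate = rate,
        reps = reps - failed, lower = band[["lower"]],
        upper = band[["upper"]], failed = failed)
      dec_store[[paste(m, n, a, mm, sep = "_")]] <- p <= a
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "decisions") <- dec_store
  attr(out, "config") <- list(B = B, seed = seed, reps = reps,
                              model3_cor = model3_cor)
  class(out) <- c("cca_sim", "data.frame")
  out
}

# Deterministic per-cell / per-replication substream seeds, all < 2^31.
# Cells (model in 1:5, n <= 9999) map to distinct streams for a given
# master seed; replication seeds within a cell are spaced by a prime.
cell_stream_seed <- function(seed, model, n) {
  ((as.double(seed) %% 32749) * 65537 + model * 4099 + n * 7) %% 2147483629
}

substream_seeds <- function(cell_seed, reps) {
  as.integer((cell_seed * 1009 + 7919 * seq_len(reps)) %% 2147483629)
}

#' @export
print.cca_sim <- function(x, digits = 3, ...) {
  cfg <- attr(x, "config")
  cat("Monte Carlo study of the bootstrap fit test (B = ", cfg$B,
      ", reps = ", cfg$reps, ", seed = ", cfg$seed, ")\n", sep = "")
  print.data.frame(cbind(x[c("model", "n", "alpha", "measure")],
                         round(x[c("rate", "lower", "upper")], digits),
                         x["reps"]), row.names = FALSE)
  invisible(x)
}

#' Rejection-rate curves of a Monte Carlo study
#'
#' One panel per (model, alpha): rejection rate against sample size, one
#' line per discrepancy measure, with the binomial band around the nominal
#' level shaded.
#'
#' @param x a [run_study()] result.
#' @param ... unused.
#' @export
plot.cca_sim <- function(x, ...) {
  combos <- unique(x[c("model", "alpha")])
  op <- graphics::par(mfrow = grDevices::n2mfrow(nrow(combos)),
                      mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (i in seq_len(nrow(combos))) {
    sub <- x[x$model == combos$model[i] & x$alpha == combos$alpha[i], ]
    graphics::plot(range(sub$n), c(0, 1), type = "n",
                   xlab = "n", ylab = "rejection rate",
                   main = sprintf("model %d, alpha = %.2f",
                                  combos$model[i], combos$alpha[i]))
    band <- sub[sub$measure == sub$measure[1], ]
    graphics::polygon(c(band$n, rev(band$n)),
                      c(band$lower, rev(band$upper)),
                      col = "grey90", border = NA)
    graphics::abline(h = combos$alpha[i], lty = 3)
    meas <- unique(sub$measure)
    for (k in seq_along(meas)) {
      mm <- sub[sub$measure == meas[k], ]
      mm <- mm[order(mm$n), ]
      graphics::lines(mm$n, mm$rate, col = k, lty = k, type = "b", pch = k)
    }
    graphics::legend("topleft", legend = meas, col = seq_along(meas),
                     lty = seq_along(meas), pch = seq_along(meas),
                     bty = "n", cex = 0.8)
  }
  invisible(x)
}
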