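#' Discrepancy measures between sample and model-implied matrices
#'
#' Three distances between the sample correlation matrix S and the
#' estimated model-implied matrix \eqn{\hat\Sigma}, all zero exactly at a
#' perfect fit:
#' \describe{
#'   \item{squared Euclidean distance}{\eqn{d_L = \frac12 \sum_{i,j}
#'     (s_{ij} - \hat\sigma_{ij})^2} over all K^2 entries.}
#'   \item{geodesic distance}{\eqn{d_G = \sqrt{\frac12 \sum_i
#'     (\log \varphi_i)^2}} where \eqn{\varphi_i} are the eigenvalues of
#'     \eqn{S^{-1}\hat\Sigma}; zero iff all eigenvalues are one.}
#'   \item{SRMR}{square root of the average squared standardized residual
#'     over the lower triangle including the diagonal,
#'     \eqn{\sqrt{2 \sum_{i \ge j} ((s_{ij}-\hat\sigma_{ij}) /
#'     \sqrt{s_{ii} s_{jj}})^2 / (K(K+1))}}.}
#' }
#' On standardized data \eqn{d_L} and SRMR are monotone transforms of one
#' another, so fit tests based on them reach identical decisions.
#'
#' @param S sample covariance/correlation matrix.
#' @param sigma_hat model-implied matrix of the same dimension.
#' @return scalars; \code{fit_measures} returns an object of class
#'   \code{"fit_measures"} holding all three plus the eigenvalues
#'   \eqn{\varphi_i}.
#' @examples
#' S <- diag(2); S[1, 2] <- S[2, 1] <- 0.5
#' Sh <- diag(2); Sh[1, 2] <- Sh[2, 1] <- 0.3
#' distance_euclidean(S, Sh)  # 0.04
#' srmr(S, Sh)                # sqrt(2 * 0.04 / 6)
#' @export
distance_euclidean <- function(S, sigma_hat) {
  check_same_dim(S, sigma_hat)
  0.5 * sum((S - sigma_hat)^2)
}

#' @rdname distance_euclidean
#' @export
distance_geodesic <- function(S, sigma_hat) {
  sqrt(0.5 * sum(log(geodesic_eigenvalues(S, sigma_hat))^2))
}

geodesic_eigenvalues <- function(S, sigma_hat) {
  check_same_dim(S, sigma_hat)
  assert_pd(sym_eigen(S, "S"), "S")
  assert_pd(sym_eigen(sigma_hat, "sigma_hat"), "sigma_hat")
  # eigenvalues of S^-1 Sigma-hat; computed via the symmetric congruent
  # form R Sigma-hat R with R = S^(-1/2), which has the same spectrum
  R <- matrix_inv_sqrt(S)
  eigen(R %*% sigma_hat %*% R, symmetric = TRUE, only.values = TRUE)$values
}

#' @rdname distance_euclidean
#' @export
srmr <- function(S, sigma_hat) {
  check_same_dim(S, sigma_hat)
  d <- diag(S)
  if (any(d <= 0))
    stop("S has non-positive diagonal entries; SRMR is undefined")
  K <- nrow(S)
  sc <- sqrt(d)
  std_res <- (S - sigma_hat) / tcrossprod(sc)
  lower <- std_res[lower.tri(std_res, diag = TRUE)]
  sqrt(2 * sum(lower^2) / (K * (K + 1)))
}

#' @rdname distance_euclidean
#' @export
fit_measures <- function(S, sigma_hat) {
  phi <- geodesic_eigenvalues(S, sigma_hat)
  structure(list(d_L = distance_euclidean(S, sigma_hat),
                 d_G = sqrt(0.5 * sum(log(phi)^2)),
                 srmr = srmr(S, sigma_hat),
                 eigenvalues = phi),
            class = "fit_measures")
}

#' @export
print.fit_measures <- function(x, digits = 5, ...) {
  cat("Discrepancy measures: dL =", format(x$d_L, digits = digits),
      " dG =", format(x$d_G, digits = digits),
      " SRMR =", format(x$srmr, digits = digits), "\n")
  invisible(x)
}

check_same_dim <- function(S, sigma_hat) {
  if (!is.matrix(S) || !is.matrix(sigma_hat) ||
      any(dim(S) != dim(sigma_hat)) || nrow(S) != ncol(S))
    stop("S and sigma_hat must be square matrices of equal dimension")
  invisible(TRUE)
}

#' Normed fit index
#'
#' Relative improvement of the fitted model's discrepancy over a baseline
#' model in which all indicators are uncorrelated (model-implied matrix =
#' identity): \eqn{1 - F(\hat\Sigma) / F(baseline)}. The discrepancy
#' function F is the geodesic distance by default. NFI is 1 at a perfect
#' fit and 0 when the model fits no better than the baseline.
#'
#' @param S sample correlation matrix.
#' @param sigma_hat model-implied matrix.
#' @param baseline baseline model-implied matrix (identity by default).
#' @param discrepancy \code{"geodesic"} or \code{"euclidean"}.
#' @return scalar.
#' @export
nfi <- function(S, sigma_hat, baseline = diag(nrow(S)),
                discrepancy = c("geodesic", "euclidean")) {
  discrepancy <- match.arg(discrepancy)
  f <- if (discrepancy == "geodesic") distance_geodesic else distance_euclidean
  fb <- f(S, baseline)
  if (fb <= 0)
    stop("baseline discrepancy is zero; NFI is undefined ",
         "(the sample matrix already equals the baseline)")
  1 - f(S, sigma_hat) / fb
}

#' Root mean square outer residual (RMS_theta)
#'
#' Square root of the mean squared residual correlation taken over
#' cross-block pairs only: pairs of indicators in different blocks and
#' indicator/free-variable pairs. Within-block residuals are excluded
#' because intra-block covariances are unconstrained (and hence zero by
#' construction in the fitted model).
#'
#' @param S sample correlation matrix.
#' @param sigma_hat model-implied matrix.
#' @param spec a [composite_spec()] giving block membership.
#' @return scalar \eqn{\ge 0}.
#' @export
rms_theta <- function(S, sigma_hat, spec) {
  spec <- as_composite_spec(spec)
  check_same_dim(S, sigma_hat)
  bidx <- all_block_index(spec)
  member <- integer(spec$K)
  for (i in seq_along(bidx)) member[bidx[[i]]] <- i
  cross <- outer(member, member, "!=") & upper.tri(S)
  if (!any(cross))
    stop("model has no cross-block indicator pairs; RMS_theta is undefined")
  res <- (S - sigma_hat)[cross]
  sqrt(mean(res^2))
}

#' Bollen-Stine data transformation
#'
#' Rotates the (centered, standardized) data so that its sample correlation
#' matrix equals the estimated model-implied matrix exactly:
#' \eqn{X^* = X S^{-1/2} \hat\Sigma^{1/2}} with symmetric (spectral) matrix
#' roots. The transformed data satisfy the null hypothesis
#' \eqn{\Sigma = \Sigma(\theta)} and are the resampling population for the
#' bootstrap fit test. Column means are preserved at zero and, under the
#' 1/N convention, \code{crossprod(out)/N} equals \code{sigma_hat} to
#' numerical precision.
#'
#' @param x centered/standardized N x K data matrix.
#' @param S its sample correlation matrix (1/N convention).
#' @param sigma_hat estimated model-implied matrix (positive-definite).
#' @return transformed N x K matrix.
#' @export
bollen_stine_transform <- function(x, S, sigma_hat) {
  x <- as.matrix(x)
  if (ncol(x) != nrow(S)) stop("data and S dimensions disagree")
  x %*% matrix_inv_sqrt(S) %*% matrix_sqrt(sigma_hat)
}

#' Bootstrap test of overall model fit
#'
#' Tests the null hypothesis that the population indicator correlation
#' matrix satisfies the composite model's constraints,
#' \eqn{H_0: \Sigma = \Sigma(\theta)}. The observed discrepancy between S
#' and \eqn{\hat\Sigma} is compared with a reference distribution obtained
#' by the Bollen-Stine scheme: the data are transformed to satisfy the null
#' exactly (see [bollen_stine_transform()]), B bootstrap resamples of N
#' rows are drawn with replacement from the transformed data, and each
#' resample is re-standardized, re-estimated, and its discrepancies
#' recomputed against its own fitted matrix. The p-value per measure is
#' the proportion of bootstrap discrepancies at or above the observed one;
#' the model is rejected when the observed discrepancy exceeds the
#' empirical (1 - alpha) quantile of the reference distribution (the
#' critical value), which coincides with p <= alpha whenever B * alpha is
#' an integer.
#'
#' Resamples whose estimation fails (e.g. a singular resampled correlation
#' matrix) are dropped and counted; if more than 5 percent fail the test
#' aborts with a diagnostic error.
#'
#' @param x N x K data matrix or data frame with the model's columns.
#' @param spec a [composite_spec()].
#' @param B number of bootstrap resamples (default 200).
#' @param alpha significance level (default 0.05).
#' @param measures subset of \code{c("dL", "dG", "srmr")}.
#' @param seed optional integer seed for the resampling.
#' @return an object of class \code{"cca_boot_test"}: list with
#'   \code{observed} (named observed discrepancies), \code{reference}
#'   (B-column matrix of bootstrap discrepancies), \code{p_values},
#'   \code{quantiles} (the empirical (1 - alpha) critical values),
#'   \code{rejected}, \code{alpha}, \code{B}, \code{n_failed}, and
#'   \code{fit}, the [cca()] fit of the original data.
#' @examples
#' spec <- composite_spec(list(c1 = c("x11", "x12", "x13"),
#'                             c2 = c("x21", "x22", "x23")))
#' x <- draw_sample(population_sigma(1)$sigma, 120, seed = 7)
#' tst <- cca_boot_test(x, spec, B = 60, seed = 1)
#' tst$p_values
#' @export
cca_boot_test <- function(x, spec, B = 200, alpha = 0.05,
                          measures = c("dL", "dG", "srmr"), seed = NULL) {
  spec <- as_composite_spec(spec)
  measures <- match.arg(measures, several.ok = TRUE)
  if (B < 1) stop("B must be at least 1")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  fit <- cca(x, spec)
  if (is.null(fit$data))
    stop("the bootstrap test needs raw data, not a correlation matrix")
  if (!is.null(seed)) set.seed(seed)
  bidx <- all_block_index(spec)
  obs <- measure_vector(fit$sample_corr, fit$sigma_hat, measures)
  xstar <- bollen_stine_transform(fit$data, fit$sample_corr, fit$sigma_hat)
  n <- nrow(xstar)
  ref <- matrix(NA_real_, length(measures), B,
                dimnames = list(measures, NULL))
  failed <- 0L
  for (b in seq_len(B)) {
    zb <- xstar[sample.int(n, n, replace = TRUE), , drop = FALSE]
    db <- tryCatch({
      zb <- standardize(zb)
      Sb <- crossprod(zb) / n
      eb <- estimate_core(Sb, bidx)
      measure_vector(Sb, eb$sigma_hat, measures)
    }, error = function(e) NULL)
    if (is.null(db)) failed <- failed + 1L else ref[, b] <- db
  }
  if (failed > 0.05 * B)
    stop("bootstrap fit test aborted: ", failed, " of ", B,
         " resamples failed estimation (more than 5%); the data or model ",
         "are too unstable for a reliable reference distribution")
  ok <- !is.na(ref[1, ])
  ref <- ref[, ok, drop = FALSE]
  p <- vapply(measures, function(m) mean(ref[m, ] >= obs[[m]]), 0)
  q <- vapply(measures, function(m)
    stats::quantile(ref[m, ], probs = 1 - alpha, names = FALSE), 0)
  structure(list(observed = obs, reference = ref, p_values = p,
                 quantiles = q, rejected = obs > q, alpha = alpha,
                 B = B, n_failed = failed, measures = measures,
                 fit = fit),
            class = "cca_boot_test")
}

# hot path: same quantities as the exported functions, minimal checking
measure_vector <- function(S, sigma_hat, measures) {
  out <- numeric(length(measures))
  names(out) <- measures
  res <- S - sigma_hat
  if ("dL" %in% measures) out[["dL"]] <- 0.5 * sum(res^2)
  if ("srmr" %in% measures) {
    K <- nrow(S)
    sc <- sqrt(diag(S))
    lower <- (res / tcrossprod(sc))[lower.tri(res, diag = TRUE)]
    out[["srmr"]] <- sqrt(2 * sum(lower^2) / (K * (K + 1)))
  }
  if ("dG" %in% measures) {
    R <- inv_sqrt_fast(S, "S")
    phi <- eigen(R %*% sigma_hat %*% R, symmetric = TRUE,
                 only.values = TRUE)$values
    if (min(phi) <= 0)
      stop("fitted matrix is not positive-definite; geodesic distance undefined")
    out[["dG"]] <- sqrt(0.5 * sum(log(phi)^2))
  }
  # clamp floating noise so exact fits tie at zero in the reference
  # distribution (saturated models would otherwise get arbitrary p-values)
  out[out < 1e-12] <- 0
  out
}

#' @export
print.cca_boot_test <- function(x, digits = 4, ...) {
  cat("Bootstrap test of overall model fit (Bollen-Stine, B = ", x$B,
      ", alpha = ", x$alpha, ")\n", sep = "")
  tab <- data.frame(observed = unname(x$observed[x$measures]),
                    crit = unname(x$quantiles[x$measures]),
                    p = unname(x$p_values[x$measures]),
                    rejected = unname(x$rejected[x$measures]),
                    row.names = x$measures)
  print(round(tab[1:3], digits))
  cat("rejected:", paste(x$measures[x$rejected], collapse = ", "), "\n")
  if (x$n_failed)
    cat("note:", x$n_failed, "bootstrap resample(s) failed and were dropped\n")
  invisible(x)
}
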