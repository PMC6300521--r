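#' Standardize an indicator data matrix
#'
#' Centers every column to mean zero and scales it to unit variance using
#' the 1/N variance convention (population denominator). Under this
#' convention the sample correlation matrix is exactly \code{crossprod(Z)/N}
#' and the Bollen-Stine transform reproduces the model-implied matrix
#' exactly as the transformed data's correlation matrix.
#'
#' @param x numeric matrix or data frame, observations in rows.
#' @return numeric matrix with columns of mean 0 and variance 1 (1/N).
#' @export
standardize <- function(x) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("data must be numeric")
  n <- nrow(x)
  ctr <- colMeans(x)
  z <- x - rep(ctr, each = n)
  sds <- sqrt(colMeans(z^2))
  if (any(sds <= 0 | !is.finite(sds))) {
    bad <- colnames(x)[sds <= 0 | !is.finite(sds)]
    if (is.null(bad)) bad <- which(sds <= 0 | !is.finite(sds))
    stop("degenerate indicator(s) with zero variance: ",
         paste(bad, collapse = ", "))
  }
  z / rep(sds, each = n)
}

# sample correlation matrix under the 1/N convention (x already standardized)
sample_corr <- function(z) crossprod(z) / nrow(z)

#' Maxvar weights from a correlation matrix
#'
#' Kettenring's maxvar criterion chooses block weights, under the
#' unit-composite-variance constraints \eqn{w_j' S_{jj} w_j = 1}, to
#' maximize the largest eigenvalue of the composite correlation matrix, so
#' that one principal component explains as much of the composites' total
#' variation as possible. The solution is closed-form: with
#' \eqn{S_D} the block-diagonal matrix of intra-block correlation
#' matrices, let \eqn{\tilde a} be the leading eigenvector of
#' \eqn{S_D^{-1/2} S S_D^{-1/2}}, partitioned into subvectors
#' \eqn{\tilde a_j} per block; then
#' \eqn{w_j = S_{jj}^{-1/2} \tilde a_j / \sqrt{\tilde a_j' \tilde a_j}},
#' and the attained maxvar objective equals the leading eigenvalue. Free
#' variables of the model participate as singleton blocks with weight 1.
#'
#' Eigenvectors are sign-indeterminate; each weight vector is fixed so its
#' entry of largest magnitude is positive (ties broken by first index). If
#' the two leading eigenvalues are closer than \code{1e-9} the solution is
#' ambiguous: the eigenvector whose absolute-value pattern is
#' lexicographically largest is chosen and a warning is issued.
#'
#' @param S K x K symmetric positive-definite sample correlation matrix,
#'   columns in (or named by) the model's variable order.
#' @param spec a [composite_spec()].
#' @return an object of class \code{"maxvar_solution"}: list with
#'   \code{weights} (named list per block, free variables included as
#'   singletons), \code{a} (the leading eigenvector), \code{eigenvalue}
#'   (the maxvar objective), \code{sample_corr} and \code{block_diag}.
#' @seealso [cca()] for the full estimator.
#' @export
maxvar_weights <- function(S, spec) {
  spec <- as_composite_spec(spec)
  S <- check_sigma_names(S, spec)
  bidx <- all_block_index(spec)
  core <- maxvar_core(S, bidx)
  if (core$tied)
    warning("leading maxvar eigenvalue is (near-)degenerate; ",
            "weights chosen by a deterministic tie-break")
  SD <- matrix(0, spec$K, spec$K, dimnames = dimnames(S))
  for (b in bidx) SD[b, b] <- S[b, b]
  structure(list(weights = core$weights, a = core$a,
                 eigenvalue = core$eigenvalue,
                 sample_corr = S, block_diag = SD),
            class = "maxvar_solution")
}

# Hot path shared with the bootstrap: no name checking, indices precomputed.
maxvar_core <- function(S, bidx) {
  K <- nrow(S)
  R <- matrix(0, K, K)
  invsq <- vector("list", length(bidx))
  for (i in seq_along(bidx)) {
    b <- bidx[[i]]
    Ri <- inv_sqrt_fast(S[b, b, drop = FALSE],
                        paste0("intra-block matrix of '", names(bidx)[i], "'"))
    invsq[[i]] <- Ri
    R[b, b] <- Ri
  }
  e <- eigen(R %*% S %*% R, symmetric = TRUE)
  tied <- length(e$values) > 1L && (e$values[1] - e$values[2]) < 1e-9
  a <- e$vectors[, 1]
  if (tied) {
    a2 <- e$vectors[, 2]
    d <- abs(a) - abs(a2)
    first <- which(abs(d) > 1e-12)
    if (length(first) && d[first[1]] < 0) a <- a2
  }
  w <- vector("list", length(bidx))
  names(w) <- names(bidx)
  for (i in seq_along(bidx)) {
    aj <- a[bidx[[i]]]
    nrm <- sqrt(sum(aj^2))
    if (nrm < 1e-12)
      stop("block '", names(bidx)[i], "' receives a zero maxvar subvector; ",
           "the composite is isolated and its weights are not identified")
    wi <- drop(invsq[[i]] %*% aj) / nrm
    m <- which.max(abs(wi))
    if (wi[m] < 0) wi <- -wi
    names(wi) <- colnames(S)[bidx[[i]]]
    w[[i]] <- wi
  }
  list(weights = w, a = a, eigenvalue = e$values[1], tied = tied)
}

#' Composite scores
#'
#' Applies the block weights to standardized indicator data to produce the
#' composite score of each observation, \eqn{c_j = w_j' x_j}. With weights
#' normalized against the data's own correlation matrix each score column
#' has unit sample variance (1/N convention).
#'
#' @param z standardized data matrix (see [standardize()]), columns in the
#'   spec's variable order.
#' @param weights named list of per-block weight vectors (free variables as
#'   singletons with weight 1), e.g. from [maxvar_weights()].
#' @param spec a [composite_spec()].
#' @return N x (J + F) matrix of composite scores (free variables pass
#'   through unchanged).
#' @export
composite_scores <- function(z, weights, spec) {
  spec <- as_composite_spec(spec)
  bidx <- all_block_index(spec)
  if (ncol(z) != spec$K)
    stop("data has ", ncol(z), " columns; the model expects ", spec$K)
  out <- matrix(0, nrow(z), length(bidx),
                dimnames = list(NULL, names(bidx)))
  for (i in seq_along(bidx))
    out[, i] <- z[, bidx[[i]], drop = FALSE] %*% weights[[names(bidx)[i]]]
  out
}

#' Composite correlations from weights
#'
#' Entry (j, l) is \eqn{w_j' S_{jl} w_l}, the correlation between
#' composites j and l when the weights are normalized against the diagonal
#' blocks of S.
#'
#' @param S indicator correlation matrix.
#' @param weights named list of per-block weight vectors.
#' @param spec a [composite_spec()].
#' @return symmetric matrix with unit diagonal over composites and free
#'   variables.
#' @export
composite_correlations <- function(S, weights, spec) {
  spec <- as_composite_spec(spec)
  S <- check_sigma_names(S, spec)
  bidx <- all_block_index(spec)
  comp_corr_core(S, bidx, weights[names(bidx)])
}

comp_corr_core <- function(S, bidx, weights) {
  nb <- length(bidx)
  cc <- diag(nb)
  dimnames(cc) <- list(names(bidx), names(bidx))
  for (i in seq_len(nb - 1L)) for (j in seq(i + 1L, nb)) {
    r <- drop(crossprod(weights[[i]],
                        S[bidx[[i]], bidx[[j]], drop = FALSE] %*% weights[[j]]))
    cc[i, j] <- r
    cc[j, i] <- r
  }
  cc
}

# sigma_hat: diagonal blocks at sample values, off-diagonal rank-one
sigma_hat_core <- function(S, bidx, weights, cc) {
  lam <- vector("list", length(bidx))
  for (i in seq_along(bidx))
    lam[[i]] <- drop(S[bidx[[i]], bidx[[i]], drop = FALSE] %*% weights[[i]])
  sh <- matrix(0, nrow(S), ncol(S), dimnames = dimnames(S))
  for (i in seq_along(bidx)) for (j in seq_along(bidx)) {
    if (i == j) sh[bidx[[i]], bidx[[i]]] <- S[bidx[[i]], bidx[[i]]]
    else sh[bidx[[i]], bidx[[j]]] <- cc[i, j] * tcrossprod(lam[[i]], lam[[j]])
  }
  list(sigma_hat = (sh + t(sh)) / 2, loadings = lam)
}

# full estimation on a precomputed correlation matrix; hot path
estimate_core <- function(S, bidx) {
  mv <- maxvar_core(S, bidx)
  cc <- comp_corr_core(S, bidx, mv$weights)
  sh <- sigma_hat_core(S, bidx, mv$weights, cc)
  list(weights = mv$weights, comp_corr = cc, sigma_hat = sh$sigma_hat,
       loadings = sh$loadings, eigenvalue = mv$eigenvalue, tied = mv$tied)
}

#' Fit a composite model by maxvar
#'
#' Estimates a composite model from indicator data (or directly from a
#' correlation matrix): indicators are standardized, the sample correlation
#' matrix S is formed (1/N convention), block weights are obtained from the
#' maxvar criterion (see [maxvar_weights()]), and the estimated
#' model-implied matrix \eqn{\hat\Sigma} is assembled with diagonal blocks
#' fixed at the sample intra-block matrices (they are unconstrained
#' parameters, fitted at their sample values) and off-diagonal blocks
#' \eqn{\hat\rho_{jl} \hat\lambda_j \hat\lambda_l'}. Free variables take
#' part as singleton blocks with weight 1. Estimation requires the model
#' not to be under-identified.
#'
#' @param x either an N x K numeric data matrix / data frame with column
#'   names covering the model's variables (N > K required), or a K x K
#'   symmetric unit-diagonal correlation matrix (in which case no scores
#'   are computed and \code{n} may record the nominal sample size).
#' @param spec a [composite_spec()].
#' @param n optional sample size annotation when \code{x} is a correlation
#'   matrix.
#' @return an object of class \code{"cca"}: list with \code{weights},
#'   \code{loadings}, \code{composite_corr} (composites and free
#'   variables), \code{sigma_hat}, \code{sample_corr}, \code{scores} (NULL
#'   for matrix input), \code{residuals} (S - \eqn{\hat\Sigma}),
#'   \code{objective} (attained maxvar eigenvalue),
#'   \code{identification}, \code{spec}, \code{n}.
#' @examples
#' spec <- composite_spec(list(c1 = c("x11", "x12", "x13"),
#'                             c2 = c("x21", "x22", "x23")))
#' sigma <- population_sigma(1)$sigma
#' fit <- cca(sigma, spec)
#' coef(fit)
#' fit$composite_corr["c1", "c2"]  # 0.3
#' @seealso [fit_measures()], [cca_boot_test()]
#' @export
cca <- function(x, spec, n = NULL) {
  spec <- as_composite_spec(spec)
  from_corr <- is_corr_matrix(x)
  if (from_corr) {
    S <- check_sigma_names(as.matrix(x), spec)
    z <- NULL
  } else {
    x <- as.matrix(x)
    if (!is.null(colnames(x))) {
      miss <- setdiff(spec$indicators, colnames(x))
      if (length(miss))
        stop("data lacks column(s): ", paste(miss, collapse = ", "))
      x <- x[, spec$indicators, drop = FALSE]
    } else if (ncol(x) != spec$K) {
      stop("data has ", ncol(x), " columns; the model expects ", spec$K)
    } else colnames(x) <- spec$indicators
    if (anyNA(x)) stop("data contains missing values")
    if (nrow(x) <= ncol(x))
      stop("need more observations (", nrow(x), ") than variables (",
           ncol(x), ")")
    n <- nrow(x)
    z <- standardize(x)
    S <- sample_corr(z)
  }
  ident <- check_identification(spec, S)
  if (ident$status == "under-identified")
    stop("model is under-identified (df = ", ident$df,
         if (length(ident$isolated_blocks))
           paste0("; isolated: ",
                  paste(ident$isolated_blocks, collapse = ", ")) else "",
         "); estimates would not be unique")
  bidx <- all_block_index(spec)
  est <- estimate_core(S, bidx)
  if (est$tied)
    warning("leading maxvar eigenvalue is (near-)degenerate; ",
            "weights chosen by a deterministic tie-break")
  names(est$loadings) <- names(bidx)
  scores <- if (is.null(z)) NULL else composite_scores(z, est$weights, spec)
  structure(list(weights = est$weights[names(spec$blocks)],
                 all_weights = est$weights,
                 loadings = est$loadings[names(spec$blocks)],
                 composite_corr = est$comp_corr,
                 sigma_hat = est$sigma_hat,
                 sample_corr = S,
                 scores = scores,
                 residuals = S - est$sigma_hat,
                 objective = est$eigenvalue,
                 identification = ident,
                 spec = spec, n = n,
                 data = z),
            class = "cca")
}

is_corr_matrix <- function(x) {
  is.matrix(x) && is.numeric(x) && nrow(x) == ncol(x) &&
    isSymmetric(unname(x), tol = 1e-8) &&
    all(abs(diag(x) - 1) < 1e-8)
}

#' @export
print.cca <- function(x, digits = 4, ...) {
  cat("Composite model fit (maxvar)\n")
  if (!is.null(x$n)) cat("  N =", x$n, "\n")
  cat("  weights:\n")
  for (nm in names(x$weights))
    cat("    ", nm, ": ",
        paste(format(round(x$weights[[nm]], digits)), collapse = "  "),
        "\n", sep = "")
  J <- x$spec$J
  if (J > 1L || length(x$spec$free)) {
    cat("  composite correlations:\n")
    print(round(x$composite_corr, digits))
  }
  cat("  df =", x$identification$df, "(", x$identification$status, ")\n")
  invisible(x)
}

#' @export
summary.cca <- function(object, ...) {
  fm <- fit_measures(object$sample_corr, object$sigma_hat)
  structure(list(fit = object, measures = fm,
                 indices = list(
                   srmr = fm$srmr,
                   nfi = nfi(object$sample_corr, object$sigma_hat),
                   rms_theta = rms_theta(object$sample_corr,
                                         object$sigma_hat, object$spec))),
            class = "summary.cca")
}

#' @export
print.summary.cca <- function(x, digits = 4, ...) {
  print(x$fit, digits = digits)
  cat("  loadings:\n")
  for (nm in names(x$fit$loadings))
    cat("    ", nm, ": ",
        paste(format(round(x$fit$loadings[[nm]], digits)), collapse = "  "),
        "\n", sep = "")
  cat("  discrepancy: dL =", format(x$measures$d_L, digits = digits),
      " dG =", format(x$measures$d_G, digits = digits),
      " SRMR =", format(x$measures$srmr, digits = digits), "\n")
  cat("  fit indices: NFI =", format(x$indices$nfi, digits = digits),
      " RMS_theta =", format(x$indices$rms_theta, digits = digits), "\n")
  invisible(x)
}

#' @export
coef.cca <- function(object, type = c("weights", "loadings"), ...) {
  type <- match.arg(type)
  part <- object[[type]]
  out <- unlist(lapply(names(part), function(nm) {
    v <- part[[nm]]
    names(v) <- object$spec$blocks[[nm]]
    v
  }))
  out
}

#' @export
fitted.cca <- function(object, ...) object$sigma_hat

#' @export
residuals.cca <- function(object, ...) object$residuals

#' Composite scores for new data
#'
#' Standardizes \code{newdata} and applies the estimated block weights.
#' Without \code{newdata}, returns the training-sample scores.
#'
#' @param object a fitted [cca()] model.
#' @param newdata optional data matrix/data frame with the model's columns.
#' @param ... unused.
#' @return matrix of composite scores.
#' @export
predict.cca <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    if (is.null(object$scores))
      stop("model was fitted from a correlation matrix; supply 'newdata'")
    return(object$scores)
  }
  newdata <- as.matrix(newdata)
  if (!is.null(colnames(newdata)))
    newdata <- newdata[, object$spec$indicators, drop = FALSE]
  composite_scores(standardize(newdata), object$all_weights, object$spec)
}

#' Simulate indicator data from a fitted composite model
#'
#' Draws standardized multivariate-normal samples with covariance equal to
#' the estimated model-implied matrix \eqn{\hat\Sigma}.
#'
#' @param object a fitted [cca()] model.
#' @param nsim number of datasets.
#' @param seed optional integer seed.
#' @param n observations per dataset (defaults to the fitted sample size).
#' @param ... unused.
#' @return list of \code{nsim} data matrices.
#' @export
simulate.cca <- function(object, nsim = 1, seed = NULL, n = object$n, ...) {
  if (is.null(n)) stop("sample size unknown; supply 'n'")
  if (!is.null(seed)) set.seed(seed)
  replicate(nsim, draw_sample(object$sigma_hat, n), simplify = FALSE)
}

#' Residual correlation image of a fitted composite model
#'
#' Displays S minus the estimated model-implied matrix as a shaded grid;
#' within-block cells are unconstrained and therefore exactly zero.
#'
#' @param x a fitted [cca()] model.
#' @param ... passed to [graphics::image()].
#' @export
plot.cca <- function(x, ...) {
  r <- x$residuals
  k <- ncol(r)
  lim <- max(abs(r), 1e-3)
  graphics::image(seq_len(k), seq_len(k), t(r[k:1, , drop = FALSE]),
                  zlim = c(-lim, lim), axes = FALSE,
                  xlab = "", ylab = "",
                  main = "Residual correlations (S - fitted)",
                  col = grDevices::hcl.colors(65, "Blue-Red 2"), ...)
  graphics::axis(1, at = seq_len(k), labels = colnames(r), las = 2,
                 cex.axis = 0.8)
  graphics::axis(2, at = seq_len(k), labels = rev(rownames(r)), las = 2,
                 cex.axis = 0.8)
  graphics::box()
  invisible(x)
}
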