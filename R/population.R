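#' Composite loadings, variance and weight normalization
#'
#' For a block with weight vector w and intra-block covariance matrix
#' \eqn{\Sigma_{jj}}, the loading vector \eqn{\lambda_j = \Sigma_{jj} w_j}
#' holds the covariances between the composite and its own indicators, and
#' the composite variance is the quadratic form \eqn{w_j' \Sigma_{jj} w_j}.
#' Identification requires each composite to be scaled to unit variance;
#' \code{rescale_weights} divides the weights by the square root of the
#' current composite variance so the constraint holds, preserving their
#' direction.
#'
#' @param weights numeric weight vector of length Kj.
#' @param intra_block_corr symmetric Kj x Kj intra-block covariance
#'   (correlation) matrix.
#' @return \code{composite_loadings}: numeric vector of length Kj;
#'   \code{composite_variance}: scalar; \code{rescale_weights}: weight
#'   vector with unit composite variance.
#' @examples
#' Sjj <- matrix(0.5, 3, 3); diag(Sjj) <- 1
#' composite_loadings(c(0.6, 0.2, 0.4), Sjj)   # (0.9, 0.7, 0.8)
#' composite_variance(c(0.6, 0.2, 0.4), Sjj)   # 1
#' rescale_weights(c(1.2, 0.4, 0.8), Sjj)      # (0.6, 0.2, 0.4)
#' @export
composite_loadings <- function(weights, intra_block_corr) {
  check_block_dims(weights, intra_block_corr)
  drop(intra_block_corr %*% weights)
}

#' @rdname composite_loadings
#' @export
composite_variance <- function(weights, intra_block_corr) {
  check_block_dims(weights, intra_block_corr)
  drop(crossprod(weights, intra_block_corr %*% weights))
}

#' @rdname composite_loadings
#' @export
rescale_weights <- function(weights, intra_block_corr) {
  v <- composite_variance(weights, intra_block_corr)
  if (!is.finite(v) || v <= 0)
    stop("degenerate block: composite variance ", format(v),
         " is not positive; weights cannot be normalized")
  weights / sqrt(v)
}

check_block_dims <- function(weights, m) {
  if (!is.numeric(weights))
    stop("weights must be numeric")
  if (!is.matrix(m) || nrow(m) != ncol(m))
    stop("intra-block matrix must be square")
  if (length(weights) != nrow(m))
    stop("weight vector of length ", length(weights),
         " does not match a ", nrow(m), "x", ncol(m), " intra-block matrix")
  if (!isSymmetric(unname(m), tol = 1e-8))
    stop("intra-block matrix must be symmetric")
  invisible(TRUE)
}

#' Define a population composite model
#'
#' Assembles the population parameters of a composite model: per-block
#' weight vectors, the composite correlation matrix, intra-block
#' correlation matrices and (optionally) correlations of free observed
#' variables with the composites and with each other. All parameters are on
#' the correlation scale (standardized indicators) and each weight vector
#' must give its composite unit variance. The model-implied indicator
#' correlation matrix is built with the rank-one inter-block rule
#' \eqn{\Sigma_{jl} = \rho_{jl} \lambda_j \lambda_l'}; a free variable acts
#' as a singleton block with weight 1, so its covariances with a block's
#' indicators are its correlation with that composite spread through the
#' loadings.
#'
#' @param spec a [composite_spec()].
#' @param weights named list of weight vectors, one per block of
#'   \code{spec}.
#' @param composite_corr J x J symmetric correlation matrix of the
#'   composites (unit diagonal), rows/columns in block order. For J = 1 use
#'   \code{matrix(1, 1, 1)}.
#' @param intra_block_corr named list of symmetric positive-definite
#'   intra-block correlation matrices, one per block.
#' @param free_var_corr when \code{spec} has F free variables, an
#'   F x (J + F) matrix: rows are the free variables, columns the
#'   composites followed by the free variables; entries are correlations of
#'   each free variable with each composite and with the other free
#'   variables (unit "diagonal" in the free-free part).
#' @param tol tolerance for the unit-composite-variance check.
#' @return an object of class \code{"composite_population"} with the
#'   parameters, the canonical loading vectors, the full composite-level
#'   correlation matrix \code{comp_corr} (composites plus free variables),
#'   and \code{sigma}, the model-implied indicator correlation matrix.
#' @examples
#' spec <- composite_spec(list(c1 = c("x11", "x12", "x13"),
#'                             c2 = c("x21", "x22", "x23")))
#' Sjj <- matrix(0.5, 3, 3); diag(Sjj) <- 1
#' pop <- composite_population(spec,
#'   weights = list(c1 = c(0.6, 0.2, 0.4), c2 = c(0.4, 0.2, 0.6)),
#'   composite_corr = matrix(c(1, 0.3, 0.3, 1), 2),
#'   intra_block_corr = list(c1 = Sjj, c2 = Sjj))
#' pop$sigma["x11", "x21"]  # 0.3 * 0.9 * 0.8 = 0.216
#' @export
composite_population <- function(spec, weights, composite_corr,
                                 intra_block_corr, free_var_corr = NULL,
                                 tol = 1e-8) {
  spec <- as_composite_spec(spec)
  J <- spec$J
  nfree <- length(spec$free)
  bn <- names(spec$blocks)
  if (!is.list(weights) || length(weights) != J)
    stop("'weights' must be a list with one vector per block")
  if (is.null(names(weights))) names(weights) <- bn
  weights <- weights[bn]
  if (!is.list(intra_block_corr) || length(intra_block_corr) != J)
    stop("'intra_block_corr' must be a list with one matrix per block")
  if (is.null(names(intra_block_corr))) names(intra_block_corr) <- bn
  intra_block_corr <- intra_block_corr[bn]
  composite_corr <- as.matrix(composite_corr)
  if (nrow(composite_corr) != J || ncol(composite_corr) != J)
    stop("'composite_corr' must be ", J, "x", J)
  if (any(abs(diag(composite_corr) - 1) > tol))
    stop("'composite_corr' must have a unit diagonal")
  if (!isSymmetric(unname(composite_corr), tol = 1e-8))
    stop("'composite_corr' must be symmetric")
  for (nm in bn) {
    kj <- length(spec$blocks[[nm]])
    if (length(weights[[nm]]) != kj || nrow(intra_block_corr[[nm]]) != kj)
      stop("block '", nm, "': weights/intra-block matrix do not match its ",
           kj, " indicators")
    v <- composite_variance(weights[[nm]], intra_block_corr[[nm]])
    if (abs(v - 1) > tol)
      stop("block '", nm, "': composite variance is ", format(v),
           ", not 1; normalize the weights (see rescale_weights)")
  }
  comp_corr <- build_comp_corr(spec, composite_corr, free_var_corr, tol)
  sigma <- model_implied_covariance(spec, weights, comp_corr,
                                    intra_block_corr)
  structure(list(spec = spec, weights = weights,
                 composite_corr = composite_corr,
                 intra_block_corr = intra_block_corr,
                 free_var_corr = free_var_corr,
                 comp_corr = comp_corr,
                 loadings = mapply(composite_loadings, weights,
                                   intra_block_corr, SIMPLIFY = FALSE),
                 sigma = sigma),
            class = "composite_population")
}

# full (J + F) x (J + F) correlation matrix of composites and free variables
build_comp_corr <- function(spec, composite_corr, free_var_corr, tol) {
  J <- spec$J
  nfree <- length(spec$free)
  units <- c(names(spec$blocks), spec$free)
  cc <- diag(J + nfree)
  dimnames(cc) <- list(units, units)
  cc[seq_len(J), seq_len(J)] <- composite_corr
  if (nfree > 0L) {
    if (is.null(free_var_corr))
      stop("the model has free variables; supply 'free_var_corr'")
    free_var_corr <- as.matrix(free_var_corr)
    if (nrow(free_var_corr) != nfree || ncol(free_var_corr) != J + nfree)
      stop("'free_var_corr' must be ", nfree, "x", J + nfree,
           " (free variables by composites-then-free-variables)")
    for (i in seq_len(nfree)) {
      cc[J + i, ] <- free_var_corr[i, ]
      cc[, J + i] <- free_var_corr[i, ]
    }
    ff <- cc[J + seq_len(nfree), J + seq_len(nfree), drop = FALSE]
    if (any(abs(diag(ff) - 1) > tol))
      stop("free-variable self-correlations must be 1")
  }
  if (!isSymmetric(unname(cc), tol = 1e-8))
    stop("composite-level correlation matrix is not symmetric; check ",
         "'free_var_corr' against 'composite_corr'")
  cc
}

#' Build the model-implied indicator covariance matrix
#'
#' Assembles the K x K indicator matrix of a composite model: diagonal
#' blocks are the unconstrained intra-block matrices; each off-diagonal
#' block is \eqn{\rho_{jl} \lambda_j \lambda_l'} where \eqn{\rho_{jl}} is
#' the correlation between composites (or a composite and a free variable,
#' or two free variables) and \eqn{\lambda_j = \Sigma_{jj} w_j}. The result
#' must be positive-definite, which holds exactly when (i) every
#' intra-block matrix is positive-definite and (ii) the composite-level
#' correlation matrix is positive-definite; the error message names the
#' failing condition.
#'
#' @param spec a [composite_spec()].
#' @param weights named list of per-block weight vectors.
#' @param comp_corr (J + F) x (J + F) correlation matrix over composites
#'   and free variables, in the order blocks-then-free (as built by
#'   [composite_population()]).
#' @param intra_block_corr named list of intra-block matrices.
#' @return K x K symmetric matrix with dimnames \code{spec$indicators} and
#'   attribute \code{"block_index"} mapping columns to blocks.
#' @export
model_implied_covariance <- function(spec, weights, comp_corr,
                                     intra_block_corr) {
  spec <- as_composite_spec(spec)
  bidx <- all_block_index(spec)
  units <- names(bidx)
  lam <- vector("list", length(units))
  names(lam) <- units
  for (nm in names(spec$blocks))
    lam[[nm]] <- composite_loadings(weights[[nm]], intra_block_corr[[nm]])
  for (v in spec$free) lam[[v]] <- 1
  comp_corr <- as.matrix(comp_corr)
  if (nrow(comp_corr) != length(units))
    stop("'comp_corr' must be ", length(units), "x", length(units))
  sigma <- matrix(0, spec$K, spec$K,
                  dimnames = list(spec$indicators, spec$indicators))
  for (i in seq_along(units)) for (j in seq_along(units)) {
    bi <- bidx[[i]]; bj <- bidx[[j]]
    if (i == j) {
      nm <- units[i]
      sigma[bi, bj] <- if (nm %in% names(spec$blocks))
        intra_block_corr[[nm]] else 1
    } else {
      sigma[bi, bj] <- comp_corr[i, j] * tcrossprod(lam[[i]], lam[[j]])
    }
  }
  sigma <- (sigma + t(sigma)) / 2
  check_sigma_pd(sigma, intra_block_corr, comp_corr, names(spec$blocks))
  attr(sigma, "block_index") <- bidx
  sigma
}

check_sigma_pd <- function(sigma, intra_block_corr, comp_corr, block_names) {
  e <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(e) > pd_tol * max(max(e), 1)) return(invisible(TRUE))
  bad <- character()
  for (nm in block_names) {
    ej <- eigen(intra_block_corr[[nm]], symmetric = TRUE,
                only.values = TRUE)$values
    if (min(ej) <= pd_tol * max(max(ej), 1))
      bad <- c(bad, paste0("intra-block matrix of '", nm,
                           "' is not positive-definite"))
  }
  ec <- eigen(comp_corr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ec) <= pd_tol * max(max(ec), 1))
    bad <- c(bad, "the composite-level correlation matrix is not positive-definite")
  if (!length(bad))
    bad <- "conditions hold individually but the assembled matrix is numerically singular"
  stop("model-implied matrix is not positive-definite: ",
       paste(bad, collapse = "; "))
}

#' @export
print.composite_population <- function(x, ...) {
  print(x$spec)
  cat("Population composite correlations:\n")
  print(round(x$composite_corr, 4))
  cat("Model-implied indicator correlation matrix: ",
      nrow(x$sigma), "x", ncol(x$sigma), "\n", sep = "")
  invisible(x)
}
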