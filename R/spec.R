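#' Specify a composite model
#'
#' A composite model partitions a set of observed indicators into blocks,
#' each block forming one composite (a weighted linear combination of its
#' indicators), plus an optional set of free observed variables that do not
#' form a composite but may correlate with the composites and with each
#' other. Intra-block covariances are unconstrained; covariances between
#' indicators of different blocks are constrained to rank one because all
#' inter-block information is carried by the composites.
#'
#' @param blocks named list of character vectors; element \code{j} lists the
#'   indicators forming composite \code{j} (at least one indicator each).
#'   Unnamed lists are given names \code{c1, c2, ...}.
#' @param free character vector of observed variables not forming any
#'   composite (default none).
#' @return an object of class \code{"composite_spec"} with components
#'   \code{blocks}, \code{free}, \code{indicators} (all variable names in
#'   canonical order: block indicators first, then free variables),
#'   \code{J} (number of composites) and \code{K} (total variable count).
#' @examples
#' spec <- composite_spec(list(c1 = c("x11", "x12", "x13"),
#'                             c2 = c("x21", "x22", "x23")))
#' spec
#' composite_spec(list(c = c("x1", "x2")), free = c("y", "z"))
#' @seealso [degrees_of_freedom()], [cca()]
#' @export
composite_spec <- function(blocks, free = character()) {
  if (!is.list(blocks) || length(blocks) < 1L)
    stop("'blocks' must be a non-empty list of indicator name vectors")
  blocks <- lapply(blocks, as.character)
  if (is.null(names(blocks)) || any(!nzchar(names(blocks))))
    names(blocks) <- paste0("c", seq_along(blocks))
  if (anyDuplicated(names(blocks)))
    stop("block names must be unique")
  if (any(vapply(blocks, length, 1L) < 1L))
    stop("every block needs at least one indicator")
  free <- as.character(free)
  all_names <- c(unlist(blocks, use.names = FALSE), free)
  if (anyDuplicated(all_names)) {
    dup <- unique(all_names[duplicated(all_names)])
    stop("variable(s) assigned more than once: ", paste(dup, collapse = ", "))
  }
  if (any(free %in% names(blocks)))
    stop("free variable names clash with block names")
  structure(list(blocks = blocks, free = free, indicators = all_names,
                 J = length(blocks), K = length(all_names)),
            class = "composite_spec")
}

#' @export
print.composite_spec <- function(x, ...) {
  cat("Composite model:", x$J,
      if (x$J == 1L) "composite," else "composites,",
      x$K, "observed variables\n")
  for (nm in names(x$blocks))
    cat("  ", nm, " <- ", paste(x$blocks[[nm]], collapse = " + "), "\n",
        sep = "")
  if (length(x$free))
    cat("  free: ", paste(x$free, collapse = ", "), "\n", sep = "")
  invisible(x)
}

# All blocks including free variables as singleton blocks, as integer column
# indices into the canonical variable order. Free variables enter estimation
# and the model-implied matrix as single-indicator composites with weight 1;
# only the df count treats them separately.
all_block_index <- function(spec) {
  idx <- integer(0)
  out <- list()
  pos <- 0L
  for (nm in names(spec$blocks)) {
    k <- length(spec$blocks[[nm]])
    out[[nm]] <- pos + seq_len(k)
    pos <- pos + k
  }
  for (v in spec$free) {
    pos <- pos + 1L
    out[[v]] <- pos
  }
  out
}

as_composite_spec <- function(x) {
  if (!inherits(x, "composite_spec"))
    stop("expected a 'composite_spec' object; see composite_spec()")
  x
}

#' Count degrees of freedom of a composite model
#'
#' The degrees of freedom equal the number of non-redundant off-diagonal
#' elements of the indicator covariance matrix minus the number of free
#' model parameters: free composite correlations, covariances between
#' composites and free variables, covariances among free variables, free
#' off-diagonal intra-block covariances, and weights; one weight per block
#' is redundant because composite variances are fixed at one, so the number
#' of blocks is added back.
#'
#' @param spec a [composite_spec()].
#' @return an object of class \code{"cca_identification"}: list with
#'   \code{df}, \code{status} (\code{"under-identified"},
#'   \code{"just-identified"} or \code{"over-identified"}),
#'   \code{isolated_blocks}, and \code{terms}, the named seven-term
#'   breakdown of the count.
#' @examples
#' # one composite of two indicators plus two free variables: df = 1
#' degrees_of_freedom(composite_spec(list(c = c("x1", "x2")),
#'                                   free = c("y", "z")))
#' @seealso [check_identification()]
#' @export
degrees_of_freedom <- function(spec) {
  spec <- as_composite_spec(spec)
  K <- spec$K
  J <- spec$J
  kj <- vapply(spec$blocks, length, 1L)
  nfree <- length(spec$free)
  terms <- c(
    nonredundant       = (K * (K - 1L)) %/% 2L,
    composite_corr     = (J * (J - 1L)) %/% 2L,
    composite_free_cov = J * nfree,
    free_free_cov      = (nfree * (nfree - 1L)) %/% 2L,
    intra_block        = sum(kj * (kj - 1L)) %/% 2L,
    weights            = sum(kj),
    blocks             = J
  )
  df <- terms[["nonredundant"]] - terms[["composite_corr"]] -
    terms[["composite_free_cov"]] - terms[["free_free_cov"]] -
    terms[["intra_block"]] - terms[["weights"]] + terms[["blocks"]]
  identification_report(spec, df, terms, isolated = structural_isolation(spec))
}

# A block is structurally isolated when there is nothing else in the model
# it could correlate with (single composite, no free variables).
structural_isolation <- function(spec) {
  if (spec$J == 1L && length(spec$free) == 0L) names(spec$blocks) else character()
}

identification_report <- function(spec, df, terms, isolated) {
  status <- if (df < 0L || length(isolated)) "under-identified"
  else if (df == 0L) "just-identified"
  else "over-identified"
  structure(list(df = as.integer(df), status = status,
                 isolated_blocks = isolated, terms = terms),
            class = "cca_identification")
}

#' @export
print.cca_identification <- function(x, ...) {
  cat("Composite model identification\n")
  cat("  degrees of freedom:", x$df, "\n")
  t <- x$terms
  cat(sprintf("    = %d - %d - %d - %d - %d - %d + %d\n",
              t[["nonredundant"]], t[["composite_corr"]],
              t[["composite_free_cov"]], t[["free_free_cov"]],
              t[["intra_block"]], t[["weights"]], t[["blocks"]]))
  cat("  status:", x$status, "\n")
  if (length(x$isolated_blocks))
    cat("  isolated composite(s):",
        paste(x$isolated_blocks, collapse = ", "),
        "- weights not uniquely retrievable\n")
  invisible(x)
}

#' Check identification of a composite model
#'
#' Combines the degrees-of-freedom count with the non-isolation condition:
#' every composite must be connected to (correlate with) at least one other
#' composite or free variable, otherwise its weights cannot be uniquely
#' retrieved from the indicator covariance matrix. When a covariance matrix
#' is supplied, isolation is checked numerically (all inter-block
#' covariances of a block zero); otherwise only structural isolation (a
#' single composite with no free variables) can be detected.
#'
#' @param spec a [composite_spec()].
#' @param sigma optional K x K indicator covariance/correlation matrix with
#'   columns in the order of \code{spec$indicators} (or named).
#' @param tol entries below \code{tol} in absolute value count as zero.
#' @return a \code{"cca_identification"} report; isolation is reported, not
#'   thrown as an error.
#' @export
check_identification <- function(spec, sigma = NULL, tol = 1e-12) {
  spec <- as_composite_spec(spec)
  rep0 <- degrees_of_freedom(spec)
  isolated <- rep0$isolated_blocks
  if (!is.null(sigma)) {
    sigma <- check_sigma_names(sigma, spec)
    bidx <- all_block_index(spec)
    isolated <- character()
    for (nm in names(spec$blocks)) {
      b <- bidx[[nm]]
      others <- setdiff(seq_len(spec$K), b)
      if (length(others) == 0L || all(abs(sigma[b, others]) < tol))
        isolated <- c(isolated, nm)
    }
  }
  identification_report(spec, rep0$df, rep0$terms, isolated)
}

# reorder a square matrix to the model's canonical variable order
check_sigma_names <- function(sigma, spec) {
  if (!is.matrix(sigma) || nrow(sigma) != ncol(sigma))
    stop("'sigma' must be a square matrix")
  if (!is.null(colnames(sigma))) {
    miss <- setdiff(spec$indicators, colnames(sigma))
    if (length(miss))
      stop("matrix lacks column(s): ", paste(miss, collapse = ", "))
    sigma <- sigma[spec$indicators, spec$indicators, drop = FALSE]
  } else if (nrow(sigma) != spec$K) {
    stop("matrix dimension ", nrow(sigma), " does not match the ",
         spec$K, " variables of the model")
  } else {
    dimnames(sigma) <- list(spec$indicators, spec$indicators)
  }
  if (!isSymmetric(unname(sigma), tol = 1e-8))
    stop("'sigma' must be symmetric")
  sigma
}
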