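#' Read and write composite model configuration files
#'
#' The model configuration is a YAML file with a \code{blocks} mapping
#' (block name to list of indicator names), an optional \code{free} list
#' of observed variables not forming a composite, and optionally a
#' \code{population} section with \code{weights} (per block),
#' \code{composite_corr} (J x J, row-major list of rows),
#' \code{intra_block_corr} (per block) and \code{free_var_corr}
#' (F x (J + F), rows over free variables):
#'
#' \preformatted{
#' blocks:
#'   c1: [x11, x12, x13]
#'   c2: [x21, x22, x23]
#' free: [y, z]
#' }
#'
#' Writing a spec and reading it back yields an identical specification.
#'
#' @param path file path.
#' @return \code{read_cca_model}: a [composite_spec()]; when the file has a
#'   \code{population} section, the corresponding
#'   [composite_population()] is attached as attribute
#'   \code{"population"}.
#' @export
read_cca_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  cfg <- yaml::read_yaml(path)
  known <- c("blocks", "free", "population")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("unknown key(s) in ", path, ": ", paste(unknown, collapse = ", "),
         " (expected: ", paste(known, collapse = ", "), ")")
  if (is.null(cfg$blocks) || !length(cfg$blocks))
    stop("model file ", path, " has no (or an empty) 'blocks' section")
  spec <- composite_spec(cfg$blocks, free = as.character(cfg$free))
  if (!is.null(cfg$population)) {
    p <- cfg$population
    pop <- composite_population(
      spec,
      weights = lapply(p$weights, as.numeric),
      composite_corr = list_to_matrix(p$composite_corr, "composite_corr"),
      intra_block_corr = lapply(p$intra_block_corr, list_to_matrix,
                                what = "intra_block_corr"),
      free_var_corr = if (!is.null(p$free_var_corr))
        list_to_matrix(p$free_var_corr, "free_var_corr"))
    attr(spec, "population") <- pop
  }
  spec
}

list_to_matrix <- function(x, what) {
  if (is.matrix(x)) return(x)
  rows <- lapply(x, as.numeric)
  len <- unique(vapply(rows, length, 1L))
  if (length(len) != 1L)
    stop("'", what, "' rows have unequal lengths")
  do.call(rbind, rows)
}

#' @rdname read_cca_model
#' @param spec a [composite_spec()] to serialize.
#' @export
write_cca_model <- function(spec, path) {
  spec <- as_composite_spec(spec)
  out <- list(blocks = spec$blocks)
  if (length(spec$free)) out$free <- spec$free
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Read an indicator data table
#'
#' Reads a delimited text file (comma, tab or semicolon separated; header
#' row required), checks that every variable of the model is present and
#' numeric with no missing entries, and returns the columns in the model's
#' canonical order.
#'
#' @param path file path.
#' @param spec a [composite_spec()].
#' @return numeric N x K matrix with N > K guaranteed.
#' @export
read_cca_data <- function(path, spec) {
  spec <- as_composite_spec(spec)
  if (!file.exists(path)) stop("data file not found: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else if (grepl(";", first)) ";" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(spec$indicators, names(df))
  if (length(miss))
    stop("data file ", path, " lacks column(s): ",
         paste(miss, collapse = ", "))
  df <- df[spec$indicators]
  notnum <- names(df)[!vapply(df, is.numeric, TRUE)]
  if (length(notnum))
    stop("non-numeric column(s): ", paste(notnum, collapse = ", "))
  x <- as.matrix(df)
  if (anyNA(x)) {
    idx <- which(is.na(x), arr.ind = TRUE)[1, ]
    stop("missing value at row ", idx[1], ", column '",
         colnames(x)[idx[2]], "'")
  }
  if (nrow(x) <= spec$K)
    stop("need more observations (", nrow(x), ") than variables (",
         spec$K, ")")
  x
}

#' Serialize results to machine-readable reports
#'
#' Writes a fitted model, bootstrap fit test or Monte Carlo study result
#' to disk: JSON for model fits and fit tests, CSV (long format, one row
#' per model/n/alpha/measure) or JSON for study results. Reports carry the
#' seed and configuration needed to reproduce them.
#'
#' @param result a \code{"cca"}, \code{"cca_boot_test"} or
#'   \code{"cca_sim"} object.
#' @param path output file path.
#' @param format \code{"json"} or (for \code{"cca_sim"}) \code{"csv"}.
#' @param seed optional seed to record in the report.
#' @return \code{path}, invisibly.
#' @export
write_cca_report <- function(result, path, format = c("json", "csv"),
                             seed = NULL) {
  format <- match.arg(format)
  if (inherits(result, "cca_sim") && format == "csv") {
    utils::write.csv(as.data.frame(result), path, row.names = FALSE)
    return(invisible(path))
  }
  payload <- report_payload(result)
  payload$version <- as.character(utils::packageVersion("ccasem"))
  if (!is.null(seed)) payload$seed <- seed
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

report_payload <- function(result) {
  if (inherits(result, "cca")) {
    list(type = "fit",
         n = result$n,
         blocks = result$spec$blocks,
         free = result$spec$free,
         weights = lapply(result$weights, unname),
         loadings = lapply(result$loadings, unname),
         composite_corr = matrix_to_list(result$composite_corr),
         sigma_hat = matrix_to_list(result$sigma_hat),
         df = result$identification$df,
         status = result$identification$status)
  } else if (inherits(result, "cca_boot_test")) {
    list(type = "fit_test",
         alpha = result$alpha, B = result$B,
         observed = as.list(result$observed),
         p_values = as.list(result$p_values),
         quantiles = as.list(result$quantiles),
         rejected = as.list(result$rejected),
         n_failed = result$n_failed)
  } else if (inherits(result, "cca_sim")) {
    cfg <- attr(result, "config")
    list(type = "simulation", config = cfg,
         table = as.data.frame(result))
  } else stop("unsupported result type: ", paste(class(result), collapse = "/"))
}

matrix_to_list <- function(m) {
  out <- lapply(seq_len(nrow(m)), function(i) unname(m[i, ]))
  names(out) <- rownames(m)
  out
}

#' Parse a bootstrap fit-test report back into R
#'
#' Inverse of [write_cca_report()] for \code{"cca_boot_test"} results
#' (numeric content only; the reference distribution is not serialized).
#'
#' @param path JSON report path.
#' @return named list mirroring the report.
#' @export
read_cca_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
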