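# Delimited-text readers/writers and JSON report serialization for the
# command-line interface.

#' Read a dataset from delimited text
#'
#' Expects a header row; the named response column becomes `y` and every other
#' column a predictor. Non-numeric or missing cells are rejected with the
#' offending row and column named.
#'
#' @param path file path (CSV; a tab-separated file is detected by extension
#'   `.tsv`).
#' @param response name of the response column.
#' @param role,id passed to [ptlr_dataset()].
#' @return a [ptlr_dataset()].
#' @export
read_dataset <- function(path, response, role = "target", id = NA_integer_) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- read.csv(path, sep = sep, check.names = FALSE)
  if (nrow(df) == 0) stop("no data rows in ", path)
  if (!response %in% names(df)) {
    stop("response column '", response, "' not found in ", path)
  }
  for (cn in names(df)) {
    col <- df[[cn]]
    if (!is.numeric(col)) {
      bad <- which(is.na(suppressWarnings(as.numeric(as.character(col)))))[1]
      stop("non-numeric value in column '", cn, "', row ",
           if (is.na(bad)) "?" else bad)
    }
    if (anyNA(col)) {
      stop("missing value in column '", cn, "', row ", which(is.na(col))[1])
    }
  }
  y <- df[[response]]
  X <- as.matrix(df[setdiff(names(df), response)])
  ptlr_dataset(X, y, role = role, id = id)
}

#' Write a dataset to CSV
#'
#' @param data a [ptlr_dataset()].
#' @param path output file.
#' @param response name for the response column.
#' @export
write_dataset <- function(data, path, response = "y") {
  X <- data$X
  cn <- colnames(X)
  if (is.null(cn)) cn <- paste0("x", seq_len(ncol(X)))
  df <- as.data.frame(X)
  names(df) <- cn
  df[[response]] <- data$y
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

sparse_coef <- function(beta) {
  idx <- which(beta != 0)
  list(index = idx, value = signif(beta[idx], 12))
}

report_payload <- function(result, seed) {
  meta <- list(package = "transptlr",
               version = as.character(packageVersion("transptlr")),
               seed = seed)
  if (inherits(result, "ptlr_fit")) {
    c(meta, list(
      type = "fit", family = result$family, p = result$p, n = result$n,
      beta = sparse_coef(result$beta), intercept = result$intercept,
      sigma2 = signif(result$sigma2, 12),
      nu = if (all(is.infinite(result$nu))) "Inf" else signif(result$nu, 12),
      lambda = signif(result$lambda, 12),
      loglik = signif(result$loglik, 12),
      penalized_obj = signif(result$penalized_obj, 12),
      n_iter = result$n_iter, converged = result$converged))
  } else if (inherits(result, "transfer_result")) {
    c(meta, list(
      type = "transfer", family = result$family,
      detected_set = as.integer(result$detected_set),
      beta_TL = sparse_coef(result$beta_TL),
      offsets = lapply(result$offsets, function(o) {
        list(source_id = o$source_id, delta = sparse_coef(o$delta_hat),
             lambda_delta = signif(o$lambda_delta, 12))
      }),
      stats = result$stats))
  } else {
    stop("unsupported result type: ", paste(class(result), collapse = "/"))
  }
}

#' Serialize a result to disk
#'
#' Model objects (`ptlr_fit`, `transfer_result`) are written as JSON with a
#' sparse index/value encoding of the coefficients; data frames (benchmark
#' tables) are written as CSV. JSON numbers are fixed to 12 significant
#' digits, so repeated runs with the same seed produce byte-identical files.
#'
#' @param result a `ptlr_fit`, `transfer_result` or data.frame.
#' @param path output file.
#' @param seed seed to record in the report.
#' @export
write_report <- function(result, path, seed = NA_integer_) {
  if (is.data.frame(result)) {
    write.csv(result, path, row.names = FALSE)
  } else {
    jsonlite::write_json(report_payload(result, seed), path,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "rows")
  }
  invisible(path)
}
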