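#' Construct a probe-by-sample expression matrix
#'
#' Light validating constructor for the container used throughout the
#' pipeline: a numeric matrix of log2 intensities with unique probe-set ids
#' as rownames and unique sample ids as colnames (the shape of an
#' RMA-summarized microarray dataset).
#'
#' @param values Numeric matrix, probes in rows, samples in columns, log2
#'   intensity units. Must carry rownames and colnames.
#' @return The validated matrix, of class `c("expr_matrix", "matrix")`.
#' @export
expression_matrix <- function(values) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  probes <- rownames(values)
  samples <- colnames(values)
  if (is.null(probes) || is.null(samples)) {
    stop("expression matrix needs probe rownames and sample colnames",
         call. = FALSE)
  }
  if (anyDuplicated(probes)) {
    stop("duplicate probe ids: ",
         paste(unique(probes[duplicated(probes)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(samples)) {
    stop("duplicate sample ids: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(values)) stop("expression matrix contains missing values", call. = FALSE)
  class(values) <- c("expr_matrix", class(unclass(values)))
  values
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expression matrix: %d probes x %d samples (log2 scale)\n",
              nrow(x), ncol(x)))
  cat("probes:", paste(head(rownames(x), 4), collapse = ", "),
      if (nrow(x) > 4) "..." else "", "\n")
  cat("samples:", paste(head(colnames(x), 4), collapse = ", "),
      if (ncol(x) > 4) "..." else "", "\n")
  invisible(x)
}

# keep the class when subsetting with drop = FALSE
#' @export
`[.expr_matrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = drop)
  if (is.matrix(out)) class(out) <- c("expr_matrix", class(unclass(out)))
  out
}

#' Write / read an expression matrix as tab-separated text
#'
#' Plain TSV with a `probe_id` first column and one column per sample.
#' The round trip is lossless to printed precision (15 significant digits).
#'
#' @param matrix An [expression_matrix()].
#' @param path File path.
#' @return `write_expression_tsv` returns `path` invisibly;
#'   `read_expression_tsv` returns an [expression_matrix()].
#' @export
write_expression_tsv <- function(matrix, path) {
  df <- data.frame(probe_id = rownames(matrix),
                   signif(unclass(matrix), 15),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path) {
  df <- tryCatch(
    read.delim(path, check.names = FALSE, stringsAsFactors = FALSE),
    error = function(e) stop("failed to parse ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  if (names(df)[1] != "probe_id") {
    stop("expected header starting with 'probe_id' in ", path, call. = FALSE)
  }
  probes <- as.character(df[[1]])
  if (anyDuplicated(probes)) {
    stop("duplicate probe id in ", path, ": ",
         probes[duplicated(probes)][1], call. = FALSE)
  }
  samples <- names(df)[-1]
  if (anyDuplicated(samples)) {
    stop("duplicate sample id in ", path, ": ",
         samples[duplicated(samples)][1], call. = FALSE)
  }
  vals <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(vals)) stop("non-numeric expression values in ", path, call. = FALSE)
  rownames(vals) <- probes
  expression_matrix(vals)
}
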