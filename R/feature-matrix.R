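#' Feature matrices and schemas
#'
#' A feature matrix is a numeric matrix (rows = islands, columns = features)
#' whose column names follow the `<class>.<feature>` convention and which
#' carries a `schema` attribute: a data frame with columns `class` and
#' `name`, one row per feature, in the fixed order of the 15 feature
#' classes. All values must be finite.
#'
#' @param mat Numeric matrix with column names.
#' @param schema Data frame with columns `class`, `name` (one row per
#'   matrix column, same order).
#' @return The matrix with class `cgi_features` and the schema attached.
#' @export
feature_matrix <- function(mat, schema) {
  stopifnot(is.matrix(mat), is.data.frame(schema),
            ncol(mat) == nrow(schema),
            all(c("class", "name") %in% names(schema)))
  if (!all(is.finite(mat))) stop("feature matrix contains non-finite values")
  colnames(mat) <- paste(schema$class, schema$name, sep = ".")
  attr(mat, "schema") <- schema
  class(mat) <- c("cgi_features", class(mat))
  mat
}

#' Schema of a feature matrix
#' @param x A `cgi_features` matrix.
#' @return Schema data frame.
#' @export
feature_schema <- function(x) attr(x, "schema")

#' Per-class feature counts of a schema
#' @param x A `cgi_features` matrix or schema data frame.
#' @return Named integer vector (class -> width), in schema order.
#' @export
class_widths <- function(x) {
  schema <- if (is.data.frame(x)) x else feature_schema(x)
  cls <- unique(schema$class)
  stats::setNames(vapply(cls, function(k) sum(schema$class == k),
                         integer(1)), cls)
}

#' Write a feature matrix to disk
#'
#' Dialect `"tsv"` writes a header of feature names, an `id` column, an
#' optional `label` column and one row per island at full precision.
#' Dialect `"sparse"` writes svmlight-style lines: the label followed by
#' `index:value` pairs (1-based, ascending) for all nonzero entries.
#'
#' @param mat `cgi_features` matrix (or plain numeric matrix).
#' @param labels Optional vector (numeric or factor) of labels, one per row.
#' @param path Output path.
#' @param dialect `"tsv"` or `"sparse"`.
#' @return Invisibly, `path`.
#' @export
write_feature_matrix <- function(mat, labels = NULL, path,
                                 dialect = c("tsv", "sparse")) {
  dialect <- match.arg(dialect)
  if (!is.null(labels) && length(labels) != nrow(mat))
    stop("labels length must match number of rows")
  if (dialect == "tsv") {
    df <- data.frame(id = if (is.null(rownames(mat))) seq_len(nrow(mat))
                          else rownames(mat),
                     stringsAsFactors = FALSE)
    if (!is.null(labels)) df$label <- labels
    df <- cbind(df, as.data.frame(unclass(mat)))
    colnames(df)[-seq_len(ncol(df) - ncol(mat))] <- colnames(mat)
    data.table::fwrite(df, path, sep = "\t", quote = FALSE)
  } else {
    if (is.null(labels)) labels <- rep(0, nrow(mat))
    y <- if (is.factor(labels)) {
      ifelse(labels == "methylated", 1L, -1L)
    } else labels
    con <- file(path, "w")
    on.exit(close(con))
    for (i in seq_len(nrow(mat))) {
      nz <- which(mat[i, ] != 0)
      pairs <- if (length(nz))
        paste(nz, vapply(mat[i, nz], format, character(1), trim = TRUE,
                         digits = 12),
              sep = ":", collapse = " ") else ""
      writeLines(trimws(paste(y[i], pairs)), con)
    }
  }
  invisible(path)
}

#' Read a TSV feature matrix written by [write_feature_matrix()]
#'
#' @param path File path.
#' @return List with `mat` (numeric matrix, feature names as columns, ids as
#'   rownames) and `labels` (or `NULL`).
#' @export
read_feature_matrix <- function(path) {
  df <- data.table::fread(path, sep = "\t", data.table = FALSE)
  ids <- df$id
  labels <- if ("label" %in% names(df)) df$label else NULL
  keep <- setdiff(names(df), c("id", "label"))
  mat <- as.matrix(df[, keep, drop = FALSE])
  rownames(mat) <- ids
  list(mat = mat, labels = labels)
}
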