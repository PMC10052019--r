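#' Feature-table container
#'
#' A `feature_table` is a data frame whose first two columns are
#' `patient_id` and binary `label` (RO = 0, ccRCC = 1), followed by feature
#' columns keyed by rendered feature names (see [render_feature_name()]).
#' A `provenance` attribute carries the extraction/simulation configuration
#' and a content hash, used to refuse comparisons between results computed
#' on different tables.
#'
#' @param df Data frame with `patient_id`, `label`, then numeric features.
#' @param provenance List of provenance fields; a `hash` of the data is
#'   appended automatically.
#' @return A `feature_table`.
#' @export
new_feature_table <- function(df, provenance = list()) {
  stopifnot(is.data.frame(df),
            identical(names(df)[1:2], c("patient_id", "label")))
  if (anyNA(df$label)) stop("label present for every row is required")
  df$label <- as_binary_labels(df$label)
  if (anyDuplicated(names(df))) stop("duplicate column names")
  provenance$hash <- content_hash(list(names(df), df$label, dim(df)))
  attr(df, "provenance") <- provenance
  class(df) <- c("feature_table", "data.frame")
  df
}

#' @rdname new_feature_table
#' @param table A `feature_table`.
#' @export
ft_features <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  as.matrix(table[, -(1:2), drop = FALSE])
}

#' @rdname new_feature_table
#' @export
ft_labels <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  table$label
}

#' @rdname new_feature_table
#' @export
ft_provenance <- function(table) attr(table, "provenance", exact = TRUE)

#' Restrict a feature table to a set of rows
#'
#' Subsets rows while keeping class and provenance, and records the split
#' role (`"train"` / `"test"` / `"full"`) so downstream stages can assert
#' they were handed the data partition they are allowed to see.
#'
#' @param table A `feature_table`.
#' @param rows Integer row indices.
#' @param role Split role recorded on the result.
#' @return A `feature_table` with attribute `split_role` and `row_ids`.
#' @export
ft_restrict <- function(table, rows, role = "full") {
  prov <- ft_provenance(table)
  out <- as.data.frame(table)[rows, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("feature_table", "data.frame")
  attr(out, "provenance") <- prov
  attr(out, "split_role") <- role
  attr(out, "row_ids") <- table$patient_id[rows]
  out
}

#' Drop feature columns containing non-finite values
#'
#' Radiomic extractions occasionally produce NaN/Inf (degenerate regions,
#' zero denominators). Any column containing a non-finite value is dropped
#' and reported via `message()`; constant columns are retained — the GA may
#' still select them and the tree simply never splits on them. Row order is
#' preserved.
#'
#' @param table A `feature_table`.
#' @return The cleaned `feature_table`.
#' @export
clean_table <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  X <- ft_features(table)
  bad <- colnames(X)[!apply(is.finite(X), 2L, all)]
  if (length(bad) == ncol(X)) stop("cleaning removed every feature column")
  if (length(bad)) {
    message("clean_table: dropping ", length(bad),
            " column(s) with non-finite values")
    keep <- setdiff(names(table), bad)
    out <- as.data.frame(table)[, keep, drop = FALSE]
    class(out) <- c("feature_table", "data.frame")
    attr(out, "provenance") <- c(ft_provenance(table),
                                 list(dropped_columns = bad))
    return(out)
  }
  table
}

#' Read / write feature tables as CSV
#'
#' Layout: first column `patient_id`, second `label`, remaining columns
#' rendered feature names.
#'
#' @param table A `feature_table`.
#' @param path CSV path.
#' @export
write_feature_table <- function(table, path) {
  stopifnot(inherits(table, "feature_table"))
  write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  new_feature_table(df, provenance = list(source = path))
}
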