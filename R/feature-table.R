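#' Load a molecular-descriptor table from delimited text
#'
#' Expects a header row of descriptor names and a first column of chemical
#' identifiers. Descriptor values are coerced to numeric; cells that are
#' empty or non-numeric (e.g. a calculator's error strings) become `NA`
#' missing markers so that the completeness filter can see them.
#'
#' @param path path to a CSV (or other single-character-delimited) file.
#' @param sep field separator (default ",").
#' @return data.frame of numeric descriptor columns with chemical
#'   identifiers as row names; column order as in the file.
#' @export
load_descriptor_table <- function(path, sep = ",") {
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE, comment.char = "",
                           quote = "\"")
  if (nrow(raw) == 0L || ncol(raw) < 2L) {
    stop("descriptor file must have an identifier column, at least one descriptor column and at least one row: ", path)
  }
  ids <- raw[[1]]
  if (anyDuplicated(ids)) {
    stop("duplicate chemical identifiers in descriptor table: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  vals <- raw[, -1, drop = FALSE]
  vals[] <- lapply(vals, function(col) suppressWarnings(as.numeric(col)))
  rownames(vals) <- ids
  vals
}

#' Keep only descriptors with no missing value for any chemical
#'
#' Mirrors the descriptor-set construction used upstream of the models:
#' from the full calculator output, only columns computed successfully for
#' the entire dataset are retained as input features. Rows are unchanged;
#' retained values are untouched; column order is preserved.
#'
#' @param table data.frame of numeric descriptor columns (chemicals as rows).
#' @return the sub-table of complete columns.
#' @export
filter_complete_descriptors <- function(table) {
  stopifnot(is.data.frame(table))
  complete <- vapply(table, function(col) !anyNA(col), logical(1))
  if (!any(complete)) {
    stop("no descriptor column is complete across all chemicals; no usable features")
  }
  table[, complete, drop = FALSE]
}

#' Standardize descriptor tables using training-set statistics
#'
#' Centers and scales every column to training mean 0 and sample
#' (n-1 denominator) standard deviation 1. Statistics are computed on the
#' training table only and applied unchanged to any additional tables, so
#' no information leaks from held-out rows. Constant columns (sd = 0) are
#' mapped to all zeros.
#'
#' @param train data.frame of complete numeric descriptors, >= 2 rows.
#' @param ... further tables with the same columns (e.g. a test split).
#' @return list with `train`, `others` (list of transformed extra tables),
#'   `center` and `scale` (named numeric vectors of training statistics;
#'   `scale` keeps the raw sd, 0 for constant columns).
#' @export
standardize_features <- function(train, ...) {
  stopifnot(is.data.frame(train), nrow(train) >= 2L)
  center <- vapply(train, mean, numeric(1))
  scale <- vapply(train, stats::sd, numeric(1))
  apply_stats <- function(tab) {
    stopifnot(identical(colnames(tab), colnames(train)))
    out <- tab
    for (j in seq_along(out)) {
      out[[j]] <- if (scale[j] > 0) (tab[[j]] - center[j]) / scale[j] else
        rep(0, nrow(tab))
    }
    out
  }
  others <- lapply(list(...), apply_stats)
  list(train = apply_stats(train), others = others,
       center = center, scale = scale)
}
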