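#' Build the fixed 94-character ASCII SMILES dictionary
#'
#' Maps every printable, non-space ASCII character (codes 33..126) to a
#' consecutive integer index starting at 1, so that `index(c) = code(c) - 32`
#' for all 94 characters. Because the dictionary covers the full printable
#' ASCII range, any character that can legally occur in a SMILES string in
#' any dialect receives an index; index 0 is reserved for padding.
#'
#' @return An object of class `char_dictionary`: a list with
#'   `index` (named integer vector, character -> index 1..94),
#'   `char` (character vector, position i holds the character with index i),
#'   and `size` (94).
#' @examples
#' d <- build_vocabulary()
#' d$index[["C"]]  # 35
#' d$char[46]      # "N"
#' @export
build_vocabulary <- function() {
  codes <- 33:126
  chars <- vapply(codes, function(k) rawToChar(as.raw(k)), character(1))
  idx <- codes - 32L
  names(idx) <- chars
  structure(list(index = idx, char = chars, size = 94L),
            class = "char_dictionary")
}

#' @export
print.char_dictionary <- function(x, ...) {
  cat("SMILES character dictionary: ", x$size,
      " printable ASCII characters ('", x$char[1], "' .. '",
      x$char[x$size], "'), indices 1..", x$size, "\n", sep = "")
  invisible(x)
}

#' Encode one SMILES string as a fixed-length integer index vector
#'
#' Each character is replaced by its dictionary index; the result is
#' right-padded with zeros (or truncated, keeping the first `max_len`
#' characters) to constant length. Surrounding whitespace is stripped;
#' any interior character outside ASCII 33..126 is an error.
#'
#' @param smiles a single SMILES string.
#' @param dict a `char_dictionary` from [build_vocabulary()].
#' @param max_len fixed output length L (default 325).
#' @return An object of class `encoded_smiles`: integer vector of length
#'   `max_len` with attribute `original_length` (the number of encoded
#'   characters before padding, after any truncation).
#' @examples
#' e <- encode_smiles("C=CC#N")
#' e[1:6]  # 35 29 35 35 3 46
#' @export
encode_smiles <- function(smiles, dict = build_vocabulary(), max_len = 325L) {
  stopifnot(is.character(smiles), length(smiles) == 1L, !is.na(smiles))
  max_len <- as.integer(max_len)
  s <- gsub("^[[:space:]]+|[[:space:]]+$", "", smiles)
  out <- integer(max_len)
  if (nchar(s) == 0L) {
    attr(out, "original_length") <- 0L
    class(out) <- "encoded_smiles"
    return(out)
  }
  codes <- utf8ToInt(s)
  bad <- which(codes < 33L | codes > 126L)
  if (length(bad) > 0L) {
    stop(sprintf(
      "invalid character '%s' (code %d) at position %d: only ASCII 33..126 is encodable",
      intToUtf8(codes[bad[1]]), codes[bad[1]], bad[1]))
  }
  idx <- codes - 32L
  n <- min(length(idx), max_len)
  out[seq_len(n)] <- idx[seq_len(n)]
  attr(out, "original_length") <- n
  class(out) <- "encoded_smiles"
  out
}

#' Encode a list of SMILES strings as a K x L integer matrix
#'
#' Row i is `encode_smiles(smiles[i])`; input order is preserved.
#'
#' @param smiles character vector of SMILES strings (may be empty).
#' @inheritParams encode_smiles
#' @return integer matrix of dimension `length(smiles)` x `max_len`, with
#'   attribute `original_length` (integer vector of per-row token counts).
#' @export
encode_batch <- function(smiles, dict = build_vocabulary(), max_len = 325L) {
  stopifnot(is.character(smiles))
  max_len <- as.integer(max_len)
  k <- length(smiles)
  m <- matrix(0L, nrow = k, ncol = max_len)
  ol <- integer(k)
  for (i in seq_len(k)) {
    e <- tryCatch(encode_smiles(smiles[i], dict, max_len),
                  error = function(err) {
                    stop(sprintf("row %d: %s", i, conditionMessage(err)),
                         call. = FALSE)
                  })
    m[i, ] <- as.integer(e)
    ol[i] <- attr(e, "original_length")
  }
  attr(m, "original_length") <- ol
  m
}

#' Decode an index vector back to a SMILES string
#'
#' Inverse of [encode_smiles()] on the unpadded prefix: nonzero leading
#' entries are mapped back through the dictionary; decoding stops at the
#' first 0 (padding).
#'
#' @param indices integer vector with entries in 0..94.
#' @param dict a `char_dictionary`.
#' @return A single string.
#' @export
decode_indices <- function(indices, dict = build_vocabulary()) {
  idx <- as.integer(indices)
  if (any(idx < 0L | idx > dict$size, na.rm = TRUE)) {
    bad <- idx[which(idx < 0L | idx > dict$size)[1]]
    stop(sprintf("invalid index %d: indices must lie in 0..%d", bad, dict$size))
  }
  zero <- which(idx == 0L)
  n <- if (length(zero) > 0L) zero[1] - 1L else length(idx)
  if (n == 0L) return("")
  paste(dict$char[idx[seq_len(n)]], collapse = "")
}

#' Legacy training-set one-hot SMILES encoder
#'
#' Reproduces the earlier vectorization scheme that the fixed ASCII
#' dictionary replaces: a dictionary is built from the distinct characters
#' of the *training* SMILES only (indexed in order of first appearance),
#' and each character of `smiles` becomes a length-M one-hot row. A
#' character absent from the training dictionary is skipped and
#' contributes no row; remaining rows up to `max_len` are zero.
#'
#' @param train_smiles non-empty character vector of training SMILES.
#' @param smiles single SMILES string to encode.
#' @param max_len fixed number of output rows (default 325).
#' @return `max_len` x M binary matrix with the dictionary as a named
#'   integer vector in attribute `dictionary`.
#' @examples
#' m <- legacy_onehot_encode(c("C=CC=C", "O=CC"), "C=CC#N")
#' attr(m, "dictionary")  # C=1, "="=2, O=3
#' @export
legacy_onehot_encode <- function(train_smiles, smiles, max_len = 325L) {
  dict <- legacy_dictionary(train_smiles)
  max_len <- as.integer(max_len)
  m <- length(dict)
  out <- matrix(0L, nrow = max_len, ncol = m)
  chars <- strsplit(smiles, "")[[1]]
  keep <- chars[chars %in% names(dict)]
  n <- min(length(keep), max_len)
  if (n > 0L) {
    rows <- seq_len(n)
    out[cbind(rows, dict[keep[rows]])] <- 1L
  }
  attr(out, "dictionary") <- dict
  out
}

#' Build the legacy training-set character dictionary
#'
#' @param train_smiles non-empty character vector of training SMILES.
#' @return named integer vector mapping each distinct training character,
#'   in order of first appearance, to 1..M.
#' @export
legacy_dictionary <- function(train_smiles) {
  if (length(train_smiles) == 0L || all(!nzchar(train_smiles))) {
    stop("legacy dictionary requires a non-empty training SMILES set")
  }
  chars <- unlist(strsplit(paste(train_smiles, collapse = ""), ""))
  u <- unique(chars)
  idx <- seq_along(u)
  names(idx) <- u
  idx
}
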