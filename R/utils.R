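#' Project a symmetric matrix to the nearest positive semi-definite matrix
#'
#' Eigenvalue clipping: negative eigenvalues are set to a small positive
#' floor and the matrix is rescaled back to unit diagonal, so the result is
#' a valid correlation matrix.
#'
#' @param m symmetric numeric matrix (intended: a correlation matrix).
#' @param eps eigenvalue floor.
#' @return a symmetric positive semi-definite matrix with unit diagonal.
#' @export
nearest_psd <- function(m, eps = 1e-10) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  m <- (m + t(m)) / 2
  e <- eigen(m, symmetric = TRUE)
  if (min(e$values) >= 0) return(m)
  v <- pmax(e$values, eps)
  out <- e$vectors %*% diag(v, nrow = length(v)) %*% t(e$vectors)
  d <- sqrt(diag(out))
  out <- out / tcrossprod(d)
  diag(out) <- 1
  (out + t(out)) / 2
}

# Case-insensitive normalization of a closed-vocabulary column. Returns the
# canonical spelling; unknown values raise an error that names the column and
# the offending 1-based row numbers.
.normalize_vocab <- function(x, vocab, column, allow_unknown = TRUE) {
  x <- trimws(as.character(x))
  lx <- tolower(x)
  full <- if (allow_unknown) c(vocab, "unknown") else vocab
  idx <- match(lx, tolower(full))
  bad <- which(is.na(idx) & !is.na(x) & nzchar(x))
  if (length(bad)) {
    stop(sprintf(
      "column '%s': value(s) %s not in {%s} (row %s)",
      column,
      paste(sQuote(unique(x[bad])), collapse = ", "),
      paste(full, collapse = ", "),
      paste(bad, collapse = ", ")
    ), call. = FALSE)
  }
  out <- full[idx]
  out[is.na(x) | !nzchar(x)] <- if (allow_unknown) "unknown" else NA_character_
  out
}

# Internal stratified index split: per class, ceiling(frac * n) indices go to
# the training set. Uses the current RNG stream (callers manage the seed).
.split_idx <- function(y, frac) {
  train <- integer(0)
  for (cl in unique(y)) {
    idx <- which(y == cl)
    if (length(idx) < 2L) {
      stop(sprintf("class '%s' has fewer than 2 records; cannot split", cl),
           call. = FALSE)
    }
    n_tr <- ceiling(frac * length(idx))
    n_tr <- min(n_tr, length(idx) - 1L)  # keep >= 1 test member
    train <- c(train, sample(idx, n_tr))
  }
  sort(train)
}
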