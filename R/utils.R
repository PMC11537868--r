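# Internal helpers shared across modules.

#' @keywords internal
#' @noRd
abmlm_log <- function(..., level = "INFO", verbose = getOption("abmlm.verbose", FALSE)) {
  if (isTRUE(verbose)) {
    message(sprintf("[%s] %s", level, paste0(...)))
  }
  invisible(NULL)
}

#' Row-wise softmax
#'
#' Numerically stable softmax applied to each row of a matrix.
#'
#' @param x numeric matrix.
#' @return matrix of the same shape; every row sums to 1.
#' @keywords internal
#' @noRd
row_softmax <- function(x) {
  m <- x[cbind(seq_len(nrow(x)), max.col(x, ties.method = "first"))]
  e <- exp(x - m)
  e / rowSums(e)
}

#' @noRd
softmax_vec <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

# stopifnot with a formatted message
#' @noRd
fail_if <- function(cond, fmt, ...) {
  if (isTRUE(cond)) stop(sprintf(fmt, ...), call. = FALSE)
  invisible(NULL)
}

#' MD5 hash of an arbitrary R object (used for the encoder freeze contract).
#' @noRd
object_hash <- function(x) {
  f <- tempfile(fileext = ".bin")
  on.exit(unlink(f), add = TRUE)
  con <- file(f, "wb")
  serialize(x, con, version = 2L)
  close(con)
  unname(tools::md5sum(f))
}
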