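# Small shared internals: numeric helpers, matrix TSV I/O, config checksums.

sigmoid <- function(x) 1 / (1 + exp(-x))

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) {
  stop(errorCondition(paste0(...), class = c("rebold_input_error", "error")))
}

assert_that <- function(cond, ...) {
  if (!isTRUE(cond)) stop_input(...)
  invisible(TRUE)
}

#' Column-wise z-scoring
#'
#' Centers and scales each column to zero mean and unit (sample) standard
#' deviation. Constant columns are set to zero; callers decide whether that
#' deserves a warning.
#'
#' @param x numeric matrix.
#' @return list with `values` (z-scored matrix), `constant` (logical per
#'   column), `center`, `scale`.
#' @keywords internal
zscore_cols <- function(x) {
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  const <- !is.finite(sdv) | sdv < .Machine$double.eps * 1e2
  scl <- ifelse(const, 1, sdv)
  out <- sweep(sweep(x, 2, mu, "-"), 2, scl, "/")
  out[, const] <- 0
  list(values = out, constant = const, center = mu, scale = scl)
}

# Row-broadcast addition of a bias vector.
add_bias <- function(m, b) m + matrix(b, nrow(m), length(b), byrow = TRUE)

col_medians <- function(x) apply(x, 2, stats::median)

#' Write / read a numeric matrix as TSV at full double precision
#'
#' The dialect is a header row of 0-based column indices followed by one row
#' per sample; `%.17g` formatting makes write/read round trips bit-exact.
#'
#' @param m numeric matrix.
#' @param path file path.
#' @keywords internal
write_matrix_tsv <- function(m, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(seq_len(ncol(m)) - 1L, collapse = "\t"), con)
  txt <- sprintf("%.17g", t(m))
  dim(txt) <- c(ncol(m), nrow(m))
  writeLines(apply(txt, 2, paste, collapse = "\t"), con)
}

#' @keywords internal
read_matrix_tsv <- function(path) {
  header <- readLines(path, n = 1L)
  p <- length(strsplit(header, "\t", fixed = TRUE)[[1]])
  vals <- scan(path, what = double(), sep = "\t", skip = 1L, quiet = TRUE)
  if (length(vals) %% p != 0) {
    stop_input("malformed matrix TSV at ", path, ": ragged rows")
  }
  matrix(vals, ncol = p, byrow = TRUE)
}

#' MD5 checksum of an arbitrary R object
#'
#' Serializes the object (version 3, no header randomness) to a temporary file
#' and returns its MD5. Used to stamp result tables with the configuration
#' that produced them and to assert purity of data operations in tests.
#'
#' @param x any R object.
#' @return character scalar.
#' @export
object_checksum <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  con <- file(tf, "wb")
  serialize(x, con, version = 3L, xdr = TRUE)
  close(con)
  unname(tools::md5sum(tf))
}

# Derive a substream seed (< 2^31) from a base seed and a stream label.
derive_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(as.character(stream)) * (seq_along(utf8ToInt(as.character(stream))) %% 7 + 1))
  as.integer((as.numeric(seed) * 48271 + h * 1009 + 12345) %% 2147483563)
}
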