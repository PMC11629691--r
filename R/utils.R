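#' @useDynLib ssvepcollab, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif fft mvfft pnorm sd var coef
#' @importFrom utils head tail
NULL

abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a deterministic sub-seed from a master seed
#'
#' Fixed integer arithmetic on (seed, stream, index) so that, e.g., adding a
#' participant to a session never perturbs the random streams of existing
#' participants. All values stay below 2^31 and the map is exact in double
#' precision.
#'
#' @param seed master seed (integer, < 2^31).
#' @param stream stream id (e.g. participant index; 0 is reserved for
#'   streams shared across participants).
#' @param index within-stream index (e.g. trial index).
#' @return an integer seed suitable for [set.seed()].
#' @keywords internal
mix_seed <- function(seed, stream = 0, index = 0) {
  s <- (abs(seed) %% 2147483647) * 1103 + stream * 10007 + index * 101
  as.integer(s %% 2147483647L)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  expr
}

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    abort("'%s' must be a single finite number", name)
}

# Encode/decode a double vector as base64 little-endian IEEE-754 doubles.
# 64-bit (not 32-bit) so that streamed samples are bit-identical to the
# in-memory pipeline input.
encode_samples <- function(x) {
  jsonlite::base64_enc(writeBin(as.double(x), raw(), size = 8L,
                                endian = "little"))
}

decode_samples <- function(b64, n) {
  r <- jsonlite::base64_dec(b64)
  if (length(r) != 8L * n)
    abort("sample payload has %d bytes, expected %d", length(r), 8L * n)
  readBin(r, what = "double", n = n, size = 8L, endian = "little")
}
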