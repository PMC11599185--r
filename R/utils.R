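#' @importFrom stats rnbinom rnorm runif rexp median var sd cor dist
#'   p.adjust phyper pnorm prcomp t.test predict loess coef uniroot
#'   setNames glm binomial ave
#' @importFrom utils head read.delim write.table
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a child seed from a parent seed and a stream label
#'
#' Keeps independent random streams (per grade, per CV iteration, ...)
#' reproducible from one user-facing seed while staying below 2^31.
#'
#' @param seed integer parent seed.
#' @param ... labels (coerced to character) identifying the stream.
#' @return An integer seed.
#' @keywords internal
derive_seed <- function(seed, ...) {
  lab <- paste(c(seed, ...), collapse = "/")
  # polynomial rolling hash, kept in [0, 2^31 - 2]
  h <- 0
  for (k in utf8ToInt(lab)) h <- (h * 31 + k) %% 2147483629
  as.integer(h)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) length(x) == 1 && is.numeric(x) && !is.na(x) &&
  x >= 1 && x == floor(x)

is_fraction <- function(x, lo = 0, hi = 1) {
  length(x) == 1 && is.numeric(x) && !is.na(x) && x >= lo && x <= hi
}
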