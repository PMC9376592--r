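#' @keywords internal
#' @useDynLib seizegraph, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

# Small shared helpers. Nothing here is exported.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

#' Biased (population) variance, the convention used by the Hjorth activity
#' parameter.
#' @noRd
biased_var <- function(x) {
  m <- mean(x)
  mean((x - m)^2)
}

#' Sample SD that returns 0 (not NA) for a single observation; summary tables
#' over folds/subjects use this so a single-fold subject reports +/- 0.
#' @noRd
sd0 <- function(x) if (length(x) < 2L) 0 else stats::sd(x)

#' Derive a child RNG seed from a base seed, kept inside 32-bit range.
#' @noRd
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(k) * 9973) %% 2147483559) + 1L
}

#' Count sign changes of a numeric sequence, ignoring exact zeros (a zero
#' inherits the preceding non-zero sign).
#' @noRd
count_sign_changes <- function(x) {
  s <- sign(x)
  s <- s[s != 0]
  if (length(s) < 2L) return(0L)
  sum(s[-1L] != s[-length(s)])
}
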