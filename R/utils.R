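#' Derive a reproducible child seed
#'
#' Counter-based scheme: one master seed plus a stream of non-negative
#' integer counters (plate index, well index, stage tag ...) maps to a child
#' seed below 2^31, so each well/field can be simulated independently and
#' reproducibly. Linear congruential mixing modulo the Mersenne prime
#' 2^31 - 1; never returns 0.
#'
#' @param master integer master seed
#' @param ... integer counters identifying the stream
#' @return integer in `[1, 2^31 - 2]`
#' @examples
#' childSeed(1, 3, 7)
#' @export
childSeed <- function(master, ...) {
  m <- 2147483647
  h <- as.numeric(master) %% m
  for (k in as.numeric(c(...))) {
    h <- (h * 48271 + k + 1) %% m
  }
  h <- (h * 48271 + 12345) %% m
  as.integer(if (h == 0) 1 else h)
}

clamp01 <- function(x) pmin(1, pmax(0, x))

stopifnot_finite <- function(x, what) {
  if (!all(is.finite(x)))
    stop(what, " must be finite", call. = FALSE)
  invisible(x)
}

#' Adjusted Rand index by pair counting
#'
#' Chance-corrected agreement between two partitions via the standard
#' contingency-table formula: ARI = (sum_ij C(n_ij,2) - E) / (M - E) with
#' E the expectation under random pairing. 1 iff the partitions are
#' identical; about 0 for unrelated partitions.
#'
#' @param a,b label vectors of equal length (factors or atomic)
#' @return numeric ARI in `[-1, 1]`
#' @export
adjustedRandIndex <- function(a, b) {
  if (length(a) != length(b))
    stop("label vectors must have equal length", call. = FALSE)
  a <- as.integer(factor(a)); b <- as.integer(factor(b))
  tab <- table(a, b)
  ch2 <- function(n) n * (n - 1) / 2
  sij <- sum(ch2(tab))
  si <- sum(ch2(rowSums(tab)))
  sj <- sum(ch2(colSums(tab)))
  n2 <- ch2(length(a))
  expct <- si * sj / n2
  mx <- (si + sj) / 2
  if (mx == expct) return(1)  # both partitions trivial (all-singletons etc.)
  (sij - expct) / (mx - expct)
}
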