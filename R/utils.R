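# Internal helpers shared across modules.

#' Evaluate an expression under a fixed RNG seed, restoring global RNG state
#' @noRd
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

#' Stable per-stage seed derivation from a global seed
#'
#' Maps (global seed, stage name) to a reproducible 31-bit integer so every
#' pipeline stage can be seeded independently of execution order.
#' @noRd
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.double(seed) * 48271 + h * 16807) %% 2147483647L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Associated Legendre functions P_n(x) and P_n^1(x), n = 1..nmax
#'
#' Ferrers convention without the Condon-Shortley phase, i.e.
#' P_1^1(cos g) = sin(g). Returns matrices length(x) x nmax via the standard
#' three-term recurrences.
#' @noRd
legendre_table <- function(x, nmax) {
  stopifnot(nmax >= 1)
  nx <- length(x)
  P  <- matrix(0, nx, nmax)
  P1 <- matrix(0, nx, nmax)
  s <- sqrt(pmax(0, 1 - x^2))
  P[, 1]  <- x
  P1[, 1] <- s
  if (nmax >= 2) {
    P[, 2]  <- 0.5 * (3 * x^2 - 1)
    P1[, 2] <- 3 * x * s
    if (nmax >= 3) {
      for (n in 2:(nmax - 1)) {
        P[, n + 1]  <- ((2 * n + 1) * x * P[, n]  - n * P[, n - 1]) / (n + 1)
        P1[, n + 1] <- ((2 * n + 1) * x * P1[, n] - (n + 1) * P1[, n - 1]) / n
      }
    }
  }
  list(P = P, P1 = P1)
}
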