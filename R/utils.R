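#' @import methods
#' @importFrom stats sd rnorm runif median aggregate complete.cases cor cor.test
#'   ecdf optim pt quantile var dist setNames
#' @importFrom utils head tail read.csv write.csv
#' @importFrom tools file_ext
#' @useDynLib coralrhythm, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

## Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
## global RNG stream is untouched.
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite number")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## Deterministic polynomial rolling hash of a character scalar (8 hex digits).
## Used for config fingerprints in run records; not cryptographic.
strHash <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  bytes <- as.integer(charToRaw(x))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

## Reflect (symmetric, edge-inclusive) padding of a matrix by r rows/cols.
reflectPad <- function(m, r) {
  nr <- nrow(m); nc <- ncol(m)
  if (r >= nr || r >= nc) stop("padding radius exceeds matrix size")
  ri <- c(r:1, seq_len(nr), nr:(nr - r + 1))
  ci <- c(r:1, seq_len(nc), nc:(nc - r + 1))
  m[ri, ci, drop = FALSE]
}

## Status code book shared across modules: PNG label maps, StatusMap grids and
## patch labels all use this order.
STATUS_LEVELS <- c("background", "bloated", "semi_bloated", "non_bloated")
CORAL_LEVELS <- STATUS_LEVELS[-1L]

statusCode <- function(status) {
  i <- match(status, STATUS_LEVELS)
  if (anyNA(i)) stop("unknown status: ", paste(status[is.na(i)], collapse = ", "))
  i - 1L
}
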