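#' @useDynLib polyarch, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats dnorm pnorm qnorm rnorm runif rbeta rbinom rt pf pchisq
#'   lm.fit coef var sd quantile median complete.cases dhyper rmultinom
#'   setNames binom.test optim anova
#' @importFrom utils head tail
NULL

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the global RNG state, so package operations are pure
#' functions of their arguments and seed and never perturb the caller's
#' random-number stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  eval.parent(substitute(expr))
}

#' Derive a child seed from a master seed
#'
#' Fixed-offset stream derivation so that pipeline stages get independent,
#' reproducible seeds from one master seed. Result is kept below 2^31.
#'
#' @param master integer master seed.
#' @param offset integer stage offset (>= 0).
#' @return integer seed.
#' @export
child_seed <- function(master, offset) {
  stopifnot(is.numeric(master), is.numeric(offset), offset >= 0)
  m <- 2147483629
  as.integer((as.double(master) %% m * 48271 + as.double(offset) * 9973 + 1) %% m)
}

stop_domain <- function(...) stop(..., call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Equal-count binning with ntile semantics
#'
#' Splits `n` ranked items into `bins` groups whose sizes differ by at most
#' one, larger groups first. Ties in `x` are broken by input order
#' (stable sort), so binning is reproducible under duplicate values.
#'
#' @param x numeric vector to rank.
#' @param bins number of bins (>= 1).
#' @return integer bin index per element of `x`.
#' @export
ntile_stable <- function(x, bins) {
  stopifnot(bins >= 1)
  n <- length(x)
  ord <- order(x)                       # radix order: stable for ties
  ranks <- integer(n)
  ranks[ord] <- seq_len(n)
  as.integer(floor((bins * (ranks - 1)) %/% n) + 1L)
}

## 1-based point position vs 0-based half-open interval membership
point_in_interval <- function(pos_bp, start0, end0) {
  (pos_bp - 1L) >= start0 & (pos_bp - 1L) < end0
}

## Quartile-based IQR with linear interpolation between order statistics
## (quantile type 7); pinned so the repeated-measure cleaning rule is exact.
iqr_type7 <- function(x) {
  q <- stats::quantile(x, c(0.25, 0.75), type = 7, names = FALSE)
  q[2] - q[1]
}

assert_cols <- function(df, cols, what = "table") {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop_domain(sprintf("%s is missing column(s): %s", what,
                        paste(miss, collapse = ", ")))
  }
  invisible(TRUE)
}

## Stable content key for cache filenames: hex digest of the serialized
## object via a simple FNV-1a over the raw bytes (no external digest dep).
content_key <- function(x) {
  raw <- serialize(x, NULL, version = 2)
  fnv1a64(raw)
}
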