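#' @useDynLib ctdnaJM, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats dnorm pnorm qnorm rnorm runif rbinom rpois quantile
#'   median sd var optim pchisq pbinom aggregate complete.cases setNames
#'   rmultinom cov2cor nlminb logLik coef
#' @importFrom utils head tail write.csv read.csv packageVersion
NULL

# days per month used wherever the field quotes months (landmarks, windows)
DAYS_PER_MONTH <- 30.44

#' Convert months to days
#'
#' Landmarks and evaluation windows are quoted in months; all internal time
#' arithmetic is in days, at 30.44 days per month.
#'
#' @param months numeric vector of months.
#' @return days as a numeric vector.
#' @export
months_to_days <- function(months) months * DAYS_PER_MONTH

## Gauss-Legendre nodes/weights on [-1, 1] via Golub-Welsch
gauss_legendre <- function(n) {
  stopifnot(n >= 1)
  if (n == 1L) return(list(nodes = 0, weights = 2))
  k <- seq_len(n - 1)
  b <- k / sqrt(4 * k^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(k, k + 1)] <- b
  J[cbind(k + 1, k)] <- b
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(nodes = e$values[ord], weights = 2 * (e$vectors[1, ord])^2)
}

## Gauss-Hermite nodes/weights (weight function exp(-x^2))
gauss_hermite <- function(n) {
  stopifnot(n >= 1)
  if (n == 1L) return(list(nodes = 0, weights = sqrt(pi)))
  k <- seq_len(n - 1)
  b <- sqrt(k / 2)
  J <- matrix(0, n, n)
  J[cbind(k, k + 1)] <- b
  J[cbind(k + 1, k)] <- b
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(nodes = e$values[ord], weights = sqrt(pi) * (e$vectors[1, ord])^2)
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

## scale Gauss-Legendre rule to [a, b]
gl_rescale <- function(rule, a, b) {
  list(nodes = (a + b) / 2 + (b - a) / 2 * rule$nodes,
       weights = (b - a) / 2 * rule$weights)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## stable hash of a config-like list (serialised to canonical JSON, md5)
config_hash <- function(x) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = 12, null = "null"),
             f)
  unname(tools::md5sum(f))
}
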