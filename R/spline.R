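## Natural cubic spline basis with closed-form value, derivative and integral.
##
## The basis spans the natural cubic splines on the given knots, excluding the
## intercept: with knots k1 < ... < kK the columns are
##   N1(x) = (x - k1) / (kK - k1)
##   Nj(x) = (d_{j-1}(x) - d_{K-1}(x)) / scale_j ,  j = 2..K-1
## where d_k(x) = ((x-kk)_+^3 - (x-kK)_+^3) / (kK - kk)  (Hastie et al.'s
## truncated-power construction).  Columns are rescaled to O(1) on the knot
## span so downstream coefficients are well-conditioned when time is in days.
## Second derivatives vanish outside the boundary knots, so evaluation beyond
## them is exact linear extrapolation.  Closed-form antiderivatives make the
## cumulative (area-under-curve) hazard association exact.

#' Natural cubic spline basis
#'
#' Constructs a natural cubic spline basis of dimension \code{df} (no
#' intercept column). By default the boundary knots sit at 0 and the 95th
#' percentile of \code{times} and \code{df - 1} interior knots at the
#' corresponding quantiles of \code{times} (for \code{df = 2}: a single
#' interior knot at the median), the convention used for modelling log ctDNA
#' trajectories after surgery.
#'
#' @param times numeric vector of observation times (days); used to place
#'   knots when \code{knots} is not given.
#' @param df basis dimension (default 2).
#' @param knots optional interior knot locations (length \code{df - 1}).
#' @param boundary optional boundary knots (length 2).
#' @return an object of class \code{ncs_basis}.
#' @seealso [ncs_eval()], [ncs_integral()]
#' @export
ncs_basis <- function(times = NULL, df = 2, knots = NULL, boundary = NULL) {
  stopifnot(df >= 2)
  if (is.null(boundary)) {
    if (is.null(times)) stop("either `times` or `boundary` must be given")
    boundary <- c(0, unname(quantile(times, 0.95)))
  }
  if (is.null(knots)) {
    if (is.null(times)) stop("either `times` or `knots` must be given")
    probs <- seq_len(df - 1) / df
    knots <- unname(quantile(times[times >= boundary[1] & times <= boundary[2]],
                             probs))
  }
  stopifnot(length(boundary) == 2, length(knots) == df - 1)
  all_knots <- sort(unique(c(boundary[1], knots, boundary[2])))
  if (length(all_knots) != df + 1)
    stop("knots must be distinct and strictly inside the boundary knots")
  K <- length(all_knots)
  span <- all_knots[K] - all_knots[1]
  ## scale of cubic columns: their value at the upper boundary knot
  cub_scale <- (all_knots[K] - all_knots[seq_len(K - 2)])^2 -
    (all_knots[K] - all_knots[K - 1])^2
  structure(list(knots = all_knots, df = df, span = span,
                 scale = c(span, cub_scale)),
            class = "ncs_basis")
}

## truncated power helpers, vectorised over x
.tp3 <- function(x, k) pmax(x - k, 0)^3
.tp2 <- function(x, k) pmax(x - k, 0)^2
.tp1 <- function(x, k) pmax(x - k, 0)
.tp4 <- function(x, k) pmax(x - k, 0)^4

#' Evaluate a natural cubic spline basis
#'
#' @param basis an [ncs_basis()] object.
#' @param t evaluation times (days). Values beyond the boundary knots are
#'   handled by the natural linear extrapolation; a warning is raised when
#'   extrapolating further than 50\% of the knot span.
#' @param deriv derivative order: 0 (value), 1 or 2.
#' @return numeric matrix, \code{length(t)} rows by \code{df} columns.
#' @export
ncs_eval <- function(basis, t, deriv = 0) {
  stopifnot(inherits(basis, "ncs_basis"), deriv %in% 0:2)
  kn <- basis$knots
  K <- length(kn)
  lim <- 0.5 * basis$span
  if (any(t < kn[1] - lim) || any(t > kn[K] + lim))
    warning("evaluating spline basis far outside its boundary knots; ",
            "natural linear extrapolation applies")
  out <- matrix(0, length(t), basis$df)
  dk <- function(x, k, ord) {
    den <- kn[K] - kn[k]
    if (ord == 0) (.tp3(x, kn[k]) - .tp3(x, kn[K])) / den
    else if (ord == 1) 3 * (.tp2(x, kn[k]) - .tp2(x, kn[K])) / den
    else 6 * (.tp1(x, kn[k]) - .tp1(x, kn[K])) / den
  }
  out[, 1] <- switch(as.character(deriv),
                     "0" = (t - kn[1]) / basis$scale[1],
                     "1" = 1 / basis$scale[1],
                     "2" = 0)
  for (j in seq_len(basis$df - 1)) {
    out[, j + 1] <- (dk(t, j, deriv) - dk(t, K - 1, deriv)) /
      basis$scale[j + 1]
  }
  out
}

#' Integrate a natural cubic spline basis from a fixed origin
#'
#' Closed-form \eqn{\int_{from}^{t} N_j(s)\,ds} for every basis column;
#' used for the cumulative (area-under-the-curve) association between a log
#' ctDNA trajectory and the recurrence hazard.
#'
#' @inheritParams ncs_eval
#' @param from lower integration limit (default 0).
#' @return numeric matrix, \code{length(t)} rows by \code{df} columns.
#' @export
ncs_integral <- function(basis, t, from = 0) {
  stopifnot(inherits(basis, "ncs_basis"))
  kn <- basis$knots
  K <- length(kn)
  ## antiderivative of column j at x (unscaled), exact everywhere
  F1 <- function(x) (x - kn[1])^2 / 2 - (from - kn[1])^2 / 2
  Fd <- function(x, k) (.tp4(x, kn[k]) - .tp4(x, kn[K])) / (4 * (kn[K] - kn[k]))
  out <- matrix(0, length(t), basis$df)
  out[, 1] <- F1(t) / basis$scale[1]
  for (j in seq_len(basis$df - 1)) {
    out[, j + 1] <- ((Fd(t, j) - Fd(from, j)) - (Fd(t, K - 1) - Fd(from, K - 1))) /
      basis$scale[j + 1]
  }
  out
}

#' @export
print.ncs_basis <- function(x, ...) {
  cat("natural cubic spline basis: df =", x$df,
      "; knots =", paste(signif(x$knots, 5), collapse = ", "), "\n")
  invisible(x)
}
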