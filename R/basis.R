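#' Spline bases with analytic derivatives
#'
#' Constructors for the two spline bases used throughout the package: a
#' natural cubic spline basis (linear beyond its boundary knots, used for the
#' smooth age trend of the longitudinal submodel and for pattern-specific
#' deviations) and a cubic B-spline basis (used for the log baseline hazard).
#' Both evaluate values and exact first derivatives via
#' [evaluate_basis()].
#'
#' The natural cubic basis is the truncated-power natural basis: for knots
#' \eqn{\xi_1 < \dots < \xi_K} (two boundary knots plus \eqn{K-2} interior
#' knots) the columns are \eqn{x} and, for \eqn{k = 1, \dots, K-2},
#' \eqn{(d_k(x) - d_{K-1}(x)) / (\xi_K - \xi_1)} with
#' \eqn{d_k(x) = [(x-\xi_k)_+^3 - (x-\xi_K)_+^3]/(\xi_K - \xi_k)}.
#' This spans the natural cubic spline space without an intercept column, so
#' `df = 3` yields a 3-column basis, and the basis is exactly linear outside
#' the boundary knots (the linear tails are also used for extrapolation, e.g.
#' when a lagged trajectory value is requested below the boundary).
#'
#' @param df degrees of freedom (number of basis columns, no intercept).
#' @param knots interior knots (ages, years). If `NULL`, placed at equally
#'   spaced quantiles of `x`.
#' @param boundary boundary knots (length 2). If `NULL`, the 0.5% and 99.5%
#'   quantiles of `x`.
#' @param x optional numeric vector of ages from which default knots are
#'   computed.
#' @return an object of class `spline_basis`.
#' @examples
#' nb <- natural_cubic_basis(df = 3, x = runif(100, 40, 90))
#' evaluate_basis(nb, c(50, 60, 70))
#' @export
natural_cubic_basis <- function(df = 3, knots = NULL, boundary = NULL,
                                x = NULL) {
  if (is.null(boundary)) {
    if (is.null(x)) stop("supply either `boundary` or `x`")
    boundary <- unname(stats::quantile(x, c(0.005, 0.995)))
  }
  if (is.null(knots)) {
    n_int <- df - 1L
    if (n_int > 0L) {
      if (is.null(x)) {
        probs <- seq_len(n_int) / (n_int + 1L)
        knots <- boundary[1] + probs * diff(boundary)
      } else {
        xi <- x[x >= boundary[1] & x <= boundary[2]]
        knots <- unname(stats::quantile(xi, seq_len(n_int) / (n_int + 1L)))
      }
    } else {
      knots <- numeric(0)
    }
  }
  b <- structure(list(kind = "natural_cubic",
                      df = length(knots) + 1L,
                      interior_knots = as.numeric(knots),
                      boundary_knots = as.numeric(boundary),
                      degree = 3L),
                 class = "spline_basis")
  validate_basis(b)
  if (!is.null(df) && b$df != df)
    stop("knot configuration yields df = ", b$df, ", not ", df)
  b
}

#' @rdname natural_cubic_basis
#' @param degree polynomial degree of the B-spline pieces (default cubic).
#' @details The B-spline basis includes its intercept span: `df` equals
#'   `length(knots) + degree + 1`. Evaluation outside the boundary knots is an
#'   error (the baseline hazard is only defined on its support).
#' @export
bspline_basis <- function(df = 9, knots = NULL, boundary = NULL, x = NULL,
                          degree = 3L) {
  if (is.null(boundary)) {
    if (is.null(x)) stop("supply either `boundary` or `x`")
    boundary <- range(x)
  }
  if (is.null(knots)) {
    n_int <- df - degree - 1L
    if (n_int < 0L) stop("df too small for degree ", degree)
    if (is.null(x)) {
      knots <- boundary[1] + seq_len(n_int) / (n_int + 1L) * diff(boundary)
    } else {
      xi <- x[x >= boundary[1] & x <= boundary[2]]
      knots <- unname(stats::quantile(xi, seq_len(n_int) / (n_int + 1L)))
    }
  }
  b <- structure(list(kind = "bspline",
                      df = length(knots) + degree + 1L,
                      interior_knots = as.numeric(knots),
                      boundary_knots = as.numeric(boundary),
                      degree = as.integer(degree)),
                 class = "spline_basis")
  validate_basis(b)
  b
}

validate_basis <- function(b) {
  ks <- c(b$boundary_knots[1], b$interior_knots, b$boundary_knots[2])
  if (any(diff(ks) <= 0)) stop("knots must be strictly increasing")
  invisible(b)
}

#' Evaluate a spline basis (values or first derivatives)
#'
#' @param basis a `spline_basis` from [natural_cubic_basis()] or
#'   [bspline_basis()].
#' @param ages numeric vector of evaluation points (years).
#' @param derivative_order 0 for basis values, 1 for exact analytic first
#'   derivatives.
#' @return a `length(ages) x basis$df` matrix; row i is the basis at
#'   `ages[i]`.
#' @export
evaluate_basis <- function(basis, ages, derivative_order = 0L) {
  stopifnot(inherits(basis, "spline_basis"))
  if (length(ages) == 0L) stop("empty age vector")
  if (!derivative_order %in% c(0L, 1L))
    stop("derivative_order must be 0 or 1")
  validate_basis(basis)
  if (basis$kind == "natural_cubic") {
    ns_truncpower(ages, basis, derivative_order)
  } else {
    bk <- basis$boundary_knots
    if (any(ages < bk[1] - 1e-10 | ages > bk[2] + 1e-10))
      stop("B-spline basis evaluated outside its boundary knots [",
           bk[1], ", ", bk[2], "]")
    ages <- pmin(pmax(ages, bk[1]), bk[2])
    akts <- c(rep(bk[1], basis$degree + 1L), basis$interior_knots,
              rep(bk[2], basis$degree + 1L))
    splines::splineDesign(akts, ages, ord = basis$degree + 1L,
                          derivs = rep(derivative_order, length(ages)))
  }
}

ns_truncpower <- function(x, basis, deriv) {
  ks <- c(basis$boundary_knots[1], basis$interior_knots,
          basis$boundary_knots[2])
  K <- length(ks)
  scale <- ks[K] - ks[1]
  p3 <- function(u) pmax(u, 0)^3
  p2 <- function(u) 3 * pmax(u, 0)^2
  dk <- function(k) {
    if (deriv == 0L) (p3(x - ks[k]) - p3(x - ks[K])) / (ks[K] - ks[k])
    else             (p2(x - ks[k]) - p2(x - ks[K])) / (ks[K] - ks[k])
  }
  out <- matrix(0, length(x), K - 1L)
  out[, 1L] <- if (deriv == 0L) x else 1
  if (K > 2L) {
    dlast <- dk(K - 1L)
    for (k in seq_len(K - 2L)) out[, k + 1L] <- (dk(k) - dlast) / scale
  }
  colnames(out) <- paste0("ns", seq_len(K - 1L))
  out
}

#' Cumulative hazard by Gauss--Legendre quadrature
#'
#' Approximates \eqn{\int_a^b h(s)\,ds} for a nonnegative hazard evaluator,
#' as needed by the survival part of the joint-model likelihood and by the
#' dynamic-prediction survival probabilities. With `n_nodes` nodes the rule is
#' exact for polynomial integrands up to degree `2 * n_nodes - 1`.
#'
#' @param hazard a vectorized function of time returning hazards (>= 0).
#' @param interval numeric length-2, `c(a, b)` with `a <= b` (years).
#' @param n_nodes number of Gauss--Legendre nodes (default 15).
#' @return the cumulative hazard over the interval (dimensionless).
#' @examples
#' cumulative_hazard(function(t) rep(0.1, length(t)), c(0, 10))  # 1
#' @export
cumulative_hazard <- function(hazard, interval, n_nodes = 15L) {
  stopifnot(length(interval) == 2L)
  a <- interval[1]; b <- interval[2]
  if (b < a) stop("interval must have b >= a")
  if (b == a) return(0)
  gq <- pracma::gaussLegendre(n_nodes, a, b)
  h <- hazard(gq$x)
  if (any(!is.finite(h))) stop("hazard evaluator returned non-finite values")
  if (any(h < 0)) stop("hazard evaluator returned negative values")
  sum(gq$w * h)
}

# Gauss-Legendre nodes/weights on [-1, 1], cached by n.
gl_cache <- new.env(parent = emptyenv())
gl_rule <- function(n) {
  key <- as.character(n)
  if (is.null(gl_cache[[key]]))
    gl_cache[[key]] <- pracma::gaussLegendre(n, -1, 1)
  gl_cache[[key]]
}
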