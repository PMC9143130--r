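#' Analytic energy surfaces
#'
#' Analytic surfaces play the role of the molecular energy function in all
#' sampling and free-energy machinery: they expose `energy(x)` and
#' `gradient(x)` closures plus a declared domain, so every estimator in the
#' package can be validated against closed-form results (Boltzmann
#' inversion, known barrier heights, known saddle locations).
#'
#' Four functional forms are provided:
#' \describe{
#'   \item{harmonic}{\eqn{V(x) = \kappa (x-x_0)^2 / 2}}
#'   \item{double_well}{\eqn{V(x) = h((x/b)^2-1)^2}: minima at \eqn{\pm b}
#'     with \eqn{V=0}, barrier \eqn{h} at the origin}
#'   \item{separable_2d}{double well in \eqn{x} plus an independent
#'     harmonic (or second double well) in \eqn{y}}
#'   \item{coupled_2d}{separable double well/harmonic plus a coupling term
#'     \eqn{c\,x^2 y^2}; the coupling vanishes to second order at the
#'     origin so the saddle stays exactly at \eqn{(0,0)}}
#' }
#'
#' @param kappa harmonic force constant, kcal/mol/A^2.
#' @param center harmonic minimum position, Angstrom.
#' @param h barrier height, kcal/mol.
#' @param b half well separation, Angstrom (minima at +/- b).
#' @name analytic_surface
NULL

new_surface <- function(form, params, dim, energy, gradient, domain) {
  structure(
    list(form = form, params = params, dim = dim,
         energy = energy, gradient = gradient, domain = domain),
    class = "analytic_surface")
}

#' @rdname analytic_surface
#' @return An `analytic_surface` object: list with `form`, `params`, `dim`,
#'   `energy` and `gradient` closures (taking a numeric vector of length
#'   `dim`, or a matrix with `dim` columns), and a `domain` matrix (rows
#'   lo/hi).
#' @export
make_harmonic <- function(kappa, center = 0) {
  stopifnot(is.numeric(kappa), length(kappa) == 1, kappa > 0)
  new_surface(
    "harmonic", c(kappa = kappa, center = center), 1L,
    energy = function(x) 0.5 * kappa * (x - center)^2,
    gradient = function(x) kappa * (x - center),
    domain = rbind(lo = center - 50, hi = center + 50))
}

#' @rdname analytic_surface
#' @examples
#' dw <- make_double_well(h = 5, b = 1)
#' dw$energy(0)    # barrier: 5
#' dw$energy(1)    # well: 0
#' @export
make_double_well <- function(h, b) {
  if (!is.numeric(h) || length(h) != 1 || h <= 0)
    stop("barrier height 'h' must be a positive scalar")
  if (!is.numeric(b) || length(b) != 1 || b <= 0)
    stop("well separation 'b' must be a positive scalar")
  new_surface(
    "double_well", c(h = h, b = b), 1L,
    energy = function(x) h * ((x / b)^2 - 1)^2,
    gradient = function(x) 4 * h * x * ((x / b)^2 - 1) / b^2,
    domain = rbind(lo = -2.5 * b, hi = 2.5 * b))
}

#' @rdname analytic_surface
#' @param ky harmonic force constant along y, kcal/mol/A^2 (ignored when
#'   `hy`/`by` are given).
#' @param hy,by optional double-well parameters for the y axis; when
#'   supplied the surface is a double well in both coordinates.
#' @export
make_separable_2d <- function(h, b, ky = 10, hy = NULL, by = NULL) {
  stopifnot(h > 0, b > 0)
  dw_y <- !is.null(hy)
  if (dw_y) stopifnot(hy > 0, !is.null(by), by > 0)
  vy <- if (dw_y) function(y) hy * ((y / by)^2 - 1)^2 else function(y) 0.5 * ky * y^2
  gy <- if (dw_y) function(y) 4 * hy * y * ((y / by)^2 - 1) / by^2 else function(y) ky * y
  params <- if (dw_y) c(h = h, b = b, hy = hy, by = by) else c(h = h, b = b, ky = ky)
  ylim <- if (dw_y) 2.5 * by else 2.5 * sqrt(2 * h / ky) + 1
  new_surface(
    "separable_2d", params, 2L,
    energy = function(x) {
      x <- as_coords(x, 2L)
      h * ((x[, 1] / b)^2 - 1)^2 + vy(x[, 2])
    },
    gradient = function(x) {
      x <- as_coords(x, 2L)
      cbind(4 * h * x[, 1] * ((x[, 1] / b)^2 - 1) / b^2, gy(x[, 2]))
    },
    domain = rbind(lo = c(-2.5 * b, -ylim), hi = c(2.5 * b, ylim)))
}

#' @rdname analytic_surface
#' @param coupling coefficient of the \eqn{x^2 y^2} coupling term,
#'   kcal/mol/A^4.
#' @export
make_coupled_2d <- function(h, b, ky = 10, coupling = 2) {
  stopifnot(h > 0, b > 0, ky > 0)
  new_surface(
    "coupled_2d", c(h = h, b = b, ky = ky, c = coupling), 2L,
    energy = function(x) {
      x <- as_coords(x, 2L)
      h * ((x[, 1] / b)^2 - 1)^2 + 0.5 * ky * x[, 2]^2 +
        coupling * x[, 1]^2 * x[, 2]^2
    },
    gradient = function(x) {
      x <- as_coords(x, 2L)
      cbind(4 * h * x[, 1] * ((x[, 1] / b)^2 - 1) / b^2 +
              2 * coupling * x[, 1] * x[, 2]^2,
            ky * x[, 2] + 2 * coupling * x[, 1]^2 * x[, 2])
    },
    domain = rbind(lo = c(-2.5 * b, -2.5 * sqrt(2 * h / ky) - 1),
                   hi = c(2.5 * b, 2.5 * sqrt(2 * h / ky) + 1)))
}

# coerce vector / matrix input to an n x dim coordinate matrix
as_coords <- function(x, dim) {
  if (is.matrix(x)) {
    stopifnot(ncol(x) == dim)
    x
  } else {
    matrix(x, ncol = dim, byrow = FALSE)
  }
}

#' @export
print.analytic_surface <- function(x, ...) {
  cat(sprintf("<analytic_surface> form=%s dim=%d\n  params: %s\n",
              x$form, x$dim,
              paste(names(x$params), signif(x$params, 6),
                    sep = "=", collapse = ", ")))
  invisible(x)
}

#' Pair of low-level and high-level surfaces
#'
#' Container emulating a dual-level calculation: the same landscape
#' described by a cheap (LL) and an accurate (HL) energy function, with the
#' closed-form difference `delta(x) = high(x) - low(x)` available for
#' validating spline corrections.
#'
#' @param low,high `analytic_surface` objects of equal dimensionality.
#' @return An `llhl_pair` with fields `low`, `high` and `delta` (closure).
#' @export
llhl_pair <- function(low, high) {
  stopifnot(inherits(low, "analytic_surface"), inherits(high, "analytic_surface"))
  if (low$dim != high$dim) stop("LL and HL surfaces must share dimensionality")
  structure(
    list(low = low, high = high,
         delta = function(x) high$energy(x) - low$energy(x)),
    class = "llhl_pair")
}
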