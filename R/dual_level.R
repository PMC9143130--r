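#' Dual-level spline correction grid
#'
#' Builds an interpolant of high-level minus low-level energy differences
#' on a rectilinear grid of reaction-coordinate nodes, implementing the
#' dual-level energy E = E_LL + S(dE_LL->HL)(xi1, xi2).  1D grids use a
#' natural cubic spline; 2D grids a tensor-product (bicubic) natural
#' spline built from row/column cubic passes.  The interpolant reproduces
#' node values exactly and is defined only inside the node hull: an
#' out-of-hull evaluation is an error, never an extrapolation (silent
#' extrapolation is the classic failure mode of dual-level schemes).
#'
#' @param x node coordinates along the first axis (sorted unique values),
#'   or, for scattered input, a vector parallel to `delta` (checked to
#'   form a complete rectilinear grid).
#' @param delta HL - LL energy differences, kcal/mol: a vector (1D), a
#'   `length(x) x length(y)` matrix, or a vector parallel to scattered
#'   `x`/`y` node coordinates.
#' @param y node coordinates along the second axis (NULL for 1D).
#' @return A `correction_grid` with an `evaluate(x, y)` closure.
#' @export
build_correction <- function(x, delta, y = NULL) {
  if (is.null(y)) {
    if (length(x) != length(delta))
      stop("x and delta lengths differ")
    ord <- order(x)
    x <- x[ord]; delta <- delta[ord]
    if (anyDuplicated(x)) stop("duplicate correction nodes")
    if (length(x) < 4)
      stop("cubic correction needs at least 4 nodes (got ", length(x), ")")
    sf <- stats::splinefun(x, delta, method = "natural")
    ev <- function(xq, yq = NULL) {
      if (any(xq < min(x) - 1e-12 | xq > max(x) + 1e-12))
        stop("correction evaluated outside its node hull [",
             min(x), ", ", max(x), "]")
      sf(xq)
    }
    grid <- list(x = x, y = NULL, delta = delta, evaluate = ev, dim = 1L)
  } else {
    if (length(x) == length(y) && length(x) == length(delta) &&
        is.null(dim(delta)) && length(unique(x)) < length(x)) {
      # scattered triplets: require that they tile a complete grid
      xs <- sort(unique(x)); ys <- sort(unique(y))
      if (length(xs) * length(ys) != length(delta))
        stop("scattered nodes do not form a rectilinear grid")
      m <- matrix(NA_real_, length(xs), length(ys))
      m[cbind(match(x, xs), match(y, ys))] <- delta
      if (anyNA(m)) stop("scattered nodes do not form a rectilinear grid")
      x <- xs; y <- ys; delta <- m
    }
    delta <- as.matrix(delta)
    if (nrow(delta) != length(x) || ncol(delta) != length(y))
      stop("delta must be a length(x) x length(y) matrix")
    if (length(x) < 4 || length(y) < 4)
      stop("bicubic correction needs at least 4x4 nodes")
    if (anyDuplicated(x) || anyDuplicated(y))
      stop("duplicate correction nodes")
    ox <- order(x); oy <- order(y)
    x <- x[ox]; y <- y[oy]; delta <- delta[ox, oy, drop = FALSE]
    row_splines <- lapply(seq_along(y), function(j)
      stats::splinefun(x, delta[, j], method = "natural"))
    ev <- function(xq, yq) {
      stopifnot(length(xq) == length(yq))
      if (any(xq < min(x) - 1e-12 | xq > max(x) + 1e-12 |
              yq < min(y) - 1e-12 | yq > max(y) + 1e-12))
        stop("correction evaluated outside its node hull")
      vapply(seq_along(xq), function(i) {
        col_vals <- vapply(row_splines, function(sf) sf(xq[i]), 1.0)
        stats::splinefun(y, col_vals, method = "natural")(yq[i])
      }, 1.0)
    }
    grid <- list(x = x, y = y, delta = delta, evaluate = ev, dim = 2L)
  }
  structure(grid, class = "correction_grid")
}

#' @export
print.correction_grid <- function(x, ...) {
  cat(sprintf("<correction_grid> %s, %s nodes\n",
              if (x$dim == 1) "cubic (1D)" else "bicubic (2D)",
              if (x$dim == 1) length(x$x)
              else paste(length(x$x), length(x$y), sep = " x ")))
  invisible(x)
}

#' Apply a dual-level correction to a PMF or scan grid
#'
#' Adds the interpolated HL-LL difference at every bin/node center
#' (corrections act on grid energies, not on individual samples, mirroring
#' per-window single-point corrections).  PMF grids are re-referenced to
#' min 0 afterwards; every bin must lie inside the correction hull.
#'
#' @param grid a [pmf_grid()] or [grid_scan()] result.
#' @param corr a [build_correction()] result of matching dimensionality.
#' @return corrected grid of the same class.
#' @export
apply_correction <- function(grid, corr) {
  stopifnot(inherits(corr, "correction_grid"))
  if (inherits(grid, "pmf_grid")) {
    if (grid$dim != corr$dim)
      stop("grid and correction dimensionality differ")
    if (grid$dim == 1) {
      S <- corr$evaluate(grid$centers[[1]])
    } else {
      pts <- expand.grid(grid$centers, KEEP.OUT.ATTRS = FALSE)
      S <- array(corr$evaluate(pts[[1]], pts[[2]]), dim = dim(grid$W))
    }
    W <- grid$W + S
    pmf_grid(grid$centers, W, grid$counts, grid$temperature,
             breaks = grid$breaks, iterations = grid$iterations,
             final_change = grid$final_change, converged = grid$converged)
  } else if (inherits(grid, "scan_grid")) {
    if (length(grid$centers) != corr$dim)
      stop("grid and correction dimensionality differ")
    if (corr$dim == 1) {
      S <- corr$evaluate(grid$centers[[1]])
      grid$energies <- grid$energies + S
    } else {
      pts <- expand.grid(grid$centers, KEEP.OUT.ATTRS = FALSE)
      grid$energies <- grid$energies +
        array(corr$evaluate(pts[[1]], pts[[2]]), dim = dim(grid$energies))
    }
    grid
  } else {
    stop("apply_correction() expects a pmf_grid or scan_grid")
  }
}

#' Read a correction table from TSV
#'
#' Accepts `(xi1, dE)`, `(xi1, E_LL, E_HL)`, `(xi1, xi2, dE)` or
#' `(xi1, xi2, E_LL, E_HL)` column layouts (with or without a header
#' line); energy pairs are differenced as HL - LL.
#'
#' @param path TSV path.
#' @return A [build_correction()] result.
#' @export
read_correction_tsv <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "",
                           comment.char = "#")
  nc <- ncol(tab)
  has_xi2 <- "xi2" %in% names(tab) || nc == 4 ||
    (nc == 3 && all(c("xi1", "xi2") %in% names(tab)))
  if (!has_xi2) {
    de <- if (nc == 2) tab[[2]] else tab[[3]] - tab[[2]]
    build_correction(tab[[1]], de)
  } else {
    de <- if (nc == 3) tab[[3]] else tab[[4]] - tab[[3]]
    build_correction(tab[[1]], de, y = tab[[2]])
  }
}
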