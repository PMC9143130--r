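#' Maximum-probability path on a 2D PMF
#'
#' Traces the most probable route between two points of a 2D free-energy
#' surface as the minimum-cost path on the 8-connected graph of covered
#' bins with node cost `exp(+W/kT)` (Dijkstra, via igraph), then recovers
#' a one-dimensional free-energy profile along the route by integrating
#' `exp(-W/kT)` over the coordinate perpendicular to the local path
#' tangent (5 bins each side, bilinear interpolation).  Cost ties are
#' broken deterministically by lexicographic bin order.
#'
#' @param grid a 2D [pmf_grid()].
#' @param start,end coordinate pairs `c(xi1, xi2)`; each is snapped to the
#'   nearest covered bin.
#' @param n_perp half-width of the perpendicular integration stencil in
#'   bins (default 5).
#' @return A `traced_path`: list with `bins` (m x 2 index matrix),
#'   `coords` (m x 2 bin-center coordinates), `s` (arc length, Angstrom),
#'   `profile` (W along the path, kcal/mol, min-referenced) and `barrier`
#'   (max of `profile`).
#' @export
trace_path <- function(grid, start, end, n_perp = 5L) {
  stopifnot(inherits(grid, "pmf_grid"), grid$dim == 2)
  kTv <- kT(grid$temperature)
  nb <- dim(grid$W)
  covered <- !is.na(grid$W)
  sb <- nearest_covered_bin(grid, start)
  eb <- nearest_covered_bin(grid, end)
  if (all(sb == eb)) {
    return(structure(list(bins = matrix(sb, 1),
                          coords = matrix(bin_coords(grid, matrix(sb, 1)), 1),
                          s = numeric(0), profile = numeric(0),
                          barrier = 0), class = "traced_path"))
  }
  lin <- function(ij) ij[, 1] + (ij[, 2] - 1) * nb[1]
  # node costs with a vanishing lexicographic tie-break term
  idx_all <- which(covered)
  cost <- exp(grid$W[idx_all] / kTv) * (1 + 1e-12 * seq_along(idx_all))
  node_of <- rep(NA_integer_, prod(nb))
  node_of[idx_all] <- seq_along(idx_all)
  edges <- integer(0); wts <- numeric(0)
  shifts <- cbind(di = c(1, 0, 1, -1), dj = c(0, 1, 1, 1))
  ij_all <- cbind((idx_all - 1) %% nb[1] + 1, (idx_all - 1) %/% nb[1] + 1)
  for (s in seq_len(nrow(shifts))) {
    ij2 <- sweep(ij_all, 2, -shifts[s, ])
    ok <- ij2[, 1] >= 1 & ij2[, 1] <= nb[1] & ij2[, 2] >= 1 & ij2[, 2] <= nb[2]
    tgt <- node_of[lin(ij2[ok, , drop = FALSE])]
    src <- node_of[idx_all[ok]]
    keep <- !is.na(tgt)
    d <- sqrt(sum(shifts[s, ]^2))
    edges <- c(edges, rbind(src[keep], tgt[keep]))
    wts <- c(wts, 0.5 * (cost[src[keep]] + cost[tgt[keep]]) * d)
  }
  g <- igraph::make_graph(edges, n = length(idx_all), directed = FALSE)
  from <- node_of[lin(matrix(sb, 1))]
  to <- node_of[lin(matrix(eb, 1))]
  sp <- suppressWarnings(
    igraph::shortest_paths(g, from = from, to = to, weights = wts,
                           output = "vpath"))
  vp <- as.integer(sp$vpath[[1]])
  if (!length(vp))
    stop("no connected route through covered bins between start and end")
  bins <- ij_all[vp, , drop = FALSE]
  coords <- bin_coords(grid, bins)
  s_arc <- c(0, cumsum(sqrt(rowSums(diff(coords)^2))))
  profile <- perpendicular_profile(grid, coords, kTv, n_perp)
  structure(list(bins = bins, coords = coords, s = s_arc,
                 profile = profile, barrier = max(profile)),
            class = "traced_path")
}

nearest_covered_bin <- function(grid, pt) {
  stopifnot(length(pt) == 2)
  covered <- which(!is.na(grid$W))
  nb <- dim(grid$W)
  ij <- cbind((covered - 1) %% nb[1] + 1, (covered - 1) %/% nb[1] + 1)
  xy <- bin_coords(grid, ij)
  d2 <- (xy[, 1] - pt[1])^2 + (xy[, 2] - pt[2])^2
  ij[which.min(d2), ]
}

bin_coords <- function(grid, ij) {
  cbind(grid$centers[[1]][ij[, 1]], grid$centers[[2]][ij[, 2]])
}

# integrate exp(-W/kT) perpendicular to the local path tangent
perpendicular_profile <- function(grid, coords, kTv, n_perp) {
  m <- nrow(coords)
  hx <- mean(diff(grid$centers[[1]]))
  hy <- mean(diff(grid$centers[[2]]))
  h <- min(hx, hy)
  # density matrix in MATLAB orientation for pracma::interp2 (rows = y)
  Wfull <- grid$W
  Wfull[is.na(Wfull)] <- max(grid$W, na.rm = TRUE) + 50
  dens <- t(exp(-Wfull / kTv))
  offs <- seq(-n_perp, n_perp) * h
  prof <- numeric(m)
  for (i in seq_len(m)) {
    lo <- max(1, i - 1); hi <- min(m, i + 1)
    tan_v <- coords[hi, ] - coords[lo, ]
    tan_v <- tan_v / sqrt(sum(tan_v^2))
    nrm <- c(-tan_v[2], tan_v[1])
    px <- coords[i, 1] + offs * nrm[1]
    py <- coords[i, 2] + offs * nrm[2]
    inside <- px >= min(grid$centers[[1]]) & px <= max(grid$centers[[1]]) &
      py >= min(grid$centers[[2]]) & py <= max(grid$centers[[2]])
    dvals <- rep(0, length(offs))
    if (any(inside))
      dvals[inside] <- pracma::interp2(grid$centers[[1]], grid$centers[[2]],
                                       dens, px[inside], py[inside],
                                       method = "linear")
    dvals[!is.finite(dvals)] <- 0
    prof[i] <- -kTv * log(max(sum(dvals) * h, .Machine$double.xmin))
  }
  prof - min(prof)
}
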