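#' PMF grids
#'
#' Result container for WHAM and for reference (Boltzmann-inversion)
#' free-energy surfaces: bin centers per axis, the free energy W in
#' kcal/mol per bin (min-referenced, NA in uncovered bins — empty bins are
#' flagged, never interpolated), per-bin sample counts, the temperature,
#' and convergence metadata.
#'
#' @param centers list of bin-center vectors (length 1 or 2).
#' @param W numeric array of free energies, kcal/mol.
#' @param counts integer array of per-bin sample counts.
#' @param temperature K.
#' @param breaks list of bin-edge vectors.
#' @param iterations,final_change,converged WHAM convergence metadata.
#' @return A `pmf_grid` object.
#' @export
pmf_grid <- function(centers, W, counts, temperature, breaks = NULL,
                     iterations = NA_integer_, final_change = NA_real_,
                     converged = NA) {
  if (!is.list(centers)) centers <- list(centers)
  W <- array(W, dim = vapply(centers, length, 1L))
  counts <- array(counts, dim = dim(W))
  covered <- counts > 0
  if (any(covered)) W <- W - min(W[covered], na.rm = TRUE)
  W[!covered] <- NA_real_
  structure(list(centers = centers, W = W, counts = counts,
                 temperature = temperature, breaks = breaks,
                 iterations = iterations, final_change = final_change,
                 converged = converged, dim = length(centers)),
            class = "pmf_grid")
}

#' @export
print.pmf_grid <- function(x, ...) {
  cat(sprintf("<pmf_grid> %s bins, T=%g K, max W=%.3f kcal/mol%s\n",
              paste(dim(x$W), collapse = " x "), x$temperature,
              max(x$W, na.rm = TRUE),
              if (isTRUE(x$converged))
                sprintf(" (WHAM converged in %d iter)", x$iterations) else ""))
  invisible(x)
}

# default bin edges: the width must resolve both the window spacing and
# the biased distributions themselves (sd = sqrt(kT/k)); with stiff
# restraints the latter is the binding constraint, and bins wider than
# about one bias sd visibly distort the recovered profile
default_breaks <- function(windows, d, kTv) {
  cts <- sort(unique(vapply(windows, function(w) w$center[d], 1.0)))
  width <- if (length(cts) > 1) min(diff(cts)) / 2 else
    diff(range(unlist(lapply(windows, function(w) w$samples[, d])))) / 25
  kmax <- max(vapply(windows, function(w) w$k[d], 1.0))
  if (kmax > 0) width <- min(width, 0.8 * sqrt(kTv / kmax))
  lo <- min(vapply(windows, function(w) min(w$samples[, d]), 1.0))
  hi <- max(vapply(windows, function(w) max(w$samples[, d]), 1.0))
  seq(lo - 1e-9, hi + width, by = width)
}

#' Weighted histogram analysis method (WHAM)
#'
#' Self-consistent unbiasing of umbrella-window histograms into a single
#' potential of mean force, in one or two dimensions (the dimensionality
#' is taken from the windows).  Iteration stops when the maximum absolute
#' change of the window normalization free energies (in kT) between
#' successive iterations drops below `tolerance`; the conventional
#' density tolerance is 1e-3.
#'
#' @param ws a sampled [window_set] (from [sample_windows()] or
#'   [read_windows()]).
#' @param bins number of bins per axis (scalar or vector), or a list of
#'   explicit break vectors.  Default: bin width equal to half the window
#'   spacing, further capped at 0.8 standard deviations of the stiffest
#'   bias so the histogram resolves the per-window distributions.
#' @param tolerance convergence tolerance on the window free-energy change
#'   in kT (default 1e-3).
#' @param max_iter iteration cap (default 50000).  Non-convergence raises
#'   an error of class `pmfkit_wham_nonconvergence` carrying the last grid
#'   in its `grid` field.
#' @return A [pmf_grid()].
#' @export
wham <- function(ws, bins = NULL, tolerance = 1e-3, max_iter = 50000L) {
  stopifnot(inherits(ws, "window_set"))
  windows <- ws$windows
  if (!length(windows)) stop("need at least one window")
  if (any(vapply(windows, function(w) is.null(w$samples), TRUE)))
    stop("windows carry no samples; run sample_windows() first")
  temps <- vapply(windows, function(w) w$temperature, 1.0)
  if (max(temps) - min(temps) > 1e-9)
    stop("mixed-temperature window sets are not supported")
  ndim <- ncol(windows[[1]]$samples)
  kTv <- kT(temps[1])

  breaks <- if (is.list(bins)) bins else lapply(seq_len(ndim), function(d) {
    if (is.null(bins)) default_breaks(windows, d, kTv) else {
      nb <- if (length(bins) > 1) bins[d] else bins
      lo <- min(vapply(windows, function(w) min(w$samples[, d]), 1.0))
      hi <- max(vapply(windows, function(w) max(w$samples[, d]), 1.0))
      seq(lo - 1e-9, hi + 1e-9, length.out = nb + 1)
    }
  })
  centers <- lapply(breaks, function(b) (b[-1] + b[-length(b)]) / 2)
  nb <- vapply(centers, length, 1L)
  B <- prod(nb)
  nw <- length(windows)

  # per-window histograms over the flattened bin grid
  counts <- matrix(0, nw, B)
  for (i in seq_len(nw)) {
    s <- windows[[i]]$samples
    ix <- findInterval(s[, 1], breaks[[1]], rightmost.closed = TRUE)
    ok <- ix >= 1 & ix <= nb[1]
    lin <- ix
    if (ndim == 2) {
      iy <- findInterval(s[, 2], breaks[[2]], rightmost.closed = TRUE)
      ok <- ok & iy >= 1 & iy <= nb[2]
      lin <- ix + (iy - 1) * nb[1]
    }
    tab <- tabulate(lin[ok], nbins = B)
    counts[i, ] <- tab
  }
  n_tot <- colSums(counts)
  check_histogram_connectivity(n_tot, nb)

  # bias Boltzmann factor of every window at every bin center
  grid_pts <- as.matrix(expand.grid(centers, KEEP.OUT.ATTRS = FALSE))
  U <- matrix(0, nw, B)
  for (i in seq_len(nw)) {
    w <- windows[[i]]
    for (d in seq_len(ndim))
      U[i, ] <- U[i, ] + 0.5 * w$k[d] * (grid_pts[, d] - w$center[d])^2
  }
  expU <- exp(-U / kTv)
  Ni <- rowSums(counts)

  f <- numeric(nw)                      # window free energies, kT units
  it <- 0L
  delta <- Inf
  repeat {
    it <- it + 1L
    denom <- colSums(Ni * exp(f) * expU)
    P <- ifelse(denom > 0, n_tot / denom, 0)
    Z <- sum(P)
    P <- P / Z
    f_new <- -log(pmax(expU %*% P, .Machine$double.xmin))[, 1]
    f_new <- f_new - f_new[1]
    delta <- max(abs(f_new - f))
    f <- f_new
    if (delta < tolerance || it >= max_iter) break
  }
  W <- -kTv * log(ifelse(P > 0, P, NA_real_))
  grid <- pmf_grid(centers, W, n_tot, temps[1], breaks = breaks,
                   iterations = it, final_change = delta,
                   converged = delta < tolerance)
  if (delta >= tolerance) {
    cond <- structure(
      class = c("pmfkit_wham_nonconvergence", "error", "condition"),
      list(message = sprintf(
        "WHAM did not converge in %d iterations (last change %.3g kT)",
        max_iter, delta), call = sys.call(-1), grid = grid))
    stop(cond)
  }
  grid
}

#' @rdname wham
#' @param bins_x,bins_y per-axis bin counts for the 2D case.
#' @export
wham2d <- function(ws, bins_x = NULL, bins_y = NULL, tolerance = 1e-3,
                   max_iter = 50000L) {
  if (ws$dim != 2) stop("wham2d() expects 2D windows")
  bins <- if (is.null(bins_x)) NULL else c(bins_x, bins_y %||% bins_x)
  wham(ws, bins = bins, tolerance = tolerance, max_iter = max_iter)
}

# coverage check: the occupied bins must essentially form one connected
# component (1D: contiguous run; 2D: 8-connected).  Sparse stray bins at
# distribution fringes are tolerated; the check fails only when more than
# 1% of all samples fall outside the dominant component, which is what
# genuinely non-overlapping windows produce.
check_histogram_connectivity <- function(n_tot, nb) {
  occ <- n_tot > 0
  if (!any(occ)) stop("all histogram bins are empty")
  lab <- if (length(nb) == 1)
    flood_components(matrix(occ, ncol = 1)) else
      flood_components(matrix(occ, nb[1], nb[2]))
  ncomp <- max(lab, na.rm = TRUE)
  if (ncomp > 1) {
    mass <- vapply(seq_len(ncomp), function(k)
      sum(n_tot[which(lab == k)]), 1.0)
    if (max(mass) < 0.99 * sum(mass))
      stop("disconnected histogram: umbrella windows do not overlap ",
           "(multiple occupied components of comparable weight)")
  }
  invisible(TRUE)
}

# 8-connected component labelling on a logical matrix (BFS)
flood_components <- function(occ) {
  lab <- array(NA_integer_, dim(occ))
  comp <- 0L
  nr <- nrow(occ); nc <- ncol(occ)
  for (start in which(occ)) {
    if (!is.na(lab[start])) next
    comp <- comp + 1L
    queue <- start
    lab[start] <- comp
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      i <- (cur - 1) %% nr + 1; j <- (cur - 1) %/% nr + 1
      for (di in -1:1) for (dj in -1:1) {
        ii <- i + di; jj <- j + dj
        if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc) {
          nxt <- ii + (jj - 1) * nr
          if (occ[nxt] && is.na(lab[nxt])) {
            lab[nxt] <- comp
            queue <- c(queue, nxt)
          }
        }
      }
    }
  }
  lab
}

#' Activation free energy from a PMF grid
#'
#' The activation free energy is approximated as the PMF change between
#' the highest covered point of the transition-state region and the lowest
#' covered point of the reactant region.  The Jacobian
#' free-energy term associated with fixing the reaction coordinate at the
#' reactant state is deliberately neglected (it is ordinarily a small
#' contribution), so the returned quantity is the plain PMF difference.
#'
#' @param grid a [pmf_grid()].
#' @param reactant_region,ts_region per-axis `c(lo, hi)` coordinate ranges
#'   (a 2-vector in 1D, a list of two 2-vectors in 2D).
#' @return Delta-W in kcal/mol.
#' @export
activation_free_energy <- function(grid, reactant_region, ts_region) {
  stopifnot(inherits(grid, "pmf_grid"))
  sel_bins <- function(region) {
    if (!is.list(region)) region <- list(region)
    stopifnot(length(region) == grid$dim)
    masks <- lapply(seq_len(grid$dim), function(d)
      grid$centers[[d]] >= region[[d]][1] & grid$centers[[d]] <= region[[d]][2])
    m <- if (grid$dim == 1) masks[[1]] else outer(masks[[1]], masks[[2]], `&`)
    vals <- grid$W[m]
    vals <- vals[!is.na(vals)]
    if (!length(vals)) stop("region contains no covered bins")
    vals
  }
  max(sel_bins(ts_region)) - min(sel_bins(reactant_region))
}

#' Reference PMF by direct Boltzmann inversion
#'
#' Exhaustive numerical integration of `exp(-V/kT)` of an analytic
#' surface over each bin cell (tensor-product midpoint quadrature),
#' giving the exact discretized free energy the WHAM estimate must
#' converge to.  This is the package's independent oracle for all
#' sampling-based estimators.
#'
#' @param model an [analytic_surface].
#' @param breaks list of bin-edge vectors (or a [pmf_grid()] whose binning
#'   should be replicated).
#' @param temperature K (default 310).
#' @param nquad quadrature points per bin per axis (default 11).
#' @return A [pmf_grid()] with `counts` set to 1 everywhere.
#' @export
reference_pmf <- function(model, breaks, temperature = 310, nquad = 11) {
  if (inherits(breaks, "pmf_grid")) breaks <- breaks$breaks
  if (!is.list(breaks)) breaks <- list(breaks)
  stopifnot(length(breaks) == model$dim)
  kTv <- kT(temperature)
  centers <- lapply(breaks, function(b) (b[-1] + b[-length(b)]) / 2)
  nb <- vapply(centers, length, 1L)
  quad <- lapply(breaks, function(b) {
    lapply(seq_len(length(b) - 1), function(i)
      seq(b[i], b[i + 1], length.out = nquad + 1)[-1] - diff(b)[i] / (2 * nquad))
  })
  if (model$dim == 1) {
    dens <- vapply(quad[[1]], function(xs)
      mean(exp(-model$energy(xs) / kTv)), 1.0)
  } else {
    dens <- array(0, nb)
    for (i in seq_len(nb[1])) for (j in seq_len(nb[2])) {
      g <- as.matrix(expand.grid(quad[[1]][[i]], quad[[2]][[j]]))
      dens[i, j] <- mean(exp(-model$energy(g) / kTv))
    }
  }
  W <- -kTv * log(dens)
  pmf_grid(centers, W, array(1L, nb), temperature, breaks = breaks,
           iterations = 0L, final_change = 0, converged = TRUE)
}

#' Write / read PMF grids as TSV
#'
#' Columns: bin center(s), W (kcal/mol), count; `#` headers carry the
#' schema version and temperature.  Empty bins are written with `NA` W.
#'
#' @param grid a [pmf_grid()].
#' @param path file path.
#' @export
write_pmf_tsv <- function(grid, path) {
  pts <- expand.grid(grid$centers, KEEP.OUT.ATTRS = FALSE)
  names(pts) <- paste0("xi", seq_len(grid$dim))
  pts$W <- as.vector(grid$W)
  pts$count <- as.vector(grid$counts)
  con <- file(path, "w")
  writeLines(c("# pmfkit-pmf v1",
               paste0("# T= ", format(grid$temperature, digits = 12)),
               paste0("# dim= ", grid$dim)), con)
  suppressWarnings(utils::write.table(pts, con, sep = "\t", quote = FALSE,
                                      row.names = FALSE))
  close(con)
  invisible(path)
}

#' @rdname write_pmf_tsv
#' @export
read_pmf_tsv <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  temp <- as.numeric(sub("^#\\s*T=\\s*", "", hdr[grepl("^#\\s*T=", hdr)][1]))
  tab <- utils::read.table(text = lines[!startsWith(lines, "#")],
                           header = TRUE, sep = "\t")
  dimn <- sum(startsWith(names(tab), "xi"))
  centers <- lapply(seq_len(dimn), function(d) sort(unique(tab[[d]])))
  nb <- vapply(centers, length, 1L)
  ord <- do.call(order, rev(tab[seq_len(dimn)]))
  tab <- tab[ord, ]
  pmf_grid(centers, tab$W, tab$count, temp, converged = TRUE, iterations = 0L)
}
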