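#' Harmonic umbrella bias
#'
#' Harmonic restraint `0.5 * k * (xi - center)^2` on one or two coordinates
#' of an energy model (or, via `rc`, on a reaction coordinate of a
#' molecular frame).  A force constant of zero leaves an axis unbiased.
#'
#' @param center bias center(s), Angstrom; one value per biased axis.
#' @param k force constant(s), kcal/mol/A^2.  The conventional default for
#'   chemically stiff coordinates is `kj_to_kcal(2500)` = 597.51.
#' @param rc optional [rc_distance()]-style coordinate when the bias acts
#'   on a molecular frame rather than a model axis.
#' @return A `bias_potential` object.
#' @export
bias_potential <- function(center, k = kj_to_kcal(2500), rc = NULL) {
  if (length(k) == 1 && length(center) > 1) k <- rep(k, length(center))
  stopifnot(length(k) == length(center), all(k >= 0))
  structure(list(center = center, k = k, rc = rc), class = "bias_potential")
}

#' @rdname bias_potential
#' @param bias a `bias_potential`.
#' @param xi coordinate value(s) (vector or matrix, one column per axis).
#' @return bias energy in kcal/mol (always >= 0).
#' @export
bias_energy <- function(bias, xi) {
  xi <- as_coords(xi, length(bias$center))
  rowSums(sweep(sweep(xi, 2, bias$center)^2, 2, 0.5 * bias$k, `*`))
}

#' Langevin sampling of an energy model
#'
#' BAOAB-discretized Langevin dynamics on an [analytic_surface] (or any
#' model exposing `energy`/`gradient` closures and `dim`), optionally
#' under a harmonic umbrella bias.  Reduced units: energies kcal/mol,
#' distances Angstrom, unit mass, time in ps-like reduced units.  The
#' known analytic forms run through a compiled kernel; arbitrary closures
#' fall back to an R-level loop.  Both draw from R's RNG, so
#' `seed` fixes the trajectory bitwise.
#'
#' @param model energy model.
#' @param bias optional [bias_potential()] (NULL = unbiased).
#' @param n_steps number of retained samples.
#' @param dt integrator time step (default 0.01).
#' @param temperature K (default 310).
#' @param friction Langevin friction, 1/time (default 5).
#' @param seed RNG seed (default 0).
#' @param x0 start coordinates (default: bias center, else model minimum
#'   guess at domain midpoint).
#' @param mass particle mass (reduced, default 1).
#' @param stride keep every `stride`-th step (default 1).
#' @param n_discard equilibration steps dropped before sampling.
#' @return list with `x` (n_steps x dim matrix of retained coordinates)
#'   and `xi` (the biased-axis series; equals `x` when unbiased).
#' @export
langevin_run <- function(model, bias = NULL, n_steps = 2000, dt = 0.01,
                         temperature = 310, friction = 5, seed = 0,
                         x0 = NULL, mass = 1, stride = 1L, n_discard = 0L) {
  stopifnot(dt > 0, friction > 0, n_steps > 0, stride >= 1)
  dim <- model$dim
  if (is.null(x0))
    x0 <- if (!is.null(bias)) bias$center else colMeans(model$domain)
  x0 <- as.numeric(x0)
  stopifnot(length(x0) == dim)
  bc <- if (is.null(bias)) rep(0, dim) else bias$center
  bk <- if (is.null(bias)) rep(0, dim) else bias$k
  stopifnot(length(bc) == dim)
  kTv <- kT(temperature)
  form_code <- c(harmonic = 1L, double_well = 2L, separable_2d = 3L,
                 coupled_2d = 5L)[model$form]
  if (!is.null(seed)) set.seed(seed)
  if (!is.na(form_code)) {
    if (model$form == "separable_2d" && "hy" %in% names(model$params))
      form_code <- 4L
    p <- unname(model$params)
    x <- langevin_kernel(form_code, p, x0, as.integer(n_steps),
                         as.integer(stride), as.integer(n_discard),
                         dt, kTv, friction, mass, bc, bk)
  } else {
    x <- langevin_r(model, x0, n_steps, stride, n_discard, dt, kTv,
                    friction, mass, bc, bk)
  }
  colnames(x) <- paste0("xi", seq_len(dim))
  xi <- if (!is.null(bias)) x[, which(bk > 0), drop = dim > 1] else x
  list(x = x, xi = xi)
}

# reference R implementation of the same BAOAB scheme (arbitrary closures)
langevin_r <- function(model, x0, n_sample, stride, n_discard, dt, kTv,
                       friction, mass, bc, bk) {
  dim <- length(x0)
  x <- x0
  v <- if (kTv > 0) sqrt(kTv / mass) * stats::rnorm(dim) else rep(0, dim)
  c1 <- exp(-friction * dt)
  c2 <- if (kTv > 0) sqrt((1 - c1^2) * kTv / mass) else 0
  force <- function(x) -as.numeric(model$gradient(x)) - bk * (x - bc)
  f <- force(x)
  total <- n_discard + n_sample * stride
  out <- matrix(NA_real_, n_sample, dim)
  kept <- 0L
  for (step in seq_len(total)) {
    v <- v + 0.5 * dt * f / mass
    x <- x + 0.5 * dt * v
    v <- c1 * v + c2 * stats::rnorm(dim)
    x <- x + 0.5 * dt * v
    f <- force(x)
    v <- v + 0.5 * dt * f / mass
    e <- as.numeric(model$energy(x)) + sum(0.5 * bk * (x - bc)^2)
    if (!is.finite(e) || e > 1e10)
      stop("Langevin trajectory diverged (energy overflow at step ", step, ")")
    if (step > n_discard && (step - n_discard) %% stride == 0) {
      kept <- kept + 1L
      out[kept, ] <- x
    }
  }
  out
}

#' Grid scan of an energy surface
#'
#' Evaluates (and, when the model has more dimensions than the scan,
#' minimizes over the remaining coordinates) the energy on a rectilinear
#' grid, marching from each node to the next so every minimization starts
#' from the previous node's relaxed configuration.  This is the standard
#' way potential energy surfaces are generated before seeding umbrella
#' windows.
#'
#' @param model energy model.
#' @param axes list of `c(start, stop, step)` triples, one per scanned
#'   coordinate (step > 0).
#' @param dims model coordinate indices the axes refer to (default
#'   `1:length(axes)`).
#' @return A `scan_grid`: list with `centers` (list of node coordinate
#'   vectors), `dims`, `energies` (array over nodes), `configs` (matrix of
#'   full relaxed coordinates, nodes x model-dim, first axis fastest).
#' @export
grid_scan <- function(model, axes, dims = seq_along(axes)) {
  if (!is.list(axes)) axes <- list(axes)
  centers <- lapply(axes, function(a) {
    stopifnot(length(a) == 3, a[3] > 0)
    seq(a[1], a[2], by = a[3])
  })
  stopifnot(length(dims) == length(axes), all(dims <= model$dim))
  nodes <- as.matrix(expand.grid(centers, KEEP.OUT.ATTRS = FALSE))
  free <- setdiff(seq_len(model$dim), dims)
  nn <- nrow(nodes)
  energies <- numeric(nn)
  configs <- matrix(0, nn, model$dim)
  prev_free <- colMeans(model$domain)[free]
  for (i in seq_len(nn)) {
    full <- numeric(model$dim)
    full[dims] <- nodes[i, ]
    if (length(free) == 0) {
      energies[i] <- as.numeric(model$energy(full))
    } else {
      obj <- function(z) { full[free] <- z; as.numeric(model$energy(full)) }
      opt <- stats::optim(prev_free, obj, method = "BFGS")
      prev_free <- opt$par
      full[free] <- opt$par
      energies[i] <- opt$value
    }
    if (!is.finite(energies[i]))
      stop("non-finite energy at scan node ", i)
    configs[i, ] <- full
  }
  structure(list(centers = centers, dims = dims,
                 energies = array(energies, vapply(centers, length, 1L)),
                 configs = configs, form = model$form),
            class = "scan_grid")
}

#' Build umbrella windows from a scan grid
#'
#' One window per selected grid node, centered at the node's coordinate
#' values and seeded with the node's relaxed configuration.
#'
#' @param grid a [grid_scan()] result.
#' @param k force constant, kcal/mol/A^2 (scalar or per-axis).  Default
#'   `kj_to_kcal(2500)` = 597.51, the conventional stiff-restraint value.
#' @param temperature K (default 310).
#' @param spacing keep every `spacing`-th node along each axis (default 1).
#' @param equil_time,prod_time equilibration discard and production length
#'   in reduced time units (defaults 5 and 20); converted to step counts
#'   at sampling time.
#' @return A `window_set`.
#' @export
build_windows <- function(grid, k = kj_to_kcal(2500), temperature = 310,
                          spacing = 1L, equil_time = 5, prod_time = 20) {
  stopifnot(inherits(grid, "scan_grid"), spacing >= 1)
  sel <- lapply(grid$centers, function(cc) seq(1, length(cc), by = spacing))
  keep_idx <- as.matrix(expand.grid(sel, KEEP.OUT.ATTRS = FALSE))
  sizes <- vapply(grid$centers, length, 1L)
  lin <- as.vector(keep_idx %*% cumprod(c(1, sizes[-length(sizes)])) -
                     sum(cumprod(c(1, sizes[-length(sizes)]))) + 1)
  if (!length(lin)) stop("empty window selection")
  dimn <- length(grid$centers)
  if (length(k) == 1) k <- rep(k, dimn)
  windows <- lapply(seq_along(lin), function(j) {
    i <- lin[j]
    list(center = vapply(seq_len(dimn),
                         function(d) grid$centers[[d]][keep_idx[j, d]], 1.0),
         k = k, temperature = temperature,
         seed_config = grid$configs[i, ],
         equil_time = equil_time, prod_time = prod_time,
         samples = NULL)
  })
  structure(list(windows = windows, temperature = temperature, dim = dimn),
            class = "window_set")
}

#' @export
print.window_set <- function(x, ...) {
  ns <- vapply(x$windows, function(w) length(w$samples) %||% 0L, 1L)
  cat(sprintf("<window_set> %d windows, dim=%d, T=%g K, %s\n",
              length(x$windows), x$dim, x$temperature,
              if (all(ns > 0)) "sampled" else "unsampled"))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run umbrella sampling over a window set
#'
#' Runs one biased Langevin trajectory per window: `equil_time/dt` steps
#' are discarded, then `prod_time/dt` production steps are retained at the
#' given stride.  Windows are sampled sequentially from a single RNG
#' stream, so `seed` makes the whole set reproducible.
#'
#' @param ws a [build_windows()] result.
#' @param model the energy model the windows were seeded from.
#' @param dt,friction,stride,mass integrator settings (see [langevin_run()]).
#' @param seed RNG seed for the whole set.
#' @param n_samples optional override of the per-window production sample
#'   count (replaces `prod_time/dt / stride`).
#' @return the window set with `samples` filled (matrix, one column per
#'   biased axis).
#' @export
sample_windows <- function(ws, model, dt = 0.01, friction = 5, stride = 1L,
                           mass = 1, seed = 0, n_samples = NULL) {
  stopifnot(inherits(ws, "window_set"))
  set.seed(seed)
  ws$windows <- lapply(ws$windows, function(w) {
    n_eq <- as.integer(round(w$equil_time / dt))
    n_pr <- if (is.null(n_samples))
      as.integer(round(w$prod_time / dt / stride)) else as.integer(n_samples)
    bias <- bias_potential(w$center, w$k)
    x0 <- w$seed_config[seq_along(w$center)]
    run <- langevin_run(model, bias, n_steps = n_pr, dt = dt,
                        temperature = w$temperature, friction = friction,
                        seed = NULL, x0 = w$seed_config, mass = mass,
                        stride = stride, n_discard = n_eq)
    w$samples <- run$x
    w
  })
  ws
}

#' Write / read umbrella-window sample files
#'
#' One plain-text file per window: `#`-prefixed header lines carrying the
#' bias center, force constant and temperature, then one sample per line
#' (two whitespace-separated columns for 2D windows).  This is the
#' interchange format between the sampling and WHAM stages.
#'
#' @param ws a sampled `window_set`.
#' @param dir output directory (created if needed).
#' @return `write_windows`: the file paths, invisibly.
#' @export
write_windows <- function(ws, dir) {
  stopifnot(inherits(ws, "window_set"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(length(ws$windows))
  for (i in seq_along(ws$windows)) {
    w <- ws$windows[[i]]
    if (is.null(w$samples)) stop("window ", i, " has no samples")
    p <- file.path(dir, sprintf("window_%04d.tsv", i))
    con <- file(p, "w")
    writeLines(c("# pmfkit-window v1",
                 paste("# center=", paste(format(w$center, digits = 12), collapse = " ")),
                 paste("# k=", paste(format(w$k, digits = 12), collapse = " ")),
                 paste("# T=", format(w$temperature, digits = 12))), con)
    utils::write.table(round(w$samples, 8), con, row.names = FALSE,
                       col.names = FALSE)
    close(con)
    paths[i] <- p
  }
  invisible(paths)
}

#' @rdname write_windows
#' @param paths directory containing window files, or explicit file paths.
#' @export
read_windows <- function(paths) {
  if (length(paths) == 1 && dir.exists(paths))
    paths <- list.files(paths, pattern = "\\.tsv$", full.names = TRUE)
  if (!length(paths)) stop("no window files found")
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("no such window file(s): ", paste(missing, collapse = ", "))
  windows <- lapply(paths, function(p) {
    lines <- readLines(p)
    hdr <- lines[startsWith(lines, "#")]
    getv <- function(key) {
      ln <- hdr[grepl(paste0("^#\\s*", key, "="), hdr)]
      if (!length(ln)) stop("window file ", p, " lacks '# ", key, "=' header")
      as.numeric(strsplit(trimws(sub(paste0("^#\\s*", key, "="), "", ln[1])),
                          "\\s+")[[1]])
    }
    center <- getv("center"); k <- getv("k"); temp <- getv("T")
    body <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
    if (!length(body)) stop("window file ", p, " has no samples")
    samples <- do.call(rbind, lapply(strsplit(trimws(body), "\\s+"), as.numeric))
    if (!all(is.finite(samples))) stop("non-finite sample in ", p)
    if (ncol(samples) != length(center))
      stop("sample dimensionality does not match center in ", p)
    list(center = center, k = k, temperature = temp,
         seed_config = center, equil_time = 0, prod_time = NA,
         samples = samples)
  })
  temps <- vapply(windows, function(w) w$temperature, 1.0)
  if (length(unique(temps)) > 1)
    stop("mixed-temperature window sets are not supported")
  structure(list(windows = windows, temperature = temps[1],
                 dim = length(windows[[1]]$center)),
            class = "window_set")
}
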