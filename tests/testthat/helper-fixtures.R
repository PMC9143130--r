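# shared helpers for building small frames and numeric oracles

make_test_frame <- function(xyz, element = rep("C", nrow(xyz))) {
  coordinate_frame(data.frame(
    name = paste0(element, seq_len(nrow(xyz))), element = element,
    resno = seq_len(nrow(xyz)),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    stringsAsFactors = FALSE))
}

random_frame <- function(n = 6, sd = 2) {
  make_test_frame(matrix(stats::rnorm(3 * n, sd = sd), n, 3))
}

# central finite-difference gradient of a reaction coordinate
fd_gradient <- function(rc, frame, h = 1e-5) {
  xyz <- frame_coords(frame)
  g <- matrix(0, nrow(xyz), 3)
  for (i in seq_len(nrow(xyz))) for (j in 1:3) {
    xp <- xyz; xp[i, j] <- xp[i, j] + h
    xm <- xyz; xm[i, j] <- xm[i, j] - h
    g[i, j] <- (rc_evaluate(rc, set_coords(frame, xp)) -
                  rc_evaluate(rc, set_coords(frame, xm))) / (2 * h)
  }
  g
}

random_rigid_transform <- function() {
  ax <- stats::rnorm(3)
  list(rotation = rotation_matrix(ax, stats::runif(1, 0, 360)),
       translation = stats::rnorm(3, sd = 5))
}

# direct measurement of an H-bond fixture (independent of detect_hbonds)
measure_hbond <- function(fx) {
  xyz <- frame_coords(fx$frame)
  d <- xyz[fx$roles$donor, ]; h <- xyz[fx$roles$hydrogen, ]
  a <- xyz[fx$roles$acceptor, ]
  v1 <- d - h; v2 <- a - h
  list(d_da = sqrt(sum((d - a)^2)),
       theta = acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi)
}

# small sampled 1D double-well window set shared by several tests
cached_dw_windows <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      dw <- make_double_well(5, 1)
      grid <- grid_scan(dw, list(c(-1.5, 1.5, 0.1)))
      ws <- build_windows(grid)
      cache <<- sample_windows(ws, dw, dt = 0.01, stride = 5, seed = 11,
                               n_samples = 5000)
    }
    cache
  }
})
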