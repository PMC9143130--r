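# shared 2D umbrella-sampled separable surface (double well in x,
# harmonic in y): the traced path should run along y = 0 and its profile
# barrier should match the 1D analytic barrier
sampled_2d_grid <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      s2 <- make_separable_2d(5, 1, ky = 10)
      g <- grid_scan(s2, list(c(-1.5, 1.5, 0.1), c(-0.9, 0.9, 0.3)))
      ws <- build_windows(g, k = c(kj_to_kcal(2500), 50))
      ws <- sample_windows(ws, s2, dt = 0.01, stride = 5, seed = 21,
                           n_samples = 10000)
      cache <<- wham(ws)
    }
    cache
  }
})

test_that("2D WHAM of a separable surface separates within tolerance", {
  grid <- sampled_2d_grid()
  expect_true(grid$converged)
  ref <- reference_pmf(make_separable_2d(5, 1, ky = 10), grid$breaks)
  # compare along the well-sampled core (|y| small, the reaction channel)
  iy <- which(abs(grid$centers[[2]]) < 0.15)
  ok <- !is.na(grid$W[, iy])
  expect_lt(sqrt(mean((grid$W[, iy][ok] - ref$W[, iy][ok])^2)), 0.3)
})

test_that("traced maximum-probability path recovers the 1D barrier", {
  grid <- sampled_2d_grid()
  tp <- trace_path(grid, c(-1, 0), c(1, 0))
  expect_lt(abs(tp$barrier - 5.0), 0.3)
  # path stays in the harmonic-minimum channel
  expect_lt(max(abs(tp$coords[, 2])), 0.25)
  # grid maximum along the path sits at the origin within one bin
  imax <- which.max(tp$profile)
  expect_lt(abs(tp$coords[imax, 1]), diff(grid$centers[[1]])[1] + 1e-9)
  expect_lt(abs(tp$coords[imax, 2]), diff(grid$centers[[2]])[1] + 1e-9)
})

test_that("degenerate path queries behave contractually", {
  grid <- sampled_2d_grid()
  tp <- trace_path(grid, c(-1, 0), c(-1, 0))
  expect_equal(nrow(tp$bins), 1L)
  expect_length(tp$profile, 0)
  expect_equal(tp$barrier, 0)
})

test_that("path tracing is deterministic on tied symmetric surfaces", {
  # two mirror channels of exactly equal cost
  x <- seq(-1, 1, 0.1); y <- seq(-1, 1, 0.1)
  W <- outer(x, y, function(a, b) 2 * (1 - b^2)^2 + 0.5 * a^2)
  g <- pmf_grid(list(x, y), W, array(10L, c(21L, 21L)), 310)
  t1 <- trace_path(g, c(-1, 0), c(1, 0))
  t2 <- trace_path(g, c(-1, 0), c(1, 0))
  expect_identical(t1$bins, t2$bins)
})

test_that("profile assembly stitches printed stationary-point segments", {
  segs <- hbelc_profile_segments()
  prof <- assemble_profile(segs)
  expect_s3_class(prof, "free_energy_profile")
  expect_equal(prof$label, c("E.I", "TS1", "E-I2", "TS3", "E-PC"))
  expect_equal(prof$type, c("minimum", "saddle", "minimum", "saddle", "minimum"))
  expect_equal(prof$G, c(0, 24.9, 1.9, 21.0, -15.6))
  expect_equal(attr(prof, "reference"), "E.I")
  # single segment is the identity
  p1 <- assemble_profile(segs[1])
  expect_equal(p1$G, segs[[1]]$G)
})

test_that("junction mismatches are rejected", {
  a <- data.frame(label = c("A", "TS", "B"),
                  type = c("minimum", "saddle", "minimum"),
                  G = c(0, 3, 1))
  b_bad_g <- data.frame(label = c("B", "TS2", "C"),
                        type = c("minimum", "saddle", "minimum"),
                        G = c(1 + 1e-6, 4, -2))
  b_bad_lab <- data.frame(label = c("X", "TS2", "C"),
                          type = c("minimum", "saddle", "minimum"),
                          G = c(1, 4, -2))
  expect_error(assemble_profile(list(a, b_bad_g)), "free-energy mismatch")
  expect_error(assemble_profile(list(a, b_bad_lab)), "label mismatch")
  expect_error(free_energy_profile(c("A", "B"), c("minimum", "minimum"),
                                   c(0, 1)), "alternate")
  expect_error(free_energy_profile(c("A", "A"), c("minimum", "saddle"),
                                   c(0, 1)), "unique")
})

test_that("barrier queries reproduce the printed profile arithmetic", {
  prof <- assemble_profile(hbelc_profile_segments())
  expect_equal(barrier_query(prof, "E.I", "TS1"), 24.9)
  expect_equal(barrier_query(prof, "E.I", "E-I2"), 24.9)
  expect_equal(barrier_query(prof, "E-I2", "E-PC"), 21.0 - 1.9)
  expect_equal(barrier_query(prof, "E-PC", "E.I"), 24.9 - (-15.6))
  expect_equal(barrier_query(prof, "E-PC", "E-PC"), 0)
  expect_error(barrier_query(prof, "E.I", "missing"), "unknown state")
})

test_that("profiles round-trip through the TSV format", {
  prof <- assemble_profile(hbelc_profile_segments())
  path <- file.path(tempdir(), "prof_rt.tsv")
  write_profile_tsv(prof, path)
  p2 <- read_profile_tsv(path)
  expect_equal(p2$label, prof$label)
  expect_equal(p2$G, prof$G)
  expect_equal(attr(p2, "reference"), attr(prof, "reference"))
})
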