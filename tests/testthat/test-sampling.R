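test_that("bias potential is a non-negative harmonic", {
  b <- bias_potential(0.5, 100)
  expect_equal(bias_energy(b, 0.5), 0)
  expect_equal(bias_energy(b, 1.5), 50)
  expect_true(all(bias_energy(b, seq(-3, 3, 0.1)) >= 0))
  expect_error(bias_potential(0, -5), "k >= 0")
})

test_that("thermostatted sampling satisfies equipartition on a harmonic well", {
  kappa <- 10
  m <- make_harmonic(kappa)
  run <- langevin_run(m, n_steps = 2e5, dt = 0.01, temperature = 310,
                      friction = 2, seed = 1)
  expect_equal(var(run$x[, 1]), kT(310) / kappa, tolerance = 0.05)
  expect_equal(mean(run$x[, 1]), 0, tolerance = 0.02)
})

test_that("identical seeds give bitwise-identical trajectories", {
  m <- make_double_well(5, 1)
  r1 <- langevin_run(m, n_steps = 500, seed = 42)
  r2 <- langevin_run(m, n_steps = 500, seed = 42)
  r3 <- langevin_run(m, n_steps = 500, seed = 43)
  expect_identical(r1$x, r2$x)
  expect_false(identical(r1$x, r3$x))
})

test_that("zero-temperature dynamics descend to the minimum", {
  m <- make_harmonic(10)
  run <- langevin_run(m, n_steps = 4000, dt = 0.01, temperature = 0,
                      friction = 20, seed = 0, x0 = 0.3)
  x <- run$x[, 1]
  expect_lt(abs(x[length(x)]), 1e-6)
  # energy decays monotonically across coarse checkpoints
  e <- m$energy(x[seq(1, length(x), by = 400)])
  expect_true(all(diff(e) <= 1e-12))
})

test_that("compiled and R reference integrators agree", {
  dw <- make_double_well(5, 1)
  # strip the form tag so langevin_run takes the R fallback path
  generic <- dw
  generic$form <- "custom"
  r_cpp <- langevin_run(dw, n_steps = 200, seed = 9)
  r_ref <- langevin_run(generic, n_steps = 200, seed = 9)
  expect_equal(r_cpp$x, r_ref$x, tolerance = 1e-12)
})

test_that("diverging trajectories abort with a diagnostic", {
  m <- make_harmonic(10)
  expect_error(langevin_run(m, n_steps = 1000, dt = 10, seed = 0, x0 = 5),
               "diverged")
})

test_that("unbiased histograms converge to the Boltzmann density", {
  m <- make_harmonic(10)
  sdev <- sqrt(kT(310) / 10)
  ks <- vapply(c(500, 5000, 50000), function(n) {
    run <- langevin_run(m, n_steps = n, dt = 0.01, friction = 2, seed = 17,
                        stride = 5)
    suppressWarnings(stats::ks.test(run$x[, 1], "pnorm", 0, sdev)$statistic)
  }, 1.0)
  expect_true(all(diff(ks) < 0))
})

test_that("biased harmonic sampling centers on the closed-form mean", {
  kappa <- 10; kb <- 50; c0 <- 0.5
  m <- make_harmonic(kappa)
  run <- langevin_run(m, bias = bias_potential(c0, kb), n_steps = 4e4,
                      dt = 0.01, friction = 2, seed = 2, stride = 2)
  expect_equal(mean(run$x[, 1]), kb * c0 / (kappa + kb), tolerance = 0.05)
  expect_equal(var(run$x[, 1]), kT(310) / (kappa + kb), tolerance = 0.1)
})

test_that("grid scan enumerates nodes and honours per-axis steps", {
  dw <- make_double_well(5, 1)
  g <- grid_scan(dw, list(c(-1.5, 1.5, 0.1)))
  expect_length(g$centers[[1]], 31)
  # the inter-well barrier node: maximum between the two minima
  mid <- abs(g$centers[[1]]) < 1
  expect_equal(g$centers[[1]][mid][which.max(g$energies[mid])], 0)
  expect_equal(g$energies[g$centers[[1]] == 0], 5)
  expect_equal(g$energies[g$centers[[1]] == 1], 0)
  s2 <- make_separable_2d(5, 1, ky = 10)
  g2 <- grid_scan(s2, list(c(-0.2, 0.2, 0.05), c(-0.3, 0.3, 0.1)))
  expect_equal(diff(g2$centers[[1]])[1], 0.05)
  expect_equal(diff(g2$centers[[2]])[1], 0.1)
  expect_equal(dim(g2$energies), c(9L, 7L))
})

test_that("1D scan of a separable 2D surface relaxes onto the y-minimum line", {
  s2 <- make_separable_2d(5, 1, ky = 10)
  g <- grid_scan(s2, list(c(-1.5, 1.5, 0.25)), dims = 1)
  expect_lt(max(abs(g$configs[, 2])), 1e-4)   # minimum-energy path at y = 0
  expect_equal(as.vector(g$energies),
               as.numeric(make_double_well(5, 1)$energy(g$centers[[1]])),
               tolerance = 1e-6)
})

test_that("windows inherit grid nodes, defaults and seed configurations", {
  dw <- make_double_well(5, 1)
  g <- grid_scan(dw, list(c(-1.5, 1.5, 0.1)))
  ws <- build_windows(g)
  expect_length(ws$windows, 31)
  expect_equal(vapply(ws$windows, function(w) w$center, 1.0), g$centers[[1]])
  w <- ws$windows[[1]]
  expect_equal(w$k, 2500 / 4.184)             # 2500 kJ/mol/A^2 in kcal
  expect_equal(w$k, 597.51, tolerance = 1e-5)
  expect_equal(w$temperature, 310)
  expect_equal(w$equil_time, 5)               # discarded equilibration
  expect_equal(w$prod_time, 20)               # production length
  ws2 <- build_windows(g, spacing = 2)
  expect_length(ws2$windows, 16)
})

test_that("window files round-trip losslessly through the text format", {
  ws <- cached_dw_windows()
  dir <- file.path(tempdir(), "win_rt")
  write_windows(ws, dir)
  ws2 <- read_windows(dir)
  expect_length(ws2$windows, length(ws$windows))
  expect_equal(vapply(ws2$windows, function(w) w$center, 1.0),
               vapply(ws$windows, function(w) w$center, 1.0))
  expect_equal(ws2$windows[[5]]$samples, round(ws$windows[[5]]$samples, 8),
               ignore_attr = TRUE)
  expect_equal(ws2$temperature, 310)
})
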