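two_atom_frame <- function(r) {
  coordinate_frame(data.frame(name = c("A1", "B1"), element = "C",
                              resno = c(1L, 2L), x = c(0, r), y = 0, z = 0))
}

test_that("Coulomb term uses the conventional constant", {
  fr <- two_atom_frame(1)
  params <- data.frame(charge = c(1, 1), eps = c(0, 0), rmin2 = c(1, 1))
  res <- interaction_energies(fr, 1L, list(B = 2L), params)
  expect_equal(res$E_elec, 332.0636)
  expect_equal(res$E_vdW, 0)
  expect_equal(res$E_int, res$E_elec + res$E_vdW)
})

test_that("Lennard-Jones minimum sits at -eps at the combined Rmin", {
  params <- data.frame(charge = c(0, 0), eps = c(0.2, 0.2),
                       rmin2 = c(1.7, 1.7))
  fr <- two_atom_frame(3.4)   # r = Rmin_ij = 1.7 + 1.7
  res <- interaction_energies(fr, 1L, list(B = 2L), params)
  expect_equal(res$E_vdW, -0.2, tolerance = 1e-12)
  # slightly off the minimum the energy rises
  res2 <- interaction_energies(two_atom_frame(3.6), 1L, list(B = 2L), params)
  expect_gt(res2$E_vdW, res$E_vdW)
})

test_that("switching function is C1-continuous and vanishes beyond r_off", {
  expect_equal(switching_function(10), 1)
  expect_equal(switching_function(16), 0)
  expect_equal(switching_function(17), 0)
  h <- 1e-6
  for (r0 in c(14.5, 16)) {
    num <- (switching_function(r0 + h) - switching_function(r0 - h)) / (2 * h)
    expect_lt(abs(num), 1e-4)   # derivative -> 0 at both bounds
  }
  # monotone decay inside the switching region
  rs <- seq(14.5, 16, length.out = 50)
  expect_true(all(diff(switching_function(rs)) <= 0))
})

test_that("pairs beyond the outer cutoff contribute exactly zero", {
  params <- data.frame(charge = c(1, -1), eps = c(0.2, 0.2),
                       rmin2 = c(1.7, 1.7))
  res <- interaction_energies(two_atom_frame(16.5), 1L, list(B = 2L), params)
  expect_identical(res$E_elec, 0)
  expect_identical(res$E_vdW, 0)
})

test_that("per-residue terms partition the total ligand-environment energy", {
  set.seed(41)
  n_lig <- 4; n_env <- 12
  xyz <- rbind(matrix(stats::rnorm(n_lig * 3, sd = 1), n_lig, 3),
               matrix(stats::rnorm(n_env * 3, sd = 6), n_env, 3))
  fr <- coordinate_frame(data.frame(
    name = paste0("X", 1:(n_lig + n_env)), element = "C",
    resno = c(rep(1L, n_lig), rep(2:5, each = 3)),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]))
  params <- data.frame(charge = stats::runif(n_lig + n_env, -0.5, 0.5),
                       eps = stats::runif(n_lig + n_env, 0.05, 0.3),
                       rmin2 = stats::runif(n_lig + n_env, 1.2, 2.0))
  sels <- split((n_lig + 1):(n_lig + n_env), rep(1:4, each = 3))
  names(sels) <- paste0("R", 1:4)
  per_res <- interaction_energies(fr, 1:n_lig, sels, params)
  whole <- interaction_energies(fr, 1:n_lig,
                                list(ALL = (n_lig + 1):(n_lig + n_env)),
                                params)
  expect_equal(sum(per_res$E_int), whole$E_int, tolerance = 1e-9)
  expect_equal(sum(per_res$E_elec), whole$E_elec, tolerance = 1e-9)
  expect_equal(per_res$E_int, per_res$E_elec + per_res$E_vdW,
               tolerance = 1e-9)
  # symmetry under swapping ligand and residue roles
  swapped <- interaction_energies(fr, sels[[1]], list(L = 1:n_lig), params)
  expect_equal(swapped$E_int, per_res$E_int[1], tolerance = 1e-9)
})

test_that("missing parameters and overlapping selections are rejected", {
  fr <- two_atom_frame(2)
  params <- data.frame(charge = c(1, NA), eps = c(0.1, 0.1),
                       rmin2 = c(1.7, 1.7))
  expect_error(interaction_energies(fr, 1L, list(B = 2L), params),
               "missing nonbonded parameters")
  good <- data.frame(charge = c(1, -1), eps = c(0.1, 0.1),
                     rmin2 = c(1.7, 1.7))
  expect_error(interaction_energies(fr, 1L, list(B = 1L), good), "disjoint")
})

test_that("interaction ranking filters, sorts and breaks ties by residue", {
  a <- structure(data.frame(residue = c("ARG19", "ASP17", "GLY47", "LYS33"),
                            E_int = c(-3, 10, -2, -4)),
                 class = c("residue_interactions", "data.frame"))
  b <- a
  b$E_int <- c(-3.5, 15.2, -2, -9.2)
  tab <- rank_interactions(a, b)
  expect_equal(tab$residue, c("ASP17", "LYS33"))   # |5.2|, |5.2| tie -> id order
  expect_equal(tab$dE_int, c(5.2, -5.2))
  expect_equal(nrow(rank_interactions(a, a)), 0L)
  one <- a; one$E_int[2] <- a$E_int[2] + 0.5
  expect_equal(nrow(rank_interactions(a, one)), 0L)   # below 1 kcal/mol
  bad <- a; bad$residue[1] <- "OTHER"
  expect_error(rank_interactions(a, bad), "residue lists differ")
})

test_that("parameter tables map onto frames by atom name", {
  path <- file.path(tempdir(), "params.tsv")
  write.table(data.frame(name = c("A1", "B1"), charge = c(0.3, -0.3),
                         eps = c(0.1, 0.2), rmin2 = c(1.5, 1.8)),
              path, sep = "\t", row.names = FALSE, quote = FALSE)
  fr <- two_atom_frame(2)
  p <- read_params_tsv(path, fr)
  expect_equal(p$charge, c(0.3, -0.3))
  fr_bad <- coordinate_frame(data.frame(name = "ZZ", element = "C",
                                        x = 0, y = 0, z = 0))
  expect_error(read_params_tsv(path, fr_bad), "ZZ")
})
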