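test_that("attack fixtures invert the attack-geometry measurement", {
  # the two Michaelis-complex geometries plus trivial edge cases
  cases <- list(c(2.46, 102, 9), c(2.35, 97, 6), c(1.5, 180, 0), c(2.5, 90, 0))
  for (p in cases) {
    g <- measure_attack(make_attack_fixture(p[1], p[2], p[3]))
    expect_equal(c(g$d_nu_c, g$alpha_bd, g$alpha_fl), p, tolerance = 1e-6)
  }
  # 200 random reachable parameter draws
  set.seed(101)
  for (i in 1:200) {
    d <- stats::runif(1, 1.2, 3.5)
    bd <- stats::runif(1, 5, 175)
    fl <- rad2deg(asin(stats::runif(1, -0.95, 0.95) * sin(deg2rad(bd))))
    g <- measure_attack(make_attack_fixture(d, bd, fl, seed = i))
    expect_equal(c(g$d_nu_c, g$alpha_bd, g$alpha_fl), c(d, bd, fl),
                 tolerance = 1e-6)
  }
})

test_that("in-plane nucleophiles have zero Flippin-Lodge angle", {
  # nucleophile placed in the plane spanned by the C->O axis and the
  # electrophile-plane normal
  xyz <- rbind(C = c(0, 0, 0), O = c(1.23, 0, 0),
               S1 = 1.5 * c(cos(-2 * pi / 3), sin(-2 * pi / 3), 0),
               S2 = 1.5 * c(cos(2 * pi / 3), sin(2 * pi / 3), 0),
               NU = c(-0.5, 0, 2.0), SP = c(5, 5, 5))
  fr <- make_test_frame(xyz)
  g <- attack_geometry(fr, 5, 1, 2, 3, 4)
  expect_equal(g$alpha_fl, 0, tolerance = 1e-9)
  expect_error(attack_geometry(fr, 5, 1, 2, 2, 4), "distinct")
  # collinear substituents leave the plane undefined
  bad <- make_test_frame(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0),
                               c(3, 0, 0), c(0, 0, 2), c(5, 5, 5)))
  expect_error(attack_geometry(bad, 5, 1, 2, 3, 4), "collinear")
})

test_that("attack geometry is invariant under rigid-body motion", {
  set.seed(13)
  for (i in 1:20) {
    fx <- make_attack_fixture(2.4, 110, -15, seed = i)
    tr <- random_rigid_transform()
    fr2 <- transform_frame(fx$frame, tr$rotation, tr$translation)
    g0 <- measure_attack(fx)
    g1 <- attack_geometry(fr2, 5, 1, 2, 3, 4)
    expect_equal(c(g1$d_nu_c, g1$alpha_bd, g1$alpha_fl),
                 c(g0$d_nu_c, g0$alpha_bd, g0$alpha_fl), tolerance = 1e-9)
  }
})

test_that("H-bond detection applies inclusive geometric criteria", {
  hit <- function(d, a) nrow(suppressWarnings(
    detect_hbonds(make_hbond_fixture(d, a)$frame))$records)
  expect_equal(hit(2.9, 160), 1L)
  expect_equal(hit(3.0, 135), 1L)   # boundary values are inclusive
  expect_equal(hit(3.1, 160), 0L)   # distance criterion fails
  expect_equal(hit(2.8, 120), 0L)   # angle criterion fails
  rec <- suppressWarnings(
    detect_hbonds(make_hbond_fixture(2.9, 160)$frame))$records
  expect_equal(rec$d_da, 2.9, tolerance = 1e-9)
  expect_equal(rec$theta_dha, 160, tolerance = 1e-9)
})

test_that("H-bond occupancy counts satisfying frames", {
  yes <- make_hbond_fixture(2.9, 160)$frame
  no <- make_hbond_fixture(3.4, 160)$frame
  hb <- suppressWarnings(detect_hbonds(list(yes, yes, no, yes)))
  expect_equal(hb$occupancy$occupancy, 0.75)
  # a donor without hydrogen warns but does not error
  noh <- make_test_frame(rbind(c(0, 0, 0), c(2.8, 0, 0)),
                         element = c("N", "O"))
  expect_warning(detect_hbonds(noh, donors = 1L), "no attached hydrogen")
})

test_that("RMSD handles translation and superposition", {
  fx <- make_attack_fixture(2.4, 105, 5)
  expect_equal(rmsd_series(fx$frame, fx$frame), 0)
  moved <- transform_frame(fx$frame, translation = c(3, 4, 0))
  expect_equal(rmsd_series(moved, fx$frame), 5)
  expect_lt(rmsd_series(moved, fx$frame, align_selection = 1:6), 1e-9)
  tr <- random_rigid_transform()
  rot <- transform_frame(fx$frame, tr$rotation, tr$translation)
  expect_lt(rmsd_series(rot, fx$frame, align_selection = 1:6), 1e-9)
  expect_error(rmsd_series(make_test_frame(matrix(0, 2, 3)), fx$frame),
               "mismatch")
})

test_that("our Kabsch superposition agrees with the bio3d reference", {
  set.seed(23)
  for (i in 1:5) {
    P <- matrix(stats::rnorm(30), 10, 3)
    tr <- random_rigid_transform()
    Q <- sweep(P %*% t(tr$rotation), 2, -tr$translation)
    fr_p <- make_test_frame(P)
    fr_q <- make_test_frame(Q)
    ours <- rmsd_series(fr_q, fr_p, align_selection = 1:10)
    theirs <- bio3d::rmsd(as.vector(t(P)), as.vector(t(Q)), fit = TRUE)
    expect_equal(ours, theirs, tolerance = 1e-6)
    expect_lt(ours, 1e-9)
  }
})

test_that("dihedral series measures constructed ring puckers", {
  base <- rbind(c(1.4, 0, 0), c(0, 0, 0), c(0, 1.4, 0))
  mk <- function(tau) {
    d <- place_atom(base[1, ], base[2, ], base[3, ], 1.4, 90, tau)
    make_test_frame(rbind(base, d))
  }
  expect_equal(dihedral_series(mk(0), 1, 2, 3, 4), 0, tolerance = 1e-9)
  # the puckering inversion range seen along a ring-opening step
  expect_equal(dihedral_series(mk(11), 1, 2, 3, 4), 11, tolerance = 1e-6)
  expect_equal(dihedral_series(mk(-3), 1, 2, 3, 4), -3, tolerance = 1e-6)
  # mirror symmetry flips the torsion sign
  fr <- mk(11)
  mirrored <- set_coords(fr, frame_coords(fr) %*% diag(c(1, 1, -1)))
  expect_equal(dihedral_series(mirrored, 1, 2, 3, 4), -11, tolerance = 1e-6)
})

test_that("series statistics match hand arithmetic", {
  s <- series_stats(c(3.2, 3.4), bins = 2)
  expect_equal(s$mean, 3.3)
  expect_equal(s$sd, sqrt(0.02), tolerance = 1e-9)   # 0.1414
  expect_equal(sum(s$histogram$count), 2)
  set.seed(5)
  x <- stats::rnorm(1000)
  expect_equal(sum(series_stats(x, bins = 17)$histogram$count), 1000)
  cst <- series_stats(rep(2.5, 10))
  expect_equal(cst$mean, 2.5)
  expect_equal(cst$sd, 0)
})

test_that("Eisenberg hydrophobicity values match the consensus scale", {
  expect_equal(unname(hydrophobicity_map("LYS")), -1.5)
  expect_equal(unname(hydrophobicity_map("THR")), -0.05)
  pocket <- unname(hydrophobicity_map(c("ILE", "VAL", "PHE")))
  expect_true(all(pocket >= 1.08 & pocket <= 1.38))
  expect_error(hydrophobicity_map("XYZ"), "XYZ")
  expect_equal(pocket_hydrophobicity(c("ILE", "VAL")), (1.38 + 1.08) / 2)
})
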