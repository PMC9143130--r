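#' Molecular fixtures
#'
#' Small constructed point sets that emulate active-site geometries with
#' exactly known descriptors, plus per-atom point charges and
#' Lennard-Jones parameters and a role map (nucleophile, electrophilic
#' carbon, carbonyl oxygen, donors, acceptors, ...).  Fixture generators
#' are exact inverses of the corresponding measurement operations in the
#' descriptor suite, which makes them the oracles for those measurements.
#'
#' @param frame a [coordinate_frame()].
#' @param params data frame with per-atom `charge` (e), `eps` (kcal/mol)
#'   and `rmin2` (Rmin/2, Angstrom).
#' @param roles named list mapping role names to atom indices.
#' @param total_charge declared total charge; the per-atom charges must
#'   sum to it within 1e-9.
#' @return A `molecular_fixture`.
#' @export
molecular_fixture <- function(frame, params, roles,
                              total_charge = sum(params$charge)) {
  stopifnot(inherits(frame, "coordinate_frame"),
            nrow(params) == nrow(frame$atoms),
            all(c("charge", "eps", "rmin2") %in% names(params)))
  n <- nrow(frame$atoms)
  for (r in names(roles)) {
    if (any(roles[[r]] < 1 | roles[[r]] > n))
      stop("role '", r, "' maps outside the atom table")
  }
  if (abs(sum(params$charge) - total_charge) > 1e-9)
    stop("per-atom charges do not sum to the declared total")
  structure(list(frame = frame, params = params, roles = roles,
                 total_charge = total_charge),
            class = "molecular_fixture")
}

#' @export
print.molecular_fixture <- function(x, ...) {
  cat(sprintf("<molecular_fixture> %d atoms, roles: %s\n",
              nrow(x$frame$atoms), paste(names(x$roles), collapse = ", ")))
  invisible(x)
}

#' Nucleophilic-attack fixture
#'
#' Builds a six-atom sp2-center fixture (carbonyl carbon, carbonyl
#' oxygen, two substituents, nucleophile, one randomly placed spectator)
#' whose measured attack descriptors reproduce the requested
#' nucleophile-carbon distance, Buergi-Dunitz angle and Flippin-Lodge
#' angle exactly.  The electrophile plane is the z=0 plane, the carbonyl
#' C->O axis is +x, and positive `alpha_fl` tips the nucleophile toward
#' substituent 1.
#'
#' A combination is geometrically reachable only when
#' `sin(alpha_bd) >= |sin(alpha_fl)|`; anything else is rejected.
#'
#' @param d_nu nucleophile-carbon distance, Angstrom (> 0).
#' @param alpha_bd Buergi-Dunitz angle, degrees in `[0, 180]` (ideal ~105).
#' @param alpha_fl Flippin-Lodge angle, degrees in `[-90, 90]` (ideal 0).
#' @param seed seed for the spectator placement (default 0).
#' @return A [molecular_fixture()] with roles `nucleophile`,
#'   `electrophile`, `carbonyl_o`, `sub1`, `sub2`, `spectator`.
#' @examples
#' fx <- make_attack_fixture(2.46, 102, 9)   # Michaelis-complex geometry
#' @export
make_attack_fixture <- function(d_nu, alpha_bd, alpha_fl, seed = 0) {
  if (d_nu <= 0) stop("d_nu must be positive")
  if (alpha_bd < 0 || alpha_bd > 180)
    stop("alpha_bd must lie in [0, 180] degrees")
  if (alpha_fl < -90 || alpha_fl > 90)
    stop("alpha_fl must lie in [-90, 90] degrees")
  th <- deg2rad(alpha_bd)
  fl <- deg2rad(alpha_fl)
  if (sin(th) + 1e-12 < abs(sin(fl)))
    stop(sprintf(
      "geometrically unreachable: |sin(alpha_fl)| = %.4f exceeds sin(alpha_bd) = %.4f",
      abs(sin(fl)), sin(th)))
  # local frame at the carbonyl carbon: u = C->O, n = plane normal,
  # w = u x n points toward sub1
  u <- c(1, 0, 0); n <- c(0, 0, 1); w <- vcross(u, n)   # (0, -1, 0)
  s_comp <- sin(fl)
  n_comp <- sqrt(max(sin(th)^2 - s_comp^2, 0))
  v <- cos(th) * u + n_comp * n + s_comp * w
  d_co <- 1.23
  pos <- rbind(
    C = c(0, 0, 0),
    O = d_co * u,
    S1 = 1.5 * c(cos(deg2rad(-120)), sin(deg2rad(-120)), 0),
    S2 = 1.5 * c(cos(deg2rad(120)), sin(deg2rad(120)), 0),
    NU = d_nu * v)
  set.seed(seed)
  spect_dir <- stats::rnorm(3)
  spect_dir <- spect_dir / sqrt(sum(spect_dir^2))
  pos <- rbind(pos, SP = c(0, 0, 0) + 6 * spect_dir)
  at <- data.frame(
    name = c("C1", "O1", "C2", "C3", "OG", "HX"),
    element = c("C", "O", "C", "C", "O", "H"),
    resname = c(rep("LIG", 4), "THR", "SPC"),
    resno = c(1L, 1L, 1L, 1L, 2L, 3L),
    x = pos[, 1], y = pos[, 2], z = pos[, 3],
    stringsAsFactors = FALSE)
  params <- data.frame(
    charge = c(0.637, -0.500, 0.000, 0.000, -0.700, 0.563),
    eps = c(0.086, 0.210, 0.086, 0.086, 0.210, 0.015),
    rmin2 = c(1.908, 1.661, 1.908, 1.908, 1.721, 0.600))
  molecular_fixture(
    coordinate_frame(at), params,
    roles = list(electrophile = 1L, carbonyl_o = 2L, sub1 = 3L, sub2 = 4L,
                 nucleophile = 5L, spectator = 6L))
}

#' Hydrogen-bond fixture
#'
#' Three-atom donor-hydrogen-acceptor arrangement with the requested
#' donor...acceptor distance and donor-H...acceptor angle (and a fixed
#' covalent D-H bond of `r_dh`).  Combinations with no valid acceptor
#' position given the covalent D-H length are rejected.
#'
#' @param d_da donor...acceptor distance, Angstrom (> 0).
#' @param theta_dha donor-H...acceptor angle, degrees in `(0, 180]`.
#' @param r_dh covalent donor-H bond length (default 1.0 A).
#' @return A [molecular_fixture()] with roles `donor`, `hydrogen`,
#'   `acceptor`.
#' @export
make_hbond_fixture <- function(d_da, theta_dha, r_dh = 1.0) {
  if (d_da <= 0) stop("d_da must be positive")
  if (theta_dha <= 0 || theta_dha > 180)
    stop("theta_dha must lie in (0, 180] degrees")
  if (r_dh < 0.8 || r_dh > 1.3)
    stop("covalent D-H length out of bounds [0.8, 1.3] A")
  th <- deg2rad(theta_dha)
  disc <- d_da^2 - (r_dh * sin(th))^2
  r_ha <- r_dh * cos(th) + sqrt(max(disc, 0))
  if (disc < 0 || r_ha <= 0 || d_da <= r_dh)
    stop("no acceptor position satisfies the requested distance/angle ",
         "with a covalent D-H bond of ", r_dh, " A")
  d_pos <- c(0, 0, 0)
  h_pos <- c(r_dh, 0, 0)
  a_pos <- h_pos + r_ha * c(-cos(th), sin(th), 0)
  at <- data.frame(
    name = c("ND", "HD", "OA"),
    element = c("N", "H", "O"),
    resname = c("DON", "DON", "ACC"),
    resno = c(1L, 1L, 2L),
    x = c(d_pos[1], h_pos[1], a_pos[1]),
    y = c(d_pos[2], h_pos[2], a_pos[2]),
    z = c(d_pos[3], h_pos[3], a_pos[3]),
    stringsAsFactors = FALSE)
  params <- data.frame(charge = c(-0.6, 0.4, 0.2),
                       eps = c(0.17, 0.015, 0.21),
                       rmin2 = c(1.824, 0.6, 1.661))
  molecular_fixture(coordinate_frame(at), params,
                    roles = list(donor = 1L, hydrogen = 2L, acceptor = 3L))
}

#' Write / read a fixture as PDB plus parameter sidecar
#'
#' The structure goes to `<prefix>.pdb` (single model, element column
#' filled) and the parameters to `<prefix>.params.tsv` with columns
#' `serial`, `name`, `charge`, `eps`, `rmin2`, `role`.
#'
#' @param fixture a [molecular_fixture()].
#' @param prefix output path prefix.
#' @return paths, invisibly.
#' @export
write_fixture <- function(fixture, prefix) {
  pdb_path <- paste0(prefix, ".pdb")
  par_path <- paste0(prefix, ".params.tsv")
  write_pdb(fixture$frame, pdb_path)
  role_col <- rep("", nrow(fixture$frame$atoms))
  for (r in names(fixture$roles)) role_col[fixture$roles[[r]]] <- r
  tab <- data.frame(serial = fixture$frame$atoms$serial,
                    name = fixture$frame$atoms$name,
                    charge = fixture$params$charge,
                    eps = fixture$params$eps,
                    rmin2 = fixture$params$rmin2,
                    role = role_col)
  con <- file(par_path, "w")
  writeLines(c("# pmfkit-fixture-params v1",
               paste0("# total_charge= ",
                      format(fixture$total_charge, digits = 12))), con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  invisible(c(pdb_path, par_path))
}

#' @rdname write_fixture
#' @param prefix path prefix used at write time.
#' @export
read_fixture <- function(prefix) {
  frame <- read_pdb(paste0(prefix, ".pdb"), multi = FALSE)
  lines <- readLines(paste0(prefix, ".params.tsv"))
  total <- as.numeric(sub("^#\\s*total_charge=\\s*", "",
                          lines[grepl("^#\\s*total_charge=", lines)][1]))
  tab <- utils::read.table(text = lines[!startsWith(lines, "#")],
                           header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  roles <- as.list(which(nzchar(tab$role)))
  names(roles) <- tab$role[nzchar(tab$role)]
  molecular_fixture(frame,
                    data.frame(charge = tab$charge, eps = tab$eps,
                               rmin2 = tab$rmin2),
                    roles = roles, total_charge = total)
}
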