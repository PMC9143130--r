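#' Nucleophilic-attack geometry
#'
#' Measures the approach of a nucleophile to an sp2 (carbonyl) carbon:
#' the nucleophile-carbon distance, the Buergi-Dunitz angle `alpha_bd`
#' (Nu...C=O angle; ideal ~105 deg), and the signed Flippin-Lodge angle
#' `alpha_fl` (azimuthal deviation of the nucleophile from the plane
#' through the C=O axis normal to the electrophile plane; ideal 0 deg).
#'
#' `alpha_fl = asin(v . w)` with `v` the unit C->Nu vector, `n` the unit
#' normal of the best-fit plane of (O, sub1, sub2) through C, and
#' `w = u x n` with `u` the unit C->O vector; the normal is oriented so
#' positive angles tip toward `sub1`.
#'
#' @param frame a [coordinate_frame()].
#' @param nu,c,o,sub1,sub2 atom indices: nucleophile, electrophilic
#'   carbon, carbonyl oxygen, the two remaining substituents on the
#'   carbon.
#' @return list with `d_nu_c` (Angstrom), `alpha_bd` and `alpha_fl`
#'   (degrees), class `attack_geometry`.
#' @export
attack_geometry <- function(frame, nu, c, o, sub1, sub2) {
  idx <- c(nu, c, o, sub1, sub2)
  if (anyDuplicated(idx)) stop("attack geometry needs five distinct atoms")
  xyz <- frame_coords(frame)
  if (any(idx < 1 | idx > nrow(xyz))) stop("atom index outside frame")
  p_nu <- xyz[nu, ]; p_c <- xyz[c, ]; p_o <- xyz[o, ]
  v <- p_nu - p_c
  d <- sqrt(sum(v^2))
  if (d < 1e-12) stop("nucleophile coincides with the carbon")
  v <- v / d
  u <- p_o - p_c
  u <- u / sqrt(sum(u^2))
  # best-fit plane through C of the three sp2 substituent directions
  M <- rbind(p_o - p_c, xyz[sub1, ] - p_c, xyz[sub2, ] - p_c)
  sv <- svd(M)
  if (sv$d[2] < 1e-8 * sv$d[1])
    stop("substituent atoms are collinear; electrophile plane undefined")
  n <- sv$v[, 3]
  w <- vcross(u, n)
  w <- w / sqrt(sum(w^2))
  if (sum(w * (xyz[sub1, ] - p_c)) < 0) { n <- -n; w <- -w }
  alpha_bd <- rad2deg(acos(max(-1, min(1, sum(v * u)))))
  alpha_fl <- rad2deg(asin(max(-1, min(1, sum(v * w)))))
  structure(list(d_nu_c = d, alpha_bd = alpha_bd, alpha_fl = alpha_fl),
            class = "attack_geometry")
}

#' @export
print.attack_geometry <- function(x, ...) {
  cat(sprintf("<attack_geometry> d = %.3f A, alpha_BD = %.1f deg, alpha_FL = %+.1f deg\n",
              x$d_nu_c, x$alpha_bd, x$alpha_fl))
  invisible(x)
}

#' @rdname attack_geometry
#' @param fixture a [make_attack_fixture()] result; convenience wrapper
#'   using the fixture's role map.
#' @export
measure_attack <- function(fixture) {
  r <- fixture$roles
  attack_geometry(fixture$frame, r$nucleophile, r$electrophile,
                  r$carbonyl_o, r$sub1, r$sub2)
}

#' Geometric hydrogen-bond detection
#'
#' Scans a trajectory for donor-hydrogen...acceptor triples satisfying
#' the geometric criteria: donor...acceptor distance `<= d_cut` and
#' donor-H...acceptor angle `>= angle_cut` (both boundaries inclusive).
#' Defaults are the conventional 3.0 Angstrom and 135 degrees.  Donor
#' hydrogens are located by a covalent-distance search; donors without an
#' attached hydrogen are skipped with a warning.
#'
#' @param traj a `coordinate_frame` or list of frames.
#' @param donors,acceptors atom indices of heavy donor/acceptor atoms;
#'   default: all N and O atoms (donors additionally need an attached H).
#' @param d_cut donor...acceptor cutoff, Angstrom (default 3.0).
#' @param angle_cut D-H...A angle cutoff, degrees (default 135).
#' @param covalent_max maximal covalent D-H distance, Angstrom (1.25).
#' @return list with `records` (data frame: frame, donor, hydrogen,
#'   acceptor, d_da, theta_dha) and `occupancy` (data frame: donor,
#'   acceptor, occupancy over frames).
#' @export
detect_hbonds <- function(traj, donors = NULL, acceptors = NULL,
                          d_cut = 3.0, angle_cut = 135.0,
                          covalent_max = 1.25) {
  if (inherits(traj, "coordinate_frame")) traj <- list(traj)
  f1 <- traj[[1]]
  el <- toupper(f1$atoms$element)
  if (is.null(donors)) donors <- which(el %in% c("N", "O"))
  if (is.null(acceptors)) acceptors <- which(el %in% c("N", "O"))
  hyd <- which(el == "H")
  recs <- list()
  pair_hits <- new.env(parent = emptyenv())
  for (fi in seq_along(traj)) {
    xyz <- frame_coords(traj[[fi]])
    for (d in donors) {
      if (length(hyd)) {
        dh <- sqrt(colSums((t(xyz[hyd, , drop = FALSE]) - xyz[d, ])^2))
        hs <- hyd[dh <= covalent_max]
      } else hs <- integer(0)
      if (!length(hs)) {
        if (fi == 1)
          warning("donor atom ", d, " has no attached hydrogen; skipped")
        next
      }
      for (a in setdiff(acceptors, c(d, hs))) {
        dda <- sqrt(sum((xyz[d, ] - xyz[a, ])^2))
        if (dda > d_cut + 1e-9) next   # inclusive boundary, fp-safe
        for (h in hs) {
          v1 <- xyz[d, ] - xyz[h, ]
          v2 <- xyz[a, ] - xyz[h, ]
          ang <- rad2deg(acos(max(-1, min(1,
            sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))))))
          if (ang >= angle_cut - 1e-9) {   # inclusive boundary, fp-safe
            recs[[length(recs) + 1L]] <-
              data.frame(frame = fi, donor = d, hydrogen = h, acceptor = a,
                         d_da = dda, theta_dha = ang)
            key <- paste(d, a)
            pair_hits[[key]] <- c(pair_hits[[key]], fi)
          }
        }
      }
    }
  }
  records <- if (length(recs)) do.call(rbind, recs) else
    data.frame(frame = integer(0), donor = integer(0), hydrogen = integer(0),
               acceptor = integer(0), d_da = numeric(0), theta_dha = numeric(0))
  keys <- ls(pair_hits)
  occupancy <- if (length(keys)) {
    da <- do.call(rbind, strsplit(keys, " "))
    data.frame(donor = as.integer(da[, 1]), acceptor = as.integer(da[, 2]),
               occupancy = vapply(keys, function(k)
                 length(unique(pair_hits[[k]])) / length(traj), 1.0),
               row.names = NULL)
  } else data.frame(donor = integer(0), acceptor = integer(0),
                    occupancy = numeric(0))
  list(records = records, occupancy = occupancy)
}

# Kabsch: optimal rotation superposing P (n x 3) onto Q after centering
kabsch_rotation <- function(P, Q) {
  H <- t(P) %*% Q
  sv <- svd(H)
  d <- sign(det(sv$u %*% t(sv$v)))
  sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
}

#' Per-frame RMSD, optionally after Kabsch superposition
#'
#' @param traj a `coordinate_frame` or list of frames.
#' @param ref reference `coordinate_frame`.
#' @param selection atom indices to measure over (default all; `heavy`
#'   restricts to non-hydrogens).
#' @param align_selection atom indices used for rigid-body superposition
#'   before measuring (NULL = no superposition).
#' @param heavy drop hydrogens from `selection` (default FALSE).
#' @return numeric vector of per-frame RMSD in Angstrom.
#' @export
rmsd_series <- function(traj, ref, selection = NULL, align_selection = NULL,
                        heavy = FALSE) {
  if (inherits(traj, "coordinate_frame")) traj <- list(traj)
  if (is.null(selection)) selection <- seq_len(nrow(ref$atoms))
  if (heavy)
    selection <- selection[toupper(ref$atoms$element[selection]) != "H"]
  if (!length(selection)) stop("empty selection")
  rq <- frame_coords(ref)
  vapply(traj, function(f) {
    if (nrow(f$atoms) != nrow(ref$atoms))
      stop("atom count mismatch between frame and reference")
    xf <- frame_coords(f)
    if (!is.null(align_selection)) {
      pc <- colMeans(xf[align_selection, , drop = FALSE])
      qc <- colMeans(rq[align_selection, , drop = FALSE])
      R <- kabsch_rotation(
        sweep(xf[align_selection, , drop = FALSE], 2, pc),
        sweep(rq[align_selection, , drop = FALSE], 2, qc))
      xf <- sweep(sweep(xf, 2, pc) %*% R, 2, -qc)
    }
    sqrt(mean(rowSums((xf[selection, , drop = FALSE] -
                         rq[selection, , drop = FALSE])^2)))
  }, 1.0)
}

#' Dihedral series along a trajectory
#'
#' Signed torsion of four atoms per frame (degrees), used as the
#' out-of-plane puckering descriptor of four-membered rings: a sign
#' change along a reaction step is a puckering inversion.
#'
#' @inheritParams rmsd_series
#' @param a,b,c,d atom indices.
#' @return numeric vector, degrees in (-180, 180].
#' @export
dihedral_series <- function(traj, a, b, c, d) {
  if (inherits(traj, "coordinate_frame")) traj <- list(traj)
  rc <- rc_dihedral(a, b, c, d)
  vapply(traj, function(f) rc_evaluate(rc, f), 1.0)
}

#' Summary statistics of a descriptor series
#'
#' @param series numeric vector.
#' @param bins histogram bin count (default 30).
#' @return list with `mean`, `sd` (sample SD), and `histogram` (data
#'   frame of bin centers and counts summing to `length(series)`), class
#'   `series_stat`.
#' @export
series_stats <- function(series, bins = 30) {
  stopifnot(length(series) >= 1)
  h <- graphics::hist(series, breaks = bins, plot = FALSE)
  structure(list(mean = mean(series),
                 sd = if (length(series) > 1) stats::sd(series) else 0,
                 histogram = data.frame(center = h$mids, count = h$counts)),
            class = "series_stat")
}

#' @export
print.series_stat <- function(x, ...) {
  cat(sprintf("<series_stat> mean = %.4g, sd = %.4g, n = %d\n",
              x$mean, x$sd, sum(x$histogram$count)))
  invisible(x)
}

#' Eisenberg consensus hydrophobicity
#'
#' Normalized consensus hydrophobicity per residue (Eisenberg scale):
#' e.g. LYS = -1.5 and THR = -0.05 (the hydrophilic catalytic residues of
#' a beta5 active site) versus ILE/VAL/PHE in the +1.08..+1.38 range that
#' line hydrophobic specificity pockets.
#'
#' @param residues character vector of three-letter residue names (case
#'   insensitive), or a `coordinate_frame` (one value per residue in it).
#' @return named numeric vector of hydrophobicity values.
#' @export
hydrophobicity_map <- function(residues) {
  if (inherits(residues, "coordinate_frame")) {
    at <- residues$atoms
    key <- !duplicated(paste(at$chain, at$resno))
    residues <- at$resname[key]
  }
  res <- toupper(residues)
  unknown <- setdiff(unique(res), names(EISENBERG_SCALE))
  if (length(unknown))
    stop("unknown residue name(s): ", paste(unknown, collapse = ", "))
  stats::setNames(EISENBERG_SCALE[res], res)
}

#' @rdname hydrophobicity_map
#' @param pocket character vector of member residue names; the pocket
#'   aggregate is the mean of member values.
#' @export
pocket_hydrophobicity <- function(pocket) mean(hydrophobicity_map(pocket))

# Eisenberg consensus scale, normalized (Eisenberg et al. 1984)
EISENBERG_SCALE <- c(
  ALA = 0.62, ARG = -2.53, ASN = -0.78, ASP = -0.90, CYS = 0.29,
  GLN = -0.85, GLU = -0.74, GLY = 0.48, HIS = -0.40, ILE = 1.38,
  LEU = 1.06, LYS = -1.50, MET = 0.64, PHE = 1.19, PRO = 0.12,
  SER = -0.18, THR = -0.05, TRP = 0.81, TYR = 0.26, VAL = 1.08)

#' Place a fourth atom from internal coordinates
#'
#' NeRF-style placement: returns the position of atom D given positions
#' A, B, C, the C-D distance, the B-C-D angle and the A-B-C-D torsion.
#' Useful for constructing frames with prescribed dihedrals (e.g. ring
#' puckering fixtures).
#'
#' @param a,b,c 3-vectors of known positions.
#' @param dist C-D bond length, Angstrom.
#' @param angle B-C-D angle, degrees.
#' @param torsion A-B-C-D torsion, degrees (IUPAC sign).
#' @return 3-vector position of D.
#' @export
place_atom <- function(a, b, c, dist, angle, torsion) {
  th <- deg2rad(angle); ph <- deg2rad(torsion)
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  n <- vcross(b - a, bc)
  n <- n / sqrt(sum(n^2))
  m <- vcross(n, bc)
  d2 <- dist * c(-cos(th), sin(th) * cos(ph), -sin(th) * sin(ph))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}
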