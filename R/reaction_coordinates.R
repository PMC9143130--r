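#' Reaction coordinates
#'
#' Scalar functions of atomic coordinates used to drive scans and umbrella
#' biases: plain interatomic distances, antisymmetric combinations of two
#' distances (the standard choice for proton-transfer and concerted
#' bond-breaking/forming steps, e.g. the antisymmetric combination of the
#' d(Og-Hg) and d(Hg-Nz) distances describing proton transfer from Thr1 to
#' Lys33), and signed dihedrals for analysis.
#'
#' The antisymmetric combination is ordered "breaking minus forming",
#' `d(a,b) - d(c,d)`, so reactant states sit at negative values.
#'
#' @param a,b,c,d atom indices into the frame.
#' @param label optional human-readable label.
#' @return A `reaction_coordinate` object.
#' @export
rc_distance <- function(a, b, label = sprintf("d(%d,%d)", a, b)) {
  if (a == b) stop("distance coordinate needs two distinct atoms")
  structure(list(kind = "distance", idx = c(a, b), label = label),
            class = "reaction_coordinate")
}

#' @rdname rc_distance
#' @export
rc_antisymmetric <- function(a, b, c, d,
                             label = sprintf("asym(d(%d,%d), d(%d,%d))", a, b, c, d)) {
  if (a == b || c == d)
    stop("each distance of the antisymmetric combination needs distinct atoms")
  structure(list(kind = "antisymmetric", idx = c(a, b, c, d), label = label),
            class = "reaction_coordinate")
}

#' @rdname rc_distance
#' @export
rc_dihedral <- function(a, b, c, d,
                        label = sprintf("dih(%d,%d,%d,%d)", a, b, c, d)) {
  if (anyDuplicated(c(a, b, c, d)))
    stop("dihedral coordinate needs four distinct atoms")
  structure(list(kind = "dihedral", idx = c(a, b, c, d), label = label),
            class = "reaction_coordinate")
}

#' @export
print.reaction_coordinate <- function(x, ...) {
  cat(sprintf("<reaction_coordinate> %s: %s\n", x$kind, x$label))
  invisible(x)
}

resolve_idx <- function(rc, frame) {
  n <- nrow(frame$atoms)
  if (any(rc$idx < 1 | rc$idx > n))
    stop("coordinate '", rc$label, "' references atom outside frame (n=", n, ")")
  rc$idx
}

#' Evaluate a reaction coordinate on a frame
#'
#' Distances and antisymmetric combinations return Angstrom; dihedrals a
#' signed torsion in degrees in (-180, 180] following the IUPAC sign
#' convention (positive clockwise looking from a along b to c).
#'
#' @param rc a `reaction_coordinate`.
#' @param frame a `coordinate_frame`.
#' @return scalar value.
#' @export
rc_evaluate <- function(rc, frame) {
  idx <- resolve_idx(rc, frame)
  xyz <- frame_coords(frame)
  switch(rc$kind,
         distance = dist_pair(xyz[idx[1], ], xyz[idx[2], ]),
         antisymmetric = dist_pair(xyz[idx[1], ], xyz[idx[2], ]) -
           dist_pair(xyz[idx[3], ], xyz[idx[4], ]),
         dihedral = torsion_angle(xyz[idx[1], ], xyz[idx[2], ],
                                  xyz[idx[3], ], xyz[idx[4], ]))
}

dist_pair <- function(p, q) {
  d <- sqrt(sum((p - q)^2))
  if (d < 1e-12) stop("degenerate geometry: coincident atoms")
  d
}

vcross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

torsion_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- vcross(b1, b2); n2 <- vcross(b2, b3)
  nb2 <- sqrt(sum(b2^2))
  if (nb2 < 1e-12 || sum(n1^2) < 1e-20 || sum(n2^2) < 1e-20)
    stop("degenerate geometry for dihedral (collinear or coincident atoms)")
  m1 <- vcross(n1, b2 / nb2)
  ang <- atan2(sum(m1 * n2), sum(n1 * n2))
  rad2deg(ang)
}

#' Analytic Cartesian gradient of a reaction coordinate
#'
#' Returns the per-atom derivative of the coordinate with respect to the
#' Cartesian positions (n_atoms x 3 matrix, zero rows for uninvolved
#' atoms).  Units: dimensionless (A/A) for distance coordinates, deg/A for
#' dihedrals, matching [rc_evaluate()].  This is what a harmonic bias
#' force on the coordinate is assembled from.
#'
#' @inheritParams rc_evaluate
#' @return n x 3 numeric matrix.
#' @export
rc_gradient <- function(rc, frame) {
  idx <- resolve_idx(rc, frame)
  xyz <- frame_coords(frame)
  g <- matrix(0, nrow(xyz), 3)
  if (rc$kind == "distance") {
    u <- xyz[idx[1], ] - xyz[idx[2], ]
    d <- sqrt(sum(u^2))
    if (d < 1e-12) stop("degenerate geometry: zero-length bond vector")
    g[idx[1], ] <- g[idx[1], ] + u / d
    g[idx[2], ] <- g[idx[2], ] - u / d
  } else if (rc$kind == "antisymmetric") {
    u <- xyz[idx[1], ] - xyz[idx[2], ]
    v <- xyz[idx[3], ] - xyz[idx[4], ]
    du <- sqrt(sum(u^2)); dv <- sqrt(sum(v^2))
    if (du < 1e-12 || dv < 1e-12)
      stop("degenerate geometry: zero-length bond vector")
    g[idx[1], ] <- g[idx[1], ] + u / du
    g[idx[2], ] <- g[idx[2], ] - u / du
    g[idx[3], ] <- g[idx[3], ] - v / dv
    g[idx[4], ] <- g[idx[4], ] + v / dv
  } else {
    g <- dihedral_gradient(xyz, idx)
  }
  g
}

# Blondel-Karplus torsion derivatives, converted to deg/A
dihedral_gradient <- function(xyz, idx) {
  p <- xyz[idx, , drop = FALSE]
  b1 <- p[2, ] - p[1, ]; b2 <- p[3, ] - p[2, ]; b3 <- p[4, ] - p[3, ]
  n1 <- vcross(b1, b2); n2 <- vcross(b2, b3)
  nb2 <- sqrt(sum(b2^2))
  if (nb2 < 1e-12 || sum(n1^2) < 1e-20 || sum(n2^2) < 1e-20)
    stop("degenerate geometry for dihedral gradient")
  d1 <- nb2 / sum(n1^2) * n1
  d4 <- -nb2 / sum(n2^2) * n2
  pfac <- sum(b1 * b2) / nb2^2
  qfac <- sum(b3 * b2) / nb2^2
  d2 <- (-pfac - 1) * d1 + qfac * d4
  d3 <- -(d1 + d2 + d4)
  g <- matrix(0, nrow(xyz), 3)
  g[idx[1], ] <- d1; g[idx[2], ] <- d2; g[idx[3], ] <- d3; g[idx[4], ] <- d4
  g * 180 / pi
}
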