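#' Coordinate frames and trajectories
#'
#' A `coordinate_frame` holds one set of atomic positions as a data frame
#' of atom records (`serial`, `name`, `element`, `resname`, `resno`,
#' `chain`, `x`, `y`, `z` in Angstrom) plus an optional frame time in ps.
#' A trajectory is a plain list of frames sharing a topology.
#'
#' @param atoms data frame with at least columns `name`, `element`, `x`,
#'   `y`, `z`; missing `serial` (1..n), `resname` ("UNK"), `resno` (1) and
#'   `chain` ("A") are filled with defaults.
#' @param time optional time stamp in ps.
#' @return A `coordinate_frame` object.
#' @export
coordinate_frame <- function(atoms, time = NA_real_) {
  stopifnot(is.data.frame(atoms))
  need <- c("name", "element", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss))
    stop("atom table lacks column(s): ", paste(miss, collapse = ", "))
  n <- nrow(atoms)
  if (is.null(atoms$serial)) atoms$serial <- seq_len(n)
  if (is.null(atoms$resname)) atoms$resname <- "UNK"
  if (is.null(atoms$resno)) atoms$resno <- 1L
  if (is.null(atoms$chain)) atoms$chain <- "A"
  atoms <- atoms[, c("serial", "name", "element", "resname", "resno",
                     "chain", "x", "y", "z")]
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite coordinates in frame")
  key <- paste(atoms$chain, atoms$resno, atoms$name)
  if (anyDuplicated(key))
    stop("duplicate (chain, resno, name) atom triple: ",
         key[which(duplicated(key))[1]])
  structure(list(atoms = atoms, time = time), class = "coordinate_frame")
}

#' @export
print.coordinate_frame <- function(x, ...) {
  cat(sprintf("<coordinate_frame> %d atoms, %d residue(s)\n",
              nrow(x$atoms), length(unique(paste(x$atoms$chain, x$atoms$resno)))))
  invisible(x)
}

#' Extract the n x 3 coordinate matrix of a frame
#' @param frame a `coordinate_frame`.
#' @param idx optional atom indices.
#' @return numeric matrix with columns x, y, z (Angstrom).
#' @export
frame_coords <- function(frame, idx = NULL) {
  m <- as.matrix(frame$atoms[, c("x", "y", "z")])
  if (!is.null(idx)) m <- m[idx, , drop = FALSE]
  dimnames(m) <- list(NULL, c("x", "y", "z"))
  m
}

#' Replace the coordinates of a frame
#' @inheritParams frame_coords
#' @param xyz n x 3 matrix of new coordinates.
#' @export
set_coords <- function(frame, xyz) {
  stopifnot(nrow(xyz) == nrow(frame$atoms), ncol(xyz) == 3)
  frame$atoms[, c("x", "y", "z")] <- xyz
  frame
}

#' Select atoms by chain / residue / atom name
#'
#' Accepts either named filter arguments or a compact selection string of
#' space-separated `key=value` clauses (keys: `chain`, `resno`, `resname`,
#' `name`, `element`; values may be comma-separated lists or `*`), e.g.
#' `"chain=A resno=33 name=NZ"` or `"element=C,N,O,S"`.
#'
#' @param frame a `coordinate_frame`.
#' @param sel optional selection string.
#' @param chain,resno,resname,name,element optional filters (vectors allowed).
#' @param heavy if TRUE, drop hydrogens.
#' @return integer vector of atom indices (possibly empty).
#' @export
select_atoms <- function(frame, sel = NULL, chain = NULL, resno = NULL,
                         resname = NULL, name = NULL, element = NULL,
                         heavy = FALSE) {
  at <- frame$atoms
  if (!is.null(sel)) {
    clauses <- strsplit(trimws(sel), "\\s+")[[1]]
    for (cl in clauses) {
      kv <- strsplit(cl, "=", fixed = TRUE)[[1]]
      if (length(kv) != 2) stop("bad selection clause: '", cl, "'")
      val <- strsplit(kv[2], ",", fixed = TRUE)[[1]]
      if (identical(val, "*")) next
      switch(kv[1],
             chain = { chain <- val },
             resno = { resno <- as.integer(val) },
             resname = { resname <- val },
             name = { name <- val },
             element = { element <- val },
             stop("unknown selection key: '", kv[1], "'"))
    }
  }
  keep <- rep(TRUE, nrow(at))
  if (!is.null(chain)) keep <- keep & at$chain %in% chain
  if (!is.null(resno)) keep <- keep & at$resno %in% resno
  if (!is.null(resname)) keep <- keep & at$resname %in% resname
  if (!is.null(name)) keep <- keep & at$name %in% name
  if (!is.null(element)) keep <- keep & at$element %in% element
  if (heavy) keep <- keep & toupper(at$element) != "H"
  which(keep)
}

#' Apply a rigid-body transform to a frame
#'
#' Rotates then translates all coordinates; used to verify the
#' rotation/translation invariance of descriptors.
#'
#' @param frame a `coordinate_frame`.
#' @param rotation 3 x 3 rotation matrix.
#' @param translation length-3 shift, Angstrom.
#' @export
transform_frame <- function(frame, rotation = diag(3), translation = c(0, 0, 0)) {
  xyz <- frame_coords(frame)
  set_coords(frame, sweep(xyz %*% t(rotation), 2, -translation))
}

#' Construct a rotation matrix from axis and angle
#' @param axis 3-vector (normalized internally).
#' @param angle rotation angle in degrees.
#' @return 3 x 3 rotation matrix.
#' @export
rotation_matrix <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  a <- deg2rad(angle)
  c_ <- cos(a); s <- sin(a)
  ux <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0),
               3, 3, byrow = TRUE)
  c_ * diag(3) + s * ux + (1 - c_) * (u %o% u)
}
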