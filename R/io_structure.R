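#' Read a PDB file into coordinate frames
#'
#' Parsing is delegated to [bio3d::read.pdb()]; records are re-validated
#' and repackaged as [coordinate_frame()] objects.  Multi-model files
#' yield one frame per MODEL.  Insertion codes are not supported and raise
#' an error rather than being dropped silently.
#'
#' @param path PDB file path.
#' @param multi if TRUE (default) return a list of frames even for a
#'   single-model file; if FALSE return a bare frame for single-model input.
#' @return A `coordinate_frame` or list of them.
#' @export
read_pdb <- function(path, multi = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0) stop("empty PDB file: ", path)
  pdb <- tryCatch(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE),
                  error = function(e) stop("PDB parse error in '", path,
                                           "': ", conditionMessage(e)))
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0) stop("no ATOM/HETATM records in: ", path)
  if (any(nzchar(at$insert) & !is.na(at$insert)))
    stop("insertion codes are not supported (found in ", path, ")")
  elem <- at$elesy
  bad <- is.na(elem) | !nzchar(trimws(elem))
  if (any(bad)) {
    warning("element column empty for ", sum(bad),
            " atom(s); inferring from atom name")
    elem[bad] <- substr(gsub("[0-9]", "", trimws(at$elety[bad])), 1, 1)
  }
  chain <- at$chain
  chain[is.na(chain) | !nzchar(chain)] <- "A"
  base <- data.frame(serial = at$eleno, name = trimws(at$elety),
                     element = trimws(elem), resname = trimws(at$resid),
                     resno = at$resno, chain = chain,
                     x = at$x, y = at$y, z = at$z,
                     stringsAsFactors = FALSE)
  xyz <- pdb$xyz
  nmod <- if (is.matrix(xyz)) nrow(xyz) else 1L
  frames <- lapply(seq_len(nmod), function(i) {
    f <- base
    if (is.matrix(xyz) && nmod > 1) {
      m <- matrix(xyz[i, ], ncol = 3, byrow = TRUE)
      f$x <- m[, 1]; f$y <- m[, 2]; f$z <- m[, 3]
    }
    coordinate_frame(f)
  })
  if (!multi && nmod == 1L) frames[[1]] else frames
}

#' Write coordinate frames as a (multi-model) PDB file
#'
#' @param frames a `coordinate_frame` or list of them (equal topology).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(frames, path) {
  if (inherits(frames, "coordinate_frame")) frames <- list(frames)
  at <- frames[[1]]$atoms
  xyz <- do.call(rbind, lapply(frames, function(f) as.vector(t(frame_coords(f)))))
  bio3d::write.pdb(file = path, xyz = xyz, resno = at$resno, resid = at$resname,
                   eleno = at$serial, elety = at$name, chain = at$chain,
                   elesy = at$element)
  invisible(path)
}

#' Read / write multi-frame XYZ trajectories
#'
#' Standard XYZ blocks: atom count line, comment line (a `time=<ps>` token
#' is honoured), then `element x y z` per atom.  XYZ carries no residue
#' topology, so atoms land in residue 1 of chain A with names equal to the
#' element plus index.
#'
#' @param path file path.
#' @return `read_xyz_traj`: list of `coordinate_frame`s.
#' @export
read_xyz_traj <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) | seq_along(lines) %% 1 == 0]
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n <= 0)
      stop("bad XYZ atom-count line ", i, ": '", lines[i], "'")
    if (i + 1L + n > length(lines))
      stop("truncated XYZ frame starting at line ", i)
    comment <- lines[i + 1L]
    tm <- regmatches(comment, regexpr("time=[-0-9.eE+]+", comment))
    tm <- if (length(tm)) as.numeric(sub("time=", "", tm)) else NA_real_
    rec <- strsplit(trimws(lines[(i + 2L):(i + 1L + n)]), "\\s+")
    bad <- which(vapply(rec, length, 1L) < 4)
    if (length(bad))
      stop("malformed XYZ atom record at line ", i + 1L + bad[1])
    el <- vapply(rec, `[`, "", 1)
    m <- t(vapply(rec, function(r) as.numeric(r[2:4]), numeric(3)))
    frames[[length(frames) + 1L]] <- coordinate_frame(
      data.frame(name = paste0(el, seq_len(n)), element = el,
                 x = m[, 1], y = m[, 2], z = m[, 3],
                 stringsAsFactors = FALSE),
      time = tm)
    i <- i + 2L + n
  }
  if (!length(frames)) stop("empty XYZ file: ", path)
  frames
}

#' @rdname read_xyz_traj
#' @param frames a `coordinate_frame` or list of them.
#' @export
write_xyz_traj <- function(frames, path) {
  if (inherits(frames, "coordinate_frame")) frames <- list(frames)
  con <- file(path, "w")
  on.exit(close(con))
  for (f in frames) {
    n <- nrow(f$atoms)
    cmt <- if (is.finite(f$time)) sprintf("time=%g", f$time) else "frame"
    writeLines(as.character(n), con)
    writeLines(cmt, con)
    writeLines(sprintf("%-3s %14.8f %14.8f %14.8f",
                       f$atoms$element, f$atoms$x, f$atoms$y, f$atoms$z), con)
  }
  invisible(path)
}
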