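#' CHARMM-style cubic switching function
#'
#' Smoothly switches nonbonded energies off between `r_on` and `r_off`:
#' 1 below `r_on`, 0 above `r_off`, C1-continuous at both bounds.  The
#' conventional bounds are 14.5 and 16 Angstrom.
#'
#' @param r distance(s), Angstrom.
#' @param r_on,r_off switching bounds, Angstrom (`r_on < r_off`).
#' @return switching factor(s) in `[0, 1]`.
#' @export
switching_function <- function(r, r_on = 14.5, r_off = 16) {
  stopifnot(r_on < r_off)
  out <- numeric(length(r))
  out[r <= r_on] <- 1
  mid <- r > r_on & r < r_off
  if (any(mid)) {
    r2 <- r[mid]^2; on2 <- r_on^2; off2 <- r_off^2
    out[mid] <- (off2 - r2)^2 * (off2 + 2 * r2 - 3 * on2) / (off2 - on2)^3
  }
  out
}

#' Per-residue ligand-environment interaction energies
#'
#' Point-charge Coulomb plus Lennard-Jones interaction between a ligand
#' selection and each environment residue, with the switching function
#' applied to both terms and Lorentz-Berthelot combination rules:
#' `eps_ij = sqrt(eps_i eps_j)`, `Rmin_ij = Rmin_i/2 + Rmin_j/2`.
#' Coulomb constant 332.0636 kcal A / mol / e^2; no distance-dependent
#' dielectric.  Per-frame energies are averaged to mean +/- sample SD,
#' mirroring the usual "E_int = E_elec + E_vdW" per-residue decomposition
#' used to rationalize intermediate stabilization.
#'
#' @param traj a `coordinate_frame` or list of frames.
#' @param ligand_sel atom indices of the ligand.
#' @param residue_sels named list of atom-index vectors, one per
#'   environment residue (must be disjoint from `ligand_sel`).
#' @param params data frame with per-atom `charge` (e), `eps` (kcal/mol)
#'   and `rmin2` (Rmin/2, Angstrom), row i = atom i.
#' @param r_on,r_off switching bounds, Angstrom.
#' @return data frame (class `residue_interactions`) with one row per
#'   residue: mean and SD of `E_elec`, `E_vdW` and `E_int` over frames;
#'   attribute `per_frame` holds the per-frame E_elec/E_vdW arrays.
#' @export
interaction_energies <- function(traj, ligand_sel, residue_sels, params,
                                 r_on = 14.5, r_off = 16) {
  if (inherits(traj, "coordinate_frame")) traj <- list(traj)
  stopifnot(length(ligand_sel) >= 1, length(residue_sels) >= 1)
  n_atoms <- nrow(traj[[1]]$atoms)
  all_idx <- c(ligand_sel, unlist(residue_sels))
  if (any(all_idx < 1 | all_idx > n_atoms)) stop("selection outside frame")
  if (any(unlist(residue_sels) %in% ligand_sel))
    stop("ligand and residue selections must be disjoint")
  if (nrow(params) < max(all_idx) ||
      any(!is.finite(params$charge[all_idx])) ||
      any(!is.finite(params$eps[all_idx])))
    stop("missing nonbonded parameters for selected atom(s)")
  if (is.null(names(residue_sels)))
    names(residue_sels) <- paste0("RES", seq_along(residue_sels))
  nf <- length(traj); nr <- length(residue_sels)
  e_elec <- matrix(0, nf, nr, dimnames = list(NULL, names(residue_sels)))
  e_vdw <- matrix(0, nf, nr, dimnames = list(NULL, names(residue_sels)))
  ql <- params$charge[ligand_sel]
  el <- params$eps[ligand_sel]
  rl <- params$rmin2[ligand_sel]
  for (fi in seq_len(nf)) {
    xyz <- frame_coords(traj[[fi]])
    xl <- xyz[ligand_sel, , drop = FALSE]
    for (ri in seq_len(nr)) {
      rs <- residue_sels[[ri]]
      xr <- xyz[rs, , drop = FALSE]
      # pairwise distances ligand x residue
      d <- sqrt(pmax(outer(rowSums(xl^2), rowSums(xr^2), `+`) -
                       2 * xl %*% t(xr), 0))
      sw <- switching_function(d, r_on, r_off)
      qq <- outer(ql, params$charge[rs])
      e_elec[fi, ri] <- sum(COULOMB_KCAL * qq / d * sw)
      epsij <- sqrt(outer(el, params$eps[rs]))
      rmin <- outer(rl, params$rmin2[rs], `+`)
      sr6 <- (rmin / d)^6
      e_vdw[fi, ri] <- sum(epsij * (sr6^2 - 2 * sr6) * sw)
    }
  }
  sdv <- function(m) if (nf > 1) apply(m, 2, stats::sd) else rep(0, nr)
  out <- data.frame(
    residue = names(residue_sels),
    E_elec = colMeans(e_elec), E_elec_sd = sdv(e_elec),
    E_vdW = colMeans(e_vdw), E_vdW_sd = sdv(e_vdw),
    E_int = colMeans(e_elec + e_vdw), E_int_sd = sdv(e_elec + e_vdw),
    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "per_frame") <- list(E_elec = e_elec, E_vdW = e_vdw)
  class(out) <- c("residue_interactions", "data.frame")
  out
}

#' Compare two interaction tables and rank the differences
#'
#' Keeps residues whose interaction-energy difference between two result
#' sets exceeds the threshold (conventionally 1 kcal/mol, the cutoff used
#' when reporting per-residue differences between inhibitors), sorted by
#' decreasing `|dE_int|`, ties broken by residue id.
#'
#' @param a,b `residue_interactions` tables over the same residue list.
#' @param threshold minimal `|dE_int|` to report, kcal/mol (default 1).
#' @return data frame with residue, both E_int values and `dE_int`.
#' @export
rank_interactions <- function(a, b, threshold = 1) {
  if (!setequal(a$residue, b$residue) || nrow(a) != nrow(b))
    stop("residue lists differ between the two result sets")
  b <- b[match(a$residue, b$residue), ]
  d <- b$E_int - a$E_int
  keep <- abs(d) > threshold
  out <- data.frame(residue = a$residue[keep],
                    E_int_a = a$E_int[keep], E_int_b = b$E_int[keep],
                    dE_int = d[keep], stringsAsFactors = FALSE)
  out[order(-abs(out$dE_int), out$residue), , drop = FALSE]
}

#' Read a minimal nonbonded parameter table
#'
#' AMBER-style TSV mapping atom name to `charge`, `eps` and `rmin2`;
#' applied to a frame by atom-name lookup.
#'
#' @param path TSV with columns `name`, `charge`, `eps`, `rmin2`.
#' @param frame optional `coordinate_frame`; when given, returns per-atom
#'   rows matched by atom name (error on unmatched atoms).
#' @return parameter data frame.
#' @export
read_params_tsv <- function(path, frame = NULL) {
  tab <- utils::read.table(path, header = TRUE, sep = "", comment.char = "#",
                           stringsAsFactors = FALSE)
  stopifnot(all(c("name", "charge", "eps", "rmin2") %in% names(tab)))
  if (is.null(frame)) return(tab)
  m <- match(frame$atoms$name, tab$name)
  if (anyNA(m))
    stop("no parameters for atom name(s): ",
         paste(unique(frame$atoms$name[is.na(m)]), collapse = ", "))
  tab[m, c("charge", "eps", "rmin2")]
}
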