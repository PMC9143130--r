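#' Free-energy profiles over labelled stationary points
#'
#' A `free_energy_profile` is an ordered table of labelled stationary
#' states (minima and saddles) with their relative free energies, e.g.
#' the canonical covalent-inhibition sequence
#' E.I -> TS1 -> E-TI -> TS2 -> E-I2 -> TS3 -> E-PC.
#'
#' @param label character vector of unique state labels.
#' @param type `"minimum"` or `"saddle"` per state; must alternate.
#' @param G free energies, kcal/mol.
#' @return A `free_energy_profile` (data frame with attribute
#'   `reference`, the label of the zero state).
#' @export
free_energy_profile <- function(label, type, G) {
  stopifnot(length(label) == length(type), length(type) == length(G))
  if (anyDuplicated(label))
    stop("state labels must be unique")
  type <- match.arg(type, c("minimum", "saddle"), several.ok = TRUE)
  if (length(type) > 1 && any(type[-1] == type[-length(type)]))
    stop("states must alternate between minima and saddles")
  first_min <- which(type == "minimum")[1]
  if (is.na(first_min)) stop("profile needs at least one minimum")
  G <- G - G[first_min]
  out <- data.frame(label = label, type = type, G = G,
                    stringsAsFactors = FALSE)
  attr(out, "reference") <- label[first_min]
  class(out) <- c("free_energy_profile", "data.frame")
  out
}

#' Assemble a profile from consecutive segments
#'
#' Stitches per-surface 1D profiles (each an ordered `label`/`type`/`G`
#' table) into one profile: consecutive segments must share their
#' junction state (same label, free energies equal within 1e-9), and the
#' result is re-referenced to its first minimum.
#'
#' @param segments list of data frames with columns `label`, `type`, `G`.
#' @return A [free_energy_profile()].
#' @examples
#' seg1 <- data.frame(label = c("E.I", "TS1", "E-I2"),
#'                    type = c("minimum", "saddle", "minimum"),
#'                    G = c(0, 24.9, 1.9))
#' seg2 <- data.frame(label = c("E-I2", "TS3", "E-PC"),
#'                    type = c("minimum", "saddle", "minimum"),
#'                    G = c(1.9, 21.0, -15.6))
#' assemble_profile(list(seg1, seg2))
#' @export
assemble_profile <- function(segments) {
  if (inherits(segments, "data.frame")) segments <- list(segments)
  stopifnot(length(segments) >= 1)
  for (s in segments)
    stopifnot(all(c("label", "type", "G") %in% names(s)))
  acc <- segments[[1]]
  if (length(segments) > 1) {
    for (k in 2:length(segments)) {
      seg <- segments[[k]]
      tail_row <- acc[nrow(acc), ]
      head_row <- seg[1, ]
      if (tail_row$label != head_row$label)
        stop("segment junction label mismatch: '", tail_row$label,
             "' vs '", head_row$label, "'")
      if (abs(tail_row$G - head_row$G) > 1e-9)
        stop(sprintf(
          "segment junction free-energy mismatch at '%s': %.12g vs %.12g",
          tail_row$label, tail_row$G, head_row$G))
      acc <- rbind(acc, seg[-1, ])
    }
  }
  free_energy_profile(acc$label, acc$type, acc$G)
}

#' Barrier between two states of a profile
#'
#' Free-energy cost of moving from `from` to `to` along the profile
#' order: the highest intervening saddle minus the free energy of the
#' starting state.  `from == to` returns 0.
#'
#' @param profile a [free_energy_profile()].
#' @param from,to state labels.
#' @return Delta-G in kcal/mol.
#' @export
barrier_query <- function(profile, from, to) {
  stopifnot(inherits(profile, "free_energy_profile"))
  i <- match(from, profile$label)
  j <- match(to, profile$label)
  if (is.na(i)) stop("unknown state: '", from, "'")
  if (is.na(j)) stop("unknown state: '", to, "'")
  if (i == j) return(0)
  rng <- seq(min(i, j), max(i, j))
  between <- setdiff(rng, c(i, j))
  saddles <- profile$G[intersect(between, which(profile$type == "saddle"))]
  # the endpoint itself may be the saddle crossed last
  for (k in c(i, j))
    if (profile$type[k] == "saddle") saddles <- c(saddles, profile$G[k])
  if (!length(saddles))
    stop("no separating saddle between '", from, "' and '", to, "'")
  max(saddles) - profile$G[i]
}

#' Write / read profiles as TSV (label, type, G)
#' @param profile a [free_energy_profile()].
#' @param path file path.
#' @export
write_profile_tsv <- function(profile, path) {
  con <- file(path, "w")
  writeLines(c("# pmfkit-profile v1",
               paste0("# reference= ", attr(profile, "reference"))), con)
  utils::write.table(as.data.frame(profile), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  close(con)
  invisible(path)
}

#' @rdname write_profile_tsv
#' @export
read_profile_tsv <- function(path) {
  lines <- readLines(path)
  tab <- utils::read.table(text = lines[!startsWith(lines, "#")],
                           header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  free_energy_profile(tab$label, tab$type, tab$G)
}
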