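# Shrake-Rupley solvent-accessible surface area and exposure classes.

#' Deterministic quasi-uniform points on the unit sphere
#'
#' Golden-section spiral: no random numbers, so SASA is bit-reproducible.
#'
#' @param n Number of points (>= 2).
#' @return n x 3 matrix of unit vectors.
#' @export
sphere_points <- function(n) {
  stopifnot(n >= 2)
  i <- seq_len(n) - 1
  z <- 1 - (2 * i + 1) / n
  phi <- i * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' For each heavy atom, `n_points` test points are distributed on the sphere
#' of radius vdW + probe; a point is accessible when it lies outside every
#' neighbouring atom's expanded sphere. Atom SASA is the accessible fraction
#' times the expanded-sphere area; residue SASA is the exact sum over the
#' residue's atoms.
#'
#' @param model A [structure_model()].
#' @param probe_radius Probe radius in Angstrom (1.4 = water).
#' @param n_points Test points per atom (>= 92; default 960).
#' @return List with `atom_sasa` (numeric, one value per atom row of
#'   `model$atoms`) and `residue_sasa` (data.frame position, aa, sasa_abs).
#' @export
compute_sasa <- function(model, probe_radius = 1.4, n_points = 960) {
  stopifnot(inherits(model, "structure_model"))
  if (n_points < 92) stop("n_points must be >= 92")
  at <- model$atoms
  bad <- setdiff(unique(at$element), names(VDW_RADII))
  if (length(bad)) stop("unknown element(s): ", paste(bad, collapse = ", "))
  xyz <- atom_coords(model)
  n_atoms <- nrow(xyz)
  radii <- unname(VDW_RADII[at$element]) + probe_radius
  pts <- sphere_points(n_points)
  atom_sasa <- numeric(n_atoms)
  # neighbour lists from the pairwise distance matrix (models are a few
  # thousand heavy atoms at most)
  d2 <- as.matrix(stats::dist(xyz))^2
  for (i in seq_len(n_atoms)) {
    ri <- radii[i]
    cutoff2 <- (ri + radii)^2
    nb <- which(d2[i, ] < cutoff2 & seq_len(n_atoms) != i)
    if (!length(nb)) {
      atom_sasa[i] <- 4 * pi * ri^2
      next
    }
    p <- pts * ri
    p <- sweep(p, 2, xyz[i, ], `+`)
    buried <- rep(FALSE, n_points)
    for (j in nb) {
      free <- !buried
      if (!any(free)) break
      dx <- p[free, 1] - xyz[j, 1]
      dy <- p[free, 2] - xyz[j, 2]
      dz <- p[free, 3] - xyz[j, 3]
      buried[free] <- (dx * dx + dy * dy + dz * dz) < radii[j]^2
    }
    atom_sasa[i] <- mean(!buried) * 4 * pi * ri^2
  }
  res_sasa <- rowsum(atom_sasa, group = at$position)
  res <- model$residues
  residue_sasa <- data.frame(
    position = res$position,
    aa = res$aa,
    sasa_abs = res_sasa[as.character(res$position), 1],
    row.names = NULL, stringsAsFactors = FALSE)
  list(atom_sasa = atom_sasa, residue_sasa = residue_sasa)
}

#' Classify residues as buried or exposed from relative accessibility
#'
#' Relative SASA is the absolute value over the residue type's theoretical
#' maximum. A residue is `buried` below `buried_below`, `partly_exposed`
#' below `exposed_above`, else `exposed`; the paper-style "largely or partly
#' exposed" class is the complement of `buried`.
#'
#' @param residue_sasa data.frame (position, aa, sasa_abs) from
#'   [compute_sasa()].
#' @param max_asa Named reference maxima per residue type
#'   (default [max_asa_reference()]).
#' @param buried_below Relative-SASA threshold below which a residue is
#'   buried (default 0.05, the common "completely buried" convention).
#' @param exposed_above Relative-SASA threshold at or above which a residue
#'   is fully `exposed` rather than `partly_exposed` (default 0.25).
#' @return data.frame (position, aa, sasa_abs, sasa_rel, class) of class
#'   `exposure_profile`.
#' @export
classify_exposure <- function(residue_sasa, max_asa = max_asa_reference(),
                              buried_below = 0.05, exposed_above = 0.25) {
  stopifnot(buried_below >= 0, exposed_above >= buried_below)
  missing_ref <- setdiff(unique(residue_sasa$aa), names(max_asa))
  if (length(missing_ref))
    stop("no max-ASA reference for residue type(s): ",
         paste(missing_ref, collapse = ", "))
  rel <- residue_sasa$sasa_abs / unname(max_asa[residue_sasa$aa])
  cls <- ifelse(rel < buried_below, "buried",
                ifelse(rel < exposed_above, "partly_exposed", "exposed"))
  out <- data.frame(
    position = residue_sasa$position,
    aa = residue_sasa$aa,
    sasa_abs = residue_sasa$sasa_abs,
    sasa_rel = rel,
    class = cls,
    stringsAsFactors = FALSE)
  class(out) <- c("exposure_profile", "data.frame")
  out
}
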