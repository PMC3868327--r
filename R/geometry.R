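# Residue proximity, face partitioning and charge environments.

# Minimum heavy-atom distance between every query residue and every target
# residue. Returns a |queries| x |targets| matrix.
min_residue_distances <- function(model, queries, targets) {
  at <- model$atoms
  modelled <- unique(at$position)
  missing_pos <- setdiff(c(queries, targets), modelled)
  if (length(missing_pos))
    stop("position(s) not modelled: ", paste(missing_pos, collapse = ", "))
  qa <- at[at$position %in% queries, , drop = FALSE]
  ta <- at[at$position %in% targets, , drop = FALSE]
  qm <- as.matrix(qa[, c("x", "y", "z")])
  tm <- as.matrix(ta[, c("x", "y", "z")])
  # squared cross-distances via the Gram expansion
  cross <- outer(rowSums(qm^2), rep(1, nrow(tm))) +
    outer(rep(1, nrow(qm)), rowSums(tm^2)) - 2 * qm %*% t(tm)
  cross[cross < 0] <- 0
  d <- sqrt(cross)
  out <- matrix(Inf, length(queries), length(targets),
                dimnames = list(queries, targets))
  qi <- match(qa$position, queries)
  ti <- match(ta$position, targets)
  for (i in seq_along(queries)) {
    rows <- qi == i
    if (!any(rows)) next
    sub <- d[rows, , drop = FALSE]
    out[i, ] <- vapply(seq_along(targets), function(j) {
      cols <- ti == j
      if (!any(cols)) return(Inf)
      min(sub[, cols])
    }, numeric(1))
  }
  out
}

#' Residue pairs within a distance cutoff
#'
#' A query/target pair is included when the minimum heavy-atom to heavy-atom
#' Euclidean distance is at most `radius` (the "sphere-radius probe" measure
#' a structure viewer reports); self-pairs are excluded. The default 5
#' Angstrom radius is the structural-proximity convention used throughout
#' the package.
#'
#' @param model A [structure_model()].
#' @param queries,targets Residue position vectors (all must be modelled).
#' @param radius Cutoff in Angstrom (> 0).
#' @return Object of class `proximity_set`: list with `radius` and `pairs`
#'   (data.frame query, target, dist).
#' @export
proximity_to_targets <- function(model, queries, targets, radius = 5.0) {
  if (!is.numeric(radius) || length(radius) != 1 || radius <= 0)
    stop("radius must be a positive number")
  queries <- sort(unique(queries))
  targets <- sort(unique(targets))
  if (!length(queries) || !length(targets)) {
    pairs <- data.frame(query = integer(0), target = integer(0),
                        dist = numeric(0))
    return(structure(list(radius = radius, pairs = pairs),
                     class = "proximity_set"))
  }
  d <- min_residue_distances(model, queries, targets)
  idx <- which(d <= radius, arr.ind = TRUE)
  pairs <- data.frame(
    query = queries[idx[, 1]],
    target = targets[idx[, 2]],
    dist = d[idx])
  pairs <- pairs[pairs$query != pairs$target, , drop = FALSE]
  pairs <- pairs[order(pairs$query, pairs$target), , drop = FALSE]
  rownames(pairs) <- NULL
  structure(list(radius = radius, pairs = pairs), class = "proximity_set")
}

#' @export
print.proximity_set <- function(x, ...) {
  cat("proximity_set:", nrow(x$pairs), "pairs within", x$radius, "A\n")
  invisible(x)
}

#' Partition the model surface into a variable and a conserved face
#'
#' The partition axis is the unit vector from the all-atom centroid of the
#' model toward the centroid of the side-chain atoms of the surface-exposed
#' variant residues; a residue whose side-chain centroid has a positive dot
#' product with the axis lies on the variable face, otherwise (including
#' exact ties) on the conserved face.
#'
#' @param model A [structure_model()].
#' @param variants data.frame of variant sites (needs columns `position` and
#'   `exposed`, as produced by [plant_variants()] or [variant_sites()]).
#' @param exposure Optional [classify_exposure()] profile; when given,
#'   variants classified `buried` are excluded from the axis construction in
#'   addition to the `exposed` flag.
#' @return Object of class `face_partition`: list with unit `axis` and
#'   `faces` (data.frame position, face).
#' @export
assign_faces <- function(model, variants, exposure = NULL) {
  stopifnot(is.data.frame(variants), "position" %in% names(variants))
  use <- if ("exposed" %in% names(variants)) variants$exposed else
    rep(TRUE, nrow(variants))
  if (!is.null(exposure)) {
    buried <- exposure$position[exposure$class == "buried"]
    use <- use & !(variants$position %in% buried)
  }
  vpos <- variants$position[use]
  if (!length(vpos)) stop("no surface-exposed variants: faces undefined")
  cent_all <- colMeans(atom_coords(model))
  sc <- side_chain_centroids(model)
  pos <- as.integer(rownames(sc))
  if (!all(vpos %in% pos))
    stop("variant position(s) not modelled: ",
         paste(setdiff(vpos, pos), collapse = ", "))
  axis <- colMeans(sc[as.character(vpos), , drop = FALSE]) - cent_all
  nrm <- sqrt(sum(axis^2))
  if (nrm == 0) stop("degenerate axis: variant centroid at model centroid")
  axis <- axis / nrm
  dots <- as.numeric(sweep(sc, 2, cent_all) %*% axis)
  faces <- data.frame(
    position = pos,
    face = ifelse(dots > 0, "variable", "conserved"),
    stringsAsFactors = FALSE)
  structure(list(axis = axis, faces = faces), class = "face_partition")
}

#' @export
print.face_partition <- function(x, ...) {
  tb <- table(x$faces$face)
  cat("face_partition: axis (", paste(sprintf("%.3f", x$axis), collapse = ", "),
      ") -", tb[["variable"]], "variable /", tb[["conserved"]],
      "conserved residues\n")
  invisible(x)
}

#' Charged residues in the structural neighbourhood of a site
#'
#' Returns aspartate/glutamate (negative) and lysine/arginine (positive)
#' residues whose minimum heavy-atom distance to the site is within
#' `radius`. A neighbour is flagged `isoform_different` when its position is
#' a variant site whose two alleles differ in formal charge sign — the
#' simple charge-neighbourhood annotation of isoform-specific electrostatic
#' context (no continuum electrostatics).
#'
#' @param model A [structure_model()].
#' @param site Modelled residue position.
#' @param radius Cutoff in Angstrom.
#' @param variants Optional variant-site data.frame (columns position,
#'   aa_A1, aa_A2).
#' @return data.frame (position, aa, charge, dist, isoform_different).
#' @export
charge_environment <- function(model, site, radius = 5.0, variants = NULL) {
  res <- model$residues
  if (!site %in% res$position) stop("site ", site, " is not modelled")
  charged <- res[res$aa %in% names(RESIDUE_CHARGE) & res$position != site, ,
                 drop = FALSE]
  empty <- data.frame(position = integer(0), aa = character(0),
                      charge = integer(0), dist = numeric(0),
                      isoform_different = logical(0))
  if (!nrow(charged)) return(empty)
  d <- min_residue_distances(model, site, charged$position)[1, ]
  keep <- d <= radius
  if (!any(keep)) return(empty)
  out <- data.frame(
    position = charged$position[keep],
    aa = charged$aa[keep],
    charge = unname(RESIDUE_CHARGE[charged$aa[keep]]),
    dist = unname(d[keep]),
    stringsAsFactors = FALSE)
  chg <- function(aa) ifelse(aa %in% names(RESIDUE_CHARGE),
                             RESIDUE_CHARGE[aa], 0L)
  out$isoform_different <- FALSE
  if (!is.null(variants) && nrow(variants)) {
    m <- match(out$position, variants$position)
    hit <- !is.na(m)
    out$isoform_different[hit] <-
      chg(variants$aa_A1[m[hit]]) != chg(variants$aa_A2[m[hit]])
  }
  out[order(out$dist), , drop = FALSE]
}
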