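# StructureModel container and PDB input/output.

#' Construct a structure model from an atom table
#'
#' The geometric substrate of the package: an ordered set of residues, each
#' with at least one heavy atom with finite coordinates in Angstrom.
#'
#' @param atoms data.frame with columns `position` (1-based residue number),
#'   `aa` (one-letter code), `atom` (atom name, e.g. "CA"), `element`
#'   (one of C/N/O/S), `x`, `y`, `z`.
#' @param chain Chain identifier (single string).
#' @return An object of class `structure_model`: list with `atoms`,
#'   `residues` (position, aa), `chain`, and `resolved_range`
#'   (first/last modelled position, inclusive).
#' @export
structure_model <- function(atoms, chain = "A") {
  stopifnot(is.data.frame(atoms), nrow(atoms) > 0)
  needed <- c("position", "aa", "atom", "element", "x", "y", "z")
  missing_cols <- setdiff(needed, names(atoms))
  if (length(missing_cols))
    stop("atom table lacks columns: ", paste(missing_cols, collapse = ", "))
  atoms <- atoms[order(atoms$position), needed, drop = FALSE]
  if (!all(is.finite(atoms$x)) || !all(is.finite(atoms$y)) ||
      !all(is.finite(atoms$z)))
    stop("non-finite atom coordinates")
  bad_el <- setdiff(unique(atoms$element), names(VDW_RADII))
  if (length(bad_el))
    stop("unknown element(s): ", paste(bad_el, collapse = ", "),
         " (heavy-atom table covers C, N, O, S)")
  res <- unique(atoms[, c("position", "aa")])
  if (anyDuplicated(res$position))
    stop("conflicting amino-acid codes for a residue position")
  bad_aa <- setdiff(unique(res$aa), AA1)
  if (length(bad_aa))
    stop("non-standard amino-acid code(s): ", paste(bad_aa, collapse = ", "))
  structure(
    list(atoms = atoms,
         residues = res[order(res$position), , drop = FALSE],
         chain = chain,
         resolved_range = range(res$position)),
    class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat("structure_model: chain", x$chain, "-", nrow(x$residues), "residues,",
      nrow(x$atoms), "heavy atoms, positions",
      x$resolved_range[1], "to", x$resolved_range[2], "\n")
  invisible(x)
}

#' Read a protein chain from a PDB file
#'
#' Reads ATOM records for one chain into a [structure_model()]. Hydrogens,
#' solvent and HETATM records are skipped; alternate locations are resolved
#' to the first conformer; non-standard residues are skipped with a warning
#' and recorded in the attached load report. Insertion codes are not
#' expected in model coordinates and raise an error.
#'
#' @param path Path to a PDB file with at least one ATOM record.
#' @param chain Chain identifier to extract.
#' @return A `structure_model`; attribute `load_report` lists skipped
#'   residues, if any.
#' @export
read_structure <- function(path, chain = "A") {
  if (!file.exists(path)) stop("no such file: ", path)
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (!nrow(at)) stop("no ATOM records in ", path)
  chains <- unique(at$chain)
  if (!chain %in% chains)
    stop("chain '", chain, "' not present; available chains: ",
         paste(chains, collapse = ", "))
  at <- at[at$chain == chain, , drop = FALSE]
  if (any(!is.na(at$insert) & at$insert != ""))
    stop("insertion codes present in chain ", chain,
         "; model coordinates must not carry insertion codes")
  # first altloc conformer only
  if (!is.null(at$alt)) {
    alt <- at$alt
    alt[is.na(alt)] <- ""
    keep_alt <- alt %in% c("", "A", "1")
    at <- at[keep_alt, , drop = FALSE]
  }
  at <- at[at$elesy != "H" & !grepl("^H", at$elety), , drop = FALSE]
  skipped <- character(0)
  std <- at$resid %in% names(AA3_TO_1)
  if (any(!std)) {
    skipped <- unique(paste0(at$resid[!std], at$resno[!std]))
    warning("skipping non-standard residue(s): ",
            paste(skipped, collapse = ", "))
    at <- at[std, , drop = FALSE]
  }
  if (!nrow(at)) stop("no standard-residue heavy atoms in chain ", chain)
  atoms <- data.frame(
    position = at$resno,
    aa = unname(AA3_TO_1[at$resid]),
    atom = at$elety,
    element = at$elesy,
    x = at$x, y = at$y, z = at$z,
    stringsAsFactors = FALSE)
  # drop duplicated atom names within a residue (stray altlocs)
  atoms <- atoms[!duplicated(atoms[, c("position", "atom")]), , drop = FALSE]
  m <- structure_model(atoms, chain = chain)
  attr(m, "load_report") <- list(skipped_residues = skipped)
  m
}

#' Write a structure model to PDB
#'
#' @param model A `structure_model`.
#' @param path Output file path.
#' @param b Optional per-atom numeric vector written to the B-factor column.
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path, b = NULL) {
  at <- model$atoms
  if (is.null(b)) b <- rep(0, nrow(at))
  stopifnot(length(b) == nrow(at))
  bio3d::write.pdb(
    pdb = NULL, file = path,
    xyz = as.numeric(t(as.matrix(at[, c("x", "y", "z")]))),
    resno = at$position,
    resid = unname(AA1_TO_3[at$aa]),
    eleno = seq_len(nrow(at)),
    elety = at$atom,
    chain = rep(model$chain, nrow(at)),
    o = rep(1, nrow(at)),
    b = b,
    elesy = at$element)
  invisible(path)
}

#' Coordinates of a model's atoms as a matrix
#' @keywords internal
atom_coords <- function(model) {
  as.matrix(model$atoms[, c("x", "y", "z")])
}

# Side-chain centroid per residue; glycine (or any residue with backbone
# atoms only) falls back to the CA atom.
side_chain_centroids <- function(model) {
  at <- model$atoms
  sc <- !(at$atom %in% backbone_atom_names)
  pos <- sort(unique(at$position))
  cent <- matrix(NA_real_, nrow = length(pos), ncol = 3,
                 dimnames = list(pos, c("x", "y", "z")))
  for (i in seq_along(pos)) {
    rows <- at$position == pos[i] & sc
    if (!any(rows)) rows <- at$position == pos[i] & at$atom == "CA"
    if (!any(rows)) rows <- at$position == pos[i]
    cent[i, ] <- colMeans(at[rows, c("x", "y", "z")])
  }
  cent
}
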