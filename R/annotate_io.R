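# Annotated-structure output: category codes in the B-factor column plus a
# PyMOL colouring script.

# category -> (numeric B-factor code, PyMOL colour)
ANNOTATION_CATEGORIES <- data.frame(
  category = c("none", "variant", "phosphorylation", "lysine_chemistry",
               "ethanolamination", "cysteine_chemistry", "O-glucosylation",
               "binding_site", "altered_ptm"),
  code = 0:8,
  color = c("grey80", "green", "orange", "blue", "yellow", "red", "pink",
            "brown", "black"),
  stringsAsFactors = FALSE)

#' Map a modification type to its display category
#' @param mod_type Modification name(s).
#' @return Category name(s) used by [write_annotated_structure()].
#' @export
annotation_category <- function(mod_type) {
  ifelse(mod_type %in% c("acetylation", "methylation", "ubiquitination",
                         "carbonylation"), "lysine_chemistry",
  ifelse(mod_type %in% c("S-nitrosylation", "S-glutathionylation"),
         "cysteine_chemistry",
  ifelse(mod_type %in% c("phosphorylation", "ethanolamination",
                         "O-glucosylation"), mod_type, "none")))
}

#' Write an annotated PDB and a companion PyMOL colouring script
#'
#' Writes the model with a numeric per-category code in the B-factor column
#' and a PyMOL-dialect command script that colours the categories in the
#' conventional scheme (variants green, phosphosites orange, lysine
#' chemistry blue, ethanolamination yellow, cysteine chemistry red,
#' O-glucosylation pink, binding sites brown, isoform-altered sites black).
#'
#' @param model A [structure_model()].
#' @param annotations Named character vector or data.frame (position,
#'   category); categories from `annotation_category()` plus "variant",
#'   "binding_site", "altered_ptm". May be empty.
#' @param path Output PDB path; the script is written next to it with a
#'   `.pml` extension.
#' @return Invisible list (pdb, script).
#' @export
write_annotated_structure <- function(model, annotations, path) {
  if (is.data.frame(annotations)) {
    ann <- stats::setNames(annotations$category,
                           annotations$position)
  } else ann <- annotations
  pos <- as.integer(names(ann))
  if (length(ann)) {
    bad_pos <- setdiff(pos, model$residues$position)
    if (length(bad_pos))
      stop("annotation at unmodelled position(s): ",
           paste(bad_pos, collapse = ", "))
    bad_cat <- setdiff(unique(ann), ANNOTATION_CATEGORIES$category)
    if (length(bad_cat))
      stop("unknown annotation category(s): ",
           paste(bad_cat, collapse = ", "))
  }
  codes <- stats::setNames(ANNOTATION_CATEGORIES$code,
                           ANNOTATION_CATEGORIES$category)
  b <- rep(0, nrow(model$atoms))
  if (length(ann)) {
    m <- match(model$atoms$position, pos)
    hit <- !is.na(m)
    b[hit] <- unname(codes[ann[m[hit]]])
  }
  write_structure(model, path, b = b)
  script <- sub("\\.pdb$", "", path)
  script <- paste0(script, ".pml")
  obj <- sub("\\.pdb$", "", basename(path))
  lines <- c(
    sprintf("load %s, %s", basename(path), obj),
    "hide everything", "show surface", "color grey80")
  used <- ANNOTATION_CATEGORIES[ANNOTATION_CATEGORIES$code > 0, ]
  lines <- c(lines, sprintf("select cat_%s, b > %.1f and b < %.1f",
                            gsub("[^A-Za-z0-9]", "_", used$category),
                            used$code - 0.5, used$code + 0.5),
             sprintf("color %s, cat_%s", used$color,
                     gsub("[^A-Za-z0-9]", "_", used$category)),
             "deselect")
  writeLines(lines, script)
  invisible(list(pdb = path, script = script))
}

#' Derive display annotations from analysis results
#'
#' Builds the per-residue category map for [write_annotated_structure()]
#' from mapped sites, variants, binding-site lists and isoform-altered
#' sites. When a residue falls in several categories the most specific wins
#' (altered > binding site > modification chemistry > variant).
#'
#' @param sites A [map_ptm_to_structure()] result.
#' @param variants Optional [variant_sites()] table.
#' @param site_lists Optional named list of binding-site position vectors.
#' @param altered Optional [detect_altered_capability()] result.
#' @return Named character vector position -> category.
#' @export
build_annotations <- function(sites, variants = NULL, site_lists = NULL,
                              altered = NULL) {
  ann <- character(0)
  if (!is.null(variants) && nrow(variants))
    ann[as.character(variants$position)] <- "variant"
  s <- sites$sites
  if (nrow(s)) {
    first_mod <- vapply(strsplit(s$mods, ","), `[`, "", 1)
    ann[as.character(s$position)] <- annotation_category(first_mod)
  }
  if (!is.null(site_lists))
    for (v in site_lists)
      ann[as.character(intersect(v, sites$sites$position))] <- "binding_site"
  if (!is.null(altered) && nrow(altered))
    ann[as.character(altered$position)] <- "altered_ptm"
  ann
}
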