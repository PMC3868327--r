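# Sequence-level PTM logic: compatibility, isoform-altered modifiability,
# structure mapping, multi-modification, reliability and overlap accounting.

#' Can a residue type carry a modification type?
#'
#' Total, vectorised predicate over the controlled vocabulary; see
#' [ptm_rules()] for the chemistry.
#'
#' @param aa One-letter residue code(s).
#' @param mod_type Modification name(s), recycled against `aa`.
#' @param rules Ruleset (editable; default [ptm_rules()]).
#' @return Logical vector.
#' @export
modification_compatibility <- function(aa, mod_type, rules = ptm_rules()) {
  n <- max(length(aa), length(mod_type))
  if (n == 0) return(logical(0))
  aa <- rep_len(aa, n)
  mod_type <- rep_len(mod_type, n)
  unknown <- setdiff(unique(mod_type), names(rules))
  if (length(unknown))
    stop("unknown modification type(s): ", paste(unknown, collapse = ", "),
         "; controlled vocabulary: ", paste(names(rules), collapse = ", "))
  mapply(function(a, m) a %in% rules[[m]], aa, mod_type, USE.NAMES = FALSE)
}

#' Isoform-altered modifiability at variant positions
#'
#' For each variant position carrying any observed modification, splits the
#' observed modification types into those chemically possible only on the
#' eEF1A1 allele and those possible only on the eEF1A2 allele. A type
#' compatible with both alleles (e.g. methylation across K273R) appears in
#' neither set; variants with no differential capability are omitted.
#'
#' @param variants A [variant_sites()] table.
#' @param table A [ptm_table()].
#' @param rules Compatibility ruleset.
#' @return data.frame (position, label, mods_only_A1, mods_only_A2) with the
#'   modification sets as comma-joined strings ("" when empty).
#' @export
detect_altered_capability <- function(variants, table, rules = ptm_rules()) {
  out <- list()
  for (i in seq_len(nrow(variants))) {
    pos <- variants$position[i]
    mods <- unique(table$mod_type[table$position == pos])
    if (!length(mods)) next
    ok1 <- modification_compatibility(variants$aa_A1[i], mods, rules)
    ok2 <- modification_compatibility(variants$aa_A2[i], mods, rules)
    only1 <- sort(mods[ok1 & !ok2])
    only2 <- sort(mods[ok2 & !ok1])
    if (!length(only1) && !length(only2)) next
    out[[length(out) + 1L]] <- data.frame(
      position = pos,
      label = variants$label[i],
      mods_only_A1 = paste(only1, collapse = ","),
      mods_only_A2 = paste(only2, collapse = ","),
      stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(position = integer(0), label = character(0),
                      mods_only_A1 = character(0),
                      mods_only_A2 = character(0)))
  do.call(rbind, out)
}

#' Map PTM table positions onto a structure model
#'
#' Distinct table positions are split into those within the modelled range
#' (up to the configured C-terminal boundary) and the disordered C-terminal
#' tail beyond it. Modification-type sets, isoform origins and evidence are
#' merged across species and isoforms per canonical position.
#'
#' @param table A [ptm_table()].
#' @param model A [structure_model()].
#' @param c_terminal_boundary Last modelled position; defaults to the last
#'   resolved residue of `model`.
#' @param sequence_length Optional full protein length; positions beyond it
#'   raise an error.
#' @return Object of class `mapped_site_set`: list with `sites` (data.frame
#'   position, aa, mods, n_mods, isoforms, n_citations_max,
#'   site_specific_any for mapped positions), `unmapped_tail` (positions
#'   beyond the boundary) and `boundary`.
#' @export
map_ptm_to_structure <- function(table, model,
                                 c_terminal_boundary = NULL,
                                 sequence_length = NULL) {
  if (is.null(c_terminal_boundary))
    c_terminal_boundary <- model$resolved_range[2]
  if (nrow(table)) {
    if (any(table$position < 1)) stop("PTM position < 1")
    if (!is.null(sequence_length) && any(table$position > sequence_length))
      stop("PTM position beyond sequence length ", sequence_length, ": ",
           paste(unique(table$position[table$position > sequence_length]),
                 collapse = ", "))
  }
  positions <- sort(unique(table$position))
  tail_pos <- positions[positions > c_terminal_boundary]
  mapped_pos <- setdiff(positions, tail_pos)
  agg <- lapply(mapped_pos, function(p) {
    rec <- table[table$position == p, , drop = FALSE]
    data.frame(
      position = p,
      aa = rec$aa[1],
      mods = paste(sort(unique(rec$mod_type)), collapse = ","),
      n_mods = length(unique(rec$mod_type)),
      isoforms = paste(sort(unique(rec$isoform)), collapse = ","),
      n_citations_max = max(rec$n_citations),
      site_specific_any = any(rec$site_specific),
      stringsAsFactors = FALSE)
  })
  sites <- if (length(agg)) do.call(rbind, agg) else
    data.frame(position = integer(0), aa = character(0),
               mods = character(0), n_mods = integer(0),
               isoforms = character(0), n_citations_max = integer(0),
               site_specific_any = logical(0))
  structure(list(sites = sites, unmapped_tail = tail_pos,
                 boundary = c_terminal_boundary),
            class = "mapped_site_set")
}

#' @export
print.mapped_site_set <- function(x, ...) {
  cat("mapped_site_set:", nrow(x$sites), "positions mapped,",
      length(x$unmapped_tail), "in the C-terminal tail (boundary",
      x$boundary, ")\n")
  invisible(x)
}

#' Positions modified in more than one way
#'
#' Groups records by canonical position and reports positions carrying two
#' or more distinct modification types (competition between modifying
#' enzymes). Species duplication of the same (position, type) does not
#' count twice.
#'
#' @param table A [ptm_table()].
#' @return data.frame (position, n_mods, mods).
#' @export
multi_modification_sites <- function(table) {
  if (!nrow(table))
    return(data.frame(position = integer(0), n_mods = integer(0),
                      mods = character(0)))
  sp <- split(table$mod_type, table$position)
  n <- vapply(sp, function(m) length(unique(m)), 1L)
  keep <- n >= 2
  data.frame(
    position = as.integer(names(sp))[keep],
    n_mods = unname(n[keep]),
    mods = vapply(sp[keep], function(m)
      paste(sort(unique(m)), collapse = ","), ""),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Filter a PTM table to high-confidence records
#'
#' A record passes when it was confirmed by a targeted site-specific
#' experiment or is supported by at least `min_citations` mass-spectrometry
#' records (the evidence-tier convention of curated PTM databases).
#'
#' @param table A [ptm_table()].
#' @param min_citations Citation threshold (default 5).
#' @return List with `table` (the passing subset, still a `ptm_table`) and
#'   `counts` (data.frame mod_type, pass, total).
#' @export
reliability_filter <- function(table, min_citations = 5) {
  if (min_citations < 0) stop("min_citations must be >= 0")
  pass <- table$site_specific | table$n_citations >= min_citations
  sub <- table[pass, , drop = FALSE]
  attr(sub, "flagged") <- attr(table, "flagged")
  attr(sub, "provenance") <- paste0(attr(table, "provenance"),
                                    " [reliable subset]")
  class(sub) <- class(table)
  types <- sort(unique(table$mod_type))
  counts <- data.frame(
    mod_type = types,
    pass = vapply(types, function(t) sum(pass & table$mod_type == t), 1L),
    total = vapply(types, function(t) sum(table$mod_type == t), 1L),
    row.names = NULL, stringsAsFactors = FALSE)
  list(table = sub, counts = counts)
}

#' Conservation of modified sites in a distant homolog
#'
#' A site is non-conserved when the comparison row's residue at the aligned
#' column differs from the reference row's residue (an alignment gap counts
#' as non-conserved).
#'
#' @param aln An [alignment_map()].
#' @param table A [ptm_table()] with positions in the reference row's
#'   ungapped numbering.
#' @param reference_row,comparison_row Sequence names in the alignment.
#' @return List with `sites` (data.frame position, aa_reference,
#'   aa_comparison, conserved) and `n_non_conserved`.
#' @export
conservation_of_sites <- function(aln, table, reference_row,
                                  comparison_row) {
  for (nm in c(reference_row, comparison_row))
    if (!nm %in% names(aln$sequences))
      stop("sequence '", nm, "' not in alignment; rows: ",
           paste(names(aln$sequences), collapse = ", "))
  positions <- sort(unique(table$position))
  cols <- aln$position_to_column[[reference_row]][positions]
  if (any(is.na(cols)))
    stop("position(s) beyond the reference row or in a reference gap: ",
         paste(positions[is.na(cols)], collapse = ", "))
  ref_chars <- alignment_chars(aln, reference_row)[cols]
  cmp_chars <- alignment_chars(aln, comparison_row)[cols]
  conserved <- !is_gap(cmp_chars) & cmp_chars == ref_chars
  sites <- data.frame(
    position = positions,
    aa_reference = ref_chars,
    aa_comparison = cmp_chars,
    conserved = conserved,
    stringsAsFactors = FALSE)
  list(sites = sites, n_non_conserved = sum(!conserved))
}

#' Overlap of modified positions with named binding-site lists
#'
#' @param table A [ptm_table()].
#' @param site_lists Named list of integer position vectors (e.g. the
#'   GTP/GDP pocket, the exchange-factor interface, actin-bundling mutants).
#' @return Named list of data.frames (position, aa, mods), one per input
#'   list, containing the modified positions that intersect it.
#' @export
binding_site_overlap <- function(table, site_lists) {
  stopifnot(is.list(site_lists))
  lapply(site_lists, function(sites) {
    hit <- sort(unique(intersect(table$position, sites)))
    data.frame(
      position = hit,
      aa = vapply(hit, function(p) table$aa[table$position == p][1], ""),
      mods = vapply(hit, function(p)
        paste(sort(unique(table$mod_type[table$position == p])),
              collapse = ","), ""),
      stringsAsFactors = FALSE)
  })
}

#' Read plain-text residue lists for binding sites
#'
#' One list per file section: lines `name<TAB>positions` where positions are
#' comma-separated integers, or a simple two-column format. Lines starting
#' with `#` are ignored.
#'
#' @param path Path to the text file.
#' @return Named list of integer vectors.
#' @export
read_site_lists <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t")[[1]]
    if (length(parts) != 2)
      stop("malformed site-list line (expect name<TAB>pos,pos,...): ", ln)
    pos <- suppressWarnings(as.integer(strsplit(parts[2], ",")[[1]]))
    if (any(is.na(pos)))
      stop("non-integer position in site list '", parts[1], "'")
    out[[parts[1]]] <- sort(unique(pos))
  }
  out
}
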