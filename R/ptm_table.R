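# Curated PTM table: container and TSV input/output.

#' Construct a curated PTM table
#'
#' @param records data.frame with columns `isoform` (eEF1A1 / eEF1A2 /
#'   ambiguous), `position` (canonical 1-based), `aa` (one-letter code of
#'   the modified residue), `mod_type` (one of [ptm_vocabulary()]),
#'   `n_citations` (non-negative integer), `site_specific` (logical),
#'   `species` (free text, carried verbatim).
#' @param provenance Free-text source label.
#' @param rules Compatibility ruleset (see [ptm_rules()]).
#' @return Object of class `ptm_table` (a data.frame of the valid records);
#'   attributes `flagged` (records failing side-chain compatibility) and
#'   `provenance`. Exact duplicate (isoform, position, mod_type) triples are
#'   deduplicated at load.
#' @export
ptm_table <- function(records, provenance = "unspecified",
                      rules = ptm_rules()) {
  needed <- c("isoform", "position", "aa", "mod_type", "n_citations",
              "site_specific", "species")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols))
    stop("PTM records lack columns: ", paste(missing_cols, collapse = ", "))
  records <- records[, needed, drop = FALSE]
  if (nrow(records)) {
    bad_iso <- !records$isoform %in% c("eEF1A1", "eEF1A2", "ambiguous")
    if (any(bad_iso))
      stop("unknown isoform label(s): ",
           paste(unique(records$isoform[bad_iso]), collapse = ", "))
    bad_mod <- !records$mod_type %in% names(rules)
    if (any(bad_mod))
      stop("unknown modification type(s): ",
           paste(unique(records$mod_type[bad_mod]), collapse = ", "),
           "; controlled vocabulary: ", paste(names(rules), collapse = ", "))
    if (any(records$n_citations < 0)) stop("n_citations must be >= 0")
  }
  ok <- modification_compatibility(records$aa, records$mod_type, rules)
  flagged <- records[!ok, , drop = FALSE]
  valid <- records[ok, , drop = FALSE]
  dup <- duplicated(valid[, c("isoform", "position", "mod_type")])
  valid <- valid[!dup, , drop = FALSE]
  rownames(valid) <- NULL
  structure(valid,
            class = c("ptm_table", "data.frame"),
            flagged = flagged,
            provenance = provenance)
}

#' @export
print.ptm_table <- function(x, ...) {
  fl <- attr(x, "flagged")
  cat("ptm_table:", nrow(x), "records at", length(unique(x$position)),
      "positions (", nrow(fl), "record(s) flagged incompatible);",
      "source:", attr(x, "provenance"), "\n")
  if (nrow(x)) print(as.data.frame(utils::head(x, 10)))
  invisible(x)
}

#' Read a curated PTM table from tab-separated text
#'
#' Expected header columns: isoform, position, residue, modification,
#' citations, site_specific, species. Lines starting with `#` are comments.
#' Rows whose (residue, modification) pair fails side-chain compatibility
#' are flagged and reported via the attached load report, never silently
#' dropped.
#'
#' @param path Path to a UTF-8 tab-separated file.
#' @param provenance Source label stored on the table (defaults to the
#'   file name).
#' @return A [ptm_table()]; attribute `load_report` summarises row counts.
#' @export
read_ptm_table <- function(path, provenance = basename(path)) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- utils::read.delim(path, comment.char = "#", sep = "\t",
                           stringsAsFactors = FALSE, quote = "")
  needed <- c("isoform", "position", "residue", "modification",
              "citations", "site_specific", "species")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols))
    stop("PTM table header lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  cit <- suppressWarnings(as.numeric(raw$citations))
  bad_cit <- which(is.na(cit) | cit != floor(cit))
  if (length(bad_cit))
    stop("non-integer citation count at data line(s): ",
         paste(bad_cit, collapse = ", "))
  pos <- suppressWarnings(as.integer(raw$position))
  bad_pos <- which(is.na(pos) | pos < 1)
  if (length(bad_pos))
    stop("invalid position at data line(s): ",
         paste(bad_pos, collapse = ", "))
  ss <- tolower(trimws(as.character(raw$site_specific))) %in%
    c("true", "t", "1", "yes")
  rec <- data.frame(
    isoform = trimws(raw$isoform),
    position = pos,
    aa = trimws(raw$residue),
    mod_type = trimws(raw$modification),
    n_citations = as.integer(cit),
    site_specific = ss,
    species = as.character(raw$species),
    stringsAsFactors = FALSE)
  tab <- ptm_table(rec, provenance = provenance)
  attr(tab, "load_report") <- list(
    records_in = nrow(rec),
    records_valid = nrow(tab),
    records_flagged = nrow(attr(tab, "flagged")),
    records_deduplicated = nrow(rec) - nrow(attr(tab, "flagged")) - nrow(tab))
  tab
}

#' Write a PTM table as tab-separated text
#' @param table A [ptm_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ptm_table <- function(table, path) {
  out <- data.frame(
    isoform = table$isoform,
    position = table$position,
    residue = table$aa,
    modification = table$mod_type,
    citations = table$n_citations,
    site_specific = ifelse(table$site_specific, "true", "false"),
    species = table$species)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Construct a variant-site table
#'
#' A variant site is an aligned position where the two isoforms carry
#' different residues, written `X{pos}Y` (eEF1A1 residue, canonical
#' position, eEF1A2 residue), e.g. "T176A".
#'
#' @param position Integer vector of canonical positions.
#' @param aa_A1,aa_A2 One-letter codes in eEF1A1 and eEF1A2 (must differ).
#' @param cluster Cluster membership: 1, 2 or NA (no cluster).
#' @param exposed Logical surface-exposure flag.
#' @return data.frame (position, aa_A1, aa_A2, label, cluster, exposed) of
#'   class `variant_sites`.
#' @export
variant_sites <- function(position, aa_A1, aa_A2,
                          cluster = NA_integer_, exposed = TRUE) {
  if (any(aa_A1 == aa_A2))
    stop("variant alleles must differ at every site")
  bad <- setdiff(unique(c(aa_A1, aa_A2)), AA1)
  if (length(bad))
    stop("non-standard amino-acid code(s): ", paste(bad, collapse = ", "))
  out <- data.frame(
    position = as.integer(position),
    aa_A1 = aa_A1, aa_A2 = aa_A2,
    label = paste0(aa_A1, position, aa_A2),
    cluster = rep_len(as.integer(cluster), length(position)),
    exposed = rep_len(exposed, length(position)),
    stringsAsFactors = FALSE)
  if (anyDuplicated(out$position)) stop("duplicate variant positions")
  class(out) <- c("variant_sites", "data.frame")
  out
}

#' Parse "X123Y" variant labels into a variant-site table
#' @param labels Character vector like c("T176A", "K273R").
#' @param ... Passed to [variant_sites()].
#' @return A [variant_sites()] table.
#' @export
parse_variant_labels <- function(labels, ...) {
  m <- regmatches(labels, regexec("^([A-Z])([0-9]+)([A-Z])$", labels))
  bad <- labels[vapply(m, length, 1L) != 4]
  if (length(bad))
    stop("malformed variant label(s): ", paste(bad, collapse = ", "))
  variant_sites(
    position = vapply(m, function(g) as.integer(g[3]), 1L),
    aa_A1 = vapply(m, `[`, "", 2),
    aa_A2 = vapply(m, `[`, "", 4),
    ...)
}
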