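# Single-call pipeline orchestration and report generation.

#' Assemble and validate a pipeline configuration
#'
#' @param structure Path to the PDB model.
#' @param ptm_table Path to the tab-separated PTM table.
#' @param chain Chain identifier (default "A").
#' @param alignment Optional alignment path (enables the distant-homolog
#'   conservation report; needs `reference_row`/`comparison_row`).
#' @param reference_row,comparison_row Alignment row names.
#' @param site_lists Optional path to a binding-site list file, or a named
#'   list of position vectors.
#' @param variants Optional [variant_sites()] table or character vector of
#'   "X123Y" labels.
#' @param radius Proximity radius in Angstrom (default 5).
#' @param buried_below Relative-SASA burial threshold (default 0.05).
#' @param min_citations Evidence threshold (default 5).
#' @param surface_only Restrict face counts and the permutation pool to
#'   non-buried residues (default TRUE).
#' @param n_perm Monte-Carlo permutations (default 10000).
#' @param seed Integer RNG seed; mandatory when `n_perm > 0`.
#' @param c_terminal_boundary Last modelled position (default: last
#'   resolved residue).
#' @param out_dir Output directory (created if absent).
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(structure, ptm_table, chain = "A",
                            alignment = NULL, reference_row = NULL,
                            comparison_row = NULL, site_lists = NULL,
                            variants = NULL, radius = 5.0,
                            buried_below = 0.05, min_citations = 5,
                            surface_only = TRUE, n_perm = 10000,
                            seed = NULL, c_terminal_boundary = NULL,
                            out_dir = "ptmsurf-out") {
  if (!is.numeric(radius) || radius <= 0)
    stop("radius must be a positive number of Angstroms")
  if (buried_below < 0 || buried_below > 1)
    stop("buried_below must lie in [0, 1]")
  if (min_citations < 0) stop("min_citations must be >= 0")
  if (n_perm > 0 && is.null(seed))
    stop("seed is mandatory when n_perm > 0")
  if (is.character(variants)) variants <- parse_variant_labels(variants)
  structure(
    list(structure = structure, ptm_table = ptm_table, chain = chain,
         alignment = alignment, reference_row = reference_row,
         comparison_row = comparison_row, site_lists = site_lists,
         variants = variants, radius = radius,
         buried_below = buried_below, min_citations = min_citations,
         surface_only = surface_only, n_perm = n_perm, seed = seed,
         c_terminal_boundary = c_terminal_boundary, out_dir = out_dir),
    class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#' @param path YAML key/value file; keys as in [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  do.call(pipeline_config, vals)
}

pipeline_log <- function(verbose, ...) {
  if (verbose) message("[ptmsurf] ", ...)
}

#' Run the full PTM surface-mapping pipeline
#'
#' Executes read -> solvent accessibility -> exposure -> faces -> site
#' mapping -> proximity -> reliability filter -> ledger counts ->
#' permutation enrichment -> writers. Outputs in `config$out_dir`:
#' `ledger.json`, `sites.tsv` (annotated site table), `residues.tsv`
#' (per-residue metrics), `annotated.pdb` + `annotated.pml`, and
#' `summary.txt`. Any stage error aborts with a stage-named message and
#' removes partial outputs.
#'
#' @param config A [pipeline_config()].
#' @param verbose Log stage progress to stderr (default TRUE).
#' @return The ledger (class `ptm_ledger`), invisibly.
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    pipeline_log(verbose, "stage: ", name)
    tryCatch(expr, error = function(e)
      stop("stage '", name, "': ", conditionMessage(e), call. = FALSE))
  }
  out_dir <- config$out_dir
  created <- !dir.exists(out_dir)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- file.path(out_dir, c("ledger.json", "sites.tsv",
                                  "residues.tsv", "annotated.pdb",
                                  "annotated.pml", "summary.txt"))
  ok <- FALSE
  on.exit({
    if (!ok) {
      unlink(outputs[file.exists(outputs)])
      if (created) unlink(out_dir, recursive = TRUE)
    }
  }, add = TRUE)

  model <- stage("read_structure",
                 if (inherits(config$structure, "structure_model"))
                   config$structure
                 else read_structure(config$structure, config$chain))
  table <- stage("read_ptm_table",
                 if (inherits(config$ptm_table, "ptm_table"))
                   config$ptm_table
                 else read_ptm_table(config$ptm_table))
  variants <- config$variants
  site_lists <- stage("site_lists",
                      if (is.character(config$site_lists))
                        read_site_lists(config$site_lists)
                      else config$site_lists)
  sasa <- stage("compute_sasa", compute_sasa(model))
  exposure <- stage("classify_exposure",
                    classify_exposure(sasa$residue_sasa,
                                      buried_below = config$buried_below))
  sites <- stage("map_ptm_to_structure",
                 map_ptm_to_structure(table, model,
                                      config$c_terminal_boundary))
  faces <- NULL
  prox <- NULL
  enrich <- NULL
  altered <- NULL
  fc <- NULL
  fc_reliable <- NULL
  pf <- NULL
  if (!is.null(variants) && nrow(variants)) {
    faces <- stage("assign_faces", assign_faces(model, variants, exposure))
    if (nrow(sites$sites)) {
      prox <- stage("proximity",
                    proximity_to_targets(model, sites$sites$position,
                                         variants$position, config$radius))
      pf <- stage("proximal_fraction", proximal_fraction(sites, prox))
      fc <- stage("face_counts",
                  face_counts(sites, faces, exposure, config$surface_only))
    }
    altered <- stage("altered_capability",
                     detect_altered_capability(variants, table))
  }
  rel <- stage("reliability_filter",
               reliability_filter(table, config$min_citations))
  multi <- stage("multi_modification", multi_modification_sites(table))
  if (!is.null(faces) && nrow(rel$table)) {
    sites_rel <- map_ptm_to_structure(rel$table, model,
                                      config$c_terminal_boundary)
    if (nrow(sites_rel$sites))
      fc_reliable <- stage("face_counts_reliable",
                           face_counts(sites_rel, faces, exposure,
                                       config$surface_only))
  }
  overlap <- NULL
  if (!is.null(site_lists))
    overlap <- stage("binding_site_overlap",
                     binding_site_overlap(table, site_lists))
  conservation <- NULL
  if (!is.null(config$alignment)) {
    aln <- stage("read_alignment", read_alignment(config$alignment))
    conservation <- stage("conservation_of_sites",
                          conservation_of_sites(aln, table,
                                                config$reference_row,
                                                config$comparison_row))
  }
  if (!is.null(prox) && config$n_perm > 0 && nrow(sites$sites)) {
    enrich <- stage("permutation_enrichment", {
      pool <- if (config$surface_only)
        exposure$position[exposure$class != "buried"]
      else exposure$position
      obs <- intersect(sites$sites$position, pool)
      hit_prox <- proximity_to_targets(model, pool, variants$position,
                                       config$radius)
      if (length(obs) == 0) NULL
      else permutation_enrichment(obs, pool,
                                  unique(hit_prox$pairs$query),
                                  n_perm = config$n_perm,
                                  seed = config$seed)
    })
  }

  ledger <- stage("ledger", build_ledger(
    table = table, sites = sites, exposure = exposure, faces = faces,
    fc = fc, fc_reliable = fc_reliable, pf = pf, rel = rel, multi = multi,
    altered = altered, overlap = overlap, conservation = conservation,
    enrich = enrich, config = config))

  stage("write_outputs", {
    site_tab <- annotated_site_table(sites, exposure, faces, prox,
                                     conservation)
    utils::write.table(site_tab, outputs[2], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    res_tab <- exposure
    if (!is.null(faces))
      res_tab$face <- faces$faces$face[match(res_tab$position,
                                             faces$faces$position)]
    utils::write.table(as.data.frame(res_tab), outputs[3], sep = "\t",
                       quote = FALSE, row.names = FALSE)
    ann <- build_annotations(sites, variants, site_lists, altered)
    write_annotated_structure(model, ann, outputs[4])
    jsonlite::write_json(unclass(ledger), outputs[1], auto_unbox = TRUE,
                         digits = NA, null = "null", pretty = TRUE)
    writeLines(utils::capture.output(print(ledger)), outputs[6])
  })
  ok <- TRUE
  class(ledger) <- "ptm_ledger"
  invisible(ledger)
}

annotated_site_table <- function(sites, exposure, faces, prox,
                                 conservation) {
  s <- sites$sites
  if (!nrow(s))
    return(cbind(s, face = character(0), exposure_class = character(0),
                 variant_proximal = logical(0)))
  s$exposure_class <- exposure$class[match(s$position, exposure$position)]
  s$face <- if (!is.null(faces))
    faces$faces$face[match(s$position, faces$faces$position)]
  else NA_character_
  s$variant_proximal <- if (!is.null(prox))
    s$position %in% unique(prox$pairs$query) else NA
  if (!is.null(conservation))
    s$conserved_in_comparison <- conservation$sites$conserved[
      match(s$position, conservation$sites$position)]
  s
}

build_ledger <- function(table, sites, exposure, faces, fc, fc_reliable,
                         pf, rel, multi, altered, overlap, conservation,
                         enrich, config) {
  n_mapped <- nrow(sites$sites)
  buried_sites <- sum(exposure$class[
    match(sites$sites$position, exposure$position)] == "buried")
  led <- list(
    n_positions_total = n_mapped + length(sites$unmapped_tail),
    n_mapped = n_mapped,
    n_tail = length(sites$unmapped_tail),
    n_buried_sites = buried_sites,
    n_exposed_sites = n_mapped - buried_sites,
    n_multi_modified = nrow(multi),
    face_counts = fc,
    face_counts_reliable = fc_reliable,
    reliability = rel$counts,
    n_reliable = nrow(rel$table),
    n_records = nrow(table),
    altered_capability = altered,
    proximal = if (!is.null(pf))
      list(n_proximal = pf$n_proximal, n_total = pf$n_total,
           fraction = pf$fraction) else NULL,
    enrichment = if (!is.null(enrich)) unclass(enrich) else NULL,
    binding_site_overlap = if (!is.null(overlap))
      lapply(overlap, function(d) d$position) else NULL,
    n_non_conserved = if (!is.null(conservation))
      conservation$n_non_conserved else NULL,
    parameters = list(radius = config$radius,
                      buried_below = config$buried_below,
                      min_citations = config$min_citations,
                      surface_only = config$surface_only,
                      n_perm = config$n_perm, seed = config$seed,
                      c_terminal_boundary = sites$boundary))
  class(led) <- "ptm_ledger"
  led
}

#' @export
print.ptm_ledger <- function(x, ...) {
  cat("PTM surface-mapping ledger\n")
  cat(sprintf("  positions: %d total = %d mapped + %d C-terminal tail\n",
              x$n_positions_total, x$n_mapped, x$n_tail))
  cat(sprintf("  exposure:  %d exposed / %d buried of %d mapped\n",
              x$n_exposed_sites, x$n_buried_sites, x$n_mapped))
  if (!is.null(x$face_counts)) {
    f <- x$face_counts
    cat(sprintf("  faces:     %d residues / %d modifications variable, %d / %d conserved\n",
                f$n_residues[f$face == "variable"],
                f$n_modifications[f$face == "variable"],
                f$n_residues[f$face == "conserved"],
                f$n_modifications[f$face == "conserved"]))
  }
  if (!is.null(x$face_counts_reliable)) {
    f <- x$face_counts_reliable
    cat(sprintf("  reliable faces: %d variable / %d conserved residues\n",
                f$n_residues[f$face == "variable"],
                f$n_residues[f$face == "conserved"]))
  }
  cat(sprintf("  multi-modified positions: %d\n", x$n_multi_modified))
  cat(sprintf("  reliable records: %d of %d\n", x$n_reliable, x$n_records))
  if (!is.null(x$proximal))
    cat(sprintf("  variant-proximal: %d of %d sites (%.1f%%)\n",
                x$proximal$n_proximal, x$proximal$n_total,
                100 * x$proximal$fraction))
  if (!is.null(x$enrichment))
    cat(sprintf("  enrichment: fold %.2f, p = %.4g (%s)\n",
                x$enrichment$fold, x$enrichment$p_perm,
                x$enrichment$method))
  if (!is.null(x$n_non_conserved))
    cat(sprintf("  sites non-conserved in comparison row: %d\n",
                x$n_non_conserved))
  invisible(x)
}
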