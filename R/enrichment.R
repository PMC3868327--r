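# Ledger counts and the permutation test of PTM enrichment.

#' Modified-residue and modification counts per face
#'
#' Residue count: distinct modified positions per face (restricted to
#' non-buried residues when `surface_only`). Modification count: sum over
#' those positions of the number of distinct modification types, so a
#' doubly-modified residue contributes two.
#'
#' @param sites A [map_ptm_to_structure()] result.
#' @param faces An [assign_faces()] partition.
#' @param exposure A [classify_exposure()] profile.
#' @param surface_only Drop buried residues from the counts (default TRUE).
#' @return data.frame (face, n_residues, n_modifications) with one row per
#'   face.
#' @export
face_counts <- function(sites, faces, exposure, surface_only = TRUE) {
  s <- sites$sites
  out <- data.frame(face = c("variable", "conserved"),
                    n_residues = 0L, n_modifications = 0L,
                    stringsAsFactors = FALSE)
  if (!nrow(s)) return(out)
  miss <- setdiff(s$position, faces$faces$position)
  if (length(miss))
    stop("mapped position(s) without a face assignment: ",
         paste(miss, collapse = ", "))
  s$face <- faces$faces$face[match(s$position, faces$faces$position)]
  if (surface_only) {
    cls <- exposure$class[match(s$position, exposure$position)]
    if (anyNA(cls))
      stop("mapped position(s) without an exposure class: ",
           paste(s$position[is.na(cls)], collapse = ", "))
    s <- s[cls != "buried", , drop = FALSE]
  }
  for (f in out$face) {
    sub <- s[s$face == f, , drop = FALSE]
    out$n_residues[out$face == f] <- nrow(sub)
    out$n_modifications[out$face == f] <- sum(sub$n_mods)
  }
  out
}

#' Fraction of modified sites structurally proximal to a variant
#'
#' @param sites A [map_ptm_to_structure()] result.
#' @param prox A [proximity_to_targets()] set computed with the mapped site
#'   positions as queries and the variant positions as targets.
#' @return List (n_proximal, n_total, fraction).
#' @export
proximal_fraction <- function(sites, prox) {
  n_total <- nrow(sites$sites)
  if (n_total == 0) stop("no mapped sites: fraction undefined")
  n_proximal <- sum(sites$sites$position %in% unique(prox$pairs$query))
  list(n_proximal = n_proximal, n_total = n_total,
       fraction = n_proximal / n_total)
}

#' Permutation test of site enrichment for a structural property
#'
#' The statistic is the number of observed sites satisfying the hit
#' predicate (e.g. variant-proximal, or variable-face). The null fixes the
#' number of sites and redraws their locations uniformly without
#' replacement from the candidate pool — by default the surface-exposed
#' residues, since modifying enzymes can only reach the surface. When the
#' number of distinct site placements `choose(|pool|, |sites|)` is at most
#' `exhaustive_limit` the null is enumerated exactly; otherwise `n_perm`
#' Monte-Carlo draws are used with the add-one correction
#' p = (1 + #\{T* >= T\}) / (n_perm + 1).
#'
#' @param observed_sites Positions of the observed sites (subset of pool).
#' @param candidate_pool Positions sites could have occupied.
#' @param is_hit Either a vector of hit positions or a predicate function
#'   over positions.
#' @param n_perm Number of Monte-Carlo permutations (default 10000).
#' @param seed Integer RNG seed (mandatory for the Monte-Carlo path).
#' @param exhaustive_limit Enumerate exactly when the number of
#'   combinations is at most this (default 1e5).
#' @return Object of class `ptm_enrichment`: statistic `n_hits_observed`,
#'   `n_observed`, `n_pool`, `n_hits_pool`, `fold` (observed hit fraction
#'   over pool hit fraction), `p_perm`, `method` ("exhaustive" or
#'   "monte-carlo"), `n_perm`, `seed`.
#' @export
permutation_enrichment <- function(observed_sites, candidate_pool, is_hit,
                                   n_perm = 10000, seed = NULL,
                                   exhaustive_limit = 1e5) {
  observed_sites <- unique(observed_sites)
  candidate_pool <- unique(candidate_pool)
  if (!all(observed_sites %in% candidate_pool))
    stop("observed sites must be a subset of the candidate pool")
  k <- length(observed_sites)
  N <- length(candidate_pool)
  if (k == 0) stop("no observed sites")
  hit <- if (is.function(is_hit)) {
    vapply(candidate_pool, function(p) isTRUE(is_hit(p)), logical(1))
  } else candidate_pool %in% is_hit
  K <- sum(hit)
  T_obs <- sum(observed_sites %in% candidate_pool[hit])
  pool_frac <- K / N
  obs_frac <- T_obs / k
  fold <- if (pool_frac > 0) obs_frac / pool_frac else NA_real_
  n_comb <- choose(N, k)
  if (is.finite(n_comb) && n_comb <= exhaustive_limit) {
    combs <- utils::combn(N, k)
    T_null <- colSums(matrix(hit[combs], nrow = k))
    p <- mean(T_null >= T_obs)
    method <- "exhaustive"
    n_used <- as.integer(n_comb)
  } else {
    if (n_perm < 1) stop("n_perm must be >= 1")
    if (is.null(seed)) stop("seed is mandatory for Monte-Carlo permutation")
    rs <- local_rng(seed)
    on.exit(rs(), add = TRUE)
    T_null <- vapply(seq_len(n_perm),
                     function(i) sum(hit[sample.int(N, k)]), numeric(1))
    p <- (1 + sum(T_null >= T_obs)) / (n_perm + 1)
    method <- "monte-carlo"
    n_used <- as.integer(n_perm)
  }
  structure(
    list(n_hits_observed = T_obs, n_observed = k,
         n_pool = N, n_hits_pool = K,
         observed_fraction = obs_frac, pool_fraction = pool_frac,
         fold = fold, p_perm = p, method = method,
         n_perm = n_used, seed = seed),
    class = "ptm_enrichment")
}

#' @export
print.ptm_enrichment <- function(x, ...) {
  cat("Permutation enrichment test\n")
  cat(sprintf("  observed: %d of %d sites are hits (%.1f%%)\n",
              x$n_hits_observed, x$n_observed, 100 * x$observed_fraction))
  cat(sprintf("  pool:     %d of %d positions are hits (%.1f%%)\n",
              x$n_hits_pool, x$n_pool, 100 * x$pool_fraction))
  cat(sprintf("  fold enrichment: %.2f\n", x$fold))
  cat(sprintf("  p = %.4g (%s, n = %d)\n", x$p_perm, x$method, x$n_perm))
  invisible(x)
}

#' @export
summary.ptm_enrichment <- function(object, ...) {
  print(object)
  invisible(object)
}

# Run code under a temporary RNG state seeded with `seed`; returns a
# restorer function.
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }
}
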