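# Desk-scale synthetic structures, variants, PTM tables and alignments with
# known ground truth. Every generator is a pure function of its parameters
# and seed.

# Substitutions used for synthetic variant alleles; chosen to include
# capability-change (S>A, C>T, K>R, T>A) and charge-change (D>A, Q>E, E>Q)
# cases of the kind seen between real paralogs.
VARIANT_SUBSTITUTION <- c(
  S = "A", C = "T", K = "R", D = "A", T = "A", E = "Q", Q = "E",
  N = "S", M = "Q", R = "K", Y = "F", A = "S", G = "A", H = "Q",
  P = "A", I = "V", L = "I", V = "A", F = "Y", W = "F")

# Element assigned to the side-chain pseudo-atom by residue class: basic ->
# N, polar/acidic -> O, sulphur-bearing -> S, else C. Sets the vdW radius.
side_chain_element <- function(aa) {
  ifelse(aa %in% c("K", "R", "H"), "N",
  ifelse(aa %in% c("S", "T", "Y", "D", "E", "N", "Q"), "O",
  ifelse(aa %in% c("C", "M"), "S", "C")))
}

serpentine_lattice <- function(n) {
  L <- ceiling(n^(1 / 3))
  cells <- matrix(0L, nrow = L^3, ncol = 3)
  r <- 1L
  for (k in 0:(L - 1)) {
    js <- if (k %% 2 == 0) 0:(L - 1) else (L - 1):0
    for (j in js) {
      is <- if ((k + j) %% 2 == 0) 0:(L - 1) else (L - 1):0
      for (i in is) {
        cells[r, ] <- c(i, j, k)
        r <- r + 1L
      }
    }
  }
  cells[seq_len(n), , drop = FALSE]
}

#' Generate a compact synthetic globule with known interior
#'
#' Builds a self-avoiding chain as a serpentine walk over a jittered cubic
#' lattice (3.8 Angstrom C-alpha spacing) with one side-chain pseudo-atom
#' per residue (1.5 Angstrom along the outward normal; glycine has none).
#' Residues whose 26 lattice neighbours are all occupied form the
#' designated interior; interior residues draw from a hydrophobic alphabet,
#' shell residues from a modifiable-rich alphabet. Deterministic per seed.
#'
#' @param n_residues Chain length (>= 20; must be large enough for the
#'   lattice block to contain at least one fully enclosed cell).
#' @param seed Integer RNG seed.
#' @return List with `model` (a [structure_model()], also carrying the
#'   truth as attribute `synthetic_truth`) and `truth` (list with
#'   `interior_positions`, `shell_positions`, `seed`).
#' @export
generate_globule <- function(n_residues, seed) {
  if (n_residues < 20) stop("n_residues must be >= 20")
  restore <- local_rng(seed)
  on.exit(restore(), add = TRUE)
  cells <- serpentine_lattice(n_residues)
  key <- function(m) paste(m[, 1], m[, 2], m[, 3], sep = ",")
  occupied <- key(cells)
  offsets <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offsets <- offsets[rowSums(abs(offsets)) > 0, , drop = FALSE]
  interior <- vapply(seq_len(n_residues), function(r) {
    nb <- sweep(offsets, 2, cells[r, ], `+`)
    all(key(nb) %in% occupied)
  }, logical(1))
  if (!any(interior))
    stop("n_residues too small for the lattice block to have an interior")
  ca <- cells * 3.8 + matrix(stats::runif(3 * n_residues, -0.1, 0.1),
                             ncol = 3)
  hydrophobic <- c("I", "L", "V", "M", "F", "W")
  shell_alphabet <- c("S", "T", "Y", "K", "R", "C", "D", "E", "N", "Q",
                      "A", "G", "H", "P", "L", "V")
  aa <- character(n_residues)
  aa[interior] <- sample(hydrophobic, sum(interior), replace = TRUE)
  aa[!interior] <- sample(shell_alphabet, sum(!interior), replace = TRUE)
  centroid <- colMeans(ca)
  rows <- vector("list", n_residues)
  for (r in seq_len(n_residues)) {
    atoms <- data.frame(
      position = r, aa = aa[r], atom = "CA", element = "C",
      x = ca[r, 1], y = ca[r, 2], z = ca[r, 3],
      stringsAsFactors = FALSE)
    if (aa[r] != "G") {
      dir <- ca[r, ] - centroid
      nrm <- sqrt(sum(dir^2))
      dir <- if (nrm < 1e-6) {
        v <- stats::rnorm(3); v / sqrt(sum(v^2))
      } else dir / nrm
      cb <- ca[r, ] + 1.5 * dir
      atoms <- rbind(atoms, data.frame(
        position = r, aa = aa[r], atom = "CB",
        element = side_chain_element(aa[r]),
        x = cb[1], y = cb[2], z = cb[3], stringsAsFactors = FALSE))
    }
    rows[[r]] <- atoms
  }
  model <- structure_model(do.call(rbind, rows), chain = "A")
  truth <- list(interior_positions = which(interior),
                shell_positions = which(!interior),
                seed = seed, n_residues = n_residues)
  attr(model, "synthetic_truth") <- truth
  list(model = model, truth = truth)
}

#' Plant surface variant clusters on one hemisphere of a globule
#'
#' Picks cluster seeds on the upper (+z) hemisphere of the shell and grows
#' spatially contiguous clusters of exposed variant sites around them.
#' Substituted alleles follow a fixed map that includes capability-change
#' and charge-change pairs.
#'
#' @param model A globule from [generate_globule()] (must carry its truth).
#' @param n_clusters 0, 1 or 2 clusters.
#' @param cluster_size Variants per cluster.
#' @param seed Integer RNG seed.
#' @param max_cluster_radius Members must lie within this C-alpha distance
#'   of their cluster seed (Angstrom, default 8).
#' @return A [variant_sites()] table (empty when `n_clusters = 0`).
#' @export
plant_variants <- function(model, n_clusters = 2, cluster_size = 6, seed = 1,
                           max_cluster_radius = 8) {
  stopifnot(n_clusters %in% 0:2)
  truth <- attr(model, "synthetic_truth")
  if (is.null(truth)) stop("model does not carry synthetic truth")
  if (n_clusters == 0)
    return(variant_sites(integer(0), character(0), character(0)))
  restore <- local_rng(seed)
  on.exit(restore(), add = TRUE)
  at <- model$atoms
  ca <- at[at$atom == "CA", , drop = FALSE]
  ca <- ca[match(sort(unique(ca$position)), ca$position), , drop = FALSE]
  centroid_z <- mean(ca$z)
  shell <- truth$shell_positions
  hemi <- shell[ca$z[match(shell, ca$position)] > centroid_z]
  if (length(hemi) < n_clusters * cluster_size)
    stop("cluster larger than hemisphere shell")
  coords <- as.matrix(ca[match(hemi, ca$position), c("x", "y", "z")])
  picked <- list()
  seed1 <- hemi[which.max(coords[, 3])]
  seeds <- seed1
  if (n_clusters == 2) {
    d1 <- sqrt(rowSums(sweep(
      coords, 2, as.numeric(coords[match(seed1, hemi), ]))^2))
    seeds <- c(seed1, hemi[which.max(d1)])
  }
  taken <- integer(0)
  out <- list()
  for (ci in seq_len(n_clusters)) {
    sc <- as.numeric(coords[match(seeds[ci], hemi), ])
    d <- sqrt(rowSums(sweep(coords, 2, sc)^2))
    cand <- hemi[order(d)]
    cand <- setdiff(cand, taken)[seq_len(cluster_size)]
    if (anyNA(cand)) stop("cluster larger than hemisphere shell")
    dmax <- max(d[match(cand, hemi)])
    if (dmax > max_cluster_radius)
      stop("cluster larger than hemisphere shell (member ",
           round(dmax, 1), " A from seed)")
    taken <- c(taken, cand)
    out[[ci]] <- data.frame(position = cand, cluster = ci)
  }
  vt <- do.call(rbind, out)
  aa1 <- model$residues$aa[match(vt$position, model$residues$position)]
  aa2 <- unname(VARIANT_SUBSTITUTION[aa1])
  variant_sites(vt$position, aa1, aa2, cluster = vt$cluster,
                exposed = TRUE)
}

#' Sample a synthetic PTM table with planted near-variant enrichment
#'
#' Every modifiable shell residue becomes a site with probability `p_near`
#' when within `radius` of a variant (minimum heavy-atom distance), else
#' `p_far`; the modification type is drawn uniformly among the types the
#' residue can chemically carry. Citation counts come from a two-component
#' geometric mixture so the reliability filter is exercisable.
#'
#' @param model A globule from [generate_globule()].
#' @param variants A [variant_sites()] table (may be empty).
#' @param p_near,p_far Site probabilities, `0 <= p_far <= p_near <= 1`.
#' @param radius Proximity radius in Angstrom (default 5).
#' @param mean_citations_high,mean_citations_low Means of the two geometric
#'   citation components.
#' @param p_high Mixture weight of the high-evidence component.
#' @param p_site_specific Probability a site carries a targeted-experiment
#'   confirmation.
#' @param seed Integer RNG seed.
#' @return List with `table` (a [ptm_table()]) and `truth` (pool, near
#'   positions, site positions, planted fold = p_near/p_far, seed).
#' @export
sample_ptms <- function(model, variants, p_near = 0.7, p_far = 0.35,
                        radius = 5, mean_citations_high = 12,
                        mean_citations_low = 1.5, p_high = 0.5,
                        p_site_specific = 0.1, seed = 1) {
  if (p_near < 0 || p_near > 1 || p_far < 0 || p_far > 1)
    stop("site probabilities must lie in [0, 1]")
  if (p_far > p_near) stop("p_far must not exceed p_near")
  truth <- attr(model, "synthetic_truth")
  if (is.null(truth)) stop("model does not carry synthetic truth")
  restore <- local_rng(seed)
  on.exit(restore(), add = TRUE)
  rules <- ptm_rules()
  modifiable_aa <- unique(unlist(rules))
  res <- model$residues
  pool <- truth$shell_positions[
    res$aa[match(truth$shell_positions, res$position)] %in% modifiable_aa]
  near <- integer(0)
  if (nrow(variants)) {
    prox <- proximity_to_targets(model, pool, variants$position, radius)
    near <- sort(unique(prox$pairs$query))
  }
  p <- ifelse(pool %in% near, p_near, p_far)
  is_site <- stats::runif(length(pool)) < p
  site_pos <- pool[is_site]
  recs <- lapply(site_pos, function(pos) {
    aa <- res$aa[res$position == pos]
    types <- names(rules)[vapply(rules, function(v) aa %in% v, logical(1))]
    mod <- if (length(types) == 1) types else sample(types, 1)
    high <- stats::runif(1) < p_high
    mu <- if (high) mean_citations_high else mean_citations_low
    data.frame(
      isoform = sample(c("eEF1A1", "eEF1A2", "ambiguous"), 1,
                       prob = c(0.45, 0.45, 0.1)),
      position = pos, aa = aa, mod_type = mod,
      n_citations = stats::rgeom(1, 1 / (1 + mu)),
      site_specific = stats::runif(1) < p_site_specific,
      species = "synthetic", stringsAsFactors = FALSE)
  })
  tab <- if (length(recs)) ptm_table(do.call(rbind, recs), "synthetic")
  else ptm_table(data.frame(
    isoform = character(0), position = integer(0), aa = character(0),
    mod_type = character(0), n_citations = integer(0),
    site_specific = logical(0), species = character(0)), "synthetic")
  list(table = tab,
       truth = list(pool = pool, near_positions = near,
                    site_positions = site_pos,
                    proximal_site_positions = intersect(site_pos, near),
                    planted_fold = if (p_far > 0) p_near / p_far else Inf,
                    seed = seed))
}

#' Generate a synthetic ortholog alignment with planted substitutions
#'
#' Ortholog rows mutate the reference at rate `divergence` everywhere
#' except the planted positions, which stay identical across orthologs and
#' are substituted only in the designated distant row (emulating sites
#' conserved among close orthologs but altered in a distant homolog).
#'
#' @param reference Ungapped reference sequence string.
#' @param n_orthologs Number of ortholog rows besides reference and the
#'   distant row.
#' @param divergence Per-position substitution rate in [0, 1].
#' @param planted_site_substitutions Positions substituted in the distant
#'   row only.
#' @param seed Integer RNG seed.
#' @param distant_name Name of the distant row (default "distant").
#' @return List with `aln` (an [alignment_map()]; reference row is named
#'   "reference") and `truth` (planted positions, seed).
#' @export
generate_alignment <- function(reference, n_orthologs = 6, divergence = 0.05,
                               planted_site_substitutions = integer(0),
                               seed = 1, distant_name = "distant") {
  if (divergence < 0 || divergence > 1)
    stop("divergence must lie in [0, 1]")
  restore <- local_rng(seed)
  on.exit(restore(), add = TRUE)
  ref <- strsplit(toupper(reference), "")[[1]]
  L <- length(ref)
  planted <- sort(unique(as.integer(planted_site_substitutions)))
  if (length(planted) && (min(planted) < 1 || max(planted) > L))
    stop("planted positions outside the reference sequence")
  mutate <- function(chars, positions) {
    for (p in positions)
      chars[p] <- sample(setdiff(AA1, chars[p]), 1)
    chars
  }
  rows <- list(reference = paste(ref, collapse = ""))
  for (i in seq_len(n_orthologs)) {
    hit <- which(stats::runif(L) < divergence)
    hit <- setdiff(hit, planted)
    rows[[paste0("ortholog_", i)]] <-
      paste(mutate(ref, hit), collapse = "")
  }
  hit <- setdiff(which(stats::runif(L) < divergence), planted)
  rows[[distant_name]] <- paste(mutate(ref, c(hit, planted)), collapse = "")
  list(aln = alignment_map(unlist(rows)),
       truth = list(planted = planted, seed = seed))
}
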