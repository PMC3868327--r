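# Shared fixtures and independent oracles, all built in code.

# Minimal hand-written PDB: one alanine, five heavy atoms.
write_tiny_pdb <- function(path = tempfile(fileext = ".pdb")) {
  writeLines(c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1       2.009   1.420   0.000  1.00  0.00           C",
    "ATOM      4  O   ALA A   1       1.251   2.390   0.000  1.00  0.00           O",
    "ATOM      5  CB  ALA A   1       1.988  -0.773  -1.199  1.00  0.00           C",
    "END"), path)
  path
}

# One serine whose OG atom carries A and B alternate locations.
write_altloc_pdb <- function(path = tempfile(fileext = ".pdb")) {
  writeLines(c(
    "ATOM      1  N   SER A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  SER A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   SER A   1       2.009   1.420   0.000  1.00  0.00           C",
    "ATOM      4  O   SER A   1       1.251   2.390   0.000  1.00  0.00           O",
    "ATOM      5  CB  SER A   1       1.988  -0.773  -1.199  1.00  0.00           C",
    "ATOM      6  OG ASER A   1       3.390  -0.800  -1.100  0.60  0.00           O",
    "ATOM      7  OG BSER A   1       3.300  -0.900  -1.300  0.40  0.00           O",
    "END"), path)
  path
}

# Build a model from bare coordinates (one CA-like atom per residue unless
# extra atoms are supplied).
toy_model <- function(coords, aa = NULL, element = "C") {
  n <- nrow(coords)
  if (is.null(aa)) aa <- rep("A", n)
  structure_model(data.frame(
    position = seq_len(n), aa = aa, atom = "CA",
    element = rep_len(element, n),
    x = coords[, 1], y = coords[, 2], z = coords[, 3],
    stringsAsFactors = FALSE))
}

# A small valid PTM record data.frame.
ptm_records <- function(position, aa, mod_type, isoform = "eEF1A1",
                        n_citations = 1L, site_specific = FALSE,
                        species = "human") {
  data.frame(isoform = rep_len(isoform, length(position)),
             position = position, aa = aa, mod_type = mod_type,
             n_citations = rep_len(as.integer(n_citations),
                                   length(position)),
             site_specific = rep_len(site_specific, length(position)),
             species = rep_len(species, length(position)),
             stringsAsFactors = FALSE)
}

# Analytic accessible area of sphere 1 (expanded radius r1) partially
# occluded by sphere 2 (r2) at centre distance d: spherical-cap formula.
two_sphere_area <- function(r1, r2, d) {
  if (d >= r1 + r2) return(4 * pi * r1^2)
  if (d + r1 <= r2) return(0)
  h <- r1 - (d^2 + r1^2 - r2^2) / (2 * d)
  4 * pi * r1^2 - 2 * pi * r1 * h
}

# Brute-force minimum heavy-atom distance between two residues.
brute_min_dist <- function(model, p1, p2) {
  a1 <- model$atoms[model$atoms$position == p1, c("x", "y", "z")]
  a2 <- model$atoms[model$atoms$position == p2, c("x", "y", "z")]
  best <- Inf
  for (i in seq_len(nrow(a1)))
    for (j in seq_len(nrow(a2)))
      best <- min(best, sqrt(sum((a1[i, ] - a2[j, ])^2)))
  best
}

# Brute-force all-pairs proximity scan (the oracle for proximity_to_targets).
brute_proximity <- function(model, queries, targets, radius) {
  out <- list()
  for (q in sort(unique(queries)))
    for (t in sort(unique(targets)))
      if (q != t && brute_min_dist(model, q, t) <= radius)
        out[[length(out) + 1L]] <- c(q, t)
  if (!length(out)) return(data.frame(query = integer(0),
                                      target = integer(0)))
  m <- do.call(rbind, out)
  data.frame(query = m[, 1], target = m[, 2])
}

# Random rigid-body transform of a structure model.
random_rigid_transform <- function(model, seed) {
  set.seed(seed)
  A <- matrix(rnorm(9), 3)
  qr_ <- qr(A)
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  shift <- rnorm(3, sd = 20)
  at <- model$atoms
  xyz <- as.matrix(at[, c("x", "y", "z")]) %*% t(R)
  at$x <- xyz[, 1] + shift[1]
  at$y <- xyz[, 2] + shift[2]
  at$z <- xyz[, 3] + shift[3]
  m2 <- structure_model(at, chain = model$chain)
  attr(m2, "synthetic_truth") <- attr(model, "synthetic_truth")
  m2
}
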