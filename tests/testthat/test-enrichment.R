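make_sites <- function(positions, model, ...) {
  tab <- ptm_table(ptm_records(
    positions,
    model$residues$aa[match(positions, model$residues$position)],
    vapply(model$residues$aa[match(positions, model$residues$position)],
           function(a) {
             rules <- ptm_rules()
             names(rules)[vapply(rules, function(v) a %in% v,
                                 logical(1))][1]
           }, "")))
  map_ptm_to_structure(tab, model, ...)
}

test_that("face counts are zero without sites and split by face with them", {
  g <- generate_globule(125, seed = 59)
  v <- plant_variants(g$model, seed = 1)
  fp <- assign_faces(g$model, v)
  ex <- classify_exposure(compute_sasa(g$model)$residue_sasa)
  empty <- map_ptm_to_structure(
    ptm_table(ptm_records(integer(0), character(0), character(0))), g$model)
  fc0 <- face_counts(empty, fp, ex)
  expect_equal(fc0$n_residues, c(0L, 0L))
  expect_equal(fc0$n_modifications, c(0L, 0L))
  sp <- sample_ptms(g$model, v, seed = 2)
  sites <- map_ptm_to_structure(sp$table, g$model)
  fc <- face_counts(sites, fp, ex, surface_only = FALSE)
  # residue counts sum to the mapped positions; modification counts to the
  # distinct (position, type) pairs
  expect_equal(sum(fc$n_residues), nrow(sites$sites))
  expect_equal(sum(fc$n_modifications), sum(sites$sites$n_mods))
  # recount from first principles
  faces <- fp$faces
  on_var <- sites$sites$position %in%
    faces$position[faces$face == "variable"]
  expect_equal(fc$n_residues[fc$face == "variable"], sum(on_var))
})

test_that("surface_only excludes buried residues from face counts", {
  g <- generate_globule(64, seed = 61)
  tr <- g$truth
  v <- plant_variants(g$model, n_clusters = 1, cluster_size = 5, seed = 3)
  fp <- assign_faces(g$model, v)
  ex <- classify_exposure(compute_sasa(g$model)$residue_sasa)
  # one shell site plus one interior (buried) site
  interior_k <- tr$interior_positions[1]
  tab <- ptm_table(ptm_records(
    c(v$position[1], interior_k), c("S", "K"),
    c("phosphorylation", "methylation")))
  sites <- map_ptm_to_structure(tab, g$model)
  fc_all <- face_counts(sites, fp, ex, surface_only = FALSE)
  fc_surf <- face_counts(sites, fp, ex, surface_only = TRUE)
  expect_equal(sum(fc_all$n_residues) - sum(fc_surf$n_residues),
               sum(ex$class[match(sites$sites$position, ex$position)] ==
                     "buried"))
})

test_that("proximal fraction counts sites with at least one nearby variant", {
  g <- generate_globule(64, seed = 67)
  v <- plant_variants(g$model, n_clusters = 1, cluster_size = 5, seed = 4)
  sp <- sample_ptms(g$model, v, seed = 5)
  sites <- map_ptm_to_structure(sp$table, g$model)
  prox <- proximity_to_targets(g$model, sites$sites$position, v$position, 5)
  pf <- proximal_fraction(sites, prox)
  expect_equal(pf$n_proximal,
               length(intersect(sites$sites$position,
                                sp$truth$near_positions)))
  expect_equal(pf$n_total, nrow(sites$sites))
  expect_equal(pf$fraction, pf$n_proximal / pf$n_total)
  # no variants: empty proximity set, fraction zero
  empty_prox <- proximity_to_targets(g$model, sites$sites$position,
                                     integer(0), 5)
  expect_equal(proximal_fraction(sites, empty_prox)$fraction, 0)
  # all sites proximal
  all_prox <- proximity_to_targets(g$model, sites$sites$position,
                                   g$model$residues$position, 50)
  expect_equal(proximal_fraction(sites, all_prox)$fraction, 1)
  empty_sites <- map_ptm_to_structure(
    ptm_table(ptm_records(integer(0), character(0), character(0))), g$model)
  expect_error(proximal_fraction(empty_sites, prox), "no mapped sites")
})

test_that("planted proximal splits are recovered exactly", {
  g <- generate_globule(125, seed = 71)
  v <- plant_variants(g$model, seed = 6)
  sp <- sample_ptms(g$model, v, p_near = 1, p_far = 1, seed = 7)
  sites <- map_ptm_to_structure(sp$table, g$model)
  prox <- proximity_to_targets(g$model, sites$sites$position, v$position, 5)
  pf <- proximal_fraction(sites, prox)
  expect_equal(pf$n_proximal, length(sp$truth$near_positions))
  expect_equal(pf$n_total, length(sp$truth$pool))
})

test_that("degenerate enrichment with all-hit pools gives fold 1, p 1", {
  res <- permutation_enrichment(1:3, 1:6, 1:6)
  expect_equal(res$fold, 1)
  expect_equal(res$p_perm, 1)
})

test_that("exhaustive enumeration reproduces the closed-form tail", {
  # pool of 6 with 3 hits, all 3 observed sites hits: p = 1/C(6,3) = 0.05
  res <- permutation_enrichment(1:3, 1:6, 1:3)
  expect_equal(res$method, "exhaustive")
  expect_equal(res$p_perm, 0.05)
  expect_equal(res$fold, 2)
})

test_that("exhaustive p equals the hypergeometric tail on random instances", {
  set.seed(73)
  for (rep in 1:10) {
    N <- sample(8:14, 1)
    K <- sample(2:(N - 2), 1)
    k <- sample(2:(N - 2), 1)
    pool <- seq_len(N)
    obs <- sample(pool, k)
    res <- permutation_enrichment(obs, pool, seq_len(K))
    expect_equal(res$method, "exhaustive")
    oracle <- stats::phyper(res$n_hits_observed - 1, K, N - K, k,
                            lower.tail = FALSE)
    expect_equal(res$p_perm, oracle, tolerance = 1e-12)
  }
})

test_that("Monte-Carlo p lands within 3 standard errors of the exact tail", {
  set.seed(79)
  for (rep in 1:5) {
    N <- 40; K <- 15; k <- 12
    pool <- seq_len(N)
    obs <- sample(pool, k)
    res <- permutation_enrichment(obs, pool, seq_len(K), n_perm = 4000,
                                  seed = 100 + rep, exhaustive_limit = 1)
    expect_equal(res$method, "monte-carlo")
    p_exact <- stats::phyper(res$n_hits_observed - 1, K, N - K, k,
                             lower.tail = FALSE)
    se <- sqrt(p_exact * (1 - p_exact) / 4000)
    expect_lt(abs(res$p_perm - p_exact), 3 * se + 2 / 4001)
  }
})

test_that("identical seed and inputs reproduce the result bit for bit", {
  a <- permutation_enrichment(1:20, 1:100, 1:30, n_perm = 500, seed = 7)
  b <- permutation_enrichment(1:20, 1:100, 1:30, n_perm = 500, seed = 7)
  expect_identical(a, b)
})

test_that("p is invariant to relabelling non-hit positions and monotone in T", {
  # relabelling non-hits leaves everything unchanged
  a <- permutation_enrichment(c(1, 2, 50), 1:60, 1:5)
  b <- permutation_enrichment(c(1, 2, 55), 1:60, 1:5)
  expect_equal(a$p_perm, b$p_perm)
  # more observed hits with the same pool -> smaller or equal p
  ps <- vapply(0:3, function(h) {
    obs <- c(seq_len(h), 20 + seq_len(3 - h))
    permutation_enrichment(obs, 1:30, 1:6)$p_perm
  }, numeric(1))
  expect_true(all(diff(ps) <= 1e-12))
})

test_that("invalid enrichment inputs are rejected", {
  expect_error(permutation_enrichment(1:10, 1:5, 1:2), "subset")
  expect_error(permutation_enrichment(1:5, 1:100, 1:10,
                                      exhaustive_limit = 1),
               "seed is mandatory")
  expect_error(permutation_enrichment(1:5, 1:100, 1:10, n_perm = 0,
                                      seed = 1, exhaustive_limit = 1),
               "n_perm")
})
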