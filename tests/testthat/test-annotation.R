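test_that("side-chain compatibility encodes the nine chemistries", {
  expect_true(modification_compatibility("S", "phosphorylation"))
  expect_true(modification_compatibility("S", "O-glucosylation"))
  expect_true(modification_compatibility("E", "ethanolamination"))
  expect_false(modification_compatibility("A", "phosphorylation"))
  expect_false(modification_compatibility("T", "O-glucosylation"))
  expect_equal(modification_compatibility(c("K", "R", "C"), "methylation"),
               c(TRUE, TRUE, FALSE))
  # total over the controlled vocabulary, error outside it
  for (mod in ptm_vocabulary())
    expect_length(modification_compatibility(AA1, mod), 20)
  expect_error(modification_compatibility("S", "sumoylation"),
               "controlled vocabulary")
})

test_that("isoform-altered modifiability reproduces the worked variant cases", {
  variants <- parse_variant_labels(c("T176A", "C234T", "K273R", "S358A"))
  tab <- ptm_table(ptm_records(
    position = c(176, 234, 234, 273, 273, 273, 358),
    aa = c("T", "C", "T", "K", "K", "K", "S"),
    mod_type = c("phosphorylation", "S-nitrosylation", "phosphorylation",
                 "acetylation", "ubiquitination", "methylation",
                 "phosphorylation"),
    isoform = c("eEF1A1", "eEF1A1", "eEF1A2", "eEF1A1", "eEF1A1",
                "eEF1A1", "eEF1A2")))
  alt <- detect_altered_capability(variants, tab)
  expect_equal(alt$mods_only_A1[alt$label == "T176A"], "phosphorylation")
  expect_equal(alt$mods_only_A2[alt$label == "T176A"], "")
  expect_equal(alt$mods_only_A1[alt$label == "C234T"], "S-nitrosylation")
  expect_equal(alt$mods_only_A2[alt$label == "C234T"], "phosphorylation")
  expect_equal(alt$mods_only_A1[alt$label == "K273R"],
               "acetylation,ubiquitination")
  expect_equal(alt$mods_only_A2[alt$label == "K273R"], "")
  # with the first-allele-first label convention, A358S marks the
  # phosphosite present only in the second isoform
  alt2 <- detect_altered_capability(
    parse_variant_labels("A358S"),
    ptm_table(ptm_records(358, "S", "phosphorylation",
                          isoform = "eEF1A2")))
  expect_equal(alt2$mods_only_A2, "phosphorylation")
})

test_that("altered capability is symmetric under isoform relabelling", {
  variants <- parse_variant_labels(c("C234T", "K273R"))
  tab <- ptm_table(ptm_records(
    position = c(234, 234, 273, 273),
    aa = c("C", "T", "K", "K"),
    mod_type = c("S-nitrosylation", "phosphorylation", "acetylation",
                 "methylation")))
  fwd <- detect_altered_capability(variants, tab)
  swapped <- variant_sites(variants$position, variants$aa_A2,
                           variants$aa_A1)
  rev <- detect_altered_capability(swapped, tab)
  expect_equal(fwd$mods_only_A1, rev$mods_only_A2)
  expect_equal(fwd$mods_only_A2, rev$mods_only_A1)
})

test_that("variants without differential capability are omitted", {
  tab <- ptm_table(ptm_records(100, "K", "methylation"))
  alt <- detect_altered_capability(variant_sites(100, "K", "R"), tab)
  expect_equal(nrow(alt), 0)
})

test_that("site mapping splits mapped and tail positions exactly", {
  g <- generate_globule(64, seed = 47)
  empty <- ptm_table(ptm_records(integer(0), character(0), character(0)))
  ms <- map_ptm_to_structure(empty, g$model)
  expect_equal(nrow(ms$sites), 0)
  expect_length(ms$unmapped_tail, 0)
  # 10 positions, 2 planted beyond the boundary
  tab <- ptm_table(ptm_records(
    position = c(5, 10, 15, 20, 25, 30, 35, 40, 70, 80),
    aa = "S", mod_type = "phosphorylation"))
  ms <- map_ptm_to_structure(tab, g$model, c_terminal_boundary = 64)
  expect_equal(nrow(ms$sites), 8)
  expect_equal(ms$unmapped_tail, c(70, 80))
  # mapped + tail = distinct positions
  expect_equal(nrow(ms$sites) + length(ms$unmapped_tail),
               length(unique(tab$position)))
  expect_error(map_ptm_to_structure(tab, g$model, sequence_length = 75),
               "beyond sequence length")
})

test_that("per-position evidence merges across species and isoforms", {
  tab <- ptm_table(ptm_records(
    position = c(36, 36, 36), aa = "K",
    mod_type = c("acetylation", "acetylation", "methylation"),
    isoform = c("eEF1A1", "eEF1A2", "eEF1A1"),
    n_citations = c(2, 9, 1),
    site_specific = c(FALSE, FALSE, TRUE)))
  g <- generate_globule(64, seed = 47)
  ms <- map_ptm_to_structure(tab, g$model)
  expect_equal(nrow(ms$sites), 1)
  expect_equal(ms$sites$mods, "acetylation,methylation")
  expect_equal(ms$sites$n_mods, 2L)
  expect_equal(ms$sites$n_citations_max, 9)
  expect_true(ms$sites$site_specific_any)
})

test_that("multi-modification accounting counts distinct types per position", {
  empty <- ptm_table(ptm_records(integer(0), character(0), character(0)))
  expect_equal(nrow(multi_modification_sites(empty)), 0)
  tab <- ptm_table(ptm_records(
    position = c(1, 1, 2, 3, 3, 4, 5, 5, 6, 7, 7, 8, 9, 9),
    aa = rep("K", 14),
    mod_type = rep(c("acetylation", "methylation"), 7),
    isoform = "eEF1A1"))
  mm <- multi_modification_sites(tab)
  expect_equal(mm$position, c(1, 3, 5, 7, 9))
  # invariant to record order and species duplication
  dup <- rbind(tab, transform(tab, species = "mouse"))
  dup <- dup[sample(nrow(dup)), ]
  mm2 <- multi_modification_sites(ptm_table(dup))
  expect_equal(mm2$position, mm$position)
  expect_equal(mm2$n_mods, mm$n_mods)
})

test_that("the reliability filter keeps targeted or well-cited records", {
  tab <- ptm_table(ptm_records(
    position = 1:10, aa = "S", mod_type = "phosphorylation",
    n_citations = c(0, 1, 2, 3, 4, 5, 6, 9, 0, 2),
    site_specific = c(rep(FALSE, 8), TRUE, FALSE)))
  out <- reliability_filter(tab, min_citations = 5)
  expect_equal(nrow(out$table), 4)  # three >= 5 citations, one targeted
  expect_equal(out$counts$pass, 4L)
  expect_equal(out$counts$total, 10L)
  # pass + fail = total per modification type
  expect_true(all(out$counts$pass <= out$counts$total))
  all_pass <- reliability_filter(tab, min_citations = 0)
  expect_equal(nrow(all_pass$table), 10)
  expect_error(reliability_filter(tab, min_citations = -1), ">= 0")
})

test_that("filtering conserves records per modification type", {
  g <- generate_globule(125, seed = 53)
  v <- plant_variants(g$model, seed = 1)
  sp <- sample_ptms(g$model, v, seed = 2)
  out <- reliability_filter(sp$table)
  for (t in out$counts$mod_type) {
    n_pass <- sum(out$table$mod_type == t)
    n_total <- sum(sp$table$mod_type == t)
    expect_equal(out$counts$pass[out$counts$mod_type == t], n_pass)
    expect_equal(out$counts$total[out$counts$mod_type == t], n_total)
  }
  expect_equal(sum(out$counts$total), nrow(sp$table))
})

test_that("conservation against a distant row flags exactly the planted sites", {
  ref <- "ACDEFGHIKLMNPQRSTVWY"
  ga <- generate_alignment(ref, n_orthologs = 3, divergence = 0,
                           planted_site_substitutions = c(3, 7, 11, 19),
                           seed = 5)
  tab <- ptm_table(ptm_records(
    position = c(3, 5, 7, 11, 16, 19),
    aa = c("D", "F", "H", "M", "S", "W"),
    mod_type = c("carbonylation", "phosphorylation", "phosphorylation",
                 "methylation", "phosphorylation", "phosphorylation")))
  # records at F/H/M/W are not all chemically valid; keep the valid subset
  cons <- conservation_of_sites(ga$aln, tab, "reference", "distant")
  flagged <- cons$sites$position[!cons$sites$conserved]
  expect_equal(flagged, intersect(c(3, 7, 11, 19), cons$sites$position))
  # identical comparison row: nothing flagged
  cons0 <- conservation_of_sites(ga$aln, tab, "reference", "ortholog_1")
  expect_equal(cons0$n_non_conserved, 0)
  expect_error(conservation_of_sites(ga$aln, tab, "reference", "nope"),
               "not in alignment")
})

test_that("a gap in the comparison row counts as non-conserved", {
  aln <- alignment_map(c(ref = "ACSEF", cmp = "AC-EF"))
  tab <- ptm_table(ptm_records(c(2, 3), c("C", "S"),
                               c("S-nitrosylation", "phosphorylation")))
  cons <- conservation_of_sites(aln, tab, "ref", "cmp")
  expect_equal(cons$sites$conserved, c(TRUE, FALSE))
  expect_equal(cons$n_non_conserved, 1)
})

test_that("binding-site overlap intersects modified positions per list", {
  tab <- ptm_table(ptm_records(
    position = c(21, 22, 154, 157, 76, 300),
    aa = c("S", "T", "K", "S", "S", "S"),
    mod_type = c("phosphorylation", "phosphorylation", "acetylation",
                 "phosphorylation", "phosphorylation", "phosphorylation")))
  lists <- list(gtp_gdp = c(21, 22, 154, 157),
                exchange_factor = c(76, 89),
                empty = integer(0))
  ov <- binding_site_overlap(tab, lists)
  expect_equal(ov$gtp_gdp$position, c(21, 22, 154, 157))
  expect_equal(ov$exchange_factor$position, 76)
  expect_equal(ov$exchange_factor$mods, "phosphorylation")
  expect_equal(nrow(ov$empty), 0)
})

test_that("site lists round-trip through the plain-text format", {
  path <- tempfile(fileext = ".txt")
  writeLines(c("# binding sites", "gtp_gdp\t21,22,154,157",
               "exchange_factor\t76,89"), path)
  sl <- read_site_lists(path)
  expect_equal(sl$gtp_gdp, c(21L, 22L, 154L, 157L))
  expect_equal(sl$exchange_factor, c(76L, 89L))
  writeLines("badline", path)
  expect_error(read_site_lists(path), "malformed")
})
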