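make_map <- function(proteins, symbols) {
  path <- write_tmp(sprintf("%s\t%s\t%d\tname of %s",
                            proteins, symbols, seq_along(proteins), symbols))
  read_protein_gene_map(path)
}

test_that("select_targets applies thresholds and the max-collapse rule", {
  tab <- interaction_table(
    chemical_id = rep("CIDm001", 3),
    protein_id = c("P1", "P2", "P3"),
    combined_score = c(200L, 450L, 900L)
  )
  map <- make_map(c("P1", "P2", "P3"), c("GA", "GB", "GC"))
  medium <- select_targets(tab, "CIDm001", "medium", map)
  expect_equal(medium$genes, c("GB", "GC"))
  all_of_them <- select_targets(tab, "CIDm001", 0L, map)
  expect_equal(all_of_them$genes, c("GA", "GB", "GC"))
  expect_error(select_targets(tab, "CIDm999", "low", map),
               class = "cmx_not_found_error")
})

test_that("several proteins collapsing to one gene keep the max score", {
  tab <- interaction_table(
    chemical_id = rep("CIDm001", 2),
    protein_id = c("P1", "P2"),
    combined_score = c(500L, 800L)
  )
  map <- make_map(c("P1", "P2"), c("G1", "G1"))
  ts <- select_targets(tab, "CIDm001", "medium", map)
  expect_equal(ts$genes, "G1")
  expect_equal(unname(ts$per_gene_score["G1"]), 800L)
  # per-protein detail keeps both rows
  expect_equal(nrow(ts$detail), 2L)
})

test_that("unmapped proteins are excluded from genes but recorded", {
  tab <- interaction_table("CIDm001", c("P1", "PX"), c(900L, 900L))
  map <- make_map("P1", "G1")
  ts <- select_targets(tab, "CIDm001", "high", map)
  expect_equal(ts$genes, "G1")
  expect_equal(ts$unmapped_proteins, "PX")
})

test_that("venn_partition covers the hand-derived examples", {
  v2 <- venn_partition(list(A = c("g1", "g2"), B = c("g2", "g3")))
  expect_equal(v2$regions[["A"]], "g1")
  expect_equal(v2$regions[["B"]], "g3")
  expect_equal(v2$regions[["A+B"]], "g2")
  expect_length(v2$regions, 3L)

  v3same <- venn_partition(list(A = "x", B = "x", C = "x"))
  expect_length(v3same$regions, 7L)
  expect_equal(v3same$regions[["A+B+C"]], "x")
  expect_equal(sum(lengths(v3same$regions)), 1L)

  v3 <- venn_partition(list(A = c("g1", "g2"), B = c("g2", "g3"), C = "g2"))
  expect_equal(v3$regions[["A+B+C"]], "g2")
  expect_equal(v3$regions[["A"]], "g1")
  expect_equal(v3$regions[["B"]], "g3")
  expect_equal(sum(lengths(v3$regions) == 0L), 4L)
})

test_that("venn_partition enforces the 2-4 set contract", {
  expect_error(venn_partition(list(A = "x")), class = "cmx_contract_error")
  five <- setNames(replicate(5, "x", simplify = FALSE), LETTERS[1:5])
  expect_error(venn_partition(five), class = "cmx_contract_error")
  expect_error(venn_partition(list(c("x"), c("y"))),
               class = "cmx_contract_error")
})

test_that("venn regions are disjoint, conserving, and label-equivariant", {
  set.seed(31)
  universe <- sprintf("e%02d", 1:25)
  for (rep in 1:30) {
    n <- sample(2:4, 1)
    sets <- setNames(
      lapply(seq_len(n), function(i) sample(universe, sample(0:15, 1))),
      LETTERS[seq_len(n)]
    )
    v <- venn_partition(sets)
    expect_length(v$regions, 2^n - 1)
    members <- unlist(v$regions, use.names = FALSE)
    expect_equal(sort(members), sort(unique(unlist(sets))))
    expect_false(anyDuplicated(members) > 0)
    # permuting label order permutes keys, not memberships
    perm <- sample(n)
    expect_equal(venn_canonical(venn_partition(sets[perm])),
                 venn_canonical(v))
  }
})

test_that("joint_pvalue reproduces the published worked examples", {
  # rifampin + efavirenz, hepatitis row
  j1 <- joint_pvalue(c(rifampin = 4.32e-08, efavirenz = 0.00906))
  expect_equal(format_pvalue(j1$joint_p), "3.91E-10")
  # daidzein + genistein, endocrine system disease row
  j2 <- joint_pvalue(c(daidzein = 9.11e-12, genistein = 5.51e-21))
  expect_equal(format_pvalue(j2$joint_p), "5.02E-32")
  # single chemical: empty-product extension
  expect_equal(joint_pvalue(c(c1 = 0.37))$joint_p, 0.37)
})

test_that("joint_pvalue handles zeros and underflow in log10 space", {
  z <- joint_pvalue(c(a = 0, b = 0.5))
  expect_true(z$zero_input)
  expect_equal(z$joint_p, 0)
  expect_equal(z$log10_joint_p, -Inf)

  u <- joint_pvalue(c(a = 1e-200, b = 1e-200))
  expect_equal(u$joint_p, 0)
  expect_true(u$underflow)
  expect_equal(u$log10_joint_p, -400)

  expect_error(joint_pvalue(numeric(0)), class = "cmx_domain_error")
  expect_error(joint_pvalue(c(a = 1.2)), class = "cmx_domain_error")
})

test_that("joint_p <= min p and log-space agrees with the direct product", {
  set.seed(32)
  for (rep in 1:100) {
    p <- runif(sample(2:4, 1))^sample(1:5, 1)
    j <- joint_pvalue(setNames(p, paste0("c", seq_along(p))))
    expect_lte(j$joint_p, min(p) + 1e-15)
    expect_equal(j$joint_p, prod(p), tolerance = 1e-9)
  }
})

test_that("shared_term_analysis intersects significant terms with joint p", {
  a <- manual_enrichment(c("T1", "T2", "T3"), c(0.001, 0.02, 0.9), "c1")
  b <- manual_enrichment(c("T1", "T2", "T3"), c(0.004, 0.5, 0.01), "c2")
  res <- shared_term_analysis(list(c1 = a, c2 = b))
  shared_ids <- vapply(res$joint, `[[`, character(1), "term_id")
  expect_equal(shared_ids, "T1")
  expect_equal(res$joint[[1]]$joint_p, 0.001 * 0.004)
  # T2 significant only for c1, T3 only for c2
  expect_equal(res$term_venn$regions[["c1"]], "T2")
  expect_equal(res$term_venn$regions[["c2"]], "T3")

  c3 <- manual_enrichment("T1", 0.05 - 1e-9, "c3")
  a1 <- manual_enrichment("T1", 0.01, "c1")
  b1 <- manual_enrichment("T1", 0.02, "c2")
  res3 <- shared_term_analysis(list(c1 = a1, c2 = b1, c3 = c3))
  expect_equal(res3$joint[[1]]$joint_p, 0.01 * 0.02 * (0.05 - 1e-9),
               tolerance = 1e-12)

  other <- manual_enrichment("T1", 0.01, "c2", namespace = "GO")
  expect_error(shared_term_analysis(list(c1 = a1, c2 = other)),
               class = "cmx_contract_error")
  expect_error(shared_term_analysis(list(c1 = a1)),
               class = "cmx_contract_error")
})

test_that("overall_enrichment unions target sets idempotently", {
  catalog <- toy_catalog()
  ts1 <- structure(list(chemical_id = "c1", genes = c("g1", "g2")),
                   class = "target_set")
  ts2 <- structure(list(chemical_id = "c2", genes = c("g3")),
                   class = "target_set")
  solo <- overall_enrichment(list(ts1), catalog)
  own <- enrich(c("g1", "g2"), catalog, label = "union")
  expect_equal(as.data.frame(solo), as.data.frame(own))
  expect_equal(attr(solo, "label"), "union")

  both <- overall_enrichment(list(ts1, ts2), catalog)
  expect_equal(as.data.frame(both),
               as.data.frame(enrich(c("g1", "g2", "g3"), catalog)),
               ignore_attr = TRUE)
  # duplicate chemicals: same result as one copy
  dup <- overall_enrichment(list(ts1, ts1, ts2), catalog)
  expect_equal(as.data.frame(dup), as.data.frame(both))
  expect_error(overall_enrichment(list(), catalog),
               class = "cmx_contract_error")
})

test_that("analyze_mixture enforces the chemical-count contract", {
  bundle <- read_fixture_bundle(generate_fixture(fixture_config(),
                                                 tempfile("fx")))
  expect_error(analyze_mixture(sprintf("chem%02d", 1:5), bundle),
               "2 and 4", class = "cmx_contract_error")
  expect_error(analyze_mixture("chem01", bundle),
               class = "cmx_contract_error")
})

test_that("identical target sets give a pure-intersection mixture", {
  # one chemical duplicated under two ids: symmetric inputs
  rows <- c(sprintf("CIDmA\tP%d\t900", 1:4), sprintf("CIDmB\tP%d\t900", 1:4))
  links <- read_stitch_links(links_file(rows))
  map <- make_map(sprintf("P%d", 1:4), sprintf("g%d", 1:4))
  catalog <- toy_catalog()
  bundle <- list(links = links, aliases = NULL, map = map,
                 catalogs = list(DO = catalog))
  rep <- analyze_mixture(c("CIDmA", "CIDmB"), bundle, level = "high")
  nonempty <- names(rep$target_venn$regions)[
    lengths(rep$target_venn$regions) > 0]
  expect_equal(nonempty, "CIDmA+CIDmB")
  expect_equal(as.data.frame(rep$enrichment$CIDmA$DO),
               as.data.frame(rep$enrichment$CIDmB$DO),
               ignore_attr = TRUE)
  for (j in rep$shared$DO$joint) {
    p <- unname(j$per_chemical_adj_p)
    expect_equal(p[1], p[2])
    expect_equal(j$joint_p, p[1]^2, tolerance = 1e-12)
  }
})

test_that("a chemical with zero post-filter targets degrades gracefully", {
  rows <- c("CIDmA\tP1\t900", "CIDmA\tP2\t800", "CIDmB\tP3\t200")
  links <- read_stitch_links(links_file(rows))
  map <- make_map(sprintf("P%d", 1:3), c("g1", "g2", "g3"))
  bundle <- list(links = links, aliases = NULL, map = map,
                 catalogs = list(DO = toy_catalog()))
  rep <- analyze_mixture(c("CIDmA", "CIDmB"), bundle, level = "high")
  expect_equal(rep$target_sets$CIDmB$genes, character(0))
  expect_equal(nrow(rep$enrichment$CIDmB$DO), 0L)
  expect_length(rep$shared$DO$joint, 0L)
  expect_equal(venn_intersection(rep$target_venn), character(0))
})

test_that("intersections are monotone when chemicals are removed", {
  cfg <- fixture_config(n_chemicals = 3L, targets_per_chemical = 40L)
  bundle <- read_fixture_bundle(generate_fixture(cfg, tempfile("fx3")))
  all3 <- analyze_mixture(sprintf("chem%02d", 1:3), bundle, level = "low")
  pair <- analyze_mixture(sprintf("chem%02d", 1:2), bundle, level = "low")
  expect_true(all(venn_intersection(all3$target_venn) %in%
                    venn_intersection(pair$target_venn)))
  for (ns in names(all3$shared)) {
    sup <- vapply(all3$shared[[ns]]$joint, `[[`, character(1), "term_id")
    sub <- vapply(pair$shared[[ns]]$joint, `[[`, character(1), "term_id")
    expect_true(all(sup %in% sub))
  }
})
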