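test_that("intrinsic states and E-states match hand evaluations", {
  et <- estate_table(parse_smiles("CO"))
  expect_equal(et$I[et$element == "O"], 6)
  expect_equal(et$I[et$element == "C"], 2)
  expect_equal(et$S[et$element == "O"], 7.0)
  expect_equal(et$S[et$element == "C"], 1.0)

  et <- estate_table(parse_smiles("CC"))
  expect_equal(et$S, c(2, 2))
  expect_equal(et$dI, c(0, 0))

  et <- estate_table(parse_smiles("CC(=O)C"))
  expect_equal(max(et$S[et$element == "O"]),
               7 + (7 - 5 / 3) / 4 + 2 * (7 - 2) / 9, tolerance = 1e-3)
})

test_that("E-state invariants hold on all fixtures", {
  for (s in fixture_smiles) {
    m <- parse_smiles(s)
    et <- estate_table(m)
    expect_lt(abs(sum(et$dI)), 1e-9)           # pairwise antisymmetry
    second_row <- et$element %in% c("C", "N", "O", "F") & et$delta > 0
    expect_equal(et$I[second_row],
                 ((et$delta_v + 1) / et$delta)[second_row], info = s)
    # independent brute-force recomputation
    br <- brute_estate(m)
    expect_equal(et$S, br$S, tolerance = 1e-9, info = s)
  }
})

test_that("atom-type E-state maxima match hand-derived values", {
  expect_equal(max_hbd(parse_smiles("C1CCCCC1")), 0)
  expect_equal(max_hbd(parse_smiles("CO")), 7.0)
  expect_equal(max_hbd(parse_smiles("CCO")), 6 + 4.5 / 4 + 4 / 9,
               tolerance = 1e-3)
  expect_equal(max_do(parse_smiles("CCCCCC")), 0)
  expect_equal(max_do(parse_smiles("CC(=O)C")), 9.4444, tolerance = 1e-3)
  expect_equal(maxdp(parse_smiles("CC")), 0)
  expect_equal(maxdp(parse_smiles("CO")), 1.0)
  expect_equal(maxdp(parse_smiles("CCC")), 0.125)
})

test_that("a molecule with two carbonyls takes the larger =O E-state", {
  m <- parse_smiles("CC(=O)CC(=O)C")
  et <- estate_table(m)
  info <- bcfqsar:::estate_atom_info(m, et)
  s_carbonyl <- et$S[et$element == "O" & info$has_double]
  expect_length(s_carbonyl, 2L)
  expect_equal(max_do(m), max(s_carbonyl))
})

test_that("walk counts agree with brute-force enumeration", {
  expect_equal(mwc4(parse_smiles("C")), 0)
  expect_equal(mwc4(parse_smiles("CC")), log(3))
  expect_equal(mwc4(parse_smiles("C1CC1")), log(49))
  for (s in fixture_smiles) {
    m <- parse_smiles(s)
    if (heavy_atom_count(m) > 12L) next
    expect_equal(walk_count(m, 4L), brute_walk_count(m, 4L), info = s)
  }
  # halved and self-returning variants relate to the directed count
  m <- parse_smiles("C1CC1")
  expect_equal(walk_count(m, 4L, halved = TRUE), 24)
  expect_equal(walk_count(m, 4L, self_returning = TRUE), 18)
})

test_that("information content matches entropy by hand and brute force", {
  expect_equal(information_content(parse_smiles("C"), 0L),
               -(0.2 * log2(0.2) + 0.8 * log2(0.8)), tolerance = 1e-6)
  expect_equal(information_content(parse_smiles("[Hg]"), 0L), 0)
  expect_equal(information_content(parse_smiles("O=O"), 0L), 0)
  for (s in fixture_smiles) {
    m <- parse_smiles(s)
    ic0 <- information_content(m, 0L)
    ic2 <- information_content(m, 2L)
    expect_gte(ic2, ic0 - 1e-12)
    expect_gte(ic0, 0)
    expect_equal(ic0, brute_ic(m, 0L), tolerance = 1e-9, info = s)
    expect_equal(ic2, brute_ic(m, 2L), tolerance = 1e-9, info = s)
  }
})

test_that("TopoPSA sums the shipped fragment contributions", {
  expect_equal(topopsa(parse_smiles("CCCCCC")), 0)
  expect_equal(topopsa(parse_smiles("CO")), 20.23)
  expect_equal(topopsa(parse_smiles("CC(=O)C")), 17.07)
  expect_equal(topopsa(parse_smiles("CCOCC")), 9.23)
  expect_equal(topopsa(parse_smiles("c1ccncc1")), 12.89)
  expect_equal(topopsa(parse_smiles("CC(=O)O")), 17.07 + 20.23)
})

test_that("substructure counts match manual matching", {
  expect_equal(substructure_count(parse_smiles("Clc1ccccc1"), "[Cl][c]"), 1L)
  expect_equal(substructure_count(
    parse_smiles("Clc1c(Cl)c(Cl)c(Cl)c(Cl)c1Cl"), "[Cl][c]"), 6L)
  expect_equal(substructure_count(parse_smiles("CCO"), "[Cl][c]"), 0L)
  expect_equal(substructure_count(parse_smiles("CCl"), "[Cl][c]"), 0L)
  expect_equal(substructure_count(parse_smiles("CCOCC"),
                                  "[#6]~[#7,#8,#16]"), 2L)
  expect_equal(substructure_count(parse_smiles("CCN(CC)CC"),
                                  "[#6]~[#7,#8,#16]"), 3L)
  expect_error(substructure_count(parse_smiles("CC"), "[Qq]"),
               "invalid SMARTS")
})

test_that("compute_descriptors assembles the nine values deterministically", {
  d <- compute_descriptors("Clc1ccccc1")
  expect_named(d, descriptor_names())
  expect_equal(unname(d["SubFPC171"]), 1)
  expect_equal(unname(d[c("maxHBd", "maxdO", "TopoPSA")]), c(0, 0, 0))
  d <- compute_descriptors("C")
  expect_equal(unname(d["MWC4"]), 0)
  expect_equal(unname(d["IC0"]), 0.7219, tolerance = 1e-3)
  expect_true(all(is.finite(compute_descriptors("CS(=O)(=O)C"))))
})

test_that("descriptors are invariant under the input atom order", {
  set.seed(7)
  for (s in c("CC(=O)CC(=O)C", "Clc1ccccc1", "CC(C)CC(=O)O", "FC(F)(F)CO")) {
    m <- parse_smiles(s)
    ref <- compute_descriptors(m)
    for (rep in 1:5) {
      mp <- permute_atoms(m, sample(n_atoms(m)))
      expect_equal(compute_descriptors(mp), ref, info = s)
    }
  }
  # two writings of the same molecule give the same vector
  expect_equal(compute_descriptors("OCC"), compute_descriptors("CCO"))
})

test_that("adding an aromatic chlorine raises SubFPC171 and not-decreases MWC4", {
  pairs <- list(c("c1ccccc1", "Clc1ccccc1"),
                c("Clc1ccccc1", "Clc1ccccc1Cl"),
                c("c1ccc2ccccc2c1", "Clc1ccc2ccccc2c1"))
  for (pr in pairs) {
    d0 <- compute_descriptors(pr[1L]); d1 <- compute_descriptors(pr[2L])
    expect_equal(unname(d1["SubFPC171"] - d0["SubFPC171"]), 1)
    expect_gte(d1[["MWC4"]], d0[["MWC4"]])
  }
})

test_that("every worked molecule matches its hand-derived values", {
  for (nm in names(worked_molecules())) {
    entry <- worked_molecules()[[nm]]
    d <- compute_descriptors(entry$smiles)
    expect_equal(unname(d[names(entry$expected)]),
                 unname(entry$expected), tolerance = 1e-3, info = nm)
  }
})
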