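test_that("parse_smiles builds the expected graphs for simple molecules", {
  m <- parse_smiles("CC")
  expect_equal(heavy_atom_count(m), 2L)
  expect_equal(nrow(m$bonds), 1L)
  expect_equal(total_h_count(m), 6L)

  m <- parse_smiles("Clc1ccccc1")
  expect_equal(heavy_atom_count(m), 7L)
  expect_equal(sum(m$atoms$aromatic), 6L)
  expect_equal(sum(m$bonds$aromatic), 6L)
  # the one non-aromatic bond joins Cl to an aromatic carbon
  plain <- m$bonds[!m$bonds$aromatic, ]
  expect_equal(nrow(plain), 1L)
  ends <- c(m$atoms$element[plain$i], m$atoms$element[plain$j])
  expect_setequal(ends, c("Cl", "C"))
  expect_true(m$atoms$aromatic[plain$i] || m$atoms$aromatic[plain$j])
})

test_that("invalid and chemically impossible SMILES are rejected", {
  expect_error(parse_smiles("C((C"), "invalid SMILES")
  expect_error(parse_smiles("C1CC"), "invalid SMILES")
  expect_error(parse_smiles(""), "invalid SMILES")
  expect_error(parse_smiles("C=#C"), "invalid SMILES")
  expect_error(parse_smiles("C(C)(C)(C)(C)C"), "unparseable structure")
})

test_that("kekulized and aromatic writings perceive the same ring", {
  a <- parse_smiles("c1ccccc1")
  k <- parse_smiles("C1=CC=CC=C1")
  expect_equal(sum(a$atoms$aromatic), 6L)
  expect_equal(sum(k$atoms$aromatic), 6L)
  expect_equal(total_h_count(k), 6L)
  # cyclohexane and quinone-like rings stay non-aromatic
  expect_equal(sum(parse_smiles("C1CCCCC1")$atoms$aromatic), 0L)
  expect_equal(sum(parse_smiles("O=C1C=CC(=O)C=C1")$atoms$aromatic), 0L)
})

test_that("canonical form identifies equal molecules and is idempotent", {
  expect_identical(canonical_form(parse_smiles("OCC")),
                   canonical_form(parse_smiles("CCO")))
  expect_identical(canonical_form(parse_smiles("c1ccccc1")),
                   canonical_form(parse_smiles("C1=CC=CC=C1")))
  expect_identical(canonical_form(parse_smiles("CC(=O)C")),
                   canonical_form(parse_smiles("O=C(C)C")))
  for (s in fixture_smiles) {
    cf <- canonical_form(parse_smiles(s))
    expect_identical(canonical_form(parse_smiles(cf)), cf)
  }
})

test_that("canonical form is invariant under atom-order permutation", {
  set.seed(42)
  for (s in fixture_smiles) {
    m <- parse_smiles(s)
    cf <- canonical_form(m)
    for (rep in 1:5) {
      mp <- permute_atoms(m, sample(n_atoms(m)))
      expect_identical(canonical_form(mp), cf)
    }
  }
})

test_that("parse of the canonical writing preserves the structure", {
  bond_multiset <- function(m) {
    sort(vapply(seq_len(nrow(m$bonds)), function(r) {
      i <- m$bonds$i[r]; j <- m$bonds$j[r]
      ord <- if (m$bonds$aromatic[r]) "a" else as.character(m$bonds$order[r])
      paste(paste(sort(c(m$atoms$element[i], m$atoms$element[j])),
                  collapse = "-"), ord)
    }, character(1L)))
  }
  for (s in fixture_smiles) {
    m <- parse_smiles(s)
    m2 <- parse_smiles(canonical_form(m))
    expect_equal(heavy_atom_count(m2), heavy_atom_count(m), info = s)
    expect_equal(bond_multiset(m2), bond_multiset(m), info = s)
    expect_equal(total_h_count(m2), total_h_count(m), info = s)
    expect_equal(sort(m2$atoms$element), sort(m$atoms$element), info = s)
  }
})

test_that("is_modellable applies the curation exclusion rules", {
  expect_false(is_modellable(parse_smiles("[Na+].[Cl-]"))$ok)
  expect_equal(is_modellable(parse_smiles("[Na+].[Cl-]"))$reason,
               "salt/mixture")
  r <- is_modellable(parse_smiles("O=S(=O)(O)O"))
  expect_false(r$ok); expect_equal(r$reason, "inorganic")
  expect_true(is_modellable(parse_smiles("CCO"))$ok)
  expect_equal(is_modellable(parse_smiles("C[Hg]C"))$reason, "metal-organic")
  expect_equal(is_modellable(parse_smiles("CC(=O)[O-]"))$reason, "ion")
})

test_that("read_dataset reads records and reports rejects by row", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,smiles,logbcf_1,logbcf_2",
               "A,CCO,1.0,2.0",
               "B,c1ccccc1,3.5,",
               "C,CCC,0.4,0.6"), path)
  ds <- read_dataset(path)
  expect_length(ds$records, 3L)
  expect_equal(nrow(ds$rejects), 0L)
  expect_equal(ds$records[[1L]]$logbcf_mean, 1.5)
  expect_equal(ds$records[[2L]]$logbcf_values, 3.5)

  writeLines(c("id,smiles,logbcf", "A,CCO,1.0", "B,C((C,2.0", "C,CC,3.0"),
             path)
  ds <- read_dataset(path)
  expect_length(ds$records, 2L)
  expect_equal(ds$rejects$row, 2L)
  expect_match(ds$rejects$reason, "invalid SMILES")

  writeLines("smiles,logbcf", path)
  expect_error(read_dataset(path), "missing required|empty")
})

test_that("prediction tables round-trip through CSV", {
  path <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(id = c("A", "B"), logbcf_pred = c(-0.11, 2.345678),
                   stringsAsFactors = FALSE)
  write_predictions(df, path)
  back <- read_predictions(path)
  expect_equal(back$id, df$id)
  expect_equal(back$logbcf_pred, df$logbcf_pred)
})
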