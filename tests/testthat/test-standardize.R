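# The hand-picked fixture records the expected post-standardization status
# of every structure; the full pass must reproduce that truth table.

std_fixture <- local({
  fx <- toy_smiles_fixture()
  list(fx = fx, res = standardize_dataset(fx))
})

test_that("the fixture truth table is reproduced exactly", {
  out <- std_fixture$res$records
  expect_equal(out$status, std_fixture$fx$expected_status,
               info = paste(out$compound_id, collapse = ","))
})

test_that("standardization report counts are conserved", {
  rep <- std_fixture$res$report
  expect_equal(rep$pre_rejected + rep$rejected_metal_or_rare +
                 rep$rejected_mixture_inorganic + rep$rejected_other_structure +
                 rep$rejected_size + rep$passed,
               rep$input_count)
})

test_that("salts convert to their neutral parent acid/base", {
  rec <- compound_records("nab", "[Na+].[O-]C(=O)c1ccccc1", "0")
  out <- standardize_structure(rec)
  expect_equal(out$status, "active")
  # benzoic acid: single neutral component, no sodium
  expect_false(grepl("Na|\\.|\\+|-\\]", out$smiles))
  ref <- standardize_structure(compound_records("ba", "OC(=O)c1ccccc1", "0"))
  expect_equal(out$canonical_key, ref$canonical_key)
})

test_that("metal-containing structures are discarded", {
  rec <- compound_records("fe", "CC[Hg]c1ccccc1", "1")
  out <- standardize_structure(rec)
  expect_equal(out$status, "rejected_structure")
  expect_match(out$reason, "metal")
})

test_that("enantiomers collapse to one canonical key", {
  rec <- compound_records(c("L", "D"),
                          c("CC(C)[C@@H](N)C(=O)O", "CC(C)[C@H](N)C(=O)O"),
                          c("0", "0"))
  out <- standardize_structure(rec)
  expect_equal(out$canonical_key[1], out$canonical_key[2])
})

test_that("the full pass is idempotent", {
  out <- std_fixture$res$records
  again <- standardize_structure(out)
  expect_identical(again$smiles, out$smiles)
  expect_identical(again$canonical_key, out$canonical_key)
  expect_identical(again$status, out$status)
})

test_that("size filters use strict boundaries: <4 carbons out, =4 kept, MW>900 out", {
  rec <- compound_records(c("propane", "butane"), c("CCC", "CCCC"), c("0", "0"))
  out <- apply_size_filters(standardize_structure(rec))
  expect_equal(out$status, c("rejected_size", "active"))
  expect_match(out$reason[1], "carbon count 3")

  big_ok <- paste(rep("C", 64), collapse = "")   # MW ~899.7
  big_no <- paste(rep("C", 65), collapse = "")   # MW ~913.8
  rec2 <- compound_records(c("c64", "c65"), c(big_ok, big_no), c("0", "0"))
  out2 <- apply_size_filters(standardize_structure(rec2))
  expect_equal(out2$status, c("active", "rejected_size"))
})

test_that("every surviving record satisfies the admission invariants", {
  act <- active_records(std_fixture$res$records)
  expect_gt(nrow(act), 10)
  for (i in seq_len(nrow(act))) {
    s <- act$smiles[i]
    expect_false(grepl(".", s, fixed = TRUE))          # single component
    expect_false(grepl("[@/\\\\]", s))                  # no stereo marks
    els <- diliqsar:::smiles_elements(s)
    expect_true(all(els %in% diliqsar:::ALLOWED_ELEMENTS))
    expect_gte(sum(els == "C"), 4)
  }
})

test_that("protonation-state neutralization handles common charge patterns", {
  expect_equal(diliqsar:::neutralize_smiles("CC(=O)[O-]"), "CC(=O)[OH]")
  expect_equal(diliqsar:::neutralize_smiles("CC[NH3+]"), "CC[NH2]")
  expect_equal(diliqsar:::neutralize_smiles("c1cc[nH+]cc1"), "c1cc[n]cc1")
  # quaternary N has no proton to shed: untouched
  expect_equal(diliqsar:::neutralize_smiles("C[N+](C)(C)C"), "C[N+](C)(C)C")
})
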