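test_that("the default descriptor set has exactly 85 named features, 30 + 55", {
  meta <- descriptor_metadata()
  expect_equal(nrow(meta), 85)
  expect_equal(sum(meta$class == "physicochemical"), 30)
  expect_equal(sum(meta$class == "topological"), 55)
  expect_false(anyDuplicated(meta$name) > 0)
  # the four mandatory descriptors are present
  expect_true(all(c("molecular_weight", "clogp", "polarizability",
                    "molar_refractivity") %in% meta$name))
})

test_that("descriptor rows match hand-computed oracles", {
  d <- compute_descriptors(c(benzene = "c1ccccc1",
                             naphthalene = "c1ccc2ccccc2c1"))
  expect_equal(ncol(d), 85)
  # oracle: sum of standard atomic masses, C6H6 = 6*12.011 + 6*1.008
  expect_equal(d["benzene", "molecular_weight"], 6 * 12.011 + 6 * 1.008,
               tolerance = 0.01)
  # oracle: naphthalene SSSR by exhaustive cycle search = 2 six-membered
  # rings (the 10-membered perimeter is their symmetric difference)
  expect_equal(unname(d["naphthalene", "ring_count"]), 2)
  expect_equal(unname(d["naphthalene", "n_aromatic_rings"]), 2)
  expect_equal(unname(d["benzene", "n_aromatic_atoms"]), 6)
  # benzene graph: 6 atoms, 6 bonds, Wiener index 6*1 + 6*2 + 3*3 = 27
  expect_equal(unname(d["benzene", "wiener_index"]), 27)
  expect_true(all(is.finite(d)))
})

test_that("descriptor computation is deterministic and standardization-invariant", {
  a <- compute_descriptors(c(x = "CC(=O)Oc1ccccc1C(=O)O"))
  b <- compute_descriptors(c(x = "CC(=O)Oc1ccccc1C(=O)O"))
  expect_identical(a, b)
  # kekulized vs aromatic input spellings of the same structure
  c1 <- compute_descriptors(c(x = "c1ccccc1"))
  c2 <- compute_descriptors(c(x = "C1=CC=CC=C1"))
  expect_equal(c1[1, ], c2[1, ], tolerance = 1e-12)
})

test_that("descriptor failures are flagged and excluded, not silently dropped", {
  expect_message(d <- compute_descriptors(c(ok = "CCCC", bad = "C1CC")),
                 "failed")
  expect_equal(rownames(d), "ok")
  expect_equal(attr(d, "failed_ids"), "bad")
})

test_that("tanimoto follows its set-overlap definition", {
  expect_equal(tanimoto(c(1, 1, 0), c(0, 1, 1)), 1 / 3)  # {1,2} vs {2,3}
  expect_equal(tanimoto(c(1, 0, 1), c(1, 0, 1)), 1)
  expect_equal(tanimoto(c(1, 1, 0, 0), c(0, 0, 1, 1)), 0)
  expect_equal(tanimoto(numeric(4), numeric(4)), 1)      # both-empty convention
  expect_error(tanimoto(c(1, 0), c(1, 0, 1)), "length mismatch")
})

test_that("tanimoto is symmetric and bounded on random fingerprints", {
  set.seed(42)
  for (i in 1:25) {
    a <- rbinom(64, 1, 0.3); b <- rbinom(64, 1, 0.3)
    s <- tanimoto(a, b)
    expect_identical(s, tanimoto(b, a))
    expect_gte(s, 0); expect_lte(s, 1)
    if (sum(a) > 0) expect_equal(tanimoto(a, a), 1)
  }
})

test_that("fingerprints are deterministic, fold correctly, and separate molecules", {
  smi <- c(a = "CC(=O)Oc1ccccc1C(=O)O", b = "CCN(CC)CC")
  f1 <- compute_fingerprint(smi)
  f2 <- compute_fingerprint(smi)
  expect_identical(f1, f2)
  expect_lt(tanimoto(f1[1, ], f1[2, ]), 1)      # two distinct drugs
  expect_gt(sum(f1[1, ]), 0)
  folded <- compute_fingerprint(smi, nbits = 256)
  expect_equal(ncol(folded), 256)
  expect_gte(sum(folded[1, ]) , 1)
  # methane has no path of length >= 1 bond pair: documented all-zero print
  m <- compute_fingerprint(c(m = "C"))
  expect_equal(sum(m), 0)
})

test_that("diversity summary equals the brute-force pairwise mean", {
  rec <- compound_records(paste0("m", 1:4),
                          c("CCCCO", "CCCCN", "c1ccccc1", "CC(=O)Oc1ccccc1C(=O)O"),
                          "0")
  rec <- standardize_structure(rec)
  ds <- diversity_summary(rec)
  fps <- compute_fingerprint(rec)
  sims <- c()
  for (i in 1:3) for (j in (i + 1):4) sims <- c(sims, tanimoto(fps[i, ], fps[j, ]))
  expect_equal(ds$mean_tanimoto, mean(sims))
  expect_equal(ds$n_pairs, 6)
  expect_true(ds$mw_range[1] <= ds$mw_range[2])

  # identical molecules: mean similarity exactly 1
  same <- compound_records(paste0("s", 1:3), "c1ccccc1CC", "0")
  same <- standardize_structure(same)
  expect_equal(diversity_summary(same)$mean_tanimoto, 1)
  expect_error(diversity_summary(same[1, ]), "at least 2")
})
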