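toy_csv <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "toy.csv")
  writeLines(c("smiles,log_s,name",
               "CCO,-0.1,ethanol",
               "C1CC,-2.0,broken",
               "OCC(O)CO,0.5,glycerol"), path)
  path
}

test_that("CSV loading drops unparsable rows and counts unique molecules", {
  path <- toy_csv()
  expect_message(rec <- read_solubility_csv(path), "1 row")
  expect_identical(nrow(rec), 2L)
  expect_identical(rec$smiles, c("CCO", "OCC(O)CO"))
  expect_identical(rec$parent_canonical, canonical_smiles(rec$smiles))
  expect_identical(attr(rec, "n_unique_molecules"), 2L)
  # determinism: loading twice gives identical records
  expect_identical(rec, suppressMessages(read_solubility_csv(path)))
  expect_error(read_solubility_csv(path, smiles_col = "nope"), "missing column")
  expect_error(read_solubility_csv(file.path(tempdir(), "absent.csv")),
               "not found")
})

test_that("augmentation preserves labels/parents and caps new strings", {
  rec <- soluq:::record_frame("CCO", -0.1, "r1", canonical_smiles("CCO"))
  aug <- augment_records(rec, max_new = 10, seed = 3)
  expect_lte(nrow(aug), 11L)
  expect_gt(nrow(aug), 1L)
  expect_true(all(aug$log_s == -0.1))
  expect_true(all(aug$parent_canonical == canonical_smiles("CCO")))
  expect_false(any(duplicated(aug$smiles)))
  expect_identical(augment_records(rec, max_new = 0), rec)
})

test_that("global dedup matches a brute-force oracle on a 100-molecule set", {
  rec <- fx_synth200()$records[1:100, ]
  aug <- augment_records(rec, max_new = 10, seed = 17)
  # brute-force oracle: regenerate every molecule's variants independently,
  # concatenate in order, keep first occurrence of each exact string
  oracle <- rec$smiles
  oracle_parent <- rec$parent_canonical
  oracle_labels <- rec$log_s
  for (i in seq_len(nrow(rec))) {
    alt <- randomize_smiles(rec$smiles[i], max_new = 10,
                            seed = soluq:::derive_seed(17, i))
    expect_lte(length(alt), 10)
    oracle <- c(oracle, alt)
    oracle_parent <- c(oracle_parent, rep(rec$parent_canonical[i], length(alt)))
    oracle_labels <- c(oracle_labels, rep(rec$log_s[i], length(alt)))
  }
  keep <- !duplicated(oracle)
  expect_identical(aug$smiles, oracle[keep])
  expect_identical(aug$log_s, oracle_labels[keep])
  expect_identical(aug$parent_canonical, oracle_parent[keep])
  expect_true(all(canonical_smiles(aug$smiles) == aug$parent_canonical))
})

test_that("splitting is deterministic, disjoint and honors the fraction", {
  rec <- fx_synth200()$records[1:10, ]
  sp <- split_records(rec, 0.8, seed = 0)
  expect_identical(nrow(sp$train), 8L)
  expect_identical(nrow(sp$test), 2L)
  expect_length(intersect(sp$train$smiles, sp$test$smiles), 0)
  sp2 <- split_records(rec, 0.8, seed = 0)
  expect_identical(sp, sp2)
  big <- split_records(fx_synth2000()$records, 0.8, seed = 1)
  frac <- nrow(big$train) / 2000
  expect_lt(abs(frac - 0.8), 0.005)
  expect_error(split_records(rec[1, ], 0.8), "at least 2")
})

test_that("the leakage report equals a brute-force parent intersection", {
  rec <- fx_synth200()$records[1:30, ]
  aug <- augment_records(rec, max_new = 3, seed = 9)
  sp <- split_records(aug, 0.8, seed = 5)
  oracle <- intersect(unique(sp$train$parent_canonical),
                      unique(sp$test$parent_canonical))
  expect_identical(sp$leakage, oracle)
  expect_gt(length(sp$leakage), 0)  # splitting after augmentation leaks
  # by-parent splitting removes the leakage entirely
  sp2 <- split_records(aug, 0.8, seed = 5, by_parent = TRUE)
  expect_length(sp2$leakage, 0)
})
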