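test_that("pIC50 conversion follows the molar convention and inverts cleanly", {
  expect_equal(ic50_to_pic50(1), 9)
  expect_equal(ic50_to_pic50(1000), 6)            # the 1 uM activity threshold
  expect_equal(ic50_to_pic50(767000), 3.115, tolerance = 1e-3)
  expect_error(ic50_to_pic50(0))
  expect_error(ic50_to_pic50(-5))
  x <- c(0.00125, 1, 50, 767000)
  expect_true(all(diff(ic50_to_pic50(x)) < 0))    # strictly decreasing
  expect_equal(pic50_to_ic50(ic50_to_pic50(x)), x, tolerance = 1e-9)
})

test_that("standardization canonicalizes, desalts and rejects gracefully", {
  std <- chem_standardize(c("CCO", "OCC", "CCN.Cl", "not_a_smiles"))
  expect_identical(std$canonical[1], std$canonical[2])  # one identity per molecule
  expect_false(grepl(".", std$canonical[3], fixed = TRUE))  # salt removed
  expect_true(is.na(std$canonical[4]))
  expect_match(std$reason[4], "unparseable")
  # idempotence
  again <- chem_standardize(std$canonical[1])
  expect_identical(again$canonical, std$canonical[1])
  log <- standardize_smiles(c("CCO", "xxx"))
  expect_equal(nrow(log$rejections), 1)
})

test_that("duplicate merging keeps the lowest IC50 per compound and target", {
  rows <- data.frame(
    canonical_smiles = c("CCO", "CCO", "CCO", "CCN"),
    target = c("JAK1", "JAK1", "JAK2", "JAK1"),
    ic50_nM = c(10, 5, 50, 7),
    stringsAsFactors = FALSE)
  rec <- merge_duplicates(rows, c("JAK1", "JAK2"))
  expect_equal(nrow(rec), 2)
  cco <- rec[rec$canonical_smiles == "CCO", ]
  expect_equal(cco$JAK1_pIC50, ic50_to_pic50(5))   # lower IC50 kept
  expect_equal(cco$JAK2_pIC50, ic50_to_pic50(50))  # one record, two targets
  expect_equal(rec$JAK1_pIC50[rec$canonical_smiles == "CCN"], ic50_to_pic50(7))
  # single row passes through; empty input gives empty output
  one <- merge_duplicates(rows[4, ], c("JAK1", "JAK2"))
  expect_equal(one$JAK1_pIC50, ic50_to_pic50(7))
  expect_true(is.na(one$JAK2_pIC50))
  expect_equal(nrow(merge_duplicates(rows[0, ], c("JAK1", "JAK2"))), 0)
  expect_error(merge_duplicates(transform(rows, target = "XXX"), c("JAK1")))
})

test_that("splitting is seed-reproducible, disjoint, exhaustive, correctly sized", {
  rec <- data.frame(canonical_smiles = paste0("m", 1:100), split = "unassigned",
                    stringsAsFactors = FALSE)
  s1 <- split_dataset(rec, c(0.8, 0.1, 0.1), seed = 3)
  expect_equal(as.vector(table(s1$split)[c("train", "valid", "test")]),
               c(80L, 10L, 10L))
  s2 <- split_dataset(rec, c(0.8, 0.1, 0.1), seed = 3)
  expect_identical(s1$split, s2$split)
  s3 <- split_dataset(rec, c(0.8, 0.1, 0.1), seed = 4)
  expect_false(identical(s1$split, s3$split))
  # rounded shares at a size where rounding matters
  big <- data.frame(canonical_smiles = paste0("m", 1:13898), split = "x",
                    stringsAsFactors = FALSE)
  sb <- table(split_dataset(big, c(0.8, 0.1, 0.1), seed = 0)$split)
  expect_equal(as.vector(sb[c("train", "valid", "test")]), c(11118L, 1390L, 1390L))
  expect_error(split_dataset(rec[1:2, ], c(0.8, 0.1, 0.1), 0))
  expect_error(split_dataset(rec, c(0.8, 0.1, 0.2), 0))
})

test_that("task tables mirror label sparsity", {
  rec <- data.frame(canonical_smiles = c("CCO", "CCN", "CCC"),
                    JAK1_pIC50 = c(7.1, NA, 6.0),
                    JAK2_pIC50 = c(6.5, NA, NA),
                    JAK3_pIC50 = c(5.0, 8.2, NA),
                    TYK2_pIC50 = c(7.7, NA, NA),
                    split = "train", stringsAsFactors = FALSE)
  tab <- build_task_table(rec, c("JAK1", "JAK2", "JAK3", "TYK2"))
  expect_equal(unname(tab$mask[1, ]), rep(TRUE, 4))
  expect_equal(unname(tab$mask[3, ]), c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(unname(colSums(tab$mask)),
               unname(colSums(!is.na(rec[, 2:5]))))
  expect_true(all(tab$labels[!tab$mask] == 0))
  expect_error(build_task_table(rec, "JAK9"))
})

test_that("the curation pipeline cleans a raw table end to end", {
  raw <- data.frame(
    smiles = c("CCO", "OCC", "CCN.Cl", "bad_smiles", "c1ccccc1O", "CCO"),
    target = c("JAK1", "JAK1", "JAK2", "JAK1", "JAK2", "JAK2"),
    ic50_nM = c(100, 20, 3, 10, 1000, -1),
    stringsAsFactors = FALSE)
  cur <- curate(raw, targets = c("JAK1", "JAK2"), seed = 1)
  expect_equal(cur$report$n_rows_rejected_structure, 1)
  expect_equal(cur$report$n_rows_dropped_ic50, 1)
  expect_equal(cur$report$n_compounds, 3)
  cco <- cur$records[cur$records$canonical_smiles == "CCO", ]
  expect_equal(cco$JAK1_pIC50, ic50_to_pic50(20))  # duplicates merged
  expect_true(all(cur$records$split %in% c("train", "valid", "test")))
  # CSV round trip preserves labels and splits
  path <- tempfile(fileext = ".csv")
  write_curated_csv(cur$records, path)
  back <- read_curated_csv(path)
  expect_equal(back$JAK1_pIC50, cur$records$JAK1_pIC50)
  expect_identical(back$split, cur$records$split)
  expect_identical(record_targets(back), c("JAK1", "JAK2"))
})
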