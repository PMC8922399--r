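test_that("weight normalization maps onto [0,1] with a degenerate midpoint", {
  expect_equal(normalize_weights(c(1, 3)), c(0, 1))
  expect_equal(normalize_weights(c(2, 2, 2)), c(0.5, 0.5, 0.5))
  expect_equal(normalize_weights(c(1, 2, 4)), c(0, 1/3, 1))
  x <- c(0.2, 0.9, 0.4, 0.4)
  expect_equal(normalize_weights(normalize_weights(x)), normalize_weights(x))
})

test_that("attribution weights behave: positive, normalized, equivariant", {
  model <- toy_model()
  smi <- "CC(=O)Nc1ccccc1"
  w_att <- atom_weights(model, smi)
  g <- mol_to_graph(smi, model$schema)
  expect_length(w_att, g$n_atoms)
  expect_true(all(w_att >= 0))
  expect_equal(sum(w_att), 1)          # readout attention sums to one
  w_grad <- atom_weights(model, smi, method = "gradient")
  expect_true(all(w_grad >= 0))
  # single-atom molecule is scorable
  expect_length(atom_weights(model, "C"), 1)
  # permuting atoms permutes weights identically
  set.seed(2)
  perm <- sample(g$n_atoms)
  for (m in c("readout_attention", "gradient")) {
    w <- atom_weights(model, g, method = m)
    wp <- atom_weights(model, permute_graph(g, perm), method = m)
    expect_equal(wp, w[perm], tolerance = 1e-10)
  }
  att <- atom_attribution(model, smi)
  expect_equal(att$key_atoms,
               which(att$normalized_weights > mean(att$normalized_weights)))
})

test_that("exact rank-sum p-values match brute-force enumeration", {
  # textbook case: A holds the two largest of four values
  res <- rank_sum_region_test(c(1, 2, 3, 4), region = c(3, 4))
  expect_equal(res$p_value, 1 / 6)
  expect_equal(res$region_mean, 3.5)
  expect_false(res$significant)
  # independent enumeration oracle over random (tied) weight vectors
  brute_p <- function(w, region) {
    rk <- rank(w)
    obs <- sum(rk[region])
    combos <- utils::combn(length(w), length(region))
    hits <- 0
    for (c_ in seq_len(ncol(combos))) {
      if (sum(rk[combos[, c_]]) >= obs - 1e-9) hits <- hits + 1
    }
    hits / ncol(combos)
  }
  set.seed(33)
  for (i in 1:25) {
    n <- sample(4:12, 1)
    w <- sample(round(runif(n), 1))   # rounding creates ties
    region <- sample(n, sample(n - 1, 1))
    expect_equal(rank_sum_region_test(w, region)$p_value, brute_p(w, region))
  }
  # without ties the exact p agrees with the classical distribution
  for (i in 1:10) {
    a <- rnorm(4)
    b <- rnorm(5)
    ours <- rank_sum_region_test(c(a, b), 1:4)$p_value
    ref <- stats::wilcox.test(a, b, alternative = "greater",
                              exact = TRUE)$p.value
    expect_equal(ours, ref, tolerance = 1e-12)
  }
})

test_that("rank-sum edge cases: full ties, null behavior, approximation", {
  # all-equal weights: no evidence, never significant
  res <- rank_sum_region_test(rep(0.5, 8), region = 1:3)
  expect_gte(res$p_value, 0.5)
  expect_false(res$significant)
  expect_error(rank_sum_region_test(c(1, 2), region = 1:2))
  expect_error(rank_sum_region_test(c(1, 2), region = integer(0)))
  # under the null, p is roughly uniform: its mean is near 0.5
  set.seed(4)
  ps <- replicate(200, {
    w <- rnorm(10)
    rank_sum_region_test(w, sample(10, 4))$p_value
  })
  expect_gt(mean(ps), 0.35)
  expect_lt(mean(ps), 0.65)
  # large-sample normal route approximates the exact route
  set.seed(5)
  w <- rnorm(14)
  region <- sample(14, 6)
  p_norm <- rank_sum_region_test(w, region)$p_value           # n > 12: normal
  p_exact <- rank_sum_region_test(w, region, exact_max = 14)$p_value
  expect_equal(p_norm, p_exact, tolerance = 0.05)
})

test_that("rendering writes the weight table and an SVG depiction", {
  model <- toy_model()
  att <- atom_attribution(model, "CC(=O)Nc1ccccc1")
  out <- render_attribution(att, tempfile("attr"))
  expect_true(file.exists(out$csv))
  tab <- read.csv(out$csv)
  expect_equal(nrow(tab), length(att$raw_weights))
  expect_true(all(tab$normalized_weight >= 0 & tab$normalized_weight <= 1))
  expect_true(file.exists(out$svg))
  expect_match(readLines(out$svg, n = 2, warn = FALSE)[1], "xml|svg")
})

test_that("SMARTS-defined regions can be tested directly", {
  model <- toy_model()
  res <- test_substructure(model, "CCS(=O)(=O)N", "S(=O)(=O)N")
  expect_s3_class(res, "substructure_test")
  expect_true(!is.null(res$raw_region_mean))
  expect_null(test_substructure(model, "CCO", "S(=O)(=O)N"))  # no match
})
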