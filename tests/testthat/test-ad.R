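hand_fps <- function() {
  # five 8-bit fingerprints with easily enumerated distances
  matrix(c(1,1,0,0, 0,0,0,0,
           1,1,1,0, 0,0,0,0,
           0,0,0,1, 1,1,0,0,
           0,0,0,1, 1,0,0,0,
           1,0,0,0, 0,0,1,1), 5, 8, byrow = TRUE)
}

test_that("threshold arithmetic is exactly linear in Z", {
  expect_equal(ad_threshold(0.1262, 0.2522, -0.25), 0.1262 - 0.25 * 0.2522)
  Z <- seq(-1, 1, by = 0.25)
  d <- ad_threshold(0.3, 0.1, Z)
  expect_equal(diff(d), rep(0.1 * 0.25, length(Z) - 1))
})

test_that("fitting matches an exhaustive nearest-neighbor oracle", {
  fps <- hand_fps()
  for (kind in c("one_minus_tanimoto", "euclidean_normalized")) {
    ad <- fit_ad(fps, distance_kind = kind, Z = -0.25, k = 2)
    # brute force over all pairs
    dist1 <- function(a, b) {
      if (kind == "one_minus_tanimoto") {
        u <- sum(a | b)
        if (u == 0) 0 else 1 - sum(a & b) / u
      } else {
        sqrt(sum((a - b)^2)) / sqrt(length(a))
      }
    }
    nn <- sapply(1:5, function(i)
      min(sapply(setdiff(1:5, i), function(j) dist1(fps[i, ], fps[j, ]))))
    expect_equal(ad$d_ave, mean(nn))
    expect_equal(ad$theta, sd(nn))
    expect_equal(ad$D_T, mean(nn) - 0.25 * sd(nn))
  }
  # duplicated training compound: zero nearest distances
  dup <- fps[c(1, 1), ]
  ad0 <- fit_ad(dup, Z = 5, k = 1)
  expect_equal(ad0$d_ave, 0)
  expect_equal(ad0$theta, 0)
  expect_equal(ad0$D_T, 0)
  expect_error(fit_ad(fps[1, , drop = FALSE]))
})

test_that("classification applies the k-nearest-neighbor rule", {
  # training set at known euclidean-normalized distances from the origin query
  train <- matrix(0, 4, 16)
  train[2, 1] <- 1          # distance 1/4
  train[3, 1:4] <- 1        # distance 2/4
  train[4, 1:9] <- 1        # distance 3/4
  query <- matrix(0, 1, 16)
  ad <- fit_ad(train, distance_kind = "euclidean_normalized", k = 3)
  ad$d_ave <- 0.4; ad$theta <- 0   # fix the threshold directly: D_T = 0.4
  ad$D_T <- 0.4
  v3 <- classify_ad(ad, query, k = 3, Z = 0)
  v2 <- classify_ad(ad, query, k = 2, Z = 0)
  expect_false(v3$in_domain)   # third neighbor at 0.5 > 0.4
  expect_true(v2$in_domain)    # first two at 0, 0.25
  expect_equal(v3$k_distances[[1]], c(0, 0.25, 0.5))
  # an exact training copy is always in domain for k = 1 and D_T >= 0
  v1 <- classify_ad(ad, train[4, , drop = FALSE], k = 1, Z = 0)
  expect_true(v1$in_domain)
  expect_equal(v1$max_k_distance, 0)
  # a hugely negative Z pushes the threshold below zero: everything is outside
  ad_spread <- ad
  ad_spread$theta <- 0.01
  vneg <- classify_ad(ad_spread, query, k = 1, Z = -100)
  expect_false(vneg$in_domain)
  expect_error(classify_ad(ad, query, k = 10), "k exceeds")
})

test_that("query distances agree with brute force on dozens of molecules", {
  smiles <- generate_library(fixture_spec(n_molecules = 50, seed = 3))
  fps <- chem_fingerprints(smiles, "morgan")
  ad <- fit_ad(fps[1:40, ], k = 1)
  verdict <- classify_ad(ad, fps[41:50, ], k = 1)
  for (i in 1:10) {
    q <- fps[40 + i, ]
    brute <- min(sapply(1:40, function(j) {
      u <- sum(q | fps[j, ])
      if (u == 0) 0 else 1 - sum(q & fps[j, ]) / u
    }))
    expect_equal(verdict$max_k_distance[i], brute, tolerance = 1e-12)
  }
})

test_that("out-of-domain counts shrink as Z grows or k shrinks", {
  smiles <- generate_library(fixture_spec(n_molecules = 60, seed = 4))
  fps <- chem_fingerprints(smiles, "morgan")
  ad <- fit_ad(fps[1:45, ], k = 3)
  sweep <- ad_sweep(ad, fps[46:60, ], k_values = 3:5,
                    Z_values = c(-0.25, -0.2, -0.15, -0.1))
  expect_equal(nrow(sweep), 12)
  for (k in 3:5) {
    nod <- sweep$n_OD[sweep$k == k][order(sweep$Z[sweep$k == k])]
    expect_true(all(diff(nod) <= 0))     # larger Z, wider domain
  }
  for (Z in unique(sweep$Z)) {
    nod <- sweep$n_OD[sweep$Z == Z][order(sweep$k[sweep$Z == Z])]
    expect_true(all(diff(nod) >= 0))     # larger k, stricter rule
  }
  expect_error(ad_sweep(ad, fps[46:60, ], k_values = integer(0)))
  # membership is monotone in k at fixed threshold
  v4 <- classify_ad(ad, fps[46:60, ], k = 4)
  v2 <- classify_ad(ad, fps[46:60, ], k = 2)
  expect_true(all(v2$in_domain[v4$in_domain]))
})

test_that("a fitted domain survives JSON serialization", {
  fps <- hand_fps()
  ad <- fit_ad(fps, Z = -0.2, k = 2)
  path <- tempfile(fileext = ".json")
  write_ad_json(ad, path)
  back <- read_ad_json(path)
  expect_equal(back$d_ave, ad$d_ave)
  expect_equal(back$D_T, ad$D_T)
  expect_equal(back$fingerprints, ad$fingerprints)
  q <- fps[3, , drop = FALSE]
  expect_identical(classify_ad(back, q)$in_domain, classify_ad(ad, q)$in_domain)
})
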