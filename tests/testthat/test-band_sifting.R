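test_that("sifting splits the toy subband as hand-computed", {
  sb <- matrix(c(-3, -0.5, 0.5, 3), 2, 2)
  q <- sift_subband(sb)
  # population SD of {-3, -0.5, 0.5, 3}: mean 0, sqrt(18.5/4)
  expect_equal(q$sigma, sqrt(18.5 / 4), tolerance = 1e-12)
  expect_equal(as.vector(q$hp), c(0, 0, 0, 3))
  expect_equal(as.vector(q$hn), c(-3, 0, 0, 0))
  expect_equal(as.vector(q$lp), c(0, 0, 0.5, 0))
  expect_equal(as.vector(q$ln), c(0, -0.5, 0, 0))
})

test_that("an all-zero subband sifts to zero everywhere", {
  q <- sift_subband(matrix(0, 4, 4))
  expect_equal(q$sigma, 0)
  for (s in c("hp", "hn", "lp", "ln")) expect_true(all(q[[s]] == 0))
})

test_that("a pixel exactly at one SD counts as low amplitude", {
  # values {1, -1, 1, -1}: sigma = 1, |v| == sigma everywhere -> all low
  q <- sift_subband(matrix(c(1, -1, 1, -1), 2, 2))
  expect_equal(q$sigma, 1)
  expect_true(all(q$hp == 0) && all(q$hn == 0))
  expect_equal(q$lp + q$ln, matrix(c(1, -1, 1, -1), 2, 2))
})

test_that("quadrants partition every subband with disjoint supports and fixed signs", {
  set.seed(41)
  for (rep in 1:5) {
    sb <- matrix(rnorm(20 * 20, sd = runif(1, 0.1, 2)), 20, 20)
    q <- sift_subband(sb)
    expect_lt(max(abs(q$hp + q$hn + q$lp + q$ln - sb)), 1e-12)
    expect_true(all(q$hp >= 0) && all(q$lp >= 0))
    expect_true(all(q$hn <= 0) && all(q$ln <= 0))
    nonzero <- (q$hp != 0) + (q$hn != 0) + (q$lp != 0) + (q$ln != 0)
    expect_true(all(nonzero <= 1))
  }
})

test_that("grouping routes quadrants by the high/low frequency split", {
  set.seed(42)
  dims <- structure(list(K = 7L, high = 1:3, low = 4:7), class = "bs_dims")
  subbands <- lapply(1:7, function(i) matrix(rnorm(64, sd = 1 / i), 8, 8))
  quads <- lapply(subbands, sift_subband)
  feats <- group_bs_features(quads, dims)

  # subband 3's hp lands in HHP, subband 4's hp in LHP
  expect_equal(feats$HHP, quads[[1]]$hp + quads[[2]]$hp + quads[[3]]$hp)
  expect_equal(feats$LHP, quads[[4]]$hp + quads[[5]]$hp + quads[[6]]$hp +
                 quads[[7]]$hp)

  # the eight features re-partition the sum of all subbands
  expect_lt(max(abs(Reduce(`+`, feats) - Reduce(`+`, subbands))), 1e-9)

  expect_error(group_bs_features(quads[1:6], dims), class = "bs_arg_error")
})

test_that("with a single subband all high-frequency features are zero", {
  dims <- structure(list(K = 1L, high = integer(0), low = 1L),
                    class = "bs_dims")
  quads <- list(sift_subband(matrix(rnorm(36), 6, 6)))
  feats <- group_bs_features(quads, dims)
  for (nm in c("HHP", "HHN", "HLP", "HLN"))
    expect_true(all(feats[[nm]] == 0))
  expect_lt(max(abs(feats$LHP + feats$LHN + feats$LLP + feats$LLN -
                      quads[[1]]$hp - quads[[1]]$hn - quads[[1]]$lp -
                      quads[[1]]$ln)), 1e-12)
})

test_that("identity factors reconstruct the original log-lightness", {
  set.seed(43)
  v <- matrix(rnorm(32 * 32), 32, 32)
  pyr <- bs_decompose(v)
  quads <- lapply(pyr$subbands, sift_subband)
  rec <- apply_factors_and_reconstruct(quads, pyr$residual,
                                       feature_factor_table(pyr$dims$K))
  expect_lt(max(abs(rec$values - v)), 1e-9)
})

test_that("scaling a BS group equals adding its grouped feature image", {
  set.seed(44)
  v <- matrix(rnorm(64 * 64, sd = 0.3), 64, 64)
  pyr <- bs_decompose(v)
  quads <- lapply(pyr$subbands, sift_subband)
  feats <- group_bs_features(quads, pyr$dims)   # independent grouping route
  base <- apply_factors_and_reconstruct(quads, pyr$residual,
                                        feature_factor_table(pyr$dims$K))

  tab0 <- feature_factor_table(pyr$dims$K)
  tab0[pyr$dims$high, "HP"] <- 0
  rec0 <- apply_factors_and_reconstruct(quads, pyr$residual, tab0)
  expect_lt(max(abs(rec0$values - (base$values - feats$HHP))), 1e-9)

  tab2 <- feature_factor_table(pyr$dims$K)
  tab2[pyr$dims$high, "HP"] <- 2
  rec2 <- apply_factors_and_reconstruct(quads, pyr$residual, tab2)
  expect_lt(max(abs(rec2$values - (base$values + feats$HHP))), 1e-9)
})

test_that("reconstruction responds linearly to any single-cell factor", {
  set.seed(45)
  v <- matrix(rnorm(32 * 32), 32, 32)
  pyr <- bs_decompose(v)
  quads <- lapply(pyr$subbands, sift_subband)
  base <- apply_factors_and_reconstruct(quads, pyr$residual,
                                        feature_factor_table(pyr$dims$K))
  for (cell in list(c(1, 1), c(2, 4), c(3, 2))) {
    i <- cell[1]; col <- colnames(unclass(feature_factor_table(1)))[cell[2]]
    unit <- local({
      tab <- feature_factor_table(pyr$dims$K)
      tab[i, col] <- 2
      apply_factors_and_reconstruct(quads, pyr$residual, tab)$values -
        base$values
    })
    for (f in c(-5, 0, 1, 2, 4)) {
      tab <- feature_factor_table(pyr$dims$K)
      tab[i, col] <- f
      rec <- apply_factors_and_reconstruct(quads, pyr$residual, tab)
      expect_lt(max(abs(rec$values - (base$values + (f - 1) * unit))), 1e-9)
    }
  }
  bad <- feature_factor_table(pyr$dims$K)
  bad[1, 1] <- Inf
  expect_error(apply_factors_and_reconstruct(quads, pyr$residual, bad),
               class = "bs_arg_error")
})
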