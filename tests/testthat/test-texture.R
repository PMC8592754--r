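# Wavelet decomposition, GLCM and Haralick texture statistics.

test_that("wavelet decomposition halves extents and kills constant detail", {
  const <- matrix(0.7, 16, 16)
  dec <- dwt_decompose(const, "haar")
  expect_equal(dim(dec$levels[[1]]$LL), c(8, 8))
  expect_lt(max(abs(dec$levels[[1]]$LH)), 1e-12)
  expect_lt(max(abs(dec$levels[[1]]$HL)), 1e-12)
  expect_lt(max(abs(dec$levels[[1]]$HH)), 1e-12)

  expect_error(dwt_decompose(matrix(0, 6, 6), levels = 2), "divisible")
})

test_that("orthogonal wavelets reconstruct exactly and conserve energy", {
  set.seed(21)
  for (wv in c("haar", "db2")) {
    x <- matrix(rnorm(64 * 64), 64, 64)
    dec <- dwt_decompose(x, wv, levels = 1)
    expect_lt(max(abs(dwt_reconstruct(dec) - x)), 1e-10)
    sb <- dec$levels[[1]]
    e_sub <- sum(sb$LL^2) + sum(sb$LH^2) + sum(sb$HL^2) + sum(sb$HH^2)
    expect_lt(abs(e_sub - sum(x^2)) / sum(x^2), 1e-8)

    dec3 <- dwt_decompose(x, wv, levels = 3)
    expect_lt(max(abs(dwt_reconstruct(dec3) - x)), 1e-10)
    expect_equal(dim(dec3$levels[[3]]$LL), c(8, 8))
  }
})

test_that("co-occurrence counting matches the brute-force pair census", {
  q2 <- matrix(3L, 2, 2)
  P <- glcm(q2, d = 1, angle = 0, levels = 8)
  expect_equal(P[4, 4], 1)   # the single populated pair class
  expect_equal(sum(P), 1)

  set.seed(22)
  for (rep in 1:25) {
    q <- matrix(sample(0:15, 64, replace = TRUE), 8, 8)
    for (ang in c(0, 45, 90, 135)) {
      expect_lt(max(abs(glcm(q, 1, ang, 16) - oracle_glcm(q, 1, ang, 16))),
                1e-12)
    }
    # symmetric mode adds the transpose
    Ps <- glcm(q, 1, 0, 16, symmetric = TRUE)
    expect_equal(Ps, t(Ps))
  }
  expect_error(glcm(q2, angle = 30), "angle")
})

test_that("Haralick statistics agree with explicit double sums", {
  G <- 16
  P1 <- matrix(0, G, G); P1[5, 5] <- 1
  f <- haralick_features(P1)
  expect_equal(as.numeric(f), c(1, 0, 1, 0, 0))  # H, CR, E, CN, ER

  Pu <- matrix(0, G, G); Pu[1:4, 1] <- 1 / 4     # uniform over 4 cells
  expect_equal(haralick_features(Pu)$ER, log2(4))

  set.seed(23)
  for (rep in 1:20) {
    M <- matrix(rexp(G * G), G, G); M <- M / sum(M)
    expect_lt(max(abs(as.numeric(haralick_features(M)) -
                        as.numeric(oracle_haralick(M)))), 1e-10)
  }
  expect_error(haralick_features(matrix(1, 4, 4)), "normalized")
})

test_that("verbatim entropy variant drops the frequency weight", {
  P <- matrix(0, 4, 4); P[1, 1] <- 0.5; P[2, 2] <- 0.5
  std <- haralick_features(P)
  vb <- haralick_features(P, verbatim_formulas = TRUE)
  expect_equal(std$ER, 1)          # -2 * 0.5 log2 0.5
  expect_equal(vb$ER, 2)           # -2 * log2 0.5
  expect_equal(std$CN, vb$CN)      # other statistics unchanged
})

test_that("region features are bounded, shift-invariant, texture-sensitive", {
  ph <- generate_phantom(phantom_spec(seed = 31))
  ft <- extract_features(ph$image, ph$truth_mask)
  expect_named(ft, c("subband", "H", "CR", "E", "CN", "ER"))
  expect_equal(ft$subband, c("LL", "HL"))
  expect_true(all(ft$H > 0 & ft$H <= 1))
  expect_true(all(ft$E > 0 & ft$E <= 1))
  expect_true(all(ft$CN >= 0))
  expect_true(all(ft$ER >= 0))

  # constant region: degenerate GLCM in every subband
  img <- matrix(0.6, 16, 16)
  msk <- matrix(0, 16, 16); msk[5:12, 5:12] <- 1
  fc <- extract_features(img, msk)
  expect_equal(as.numeric(as.matrix(fc[, -1])),
               as.numeric(rbind(c(1, 0, 1, 0, 0), c(1, 0, 1, 0, 0))))

  # adding a constant (pre-quantization) leaves the features unchanged
  set.seed(32)
  base <- matrix(runif(32 * 32, 0.2, 0.6), 32, 32)
  m <- matrix(0, 32, 32); m[8:25, 8:25] <- 1
  f0 <- extract_features(base, m)
  f1 <- extract_features(base + 0.2, m)
  expect_equal(f0[, c("H", "CR", "E", "CN")], f1[, c("H", "CR", "E", "CN")],
               tolerance = 1e-12)

  # rougher mass texture -> higher contrast
  smooth <- generate_phantom(phantom_spec(seed = 33, roughness = 3.5,
                                          texture_amp = 0.08))
  rough <- generate_phantom(phantom_spec(seed = 33, roughness = 1.0,
                                         texture_amp = 0.08))
  cn_s <- extract_features(smooth$image, smooth$truth_mask)
  cn_r <- extract_features(rough$image, rough$truth_mask)
  expect_gt(cn_r$CN[cn_r$subband == "HL"], cn_s$CN[cn_s$subband == "HL"])

  expect_error(extract_features(img, matrix(0, 16, 16)), "empty mask")
})
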