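test_that("compute_glcm reproduces the hand-counted 2x2 cases", {
  # two gray levels encoded as 0 and 128 -> bins 0 and 1 at levels = 2
  img1 <- rbind(c(0, 0), c(128, 128))
  g1 <- compute_glcm(img1, levels = 2, distance = 1, angle = 0)
  expect_equal(g1$P, rbind(c(0.5, 0), c(0, 0.5)))

  img2 <- rbind(c(0, 128), c(128, 0))
  g2 <- compute_glcm(img2, levels = 2, distance = 1, angle = 0)
  expect_equal(g2$P, rbind(c(0, 0.5), c(0.5, 0)))
})

test_that("GLCM is symmetric, normalized, and matches the pair-loop oracle", {
  withr::with_seed(2024, {
    for (rep in 1:20) {
      g <- matrix(sample(0:255, 64, TRUE), 8, 8)
      mask <- matrix(sample(c(TRUE, TRUE, TRUE, FALSE), 64, TRUE), 8, 8)
      ang <- sample(c(0, 45, 90, 135), 1)
      got <- compute_glcm(g, mask, levels = 4, distance = 1, angle = ang)
      expect_equal(sum(got$P), 1, tolerance = 1e-12)
      expect_equal(got$P, t(got$P), tolerance = 1e-15)
      expect_equal(got$P, oracle_glcm(g, mask, 4, 1, ang), tolerance = 1e-12)
    }
  })
})

test_that("glcm_features matches hand evaluation on the worked matrices", {
  f1 <- glcm_features(rbind(c(0.5, 0), c(0, 0.5)))
  expect_equal(f1$contrast, 0)
  expect_equal(f1$dissimilarity, 0)
  expect_equal(f1$homogeneity, 1)
  expect_equal(f1$ASM, 0.5)
  expect_equal(f1$energy, sqrt(0.5), tolerance = 1e-12)
  expect_equal(f1$correlation, 1)

  f2 <- glcm_features(rbind(c(0, 0.5), c(0.5, 0)))
  expect_equal(f2$contrast, 1)
  expect_equal(f2$dissimilarity, 1)
  expect_equal(f2$homogeneity, 0.5)
  expect_equal(f2$ASM, 0.5)
  expect_equal(f2$correlation, -1)

  # constant image: single occupied level, degenerate correlation := 1
  f3 <- glcm_features(matrix(1, 1, 1))
  expect_equal(f3$contrast, 0)
  expect_equal(f3$homogeneity, 1)
  expect_equal(f3$energy, 1)
  expect_equal(f3$ASM, 1)
  expect_equal(f3$correlation, 1)
})

test_that("glcm_features agrees with the double-loop oracle to 1e-12", {
  withr::with_seed(31, {
    for (rep in 1:20) {
      g <- matrix(sample(0:255, 64, TRUE), 8, 8)
      P <- compute_glcm(g, levels = 4, distance = 1, angle = 0)
      got <- glcm_features(P)
      want <- oracle_glcm_features(P$P)
      expect_equal(unlist(got), want[names(unlist(got))], tolerance = 1e-12)
    }
  })
})

test_that("angle-averaged GLCM features are invariant to 90-degree rotation", {
  withr::with_seed(5, {
    g <- matrix(sample(0:255, 16 * 16, TRUE), 16, 16)
  })
  rot90 <- t(g)[ncol(g):1, ]
  a <- fireice:::glcm_features_avg(g, levels = 8)
  b <- fireice:::glcm_features_avg(rot90, levels = 8)
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("laws_kernels have the required sums and transpose structure", {
  ks <- laws_kernels()
  expect_identical(names(ks), c(
    "L5L5", "L5E5", "L5S5", "L5R5", "E5L5", "E5E5", "E5S5", "E5R5",
    "S5L5", "S5E5", "S5S5", "S5R5", "R5L5", "R5E5", "R5S5", "R5R5"
  ))
  expect_equal(sum(ks$L5L5), 256)
  zero_sum <- setdiff(names(ks), "L5L5")
  for (nm in zero_sum) expect_equal(sum(ks[[nm]]), 0)
  expect_identical(ks$L5E5, t(ks$E5L5))
  expect_identical(ks$S5R5, t(ks$R5S5))
})

test_that("separable Law's convolution equals the direct 2-D oracle", {
  withr::with_seed(8, {
    m <- matrix(rnorm(24 * 20), 24, 20)
  })
  ks <- laws_kernels()
  for (nm in c("L5L5", "E5S5", "R5R5", "S5E5")) {
    v <- strsplit(nm, "5")[[1]]
    taps <- fireice:::laws_vectors()
    got <- fireice:::conv_sep(m, taps[[paste0(v[1], "5")]], taps[[paste0(v[2], "5")]])
    expect_equal(got, oracle_conv2d(m, ks[[nm]]), tolerance = 1e-9)
  }
})

test_that("constant images give all-zero Law's features and DC offsets do not matter", {
  const <- matrix(55, 48, 48)
  mask <- matrix(TRUE, 48, 48)
  f <- laws_features(const, mask)
  expect_true(all(abs(unlist(f)) < 1e-9))
  expect_equal(ncol(f), 16)

  withr::with_seed(12, {
    g <- matrix(runif(48 * 48, 40, 200), 48, 48)
  })
  f1 <- laws_features(g, mask)
  f2 <- laws_features(g + 17.5, mask)
  expect_equal(f1, f2, tolerance = 1e-9)
})

test_that("an edge excites the kernel that differentiates across it", {
  # intensity step between the top and bottom halves: variation along
  # rows, so E5-along-rows (E5L5) must out-respond L5E5
  g <- matrix(50, 32, 32)
  g[17:32, ] <- 200
  mask <- matrix(TRUE, 32, 32)
  f <- laws_features(g, mask)
  expect_gt(f$e_E5L5, f$e_L5E5)
  # and the transposed image flips the relation
  ft <- laws_features(t(g), mask)
  expect_gt(ft$e_L5E5, ft$e_E5L5)
})

test_that("texture_features returns the 22 categories in paper order", {
  e <- draw_ellipse_image(48, 48)
  withr::with_seed(3, {
    g <- e$gray + matrix(rnorm(48 * 48, 0, 10), 48, 48)
  })
  g <- pmin(pmax(g, 0), 255)
  tf <- texture_features(g, e$mask)
  expect_identical(
    setdiff(names(tf), c("sample_id", "label")),
    fireice:::texture_feature_names()
  )
  expect_true(all(unlist(tf[paste0("e_", names(laws_kernels()))]) >= 0))
  expect_true(tf$homogeneity >= 0 && tf$homogeneity <= 1)
  # ASM = energy^2 holds per angle (averaging over angles then breaks
  # the exact identity, so check it on a single-angle matrix)
  P1 <- compute_glcm(g, e$mask, levels = 32, distance = 1, angle = 45)
  f1 <- glcm_features(P1)
  expect_equal(f1$ASM, f1$energy^2, tolerance = 1e-12)
})

test_that("degenerate masks raise errors", {
  g <- matrix(1:16 * 10, 4, 4)
  expect_error(compute_glcm(g, mask = matrix(FALSE, 4, 4)), "mask")
  expect_error(laws_features(g, matrix(TRUE, 4, 4)), "too small")
})
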