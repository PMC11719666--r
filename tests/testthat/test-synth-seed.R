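test_that("default class parameters satisfy their invariants", {
  p <- synth_class_params()
  expect_equal(nrow(p), 3)
  expect_true(all(p$L >= 0 & p$L <= 100))
  expect_true(all(p$noise_amplitude >= 0))
  expect_true(all(p$speckle_density >= 0 & p$speckle_density < 1))
  expect_true(all(p$r_major_max * 2 < 256 - 20))
  # the brightness ordering is built into the base colours
  expect_identical(p$name[order(-p$L)], c("synthHAS", "synthZSS", "synthZMS"))
  # redness and yellowness peak in the ZMS analog
  expect_identical(p$name[which.max(p$a)], "synthZMS")
  expect_identical(p$name[which.max(p$b)], "synthZMS")
})

test_that("base colours survive the Lab -> RGB -> Lab round trip", {
  p <- synth_class_params()
  rgb <- lab_to_rgb(p$L, p$a, p$b)
  px <- array(0, dim = c(3, 1, 3))
  px[, 1, ] <- rgb
  lab <- rgb_to_lab(px)
  expect_true(all(abs(lab[, 1, 1] - p$L) < 0.5))
})

test_that("image generation is deterministic per seed", {
  p <- synth_class_params()[1, ]
  a <- generate_seed_image(p, seed = 123)
  b <- generate_seed_image(p, seed = 123)
  expect_identical(a$pixels, b$pixels)
  expect_identical(a$mask, b$mask)
  c <- generate_seed_image(p, seed = 124)
  expect_false(identical(a$pixels, c$pixels))
})

test_that("with no noise and no speckle, foreground variation is shading only", {
  p <- synth_class_params()[1, ]
  p$noise_amplitude <- 0
  p$speckle_density <- 0
  img <- generate_seed_image(p, seed = 5)
  gray <- to_gray(img)
  expect_lt(stats::sd(gray[img$mask]), 6)
})

test_that("ground-truth mask area is inside the range the radii imply", {
  p <- synth_class_params()[2, ]
  for (s in 1:5) {
    img <- generate_seed_image(p, seed = s)
    area <- attr(img, "true_area")
    expect_gte(area, pi * p$r_major_min * p$r_minor_min * 0.95)
    expect_lte(area, pi * p$r_major_max * p$r_minor_max * 1.05)
    expect_equal(area, sum(img$mask))
  }
})

test_that("oversized radii are rejected", {
  p <- synth_class_params()[1, ]
  p$r_major_max <- 200
  expect_error(generate_seed_image(p, canvas = c(256, 256), seed = 1), "too large")
})

test_that("generate_dataset builds the manifest and honours class counts", {
  ds <- tiny_dataset() # n = 3 per class, seed 42
  expect_equal(length(ds$images), 9)
  expect_equal(nrow(ds$manifest), 9)
  expect_equal(unname(table(ds$manifest$label)), rep(3L, 3), ignore_attr = TRUE)
  expect_identical(
    ds$manifest$true_area,
    purrr::map_dbl(ds$images, function(x) attr(x, "true_area"))
  )
  # unequal class sizes
  ds2 <- generate_dataset(c(2, 1, 1), seed = 1, canvas = c(256, 256))
  expect_equal(unname(table(ds2$manifest$label)["synthHAS"]), 2L, ignore_attr = TRUE)
})

test_that("written datasets round-trip through PNG within quantization error", {
  dir <- withr::local_tempdir()
  ds <- generate_dataset(1, seed = 7, dir = dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  expect_true(all(file.exists(ds$manifest$path)))
  back <- read_seed_image(ds$manifest$path[1])
  expect_lt(max(abs(back$pixels - ds$images[[1]]$pixels)), 0.51)
  # masks saved alongside
  mask_path <- file.path(dir, paste0(ds$manifest$sample_id[1], "_mask.png"))
  expect_true(file.exists(mask_path))
  m <- png::readPNG(mask_path)
  expect_equal(m > 0.5, ds$images[[1]]$mask, ignore_attr = TRUE)
})

test_that("segmentation on synthetic images matches the ground truth closely", {
  ds <- tiny_dataset()
  for (img in ds$images[c(1, 4, 7)]) { # one per class
    fg <- extract_foreground(img)
    area_ratio <- sum(fg) / sum(img$mask)
    expect_gt(area_ratio, 0.9)
    expect_lt(area_ratio, 1.1)
    cf_truth <- color_features(img, img$mask)
    cf_auto <- color_features(img, fg)
    expect_lt(abs(cf_truth$mean_Lstar - cf_auto$mean_Lstar), 2)
  }
})

test_that("class feature orderings match the intended qualitative structure", {
  # small per-class sample; the full study conditions are exercised in
  # the acceptance suite
  ds <- tiny_dataset()
  feats <- extract_features(ds, mask_source = "truth")
  agg <- dplyr::summarise(
    dplyr::group_by(feats, label),
    dplyr::across(dplyr::where(is.numeric), mean)
  )
  g <- function(cls, col) agg[[col]][agg$label == cls]
  # brightness ordering
  expect_gt(g("synthHAS", "mean_Lstar"), g("synthZSS", "mean_Lstar"))
  expect_gt(g("synthZSS", "mean_Lstar"), g("synthZMS", "mean_Lstar"))
  # chroma peaks in the ZMS analog
  expect_equal(agg$label[which.max(agg$mean_astar)], "synthZMS")
  expect_equal(agg$label[which.max(agg$mean_bstar)], "synthZMS")
  # GLCM structure: ZSS most contrasted, HAS smoothest
  expect_equal(agg$label[which.max(agg$contrast)], "synthZSS")
  expect_equal(agg$label[which.max(agg$homogeneity)], "synthHAS")
  expect_equal(agg$label[which.max(agg$energy)], "synthHAS")
  # Law's energies: the smooth HAS analog is lowest on all 16 kernels,
  # and the strongly textured ZMS analog leads on the luminance-edge
  # kernels (the high-frequency kernels are dominated by ZSS's speckle)
  laws_cols <- grep("^e_", names(agg), value = TRUE)
  for (cl in laws_cols) {
    expect_equal(agg$label[which.min(agg[[cl]])], "synthHAS")
  }
  for (cl in c("e_L5L5", "e_L5E5", "e_E5L5")) {
    expect_equal(agg$label[which.max(agg[[cl]])], "synthZMS")
  }
})
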