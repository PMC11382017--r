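test_that("vdvi matches hand-computed values and conventions", {
  expect_equal(vdvi(c(100, 100, 100)), 0)
  expect_equal(vdvi(c(0, 255, 0)), 1)
  expect_equal(vdvi(c(50, 100, 30)), 120 / 280)
  expect_equal(vdvi(c(0, 0, 0)), 0) # denominator-zero convention
})

test_that("vdvi stays in [-1, 1] over the 8-bit lattice", {
  set.seed(1)
  px <- matrix(sample(0:255, 3000, replace = TRUE), ncol = 3)
  v <- apply(px, 1, vdvi)
  expect_true(all(v >= -1 & v <= 1))
})

test_that("vegetation_mask applies threshold, green floor, and exclusion", {
  img <- array(0L, c(2, 2, 3))
  img[1, 1, ] <- c(0, 9, 0)    # VDVI = 1 but G < 10: dark-pixel removal
  img[1, 2, ] <- c(0, 200, 0)  # clear vegetation
  img[2, 1, ] <- c(120, 100, 80) # soil-ish
  vm <- vegetation_mask(img)
  expect_false(vm$mask[1, 1])
  expect_true(vm$mask[1, 2])
  expect_false(vm$mask[2, 1])
  expect_equal(vm$count, 1)

  # all-soil scene: empty mask, exclusion flag
  cfg <- field_config(image_height = 32, image_width = 32)
  soil <- render_plot_scene(c(DW = 0, SL = 0, NN = 0, NB = 0, PH = 0), cfg, 1)
  vs <- vegetation_mask(soil$rgb)
  expect_true(vs$excluded)
  expect_equal(vs$count, 0)

  # vacuous threshold covers every pixel with positive intensity
  vv <- vegetation_mask(img, threshold = -1, min_green = 0)
  expect_equal(vv$mask, img[, , 1] + img[, , 2] + img[, , 3] > 0,
               ignore_attr = TRUE)
})

make_blob_pair <- function(H = 40, W = 40, cy = 20, cx = 20, r = 6) {
  yy <- matrix(seq_len(H), H, W); xx <- matrix(seq_len(W), H, W, byrow = TRUE)
  mask <- (yy - cy)^2 + (xx - cx)^2 <= r^2
  rgb <- array(0L, c(H, W, 3))
  rgb[, , 1][mask] <- 50L; rgb[, , 2][mask] <- 150L; rgb[, , 3][mask] <- 40L
  dsm <- matrix(0.1, H, W); dsm[mask] <- 0.6
  structure(list(rgb = rgb, dsm = dsm, mask = mask, plot_id = "blob"),
            class = "plot_image_pair")
}

test_that("geometry standardization is translation invariant", {
  p1 <- make_blob_pair(cy = 20, cx = 20)
  p2 <- make_blob_pair(cy = 12, cx = 27)
  s1 <- standardize_geometry(p1, 40, 40)
  s2 <- standardize_geometry(p2, 40, 40)
  expect_identical(s1$mask, s2$mask)
  expect_identical(s1$rgb, s2$rgb)
  expect_equal(s1$dsm, s2$dsm)
})

test_that("a centered symmetric blob is a fixed point up to padding", {
  p <- make_blob_pair(H = 40, W = 40, cy = 20, cx = 20)
  s <- standardize_geometry(p, 48, 48)
  inner <- s$mask[5:44, 5:44]
  # centroid at 20.5,20.5 maps to 24.5,24.5: integer shift, mask preserved
  expect_identical(sum(s$mask), sum(p$mask))
  expect_identical(inner, p$mask)
})

test_that("rigid alignment preserves mask pixel count within 1%", {
  field <- small_field()
  for (img in field$images[c(2, 9, 23)]) {
    img$mask <- vegetation_mask(img$rgb)$mask
    before <- sum(img$mask)
    after <- sum(standardize_geometry(img, 48, 48)$mask)
    expect_lte(abs(after - before) / before, 0.01)
  }
})

test_that("DSM is referenced to local ground and off-mask values zeroed", {
  p <- make_blob_pair()
  s <- standardize_geometry(p, 40, 40)
  expect_equal(max(s$dsm), 0.5, tolerance = 1e-12) # 0.6 canopy - 0.1 soil
  expect_true(all(s$dsm[!s$mask] == 0))
  expect_true(all(s$rgb[, , 1][!s$mask] == 0))
})

test_that("standardize_geometry rejects empty masks and warns on overflow", {
  p <- make_blob_pair()
  p$mask[] <- FALSE
  expect_error(standardize_geometry(p, 40, 40), "empty")
  big <- make_blob_pair(H = 60, W = 60, cy = 30, cx = 30, r = 20)
  expect_warning(standardize_geometry(big, 32, 32), "crop")
})

test_that("augmentation quadruples, is involutive, and keeps labels", {
  field <- small_field()
  pairs <- field$images[1:10]
  pairs <- lapply(pairs, function(p) { p$traits <- c(DW = 1); p })
  aug <- augment(pairs)
  expect_length(aug, 40)
  expect_true(all(vapply(aug, function(p) identical(p$traits, c(DW = 1)),
                         TRUE)))
  # flipping twice restores the original
  twice <- lspheno:::flip_pair(lspheno:::flip_pair(pairs[[1]], TRUE, FALSE),
                               TRUE, FALSE)
  expect_identical(twice$rgb, pairs[[1]]$rgb)
  expect_identical(twice$dsm, pairs[[1]]$dsm)
})

test_that("masking commutes with flipping", {
  img <- small_field()$images[[5]]
  flipped <- lspheno:::flip_pair(img, TRUE, TRUE)
  m_then_f <- vegetation_mask(img$rgb)$mask
  m_then_f <- m_then_f[rev(seq_len(nrow(m_then_f))),
                       rev(seq_len(ncol(m_then_f)))]
  f_then_m <- vegetation_mask(flipped$rgb)$mask
  expect_identical(m_then_f, f_then_m)
})

test_that("trait normalization hits mean 0 / variance 1 and round-trips", {
  set.seed(4)
  raw <- matrix(rnorm(50 * 5, mean = 30, sd = 7), 50, 5,
                dimnames = list(NULL, TRAITS))
  tt <- normalize_traits(raw)
  expect_true(all(abs(colMeans(tt$normalized)) < 1e-10))
  expect_true(all(abs(apply(tt$normalized, 2, var) - 1) < 1e-10))
  expect_true(max(abs(denormalize_traits(tt) - raw)) < 1e-10)

  # statistics fitted on a subset, applied everywhere
  tt2 <- normalize_traits(raw, fit_rows = 1:20)
  expect_true(all(abs(colMeans(tt2$normalized[1:20, ])) < 1e-10))
  expect_equal(tt2$norm_mean, colMeans(raw[1:20, ]))

  raw[, 3] <- 5
  expect_error(normalize_traits(raw), "NN")
})
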