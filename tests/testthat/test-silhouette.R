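test_that("binarize recovers a disc and drops speckle noise", {
  img <- matrix(0, 101, 101)
  img[disc_mask(101, 30)] <- 1
  s <- binarize(img)
  expect_s3_class(s, "silhouette")
  expect_equal(count_components(s$mask), 1)
  expect_equal(sum(s$mask), sum(disc_mask(101, 30)))

  # salt speckles are minor components and must be dropped (kept clear of
  # the disc so they cannot merge with it under 8-connectivity)
  set.seed(5)
  noisy <- img
  clear <- !disc_mask(101, 33)
  noisy[sample(which(img == 0 & clear), 50)] <- 1
  s2 <- binarize(noisy)
  expect_equal(count_components(s2$mask), 1)
  expect_equal(sum(s2$mask), sum(s$mask))
})

test_that("binarize picks polarity automatically and fills holes", {
  img <- matrix(1, 101, 101)            # dark object on light ground
  d <- disc_mask(101, 30)
  img[d] <- 0.1
  ring <- d & !disc_mask(101, 12)       # object with an interior hole
  img2 <- matrix(0, 101, 101); img2[ring] <- 1
  s1 <- binarize(img)
  s2 <- binarize(img2)
  expect_equal(sum(s1$mask), sum(d))
  expect_equal(sum(s2$mask), sum(d))    # hole filled
})

test_that("degenerate images are rejected", {
  expect_error(binarize(matrix(0, 50, 50)), "segmentation failed")
  expect_error(binarize(matrix(1, 50, 50)), "segmentation failed")
})

test_that("rasterize fills squares and circles to within analytic area", {
  sq <- structure(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1), c(0, 0)),
                  class = "boundary_polygon")
  s <- rasterize(sq, 100, pad = 0)
  expect_equal(sum(s$mask), 100 * 100)

  circ <- build_polygon(curve_model("c", "ellipse", list(b = 1)), 4096)
  s2 <- rasterize(circ, 512)
  r_px <- 512 / 2
  expect_equal(sum(s2$mask), pi * r_px^2, tolerance = 0.01)
})

test_that("rasterized mirror-symmetric polygons are symmetric up to one pixel", {
  s <- rasterize(build_polygon(get_model("ACO1"), 2048), 256)
  m <- s$mask
  flipped <- m[, rev(seq_len(ncol(m)))]
  disagree <- sum(xor(m, flipped))
  boundary <- sum(m & !(m[c(1, seq_len(nrow(m) - 1)), ] &
                        m[c(2:nrow(m), nrow(m)), ] &
                        m[, c(1, seq_len(ncol(m) - 1))] &
                        m[, c(2:ncol(m), ncol(m))]))
  expect_lte(disagree, 2 * boundary)
})

test_that("orientation normalization recovers a rotated render", {
  s <- rasterize(build_polygon(get_model("VAM1"), 1024), 256)
  rot <- silhouette(seedgeom:::mask_trim_pad(
    seedgeom:::rotate_mask(s$mask, 37 * pi / 180)))
  expect_gte(best_superposition(rot, "VAM1")$J, 99)
})

test_that("orientation normalization is idempotent and flags isotropy", {
  s <- normalize_orientation(
    rasterize(build_polygon(get_model("AAR1"), 1024), 192))
  s2 <- normalize_orientation(s)
  expect_identical(s$mask, s2$mask)
  expect_true(s2$oriented)

  circ <- rasterize(build_polygon(curve_model("c", "ellipse", list(b = 1)),
                                  1024), 128)
  c2 <- normalize_orientation(circ)
  expect_true(c2$isotropic)
  expect_identical(c2$mask, circ$mask)
})

test_that("the narrow pole ends up on top", {
  # render AAR1 (strong beak), flip it upside down, and normalize
  s <- normalize_orientation(
    rasterize(build_polygon(get_model("AAR1"), 1024), 192))
  upside <- silhouette(s$mask[rev(seq_len(nrow(s$mask))), ])
  fixed <- normalize_orientation(upside)
  expect_gte(j_index(fixed, s), 99)
})

test_that("PNG round trip through binarize reproduces every registered render", {
  dir <- withr::local_tempdir()
  for (nm in model_names()) {
    s <- rasterize(build_polygon(get_model(nm), 1024), 192)
    f <- file.path(dir, paste0(nm, ".png"))
    write_mask(s, f)
    s2 <- binarize(f)
    agree <- j_index(s2, s)
    expect_gte(agree, 99.5)
  }
})

test_that("silhouette validation reports structural defects", {
  m <- matrix(FALSE, 20, 20); m[5:10, 5:10] <- TRUE; m[15, 15] <- TRUE
  expect_error(silhouette(m, validate = TRUE), "components")
  chk <- seedgeom:::silhouette_check(m)
  expect_false(chk$ok)
  expect_equal(chk$n_components, 2)
})
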