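test_that("the J index is 100 on identity, 0 on disjoint, exact on offset squares", {
  A <- matrix(FALSE, 120, 220); A[11:110, 11:110] <- TRUE
  expect_equal(j_index(A, A), 100)
  B <- matrix(FALSE, 120, 220); B[11:110, 111:210] <- TRUE
  expect_equal(j_index(A, B), 0)
  # 100x100 squares offset by 50 px: overlap 50*100, union 150*100
  C <- matrix(FALSE, 120, 220); C[11:110, 61:160] <- TRUE
  expect_equal(j_index(A, C), 100 / 3)
  expect_equal(j_index(C, A), j_index(A, C)) # symmetry
})

test_that("the J index is invariant to translating both masks together", {
  s <- rasterize(build_polygon(get_model("PPE1"), 512), 96)$mask
  pad <- function(m, top, left) {
    out <- matrix(FALSE, nrow(m) + top, ncol(m) + left)
    out[top + seq_len(nrow(m)), left + seq_len(ncol(m))] <- m
    out
  }
  ref <- rasterize(build_polygon(get_model("VAM1"), 512), 96)$mask
  j0 <- j_index(s, ref)
  expect_equal(j_index(pad(s, 7, 13), pad(ref, 7, 13)), j0)
})

test_that("j_index rejects empty input", {
  expect_error(j_index(matrix(FALSE, 4, 4), matrix(FALSE, 4, 4)), "empty")
})

test_that("superposition recovers a known scale and shift of the same shape", {
  poly <- build_polygon(get_model("VAM1"), 1024)
  s <- rasterize(poly, 180)
  big <- rasterize(poly, 252)           # x1.4 scale
  grown <- matrix(FALSE, nrow(big$mask) + 40, ncol(big$mask) + 60)
  grown[17 + seq_len(nrow(big$mask)), 31 + seq_len(ncol(big$mask))] <-
    big$mask                            # arbitrary shift
  js <- best_superposition(silhouette(grown), "VAM1")
  expect_gte(js$J, 99.5)
})

test_that("self-superposition reaches J >= 99 at resolution 512 and never drops below init", {
  for (nm in model_names()) {
    s <- rasterize(build_polygon(get_model(nm), 2048), 512)
    js <- best_superposition(s, nm)
    expect_gte(js$J, 99)
    expect_gte(js$J, js$J_init) # monotone improvement contract
    expect_lte(js$J, 100)
  }
})

test_that("superposition J is stable in resolution and pre-scaling", {
  for (nm in c("VAM1", "ACO1", "SE1")) {
    poly <- build_polygon(get_model(nm), 1024)
    j256 <- best_superposition(rasterize(poly, 256), nm)$J
    j512 <- best_superposition(rasterize(poly, 512), nm)$J
    expect_lt(abs(j512 - j256), 1)
    for (f in c(0.7, 1.4)) {
      jf <- best_superposition(rasterize(poly, round(256 * f)), nm)$J
      expect_lt(abs(jf - j256), 0.5)
    }
  }
})

test_that("a different model scores strictly below the self match", {
  s <- rasterize(build_polygon(get_model("VAM1"), 1024), 256)
  expect_lt(best_superposition(s, "AAR1")$J, best_superposition(s, "VAM1")$J)
})

test_that("noise-free renders classify to their own group", {
  for (nm in c("VAM1", "PPE1", "LENS1")) {
    s <- rasterize(build_polygon(get_model(nm), 1024), 192)
    ga <- classify_seed(s)
    expect_equal(ga$best$model, nm)
    expect_equal(ga$group, get_model(nm)$group)
    expect_gte(ga$best$J, 99)
  }
  # a non-registry superellipse still lands in the superellipse group
  se <- curve_model("se4", "superellipse", list(a = 1, b = 1, p = 4, q = 4))
  ga <- classify_seed(rasterize(build_polygon(se, 1024), 192))
  expect_equal(ga$group, "II")
})

test_that("unmatchable masks fall back to UNDEFINED at the default threshold", {
  set.seed(9)
  salt <- matrix(stats::runif(150 * 150) < 0.05, 150, 150)
  ga <- classify_seed(silhouette(salt), tau = 80)
  expect_equal(ga$group, "UNDEFINED")
  expect_lt(ga$best$J, 80)
  # threshold is user-configurable
  ga2 <- classify_seed(silhouette(salt), tau = 0)
  expect_false(ga2$group == "UNDEFINED")
})

test_that("classification output is tidy and ranked", {
  s <- rasterize(build_polygon(get_model("AAR1"), 512), 128)
  ga <- classify_seed(s)
  rk <- tidy(ga)
  expect_s3_class(rk, "tbl_df")
  expect_equal(nrow(rk), length(model_names()))
  expect_true(all(diff(rk$J) <= 0))
  gl <- glance(ga)
  expect_equal(gl$group, "III")
  js <- tidy(best_superposition(s, "AAR1"))
  expect_named(js, c("model", "J", "J_init", "scale", "scale_rel",
                     "tx", "ty", "theta"))
  expect_true(js$scale_rel >= 0.5 && js$scale_rel <= 2)
  expect_error(classify_seed(s, models = character(0)), "no models")
})
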