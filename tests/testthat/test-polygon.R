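test_that("polygon area converges to closed forms", {
  circ <- build_polygon(curve_model("c", "ellipse", list(b = 1)), 3600)
  expect_equal(polygon_area(circ), pi, tolerance = 1e-3 / pi)

  # |x|^4 + |y|^4 = 1 has area 4 Gamma(5/4)^2 / Gamma(3/2)
  se <- curve_model("se", "superellipse", list(a = 1, b = 1, p = 4, q = 4))
  a <- polygon_area(build_polygon(se, 10000))
  expect_equal(a, 4 * gamma(5 / 4)^2 / gamma(3 / 2), tolerance = 1e-4)
})

test_that("shoelace area is exact on a unit square and flips sign on reversal", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1), c(0, 0))
  expect_equal(polygon_area(sq), 1)
  expect_equal(polygon_area(sq[5:1, ]), -1)
  expect_error(polygon_area(rbind(c(0, 0), c(1, 1), c(0, 0))), "3 distinct")
})

test_that("every registered model renders a closed, simple, CCW polygon", {
  for (m in lapply(model_names(parameterized_only = FALSE), get_model)) {
    poly <- build_polygon(m, 1024)
    expect_identical(poly[1, ], poly[nrow(poly), ])
    expect_gt(polygon_area(poly), 0) # positive area, CCW
    # brute-force O(n^2) simplicity oracle at reduced sampling
    expect_true(is_simple_polygon(unclass(build_polygon(m, 96))),
                info = m$name)
  }
})

test_that("registered model boundaries are mirror-symmetric about x = 0", {
  for (m in lapply(model_names(parameterized_only = FALSE), get_model)) {
    if (m$family == "superellipse") {
      poly <- build_polygon(m, 512)
      v <- unclass(poly)
      mirrored <- cbind(-v[, 1], v[, 2])
      # every mirrored vertex is a vertex of the original (sampling is
      # symmetric in t); tolerance reflects the fractional power |cos t|^(2/p)
      # amplifying float noise near the poles
      d <- vapply(seq_len(nrow(v)), function(i)
        min(sqrt(colSums((t(v) - mirrored[i, ])^2))), 0)
      expect_lt(max(d), 1e-7)
    } else {
      x <- seq(0, 0.99, by = 0.07)
      l <- evaluate_branches(m, x); r <- evaluate_branches(m, -x)
      expect_lt(max(abs(l$y_lower - r$y_lower),
                    abs(l$y_upper - r$y_upper)), 1e-9)
    }
  }
})

test_that("polygon area is stable under refinement", {
  for (m in lapply(model_names(parameterized_only = FALSE), get_model)) {
    a1 <- abs(polygon_area(build_polygon(m, 512)))
    a2 <- abs(polygon_area(build_polygon(m, 1024)))
    expect_lt(abs(a2 - a1) / a2, 0.005)
  }
})

test_that("the superellipse area approaches pi a b as p = q -> 2", {
  m <- curve_model("s", "superellipse",
                   list(a = 1.2, b = 0.7, p = 2.001, q = 2.001))
  a <- abs(polygon_area(build_polygon(m, 8192)))
  expect_equal(a, pi * 1.2 * 0.7, tolerance = 1e-3)
})

test_that("shape descriptors: circle is featureless, beak grows with its amplitude", {
  circ <- curve_model("c", "ellipse", list(b = 1))
  d <- shape_descriptors(circ)
  expect_equal(d$aspect_ratio, 1, tolerance = 1e-4)
  expect_equal(d$beak_height, 0)
  expect_equal(d$entry_depth, 0)

  beaks <- vapply(c(0.3, 0.6, 1, 3), function(a)
    shape_descriptors(curve_model("w", "waterdrop",
                                  list(a = a, b = 1, c = 2)))$beak_height, 0)
  expect_true(all(diff(beaks) > 0))

  # mirroring the geometry cannot change the descriptors
  aco <- shape_descriptors(get_model("ACO1"))
  expect_gt(aco$entry_depth, 0)
  expect_gt(aco$beak_height, 0)
})

test_that("degenerate models are rejected", {
  # lower branch above upper everywhere: impossible for valid params, force
  # via a heart with huge entry kernel pushing lo above up at x = 0 only is
  # still non-empty; instead check the rasterizer rejects a flat polygon
  flat <- structure(cbind(c(0, 1, 2, 0), c(0, 0, 0, 0)),
                    class = "boundary_polygon")
  expect_error(rasterize(flat, 64), "degenerate")
})

test_that("WKT and SVG exports carry the vertex ring", {
  poly <- build_polygon(get_model("VAM1"), 64)
  wkt <- polygon_wkt(poly)
  expect_match(wkt, "^POLYGON \\(\\(")
  expect_equal(lengths(regmatches(wkt, gregexpr(",", wkt))),
               nrow(poly) - 1)
  svg <- polygon_svg_path(poly)
  expect_match(svg, "^M ")
  expect_match(svg, " Z$")
})
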