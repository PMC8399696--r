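#' Discretize a curve model into a closed boundary polygon
#'
#' Factor-product families are sampled along both explicit branches. The
#' branches either cross at some `x* <= 1` (located by bisection on the
#' branch gap, tolerance 1e-10) or remain separated up to `x = 1`, in which
#' case the polygon is closed by short vertical edges at `x = +/-1`.
#' Superellipse-family boundaries are sampled with the explicit
#' parameterization `x = a sgn(cos t)|cos t|^(2/p)`,
#' `y = b sgn(sin t)|sin t|^(2/q)`.
#'
#' Vertices are ordered counter-clockwise and the first vertex is repeated
#' as the last. Abscissae are cosine-spaced so sampling densifies near the
#' poles where curvature is highest.
#'
#' @param model A `curve_model`.
#' @param n_samples Approximate number of vertices (>= 8; default 1024).
#' @return A `boundary_polygon`: a two-column matrix (`x`, `y`) in model
#'   units with attribute `model_name`.
#' @export
#' @examples
#' poly <- build_polygon(curve_model("e", "ellipse", list(b = 1)), 256)
#' polygon_area(poly) # ~ pi
build_polygon <- function(model, n_samples = 1024) {
  stopifnot(inherits(model, "curve_model"), n_samples >= 8)
  if (model$family == "superellipse") {
    p <- model$params
    t <- seq(0, 2 * pi, length.out = n_samples + 1)[-(n_samples + 1)]
    v <- cbind(x = p$a * sign(cos(t)) * abs(cos(t))^(2 / p$p),
               y = p$b * sign(sin(t)) * abs(sin(t))^(2 / p$q))
  } else {
    fn <- branch_functions(model)
    gap <- function(x) fn$up(x) - fn$lo(x)
    if (gap(0) <= 0)
      stop("model '", model$name, "' encloses no region (empty at x = 0)",
           call. = FALSE)
    xs <- crossing_abscissa(gap)
    m <- max(4L, floor(n_samples / 2))
    t <- seq(0, pi, length.out = m)
    xup <- xs * cos(t)              # +xs -> -xs along the upper branch
    xlo <- -xs * cos(t)             # -xs -> +xs along the lower branch
    v <- rbind(cbind(x = xup, y = fn$up(xup)),
               cbind(x = xlo, y = fn$lo(xlo)))
    # drop consecutive duplicates where the branches meet at +/-xs
    keep <- c(TRUE, rowSums(abs(diff(v))) > 1e-12)
    v <- v[keep, , drop = FALSE]
  }
  if (signed_area(rbind(v, v[1, ])) < 0) v <- v[rev(seq_len(nrow(v))), ]
  v <- rbind(v, v[1, ])
  if (abs(signed_area(v)) <= 0)
    stop("model '", model$name, "' produced a degenerate polygon",
         call. = FALSE)
  structure(v, class = "boundary_polygon", model_name = model$name)
}

# largest x in (0, 1] with a positive branch gap; 1 when the gap stays
# positive on the whole domain. Returns the gap-positive bisection endpoint
# so the two sampled branches never micro-cross at the joint.
crossing_abscissa <- function(gap, tol = 1e-10) {
  if (gap(1) >= 0) return(1)
  lo <- 0; hi <- 1
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (gap(mid) > 0) lo <- mid else hi <- mid
  }
  lo
}

signed_area <- function(v) {
  n <- nrow(v)
  x <- v[, 1]; y <- v[, 2]
  sum(x[-n] * y[-1] - x[-1] * y[-n]) / 2
}

#' Signed area of a closed polygon (shoelace formula)
#'
#' Positive for counter-clockwise vertex order, negative for clockwise.
#'
#' @param poly A `boundary_polygon` or a two-column vertex matrix whose
#'   first vertex is repeated as the last.
#' @return Signed area in model units squared.
#' @export
polygon_area <- function(poly) {
  v <- unclass(poly)
  stopifnot(is.matrix(v), ncol(v) == 2)
  if (nrow(unique(v)) < 3)
    stop("polygon needs at least 3 distinct vertices", call. = FALSE)
  if (any(v[1, ] != v[nrow(v), ])) v <- rbind(v, v[1, ])
  signed_area(v)
}

#' Gross shape descriptors of a curve model
#'
#' Operational summaries of the rendered outline:
#' * `aspect_ratio` — bounding-box height / width;
#' * `beak_height` — central protrusion of the upper branch beyond its
#'   shoulders, measured relative to the kernel-free semi-ellipse so a pure
#'   ellipse scores exactly 0:
#'   `(y_upper(0) - max(y_upper : |x| >= 0.3)) - (e(0) - max(e : |x| >=
#'   0.3))` with `e` the branch's semi-ellipse component, clipped at 0;
#' * `entry_depth` — depth of the basal notch:
#'   `y_lower(0) - min(y_lower)`, clipped at 0.
#'
#' Superellipse-family models have no beak or entry (both 0).
#'
#' @param model A `curve_model`.
#' @param n Number of abscissae used to probe the branches.
#' @return A one-row tibble with `model`, `aspect_ratio`, `beak_height`,
#'   `entry_depth`.
#' @export
shape_descriptors <- function(model, n = 2001) {
  stopifnot(inherits(model, "curve_model"))
  poly <- build_polygon(model, 1024)
  aspect <- diff(range(poly[, 2])) / diff(range(poly[, 1]))
  if (model$family == "superellipse") {
    beak <- 0; entry <- 0
  } else {
    fn <- branch_functions(model)
    x <- seq(-1, 1, length.out = n)
    up <- fn$up(x); lo <- fn$lo(x)
    ycu <- upper_ycoef(model)
    e <- semi_ellipse(x) / ycu
    sh <- abs(x) >= 0.3
    beak <- max(0, (fn$up(0) - max(up[sh])) - (1 / ycu - max(e[sh])))
    entry <- max(0, fn$lo(0) - min(lo))
  }
  tibble(model = model$name, aspect_ratio = aspect,
         beak_height = beak, entry_depth = entry)
}

#' Export a polygon as Well-Known Text
#'
#' @param poly A `boundary_polygon`.
#' @param digits Significant digits for coordinates.
#' @return A `POLYGON ((...))` string.
#' @export
polygon_wkt <- function(poly, digits = 8) {
  v <- unclass(poly)
  coords <- paste(signif(v[, 1], digits), signif(v[, 2], digits),
                  collapse = ", ")
  paste0("POLYGON ((", coords, "))")
}

#' Export a polygon as an SVG path element
#'
#' The y-axis is flipped so the beak points up in SVG's y-down coordinates.
#'
#' @param poly A `boundary_polygon`.
#' @param digits Significant digits for coordinates.
#' @return A string holding an SVG `path` `d` attribute value.
#' @export
polygon_svg_path <- function(poly, digits = 6) {
  v <- unclass(poly)
  d <- paste0("M ", paste(signif(v[, 1], digits), signif(-v[, 2], digits),
                          sep = ",", collapse = " L "), " Z")
  d
}

# Tabulated region of a model on a uniform x-grid, centred at the region
# centroid: list(x0, dx, ylo, yup, area, nx). Rows where the region is empty
# are NaN. Used by the superposition scorer; cached per model.
model_lookup <- function(model, nx = 2048) {
  key <- paste0(model$name, "|", model$kernel_kind, "|", nx, "|",
                paste(unlist(model$params), collapse = ","))
  cache <- the_registry$lookup_cache
  if (is.null(cache)) {
    cache <- new.env(parent = emptyenv())
    the_registry$lookup_cache <- cache
  }
  if (!is.null(cache[[key]])) return(cache[[key]])
  if (model$family == "superellipse") {
    p <- model$params
    x <- seq(-p$a, p$a, length.out = nx)
    inner <- pmax(0, 1 - abs(x / p$a)^p$p)
    yup <- p$b * inner^(1 / p$q)
    ylo <- -yup
  } else {
    fn <- branch_functions(model)
    x <- seq(-1, 1, length.out = nx)
    yup <- fn$up(x); ylo <- fn$lo(x)
    empty <- yup < ylo
    yup[empty] <- NaN; ylo[empty] <- NaN
  }
  dx <- x[2] - x[1]
  w <- yup - ylo
  wok <- ifelse(is.finite(w), w, 0)
  area <- sum((wok[-1] + wok[-nx]) / 2) * dx
  mid <- (yup + ylo) / 2
  cy <- sum(((wok * ifelse(is.finite(mid), mid, 0))[-1] +
             (wok * ifelse(is.finite(mid), mid, 0))[-nx]) / 2) * dx / area
  ylo <- ylo - cy; yup <- yup - cy
  bad <- !is.finite(ylo) | !is.finite(yup)
  ylo[bad] <- 1e30; yup[bad] <- -1e30  # sentinel: interval test always fails
  out <- list(x0 = x[1], dx = dx, ylo = ylo, yup = yup,
              area = area, nx = nx, cy = cy)
  cache[[key]] <- out
  out
}
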