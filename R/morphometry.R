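#' J index between two binary masks
#'
#' The J index is the percentage ratio between shared and total surface
#' area of two superimposed silhouettes: `100 * |A intersect B| / |A union
#' B|`. It is 100 exactly when the masks are identical and 0 when they are
#' disjoint. This is the raw overlap on a fixed grid; use
#' [best_superposition()] to maximize it over a similarity transform.
#'
#' Masks of unequal size are padded to a common grid anchored at the
#' lower-left corner.
#'
#' @param a,b `silhouette` objects or logical matrices.
#' @return The J value in `[0, 100]`.
#' @export
#' @examples
#' m <- matrix(FALSE, 10, 10); m[3:7, 3:7] <- TRUE
#' j_index(m, m)
j_index <- function(a, b) {
  ma <- if (inherits(a, "silhouette")) a$mask else a
  mb <- if (inherits(b, "silhouette")) b$mask else b
  if (!any(ma) && !any(mb))
    stop("both masks are empty", call. = FALSE)
  nr <- max(nrow(ma), nrow(mb)); nc <- max(ncol(ma), ncol(mb))
  grow <- function(m) {
    out <- matrix(FALSE, nr, nc)
    out[seq.int(nr - nrow(m) + 1, nr), seq_len(ncol(m))] <- m
    out
  }
  ma <- grow(ma); mb <- grow(mb)
  100 * sum(ma & mb) / sum(ma | mb)
}

# clamp helper for the bounded search space
.clamp <- function(x, lo, hi) pmin(hi, pmax(lo, x))

#' Maximize the J index between a silhouette and a curve model
#'
#' The model region is superimposed on the silhouette under a similarity
#' transform (uniform scale, translation, bounded rotation) and the J index
#' is maximized. The search is deterministic: the transform is initialized
#' by matching centroids and total areas, the best of four right-angle
#' orientation hypotheses is taken (the principal-axis normalization leaves
#' a quadrant ambiguity for nearly isotropic shapes), then a 3x3x3 coarse
#' grid over (scale, tx, ty) crossed with rotations of -10, 0, +10 degrees
#' seeds a Nelder-Mead refinement. Scale is bounded to `[0.5, 2]` times the
#' area-matched value and rotation to 15 degrees about the chosen
#' hypothesis. The returned J never falls below the value at
#' initialization.
#'
#' The J evaluation counts silhouette pixel centres falling inside the
#' transformed model region (tabulated analytically), so the model side is
#' not re-rasterized; this agrees with the mask-on-mask [j_index()] up to
#' pixel quantization.
#'
#' @param seed A `silhouette`; orientation-normalized automatically if not
#'   already.
#' @param model A `curve_model` or registered model name.
#' @param maxit Nelder-Mead iteration budget.
#' @return A `jscore` object: fields `model`, `J`, `transform` (scale in
#'   pixels per model unit, `scale_rel` to the area-matched scale, `tx`,
#'   `ty`, `theta`), `J_init`.
#' @seealso [classify_seed()]
#' @export
#' @examples
#' s <- rasterize(build_polygon(get_model("VAM1"), 512), 128)
#' best_superposition(s, "VAM1")
best_superposition <- function(seed, model, maxit = 60) {
  stopifnot(inherits(seed, "silhouette"))
  if (is.character(model)) model <- get_model(model)
  if (!seed$oriented) seed <- normalize_orientation(seed)
  xy <- mask_xy(seed$mask)
  if (nrow(xy) < 8)
    stop("degenerate silhouette: fewer than 8 foreground pixels",
         call. = FALSE)
  score_one(xy, model, maxit)
}

# principal-axis standard-deviation ratio of a point cloud
axis_ratio <- function(xy) {
  e <- eigen(stats::cov(xy), symmetric = TRUE, only.values = TRUE)$values
  sqrt(e[1] / max(e[2], .Machine$double.eps))
}

# core scorer on pre-extracted foreground pixel centres. For clearly
# anisotropic seeds the orientation normalization pins the axis and only the
# four right-angle hypotheses are probed; weakly anisotropic seeds get a full
# 30-degree rotation sweep because their normalization angle is noise-driven.
score_one <- function(xy, model, maxit = 60) {
  lk <- model_lookup(model)
  px <- xy[, 1]; py <- xy[, 2]
  nA <- length(px)
  cx <- mean(px); cy <- mean(py)
  s0 <- sqrt(nA / lk$area)
  jeval <- function(s, tx, ty, th) {
    I <- overlap_count(px, py, s, tx, ty, th, lk$x0, lk$dx, lk$ylo, lk$yup)
    # model area in pixel units is analytic (s^2 * area); guard against the
    # quantization case I > s^2 * area so J stays in [0, 100]
    100 * I / (nA + max(s * s * lk$area, I) - I)
  }
  best <- list(J = -Inf)
  consider <- function(s, tx, ty, th) {
    J <- jeval(s, tx, ty, th)
    if (J > best$J) best <<- list(J = J, s = s, tx = tx, ty = ty, th = th)
    J
  }
  # orientation hypotheses at the area-matched initialization
  hyp <- if (axis_ratio(xy) >= 1.15) c(0, pi / 2, pi, 3 * pi / 2)
         else seq(0, 2 * pi, by = pi / 6)[-13]
  hj <- vapply(hyp, function(th) consider(s0, cx, cy, th), 0)
  th0 <- hyp[which.max(hj)]
  J_init <- max(hj)
  # coarse grid over (scale, tx, ty) plus rotation probes about the chosen
  # hypothesis
  dt <- 0.03 * sqrt(nA)
  for (sr in c(0.92, 1, 1.08))
    for (ax in c(-dt, 0, dt))
      for (ay in c(-dt, 0, dt))
        consider(s0 * sr, cx + ax, cy + ay, th0)
  for (dth in c(-10, 10) * pi / 180)
    consider(best$s, best$tx, best$ty, th0 + dth)
  start <- c(log(best$s / s0), best$tx - cx, best$ty - cy, best$th - th0)
  obj <- function(par) {
    sr <- .clamp(exp(par[1]), 0.5, 2)
    th <- th0 + .clamp(par[4], -15 * pi / 180, 15 * pi / 180)
    -consider(s0 * sr, cx + par[2], cy + par[3], th)
  }
  optim(start, obj, method = "Nelder-Mead",
        control = list(maxit = maxit, reltol = 1e-5,
                       parscale = c(0.04, dt / 2, dt / 2, 0.04)))
  structure(
    list(model = model$name, J = best$J, J_init = J_init,
         transform = list(scale = best$s, scale_rel = best$s / s0,
                          tx = best$tx, ty = best$ty, theta = best$th)),
    class = "jscore")
}

#' @export
print.jscore <- function(x, ...) {
  cat(sprintf("<jscore> %s: J = %.2f (scale %.3f px/unit, theta %.1f deg)\n",
              x$model, x$J, x$transform$scale, 180 / pi * x$transform$theta))
  invisible(x)
}

#' Assign a silhouette to a morphological seed-shape group
#'
#' Scores the silhouette against every model in `models` with
#' [best_superposition()] and assigns the group of the best-scoring model
#' when its J value reaches the threshold `tau`; otherwise the silhouette is
#' left `UNDEFINED`, mirroring the species for which no adequate model
#' could be identified. Ties are broken by model name.
#'
#' @param seed A `silhouette`.
#' @param models Character vector of registered model names (default: all
#'   models with verified parameters), or a list of `curve_model` objects.
#' @param tau Acceptance threshold on the best J (default 80).
#' @param maxit Per-model optimizer budget, passed to the scorer.
#' @return A `group_assignment`: fields `group`, `best` (a `jscore`),
#'   `ranked` (tibble of all scores, descending), `tau`.
#' @export
#' @examples
#' s <- rasterize(build_polygon(get_model("PPE1"), 512), 128)
#' classify_seed(s)
classify_seed <- function(seed, models = NULL, tau = 80, maxit = 60) {
  stopifnot(inherits(seed, "silhouette"))
  if (is.null(models)) models <- model_names(parameterized_only = TRUE)
  if (is.character(models)) models <- lapply(models, get_model)
  if (length(models) == 0)
    stop("no models to score against", call. = FALSE)
  if (!seed$oriented) seed <- normalize_orientation(seed)
  xy <- mask_xy(seed$mask)
  if (nrow(xy) < 8)
    stop("degenerate silhouette: fewer than 8 foreground pixels",
         call. = FALSE)
  scores <- lapply(models, function(m) score_one(xy, m, maxit))
  ranked <- dplyr::bind_rows(lapply(scores, function(sc)
    tibble(model = sc$model, group = get_model(sc$model)$group, J = sc$J,
           scale = sc$transform$scale, theta = sc$transform$theta)))
  ord <- order(-ranked$J, ranked$model)
  ranked <- ranked[ord, ]
  best <- scores[[ord[1]]]
  group <- if (best$J >= tau) ranked$group[1] else "UNDEFINED"
  structure(list(group = group, best = best, ranked = ranked, tau = tau),
            class = "group_assignment")
}

#' @export
print.group_assignment <- function(x, ...) {
  cat(sprintf("<group_assignment> group %s (best model %s, J = %.2f, tau = %g)\n",
              x$group, x$best$model, x$best$J, x$tau))
  print(utils::head(x$ranked, 5))
  invisible(x)
}
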