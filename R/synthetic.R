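#' Specification for synthetic seed silhouettes
#'
#' Synthetic silhouettes stand in for photographs of real seeds: a
#' registered model is rendered, its boundary radius is perturbed with a
#' low-order radial harmonic field, a random similarity jitter is applied
#' and the result is rasterized. Deformation preserves closedness and the
#' acute/bi-lobed pole structure the morphological groups are defined by.
#'
#' @param model Registered model name the silhouettes are drawn from.
#' @param n Number of silhouettes the spec describes.
#' @param seed Integer RNG key; each `(seed, index)` pair is reproducible in
#'   isolation (counter-based keying).
#' @param deform_amp Fractional radial amplitude of each harmonic, in
#'   `[0, 0.2)`. Beyond 0.2 label fidelity is not guaranteed and the spec is
#'   rejected.
#' @param deform_order Highest radial harmonic (>= 2; harmonics start at 2
#'   so the perturbation adds no net translation or inflation).
#' @param jitter_scale Two-element range of uniform scale jitter.
#' @param jitter_rot Rotation jitter half-range in degrees.
#' @param resolution Pixels along the longer axis of the rasterized mask.
#' @return A `synthetic_spec` object.
#' @export
#' @examples
#' synthetic_spec("VAM1", n = 3, seed = 42)
synthetic_spec <- function(model, n = 1, seed = 1, deform_amp = 0.05,
                           deform_order = 4, jitter_scale = c(0.9, 1.1),
                           jitter_rot = 10, resolution = 256) {
  stopifnot(n >= 1, deform_amp >= 0, deform_order >= 2,
            length(jitter_scale) == 2, all(jitter_scale > 0),
            jitter_rot >= 0, resolution >= 32)
  if (deform_amp >= 0.2)
    stop("deform_amp must be below 0.2: label fidelity is not guaranteed ",
         "for stronger deformation", call. = FALSE)
  get_model(model) # fail early on unknown models
  structure(list(model = model, n = as.integer(n), seed = as.integer(seed),
                 deform_amp = deform_amp,
                 deform_order = as.integer(deform_order),
                 jitter_scale = jitter_scale, jitter_rot = jitter_rot,
                 resolution = as.integer(resolution)),
            class = "synthetic_spec")
}

# counter-based sub-stream key for (seed, index): reproducible without
# generating predecessors, and kept inside 32-bit integer range
derive_seed <- function(seed, index) {
  k <- (as.double(seed) * 1000003 + as.double(index) * 7919 + 1) %% 2147483647
  as.integer(k)
}

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv())
  on.exit(if (had) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  force(code)
}

#' Generate one labeled synthetic silhouette
#'
#' Renders the spec's model polygon, scales each boundary vertex radius
#' (about the region centroid) by `1 + sum_k eps_k cos(k phi + psi_k)` for
#' harmonics `k = 2..deform_order` with `eps_k` uniform in
#' `[-deform_amp, deform_amp]`, applies the similarity jitter, rasterizes,
#' and checks the result is a single hole-free component (up to 10 redraws
#' otherwise). Fully reproducible for fixed `(seed, index)`.
#'
#' @param spec A `synthetic_spec`.
#' @param index Zero-based draw index, `0 <= index < n`.
#' @return A list: `silhouette`, `model`, `group`, `index`.
#' @export
#' @examples
#' sp <- synthetic_spec("ACO1", n = 1, seed = 7)
#' generate_silhouette(sp, 0)
generate_silhouette <- function(spec, index = 0) {
  stopifnot(inherits(spec, "synthetic_spec"), index >= 0, index < spec$n)
  model <- get_model(spec$model)
  poly <- build_polygon(model, 512)
  v <- unclass(poly)[-1, , drop = FALSE] # drop repeated closing vertex
  ctr <- colMeans(v)
  with_seed(derive_seed(spec$seed, index), {
    for (attempt in seq_len(10)) {
      ks <- seq.int(2, spec$deform_order)
      eps <- stats::runif(length(ks), -spec$deform_amp, spec$deform_amp)
      psi <- stats::runif(length(ks), 0, 2 * pi)
      rot <- stats::runif(1, -spec$jitter_rot, spec$jitter_rot) * pi / 180
      sc <- stats::runif(1, spec$jitter_scale[1], spec$jitter_scale[2])
      dx <- sweep(v, 2, ctr)
      phi <- atan2(dx[, 2], dx[, 1])
      fac <- 1 + colSums(eps * cos(outer(ks, phi) + psi))
      if (any(fac <= 0)) next
      w <- dx * fac * sc
      co <- cos(rot); si <- sin(rot)
      w <- cbind(co * w[, 1] - si * w[, 2], si * w[, 1] + co * w[, 2])
      w <- rbind(w, w[1, ])
      mask <- try(rasterize(structure(w, class = "boundary_polygon",
                                      model_name = model$name),
                            spec$resolution), silent = TRUE)
      if (inherits(mask, "try-error")) next
      chk <- silhouette_check(mask$mask)
      if (!chk$ok) next
      mask$provenance <- sprintf("synthetic %s seed=%d index=%d amp=%g",
                                 model$name, spec$seed, index,
                                 spec$deform_amp)
      return(list(silhouette = mask, model = model$name,
                  group = model$group, index = index))
    }
    stop("failed to generate a valid silhouette for '", model$name,
         "' after 10 attempts (deformation too strong?)", call. = FALSE)
  })
}

#' Write a set of synthetic fixtures to disk
#'
#' Generates every silhouette described by `specs`, writes one PNG mask per
#' draw and a CSV manifest describing them.
#'
#' @param specs A `synthetic_spec` or list of them.
#' @param out_dir Destination directory (created if needed).
#' @return The manifest tibble: `file`, `model`, `group`, `seed`, `index`,
#'   `deform_amp`, `resolution`.
#' @export
generate_fixture_set <- function(specs, out_dir) {
  if (inherits(specs, "synthetic_spec")) specs <- list(specs)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (spec in specs) {
    for (i in seq_len(spec$n) - 1L) {
      g <- generate_silhouette(spec, i)
      file <- sprintf("%s_s%d_i%03d.png", spec$model, spec$seed, i)
      write_mask(g$silhouette, file.path(out_dir, file))
      rows[[length(rows) + 1]] <- tibble(
        file = file, model = g$model, group = g$group, seed = spec$seed,
        index = i, deform_amp = spec$deform_amp,
        resolution = spec$resolution)
    }
  }
  manifest <- dplyr::bind_rows(rows)
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  manifest
}
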