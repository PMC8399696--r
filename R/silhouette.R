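#' Construct a silhouette object
#'
#' A silhouette is a binary raster mask of a single seed region. The mask is
#' a logical matrix in image orientation: row 1 is the top of the image and
#' pixel `(i, j)` has centre `(j - 0.5, nrow - i + 0.5)` in y-up pixel
#' coordinates. A clean silhouette holds exactly one connected foreground
#' component with no interior holes and does not touch the image border;
#' [binarize()] guarantees this, the raw constructor only checks shape when
#' `validate = TRUE`.
#'
#' @param mask Logical (or 0/1) matrix.
#' @param pixel_size Physical size of one pixel (units/pixel); `NA` when
#'   unknown.
#' @param oriented Logical; `TRUE` once [normalize_orientation()] has run.
#' @param provenance Free-text origin note.
#' @param validate Check the single-component / no-holes / clear-border
#'   invariants and fail if violated.
#' @return An object of class `silhouette`.
#' @export
silhouette <- function(mask, pixel_size = NA_real_, oriented = FALSE,
                       provenance = "", validate = FALSE) {
  mask <- matrix(as.logical(mask), nrow = nrow(mask))
  if (validate) {
    chk <- silhouette_check(mask)
    if (!chk$ok)
      stop("invalid silhouette: ", chk$why, call. = FALSE)
  }
  structure(list(mask = mask, pixel_size = pixel_size, oriented = oriented,
                 isotropic = FALSE, provenance = provenance),
            class = "silhouette")
}

#' @export
print.silhouette <- function(x, ...) {
  cat("<silhouette> ", nrow(x$mask), "x", ncol(x$mask), " px, ",
      sum(x$mask), " foreground px",
      if (x$oriented) ", oriented" else "",
      if (isTRUE(x$isotropic)) " (isotropic)" else "", "\n", sep = "")
  invisible(x)
}

# structural checks used by binarize(), the synthetic generator and tests
silhouette_check <- function(mask) {
  if (!any(mask)) return(list(ok = FALSE, why = "empty foreground"))
  lab <- EBImage::bwlabel(mask * 1L)
  ncomp <- max(lab)
  filled <- EBImage::fillHull(mask * 1L) > 0
  holes <- sum(filled) - sum(mask)
  border <- any(mask[1, ]) || any(mask[nrow(mask), ]) ||
    any(mask[, 1]) || any(mask[, ncol(mask)])
  why <- c(
    if (ncomp != 1) sprintf("%d connected components", ncomp),
    if (holes > 0) sprintf("%d interior hole pixels", holes),
    if (border) "foreground touches the image border")
  list(ok = length(why) == 0, why = paste(why, collapse = "; "),
       n_components = ncomp, hole_pixels = holes)
}

#' Read a grayscale seed image from PNG or TIFF
#'
#' RGB(A) images are reduced to luma; values are rescaled to `[0, 1]`.
#'
#' @param path Image file; format chosen by extension (`.png`, `.tif(f)`).
#' @return A numeric matrix, row 1 at the top of the image.
#' @export
read_seed_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format '.", ext, "' (use PNG or TIFF)",
         call. = FALSE))
  if (length(dim(img)) == 3) {
    nch <- dim(img)[3]
    img <- if (nch >= 3)
      0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
    else img[, , 1]
  }
  img
}

#' Segment a single seed silhouette from a grayscale image
#'
#' Deterministic replacement for interactive two-layer image editing:
#' a global Otsu threshold splits the histogram, polarity is chosen so the
#' object (the minority phase) is foreground, only the largest connected
#' component is kept, interior holes are filled, and the mask is cropped and
#' padded with a clear margin.
#'
#' @param image Numeric matrix in `[0, 1]` (or 0--255), a 3-channel array,
#'   or a file path understood by [read_seed_image()].
#' @param pad Margin added around the cropped mask, as a fraction of the
#'   longer side.
#' @param pixel_size Optional physical pixel size, stored as metadata.
#' @return A `silhouette`.
#' @export
#' @examples
#' img <- matrix(0, 64, 64); img[20:44, 20:44] <- 1
#' binarize(img)
binarize <- function(image, pad = 0.05, pixel_size = NA_real_) {
  prov <- "binarize"
  if (is.character(image)) {
    prov <- paste0("binarize(", basename(image), ")")
    image <- read_seed_image(image)
  }
  if (length(dim(image)) == 3) {
    image <- 0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
  }
  stopifnot(is.matrix(image))
  image <- image / max(1, max(image))
  vals <- unique(as.vector(image))
  th <- if (length(vals) <= 2) mean(range(image))
        else EBImage::otsu(EBImage::Image(image), range = c(0, 1))
  fg <- image > th
  # polarity: the object does not touch the border, so foreground is the
  # phase with the smaller border fraction (minority phase as tie-break)
  border <- c(fg[1, ], fg[nrow(fg), ], fg[, 1], fg[, ncol(fg)])
  bf <- mean(border)
  if (bf > 0.5 || (bf == 0.5 && mean(fg) > 0.5)) fg <- !fg
  frac <- mean(fg)
  if (!any(fg) || frac > 0.95)
    stop("segmentation failed: foreground covers ",
         sprintf("%.1f%%", 100 * frac), " of the image", call. = FALSE)
  lab <- EBImage::bwlabel(fg * 1L)
  sizes <- tabulate(lab[lab > 0])
  fg <- lab == which.max(sizes)
  fg <- EBImage::fillHull(fg * 1L) > 0
  mask <- mask_trim_pad(fg, pad)
  silhouette(mask, pixel_size = pixel_size, provenance = prov)
}

# crop to the foreground bounding box, then add a clear margin
mask_trim_pad <- function(mask, pad = 0.05) {
  idx <- which(mask, arr.ind = TRUE)
  r <- range(idx[, 1]); cc <- range(idx[, 2])
  core <- mask[r[1]:r[2], cc[1]:cc[2], drop = FALSE]
  m <- max(2L, ceiling(pad * max(dim(core))))
  out <- matrix(FALSE, nrow(core) + 2 * m, ncol(core) + 2 * m)
  out[m + seq_len(nrow(core)), m + seq_len(ncol(core))] <- core
  out
}

# y-up pixel-centre coordinates of foreground pixels
mask_xy <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  cbind(x = idx[, 2] - 0.5, y = nrow(mask) - idx[, 1] + 0.5)
}

# nearest-neighbour resample of a rotated mask (angle in radians, CCW)
rotate_mask <- function(mask, angle) {
  n <- nrow(mask); m <- ncol(mask)
  cx <- m / 2; cy <- n / 2
  co <- cos(angle); si <- sin(angle)
  half <- abs(co) * c(m, n) / 2 + abs(si) * c(n, m) / 2
  m2 <- ceiling(2 * half[1]) + 2L; n2 <- ceiling(2 * half[2]) + 2L
  xo <- rep(seq_len(m2) - 0.5 - m2 / 2, each = n2)
  yo <- rep(n2 / 2 - seq_len(n2) + 0.5, times = m2)
  xi <- co * xo + si * yo + cx   # inverse rotation by -angle
  yi <- -si * xo + co * yo + cy
  j <- ceiling(xi); i <- n - floor(yi)
  ok <- i >= 1 & i <= n & j >= 1 & j <= m
  val <- logical(n2 * m2)
  val[ok] <- mask[cbind(i[ok], j[ok])]
  matrix(val, nrow = n2, ncol = m2)
}

#' Normalize the orientation of a silhouette
#'
#' Rotates the mask so its major principal axis is vertical and flips it so
#' the narrower pole (smaller mean row width over the outer quarter of the
#' height) points up -- the acute pole (beak) convention of the model
#' figures. Nearly isotropic shapes (principal-axis ratio below
#' `iso_ratio`) are returned unrotated with the `isotropic` flag set. The
#' operation is idempotent: an already-normalized mask is returned
#' unchanged.
#'
#' @param s A `silhouette`.
#' @param iso_ratio Principal-axis standard-deviation ratio below which the
#'   shape is treated as isotropic.
#' @param angle_tol Residual tilt (radians) accepted without resampling.
#' @return The oriented `silhouette`.
#' @export
normalize_orientation <- function(s, iso_ratio = 1.02, angle_tol = 0.0075) {
  stopifnot(inherits(s, "silhouette"))
  xy <- mask_xy(s$mask)
  e <- eigen(stats::cov(xy), symmetric = TRUE)
  ratio <- sqrt(e$values[1] / max(e$values[2], .Machine$double.eps))
  if (ratio < iso_ratio) {
    s$isotropic <- TRUE
    s$oriented <- TRUE
    return(s)
  }
  major <- e$vectors[, 1]
  alpha <- atan2(major[2], major[1])
  beta <- pi / 2 - alpha                 # rotation bringing major axis vertical
  beta <- atan2(sin(beta), cos(beta))
  if (abs(beta) > pi / 2) beta <- beta - sign(beta) * pi # smaller of the two
  mask <- s$mask
  rotated <- FALSE
  if (abs(beta) > angle_tol) {
    mask <- rotate_mask(mask, beta)
    mask <- mask_trim_pad(mask)
    rotated <- TRUE
  }
  flipped <- FALSE
  if (pole_is_inverted(mask)) {
    mask <- mask[rev(seq_len(nrow(mask))), , drop = FALSE]
    flipped <- TRUE
  }
  if (!rotated && !flipped) {
    s$oriented <- TRUE
    return(s)
  }
  out <- silhouette(mask, pixel_size = s$pixel_size, oriented = TRUE,
                    provenance = s$provenance)
  out
}

# TRUE when the wider pole is on top (mean row width over the outer 25%)
pole_is_inverted <- function(mask) {
  w <- rowSums(mask)
  rows <- which(w > 0)
  h <- length(rows)
  k <- max(1L, floor(h / 4))
  top <- mean(w[rows[seq_len(k)]])
  bottom <- mean(w[rows[seq.int(h - k + 1, h)]])
  top > bottom
}

#' Rasterize a boundary polygon to a binary mask
#'
#' Pixels are set when their centre lies inside the polygon (even-odd rule).
#' The polygon is scaled so its longer bounding-box side spans `resolution`
#' pixels.
#'
#' @param poly A `boundary_polygon`.
#' @param resolution Pixels along the longer axis (>= 32).
#' @param pad Clear margin fraction added around the mask.
#' @return A `silhouette` (already in the model's beak-up orientation).
#' @export
#' @examples
#' poly <- build_polygon(get_model("VAM1"), 512)
#' rasterize(poly, 128)
rasterize <- function(poly, resolution, pad = 0.05) {
  v <- unclass(poly)
  stopifnot(is.matrix(v), ncol(v) == 2, resolution >= 32)
  if (abs(signed_area(v)) <= 0)
    stop("degenerate polygon", call. = FALSE)
  rx <- range(v[, 1]); ry <- range(v[, 2])
  scale <- resolution / max(diff(rx), diff(ry))
  px <- (v[, 1] - rx[1]) * scale
  py <- (v[, 2] - ry[1]) * scale
  ncol <- max(1L, ceiling(max(px))); nrow <- max(1L, ceiling(max(py)))
  mask <- fill_polygon(px, py, nrow, ncol) > 0
  if (!any(mask))
    stop("degenerate polygon: rasterization produced no pixels", call. = FALSE)
  mask <- mask_trim_pad(mask, pad)
  silhouette(mask, pixel_size = 1 / scale,
             provenance = paste0("rasterize(", attr(poly, "model_name"), ")"))
}

#' Write a silhouette mask to a PNG file
#'
#' @param s A `silhouette`.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(s, path) {
  stopifnot(inherits(s, "silhouette"))
  png::writePNG(s$mask * 1, target = path)
  invisible(path)
}
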