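#' Algebraic seed-shape curve models
#'
#' A curve model is a closed planar region in dimensionless model units whose
#' silhouette resembles a well-oriented seed. Two constructions are supported:
#'
#' * **Factor-product families** (`ellipse`, `waterdrop`, `heart`,
#'   `heart_phi`, `heart_ppe`): the boundary is the zero set of a product of
#'   two factors, each an explicit modification of a semi-ellipse
#'   `sqrt(1 - x^2)`. Solving each factor for `y` gives a lower and an upper
#'   branch on `x` in `[-1, 1]`. Localized beak and basal-entry features are
#'   carried by a shape kernel `K(x) = amp / D(x)` (or `amp * sqrt(D(x))`
#'   when `kernel_kind = "radical"`), where `D(x)` is a positive polynomial
#'   in `x^2`, `x^4`, `|x|` and `|x|^3`, so every branch is an even function
#'   of `x` and the region is mirror-symmetric about `x = 0`.
#' * **Superellipse family** (`superellipse`, covering lenses): the region
#'   `|x/a|^p + |y/b|^q <= 1`. Exponents `p, q > 2` give a superellipse;
#'   `p > 2` with `1 < q < 2` gives a lens, pointed at the `y`-extremes.
#'
#' The acute pole (beak) points towards `+y` in model units.
#'
#' @param name Model identifier (used for registry lookup and reporting).
#' @param family One of `"ellipse"`, `"waterdrop"`, `"heart"`, `"heart_phi"`,
#'   `"heart_ppe"`, `"superellipse"`.
#' @param params Named list of parameter values. Factor families use `a`,
#'   `b` (and `c` for water drops); the superellipse family uses `a`, `b`,
#'   `p`, `q`.
#' @param group Roman-numeral morphological group the model exemplifies
#'   (`"I"` to `"X"`), or `NA`.
#' @param parameterized Logical; `TRUE` when the parameter values are
#'   published or otherwise verified. Unverified template models are kept in
#'   the registry but excluded from classification by default.
#' @param kernel_kind `"rational"` (default) or `"radical"`; how the shape
#'   kernel enters the branch equations. The rational reading closes the
#'   region and is the package default.
#' @param provenance Free-text note on where the model comes from.
#'
#' @return An object of class `curve_model`.
#' @seealso [build_polygon()], [evaluate_branches()], [shape_descriptors()],
#'   [get_model()]
#' @export
#' @examples
#' m <- curve_model("drop", "waterdrop", list(a = 1, b = 1, c = 2))
#' evaluate_branches(m, c(0, 0.5))
curve_model <- function(name, family, params, group = NA_character_,
                        parameterized = TRUE, kernel_kind = c("rational", "radical"),
                        provenance = "") {
  family <- match.arg(family, c("ellipse", "waterdrop", "heart", "heart_phi",
                                "heart_ppe", "superellipse"))
  kernel_kind <- match.arg(kernel_kind)
  params <- lapply(params, as.numeric)
  need <- switch(family,
    ellipse      = "b",
    waterdrop    = c("a", "b", "c"),
    heart        = c("a", "b"),
    heart_phi    = c("a", "b"),
    heart_ppe    = c("a", "b"),
    superellipse = c("a", "b", "p", "q"))
  missing <- setdiff(need, names(params))
  if (length(missing))
    stop("model '", name, "' (", family, ") is missing parameter(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  vals <- unlist(params[need])
  if (!all(is.finite(vals)))
    stop("model '", name, "' has non-finite parameters", call. = FALSE)
  if (family == "superellipse") {
    with(params, stopifnot(a > 0, b > 0, p > 0, q > 0))
  } else if (any(vals[setdiff(need, "a")] <= 0)) {
    stop("model '", name, "' requires positive b (and c)", call. = FALSE)
  }
  structure(
    list(name = name, family = family, params = params, group = group,
         parameterized = isTRUE(parameterized), kernel_kind = kernel_kind,
         provenance = provenance),
    class = "curve_model")
}

#' @export
print.curve_model <- function(x, ...) {
  p <- paste(names(x$params), vapply(x$params, format, ""), sep = "=",
             collapse = ", ")
  cat("<curve_model> ", x$name, " [", x$family, "] ", p,
      if (!is.na(x$group)) paste0("  group ", x$group) else "",
      if (!x$parameterized) "  (unverified template)" else "", "\n", sep = "")
  invisible(x)
}

#' Sub-family of a superellipse-type model
#'
#' Classifies the exponents: `p, q > 2` is a superellipse, `p > 2` with
#' `1 < q < 2` is a lens, `p = q = 2` is an ellipse; anything else is
#' reported as `"other"`.
#'
#' @param params A list with entries `p` and `q`, or a `curve_model` of the
#'   superellipse family.
#' @return One of `"superellipse"`, `"lens"`, `"ellipse"`, `"other"`.
#' @export
superellipse_class <- function(params) {
  if (inherits(params, "curve_model")) params <- params$params
  p <- params$p; q <- params$q
  if (p > 2 && q > 2) "superellipse"
  else if (p > 2 && q > 1 && q < 2) "lens"
  else if (p == 2 && q == 2) "ellipse"
  else "other"
}

# upper half of the unit semicircle, clamped against fp noise at |x| = 1
semi_ellipse <- function(x) sqrt(pmax(0, 1 - x * x))

# shape kernels K(x) = amp/D(x) (rational) or amp*sqrt(D(x)) (radical);
# D is one of the fixed positive polynomials used by the model families
shape_kernel <- function(D, kind) {
  if (kind == "rational") function(x, amp) amp / D(x)
  else function(x, amp) amp * sqrt(D(x))
}

kernel_D <- list(
  drop_beak   = function(x, c) 50 * x^2 + c,
  heart_both  = function(x) 54 * x^2 + 9 * abs(x) + 3,
  phi_beak    = function(x) 10 * x^2 + 1,
  ppe_beak    = function(x) 5 * x^4 + 25 * x^2 + 1,
  ppe_entry   = function(x) 5 * x^4 + 25 * abs(x)^3 + 1
)

# Branch functions y = g(x) for the factor-product families, solving each
# factor for y. Returns list(lo = fn, up = fn).
branch_functions <- function(model) {
  p <- model$params
  kk <- model$kernel_kind
  kern <- function(D) shape_kernel(D, kk)
  switch(model$family,
    ellipse = list(
      lo = function(x) -semi_ellipse(x) / p$b,
      up = function(x)  semi_ellipse(x) / p$b),
    waterdrop = {
      K <- kern(function(x) kernel_D$drop_beak(x, p$c))
      list(lo = function(x) -semi_ellipse(x) / p$b,
           up = function(x) (semi_ellipse(x) + K(x, p$a)) / p$b)
    },
    heart = {
      K <- kern(kernel_D$heart_both)
      list(lo = function(x) K(x, p$a) - semi_ellipse(x),
           up = function(x) semi_ellipse(x) + K(x, p$b))
    },
    heart_phi = {
      Kb <- kern(kernel_D$phi_beak); Ke <- kern(kernel_D$heart_both)
      list(lo = function(x) Ke(x, p$b) - semi_ellipse(x),
           up = function(x) semi_ellipse(x) + Kb(x, p$a))
    },
    heart_ppe = {
      Kb <- kern(kernel_D$ppe_beak); Ke <- kern(kernel_D$ppe_entry)
      yc <- 9 / 10
      list(lo = function(x) (Ke(x, p$b) - semi_ellipse(x)) / yc,
           up = function(x) (semi_ellipse(x) + Kb(x, p$a)) / yc)
    },
    stop("family '", model$family, "' has no explicit branch pair",
         call. = FALSE))
}

# coefficient of y in the upper factor: the semi-ellipse component of the
# upper branch is semi_ellipse(x) / upper_ycoef(model)
upper_ycoef <- function(model) {
  switch(model$family,
    ellipse = ,
    waterdrop = model$params$b,
    heart = ,
    heart_phi = 1,
    heart_ppe = 9 / 10,
    stop("no branch pair for family '", model$family, "'", call. = FALSE))
}

#' Evaluate the lower and upper boundary branches of a factor-product model
#'
#' Solves the two factors of the model's defining equation for `y` at the
#' given abscissae. Both branches are even functions of `x`.
#'
#' @param model A `curve_model` of a factor-product family (not
#'   superellipse).
#' @param x Numeric vector of abscissae in `[-1, 1]` (model units).
#' @return A tibble with columns `x`, `y_lower`, `y_upper`.
#' @export
#' @examples
#' evaluate_branches(curve_model("e", "ellipse", list(b = 1)), 0)
evaluate_branches <- function(model, x) {
  stopifnot(inherits(model, "curve_model"))
  if (model$family == "superellipse")
    stop("evaluate_branches() does not apply to the superellipse family; ",
         "use superellipse_membership() or build_polygon()", call. = FALSE)
  if (any(!is.finite(x)) || any(abs(x) > 1 + 1e-12))
    stop("x must lie in [-1, 1] (model units)", call. = FALSE)
  x <- pmin(1, pmax(-1, x))
  fn <- branch_functions(model)
  tibble(x = x, y_lower = fn$lo(x), y_upper = fn$up(x))
}

#' Point membership for superellipse and lens models
#'
#' Evaluates the sign of `|x/a|^p + |y/b|^q - 1`.
#'
#' @param params A `curve_model` of the superellipse family, or a list with
#'   `a`, `b`, `p`, `q`.
#' @param x,y Point coordinates in model units (vectorized).
#' @param tol Half-width of the band reported as `"boundary"`.
#' @return Character vector: `"inside"`, `"boundary"` or `"outside"`.
#' @export
#' @examples
#' superellipse_membership(list(a = 1, b = 1, p = 2, q = 2), c(0, 1), c(0, 0))
superellipse_membership <- function(params, x, y, tol = 1e-9) {
  if (inherits(params, "curve_model")) {
    stopifnot(params$family == "superellipse")
    params <- params$params
  }
  stopifnot(params$a > 0, params$b > 0, params$p > 0, params$q > 0)
  v <- abs(x / params$a)^params$p + abs(y / params$b)^params$q - 1
  out <- ifelse(abs(v) <= tol, "boundary", ifelse(v < 0, "inside", "outside"))
  as.character(out)
}
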