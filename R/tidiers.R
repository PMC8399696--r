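#' Tidy a J-score
#'
#' @param x A `jscore` from [best_superposition()].
#' @param ... Unused.
#' @return One-row tibble: `model`, `J`, `J_init`, `scale`, `scale_rel`,
#'   `tx`, `ty`, `theta`.
#' @method tidy jscore
#' @export
tidy.jscore <- function(x, ...) {
  tr <- x$transform
  tibble(model = x$model, J = x$J, J_init = x$J_init, scale = tr$scale,
         scale_rel = tr$scale_rel, tx = tr$tx, ty = tr$ty, theta = tr$theta)
}

#' Tidy a group assignment: the full ranked model table
#'
#' @param x A `group_assignment` from [classify_seed()].
#' @param ... Unused.
#' @return Tibble of per-model scores, descending by `J`.
#' @method tidy group_assignment
#' @export
tidy.group_assignment <- function(x, ...) x$ranked

#' One-row summary of a group assignment
#'
#' @param x A `group_assignment`.
#' @param ... Unused.
#' @return One-row tibble: `group`, `best_model`, `best_J`, `tau`,
#'   `n_models`.
#' @method glance group_assignment
#' @export
glance.group_assignment <- function(x, ...) {
  tibble(group = x$group, best_model = x$best$model, best_J = x$best$J,
         tau = x$tau, n_models = nrow(x$ranked))
}
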