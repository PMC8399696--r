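extdata <- function(file) {
  path <- system.file("extdata", file, package = "seedgeom")
  if (path == "") path <- file.path("inst", "extdata", file) # load_all fallback
  path
}

registry_load <- function() {
  if (!is.null(the_registry$models)) return(invisible())
  raw <- jsonlite::fromJSON(extdata("models.json"), simplifyVector = FALSE)
  models <- lapply(raw, function(m)
    curve_model(m$name, m$family, m$params, group = m$group,
                parameterized = isTRUE(m$parameterized),
                kernel_kind = m$kernel_kind, provenance = m$provenance))
  names(models) <- vapply(models, `[[`, "", "name")
  the_registry$models <- models
  the_registry$exemplars <- setNames(
    lapply(raw, function(m) unlist(m$exemplars)),
    names(models))
  the_registry$groups <- as_tibble(read.csv(
    extdata("vitaceae_groups.csv"), stringsAsFactors = FALSE))
  the_registry$species <- as_tibble(read.csv(
    extdata("vitaceae_species.csv"), stringsAsFactors = FALSE))
  the_registry$genera <- as_tibble(read.csv(
    extdata("vitaceae_genera.csv"), stringsAsFactors = FALSE,
    na.strings = "NA"))
  invisible()
}

#' The packaged curve-model registry
#'
#' One row per registered model. Models flagged `parameterized` carry
#' published parameter values; the remaining rows are family templates with
#' placeholder parameters (their `provenance` says so) and are excluded from
#' classification unless explicitly requested.
#'
#' @return A tibble with columns `model`, `family`, `group`, `parameterized`,
#'   the parameter columns `a`, `b`, `c`, `p`, `q` (NA where not used) and
#'   `provenance`.
#' @seealso [get_model()], [model_names()]
#' @export
#' @examples
#' seed_models()
seed_models <- function() {
  registry_load()
  rows <- lapply(the_registry$models, function(m) {
    pp <- m$params
    tibble(model = m$name, family = m$family, group = m$group,
           parameterized = m$parameterized,
           a = pp$a %||% NA_real_, b = pp$b %||% NA_real_,
           c = pp$c %||% NA_real_, p = pp$p %||% NA_real_,
           q = pp$q %||% NA_real_, provenance = m$provenance)
  })
  dplyr::bind_rows(rows)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Retrieve a registered curve model by name
#'
#' @param name Model identifier, e.g. `"VAM1"`.
#' @return A `curve_model`.
#' @export
#' @examples
#' get_model("VAM1")
get_model <- function(name) {
  registry_load()
  m <- the_registry$models[[name]]
  if (is.null(m))
    stop("unknown model '", name, "'; available models: ",
         paste(names(the_registry$models), collapse = ", "), call. = FALSE)
  m
}

#' Names of registered models
#'
#' @param parameterized_only If `TRUE` (default) only models with verified
#'   (published) parameter values are returned; these are the models used for
#'   classification by default.
#' @return Character vector of model names.
#' @export
model_names <- function(parameterized_only = TRUE) {
  registry_load()
  ms <- the_registry$models
  if (parameterized_only)
    ms <- Filter(function(m) m$parameterized, ms)
  names(ms)
}

#' The ten morphological seed-shape groups of the Vitaceae
#'
#' @return A tibble with one row per group member: `group_id` (Roman numeral
#'   `I`--`X` or `UNDEFINED`), `label`, `species`, `refs` (semicolon-separated
#'   source citation keys, as printed).
#' @export
seed_groups <- function() {
  registry_load()
  the_registry$groups
}

#' Member species of one morphological group
#'
#' @param group_id Roman numeral `"I"`--`"X"` or `"UNDEFINED"`.
#' @return A tibble of the group's member species, in printed order.
#' @export
#' @examples
#' group_members("I")
group_members <- function(group_id) {
  g <- seed_groups()
  ok <- c(as.character(as.roman(1:10)), "UNDEFINED")
  if (!toupper(group_id) %in% ok)
    stop("invalid group id '", group_id, "'; use I..X or UNDEFINED",
         call. = FALSE)
  g[g$group_id == toupper(group_id), ]
}

#' Observed species of the Vitaceae, as packaged
#'
#' @return A tibble with `tribe`, `genus`, `species`, `refs` for each of the
#'   observed species, names spelled as printed in the source table.
#' @export
seed_species <- function() {
  registry_load()
  the_registry$species
}

#' Genus-level taxonomy of the Vitaceae
#'
#' `species_total` is the approximate species count of the taxonomy summary;
#' `species_total_listed` is the (sometimes differing) total printed in the
#' observed-species table header; `species_observed` counts the species whose
#' seeds were examined. Both totals are exposed because the source tables do
#' not always agree.
#'
#' @return A tibble with one row per genus.
#' @export
seed_genera <- function() {
  registry_load()
  the_registry$genera
}

#' Summary counts of the packaged registries
#'
#' Counts are computed from the packaged tables, not hard-coded.
#'
#' @return A one-row tibble: `n_groups` (Roman-numeral groups, excluding
#'   `UNDEFINED`), `n_species_observed`, `n_genera`.
#' @export
#' @examples
#' registry_stats()
registry_stats <- function() {
  g <- seed_groups(); s <- seed_species(); gen <- seed_genera()
  tibble(
    n_groups = length(setdiff(unique(g$group_id), "UNDEFINED")),
    n_species_observed = length(unique(s$species)),
    n_genera = nrow(gen))
}

#' Exemplar species associated with a registered model
#'
#' @param name Model identifier.
#' @return Character vector of species names.
#' @export
model_exemplars <- function(name) {
  registry_load()
  if (!name %in% names(the_registry$exemplars))
    stop("unknown model '", name, "'", call. = FALSE)
  the_registry$exemplars[[name]]
}
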