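#' Covariate schema
#'
#' A covariate schema lists the categorical covariates of the analysis in a
#' fixed order, each with an ordered set of levels and a designated
#' reference level.  The reference level is the one whose coefficient is
#' pinned at zero in the regression and which serves as the comparator arm
#' of every counterfactual contrast.
#'
#' @param variables a named list; each element is either a character vector
#'   of levels (the first is taken as reference) or a list with components
#'   `levels` and `reference`.
#' @return An object of class `covariate_schema`.
#' @examples
#' sch <- covariate_schema(list(
#'   sex = list(levels = c("female", "male"), reference = "female"),
#'   age = c("16-44", "45+")))
#' n_cells(sch)
#' @export
covariate_schema <- function(variables) {
  if (length(variables) == 0)
    hl_abort("schema must contain at least one variable", "hlmrp_invalid_schema")
  nms <- names(variables)
  if (is.null(nms) || any(nms == "") || anyDuplicated(nms))
    hl_abort("schema variables must have unique, non-empty names",
             "hlmrp_invalid_schema")
  vars <- lapply(nms, function(nm) {
    v <- variables[[nm]]
    if (is.character(v)) v <- list(levels = v, reference = v[[1]])
    if (is.null(v$reference)) v$reference <- v$levels[[1]]
    if (length(v$levels) < 2 || anyDuplicated(v$levels))
      hl_abort(sprintf("variable '%s' needs >= 2 distinct levels", nm),
               "hlmrp_invalid_schema")
    if (!v$reference %in% v$levels)
      hl_abort(sprintf("reference level '%s' of '%s' is not among its levels",
                       v$reference, nm), "hlmrp_invalid_schema")
    list(name = nm, levels = as.character(v$levels),
         reference = as.character(v$reference))
  })
  names(vars) <- nms
  structure(list(variables = vars), class = "covariate_schema")
}

#' @export
print.covariate_schema <- function(x, ...) {
  cat("Covariate schema:", length(x$variables), "variables,",
      n_cells(x), "cells\n")
  for (v in x$variables)
    cat(sprintf("  %-14s %s (ref: %s)\n", v$name,
                paste(v$levels, collapse = "/"), v$reference))
  invisible(x)
}

schema_names <- function(schema) names(schema$variables)

schema_levels <- function(schema, variable) {
  v <- schema$variables[[variable]]
  if (is.null(v))
    hl_abort(sprintf("unknown variable '%s'", variable), "hlmrp_schema_mismatch")
  v$levels
}

schema_reference <- function(schema, variable) {
  schema$variables[[variable]]$reference
}

#' Default 11-covariate schema for the health-literacy analysis
#'
#' Eight binary socio-demographic covariates, two three-level covariates
#' (gross annual income and occupational class) and the deprivation
#' quintile (`imd`, modelled as a partially pooled group effect).
#' Reference levels are the comparator categories omitted from the
#' effect tables: age 16-44, female, non-white ethnicity, English not
#' first language, not UK born, qualification at level 1 or below,
#' income under 10k, higher (managerial/professional) occupation, not
#' working, not a home owner, deprivation quintile 1 (most deprived).
#'
#' @return A `covariate_schema` with 11 variables and 11520 cells.
#' @export
default_schema <- function() {
  covariate_schema(list(
    age           = c("16-44", "45+"),
    sex           = c("female", "male"),
    ethnicity     = c("non-white", "white"),
    english       = c("no", "yes"),
    ukborn        = c("no", "yes"),
    qualification = c("level1_or_below", "level2_plus"),
    income        = c("lt10k", "ge10k", "other"),
    job           = c("higher", "intermediate", "lower"),
    working       = c("no", "yes"),
    ownhome       = c("no", "yes"),
    imd           = c("q1", "q2", "q3", "q4", "q5")
  ))
}

#' Number of post-stratification cells implied by a schema
#' @param schema a `covariate_schema`.
#' @return Integer product of per-variable level counts.
#' @export
n_cells <- function(schema) {
  prod(vapply(schema$variables, function(v) length(v$levels), numeric(1)))
}

#' Enumerate all post-stratification cells
#'
#' Builds the full cartesian product of covariate levels in a
#' deterministic order: lexicographic by declared variable and level
#' order, with the first declared variable varying slowest.
#'
#' @param schema a `covariate_schema`.
#' @return A data frame with one character column per variable and one row
#'   per cell, carrying the schema as an attribute.
#' @export
enumerate_cells <- function(schema) {
  if (!inherits(schema, "covariate_schema"))
    hl_abort("schema must be a covariate_schema", "hlmrp_invalid_schema")
  grids <- lapply(rev(schema$variables), function(v) v$levels)
  cells <- expand.grid(grids, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cells <- cells[, rev(seq_along(cells)), drop = FALSE]
  names(cells) <- schema_names(schema)
  rownames(cells) <- NULL
  attr(cells, "schema") <- schema
  cells
}

#' Look up cell ordinals for covariate assignments
#'
#' @param cells a cell enumeration from [enumerate_cells()].
#' @param assignments a data frame of covariate assignments (same columns).
#' @return Integer vector of row indices into `cells`.
#' @export
cell_index <- function(cells, assignments) {
  idx <- match(cell_paste_key(assignments[names(cells)]),
               cell_paste_key(cells))
  if (anyNA(idx))
    hl_abort("assignment does not match any enumerated cell",
             "hlmrp_schema_mismatch")
  idx
}

#' Read / write a covariate schema
#'
#' Schemas are stored as YAML (or JSON, chosen by file extension) listing
#' each variable's name, levels and reference level.
#'
#' @param path file path ending in `.yaml`, `.yml` or `.json`.
#' @return `read_schema()` returns a `covariate_schema`.
#' @export
read_schema <- function(path) {
  doc <- if (grepl("\\.json$", path)) jsonlite::read_json(path)
         else yaml::read_yaml(path)
  vars <- lapply(doc$variables, function(v)
    list(levels = unlist(v$levels), reference = v$reference))
  names(vars) <- vapply(doc$variables, `[[`, character(1), "name")
  covariate_schema(vars)
}

#' @param schema a `covariate_schema`.
#' @rdname read_schema
#' @export
write_schema <- function(schema, path) {
  doc <- list(variables = lapply(unname(schema$variables), function(v)
    list(name = v$name, levels = as.list(v$levels), reference = v$reference)))
  if (grepl("\\.json$", path))
    jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE)
  else writeLines(yaml::as.yaml(doc), path)
  invisible(path)
}
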