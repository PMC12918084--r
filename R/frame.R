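#' Joint probability table over a subset of covariates
#'
#' @param variables character vector of schema variable names (dimension
#'   order of `prob`).
#' @param prob numeric array with one dimension per variable, dimnames set
#'   to the schema levels; nonnegative, summing to 1.
#' @return An object of class `joint_table`.
#' @export
joint_table <- function(variables, prob) {
  prob <- as.array(prob)
  if (length(dim(prob)) != length(variables))
    hl_abort("probability array dimension must match variable count",
             "hlmrp_invalid_joint")
  if (any(prob < 0) || abs(sum(prob) - 1) > 1e-9)
    hl_abort("joint probabilities must be nonnegative and sum to 1",
             "hlmrp_invalid_joint")
  names(dimnames(prob)) <- NULL
  structure(list(variables = as.character(variables), prob = prob),
            class = "joint_table")
}

#' @export
print.joint_table <- function(x, ...) {
  cat("Joint table over:", paste(x$variables, collapse = ", "),
      sprintf("(%d cells)\n", length(x$prob)))
  invisible(x)
}

#' Marginal distribution of a single covariate
#'
#' @param variable schema variable name.
#' @param proportions named nonnegative numeric vector over the variable's
#'   levels, summing to 1.
#' @return An object of class `marginal_table`.
#' @export
marginal_table <- function(variable, proportions) {
  if (any(proportions < 0) || abs(sum(proportions) - 1) > 1e-9)
    hl_abort("marginal proportions must be nonnegative and sum to 1",
             "hlmrp_invalid_marginal")
  structure(list(variable = variable, proportions = proportions),
            class = "marginal_table")
}

# promote a marginal to a 1-dimensional joint
as_joint <- function(x) {
  if (inherits(x, "joint_table")) return(x)
  p <- array(unname(x$proportions), dim = length(x$proportions),
             dimnames = list(names(x$proportions)))
  joint_table(x$variable, p)
}

#' Estimate a joint covariate distribution from microdata
#'
#' The joint probability of each level combination is its (optionally
#' weighted) relative frequency among the records; combinations absent
#' from the data get probability 0.
#'
#' @param records data frame of covariate assignments.
#' @param variables names of the covariates to cross-tabulate.
#' @param schema a `covariate_schema` supplying the level sets.
#' @param record_weights optional nonnegative per-record weights
#'   (default: equal).
#' @return A `joint_table` over `variables`.
#' @export
estimate_joint_from_microdata <- function(records, variables, schema,
                                          record_weights = NULL) {
  if (is.null(record_weights)) record_weights <- rep(1, nrow(records))
  if (any(record_weights < 0))
    hl_abort("record weights must be nonnegative", "hlmrp_invalid_weights")
  fs <- lapply(variables, function(v) {
    lv <- schema_levels(schema, v)
    bad <- which(!records[[v]] %in% lv)
    if (length(bad))
      hl_abort(sprintf("record %d has unknown level '%s' for variable '%s'",
                       bad[1], records[[v]][bad[1]], v),
               "hlmrp_schema_mismatch")
    factor(records[[v]], levels = lv)
  })
  names(fs) <- variables
  tab <- tapply(record_weights, fs, sum, default = 0)
  tab <- as.array(tab)
  joint_table(variables, tab / sum(tab))
}

#' Iterative proportional fitting (raking)
#'
#' Cycles proportional adjustments of a seed joint distribution over a set
#' of target marginals until every fitted margin matches its target within
#' `tol` (maximum absolute deviation, assessed after a full cycle).
#' Structural zeros of the seed are preserved, and so is every conditional
#' odds ratio of the seed (IPF only alters the margins, not the
#' interaction structure).
#'
#' @param seed a `joint_table` whose dimensions include every target
#'   variable.
#' @param targets list of `marginal_table`s.
#' @param tol convergence tolerance on margin deviation (default 1e-10).
#' @param max_iter maximum number of full cycles (default 1000).
#' @return The fitted `joint_table`, with attributes `iterations` and
#'   `deviation`.
#' @export
ipf_rake <- function(seed, targets, tol = 1e-10, max_iter = 1000) {
  prob <- seed$prob
  dims <- lapply(targets, function(tg) {
    d <- match(tg$variable, seed$variables)
    if (is.na(d))
      hl_abort(sprintf("target variable '%s' is not a dimension of the seed",
                       tg$variable), "hlmrp_schema_mismatch")
    d
  })
  # feasibility: positive target mass needs positive seed margin
  for (i in seq_along(targets)) {
    m <- apply(prob, dims[[i]], sum)
    tp <- targets[[i]]$proportions[dimnames(prob)[[dims[[i]]]]]
    if (any(tp > 0 & m == 0))
      hl_abort(sprintf(
        "target for '%s' puts mass on a level with zero seed margin",
        targets[[i]]$variable), "hlmrp_ipf_infeasible")
  }
  deviation <- Inf
  it <- 0
  while (it < max_iter) {
    it <- it + 1
    for (i in seq_along(targets)) {
      d <- dims[[i]]
      m <- apply(prob, d, sum)
      tp <- targets[[i]]$proportions[dimnames(prob)[[d]]]
      ratio <- ifelse(m > 0, tp / m, 0)
      prob <- sweep(prob, d, ratio, `*`)
    }
    deviation <- max(vapply(seq_along(targets), function(i) {
      m <- apply(prob, dims[[i]], sum)
      tp <- targets[[i]]$proportions[dimnames(prob)[[dims[[i]]]]]
      max(abs(m - tp))
    }, numeric(1)))
    if (deviation <= tol) break
  }
  if (deviation > tol)
    hl_abort(sprintf(
      "IPF did not converge in %d cycles (final margin deviation %.3g)",
      max_iter, deviation), "hlmrp_ipf_nonconvergence")
  out <- joint_table(seed$variables, prob / sum(prob))
  attr(out, "iterations") <- it
  attr(out, "deviation") <- deviation
  out
}

#' Aggregate a small-area deprivation table to quintile proportions
#'
#' Pools index-of-multiple-deprivation deciles pairwise into quintiles
#' (quintile q pools deciles 2q-1 and 2q) and converts pooled population
#' totals into proportions.
#'
#' @param lsoa data frame with columns `lsoa_id`, `imd_decile` (1..10) and
#'   `population` (nonnegative).
#' @param variable schema name of the deprivation covariate
#'   (default `"imd"`).
#' @param levels quintile level labels (default `q1`..`q5`).
#' @return A `marginal_table` over the five quintiles.
#' @export
aggregate_imd <- function(lsoa, variable = "imd",
                          levels = paste0("q", 1:5)) {
  if (nrow(lsoa) == 0)
    hl_abort("LSOA table is empty", "hlmrp_degenerate_input")
  if (any(!lsoa$imd_decile %in% 1:10))
    hl_abort("IMD deciles must be integers in 1..10", "hlmrp_invalid_input")
  if (any(lsoa$population < 0))
    hl_abort("populations must be nonnegative", "hlmrp_invalid_input")
  total <- sum(lsoa$population)
  if (total == 0)
    hl_abort("total population is zero", "hlmrp_degenerate_input")
  q <- factor(ceiling(lsoa$imd_decile / 2), levels = 1:5)
  pooled <- tapply(lsoa$population, q, sum, default = 0)
  marginal_table(variable, setNames(as.numeric(pooled) / total, levels))
}

#' Post-stratification frame
#'
#' The frame pairs the full cell enumeration of a schema with nonnegative
#' cell weights summing to 1 (each cell's share of the target population).
#'
#' @param cells cell enumeration from [enumerate_cells()].
#' @param weights numeric vector of cell weights.
#' @param schema the `covariate_schema` (defaults to the one attached to
#'   `cells`).
#' @return An object of class `poststrat_frame`.
#' @export
poststrat_frame <- function(cells, weights, schema = attr(cells, "schema")) {
  if (length(weights) != nrow(cells))
    hl_abort("weight length must equal cell count", "hlmrp_invalid_frame")
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-12)
    hl_abort("frame weights must be nonnegative and sum to 1",
             "hlmrp_invalid_frame")
  structure(list(cells = cells, weights = as.numeric(weights),
                 schema = schema),
            class = "poststrat_frame")
}

#' @export
print.poststrat_frame <- function(x, ...) {
  cat("Post-stratification frame:", nrow(x$cells), "cells over",
      length(x$schema$variables), "covariates\n")
  invisible(x)
}

#' Combine disjoint covariate blocks into a post-stratification frame
#'
#' Each block is a joint (or marginal) distribution over a subset of the
#' schema's covariates; the blocks must partition the schema.  Cell
#' weights are the products of the block probabilities for the cell's
#' level assignment, i.e. the blocks are combined under mutual
#' independence.
#'
#' @param blocks list of `joint_table` / `marginal_table` objects.
#' @param schema a `covariate_schema`.
#' @return A `poststrat_frame`.
#' @export
combine_blocks <- function(blocks, schema) {
  blocks <- lapply(blocks, as_joint)
  covered <- unlist(lapply(blocks, `[[`, "variables"))
  if (anyDuplicated(covered) ||
      !setequal(covered, schema_names(schema)) ||
      length(covered) != length(schema_names(schema)))
    hl_abort("blocks must cover disjoint variable sets whose union is the schema",
             "hlmrp_block_coverage")
  cells <- enumerate_cells(schema)
  w <- rep(1, nrow(cells))
  for (b in blocks) {
    if (length(b$variables) == 1)
      w <- w * as.numeric(b$prob[cells[[b$variables]]])
    else
      w <- w * b$prob[as.matrix(cells[b$variables])]
  }
  poststrat_frame(cells, w / sum(w), schema)
}

#' Marginalise a frame (or frame weights) onto a covariate subset
#'
#' @param frame a `poststrat_frame`.
#' @param variables covariates to keep.
#' @return A `joint_table` over `variables` (a `marginal_table` if one
#'   variable is requested).
#' @export
frame_margin <- function(frame, variables) {
  fs <- lapply(variables, function(v)
    factor(frame$cells[[v]], levels = schema_levels(frame$schema, v)))
  names(fs) <- variables
  tab <- as.array(tapply(frame$weights, fs, sum, default = 0))
  if (length(variables) == 1)
    marginal_table(variables, setNames(as.numeric(tab), dimnames(tab)[[1]]))
  else joint_table(variables, tab / sum(tab))
}

#' Build the target-population frame from its component sources
#'
#' Estimates the joint distribution of the covariates observed in the
#' target-area microdata, rakes the joint estimated from the auxiliary
#' microdata to the target-area margins, aggregates the small-area
#' deprivation table to quintile proportions, and combines the three
#' blocks under mutual independence.
#'
#' @param schema a `covariate_schema`.
#' @param target_microdata data frame over the target-area covariate block.
#' @param target_variables names of the covariates in `target_microdata`.
#' @param aux_microdata data frame over the remaining (auxiliary) block.
#' @param aux_variables names of the covariates in `aux_microdata`.
#' @param aux_target_margins list of `marginal_table`s giving the
#'   target-area margins the auxiliary joint is raked to.
#' @param lsoa_table small-area deprivation table (see [aggregate_imd()]).
#' @param record_weights optional weights for the target microdata records.
#' @param tol,max_iter raking controls passed to [ipf_rake()].
#' @return A `poststrat_frame`.
#' @export
build_poststrat_frame <- function(schema, target_microdata, target_variables,
                                  aux_microdata, aux_variables,
                                  aux_target_margins, lsoa_table,
                                  record_weights = NULL,
                                  tol = 1e-10, max_iter = 1000) {
  target_joint <- estimate_joint_from_microdata(
    target_microdata, target_variables, schema, record_weights)
  aux_seed <- estimate_joint_from_microdata(aux_microdata, aux_variables, schema)
  aux_joint <- ipf_rake(aux_seed, aux_target_margins,
                        tol = tol, max_iter = max_iter)
  imd_margin <- aggregate_imd(lsoa_table)
  combine_blocks(list(target_joint, aux_joint, imd_margin), schema)
}

#' Export / import a post-stratification frame as CSV
#'
#' One column per covariate plus a `weight` column; row order is the
#' [enumerate_cells()] order.
#'
#' @param frame a `poststrat_frame`.
#' @param path CSV file path.
#' @param schema schema used to validate on read.
#' @return `read_frame_csv()` returns a `poststrat_frame`.
#' @export
write_frame_csv <- function(frame, path) {
  df <- cbind(frame$cells, weight = frame$weights)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_frame_csv
#' @export
read_frame_csv <- function(path, schema) {
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(setNames(rep("character",
                                             length(schema_names(schema))),
                                         schema_names(schema)),
                                weight = "numeric"))
  cells <- enumerate_cells(schema)
  idx <- cell_index(cells, df[schema_names(schema)])
  w <- numeric(nrow(cells))
  w[idx] <- df$weight
  poststrat_frame(cells, w / sum(w), schema)
}
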