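#' Counterfactual post-stratification frame
#'
#' Moves, within every stratum of the remaining covariates, all of that
#' stratum's weight onto the cell where `variable = level` — the frame of
#' a population in which everyone is assigned the focal level while the
#' joint distribution of all other covariates is unchanged.
#'
#' @param frame a `poststrat_frame`.
#' @param variable focal covariate.
#' @param level level everyone is assigned to.
#' @return A `poststrat_frame` with the same cell enumeration.
#' @export
counterfactual_frame <- function(frame, variable, level) {
  if (!variable %in% schema_names(frame$schema))
    hl_abort(sprintf("unknown variable '%s'", variable),
             "hlmrp_schema_mismatch")
  if (!level %in% schema_levels(frame$schema, variable))
    hl_abort(sprintf("unknown level '%s' of '%s'", level, variable),
             "hlmrp_schema_mismatch")
  others <- setdiff(names(frame$cells), variable)
  stratum <- if (length(others)) cell_paste_key(frame$cells[others])
             else rep("", nrow(frame$cells))
  stratum_total <- stats::ave(frame$weights, stratum, FUN = sum)
  w <- ifelse(frame$cells[[variable]] == level, stratum_total, 0)
  poststrat_frame(frame$cells, w, frame$schema)
}

#' Per-draw counterfactual average treatment effect (MRP-ATE)
#'
#' For each posterior draw, the post-stratified prevalence when everyone
#' is assigned `level` minus the prevalence when everyone is assigned
#' `reference`, averaging over the target-population distribution of the
#' remaining covariates.  With the outcome coded as probability of *not*
#' being health literate, negative values are improvements.
#'
#' @param preds a `cell_predictions` matrix.
#' @param frame a `poststrat_frame`.
#' @param variable focal covariate.
#' @param level "treated" level.
#' @param reference comparator level (default: the schema's reference).
#' @return An object of class `ate_draws`: list with `draws` (one value
#'   per posterior draw) and the contrast metadata.
#' @export
mrp_ate <- function(preds, frame, variable, level, reference = NULL) {
  if (is.null(reference))
    reference <- schema_reference(frame$schema, variable)
  if (identical(level, reference))
    hl_abort("level and reference must differ", "hlmrp_config_error")
  p1 <- poststratify(preds, counterfactual_frame(frame, variable, level))
  p0 <- poststratify(preds, counterfactual_frame(frame, variable, reference))
  structure(list(draws = p1 - p0, variable = variable, level = level,
                 reference = reference),
            class = "ate_draws")
}

#' @export
print.ate_draws <- function(x, ...) {
  s <- summarize_ate(x)
  cat(sprintf("MRP-ATE %s: %s vs %s  %.3f [%.3f, %.3f] (%d draws)\n",
              x$variable, x$level, x$reference,
              s$mean, s$lower95, s$upper95, length(x$draws)))
  invisible(x)
}

#' Summarise ATE draws
#'
#' Posterior mean and equal-tailed 95% interval (2.5% and 97.5% empirical
#' quantiles, linear-interpolation rule, `stats::quantile` type 7).
#'
#' @param d an `ate_draws` (or bare numeric vector of draws).
#' @param round_dp optional decimal places for reporting; `NULL` keeps
#'   full precision.
#' @return One-row data frame with columns `mean`, `lower95`, `upper95`.
#' @export
summarize_ate <- function(d, round_dp = NULL) {
  x <- if (inherits(d, "ate_draws")) d$draws else as.numeric(d)
  if (length(x) < 2)
    hl_abort("need at least 2 draws to summarise", "hlmrp_input_error")
  q <- unname(quantile(x, c(0.025, 0.975), type = 7))
  out <- data.frame(mean = mean(x), lower95 = q[1], upper95 = q[2])
  if (!is.null(round_dp)) out[] <- lapply(out, round, digits = round_dp)
  out
}

#' All non-reference contrasts of a schema
#'
#' @param schema a `covariate_schema`.
#' @return Data frame with columns `variable`, `level`, `reference` — one
#'   row per ranked item.
#' @export
contrast_table <- function(schema) {
  rows <- do.call(rbind, lapply(schema$variables, function(v) {
    data.frame(variable = v$name, level = setdiff(v$levels, v$reference),
               reference = v$reference, stringsAsFactors = FALSE)
  }))
  rownames(rows) <- NULL
  rows
}

#' MRP-ATE draws and summaries for every non-reference covariate level
#'
#' @param preds a `cell_predictions` matrix.
#' @param frame a `poststrat_frame`.
#' @param outcome outcome label carried into the summary table.
#' @param round_dp reporting rounding for the summary (default 3 dp);
#'   draws are kept at full precision.
#' @return List with `draws` (draws x contrasts matrix of ATE values),
#'   `contrasts` (the contrast table) and `summary` (data frame with
#'   columns outcome, variable, level, mean, lower95, upper95, unrounded,
#'   plus rounded columns `mean_r`, `lower95_r`, `upper95_r`).
#' @export
ate_table <- function(preds, frame, outcome = "outcome", round_dp = 3) {
  ct <- contrast_table(frame$schema)
  mat <- vapply(seq_len(nrow(ct)), function(i)
    mrp_ate(preds, frame, ct$variable[i], ct$level[i])$draws,
    numeric(nrow(preds)))
  colnames(mat) <- paste0(ct$variable, ":", ct$level)
  sm <- do.call(rbind, lapply(seq_len(ncol(mat)), function(i)
    summarize_ate(mat[, i])))
  summary <- cbind(data.frame(outcome = outcome, variable = ct$variable,
                              level = ct$level, stringsAsFactors = FALSE),
                   sm,
                   mean_r = round(sm$mean, round_dp),
                   lower95_r = round(sm$lower95, round_dp),
                   upper95_r = round(sm$upper95, round_dp))
  rownames(summary) <- NULL
  list(draws = mat, contrasts = ct, summary = summary)
}

#' Analytic MRP-ATE under ground-truth parameters
#'
#' Enumerates the true-parameter cell probabilities over the frame and
#' takes the weighted counterfactual difference — the target the
#' posterior-mean MRP-ATE should recover on synthetic data.
#'
#' @param params a `true_params`.
#' @param frame a `poststrat_frame`.
#' @param variable,level focal contrast.
#' @param reference comparator (default: schema reference).
#' @return Single numeric ATE value.
#' @export
analytic_mrp_ate <- function(params, frame, variable, level,
                             reference = NULL) {
  if (is.null(reference))
    reference <- schema_reference(frame$schema, variable)
  cells1 <- frame$cells
  cells1[[variable]] <- level
  cells0 <- frame$cells
  cells0[[variable]] <- reference
  p1 <- plogis(linear_predictor(params, cells1))
  p0 <- plogis(linear_predictor(params, cells0))
  sum(frame$weights * (p1 - p0))
}
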