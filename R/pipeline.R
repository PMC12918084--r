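#' Pipeline configuration
#'
#' @param mode `"synthetic"` (inputs generated from `seed`) or `"files"`
#'   (inputs read from `paths`).
#' @param seed master seed (required in synthetic mode; also seeds MCMC).
#' @param outcomes outcomes to analyse.
#' @param schema a `covariate_schema`.
#' @param priors a [prior_spec()].
#' @param mcmc an [mcmc_settings()] (default: the `"test"` profile).
#' @param n_source,n_target,n_lfs,n_lsoa synthetic input sizes.
#' @param round_dp reporting rounding (default 3).
#' @param rank_top_ranks,rank_min_prob rankogram filter (defaults 4, 0.25).
#' @param paths named list of input files for files mode:
#'   `source_survey`, `target_microdata`, `lfs_microdata`,
#'   `lfs_target_margins`, `lsoa_table`, `schema` (as written by
#'   [write_bundle_csv()]).
#' @param outdir output directory, or `NULL` to skip writing.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("synthetic", "files"), seed = 1,
                            outcomes = c("literacy", "numeracy", "ict"),
                            schema = default_schema(),
                            priors = prior_spec(),
                            mcmc = mcmc_profile("test", seed = seed),
                            n_source = 4000, n_target = 3000,
                            n_lfs = 3000, n_lsoa = 164,
                            round_dp = 3, rank_top_ranks = 4,
                            rank_min_prob = 0.25,
                            paths = NULL, outdir = NULL) {
  mode <- match.arg(mode)
  if (mode == "synthetic" && is.null(seed))
    hl_abort("synthetic mode requires a seed", "hlmrp_config_error")
  if (mode == "files") {
    needed <- c("source_survey", "target_microdata", "lfs_microdata",
                "lfs_target_margins", "lsoa_table", "schema")
    for (nm in needed) {
      if (is.null(paths[[nm]]))
        hl_abort(sprintf("files mode requires path '%s'", nm),
                 "hlmrp_config_error")
      if (!file.exists(paths[[nm]]))
        hl_abort(sprintf("input file not found: %s", paths[[nm]]),
                 "hlmrp_config_error")
    }
  }
  structure(list(mode = mode, seed = seed, outcomes = outcomes,
                 schema = schema, priors = priors, mcmc = mcmc,
                 n_source = n_source, n_target = n_target, n_lfs = n_lfs,
                 n_lsoa = n_lsoa, round_dp = round_dp,
                 rank_top_ranks = rank_top_ranks,
                 rank_min_prob = rank_min_prob,
                 paths = paths, outdir = outdir),
            class = "pipeline_config")
}

# read the file-mode inputs written by write_bundle_csv()
read_pipeline_inputs <- function(paths) {
  schema <- read_schema(paths$schema)
  df <- read.csv(paths$source_survey, stringsAsFactors = FALSE)
  ycols <- grep("^y_", names(df), value = TRUE)
  outcomes <- lapply(ycols, function(cl) {
    idx <- which(!is.na(df[[cl]]))
    list(idx = idx, y = df[[cl]][idx])
  })
  names(outcomes) <- sub("^y_", "", ycols)
  survey <- structure(list(covariates = df[setdiff(names(df), ycols)],
                           outcomes = outcomes, schema = schema,
                           n = nrow(df)),
                      class = "source_survey")
  margins <- lapply(jsonlite::read_json(paths$lfs_target_margins),
                    function(m) marginal_table(m$variable,
                                               unlist(m$proportions)))
  list(schema = schema, source_survey = survey,
       target_microdata = read.csv(paths$target_microdata,
                                   stringsAsFactors = FALSE),
       lfs_microdata = read.csv(paths$lfs_microdata,
                                stringsAsFactors = FALSE),
       lfs_margins = margins,
       lsoa_table = read.csv(paths$lsoa_table, stringsAsFactors = FALSE))
}

#' Compare source-survey and target-population demographics
#'
#' For every covariate level: the proportion in each outcome's source
#' subsample, the target-population proportion (frame margin), and the
#' difference (target minus source) — the dumbbell-plot table that
#' motivates post-stratification.
#'
#' @param survey a `source_survey`.
#' @param frame a `poststrat_frame` over the same schema.
#' @return Long data frame with columns `variable`, `level`, `outcome`,
#'   `source_prop`, `target_prop`, `difference`.
#' @export
compare_demographics <- function(survey, frame) {
  schema <- frame$schema
  if (!setequal(names(survey$covariates), schema_names(schema)))
    hl_abort("survey and frame cover different covariates",
             "hlmrp_schema_mismatch")
  rows <- list()
  for (v in schema_names(schema)) {
    lv <- schema_levels(schema, v)
    tprop <- frame_margin(frame, v)$proportions[lv]
    for (oc in names(survey$outcomes)) {
      x <- survey$covariates[[v]][survey$outcomes[[oc]]$idx]
      sprop <- as.numeric(table(factor(x, levels = lv))) / length(x)
      rows[[length(rows) + 1]] <- data.frame(
        variable = v, level = lv, outcome = oc, source_prop = sprop,
        target_prop = as.numeric(tprop),
        difference = as.numeric(tprop) - sprop,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the full MRP / ATE / ranking pipeline
#'
#' Stages: input generation (or file ingest), frame construction (joint
#' estimation, raking, deprivation aggregation, block combination),
#' per-outcome model fit, cell prediction and post-stratification,
#' counterfactual ATEs for every non-reference level, probabilistic
#' ranking, and report assembly.  Fully reproducible from the config:
#' every random stage is driven by `config$seed`.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress stage messages.
#' @return An object of class `report_bundle`: list with `ate` (summary
#'   table), `ate_draws` (per outcome), `sucra`, `rankogram`,
#'   `rankogram_full`, `prevalence`, `comparison`, `frame`, `fits`,
#'   `manifest`.  If `config$outdir` is set the tables are also written
#'   as CSV plus a JSON manifest.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) hl_abort(
      sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
      "hlmrp_stage_error"))
  }

  say("stage: inputs (%s mode)", config$mode)
  inputs <- stage("inputs", {
    if (config$mode == "synthetic") {
      b <- make_default_bundle(config$seed, n_source = config$n_source,
                               n_target = config$n_target,
                               n_lfs = config$n_lfs,
                               n_lsoa = config$n_lsoa,
                               schema = config$schema)
      list(schema = b$schema, source_survey = b$source_survey,
           target_microdata = b$target_microdata,
           lfs_microdata = b$lfs_microdata, lfs_margins = b$lfs_margins,
           lsoa_table = b$lsoa_table, bundle = b)
    } else read_pipeline_inputs(config$paths)
  })
  schema <- inputs$schema

  say("stage: frame")
  frame <- stage("frame", build_poststrat_frame(
    schema, inputs$target_microdata,
    c("age", "sex", "ethnicity", "working", "ownhome"),
    inputs$lfs_microdata,
    c("qualification", "english", "ukborn", "job", "income"),
    inputs$lfs_margins, inputs$lsoa_table))

  cells <- frame$cells
  fits <- list(); ates <- list(); sucras <- list()
  rankos <- list(); rankos_full <- list(); prev <- list()
  for (i in seq_along(config$outcomes)) {
    oc <- config$outcomes[i]
    say("stage: fit (%s)", oc)
    settings <- config$mcmc
    settings$seed <- config$mcmc$seed + i - 1 # distinct MCMC seed per outcome
    fit <- stage(paste0("fit:", oc),
                 fit_mrp(inputs$source_survey, oc, schema,
                         priors = config$priors, settings = settings))
    say("stage: predict/poststratify (%s)", oc)
    preds <- stage(paste0("predict:", oc), predict_cells(fit, cells))
    pi_mrp <- poststratify(preds, frame)
    say("stage: ate (%s)", oc)
    at <- stage(paste0("ate:", oc),
                ate_table(preds, frame, outcome = oc,
                          round_dp = config$round_dp))
    say("stage: rank (%s)", oc)
    profile <- cumulative_rank_probs(rank_draws(at$draws))
    su <- sucra(profile)
    su$outcome <- oc
    su$variable <- at$contrasts$variable
    su$level <- at$contrasts$level
    ro <- rankogram_table(profile, config$rank_top_ranks,
                          config$rank_min_prob)
    ro$outcome <- oc
    rof <- rankogram_table(profile, profile$n, 0)
    rof$outcome <- oc
    fits[[oc]] <- fit; ates[[oc]] <- at; sucras[[oc]] <- su
    rankos[[oc]] <- ro; rankos_full[[oc]] <- rof
    prev[[oc]] <- data.frame(
      outcome = oc, mean = mean(pi_mrp),
      lower95 = unname(quantile(pi_mrp, 0.025, type = 7)),
      upper95 = unname(quantile(pi_mrp, 0.975, type = 7)),
      stringsAsFactors = FALSE)
  }

  say("stage: comparison")
  comparison <- stage("comparison",
                      compare_demographics(inputs$source_survey, frame))

  manifest <- list(
    package_version = as.character(utils::packageVersion("hlmrp")),
    mode = config$mode, seed = config$seed,
    mcmc = unclass(config$mcmc), priors = unclass(config$priors),
    outcomes = config$outcomes,
    sizes = list(n_source = config$n_source, n_target = config$n_target,
                 n_lfs = config$n_lfs, n_lsoa = config$n_lsoa),
    n_cells = nrow(cells),
    diagnostics = lapply(fits, function(f)
      list(max_rhat = max(f$diagnostics$rhat),
           min_ess = min(f$diagnostics$ess))))

  bundle <- structure(list(
    ate = do.call(rbind, lapply(ates, `[[`, "summary")),
    ate_draws = lapply(ates, `[[`, "draws"),
    sucra = do.call(rbind, sucras),
    rankogram = do.call(rbind, rankos),
    rankogram_full = do.call(rbind, rankos_full),
    prevalence = do.call(rbind, prev),
    comparison = comparison, frame = frame, fits = fits,
    manifest = manifest), class = "report_bundle")
  rownames(bundle$ate) <- rownames(bundle$sucra) <- NULL
  rownames(bundle$rankogram) <- rownames(bundle$rankogram_full) <- NULL
  rownames(bundle$prevalence) <- NULL

  if (!is.null(config$outdir)) {
    say("stage: report -> %s", config$outdir)
    write_report_bundle(bundle, config$outdir)
  }
  bundle
}

#' Write a report bundle's tables to disk
#'
#' CSV tables (effect estimates in long forest-plot form, SUCRA, filtered
#' and full rankograms, prevalences, demographic comparison, the frame)
#' plus a JSON manifest recording seeds, settings and diagnostics.
#'
#' @param bundle a `report_bundle`.
#' @param dir output directory (created if missing).
#' @return Invisibly, the directory.
#' @export
write_report_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, name)
    write.csv(df, file.path(dir, name), row.names = FALSE, quote = FALSE)
  wr(bundle$ate, "ate_table.csv")
  wr(bundle$ate[c("outcome", "variable", "level", "mean", "lower95",
                  "upper95")], "forest_data.csv")
  wr(bundle$sucra[c("variable", "level", "outcome", "sucra",
                    "expected_rank", "sucra_pct", "expected_rank_r")],
     "sucra_table.csv")
  wr(bundle$rankogram, "rankogram.csv")
  wr(bundle$rankogram_full, "rankogram_full.csv")
  wr(bundle$prevalence, "mrp_prevalence.csv")
  wr(bundle$comparison, "demographic_comparison.csv")
  write_frame_csv(bundle$frame, file.path(dir, "poststrat_frame.csv"))
  jsonlite::write_json(bundle$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("MRP report bundle:\n")
  cat("  outcomes:", paste(unique(x$ate$outcome), collapse = ", "), "\n")
  cat("  contrasts per outcome:", sum(x$ate$outcome == x$ate$outcome[1]),
      "\n")
  cat("  post-stratified prevalence:\n")
  for (i in seq_len(nrow(x$prevalence)))
    cat(sprintf("    %-9s %.3f [%.3f, %.3f]\n", x$prevalence$outcome[i],
                x$prevalence$mean[i], x$prevalence$lower95[i],
                x$prevalence$upper95[i]))
  invisible(x)
}
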