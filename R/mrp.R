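#' Prior specification for the multilevel logistic model
#'
#' Weakly informative defaults: Normal(0, 2.5) for the intercept and fixed
#' effects, Normal(0, 2.5) for the group-effect mean, HalfNormal(1) for
#' the group-effect standard deviation.  `flat = TRUE` switches to very
#' diffuse (effectively flat) normals, sd 100 (scale 50 for the group sd).
#'
#' @param fixed_effect_sd,intercept_sd,imd_mu_sd normal prior sds.
#' @param imd_sigma_scale half-normal scale of the group sd.
#' @param flat use effectively flat priors instead.
#' @return An object of class `prior_spec`.
#' @export
prior_spec <- function(fixed_effect_sd = 2.5, intercept_sd = 2.5,
                       imd_sigma_scale = 1, imd_mu_sd = 2.5, flat = FALSE) {
  if (flat) {
    fixed_effect_sd <- 100; intercept_sd <- 100
    imd_mu_sd <- 100; imd_sigma_scale <- 50
  }
  if (any(c(fixed_effect_sd, intercept_sd, imd_sigma_scale, imd_mu_sd) <= 0))
    hl_abort("prior scales must be positive", "hlmrp_config_error")
  structure(list(fixed_effect_sd = fixed_effect_sd,
                 intercept_sd = intercept_sd,
                 imd_sigma_scale = imd_sigma_scale,
                 imd_mu_sd = imd_mu_sd, flat = flat),
            class = "prior_spec")
}

#' MCMC settings
#'
#' @param chains number of chains (default 4).
#' @param warmup warmup iterations per chain (default 1000).
#' @param draws retained iterations per chain (default 1000).
#' @param seed integer seed.
#' @param rhat_threshold convergence warning threshold (default 1.01).
#' @return An object of class `mcmc_settings`.
#' @export
mcmc_settings <- function(chains = 4, warmup = 1000, draws = 1000, seed = 1,
                          rhat_threshold = 1.01) {
  if (chains < 1 || draws <= 0 || warmup < 0)
    hl_abort("invalid MCMC settings", "hlmrp_config_error")
  structure(list(chains = chains, warmup = warmup, draws = draws,
                 seed = seed, rhat_threshold = rhat_threshold),
            class = "mcmc_settings")
}

#' Preset MCMC profiles
#'
#' `"full"` is 4 chains x 1000 warmup x 1000 draws; `"test"` is the
#' desk-scale 2 x 500 x 500 profile; `"smoke"` is 2 x 250 x 250 for quick
#' end-to-end runs.
#'
#' @param profile one of `"full"`, `"test"`, `"smoke"`.
#' @param seed integer seed.
#' @return An `mcmc_settings`.
#' @export
mcmc_profile <- function(profile = c("full", "test", "smoke"), seed = 1) {
  profile <- match.arg(profile)
  switch(profile,
         full  = mcmc_settings(4, 1000, 1000, seed),
         test  = mcmc_settings(2, 500, 500, seed),
         smoke = mcmc_settings(2, 250, 250, seed))
}

# split-chain potential scale reduction factor (classic R-hat on
# half-chains)
split_rhat <- function(mat_list) {
  halves <- list()
  for (m in mat_list) {
    n <- nrow(m)
    h <- floor(n / 2)
    halves <- c(halves, list(m[seq_len(h), , drop = FALSE],
                             m[(n - h + 1):n, , drop = FALSE]))
  }
  n <- nrow(halves[[1]])
  vapply(seq_len(ncol(halves[[1]])), function(j) {
    ch <- vapply(halves, function(h) mean(h[, j]), numeric(1))
    vj <- vapply(halves, function(h) var(h[, j]), numeric(1))
    W <- mean(vj)
    B <- n * var(ch)
    if (W <= 0) return(1)
    sqrt(((n - 1) / n * W + B / n) / W)
  }, numeric(1))
}

# effective sample size via Geyer's initial positive sequence, summed
# over chains
ess_geyer <- function(mat_list) {
  vapply(seq_len(ncol(mat_list[[1]])), function(j) {
    sum(vapply(mat_list, function(m) {
      x <- m[, j]
      n <- length(x)
      v <- var(x)
      if (v <= 0) return(n)
      ac <- stats::acf(x, lag.max = min(n - 1, 200), plot = FALSE,
                       demean = TRUE)$acf[-1]
      s <- 0
      k <- 1
      while (k < length(ac)) {
        pair <- ac[k] + ac[k + 1]
        if (pair < 0) break
        s <- s + pair
        k <- k + 2
      }
      n / (1 + 2 * s)
    }, numeric(1)))
  }, numeric(1))
}

#' Fit the Bayesian multilevel logistic model to a source survey outcome
#'
#' The model is `y ~ Bernoulli(logit^-1(b0 + sum_x b_x[level] + u[imd]))`
#' with reference-level coefficients pinned at 0 and partially pooled
#' deprivation-quintile effects `u_j ~ N(mu, sigma^2)`.  Sampling uses a
#' Polya-Gamma data-augmentation Gibbs sampler (compiled); records are
#' first aggregated to binomial counts per unique covariate pattern.
#' Convergence diagnostics (split R-hat, effective sample size) are
#' computed per parameter and a warning is raised if any R-hat exceeds
#' the threshold.
#'
#' @param survey a `source_survey` (or any list with the same shape).
#' @param outcome outcome name (e.g. `"literacy"`).
#' @param schema a `covariate_schema`; its `imd` variable is the
#'   random-effect grouping.
#' @param priors a [prior_spec()].
#' @param settings an [mcmc_settings()].
#' @param imd_variable name of the grouped covariate (default `"imd"`).
#' @return An object of class `posterior_draws`: draw matrix (chains
#'   stacked) with named columns (`intercept`, `var:level` fixed effects,
#'   `imd_mu`, `imd_sigma`, `imd:qx` group effects), plus diagnostics and
#'   the fixed-effect term map.
#' @export
fit_mrp <- function(survey, outcome, schema, priors = prior_spec(),
                    settings = mcmc_settings(), imd_variable = "imd") {
  oc <- survey$outcomes[[outcome]]
  if (is.null(oc) || length(oc$idx) == 0)
    hl_abort(sprintf("outcome '%s' has an empty subsample", outcome),
             "hlmrp_data_error")
  y <- oc$y
  if (length(unique(y)) < 2)
    hl_abort(sprintf("outcome '%s' has a single class; model is separable",
                     outcome), "hlmrp_separation_error")
  covs <- survey$covariates[oc$idx, , drop = FALSE]
  miss <- setdiff(schema_names(schema), names(covs))
  if (length(miss))
    hl_abort(paste("missing covariates:", paste(miss, collapse = ", ")),
             "hlmrp_data_error")

  fe_map <- fixed_effect_map(schema, imd_variable)
  X <- design_matrix(covs, schema, fe_map, imd_variable)
  gl <- schema_levels(schema, imd_variable)
  g <- match(covs[[imd_variable]], gl)

  # sufficient statistics: binomial counts per unique covariate pattern
  key <- paste(cell_paste_key(covs[schema_names(schema)]))
  agg <- rowsum(cbind(succ = y, trials = 1), key)
  first <- match(rownames(agg), key)
  Xa <- X[first, , drop = FALSE]
  ga <- g[first]
  J <- length(gl)
  Z <- cbind(1, Xa, outer(ga, seq_len(J), `==`) * 1)

  n_fixed <- ncol(Xa)
  draws_list <- with_seed(settings$seed, {
    lapply(seq_len(settings$chains), function(ch) {
      theta0 <- c(stats::rnorm(1 + n_fixed, 0, 0.1), stats::rnorm(J, 0, 0.1))
      pg_gibbs_chain(Z, agg[, "succ"], agg[, "trials"], n_fixed, J,
                     priors$intercept_sd, priors$fixed_effect_sd,
                     priors$imd_mu_sd, priors$imd_sigma_scale,
                     settings$warmup, settings$draws, theta0,
                     stats::rnorm(1, 0, 0.1),
                     abs(stats::rnorm(1, 0.5, 0.1)))
    })
  })
  pnames <- c("intercept",
              paste0(fe_map$variable, ":", fe_map$level),
              paste0(imd_variable, ":", gl), "imd_mu", "imd_sigma")
  # reorder chain columns: sampler returns theta, mu, sigma
  draws_list <- lapply(draws_list, function(m) {
    colnames(m) <- pnames
    m
  })
  draws <- do.call(rbind, draws_list)
  rhat <- split_rhat(draws_list)
  ess <- ess_geyer(draws_list)
  diagnostics <- data.frame(parameter = pnames, rhat = rhat, ess = ess,
                            stringsAsFactors = FALSE)
  if (max(rhat, na.rm = TRUE) > settings$rhat_threshold)
    warning(sprintf("max split R-hat %.3f exceeds threshold %.2f (%s)",
                    max(rhat), settings$rhat_threshold,
                    pnames[which.max(rhat)]))
  structure(list(draws = draws, fe_map = fe_map, schema = schema,
                 outcome = outcome, imd_variable = imd_variable,
                 imd_levels = gl, diagnostics = diagnostics,
                 settings = settings, priors = priors),
            class = "posterior_draws")
}

#' @export
print.posterior_draws <- function(x, ...) {
  cat(sprintf("Posterior draws for outcome '%s': %d draws x %d parameters\n",
              x$outcome, nrow(x$draws), ncol(x$draws)))
  cat(sprintf("  max split R-hat %.3f, min ESS %.0f\n",
              max(x$diagnostics$rhat), min(x$diagnostics$ess)))
  invisible(x)
}

# map of fixed-effect terms: one row per non-reference level of every
# covariate except the grouped one
fixed_effect_map <- function(schema, imd_variable = "imd") {
  rows <- do.call(rbind, lapply(schema$variables, function(v) {
    if (v$name == imd_variable) return(NULL)
    lv <- setdiff(v$levels, v$reference)
    data.frame(variable = v$name, level = lv, stringsAsFactors = FALSE)
  }))
  rownames(rows) <- NULL
  rows
}

# dummy design matrix over the fixed-effect terms
design_matrix <- function(records, schema, fe_map, imd_variable = "imd") {
  X <- matrix(0, nrow(records), nrow(fe_map))
  colnames(X) <- paste0(fe_map$variable, ":", fe_map$level)
  for (k in seq_len(nrow(fe_map)))
    X[, k] <- as.numeric(records[[fe_map$variable[k]]] == fe_map$level[k])
  X
}

#' Posterior cell-level probabilities
#'
#' For every posterior draw and every post-stratification cell, computes
#' `logit^-1(intercept + fixed effects of the cell's levels + group
#' effect of the cell's quintile)`.
#'
#' @param draws a `posterior_draws`.
#' @param cells a cell enumeration from [enumerate_cells()] (or the
#'   `cells` of a frame).
#' @return A draws x cells matrix of probabilities (class
#'   `cell_predictions`), aligned to the row order of `cells`.
#' @export
predict_cells <- function(draws, cells) {
  miss <- setdiff(c(draws$fe_map$variable, draws$imd_variable), names(cells))
  if (length(miss))
    hl_abort(paste("cells lack model covariates:",
                   paste(miss, collapse = ", ")), "hlmrp_alignment_error")
  X <- design_matrix(cells, draws$schema, draws$fe_map, draws$imd_variable)
  g <- match(cells[[draws$imd_variable]], draws$imd_levels)
  if (anyNA(g))
    hl_abort("cell level absent from draw coefficients",
             "hlmrp_alignment_error")
  fe_cols <- paste0(draws$fe_map$variable, ":", draws$fe_map$level)
  u_cols <- paste0(draws$imd_variable, ":", draws$imd_levels)
  eta <- draws$draws[, "intercept"] +
    draws$draws[, fe_cols, drop = FALSE] %*% t(X) +
    draws$draws[, u_cols, drop = FALSE][, g, drop = FALSE]
  p <- plogis(eta)
  class(p) <- c("cell_predictions", class(p))
  attr(p, "cell_key") <- cell_paste_key(cells)
  p
}

#' Post-stratify cell predictions over a frame
#'
#' Per posterior draw, the weighted mean of cell probabilities with the
#' frame's cell weights: the small-area prevalence estimate.
#'
#' @param preds a `cell_predictions` matrix (draws x cells).
#' @param frame a `poststrat_frame` sharing the cell enumeration.
#' @return Numeric vector with one post-stratified prevalence per draw.
#' @export
poststratify <- function(preds, frame) {
  if (ncol(preds) != nrow(frame$cells))
    hl_abort("predictions and frame have different cell counts",
             "hlmrp_alignment_error")
  key <- attr(preds, "cell_key")
  if (!is.null(key) && !identical(key, cell_paste_key(frame$cells)))
    hl_abort("predictions and frame are aligned to different cell orders",
             "hlmrp_alignment_error")
  as.numeric(preds %*% frame$weights)
}

#' Persist posterior draws as CSV with a JSON diagnostics sidecar
#'
#' One row per draw, one column per parameter; the model configuration is
#' echoed into commented header lines for provenance.  The sidecar
#' (`<path>.diagnostics.json`) carries split R-hat and effective sample
#' size per parameter.
#'
#' @param draws a `posterior_draws`.
#' @param path CSV file path.
#' @return Invisibly, `path`.
#' @export
write_posterior_csv <- function(draws, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# outcome: %s", draws$outcome), con)
  writeLines(sprintf("# chains: %d warmup: %d draws: %d seed: %d",
                     draws$settings$chains, draws$settings$warmup,
                     draws$settings$draws, draws$settings$seed), con)
  writeLines(sprintf(
    "# priors: fixed_sd=%g intercept_sd=%g imd_sigma_scale=%g imd_mu_sd=%g",
    draws$priors$fixed_effect_sd, draws$priors$intercept_sd,
    draws$priors$imd_sigma_scale, draws$priors$imd_mu_sd), con)
  utils::write.csv(as.data.frame(draws$draws), con, row.names = FALSE,
                   quote = FALSE)
  jsonlite::write_json(draws$diagnostics,
                       paste0(path, ".diagnostics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read posterior draws written by [write_posterior_csv()]
#'
#' Reconstructs a usable `posterior_draws` (draw matrix plus term map)
#' given the schema the model was fitted under.
#'
#' @param path CSV file path.
#' @param schema the `covariate_schema` of the fit.
#' @param imd_variable grouped covariate name (default `"imd"`).
#' @return A `posterior_draws`.
#' @export
read_posterior_csv <- function(path, schema, imd_variable = "imd") {
  hdr <- readLines(path, n = 10)
  outcome <- sub("^# outcome: ", "", hdr[grepl("^# outcome:", hdr)][1])
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  m <- as.matrix(df)
  diag_path <- paste0(path, ".diagnostics.json")
  diagnostics <- if (file.exists(diag_path)) {
    d <- jsonlite::read_json(diag_path, simplifyVector = TRUE)
    as.data.frame(d)
  } else data.frame(parameter = colnames(m), rhat = NA_real_,
                    ess = NA_real_)
  structure(list(draws = m, fe_map = fixed_effect_map(schema, imd_variable),
                 schema = schema, outcome = outcome,
                 imd_variable = imd_variable,
                 imd_levels = schema_levels(schema, imd_variable),
                 diagnostics = diagnostics),
            class = "posterior_draws")
}
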