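# Independent brute-force oracles and small fixture builders.  Every
# oracle recomputes its quantity by explicit looping, independent of the
# package's vectorised implementations.

# small schema with a grouped deprivation-like covariate
toy_schema <- function() {
  covariate_schema(list(
    t = c("a", "b"),
    x = c("lo", "hi"),
    imd = c("q1", "q2", "q3")))
}

# posterior_draws-shaped object with random coefficients (no MCMC)
fake_draws <- function(schema, ndraws, seed, imd_variable = "imd") {
  fe_map <- hlmrp:::fixed_effect_map(schema, imd_variable)
  gl <- schema_levels_of(schema, imd_variable)
  pnames <- c("intercept", paste0(fe_map$variable, ":", fe_map$level),
              paste0(imd_variable, ":", gl), "imd_mu", "imd_sigma")
  set.seed(seed)
  m <- matrix(rnorm(ndraws * length(pnames), 0, 0.8), ndraws,
              dimnames = list(NULL, pnames))
  m[, "imd_sigma"] <- abs(m[, "imd_sigma"]) + 0.05
  structure(list(draws = m, fe_map = fe_map, schema = schema,
                 outcome = "toy", imd_variable = imd_variable,
                 imd_levels = gl,
                 diagnostics = data.frame(parameter = pnames, rhat = 1,
                                          ess = ndraws)),
            class = "posterior_draws")
}

schema_levels_of <- function(schema, v) schema$variables[[v]]$levels
schema_names_of <- function(schema) names(schema$variables)

random_frame <- function(schema, seed) {
  cells <- enumerate_cells(schema)
  set.seed(seed)
  w <- runif(nrow(cells))
  poststrat_frame(cells, w / sum(w), schema)
}

# cell probabilities by per-draw, per-cell looping over named coefficients
oracle_predict <- function(draws, cells) {
  out <- matrix(NA_real_, nrow(draws$draws), nrow(cells))
  for (d in seq_len(nrow(draws$draws))) {
    co <- draws$draws[d, ]
    for (c in seq_len(nrow(cells))) {
      eta <- co[["intercept"]]
      for (k in seq_len(nrow(draws$fe_map))) {
        v <- draws$fe_map$variable[k]
        l <- draws$fe_map$level[k]
        if (cells[[v]][c] == l) eta <- eta + co[[paste0(v, ":", l)]]
      }
      eta <- eta + co[[paste0(draws$imd_variable, ":",
                              cells[[draws$imd_variable]][c])]]
      out[d, c] <- 1 / (1 + exp(-eta))
    }
  }
  out
}

# weighted mean per draw by explicit summation
oracle_poststratify <- function(preds, weights) {
  vapply(seq_len(nrow(preds)), function(d) {
    s <- 0
    for (c in seq_len(ncol(preds))) s <- s + weights[c] * preds[d, c]
    s
  }, numeric(1))
}

# counterfactual weights by explicit stratum matching
oracle_counterfactual <- function(frame, variable, level) {
  cells <- frame$cells
  others <- setdiff(names(cells), variable)
  w <- numeric(nrow(cells))
  for (c in seq_len(nrow(cells))) {
    if (cells[[variable]][c] != level) next
    for (k in seq_len(nrow(cells))) {
      same <- all(vapply(others, function(v)
        cells[[v]][k] == cells[[v]][c], logical(1)))
      if (same) w[c] <- w[c] + frame$weights[k]
    }
  }
  w
}

# marginal of a joint/frame by explicit summation
oracle_margin <- function(cells, weights, variable, levels) {
  vapply(levels, function(l) sum(weights[cells[[variable]] == l]),
         numeric(1))
}

# cumulative rank probabilities by direct counting
oracle_cum_rank <- function(ranks) {
  n <- ncol(ranks)
  out <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) {
    for (r in seq_len(n)) {
      cnt <- 0
      for (d in seq_len(nrow(ranks))) if (ranks[d, i] <= r) cnt <- cnt + 1
      out[i, r] <- cnt / nrow(ranks)
    }
  }
  out
}

# ---------------------------------------------------------------------
# Shared replicate study for the stochastic acceptance checks: 20 source
# surveys (n = 4000) from the default literacy ground truth, each fitted
# with the desk-scale MCMC profile and pushed through prediction, ATE and
# ranking over one fixed target frame.  Memoised so the calibration and
# null-behaviour tests reuse one batch.
.replicate_cache <- new.env(parent = emptyenv())

replicate_study <- function(n_rep = 20) {
  key <- paste0("batch", n_rep)
  if (!is.null(.replicate_cache[[key]])) return(.replicate_cache[[key]])
  sch <- default_schema()
  tp <- default_true_params()
  bundle <- make_default_bundle(20260)
  frame <- bundle_frame(bundle)
  ct <- contrast_table(sch)
  analytic <- vapply(seq_len(nrow(ct)), function(i)
    analytic_mrp_ate(tp$literacy, frame, ct$variable[i], ct$level[i]),
    numeric(1))
  names(analytic) <- paste0(ct$variable, ":", ct$level)

  reps <- lapply(seq_len(n_rep), function(r) {
    sv <- generate_source_survey(sch, tp, 4000, seed = 7000 + r)
    fit <- suppressWarnings(
      fit_mrp(sv, "literacy", sch,
              settings = mcmc_profile("test", seed = 100 + r)))
    preds <- predict_cells(fit, frame$cells)
    at <- ate_table(preds, frame, "literacy")
    su <- sucra(cumulative_rank_probs(rank_draws(at$draws)))
    list(fit = fit, ate = at$summary, sucra = su)
  })
  out <- list(schema = sch, true_params = tp$literacy, frame = frame,
              contrasts = ct, analytic = analytic, reps = reps)
  .replicate_cache[[key]] <- out
  out
}
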