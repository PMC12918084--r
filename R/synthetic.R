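#' Ground-truth parameters of the synthetic multilevel logistic process
#'
#' Holds the data-generating parameters for one binary outcome: intercept,
#' fixed effects per non-reference covariate level (reference levels are
#' implicitly 0), and the deprivation-quintile group effects together with
#' the population mean and standard deviation they are drawn from.
#'
#' @param intercept logit-scale intercept.
#' @param effects named list: variable -> named numeric vector of effects
#'   for its non-reference levels.
#' @param imd_sigma nonnegative group-effect standard deviation.
#' @param imd_mu group-effect mean (default 0).
#' @param imd_effects optional fixed quintile effects (named by quintile
#'   level); if `NULL` they are drawn from N(`imd_mu`, `imd_sigma`^2)
#'   using the current RNG state.
#' @param imd_levels quintile labels (default `q1`..`q5`).
#' @return An object of class `true_params`.
#' @export
true_params <- function(intercept, effects, imd_sigma, imd_mu = 0,
                        imd_effects = NULL,
                        imd_levels = paste0("q", 1:5)) {
  if (imd_sigma < 0)
    hl_abort("imd_sigma must be nonnegative", "hlmrp_invalid_params")
  if (is.null(imd_effects))
    imd_effects <- setNames(stats::rnorm(length(imd_levels), imd_mu, imd_sigma),
                            imd_levels)
  structure(list(intercept = intercept, effects = effects,
                 imd_mu = imd_mu, imd_sigma = imd_sigma,
                 imd_effects = imd_effects),
            class = "true_params")
}

#' Default ground-truth parameters per outcome
#'
#' Three parameter sets (literacy, numeracy, ICT) with effect patterns
#' chosen to mirror the qualitative structure reported for the three
#' skills: qualification level dominates literacy and numeracy, age
#' dominates ICT, English as first language matters mostly for literacy,
#' and working status carries a true zero effect (a built-in negative
#' control for null-recovery checks).
#'
#' @return Named list of `true_params`, one per outcome.
#' @export
default_true_params <- function() {
  list(
    literacy = true_params(
      intercept = -0.8,
      effects = list(
        age = c("45+" = 0.45), sex = c(male = 0.15),
        ethnicity = c(white = -0.35), english = c(yes = -1.0),
        ukborn = c(yes = -0.15),
        qualification = c(level2_plus = -1.2),
        income = c(ge10k = -0.15, other = 0.3),
        job = c(intermediate = 0.3, lower = 0.8),
        working = c(yes = 0), ownhome = c(yes = -0.4)),
      imd_sigma = 0.3,
      imd_effects = c(q1 = 0, q2 = 0.15, q3 = 0.3, q4 = -0.1, q5 = -0.35)),
    numeracy = true_params(
      intercept = -0.3,
      effects = list(
        age = c("45+" = 0.15), sex = c(male = -0.45),
        ethnicity = c(white = -0.7), english = c(yes = 0.15),
        ukborn = c(yes = -0.05),
        qualification = c(level2_plus = -0.8),
        income = c(ge10k = -0.15, other = 0.2),
        job = c(intermediate = 0.35, lower = 0.7),
        working = c(yes = 0), ownhome = c(yes = -0.35)),
      imd_sigma = 0.3,
      imd_effects = c(q1 = 0.05, q2 = 0.2, q3 = 0, q4 = -0.15, q5 = -0.5)),
    ict = true_params(
      intercept = -0.9,
      effects = list(
        age = c("45+" = 1.3), sex = c(male = 0.1),
        ethnicity = c(white = -0.25), english = c(yes = 0.05),
        ukborn = c(yes = -0.35),
        qualification = c(level2_plus = -0.8),
        income = c(ge10k = -0.3, other = 0.25),
        job = c(intermediate = -0.05, lower = 0.6),
        working = c(yes = -0.05), ownhome = c(yes = -0.15)),
      imd_sigma = 0.2,
      imd_effects = c(q1 = 0.05, q2 = 0.1, q3 = 0, q4 = -0.1, q5 = -0.2))
  )
}

#' Logit-scale linear predictor under ground-truth parameters
#'
#' @param params a `true_params`.
#' @param records data frame of covariate assignments (must include every
#'   effect variable and the deprivation quintile column `imd`).
#' @return Numeric vector of linear predictors.
#' @export
linear_predictor <- function(params, records) {
  eta <- rep(params$intercept, nrow(records))
  for (v in names(params$effects)) {
    eff <- params$effects[[v]]
    m <- eff[match(records[[v]], names(eff))]
    m[is.na(m)] <- 0 # reference level
    eta <- eta + m
  }
  if (!is.null(records[["imd"]]))
    eta <- eta + unname(params$imd_effects[records[["imd"]]])
  eta
}

#' Default source-survey covariate level probabilities
#'
#' Marginal level probabilities emulating a national adult skills survey:
#' predominantly UK-born, white, English-first-language respondents with a
#' roughly even deprivation profile.
#'
#' @return Named list: variable -> named probability vector.
#' @export
default_source_probs <- function() {
  list(
    age           = c("16-44" = 0.54, "45+" = 0.46),
    sex           = c(female = 0.57, male = 0.43),
    ethnicity     = c("non-white" = 0.11, white = 0.89),
    english       = c(no = 0.08, yes = 0.92),
    ukborn        = c(no = 0.12, yes = 0.88),
    qualification = c(level1_or_below = 0.31, level2_plus = 0.69),
    income        = c(lt10k = 0.14, ge10k = 0.39, other = 0.47),
    job           = c(higher = 0.38, intermediate = 0.10, lower = 0.52),
    working       = c(no = 0.32, yes = 0.68),
    ownhome       = c(no = 0.41, yes = 0.59),
    imd           = c(q1 = 0.16, q2 = 0.21, q3 = 0.18, q4 = 0.24, q5 = 0.21)
  )
}

# solve the 2x2 cell probability p11 given margins and an odds ratio
tilted_p11 <- function(pa, pb, psi) {
  if (abs(psi - 1) < 1e-12) return(pa * pb)
  a <- psi - 1
  B <- 1 + (pa + pb) * a
  p11 <- (B - sqrt(B * B - 4 * a * psi * pa * pb)) / (2 * a)
  min(max(p11, max(0, pa + pb - 1)), min(pa, pb))
}

#' Joint distribution from margins with pairwise log-linear tilts
#'
#' Builds a joint table as the independence product of per-variable
#' margins, multiplied by `exp(log_or)` on the cells where a tilted pair
#' of levels co-occurs, then renormalised.  Used to give synthetic
#' microdata a controlled association structure.
#'
#' @param schema a `covariate_schema`.
#' @param variables variables of the joint, in dimension order.
#' @param margins named list: variable -> named probability vector.
#' @param tilts list of `list(v1=, l1=, v2=, l2=, log_or=)`.
#' @return A `joint_table`.
#' @export
loglinear_joint <- function(schema, variables, margins, tilts = list()) {
  grids <- lapply(variables, function(v) schema_levels(schema, v))
  names(grids) <- variables
  g <- expand.grid(rev(grids), KEEP.OUT.ATTRS = FALSE,
                   stringsAsFactors = FALSE)
  g <- g[, rev(seq_along(g)), drop = FALSE]
  w <- rep(1, nrow(g))
  for (v in variables) w <- w * unname(margins[[v]][g[[v]]])
  for (tl in tilts)
    w <- w * ifelse(g[[tl$v1]] == tl$l1 & g[[tl$v2]] == tl$l2,
                    exp(tl$log_or), 1)
  fs <- lapply(variables, function(v) factor(g[[v]], levels = grids[[v]]))
  tab <- as.array(tapply(w, fs, sum, default = 0))
  joint_table(variables, tab / sum(tab))
}

# draw n rows from a joint_table
sample_joint <- function(joint, n) {
  combos <- expand.grid(dimnames(joint$prob), KEEP.OUT.ATTRS = FALSE,
                        stringsAsFactors = FALSE)
  names(combos) <- joint$variables
  idx <- sample.int(nrow(combos), n, replace = TRUE,
                    prob = as.vector(joint$prob))
  df <- combos[idx, , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Generate a synthetic source skills survey
#'
#' Draws `n` respondents' covariates (independently from per-variable
#' level probabilities, optionally with pairwise association tilts), then
#' for each outcome assigns its planned assessment subsample and draws the
#' binary outcome from the multilevel logistic process under that
#' outcome's ground-truth parameters.  Outcome value 1 codes *not*
#' meeting the health-literacy threshold.  Subsamples are nested heads of
#' one random permutation (mirroring a survey design that administers the
#' more intensive assessments to planned subsets).
#'
#' @param schema a `covariate_schema`.
#' @param true_params_per_outcome named list of `true_params`.
#' @param n number of respondents.
#' @param subsample_fractions named fractions in (0, 1] per outcome;
#'   subsample size is `round(n * fraction)`.
#' @param seed integer seed.
#' @param covariate_probs per-variable level probabilities
#'   (default [default_source_probs()]).
#' @param assoc optional list of pairwise tilts
#'   (`list(v1=, l1=, v2=, l2=, log_or=)`, binary variables only).
#' @return An object of class `source_survey`: list with `covariates`
#'   (data frame), `outcomes` (per outcome: subsample `idx` and outcome
#'   vector `y`), `schema`, `n`.
#' @export
generate_source_survey <- function(schema, true_params_per_outcome, n,
                                   subsample_fractions = c(literacy = 1,
                                                           numeracy = 0.75,
                                                           ict = 0.4),
                                   seed = 1,
                                   covariate_probs = default_source_probs(),
                                   assoc = NULL) {
  if (n <= 0) hl_abort("n must be positive", "hlmrp_config_error")
  if (any(subsample_fractions <= 0 | subsample_fractions > 1))
    hl_abort("subsample fractions must be in (0, 1]", "hlmrp_config_error")
  with_seed(seed, {
    cov <- lapply(schema_names(schema), function(v) {
      p <- covariate_probs[[v]]
      sample(names(p), n, replace = TRUE, prob = p)
    })
    names(cov) <- schema_names(schema)
    cov <- as.data.frame(cov, stringsAsFactors = FALSE)
    for (tl in assoc) {
      pa <- unname(covariate_probs[[tl$v1]][tl$l1])
      pb <- unname(covariate_probs[[tl$v2]][tl$l2])
      p11 <- tilted_p11(pa, pb, exp(tl$log_or))
      probs <- c(p11, pa - p11, pb - p11, 1 - pa - pb + p11)
      pick <- sample.int(4, n, replace = TRUE, prob = probs)
      o1 <- setdiff(schema_levels(schema, tl$v1), tl$l1)[1]
      o2 <- setdiff(schema_levels(schema, tl$v2), tl$l2)[1]
      cov[[tl$v1]] <- c(tl$l1, tl$l1, o1, o1)[pick]
      cov[[tl$v2]] <- c(tl$l2, o2, tl$l2, o2)[pick]
    }
    perm <- sample.int(n)
    outcomes <- lapply(names(true_params_per_outcome), function(oc) {
      size <- round(n * unname(subsample_fractions[[oc]]))
      idx <- sort(perm[seq_len(size)])
      eta <- linear_predictor(true_params_per_outcome[[oc]],
                              cov[idx, , drop = FALSE])
      list(idx = idx, y = rbinom(length(idx), 1, plogis(eta)))
    })
    names(outcomes) <- names(true_params_per_outcome)
    structure(list(covariates = cov, outcomes = outcomes,
                   schema = schema, n = n),
              class = "source_survey")
  })
}

#' @export
print.source_survey <- function(x, ...) {
  sizes <- vapply(x$outcomes, function(o) length(o$idx), numeric(1))
  cat("Synthetic source survey:", x$n, "respondents; subsamples:",
      paste(sprintf("%s=%d", names(sizes), sizes), collapse = ", "), "\n")
  invisible(x)
}

#' Generate target-area microdata
#'
#' Draws `n` iid records from a joint distribution restricted to a named
#' covariate subset, emulating a local residents survey.
#'
#' @param schema a `covariate_schema`.
#' @param target_joint a `joint_table` over `variables`.
#' @param variables covariate subset.
#' @param n number of records.
#' @param seed integer seed.
#' @return Data frame with one column per variable.
#' @export
generate_target_microdata <- function(schema, target_joint, variables, n,
                                      seed = 1) {
  if (!all(variables %in% schema_names(schema)))
    hl_abort("variables must belong to the schema", "hlmrp_config_error")
  if (!setequal(variables, target_joint$variables))
    hl_abort("target_joint must cover exactly the requested variables",
             "hlmrp_config_error")
  if (n <= 0) hl_abort("n must be positive", "hlmrp_config_error")
  with_seed(seed, sample_joint(target_joint, n)[variables])
}

#' Default target-area joint for the residents-survey covariate block
#'
#' Margins emulate a young, diverse, largely renting inner-city borough;
#' mild log-linear tilts couple working status with home ownership and
#' age.
#'
#' @param schema a `covariate_schema`.
#' @return A `joint_table` over age, sex, ethnicity, working, ownhome.
#' @export
default_target_joint <- function(schema) {
  loglinear_joint(
    schema, c("age", "sex", "ethnicity", "working", "ownhome"),
    margins = list(
      age = c("16-44" = 0.64, "45+" = 0.36),
      sex = c(female = 0.46, male = 0.54),
      ethnicity = c("non-white" = 0.70, white = 0.30),
      working = c(no = 0.35, yes = 0.65),
      ownhome = c(no = 0.65, yes = 0.35)),
    tilts = list(
      list(v1 = "working", l1 = "yes", v2 = "ownhome", l2 = "yes",
           log_or = 0.5),
      list(v1 = "age", l1 = "45+", v2 = "working", l2 = "yes",
           log_or = -0.4),
      list(v1 = "ethnicity", l1 = "white", v2 = "ownhome", l2 = "yes",
           log_or = 0.3)))
}

#' Default auxiliary (labour-force style) joint and target margins
#'
#' The auxiliary microdata joint carries national-survey-like margins
#' (mostly UK-born, English-first-language) plus associations between
#' English language, country of birth and qualification, so that raking
#' it to the target-area margins is a non-trivial adjustment.
#'
#' @param schema a `covariate_schema`.
#' @return `default_aux_joint()`: a `joint_table` over qualification,
#'   english, ukborn, job, income.  `default_aux_target_margins()`: list
#'   of `marginal_table`s giving the target-area margins for that block.
#' @export
default_aux_joint <- function(schema) {
  loglinear_joint(
    schema, c("qualification", "english", "ukborn", "job", "income"),
    margins = list(
      qualification = c(level1_or_below = 0.31, level2_plus = 0.69),
      english = c(no = 0.08, yes = 0.92),
      ukborn = c(no = 0.12, yes = 0.88),
      job = c(higher = 0.38, intermediate = 0.10, lower = 0.52),
      income = c(lt10k = 0.14, ge10k = 0.39, other = 0.47)),
    tilts = list(
      list(v1 = "english", l1 = "yes", v2 = "ukborn", l2 = "yes",
           log_or = 1.0),
      list(v1 = "qualification", l1 = "level2_plus", v2 = "english",
           l2 = "yes", log_or = 0.3)))
}

#' @rdname default_aux_joint
#' @export
default_aux_target_margins <- function(schema) {
  list(
    marginal_table("qualification",
                   c(level1_or_below = 0.43, level2_plus = 0.57)),
    marginal_table("english", c(no = 0.35, yes = 0.65)),
    marginal_table("ukborn", c(no = 0.54, yes = 0.46)),
    marginal_table("job",
                   c(higher = 0.16, intermediate = 0.28, lower = 0.56)),
    marginal_table("income", c(lt10k = 0.10, ge10k = 0.85, other = 0.05)))
}

#' Generate auxiliary microdata plus the margins raking must reproduce
#'
#' @param schema a `covariate_schema`.
#' @param joint source joint of the auxiliary microdata
#'   (default [default_aux_joint()]).
#' @param variables the auxiliary covariate block (default: qualification,
#'   english, ukborn, job, income).
#' @param n number of microdata records.
#' @param seed integer seed.
#' @param target_margins the target-area margins emitted alongside
#'   (default [default_aux_target_margins()]).
#' @return List with `microdata` (data frame) and `margins`
#'   (list of `marginal_table`).
#' @export
generate_lfs_inputs <- function(schema, joint = default_aux_joint(schema),
                                variables = c("qualification", "english",
                                              "ukborn", "job", "income"),
                                n = 3000, seed = 1,
                                target_margins =
                                  default_aux_target_margins(schema)) {
  if (!setequal(variables, joint$variables))
    hl_abort("joint must cover exactly the auxiliary variables",
             "hlmrp_config_error")
  micro <- with_seed(seed, sample_joint(joint, n)[variables])
  list(microdata = micro, margins = target_margins)
}

#' Generate a synthetic small-area deprivation table
#'
#' @param n_lsoa number of small areas (default 164).
#' @param seed integer seed.
#' @param decile_probs sampling probabilities of deciles 1..10; the
#'   default concentrates areas in deciles 2-4, as in a deprived inner
#'   London borough.
#' @param mean_population Poisson mean of the per-area population.
#' @return Data frame with columns `lsoa_id`, `imd_decile`, `population`.
#' @export
generate_lsoa_table <- function(n_lsoa = 164, seed = 1,
                                decile_probs = c(0.03, 0.26, 0.30, 0.20,
                                                 0.08, 0.05, 0.04, 0.02,
                                                 0.01, 0.01),
                                mean_population = 2200) {
  with_seed(seed, data.frame(
    lsoa_id = sprintf("LSOA%03d", seq_len(n_lsoa)),
    imd_decile = sample(1:10, n_lsoa, replace = TRUE, prob = decile_probs),
    population = rpois(n_lsoa, mean_population),
    stringsAsFactors = FALSE))
}

#' Map a skills grade to the binary health-literacy flag
#'
#' Grades sit on the five-level qualifications ladder
#' EL1 < EL2 < EL3 < L1 < L2plus.  The flag is 1 (health literate) iff
#' the grade meets or exceeds the outcome's threshold: L2plus for
#' literacy, L1 for numeracy, EL3 for ICT.
#'
#' @param outcome one of `"literacy"`, `"numeracy"`, `"ict"` (vectorised).
#' @param grade one of `"EL1"`, `"EL2"`, `"EL3"`, `"L1"`, `"L2plus"`
#'   (vectorised).
#' @return Integer 0/1 vector.
#' @export
grade_to_binary <- function(outcome, grade) {
  ladder <- c("EL1", "EL2", "EL3", "L1", "L2plus")
  thresholds <- c(literacy = "L2plus", numeracy = "L1", ict = "EL3")
  if (any(!outcome %in% names(thresholds)))
    hl_abort("unknown outcome", "hlmrp_mapping_error")
  g <- match(grade, ladder)
  if (anyNA(g))
    hl_abort("unknown grade", "hlmrp_mapping_error")
  as.integer(g >= match(thresholds[outcome], ladder))
}

#' Generate the complete synthetic input bundle
#'
#' One call produces every input the pipeline consumes, all derived from a
#' single seed: the source skills survey, target-area microdata, auxiliary
#' microdata plus raking margins, the small-area deprivation table, and
#' the ground-truth parameters.
#'
#' @param seed integer master seed.
#' @param n_source source-survey size (default 4000).
#' @param n_target target-microdata size (default 3000).
#' @param n_lfs auxiliary-microdata size (default 3000).
#' @param n_lsoa number of small areas (default 164).
#' @param true_params_per_outcome ground truth
#'   (default [default_true_params()]).
#' @param schema a `covariate_schema` (default [default_schema()]).
#' @return An object of class `synthetic_bundle`.
#' @export
make_default_bundle <- function(seed, n_source = 4000, n_target = 3000,
                                n_lfs = 3000, n_lsoa = 164,
                                true_params_per_outcome = default_true_params(),
                                schema = default_schema()) {
  subseeds <- with_seed(seed, sample.int(.Machine$integer.max - 1, 4))
  target_joint <- default_target_joint(schema)
  lfs <- generate_lfs_inputs(schema, n = n_lfs, seed = subseeds[2])
  structure(list(
    schema = schema,
    source_survey = generate_source_survey(
      schema, true_params_per_outcome, n_source, seed = subseeds[1]),
    target_microdata = generate_target_microdata(
      schema, target_joint, target_joint$variables, n_target,
      seed = subseeds[3]),
    target_variables = target_joint$variables,
    lfs_microdata = lfs$microdata,
    lfs_variables = c("qualification", "english", "ukborn", "job", "income"),
    lfs_margins = lfs$margins,
    lsoa_table = generate_lsoa_table(n_lsoa, seed = subseeds[4]),
    true_params = true_params_per_outcome,
    target_joint = target_joint,
    seed = seed), class = "synthetic_bundle")
}

#' @export
print.synthetic_bundle <- function(x, ...) {
  cat("Synthetic input bundle (seed", x$seed, "):\n")
  print(x$source_survey)
  cat("  target microdata:", nrow(x$target_microdata), "records over",
      paste(x$target_variables, collapse = ", "), "\n")
  cat("  auxiliary microdata:", nrow(x$lfs_microdata), "records over",
      paste(x$lfs_variables, collapse = ", "), "\n")
  cat("  LSOA table:", nrow(x$lsoa_table), "areas\n")
  invisible(x)
}

#' Build the post-stratification frame for a synthetic bundle
#'
#' @param bundle a `synthetic_bundle`.
#' @param record_weights optional weights for the target microdata.
#' @return A `poststrat_frame`.
#' @export
bundle_frame <- function(bundle, record_weights = NULL) {
  build_poststrat_frame(
    bundle$schema, bundle$target_microdata, bundle$target_variables,
    bundle$lfs_microdata, bundle$lfs_variables, bundle$lfs_margins,
    bundle$lsoa_table, record_weights = record_weights)
}

#' Write a synthetic bundle to CSV/JSON files
#'
#' Emits the CSV dialects the pipeline's file mode reads back, plus the
#' ground-truth parameters as JSON for test harness consumption.
#'
#' @param bundle a `synthetic_bundle`.
#' @param dir output directory (created if missing).
#' @return Invisibly, the directory.
#' @export
write_bundle_csv <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sv <- bundle$source_survey
  df <- sv$covariates
  for (oc in names(sv$outcomes)) {
    y <- rep(NA_integer_, sv$n)
    y[sv$outcomes[[oc]]$idx] <- sv$outcomes[[oc]]$y
    df[[paste0("y_", oc)]] <- y
  }
  write.csv(df, file.path(dir, "source_survey.csv"), row.names = FALSE,
            quote = FALSE)
  write.csv(bundle$target_microdata, file.path(dir, "target_microdata.csv"),
            row.names = FALSE, quote = FALSE)
  write.csv(bundle$lfs_microdata, file.path(dir, "lfs_microdata.csv"),
            row.names = FALSE, quote = FALSE)
  write.csv(bundle$lsoa_table, file.path(dir, "lsoa_imd.csv"),
            row.names = FALSE, quote = FALSE)
  margins <- lapply(bundle$lfs_margins, function(m)
    list(variable = m$variable, proportions = as.list(m$proportions)))
  jsonlite::write_json(margins, file.path(dir, "lfs_target_margins.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  tp <- lapply(bundle$true_params, unclass)
  jsonlite::write_json(tp, file.path(dir, "true_params.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_schema(bundle$schema, file.path(dir, "schema.yaml"))
  invisible(dir)
}
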