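test_that("cell predictions match the closed form and a loop oracle", {
  sch <- toy_schema()
  cells <- enumerate_cells(sch)

  # all coefficients zero -> every entry 0.5
  d0 <- fake_draws(sch, 3, seed = 1)
  d0$draws[] <- 0
  expect_true(all(predict_cells(d0, cells) == 0.5))

  # single binary covariate, b0 = 0, b1 = 1 -> (0.5, inv-logit(1))
  sch1 <- covariate_schema(list(z = c("z0", "z1"), imd = c("g1", "g2")))
  d1 <- fake_draws(sch1, 1, seed = 2, imd_variable = "imd")
  d1$draws[] <- 0
  d1$draws[, "z:z1"] <- 1
  p <- predict_cells(d1, enumerate_cells(sch1))
  expect_equal(as.numeric(p), c(0.5, 0.5, plogis(1), plogis(1)),
               tolerance = 1e-15)

  # random draws vs brute-force loop
  dr <- fake_draws(sch, 20, seed = 3)
  expect_equal(unclass(predict_cells(dr, cells))[, ],
               oracle_predict(dr, cells),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("prediction commutes with cell permutation", {
  sch <- toy_schema()
  cells <- enumerate_cells(sch)
  dr <- fake_draws(sch, 10, seed = 5)
  set.seed(6)
  perm <- sample.int(nrow(cells))
  p_then_permute <- predict_cells(dr, cells)[, perm]
  permute_then_p <- predict_cells(dr, cells[perm, ])
  expect_equal(unclass(permute_then_p), unclass(p_then_permute),
               tolerance = 1e-15, ignore_attr = TRUE)
})

test_that("post-stratification is the weighted cell mean", {
  sch <- toy_schema()
  frame <- random_frame(sch, 7)
  dr <- fake_draws(sch, 25, seed = 8)
  preds <- predict_cells(dr, frame$cells)

  # constant predictions -> the constant, for any frame
  pc <- preds
  pc[] <- 0.37
  expect_equal(poststratify(pc, frame), rep(0.37, 25), tolerance = 1e-12)

  # two-cell hand example
  sch2 <- covariate_schema(list(t = c("t0", "t1")))
  fr2 <- poststrat_frame(enumerate_cells(sch2), c(0.25, 0.75), sch2)
  p2 <- matrix(c(0.2, 0.6), 1, 2)
  expect_equal(poststratify(p2, fr2), 0.5)

  # loop oracle + boundedness
  got <- poststratify(preds, frame)
  expect_equal(got, oracle_poststratify(preds, frame$weights),
               tolerance = 1e-12)
  expect_true(all(got >= apply(preds, 1, min) - 1e-12 &
                  got <= apply(preds, 1, max) + 1e-12))

  expect_error(poststratify(preds[, 1:5], frame),
               class = "hlmrp_alignment_error")
})

test_that("the model recovers a null data-generating process", {
  sch <- default_schema()
  null_effects <- lapply(default_true_params()$literacy$effects,
                         function(e) e * 0)
  tp <- list(literacy = true_params(0, null_effects, imd_sigma = 0,
                                    imd_effects = setNames(rep(0, 5),
                                                           paste0("q", 1:5))))
  sv <- generate_source_survey(sch, tp, 4000,
                               subsample_fractions = c(literacy = 1),
                               seed = 30)
  fit <- suppressWarnings(
    fit_mrp(sv, "literacy", sch, settings = mcmc_profile("test", seed = 31)))
  pm <- colMeans(fit$draws)
  fe_cols <- paste0(fit$fe_map$variable, ":", fit$fe_map$level)
  fe <- pm[fe_cols]
  fe_sd <- apply(fit$draws[, fe_cols], 2, stats::sd)
  # no coefficient is spuriously detected: each within 3 posterior sds of
  # zero, and none drifts far in absolute terms (rare levels have larger
  # sampling noise, ~0.1 on the logit scale at this n)
  expect_true(all(abs(fe) / fe_sd < 3))
  expect_true(all(abs(fe) < 0.3))
  expect_lt(mean(abs(fe)), 0.1)
  b0u <- pm["intercept"] + pm[paste0("imd:q", 1:5)]
  expect_true(all(abs(b0u) < 0.15))
})

test_that("posterior means agree with an independent mixed-model fit", {
  sch <- default_schema()
  tp <- default_true_params()
  sv <- generate_source_survey(sch, tp, 4000, seed = 7)
  fit <- suppressWarnings(
    fit_mrp(sv, "literacy", sch, settings = mcmc_profile("test", seed = 3)))
  pm <- colMeans(fit$draws)
  df <- sv$covariates[sv$outcomes$literacy$idx, ]
  for (v in names(df))
    df[[v]] <- factor(df[[v]], levels = hlmrp:::schema_levels(sch, v))
  df$y <- sv$outcomes$literacy$y
  gl <- lme4::glmer(
    y ~ age + sex + ethnicity + english + ukborn + qualification +
      income + job + working + ownhome + (1 | imd),
    data = df, family = stats::binomial)
  fe <- lme4::fixef(gl)[-1]
  mine <- pm[paste0(fit$fe_map$variable, ":", fit$fe_map$level)]
  # with n = 4000 and weak priors the posterior mean tracks the MLE
  expect_lt(max(abs(unname(mine) - unname(fe))), 0.08)
})

test_that("posterior matches an independent MCMC implementation", {
  sch <- covariate_schema(list(z = c("z0", "z1"), w = c("w0", "w1"),
                               imd = paste0("q", 1:5)))
  probs <- list(z = c(z0 = 0.5, z1 = 0.5), w = c(w0 = 0.6, w1 = 0.4),
                imd = setNames(rep(0.2, 5), paste0("q", 1:5)))
  tp <- list(o = true_params(-0.4, list(z = c(z1 = 0.8), w = c(w1 = -0.6)),
                             imd_sigma = 0.3,
                             imd_effects = c(q1 = 0, q2 = 0.2, q3 = 0.3,
                                             q4 = -0.2, q5 = -0.3)))
  sv <- generate_source_survey(sch, tp, 1500,
                               subsample_fractions = c(o = 1), seed = 41,
                               covariate_probs = probs)
  fit <- suppressWarnings(
    fit_mrp(sv, "o", sch, settings = mcmc_settings(2, 500, 1500, seed = 42)))
  pm <- colMeans(fit$draws)

  # same model, same priors, in JAGS
  df <- sv$covariates
  dat <- list(y = sv$outcomes$o$y,
              z = as.integer(df$z == "z1"), w = as.integer(df$w == "w1"),
              g = match(df$imd, paste0("q", 1:5)), N = nrow(df))
  model <- "model {
    for (i in 1:N) {
      y[i] ~ dbern(p[i])
      logit(p[i]) <- b0 + bz*z[i] + bw*w[i] + u[g[i]]
    }
    b0 ~ dnorm(0, 0.16); bz ~ dnorm(0, 0.16); bw ~ dnorm(0, 0.16)
    for (j in 1:5) { u[j] ~ dnorm(mu, pow(sigma, -2)) }
    mu ~ dnorm(0, 0.16)
    sigma ~ dnorm(0, 1) T(0,)
  }"
  jm <- rjags::jags.model(
    textConnection(model), data = dat, n.chains = 1, n.adapt = 300,
    inits = list(.RNG.name = "base::Mersenne-Twister", .RNG.seed = 9),
    quiet = TRUE)
  stats::update(jm, 500)
  sm <- rjags::coda.samples(jm, c("b0", "bz", "bw", "mu", "sigma", "u"),
                            n.iter = 2500)
  jg <- colMeans(as.matrix(sm))
  expect_lt(abs(pm[["z:z1"]] - jg[["bz"]]), 0.1)
  expect_lt(abs(pm[["w:w1"]] - jg[["bw"]]), 0.1)
  expect_lt(abs(pm[["imd_sigma"]] - jg[["sigma"]]), 0.12)
  for (j in 1:5)
    expect_lt(abs((pm[["intercept"]] + pm[[paste0("imd:q", j)]]) -
                  (jg[["b0"]] + jg[[paste0("u[", j, "]")]])), 0.12)
})

test_that("posterior predictive prevalence tracks the sample prevalence", {
  sch <- default_schema()
  sv <- generate_source_survey(sch, default_true_params(), 4000, seed = 55)
  fit <- suppressWarnings(
    fit_mrp(sv, "literacy", sch, settings = mcmc_profile("test", seed = 56)))
  # empirical frame of the source sample itself
  idx <- sv$outcomes$literacy$idx
  j <- estimate_joint_from_microdata(sv$covariates[idx, ],
                                     schema_names_of(sch), sch)
  fr <- poststrat_frame(enumerate_cells(sch), as.vector(aperm(j$prob)), sch)
  preds <- predict_cells(fit, fr$cells)
  pp <- mean(poststratify(preds, fr))
  expect_lt(abs(pp - mean(sv$outcomes$literacy$y)), 0.03)
})

test_that("degenerate inputs raise classed fit errors", {
  sch <- toy_schema()
  sv <- list(covariates = data.frame(t = c("a", "b"), x = c("lo", "hi"),
                                     imd = c("q1", "q2")),
             outcomes = list(o = list(idx = 1:2, y = c(1, 1))), n = 2)
  expect_error(fit_mrp(sv, "o", sch), class = "hlmrp_separation_error")
  expect_error(fit_mrp(sv, "missing", sch), class = "hlmrp_data_error")
})
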