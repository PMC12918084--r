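test_that("generators are pure functions of (config, seed)", {
  b1 <- make_default_bundle(42, n_source = 300, n_target = 200, n_lfs = 200)
  b2 <- make_default_bundle(42, n_source = 300, n_target = 200, n_lfs = 200)
  expect_identical(b1$source_survey, b2$source_survey)
  expect_identical(b1$target_microdata, b2$target_microdata)
  expect_identical(b1$lfs_microdata, b2$lfs_microdata)
  expect_identical(b1$lsoa_table, b2$lsoa_table)
  b3 <- make_default_bundle(43, n_source = 300, n_target = 200, n_lfs = 200)
  expect_false(identical(b1$source_survey, b3$source_survey))
})

test_that("subsample sizes follow the rounding rule and are nested", {
  sch <- default_schema()
  sv <- generate_source_survey(sch, default_true_params(), 1000,
                               subsample_fractions = c(literacy = 1,
                                                       numeracy = 0.75,
                                                       ict = 0.4),
                               seed = 8)
  sizes <- vapply(sv$outcomes, function(o) length(o$idx), numeric(1))
  expect_equal(unname(sizes), c(1000, 750, 400))
  expect_true(all(sv$outcomes$ict$idx %in% sv$outcomes$numeracy$idx))
  expect_true(all(sv$outcomes$numeracy$idx %in% sv$outcomes$literacy$idx))
  expect_error(
    generate_source_survey(sch, default_true_params(), 100,
                           subsample_fractions = c(literacy = 1.2),
                           seed = 1),
    class = "hlmrp_config_error")
})

test_that("null process yields prevalence 0.5 and known effects shift it", {
  sch <- covariate_schema(list(z = c("z0", "z1"),
                               imd = paste0("q", 1:5)))
  null_tp <- list(o = true_params(0, list(z = c(z1 = 0)), imd_sigma = 0,
                                  imd_effects = setNames(rep(0, 5),
                                                         paste0("q", 1:5))))
  probs <- list(z = c(z0 = 0.5, z1 = 0.5),
                imd = setNames(rep(0.2, 5), paste0("q", 1:5)))
  sv <- generate_source_survey(sch, null_tp, 20000,
                               subsample_fractions = c(o = 1), seed = 11,
                               covariate_probs = probs)
  expect_lt(abs(mean(sv$outcomes$o$y) - 0.5), 0.01)

  # forced covariate: effect +1 on everyone -> prevalence inv-logit(1)
  tp1 <- list(o = true_params(0, list(z = c(z1 = 1)), imd_sigma = 0,
                              imd_effects = setNames(rep(0, 5),
                                                     paste0("q", 1:5))))
  probs1 <- list(z = c(z0 = 0, z1 = 1), imd = probs$imd)
  sv1 <- generate_source_survey(sch, tp1, 20000,
                                subsample_fractions = c(o = 1), seed = 12,
                                covariate_probs = probs1)
  expect_lt(abs(mean(sv1$outcomes$o$y) - plogis(1)), 0.01)
})

test_that("target microdata reproduces the generating joint", {
  sch <- toy_schema()
  gen <- loglinear_joint(sch, c("t", "x"),
                         margins = list(t = c(a = 0.35, b = 0.65),
                                        x = c(lo = 0.5, hi = 0.5)),
                         tilts = list(list(v1 = "t", l1 = "b", v2 = "x",
                                           l2 = "hi", log_or = 1)))
  md <- generate_target_microdata(sch, gen, c("t", "x"), 50000, seed = 21)
  est <- estimate_joint_from_microdata(md, c("t", "x"), sch)
  expect_lt(max(abs(est$prob - gen$prob)), 0.01)

  # degenerate joint -> identical records; n = 1 -> single valid record
  deg <- joint_table(c("t", "x"),
                     array(c(0, 0, 0, 1), c(2, 2),
                           dimnames = list(c("a", "b"), c("lo", "hi"))))
  md1 <- generate_target_microdata(sch, deg, c("t", "x"), 50, seed = 3)
  expect_true(all(md1$t == "b" & md1$x == "hi"))
  expect_equal(nrow(generate_target_microdata(sch, deg, c("t", "x"), 1,
                                              seed = 3)), 1)
  expect_error(generate_target_microdata(sch, gen, c("t", "nope"), 10, 1),
               class = "hlmrp_config_error")
})

test_that("auxiliary inputs emit unit-sum margins that raking can hit", {
  sch <- default_schema()
  lfs <- generate_lfs_inputs(sch, n = 2000, seed = 14)
  for (m in lfs$margins) expect_equal(sum(m$proportions), 1,
                                      tolerance = 1e-9)
  seed_joint <- estimate_joint_from_microdata(
    lfs$microdata, c("qualification", "english", "ukborn", "job", "income"),
    sch)
  raked <- ipf_rake(seed_joint, lfs$margins, tol = 1e-10)
  for (m in lfs$margins) {
    d <- match(m$variable, raked$variables)
    got <- apply(raked$prob, d, sum)
    expect_lt(max(abs(got[names(m$proportions)] - m$proportions)), 1e-9)
  }
  lfs2 <- generate_lfs_inputs(sch, n = 2000, seed = 14)
  expect_identical(lfs$microdata, lfs2$microdata)
})

test_that("grade thresholds map to the binary flag and are monotone", {
  # at-threshold counts as literate; below does not
  expect_equal(grade_to_binary("literacy", "L1"), 0L)
  expect_equal(grade_to_binary("literacy", "L2plus"), 1L)
  expect_equal(grade_to_binary("numeracy", "L1"), 1L)
  expect_equal(grade_to_binary("numeracy", "EL3"), 0L)
  expect_equal(grade_to_binary("ict", "EL3"), 1L)
  expect_equal(grade_to_binary("ict", "EL2"), 0L)
  ladder <- c("EL1", "EL2", "EL3", "L1", "L2plus")
  for (oc in c("literacy", "numeracy", "ict")) {
    flags <- grade_to_binary(rep(oc, 5), ladder)
    expect_true(all(diff(flags) >= 0)) # monotone in the ladder
    expect_equal(sum(flags == 0) + sum(flags == 1), 5) # total
  }
  expect_error(grade_to_binary("literacy", "L9"),
               class = "hlmrp_mapping_error")
  expect_error(grade_to_binary("spelling", "L1"),
               class = "hlmrp_mapping_error")
})

test_that("default bundle is internally consistent", {
  b <- make_default_bundle(9, n_source = 400, n_target = 300, n_lfs = 2000)
  expect_setequal(c(b$target_variables, b$lfs_variables, "imd"),
                  names(b$schema$variables))
  expect_equal(nrow(b$lsoa_table), 164)
  # analytic prevalence under the truth is finite and interior
  fr <- bundle_frame(b)
  for (oc in names(b$true_params)) {
    eta <- linear_predictor(b$true_params[[oc]], fr$cells)
    prev <- sum(fr$weights * plogis(eta))
    expect_true(is.finite(prev) && prev > 0 && prev < 1)
  }
})

test_that("pairwise association tilt induces the requested odds ratio", {
  sch <- default_schema()
  sv <- generate_source_survey(
    sch, default_true_params()["literacy"], 30000, seed = 17,
    subsample_fractions = c(literacy = 1),
    assoc = list(list(v1 = "working", l1 = "yes", v2 = "ownhome",
                      l2 = "yes", log_or = 1)))
  tab <- table(sv$covariates$working == "yes", sv$covariates$ownhome == "yes")
  or <- (tab[2, 2] * tab[1, 1]) / (tab[1, 2] * tab[2, 1])
  expect_lt(abs(log(or) - 1), 0.15)
})

test_that("bundles round-trip through the CSV/JSON file interface", {
  b <- make_default_bundle(3, n_source = 250, n_target = 200, n_lfs = 200)
  dir <- tempfile()
  write_bundle_csv(b, dir)
  inputs <- hlmrp:::read_pipeline_inputs(list(
    source_survey = file.path(dir, "source_survey.csv"),
    target_microdata = file.path(dir, "target_microdata.csv"),
    lfs_microdata = file.path(dir, "lfs_microdata.csv"),
    lfs_target_margins = file.path(dir, "lfs_target_margins.json"),
    lsoa_table = file.path(dir, "lsoa_imd.csv"),
    schema = file.path(dir, "schema.yaml")))
  expect_equal(inputs$source_survey$covariates, b$source_survey$covariates)
  for (oc in names(b$source_survey$outcomes)) {
    expect_equal(inputs$source_survey$outcomes[[oc]]$idx,
                 b$source_survey$outcomes[[oc]]$idx)
    expect_equal(inputs$source_survey$outcomes[[oc]]$y,
                 b$source_survey$outcomes[[oc]]$y)
  }
  expect_equal(inputs$target_microdata, b$target_microdata)
  expect_equal(length(inputs$lfs_margins), length(b$lfs_margins))
  unlink(dir, recursive = TRUE)
})
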