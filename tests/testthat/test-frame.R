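make_2x2_seed <- function(p, vars = c("r", "c"),
                          lv = list(c("r1", "r2"), c("c1", "c2"))) {
  joint_table(vars, array(p, dim = c(2, 2), dimnames = lv))
}

test_that("joint estimation from microdata matches (weighted) frequencies", {
  sch <- covariate_schema(list(v = c("a", "b")))
  rec <- data.frame(v = c("a", "a", "a", "b"), stringsAsFactors = FALSE)
  j <- estimate_joint_from_microdata(rec, "v", sch)
  expect_equal(as.numeric(j$prob), c(0.75, 0.25))
  jw <- estimate_joint_from_microdata(rec, "v", sch,
                                      record_weights = c(1, 1, 1, 3))
  expect_equal(as.numeric(jw$prob), c(0.5, 0.5))
  rec$v[2] <- "zz"
  expect_error(estimate_joint_from_microdata(rec, "v", sch),
               class = "hlmrp_schema_mismatch")
})

test_that("estimated joint converges to the generating joint", {
  sch <- toy_schema()
  gen <- loglinear_joint(sch, c("t", "x"),
                         margins = list(t = c(a = 0.3, b = 0.7),
                                        x = c(lo = 0.6, hi = 0.4)),
                         tilts = list(list(v1 = "t", l1 = "b", v2 = "x",
                                           l2 = "hi", log_or = 0.8)))
  rec <- with(new.env(), {
    set.seed(99)
    hlmrp:::sample_joint(gen, 1000)
  })
  est <- estimate_joint_from_microdata(rec, c("t", "x"), sch)
  expect_lt(max(abs(est$prob - gen$prob)), 0.05)
})

test_that("IPF from an independence seed is the product of margins", {
  seed <- make_2x2_seed(rep(0.25, 4))
  fitted <- ipf_rake(seed, list(marginal_table("r", c(r1 = 0.6, r2 = 0.4)),
                                marginal_table("c", c(c1 = 0.7, c2 = 0.3))))
  expect_equal(as.numeric(fitted$prob), c(0.42, 0.28, 0.18, 0.12),
               tolerance = 1e-10)
})

test_that("IPF leaves an already-feasible table unchanged", {
  seed <- make_2x2_seed(c(0.4, 0.1, 0.1, 0.4))
  fitted <- ipf_rake(seed, list(marginal_table("r", c(r1 = 0.5, r2 = 0.5)),
                                marginal_table("c", c(c1 = 0.5, c2 = 0.5))))
  expect_equal(fitted$prob, seed$prob, tolerance = 1e-10)
})

test_that("IPF matches margins while preserving the seed odds ratio", {
  seed <- make_2x2_seed(c(0.35, 0.25, 0.15, 0.25))
  tr <- marginal_table("r", c(r1 = 0.6, r2 = 0.4))
  tc <- marginal_table("c", c(c1 = 0.5, c2 = 0.5))
  fitted <- ipf_rake(seed, list(tr, tc), tol = 1e-12)
  p <- fitted$prob
  expect_equal(as.numeric(apply(p, 1, sum)), c(0.6, 0.4), tolerance = 1e-10)
  expect_equal(as.numeric(apply(p, 2, sum)), c(0.5, 0.5), tolerance = 1e-10)
  or_seed <- (0.35 * 0.25) / (0.15 * 0.25)
  or_fit <- (p[1, 1] * p[2, 2]) / (p[1, 2] * p[2, 1])
  expect_equal(or_fit, or_seed, tolerance = 1e-9)
})

test_that("IPF preserves conditional odds ratios on random 3-way tables", {
  sch <- toy_schema()
  for (s in 1:5) {
    set.seed(200 + s)
    arr <- array(runif(12, 0.2, 1), dim = c(2, 2, 3),
                 dimnames = list(c("a", "b"), c("lo", "hi"),
                                 c("q1", "q2", "q3")))
    seed <- joint_table(c("t", "x", "imd"), arr / sum(arr))
    t1 <- runif(1, 0.2, 0.8)
    t2 <- runif(1, 0.2, 0.8)
    fitted <- ipf_rake(seed, list(
      marginal_table("t", c(a = t1, b = 1 - t1)),
      marginal_table("x", c(lo = t2, hi = 1 - t2))), tol = 1e-12)
    # every conditional 2x2 odds ratio given the third variable survives
    for (k in 1:3) {
      or0 <- (seed$prob[1, 1, k] * seed$prob[2, 2, k]) /
             (seed$prob[1, 2, k] * seed$prob[2, 1, k])
      or1 <- (fitted$prob[1, 1, k] * fitted$prob[2, 2, k]) /
             (fitted$prob[1, 2, k] * fitted$prob[2, 1, k])
      expect_equal(or1, or0, tolerance = 1e-8)
    }
    # margins hit their targets
    expect_lt(max(abs(apply(fitted$prob, 1, sum) - c(t1, 1 - t1))), 1e-12)
  }
})

test_that("IPF preserves structural zeros and detects infeasibility", {
  seed <- make_2x2_seed(c(0.5, 0, 0.3, 0.2))
  fitted <- ipf_rake(seed, list(marginal_table("r", c(r1 = 0.7, r2 = 0.3)),
                                marginal_table("c", c(c1 = 0.6, c2 = 0.4))))
  expect_equal(fitted$prob[2, 1], 0)
  # positive target mass on an all-zero seed margin
  seed0 <- make_2x2_seed(c(0.6, 0.4, 0, 0)) # second column all zero
  expect_error(
    ipf_rake(seed0, list(marginal_table("c", c(c1 = 0.5, c2 = 0.5)))),
    class = "hlmrp_ipf_infeasible")
})

test_that("IMD deciles pool pairwise into quintiles", {
  m <- aggregate_imd(data.frame(lsoa_id = c("x", "y"),
                                imd_decile = c(1, 2),
                                population = c(100, 200)))
  expect_equal(unname(m$proportions), c(1, 0, 0, 0, 0))

  even <- data.frame(lsoa_id = paste0("l", 1:10), imd_decile = 1:10,
                     population = rep(50, 10))
  expect_equal(unname(aggregate_imd(even)$proportions), rep(0.2, 5))

  set.seed(4)
  mid <- data.frame(lsoa_id = sprintf("l%03d", 1:164),
                    imd_decile = sample(3:8, 164, replace = TRUE),
                    population = rpois(164, 1500))
  q <- aggregate_imd(mid)$proportions
  expect_equal(unname(q[c(1, 5)]), c(0, 0))
  expect_equal(sum(q), 1, tolerance = 1e-12)
  # direct pooling oracle
  byq <- vapply(1:5, function(k)
    sum(mid$population[ceiling(mid$imd_decile / 2) == k]), numeric(1))
  expect_equal(unname(q), byq / sum(mid$population), tolerance = 1e-12)

  expect_error(aggregate_imd(data.frame(lsoa_id = "x", imd_decile = 1,
                                        population = 0)),
               class = "hlmrp_degenerate_input")
})

test_that("combine_blocks multiplies block probabilities", {
  sch <- covariate_schema(list(A = c("a0", "a1"), B = c("b0", "b1")))
  fr <- combine_blocks(list(
    marginal_table("A", c(a0 = 0.3, a1 = 0.7)),
    marginal_table("B", c(b0 = 0.5, b1 = 0.5))), sch)
  expect_equal(fr$weights, c(0.15, 0.15, 0.35, 0.35))
})

test_that("combine_blocks recovers each block margin and matches a loop oracle", {
  sch <- toy_schema()
  joint_tx <- loglinear_joint(sch, c("t", "x"),
                              margins = list(t = c(a = 0.4, b = 0.6),
                                             x = c(lo = 0.3, hi = 0.7)),
                              tilts = list(list(v1 = "t", l1 = "b",
                                                v2 = "x", l2 = "hi",
                                                log_or = 0.7)))
  imd_m <- marginal_table("imd", c(q1 = 0.2, q2 = 0.5, q3 = 0.3))
  fr <- combine_blocks(list(joint_tx, imd_m), sch)
  expect_equal(sum(fr$weights), 1, tolerance = 1e-12)
  expect_true(all(fr$weights >= 0))
  # marginalisation identity
  back <- frame_margin(fr, c("t", "x"))
  expect_equal(back$prob, joint_tx$prob, tolerance = 1e-12)
  expect_equal(frame_margin(fr, "imd")$proportions, imd_m$proportions,
               tolerance = 1e-12)
  # brute-force product enumeration
  w <- numeric(nrow(fr$cells))
  for (c in seq_len(nrow(fr$cells))) {
    w[c] <- joint_tx$prob[fr$cells$t[c], fr$cells$x[c]] *
      imd_m$proportions[[fr$cells$imd[c]]]
  }
  expect_equal(fr$weights, w, tolerance = 1e-12)

  expect_error(combine_blocks(list(joint_tx), sch),
               class = "hlmrp_block_coverage")
})

test_that("frames round-trip through CSV", {
  sch <- toy_schema()
  fr <- random_frame(sch, 31)
  path <- tempfile(fileext = ".csv")
  write_frame_csv(fr, path)
  back <- read_frame_csv(path, sch)
  expect_equal(back$weights, fr$weights, tolerance = 1e-12)
  unlink(path)
})

test_that("full frame construction yields a valid 11520-cell frame", {
  b <- make_default_bundle(5, n_source = 500, n_target = 1500, n_lfs = 1500)
  fr <- bundle_frame(b)
  expect_s3_class(fr, "poststrat_frame")
  expect_equal(nrow(fr$cells), 11520)
  expect_equal(sum(fr$weights), 1, tolerance = 1e-12)
  expect_true(all(fr$weights >= 0))
  # raked block margins hit the emitted target margins
  for (m in b$lfs_margins) {
    got <- frame_margin(fr, m$variable)$proportions
    expect_equal(got[names(m$proportions)], m$proportions,
                 tolerance = 1e-8)
  }
})
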