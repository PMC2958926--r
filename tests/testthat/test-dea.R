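test_that("transform_nonstandard reflects columns with a 10%-range margin", {
  expect_equal(transform_nonstandard(c(3, 5, 9)), c(6.6, 4.6, 0.6))
  # constant column maps to the positive floor
  expect_equal(transform_nonstandard(c(4, 4, 4)), rep(1e-3, 3))
  # rank order is exactly reversed, outputs positive
  withr::with_seed(1, {
    for (rep in 1:20) {
      x <- stats::runif(8, 0.5, 20)
      y <- transform_nonstandard(x)
      expect_true(all(y > 0))
      expect_equal(order(y), rev(order(x)))
    }
  })
  expect_error(transform_nonstandard(c(1, -2)), "positive")
})

test_that("solve_dea matches closed forms on tiny instances", {
  # identical DMUs both score 1
  inst <- dea_instance(matrix(c(2, 2), 2, 1), matrix(c(3, 3), 2, 1))
  expect_equal(unname(solve_dea_all(inst, dea_config())), c(1, 1))
  # 1x1 constant-returns case: theta = (y/x) / max(y/x)
  inst <- dea_instance(matrix(c(1, 2), 2, 1), matrix(c(1, 1), 2, 1))
  expect_equal(solve_dea(inst, dea_config("input", "constant"), 2), 0.5,
               tolerance = 1e-9)
  # variable returns makes B efficient while constant returns does not
  inst <- dea_instance(matrix(c(1, 3), 2, 1), matrix(c(1, 2), 2, 1))
  expect_equal(solve_dea(inst, dea_config("input", "variable"), 2), 1,
               tolerance = 1e-9)
  expect_equal(solve_dea(inst, dea_config("input", "constant"), 2), 2 / 3,
               tolerance = 1e-9)
  # output orientation reported on the same (0,1] scale: for CRS 1x1 the
  # input and output radial scores coincide
  expect_equal(solve_dea(inst, dea_config("output", "constant"), 2), 2 / 3,
               tolerance = 1e-9)
  # instance validation
  expect_error(dea_instance(matrix(1, 1, 1), matrix(1, 1, 1)), "2 units")
  expect_error(dea_instance(matrix(c(1, 0), 2, 1), matrix(c(1, 1), 2, 1)),
               "positive")
})

test_that("unit invariance and dominance monotonicity hold", {
  withr::with_seed(7, {
    for (rep in 1:10) {
      X <- matrix(stats::runif(10, 1, 10), 5, 2)
      Y <- matrix(stats::runif(10, 1, 10), 5, 2)
      s1 <- solve_dea_all(dea_instance(X, Y), dea_config("input", "constant"))
      # scaling an input column leaves constant-returns scores unchanged
      X2 <- X; X2[, 1] <- X2[, 1] * 7.3
      s2 <- solve_dea_all(dea_instance(X2, Y), dea_config("input", "constant"))
      expect_equal(s1, s2, tolerance = 1e-6)
      # adding a dominated DMU never raises an incumbent's score
      Xd <- rbind(X, X[1, ] * 1.4)
      Yd <- rbind(Y, Y[1, ] * 0.8)
      s3 <- solve_dea_all(dea_instance(Xd, Yd), dea_config("input", "constant"))
      expect_true(all(s3[1:5] <= s1 + 1e-8))
    }
  })
})

test_that("Monte-Carlo engine is seeded, convergent and frontier-anchored", {
  g <- generate_sha(sha_config(n_units = 6), seed = 3)
  sp <- table_specs(g$table)
  roles <- vapply(sp, `[[`, character(1), "role")
  scen <- scenario("s", names(sp)[roles == "dea-input"][1:3],
                   names(sp)[roles == "dea-output"][1:2])
  ctrl <- mc_control(block_size = 40, max_runs = 400)
  pool <- run_monte_carlo(g$spec, config = dea_config(), scen = scen,
                          seed = 5, control = ctrl)
  expect_true(pool$converged)
  expect_true(all(pool$scores > 0 & pool$scores <= 1))
  # at least one DMU on the frontier in every run
  expect_true(all(apply(pool$scores, 1, max) >= 1 - 1e-6))
  # same seed -> bit-identical pool
  pool2 <- run_monte_carlo(g$spec, config = dea_config(), scen = scen,
                           seed = 5, control = ctrl)
  expect_identical(pool$scores, pool2$scores)
  # different seed -> different draws
  pool3 <- run_monte_carlo(g$spec, config = dea_config(), scen = scen,
                           seed = 6, control = ctrl)
  expect_false(identical(pool$scores, pool3$scores))
  # summaries recomputable from the score lists
  ps <- pool_summary(pool)
  expect_equal(ps$mean, unname(colMeans(pool$scores)))
  # non-standard annotation is applied per run (reflected column)
  ann <- read_io_annotations(annotations = list(
    UR2 = list(role = "output", orientation = "non-standard")))
  pool4 <- run_monte_carlo(g$spec, annotations = ann, config = dea_config(),
                           scen = scen, seed = 5, control = ctrl)
  expect_false(identical(pool$scores, pool4$scores))
})

test_that("point-mass specs converge in two blocks with zero variance", {
  g <- generate_sha(sha_config(n_units = 5, halfwidth_frac = 0),
                    seed = 11)
  sp <- table_specs(g$table)
  roles <- vapply(sp, `[[`, character(1), "role")
  scen <- scenario("s", names(sp)[roles == "dea-input"][1:2],
                   names(sp)[roles == "dea-output"][1:2])
  pool <- run_monte_carlo(g$spec, config = dea_config(), scen = scen,
                          seed = 1, control = mc_control(block_size = 20,
                                                         max_runs = 400))
  expect_true(pool$converged)
  expect_equal(pool$runs, 40L)       # exactly two blocks
  expect_equal(unname(apply(pool$scores, 2, stats::sd)), rep(0, 5))
})

test_that("tier classification applies the documented thresholds", {
  mk <- function(mean, frac) {
    # a 10-run single-DMU pool with the requested mean and
    # fraction-efficient (epsilon = 0.01)
    n_eff <- round(frac * 10)
    s <- matrix(1, 10, 1, dimnames = list(NULL, "dmu1"))
    if (n_eff < 10)
      s[(n_eff + 1):10, 1] <- (10 * mean - n_eff) / (10 - n_eff)
    structure(list(scores = s, runs = 10L, converged = TRUE,
                   config = dea_config(epsilon = 0.01)),
              class = "ebca_pool")
  }
  t1 <- classify_tiers(mk(1, 1))
  expect_equal(t1$tier, "efficient")
  expect_equal(t1$group, "efficient-group")
  t2 <- classify_tiers(mk(0.60, 0))
  expect_equal(t2$tier, "inefficient")
  expect_equal(t2$group, "inefficient-group")
  t3 <- classify_tiers(mk(0.92, 0.1))
  expect_equal(t3$tier, "nearly-efficient")
  expect_equal(t3$group, "efficient-group")
  t4 <- classify_tiers(mk(0.80, 0.1))
  expect_equal(t4$tier, "uncertain")
  expect_equal(t4$group, "inefficient-group")
  # binary collapse invariant
  for (p in list(t1, t2, t3, t4))
    expect_equal(p$group == "efficient-group",
                 p$tier %in% c("efficient", "nearly-efficient"))
})

test_that("scenario enumeration counts, prunes and orders deterministically", {
  specs <- list(variable_spec("i1", "numeric", "dea-input"),
                variable_spec("i2", "numeric", "dea-input"),
                variable_spec("o1", "numeric", "dea-output"),
                variable_spec("o2", "numeric", "dea-output"))
  sc <- enumerate_scenarios(specs, "automatic", max_inputs = 2,
                            max_outputs = 2)
  expect_length(sc, 9)      # (2^2-1)^2
  expect_identical(sc, enumerate_scenarios(specs, "automatic",
                                           max_inputs = 2, max_outputs = 2))
  # expert combinations pass through verbatim
  sc7 <- enumerate_scenarios(specs, "expert", expert = rep(list(
    list(inputs = "i1", outputs = "o1")), 7))
  expect_length(sc7, 7)
  expect_true(all(vapply(sc7, `[[`, character(1), "provenance") == "expert"))
  # a correlated output pair never co-occurs
  corr <- data.frame(var1 = "o1", var2 = "o2", correlation = 1)
  scp <- enumerate_scenarios(specs, "automatic", correlation = corr,
                             max_inputs = 2, max_outputs = 2)
  expect_true(all(vapply(scp, function(s)
    !all(c("o1", "o2") %in% s$outputs), logical(1))))
  # pruning everything is an error with advice
  corr_all <- data.frame(var1 = c("i1", "o1"), var2 = c("i2", "o2"))
  expect_error(enumerate_scenarios(specs, "automatic",
                                   correlation = corr_all, max_inputs = 1,
                                   max_outputs = 1), NA)
  expect_error(scenario("x", "a", "a"), "disjoint")
})
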