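two_class_table <- function(n = 40, shift = 5, seed = 1) {
  withr::with_seed(seed, {
    g <- rep(c("A", "B"), each = n / 2)
    df <- data.frame(
      x = stats::rnorm(n) + ifelse(g == "A", 0, shift),
      z = stats::rnorm(n),
      c = ifelse(stats::runif(n) < ifelse(g == "A", 0.9, 0.1), "red", "blue"))
    tab <- mixed_table(df, list(
      variable_spec("x", "numeric"), variable_spec("z", "numeric"),
      variable_spec("c", "categorical", categories = c("red", "blue"))),
      ids = sprintf("p%02d", seq_len(n)))
    list(table = tab, partition = factor(g))
  })
}

test_that("test_variables picks sensible tests and adjusts p-values", {
  tc <- two_class_table()
  res <- test_variables(tc$table, tc$partition)
  expect_setequal(res$variable, c("x", "z", "c"))
  expect_true(all(res$p_adj >= res$p, na.rm = TRUE))
  expect_true(all(res$p >= 0 & res$p <= 1, na.rm = TRUE))
  # shifted variable is significant, noise variable is not
  expect_lt(res$p_adj[res$variable == "x"], 0.01)
  expect_gt(res$p[res$variable == "z"], 0.05)
  expect_lt(res$p_adj[res$variable == "c"], 0.01)
  expect_equal(res$test[res$variable == "c"], "chi-squared")
  # two obviously separated tiny groups: a location test fires
  tab <- mixed_table(data.frame(v = c(1, 2, 3, 11, 12, 13)),
                     list(variable_spec("v", "numeric")),
                     ids = letters[1:6])
  res2 <- test_variables(tab, factor(rep(c("A", "B"), each = 3)))
  expect_lt(res2$p, 0.05)
  # constant variable skipped with a note
  tabc <- mixed_table(data.frame(v = rep(1, 6), w = c(1:3, 11:13)),
                      list(variable_spec("v", "numeric"),
                           variable_spec("w", "numeric")),
                      ids = letters[1:6])
  res3 <- test_variables(tabc, factor(rep(c("A", "B"), each = 3)))
  expect_equal(res3$test[res3$variable == "v"], "skipped")
  # label permutation leaves results unchanged
  perm <- factor(tc$partition, levels = c("B", "A"))
  res4 <- test_variables(tc$table, perm)
  expect_equal(res4[order(res4$variable), c("statistic", "p")],
               res[order(res$variable), c("statistic", "p")],
               ignore_attr = TRUE)
})

test_that("class panel graph cells are shared-binned, normalised distributions", {
  tc <- two_class_table()
  cpg <- build_cpg(tc$table, tc$partition)
  # frequencies sum to 1 in every occupied cell
  agg <- stats::aggregate(freq ~ class + variable, data = cpg, FUN = sum)
  expect_true(all(abs(agg$freq - 1) < 1e-9))
  # bins identical across classes within a variable
  for (v in unique(cpg$variable)) {
    bins_by_class <- split(cpg$bin[cpg$variable == v],
                           cpg$class[cpg$variable == v])
    expect_length(unique(lapply(bins_by_class, sort)), 1)
  }
  # single class, one categorical variable: plain frequencies
  tab <- mixed_table(data.frame(c = c("red", "red", "blue", "blue")),
                     list(variable_spec("c", "categorical",
                                        categories = c("red", "blue"))),
                     ids = letters[1:4])
  cpg1 <- build_cpg(tab, factor(rep("A", 4)))
  expect_equal(sort(cpg1$freq), c(0.5, 0.5))
  # disjoint supports occupy disjoint bins
  tab2 <- mixed_table(data.frame(v = c(1, 2, 101, 102)),
                      list(variable_spec("v", "numeric")),
                      ids = letters[1:4])
  cpg2 <- build_cpg(tab2, factor(c("A", "A", "B", "B")))
  occA <- cpg2$bin[cpg2$class == "A" & cpg2$count > 0]
  occB <- cpg2$bin[cpg2$class == "B" & cpg2$count > 0]
  expect_length(intersect(occA, occB), 0)
})

test_that("mark_cells flags association via adjusted residuals", {
  # 2x2 counts [[20,0],[0,20]]: all four residuals exceed 2 in magnitude
  tab <- mixed_table(
    data.frame(c = rep(c("red", "blue"), each = 20)),
    list(variable_spec("c", "categorical", categories = c("red", "blue"))),
    ids = sprintf("u%02d", 1:40))
  part <- factor(rep(c("A", "B"), each = 20))
  cpg <- mark_cells(build_cpg(tab, part))
  expect_equal(sum(cpg$marked), 4)
  # hand-check one adjusted residual: (20-10)/sqrt(10*0.5*0.5)
  # = 6.32 > 2 (verified against the closed form)
  expect_gt(abs(20 - 10) / sqrt(10 * 0.5 * 0.5), 2)
  # no association -> no marks
  withr::with_seed(3, {
    tabu <- mixed_table(
      data.frame(c = sample(c("red", "blue"), 200, replace = TRUE)),
      list(variable_spec("c", "categorical", categories = c("red", "blue"))),
      ids = sprintf("u%03d", 1:200))
    partu <- factor(rep(c("A", "B"), 100))
  })
  cpgu <- mark_cells(build_cpg(tabu, partu))
  expect_lte(sum(cpgu$marked), 4)  # only chance-level marks possible
  # shuffled labels produce near-zero marks at threshold 3
  tc <- two_class_table(n = 60)
  total_marks <- 0; total_cells <- 0
  withr::with_seed(11, {
    for (rep_i in 1:100) {
      sh <- sample(tc$partition)
      cpg_s <- mark_cells(build_cpg(tc$table, sh), threshold = 3)
      total_marks <- total_marks + sum(cpg_s$marked)
      total_cells <- total_cells + nrow(cpg_s)
    }
  })
  expect_lt(total_marks / total_cells, 0.01)
})

test_that("detect_inconsistencies flags planted anomalies, not noise", {
  # a class formed by two Gaussians 8 sd apart is bimodal
  withr::with_seed(21, {
    x <- c(stats::rnorm(40, 0), stats::rnorm(40, 8))
    y <- stats::rnorm(80)
  })
  tab <- mixed_table(data.frame(x = x, y = y),
                     list(variable_spec("x", "numeric"),
                          variable_spec("y", "numeric")),
                     ids = sprintf("p%03d", 1:80))
  part <- factor(rep(c("A", "B"), 40))   # interleaved: A holds both modes
  inc <- detect_inconsistencies(tab, part)
  expect_true(any(inc$variable == "x" & inc$anomaly == "bimodality"))
  # homogeneous Gaussian classes: false-positive rate below 5%
  n_flagged <- 0
  for (seed in 1:100) {
    withr::with_seed(seed + 500, {
      df <- data.frame(v = stats::rnorm(60))
    })
    tabh <- mixed_table(df, list(variable_spec("v", "numeric")),
                        ids = sprintf("p%02d", 1:60))
    inch <- detect_inconsistencies(tabh, factor(rep(c("A", "B"), 30)))
    if (any(inch$anomaly == "bimodality")) n_flagged <- n_flagged + 1
  }
  expect_lte(n_flagged, 5)
  # constant variable in a class is skipped
  tabc <- mixed_table(data.frame(v = rep(3, 30)),
                      list(variable_spec("v", "numeric")),
                      ids = sprintf("p%02d", 1:30))
  expect_equal(nrow(detect_inconsistencies(tabc, factor(rep("A", 30)))), 0)
})
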