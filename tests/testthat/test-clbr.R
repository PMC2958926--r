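test_that("mixed_distance matches the stated formula", {
  specs <- list(variable_spec("x", "numeric"),
                variable_spec("c", "categorical",
                              categories = c("red", "blue")))
  tab <- mixed_table(data.frame(x = c(0, 1), c = c("red", "blue")), specs,
                     ids = c("a", "b"))
  p <- mixed_params(alpha = 0.5, beta = 0.5, scale = c(x = 1))
  a <- tab[1, , drop = FALSE]; b <- tab[2, , drop = FALSE]
  # 0.5 * 1 + 0.5 * 1 = 1
  expect_equal(mixed_distance(a, b, p, tab), 1)
  expect_equal(mixed_distance(a, a, p, tab), 0)
  # purely numeric schema reduces to scaled squared Euclidean
  specs2 <- list(variable_spec("x", "numeric"), variable_spec("y", "numeric"))
  tab2 <- mixed_table(data.frame(x = c(0, 3), y = c(0, 4)), specs2,
                      ids = c("a", "b"))
  p2 <- mixed_params(alpha = 1, beta = 0, scale = c(x = 1, y = 1))
  expect_equal(mixed_distance(tab2[1, ], tab2[2, ], p2, tab2),
               (9 + 16) / 2)
  # symmetry and identity on random pairs; triangle inequality for the
  # numeric-only unsquared form
  for (seed in 1:10) {
    t3 <- random_mixed_table(3, nQ = 3, nC = 0, seed = seed)
    p3 <- mixed_params(t3)
    d_ab <- mixed_distance(t3[1, ], t3[2, ], p3, t3, squared = FALSE)
    d_ba <- mixed_distance(t3[2, ], t3[1, ], p3, t3, squared = FALSE)
    d_ac <- mixed_distance(t3[1, ], t3[3, ], p3, t3, squared = FALSE)
    d_cb <- mixed_distance(t3[3, ], t3[2, ], p3, t3, squared = FALSE)
    expect_equal(d_ab, d_ba)
    expect_lte(d_ab, d_ac + d_cb + 1e-12)
  }
  # pairwise-complete renormalisation: numeric missing leaves the
  # categorical block renormalised to full weight
  tabm <- mixed_table(data.frame(x = c(NA, 1), c = c("red", "blue")), specs,
                      ids = c("a", "b"))
  expect_equal(mixed_distance(tabm[1, ], tabm[2, ], p, tabm), 1)
})

test_that("build_prototype induces means, frequencies and mass", {
  specs <- list(variable_spec("x", "numeric"),
                variable_spec("c", "categorical",
                              categories = c("red", "blue")))
  tab <- mixed_table(data.frame(x = c(2, 4, NA), c = c("red", "red", "blue")),
                     specs, ids = c("a", "b", "d"))
  pr <- build_prototype(tab, 1:3)
  expect_equal(unname(pr$num["x"]), 3)
  expect_equal(unname(pr$cat$c), c(2 / 3, 1 / 3), ignore_attr = TRUE)
  expect_equal(pr$mass, 3)
  expect_equal(sum(pr$cat$c), 1)
  # singleton prototype equals the record
  pr1 <- build_prototype(tab, 1)
  expect_equal(unname(pr1$num["x"]), 2)
  expect_equal(unname(pr1$cat$c["red"]), 1)
  expect_equal(pr1$mass, 1)
  expect_error(build_prototype(tab, integer(0)), "empty")
})

test_that("rnn_ward_cluster reproduces the worked 1-D example", {
  tab <- mixed_table(data.frame(x = c(0, 1, 10, 11)),
                     list(variable_spec("x", "numeric")),
                     ids = c("a", "b", "c", "d"))
  d <- rnn_ward_cluster(tab, mixed_params(alpha = 1, beta = 0,
                                          scale = c(x = 1)))
  expect_equal(d$height, c(0.5, 0.5, 100))
  sets <- dendro_merge_sets(d)
  expect_equal(sets[[1]], c("a", "b"))
  expect_equal(sets[[2]], c("c", "d"))
  # two identical leaves merge at height 0
  tab0 <- mixed_table(data.frame(x = c(5, 5, 9)),
                      list(variable_spec("x", "numeric")),
                      ids = c("a", "b", "c"))
  d0 <- rnn_ward_cluster(tab0, mixed_params(alpha = 1, beta = 0,
                                            scale = c(x = 1)))
  expect_equal(d0$height[1], 0)
  expect_error(rnn_ward_cluster(tab0[1, , drop = FALSE]), "2 leaves")
})

test_that("dendrogram structure invariants hold on random tables", {
  for (seed in 1:10) {
    n <- 5 + seed
    tab <- random_mixed_table(n, nQ = 2, nC = 1, seed = seed)
    d <- rnn_ward_cluster(tab, mixed_params(tab))
    expect_equal(nrow(d$merge), n - 1)
    expect_true(all(diff(d$height) >= -1e-10))
    # cut sizes sum to n, for every k
    for (k in c(2, 3)) {
      lab <- cut_dendrogram(d, k)
      expect_equal(length(unique(lab)), k)
      expect_equal(length(lab), n)
    }
    # hclust conversion round-trips merges and heights
    h <- as.hclust(d)
    expect_s3_class(h, "hclust")
    expect_equal(h$height, d$height)
    expect_equal(sort(h$order), seq_len(n))
  }
})

test_that("dendrogram equals exhaustive greedy Ward agglomeration (oracle)", {
  for (seed in 1:12) {
    n <- 4 + (seed %% 5)
    tab <- random_mixed_table(n, nQ = 2, nC = 1, seed = seed + 50)
    params <- mixed_params(tab)
    d <- rnn_ward_cluster(tab, params)
    # oracle distance matrix via the independent record-level formula
    kinds <- vapply(table_specs(tab), `[[`, character(1), "kind")
    df <- as.data.frame(tab)
    d2 <- matrix(0, n, n)
    for (i in seq_len(n)) for (j in seq_len(n)) if (i != j)
      d2[i, j] <- oracle_mixed_d2(df[i, ], df[j, ], kinds, params$scale,
                                  params$alpha, params$beta)
    orc <- oracle_greedy_ward(d2, rep(1, n), table_ids(tab))
    expect_equal(d$height, orc$heights, tolerance = 1e-9)
    expect_equal(dendro_merge_sets(d), orc$sets)
  }
})

test_that("calinski_cut reproduces the worked example and finds k", {
  tab <- mixed_table(data.frame(x = c(0, 2, 10, 12)),
                     list(variable_spec("x", "numeric")),
                     ids = letters[1:4])
  d <- rnn_ward_cluster(tab, mixed_params(alpha = 1, beta = 0,
                                          scale = c(x = 1)))
  ch <- calinski_cut(d, kmax = 3)
  expect_equal(ch$ch[ch$k == 2], 50)       # B=100, W=4, n=4, k=2
  expect_equal(attr(ch, "k_star"), 2)
  # zero within-class scatter -> Inf sentinel
  tab0 <- mixed_table(data.frame(x = c(0, 0, 10, 10)),
                      list(variable_spec("x", "numeric")),
                      ids = letters[1:4])
  d0 <- rnn_ward_cluster(tab0, mixed_params(alpha = 1, beta = 0,
                                            scale = c(x = 1)))
  ch0 <- calinski_cut(d0, kmax = 3)
  expect_equal(ch0$ch[ch0$k == 2], Inf)
  expect_equal(attr(ch0, "k_star"), 2)
  expect_error(calinski_cut(d0, kmax = 9), "kmax")
})

test_that("empty-KB clustering reduces to plain Ward clustering", {
  for (seed in 1:5) {
    tab <- random_mixed_table(25, nQ = 2, nC = 1, seed = seed)
    params <- mixed_params(tab)
    res <- clbr_cluster(tab, kb_empty("clbr"), params = params, kmax = 6)
    dend <- rnn_ward_cluster(tab, params)
    plain <- cut_dendrogram(dend, res$k)
    expect_true(same_partition(res$partition, plain))
    expect_true(all(attr(res$partition, "provenance") == "data-driven"))
  }
})

test_that("rule classes land intact in one final class", {
  for (seed in 1:15) {
    tab <- random_mixed_table(30, nQ = 2, nC = 1, seed = seed + 7)
    kb <- random_kb(tab, n_rules = 2, seed = seed)
    res <- suppressWarnings(clbr_cluster(tab, kb, kmax = 5))
    rg <- res$rule_groups
    for (rid in setdiff(levels(rg), "residual")) {
      rows <- rg == rid
      if (any(rows))
        expect_length(unique(res$partition[rows]), 1)
    }
    # group sizes sum to n
    expect_equal(length(res$partition), 30L)
    expect_false(anyNA(res$partition))
  }
})

test_that("a rule capturing a planted cluster preserves the solution", {
  g <- generate_patients(patient_config(n = 150, k = 3, separation = 6,
                                        seed = 31))
  res0 <- clbr_cluster(g$table, kb_empty("clbr"), kmax = 6)
  kb <- example_patient_kb(g$table)
  res1 <- suppressWarnings(clbr_cluster(g$table, kb, kmax = 6))
  expect_equal(res0$k, res1$k)
  expect_gte(adjusted_rand_index(res1$partition, g$truth), 0.9)
  # the rule-seeded classes are labelled as such
  expect_true("rule-seeded" %in% attr(res1$partition, "provenance"))
})

test_that("newick export is well formed", {
  skip_if_not_installed("ape")
  tab <- random_mixed_table(6, seed = 2)
  d <- rnn_ward_cluster(tab, mixed_params(tab))
  nwk <- dendrogram_newick(d)
  expect_match(nwk, "^\\(.*\\);$")
  ph <- ape::read.tree(text = nwk)
  expect_setequal(ph$tip.label, table_ids(tab))
})

test_that("adjusted_rand_index behaves at the extremes", {
  a <- rep(1:3, each = 10)
  expect_equal(adjusted_rand_index(a, a), 1)
  b <- a; b[a == 1] <- 4          # pure relabelling
  expect_equal(adjusted_rand_index(a, b), 1)
  withr::with_seed(5, {
    r <- replicate(50, adjusted_rand_index(a, sample(a)))
    expect_lt(abs(mean(r)), 0.05)
  })
})
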