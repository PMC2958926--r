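patient_meta <- function() {
  list(variable_spec("GAFCLA", "numeric"),
       variable_spec("GAFSOCIAL", "numeric"),
       variable_spec("MAXECFOS_A", "numeric"),
       variable_spec("MAXECFOS_B", "categorical",
                     categories = c("Never", "Some_Days", "Every_Day")),
       variable_spec("INGRESE", "categorical",
                     categories = c("WORK", "PENSION", "UNEMPLOYED")))
}

example_rules <- c(
  "r1: if ((GAFCLA < 40) or (GAFSOCIAL < 40)) and ((MAXECFOS_A > 15) and (MAXECFOS_B = Every_Day)) then severely-ill",
  "r2: if (INGRESE = WORK) and ((GAFCLA > 70) or (GAFSOCIAL > 70)) then good-condition")

test_that("parsing the example rules yields the expected trees", {
  kb <- kb_parse(example_rules, patient_meta())
  expect_s3_class(kb, "ebca_kb")
  expect_length(kb$rules, 2)
  r1 <- kb$rules[[1]]
  expect_equal(r1$id, "r1")
  expect_equal(r1$conclusion, "severely-ill")
  # 4 leaf conditions in r1
  count_leaves <- function(node) {
    if (node$node == "cond") return(1)
    if (node$node == "not") return(count_leaves(node$arg))
    sum(vapply(node$args, count_leaves, numeric(1)))
  }
  expect_equal(count_leaves(r1$antecedent), 4)
  expect_equal(r1$antecedent$node, "and")
  # empty text is a valid blind-analysis KB
  kb0 <- kb_parse("", patient_meta())
  expect_length(kb0$rules, 0)
  # comments and blank lines ignored
  kbc <- kb_parse(c("# header", "", example_rules[1]), patient_meta())
  expect_length(kbc$rules, 1)
})

test_that("parser rejects bad input loudly", {
  meta <- patient_meta()
  expect_error(kb_parse("r: if (FOO < 1) then x", meta), "FOO")
  expect_error(
    kb_parse("r: if (GAFCLA<40) and (GAFSOCIAL<40) or (MAXECFOS_A>15) then x",
             meta),
    "parentheses")
  expect_error(kb_parse("r: if (MAXECFOS_B < 3) then x", meta), "ordering")
  expect_error(kb_parse("r: if (GAFCLA = WORK) then x", meta), "category")
  expect_error(kb_parse("r: if (GAFCLA in [5,1]) then x", meta), "order")
  expect_error(kb_parse("r: if (INGRESE = FARMER) then x", meta),
               "not declared")
  expect_error(kb_parse(rep(example_rules[1], 2), meta), "duplicate")
})

test_that("serialisation round-trips the expression tree identically", {
  meta <- patient_meta()
  kb <- kb_parse(example_rules, meta)
  kb2 <- kb_parse(kb_format(kb), meta)
  expect_identical(lapply(kb$rules, `[[`, "antecedent"),
                   lapply(kb2$rules, `[[`, "antecedent"))
  # with intervals, sets and negation (extension operators)
  kb3 <- kb_parse(
    "rx: if (not (GAFCLA in [40,70))) and (INGRESE in {WORK,PENSION}) then mid",
    meta)
  kb4 <- kb_parse(kb_format(kb3), meta)
  expect_identical(kb3$rules[[1]]$antecedent, kb4$rules[[1]]$antecedent)
  # JSON round trip preserves rules, mode and version
  f <- tempfile(fileext = ".json")
  kb$version <- 3L
  kb_to_json(kb, f)
  kb5 <- kb_from_json(f)
  expect_identical(kb_format(kb5), kb_format(kb))
  expect_identical(kb5$version, 3L)
})

test_that("round-trip identity holds on randomly generated rules", {
  for (seed in 1:25) {
    tab <- random_mixed_table(20, nQ = 2, nC = 2, seed = seed)
    kb <- random_kb(tab, n_rules = 3, seed = seed)
    kb2 <- kb_parse(kb_format(kb), table_specs(tab))
    expect_identical(lapply(kb$rules, `[[`, "antecedent"),
                     lapply(kb2$rules, `[[`, "antecedent"))
  }
})

test_that("rule evaluation follows Kleene three-valued logic", {
  kb <- kb_parse(example_rules, patient_meta())
  r1 <- kb$rules[[1]]; r2 <- kb$rules[[2]]
  expect_equal(evaluate_rule(r1, list(GAFCLA = 35, GAFSOCIAL = 60,
                                      MAXECFOS_A = 20,
                                      MAXECFOS_B = "Every_Day")), "fires")
  expect_equal(evaluate_rule(r2, list(INGRESE = "WORK", GAFCLA = 75,
                                      GAFSOCIAL = 50)), "fires")
  expect_equal(evaluate_rule(r2, list(INGRESE = "PENSION", GAFCLA = 75,
                                      GAFSOCIAL = 75)), "no-fire")
  # missing GAFCLA, GAFSOCIAL = 60: first disjunct undetermined -> unknown
  expect_equal(evaluate_rule(r1, list(GAFCLA = NA, GAFSOCIAL = 60,
                                      MAXECFOS_A = 20,
                                      MAXECFOS_B = "Every_Day")), "unknown")
  # FALSE and NA is still FALSE (burden condition fails decisively)
  expect_equal(evaluate_rule(r1, list(GAFCLA = NA, GAFSOCIAL = 60,
                                      MAXECFOS_A = 5,
                                      MAXECFOS_B = "Every_Day")), "no-fire")
  # TRUE or NA is still TRUE inside the disjunct
  expect_equal(evaluate_rule(r1, list(GAFCLA = 30, GAFSOCIAL = NA,
                                      MAXECFOS_A = 20,
                                      MAXECFOS_B = "Every_Day")), "fires")
  # records without missing values never yield unknown
  for (seed in 1:10) {
    tab <- random_mixed_table(15, seed = seed)
    kb <- random_kb(tab, seed = seed)
    df <- as.data.frame(tab)
    for (i in seq_len(nrow(df)))
      for (r in kb$rules)
        expect_false(evaluate_rule(r, df[i, , drop = FALSE]) == "unknown")
  }
})

test_that("evaluation errors on kind mismatches", {
  kb <- kb_parse("r: if GAFCLA < 40 then x",
                 list(variable_spec("GAFCLA", "numeric")))
  expect_error(evaluate_rule(kb$rules[[1]], list(GAFCLA = "oops")),
               "numeric")
  expect_error(evaluate_rule(kb$rules[[1]], list(OTHER = 1)), "absent")
})

test_that("partition_by_rules assigns first match and counts groups", {
  meta <- patient_meta()
  kb <- kb_parse(example_rules, meta)
  df <- data.frame(
    GAFCLA = c(30, 35, 80, 55, 60),
    GAFSOCIAL = c(35, 30, 90, 50, 55),
    MAXECFOS_A = c(20, 25, 2, 5, 8),
    MAXECFOS_B = c("Every_Day", "Every_Day", "Never", "Some_Days", "Never"),
    INGRESE = c("PENSION", "UNEMPLOYED", "WORK", "PENSION", "PENSION"))
  tab <- mixed_table(df, meta, ids = paste0("p", 1:5))
  part <- kb_partition(kb, tab)
  expect_equal(as.vector(attr(part, "counts")), c(2, 1, 2))
  expect_equal(sum(attr(part, "counts")), nrow(tab))
  # overlap: a record firing both rules goes to r1 with a warning
  df2 <- df
  df2[1, ] <- list(30, 35, 20, "Every_Day", "WORK")
  df2$GAFSOCIAL[1] <- 75   # r1: GAFCLA<40 ok; r2: WORK & GAFSOCIAL>70 ok
  tab2 <- mixed_table(df2, meta, ids = paste0("p", 1:5))
  expect_warning(p2 <- kb_partition(kb, tab2), "more than one rule")
  expect_equal(as.character(p2[1]), "r1")
  # unknown status -> residual with warning
  df3 <- df
  df3$GAFCLA[1] <- NA; df3$GAFSOCIAL[1] <- NA
  tab3 <- mixed_table(df3, meta, ids = paste0("p", 1:5))
  expect_warning(p3 <- kb_partition(kb, tab3), "unknown")
  expect_equal(as.character(p3[1]), "residual")
  expect_equal(attr(p3, "n_unknown"), 1L)
  # empty KB: everything residual
  p0 <- kb_partition(kb_empty("clbr"), tab)
  expect_true(all(p0 == "residual"))
})

test_that("adding a later rule never reassigns earlier-captured records", {
  for (seed in 1:10) {
    tab <- random_mixed_table(25, seed = seed)
    kb2 <- random_kb(tab, n_rules = 2, seed = seed)
    kb3 <- kb2
    extra <- random_kb(tab, n_rules = 1, seed = seed + 100)$rules[[1]]
    extra$id <- "k99"
    kb3$rules <- c(kb3$rules, list(extra))
    p2 <- suppressWarnings(kb_partition(kb2, tab))
    p3 <- suppressWarnings(kb_partition(kb3, tab))
    captured <- p2 != "residual"
    expect_identical(as.character(p2[captured]), as.character(p3[captured]))
  }
})

test_that("kb_diff reports added/removed/modified and versions the KB", {
  meta <- patient_meta()
  kb_a <- kb_parse(example_rules, meta)
  kb_b <- kb_parse(c(example_rules,
                     "r3: if (MAXECFOS_A > 30) then institutionalised"), meta)
  d <- kb_diff(kb_a, kb_b)
  expect_equal(d$added, "r3")
  expect_length(d$removed, 0)
  expect_length(d$modified, 0)
  expect_equal(d$new_kb$version, 2L)
  expect_match(d$new_kb$changelog[1], "added\\{r3\\}")
  # identical KBs -> empty changeset
  d0 <- kb_diff(kb_a, kb_a)
  expect_length(c(d0$added, d0$removed, d0$modified), 0)
  # same id, different antecedent -> modified
  kb_c <- kb_parse(sub("< 40", "< 45", example_rules), meta)
  dm <- kb_diff(kb_a, kb_c)
  expect_equal(dm$modified, "r1")
  # mode mismatch is an error
  expect_error(kb_diff(kb_a, kb_empty("dea")), "mode")
})

test_that("io annotations validate orientation/margin coupling", {
  f <- tempfile(fileext = ".yaml")
  writeLines(c("UR2:", "  role: output", "  orientation: standard",
               "TR4R7:", "  role: input", "  orientation: non-standard",
               "  margin: 0.2"), f)
  ann <- read_io_annotations(f)
  expect_equal(ann$UR2$orientation, "standard")
  expect_equal(ann$TR4R7$margin, 0.2)
  expect_error(read_io_annotations(annotations = list(
    X = list(role = "input", orientation = "standard", margin = 0.1))),
    "margin")
})
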