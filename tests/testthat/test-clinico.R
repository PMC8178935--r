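test_that("the 2x2 chi-square matches the closed form and chisq.test", {
  x <- rep(c(TRUE, FALSE), c(10, 10))
  y <- c(rep(TRUE, 8), rep(FALSE, 2), rep(TRUE, 2), rep(FALSE, 8))
  res <- chisq2x2(x, y)
  # hand formula: n(ad-bc)^2 / (row and column margins)
  expect_equal(res[1], 20 * (8 * 8 - 2 * 2)^2 / (10 * 10 * 10 * 10))
  ref <- suppressWarnings(chisq.test(table(x, y), correct = FALSE))
  expect_equal(res[1], unname(ref$statistic))
  expect_equal(res[2], ref$p.value)
  # empty margin -> NA
  expect_true(is.na(chisq2x2(rep(TRUE, 5), c(1, 0, 1, 0, 1) == 1)[1]))
})

test_that("age dichotomization recovers a planted threshold near 65", {
  hits <- 0L
  for (s in 1:50) {
    cfg <- simulation_config(n_patients = 500, n_probes = 50, event_rate = 0.3,
                             clinical_effects = c(age = 4), seed = s)
    co <- generate_cohort(cfg)
    cut <- dichotomize_continuous(co, "age")
    if (cut %in% c(60, 65, 70)) hits <- hits + 1L
  }
  expect_gte(hits / 50, 0.9)
  # constant feature errors
  co$age <- 60
  expect_error(dichotomize_continuous(co, "age"), "constant")
})

test_that("the tree recovers a single planted factor as a depth-1 split", {
  hits <- 0L
  for (s in 1:50) {
    cfg <- simulation_config(n_patients = 400, n_probes = 50, event_rate = 0.3,
                             clinical_effects = c(pni = 5), seed = s + 200)
    co <- generate_cohort(cfg)
    tree <- build_partition_tree(co)
    if (!isTRUE(tree$root$leaf) && tree$root$condition$feature == "pni") {
      hits <- hits + 1L
    }
  }
  expect_gte(hits / 50, 0.9)
})

test_that("pure-noise features usually yield a single-leaf tree", {
  null_eff <- setNames(rep(1, 10), clinico_panel_features())
  single <- 0L
  for (s in 1:50) {
    cfg <- simulation_config(n_patients = 300, n_probes = 50, event_rate = 0.3,
                             clinical_effects = null_eff, seed = s + 400)
    co <- generate_cohort(cfg)
    tree <- build_partition_tree(co)
    if (isTRUE(tree$root$leaf)) single <- single + 1L
  }
  # the split search runs ~13 correlated candidate tests per node at
  # alpha = 0.05, so a no-split tree should still dominate under the null
  expect_gte(single / 50, 0.6)
})

test_that("a deterministic outcome gives pure leaves", {
  co <- data.frame(patient_id = sprintf("P%02d", 1:100),
                   pni = rep(c("Yes", "No"), each = 50),
                   outcome = rep(c(1L, 0L), each = 50),
                   stringsAsFactors = FALSE)
  tree <- build_partition_tree(co, features = "pni", min_leaf = 10)
  expect_false(isTRUE(tree$root$leaf))
  rates <- c(tree$root$yes$n_event / tree$root$yes$n,
             tree$root$no$n_event / tree$root$no$n)
  expect_setequal(rates, c(0, 1))
})

test_that("node odds ratios convert to integer points as specified", {
  # 8 dead/2 alive exposed vs 2 dead/8 alive unexposed: OR (8*8)/(2*2) = 16
  co <- data.frame(
    patient_id = sprintf("P%02d", 1:20),
    pni = rep(c("Yes", "No"), each = 10),
    outcome = c(rep(1L, 8), 0L, 0L, 1L, 1L, rep(0L, 8)),
    stringsAsFactors = FALSE
  )
  tree <- build_partition_tree(co, features = "pni", min_leaf = 5, stop_alpha = 0.5)
  model <- tree_to_score(tree, co)
  expect_equal(length(model$rules), 1)
  expect_equal(model$rules[[1]]$node_or, 16)
  expect_equal(model$rules[[1]]$points, 16)
  # rounding convention is round-half-even
  expect_equal(round(1.4), 1)
  expect_equal(round(2.5), 2)
  # single-leaf tree scores everyone zero
  null_tree <- build_partition_tree(co, features = "pni", min_leaf = 50)
  null_model <- tree_to_score(null_tree, co)
  expect_equal(unname(score_patients(null_model, co)), rep(0L, 20))
})

test_that("zero cells use the Haldane-Anscombe correction instead of failing", {
  co <- data.frame(
    patient_id = sprintf("P%02d", 1:40),
    pni = rep(c("Yes", "No"), each = 20),
    outcome = c(rep(1L, 12), rep(0L, 8), rep(0L, 20)),
    stringsAsFactors = FALSE
  )
  model <- fit_clinico_score(co, features = "pni", min_leaf = 10)
  or_expected <- (12.5 * 20.5) / (8.5 * 0.5)
  expect_equal(model$rules[[1]]$node_or, or_expected)
  expect_equal(model$rules[[1]]$points, round(or_expected))
})

test_that("patient scoring tallies satisfied rules, skips missing, rejects unknown levels", {
  co <- data.frame(
    patient_id = sprintf("P%02d", 1:60),
    pni = rep(c("Yes", "No"), each = 30),
    stage = rep(c("II", "I"), 30),
    outcome = c(rep(1L, 20), rep(0L, 10), rep(1L, 5), rep(0L, 25)),
    stringsAsFactors = FALSE
  )
  model <- fit_clinico_score(co, features = c("pni", "stage"), min_leaf = 10)
  expect_gte(length(model$rules), 1)
  scores <- score_patients(model, co)
  # manual tally over the rule list
  manual <- integer(60)
  for (r in model$rules) {
    sat <- rep(TRUE, 60)
    for (cond in r$conjuncts) {
      v <- co[[cond$feature]] %in% cond$levels
      if (isTRUE(cond$negate)) v <- !v
      sat <- sat & v
    }
    manual <- manual + r$points * sat
  }
  expect_equal(unname(scores), manual)
  # monotone: satisfying an extra rule never lowers a score
  expect_true(all(scores >= 0))
  # missing value in a used feature skips the rule with a message
  co_na <- co; co_na$pni[1] <- NA
  expect_message(s_na <- score_patients(model, co_na), "skipped")
  expect_lte(s_na[1], scores[1])
  # unknown category level errors by name
  co_bad <- co; co_bad$pni[2] <- "Maybe"
  expect_error(score_patients(model, co_bad), "Maybe")
})

test_that("tree construction is deterministic given the cohort", {
  cfg <- simulation_config(n_patients = 300, n_probes = 50, event_rate = 0.37,
                           clinical_effects = c(pni = 3.5, stage = 3), seed = 9)
  co <- generate_cohort(cfg)
  m1 <- fit_clinico_score(co)
  m2 <- fit_clinico_score(co)
  expect_identical(attr(m1, "training_scores"), attr(m2, "training_scores"))
  expect_equal(length(m1$rules), length(m2$rules))
})
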