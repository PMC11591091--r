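test_that("the default cohort reproduces the deposited structural counts", {
  co <- simulate_cohort(cohort_spec(seed = 7))
  expect_equal(nrow(co), 88)
  schema <- attr(co, "schema")
  expect_equal(nrow(schema), 127)
  expect_equal(as.integer(table(schema$category)[c(
    "personal", "medical_exam1", "medical_exam2", "lifestyle", "nutrient")]),
    c(6L, 16L, 16L, 10L, 79L))
  ck <- check_diabmini(co)
  expect_true(ck$ok_samples)
  expect_true(ck$ok_features)
  expect_equal(ck$label_counts, c(21L, 15L, 52L))
  expect_equal(ck$drinking_never, 69L)
})

test_that("simulated exam columns reproduce the intended classes exactly", {
  for (s in c(1, 5, 9)) {
    spec <- cohort_spec(seed = s)
    co <- simulate_cohort(spec)
    labs <- label_change(co$hba1c_exam1, co$hba1c_exam2, epsilon = 0)$class
    expect_identical(labs, attr(co, "classes"))
    expect_equal(as.integer(table(factor(labs, 0:2))), spec$counts)
  }
})

test_that("planted effects shift the driven class by the requested size", {
  eff <- data.frame(feature = c("age", "se"), class = c(0, 1),
                    size = c(2, -2))
  co <- simulate_cohort(cohort_spec(effects = eff, seed = 3))
  y <- attr(co, "classes")
  # age is shifted upward in class 0 by ~2 pooled sd
  shift_age <- (mean(co$age[y == 0]) - mean(co$age[y != 0])) / sd(co$age)
  expect_gt(shift_age, 1)
  # se is shifted downward in class 1 (log scale: compare medians)
  expect_lt(median(co$se[y == 1]), median(co$se[y != 1]))
})

test_that("simulation is deterministic and fixtures are byte-identical per seed", {
  co1 <- simulate_cohort(cohort_spec(seed = 12))
  co2 <- simulate_cohort(cohort_spec(seed = 12))
  expect_identical(co1, co2)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_cohort_fixture(co1, d1)
  write_cohort_fixture(co2, d2)
  expect_identical(readLines(file.path(d1, "cohort.csv")),
                   readLines(file.path(d2, "cohort.csv")))
  expect_identical(readLines(file.path(d1, "schema.yaml")),
                   readLines(file.path(d2, "schema.yaml")))
})

test_that("cohort fixtures round-trip through write and load", {
  co <- simulate_cohort(cohort_spec(seed = 15))
  dir <- withr::local_tempdir()
  write_cohort_fixture(co, dir)
  back <- load_cohort(file.path(dir, "cohort.csv"),
                      file.path(dir, "schema.yaml"))
  expect_equal(back[names(co)], as.data.frame(co), ignore_attr = TRUE)
  # loaded cohorts feed the predictor assembly unchanged
  ap1 <- assemble_predictors(co)
  ap2 <- assemble_predictors(back)
  expect_equal(ap1$X, ap2$X)
  expect_equal(ap1$y, ap2$y)
})

test_that("infeasible specs and unknown planted features are rejected", {
  expect_error(cohort_spec(proportions = c(-1, 2, 3)), class = "dk_spec_error")
  expect_error(cohort_spec(effects = data.frame(feature = "nonesuch",
                                                class = 0, size = 1)),
               class = "dk_spec_error")
  # weights that do not sum to n are rescaled by largest remainder
  sp <- cohort_spec(n = 40, proportions = c(21, 15, 52))
  expect_equal(sum(sp$counts), 40)
})

test_that("stronger planted effects never weaken that feature's attribution", {
  # effect-size monotonicity, averaged over seeds, on a compact grid
  sizes <- c(0, 1, 2.5)
  mean_abs <- sapply(sizes, function(sz) {
    vals <- sapply(1:3, function(s) {
      eff <- data.frame(feature = "se", class = 1, size = -sz)
      co <- simulate_cohort(cohort_spec(effects = eff, seed = 100 + s))
      ap <- assemble_predictors(co)
      model <- fit_stacked(ap$X, ap$y, config = fast_config(), seed = s)
      idx <- seq(1, 88, by = 4)
      bg <- ap$X[seq(2, 88, by = 8), , drop = FALSE]
      rep_ <- shapley_attribution(model, ap$X[idx, , drop = FALSE], bg,
                                  nsim = 8, seed = s)
      mean(abs(rep_$phi[, "se", ]))
    })
    mean(vals)
  })
  expect_gt(mean_abs[3], mean_abs[1])
  expect_gte(mean_abs[2], mean_abs[1] * 0.8)
})
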