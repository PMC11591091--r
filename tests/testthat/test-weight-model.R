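test_that("a planted linear law is recovered exactly without penalty", {
  ds <- make_cuisine_dataset(300, F = 5, seed = 2)
  ds$weight <- 3 * ds$area
  m <- fit_weight_model(ds, lambda = 0)
  cf <- coef(m)
  expect_equal(unname(cf["area"]), 3, tolerance = 1e-6)
  others <- cf[setdiff(names(cf), c("area", "(Intercept)"))]
  expect_lt(max(abs(others)), 1e-6)
  # prediction on a training row of the exact fit returns the label
  expect_equal(predict(m, ds[7, ]), ds$weight[7], tolerance = 1e-8)
})

test_that("a large penalty shrinks all coefficients and leaves the mean", {
  ds <- make_cuisine_dataset(200, F = 4, seed = 3)
  ds$weight <- 3 * ds$area
  m <- fit_weight_model(ds, lambda = 1e6)
  expect_equal(sum(abs(coef(m)[-1]) > 1e-10), 0)
  expect_equal(unname(coef(m)[1]), mean(ds$weight), tolerance = 1e-6)
})

test_that("noiseless parameter recovery holds with per-type densities", {
  # truth: weight = density_t * area (type-specific slope, no noise)
  ds <- make_cuisine_dataset(400, F = 4, seed = 5, sigma = 0)
  ds$weight <- ds$weight_true
  m <- fit_weight_model(ds, lambda = 1e-4, interactions = TRUE, seed = 1)
  # per-type slope = area coef + interaction coef; compare against the
  # simulator's planted densities (area is the pixelated footprint, weight
  # uses the exact one -> tolerance covers pixelation)
  types <- diabkit:::cuisine_types(4, seed = 5)
  cf <- coef(m)
  for (t in 1:4) {
    slope <- unname(cf["area"] + cf[paste0("area:type", t)])
    expect_equal(slope, types$density[t], tolerance = 0.02)
  }
})

test_that("prediction clamps at zero, vectorizes, and rejects unseen types", {
  ds <- make_cuisine_dataset(100, F = 3, seed = 6)
  m <- fit_weight_model(ds, lambda = 0)
  batch <- predict(m, ds[1:10, ])
  rowwise <- vapply(1:10, function(i) predict(m, ds[i, , drop = FALSE]),
                    numeric(1))
  expect_equal(batch, rowwise)
  expect_true(all(batch >= 0))
  expect_equal(predict_weight(m, ds$type_id[1], ds$alpha[1], ds$distance[1],
                              ds$area[1]), batch[1])
  expect_error(predict(m, data.frame(type_id = 99, alpha = 1, distance = 0.5,
                                     area = 0.01)),
               class = "dk_unknown_type")
  expect_error(fit_weight_model(ds[1, ]), class = "dk_input_error")
})

test_that("MAE evaluation matches its definition and is row-order invariant", {
  ds <- make_cuisine_dataset(60, F = 3, seed = 8)
  m <- fit_weight_model(ds, lambda = 0)
  ev <- evaluate_mae(m, ds)
  expect_equal(ev$mae, mean(abs(predict(m, ds) - ds$weight)))
  perm <- sample(nrow(ds))
  expect_equal(evaluate_mae(m, ds[perm, ])$mae, ev$mae)
  # perfect model scores 0; constant-0 model on labels all 10 scores 10
  ds0 <- ds; ds0$weight <- predict(m, ds)
  expect_equal(evaluate_mae(m, ds0)$mae, 0)
  zero <- m; zero$coefficients[] <- 0
  ds10 <- ds; ds10$weight <- 10
  expect_equal(evaluate_mae(zero, ds10)$mae, 10)
})

test_that("cross-validated MAE matches a brute-force fold loop", {
  ds <- make_cuisine_dataset(120, F = 4, seed = 12)
  cv <- cv_weight_mae(ds, lambda = 0, K = 4, seed = 3)
  plan <- stratified_folds(factor(ds$type_id), 4, 3)
  brute <- sapply(plan$folds, function(idx) {
    fit <- fit_weight_model(ds[-idx, ], lambda = 0, seed = 3)
    mean(abs(predict(fit, ds[idx, ]) - ds$weight[idx]))
  })
  expect_equal(cv$per_fold, unname(brute))
  expect_equal(cv$mae, mean(brute))
})

test_that("held-out MAE stays within 1.5x the noise floor at n = 1000", {
  ds <- make_cuisine_dataset(1000, F = 19, seed = 4, sigma = 0.05)
  noise_floor <- mean(abs(ds$weight - ds$weight_true))
  cv <- cv_weight_mae(ds, lambda = 0, interactions = TRUE, seed = 9)
  expect_lt(cv$mae, 1.5 * noise_floor)
})

test_that("the active set never grows as the penalty increases", {
  ds <- make_cuisine_dataset(300, F = 6, seed = 13)
  path <- 10^seq(-3, 2, length.out = 12)
  nz <- sapply(path, function(l)
    sum(abs(coef(fit_weight_model(ds, lambda = l, interactions = TRUE))[-1]) > 1e-8))
  expect_true(all(diff(nz) <= 0))
})
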