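test_that("camera position follows the tilt angle", {
  spec <- phone_spec(0.15, pi / 6)
  expect_equal(unname(camera_position(spec, pi / 2)), c(0, 0.15),
               tolerance = 1e-12)
  expect_equal(unname(camera_position(spec, pi / 3)),
               c(0.15 * cos(pi / 3), 0.15 * sin(pi / 3)), tolerance = 1e-12)
  # flat-phone limit
  expect_equal(unname(camera_position(spec, 1e-9)), c(0.15, 0),
               tolerance = 1e-9)
  expect_error(camera_position(spec, 0), class = "dk_input_error")
})

test_that("field-boundary table intersection matches the sine-rule value and identities", {
  spec <- phone_spec(0.15, pi / 6)
  expect_equal(base_intersection(spec, pi / 3), 0.075, tolerance = 1e-12)
  # vertical phone: l_OB = p tan(beta)
  expect_equal(base_intersection(spec, pi / 2), 0.15 * tan(pi / 6),
               tolerance = 1e-12)
  # beta -> 0 grazes the base
  expect_lt(base_intersection(phone_spec(0.15, 1e-9), pi / 3), 1e-8)
})

test_that("image point scales linearly with k and flags the vertical phone", {
  spec <- phone_spec(0.15, pi / 6)
  expect_equal(unname(image_point(spec, pi / 3, 0)), c(0, 0))
  d <- 2 * 0.15 * 0.5 * sin(pi / 3) * cos(pi / 6) / sin(pi / 3 + pi / 6)
  expect_equal(unname(image_point(spec, pi / 3, 0.5)),
               d * c(cos(pi / 3), -sin(pi / 3)), tolerance = 1e-12)
  D_vert <- image_point(spec, pi / 2, 0.5)
  expect_equal(unname(D_vert[1]), 0, tolerance = 1e-12)
  expect_true(isTRUE(attr(D_vert, "degenerate")))
  expect_error(image_point(spec, pi / 3, 1.5), class = "dk_input_error")
})

test_that("shooting distance intersects the camera ray with the table", {
  # 45-degree line to the table
  expect_equal(shooting_distance(c(0, 2), c(1, 1)), 2)
  # vertical ray is degenerate at the origin
  l <- shooting_distance(c(0, 0.15), c(0, -0.1))
  expect_equal(as.numeric(l), 0)
  expect_true(isTRUE(attr(l, "degenerate")))
  expect_error(shooting_distance(c(0, 1), c(2, 1)), class = "dk_parallel_ray")
  expect_error(shooting_distance(c(1, 1), c(1, 1)), class = "dk_input_error")
  # random non-degenerate pairs agree with a parametric intersection oracle
  set.seed(7)
  for (i in 1:25) {
    A <- c(runif(1, -1, 1), runif(1, 0.2, 2))
    D <- c(runif(1, -1, 1), runif(1, -2, -0.2))
    t_star <- A[2] / (A[2] - D[2])            # parametric line-plane oracle
    oracle <- A[1] + t_star * (D[1] - A[1])
    expect_equal(unname(shooting_distance(A, D)), oracle, tolerance = 1e-9)
  }
})

test_that("literal printed form is available for audit and differs from the default", {
  spec <- phone_spec(0.15, pi / 6)
  lit <- shot_distance(spec, pi / 3, 0.5, mode = "literal")
  def <- shot_distance(spec, pi / 3, 0.5)
  expect_false(isTRUE(all.equal(lit, def)))
})

test_that("distance is monotone in k and scale-equivariant in p", {
  spec <- phone_spec(0.15, pi / 6)
  ks <- seq(0.02, 0.98, length.out = 30)
  for (alpha in c(0.6, 0.9, 1.2)) {
    d <- vapply(ks, function(k) shot_distance(spec, alpha, k), numeric(1))
    expect_true(all(diff(d) > 0))
  }
  c_factor <- 3
  spec3 <- phone_spec(0.15 * c_factor, pi / 6)
  for (alpha in c(0.7, 1.1)) {
    expect_equal(camera_position(spec3, alpha),
                 c_factor * camera_position(spec, alpha), tolerance = 1e-12)
    expect_equal(base_intersection(spec3, alpha),
                 c_factor * base_intersection(spec, alpha), tolerance = 1e-12)
    expect_equal(unname(image_point(spec3, alpha, 0.4)),
                 c_factor * unname(image_point(spec, alpha, 0.4)),
                 tolerance = 1e-12)
    expect_equal(shot_distance(spec3, alpha, 0.4),
                 c_factor * shot_distance(spec, alpha, 0.4), tolerance = 1e-12)
  }
})

test_that("projected area counts pixels and locates the mask for k", {
  full <- matrix(TRUE, 10, 10)
  pa <- projected_area(full, 0.001)
  expect_equal(pa$S, 1e-4)
  # centered 2-px-tall blob in a 100-row image
  m <- matrix(FALSE, 100, 20)
  m[50:51, 8:12] <- TRUE
  pa2 <- projected_area(m, 0.01)
  expect_lt(abs(pa2$a - 50), 0.5)
  expect_equal(pa2$b, 100)
  # random blob: S equals brute-force pixel count x pitch^2
  set.seed(3)
  rb <- matrix(runif(400) > 0.6, 20, 20)
  expect_equal(projected_area(rb, 0.002)$S, sum(rb) * 0.002^2)
  expect_error(projected_area(matrix(FALSE, 5, 5), 0.001),
               class = "dk_empty_mask")
})

test_that("run-length mask files round-trip through write and read", {
  m <- matrix(FALSE, 30, 40)
  m[10:20, 5:25] <- TRUE
  m[3, c(2, 4, 6)] <- TRUE
  path <- withr::local_tempfile(fileext = ".rle")
  write_mask(m, path)
  expect_identical(read_mask(path), m)
})
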