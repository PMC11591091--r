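#' Synthetic tabletop scenes with known ground truth
#'
#' The simulator builds pinhole-camera tabletop scenes — a disk-shaped food
#' on the table, a phone leaning at tilt `alpha` — with known food position,
#' footprint area and weight. It serves two roles: an independent geometric
#' oracle for the perspective equations (the ray-cast here shares no closed
#' form with [photo_geometry]), and a ground-truth data source for the weight
#' regression.
#'
#' @name scene_simulator
NULL

rot2 <- function(v, theta) {
  c(cos(theta) * v[1] - sin(theta) * v[2],
    sin(theta) * v[1] + cos(theta) * v[2])
}

# numeric intersection of the ray origin + t*dir with the table plane y = 0
ray_table_intersection <- function(origin, dir, t_max = 1e3) {
  f <- function(t) origin[2] + t * dir[2]
  if (abs(dir[2]) < 1e-12 || f(0) * f(t_max) > 0)
    dk_stop("dk_parallel_ray", "ray does not reach the table plane")
  t0 <- stats::uniroot(f, c(0, t_max), tol = 1e-14)$root
  origin + t0 * dir
}

#' Ray-cast shooting distance (independent oracle)
#'
#' Constructs the scene geometrically — phone-body unit vector, camera
#' position, the field-boundary ray rotated by `beta`, the table point B by
#' numeric root finding, the image-plane point at fractional height `k` at
#' distance `2 k |AB| cos(beta)` along the phone body — and numerically
#' intersects the camera-to-image-point ray with the table plane. No
#' closed-form sine-rule expression from [photo_geometry] is reused.
#'
#' @inheritParams image_point
#' @return distance from the origin to the food's table point, metres.
#' @export
raycast_distance <- function(spec, alpha, k) {
  check_alpha(alpha)
  if (k < 0 || k > 1) dk_stop("dk_input_error", "k must be in [0, 1]")
  u <- c(cos(alpha), sin(alpha))              # phone-body direction
  A <- spec$p * u                             # camera
  d_B <- rot2(-u, spec$beta)                  # field-boundary ray direction
  B <- ray_table_intersection(A, d_B)
  AB <- sqrt(sum((B - A)^2))
  cos_beta <- sum(-u * d_B)                   # from the constructed vectors
  u_m <- c(u[1], -u[2])                       # phone body mirrored in the table
  D <- (2 * k * AB * cos_beta) * u_m          # virtual-image point
  if (sqrt(sum((D - A)^2)) < 1e-12)
    dk_stop("dk_input_error", "image point coincides with the camera")
  dirAD <- (D - A) / sqrt(sum((D - A)^2))
  C <- ray_table_intersection(A, dirAD)
  unname(C[1])
}

#' Synthetic food description
#'
#' Mass model: `weight_g = density * pi * radius^2 * shape_factor`, with a
#' type-specific areal density coefficient (g per m^2 of footprint).
#'
#' @param type_id integer food-type label.
#' @param radius footprint disk radius, metres.
#' @param height food height, metres (descriptive; enters only through
#'   `shape_factor` if the caller ties them).
#' @param density areal density coefficient, g/m^2.
#' @param shape_factor dimensionless mass shape factor (default 1).
#' @return object of class `synthetic_food`.
#' @export
synthetic_food <- function(type_id, radius, height = 0.03, density = 5e4,
                           shape_factor = 1) {
  stopifnot(radius > 0, height > 0, density > 0, shape_factor > 0)
  structure(list(type_id = as.integer(type_id), radius = radius,
                 height = height, density = density,
                 shape_factor = shape_factor), class = "synthetic_food")
}

true_weight <- function(food) {
  food$density * pi * food$radius^2 * food$shape_factor
}

#' Render a synthetic scene
#'
#' Places the food at fractional image height `k`, computes the true shooting
#' distance by [raycast_distance()], and rasterizes the food's footprint in a
#' table-rectified mask (pixel pitch at table scale, so the mask-derived area
#' estimates the physical footprint area up to pixelation). The recorded
#' weight carries multiplicative log-normal noise; mask rendering is
#' noise-free. Deterministic given `seed`.
#'
#' @param food a [synthetic_food()].
#' @param spec a [phone_spec()].
#' @param alpha tilt angle, radians.
#' @param k food position in the image, fraction of image length.
#' @param seed integer seed for the weight-noise draw.
#' @param res mask resolution (res x res pixels), default 128.
#' @param sigma log-normal weight noise sd, default 0.05 (5%).
#' @return a `scene_record` list: `mask`, `pitch`, `a`, `b`, `k`, `alpha`,
#'   `distance` (true l_OC), `S_true` (analytic footprint area m^2),
#'   `S_mask` (pixel-counted), `weight_true`, `weight_g` (noisy), `food`,
#'   `spec`, `seed`.
#' @export
render_scene <- function(food, spec, alpha, k, seed = 1, res = 128,
                         sigma = 0.05) {
  distance <- raycast_distance(spec, alpha, k)
  pitch <- 4 * food$radius / res          # physical window = 4 radii
  r_px <- food$radius / pitch
  row_c <- res - k * res                  # mask centroid row (pixel units)
  col_c <- res / 2
  if (row_c - r_px < 0 || row_c + r_px > res ||
      col_c - r_px < 0 || col_c + r_px > res)
    dk_stop("dk_placement_error", "food footprint falls outside the field of view")
  rr <- matrix(seq_len(res) - 0.5, res, res)        # row centres
  cc <- matrix(rep(seq_len(res) - 0.5, each = res), res, res)
  mask <- (rr - row_c)^2 + (cc - col_c)^2 <= r_px^2
  w_true <- true_weight(food)
  set.seed(dk_child_seed(seed, paste0("scene", food$type_id)))
  w_obs <- w_true * exp(stats::rnorm(1, 0, sigma))
  structure(list(mask = mask, pitch = pitch, a = k * res, b = res, k = k,
                 alpha = alpha, distance = distance,
                 S_true = pi * food$radius^2, S_mask = sum(mask) * pitch^2,
                 weight_true = w_true, weight_g = w_obs,
                 food = food, spec = spec, seed = seed),
            class = "scene_record")
}

# per-type parameters, deterministic in the seed: mean radius and areal density
cuisine_types <- function(F, seed) {
  set.seed(dk_child_seed(seed, "types"))
  data.frame(type_id = seq_len(F),
             mean_radius = stats::runif(F, 0.03, 0.08),
             density = stats::runif(F, 2e4, 8e4))
}

#' Generate a synthetic cuisine dataset
#'
#' `n` scenes stratified over `F` food types: per-sample footprint radius is
#' log-normal around the type mean (sd 0.15 on the log scale), tilt angle
#' uniform over `alpha_range`, image position `k` uniform in [0.25, 0.75].
#' The area column is the mask-derived measurement (pixelation included);
#' `weight_true` is the noise-free mass for noise-floor calculations.
#'
#' @param n number of scenes.
#' @param F number of food types (default 19).
#' @param seed integer seed; two calls with the same seed give identical
#'   tables.
#' @param sigma weight-noise sd (default 0.05).
#' @param alpha_range tilt-angle range in radians, default 30--80 degrees.
#' @param res mask resolution.
#' @param spec a [phone_spec()].
#' @return data frame with columns `type_id`, `alpha`, `distance`, `area`,
#'   `weight`, `weight_true`, `radius`.
#' @export
make_cuisine_dataset <- function(n, F = 19, seed = 1, sigma = 0.05,
                                 alpha_range = c(30, 80) * pi / 180,
                                 res = 128, spec = phone_spec()) {
  types <- cuisine_types(F, seed)
  type_of <- sort(rep(seq_len(F), length.out = n))
  set.seed(dk_child_seed(seed, "scenes"))
  radius <- types$mean_radius[type_of] * exp(stats::rnorm(n, 0, 0.15))
  alpha <- stats::runif(n, alpha_range[1], alpha_range[2])
  k <- stats::runif(n, 0.25, 0.75)
  noise <- exp(stats::rnorm(n, 0, sigma))
  out <- data.frame(type_id = type_of, alpha = alpha, distance = NA_real_,
                    area = NA_real_, weight = NA_real_, weight_true = NA_real_,
                    radius = radius)
  for (i in seq_len(n)) {
    food <- synthetic_food(type_of[i], radius[i],
                           density = types$density[type_of[i]])
    out$distance[i] <- raycast_distance(spec, alpha[i], k[i])
    pitch <- 4 * radius[i] / res
    r_px <- radius[i] / pitch
    rr <- matrix(seq_len(res) - 0.5, res, res)
    cc <- matrix(rep(seq_len(res) - 0.5, each = res), res, res)
    m <- (rr - res / 2)^2 + (cc - res / 2)^2 <= r_px^2
    out$area[i] <- sum(m) * pitch^2
    out$weight_true[i] <- true_weight(food)
    out$weight[i] <- out$weight_true[i] * noise[i]
  }
  out
}
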