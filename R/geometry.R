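#' Perspective geometry for single-shot food photography
#'
#' A phone leans on the table at tilt angle `alpha` (from the gyroscope),
#' with the phone--table contact point as the origin O, x along the table and
#' y vertical. The camera sits at distance `p` from the bottom of the phone;
#' `beta` is the phone-model constant angle between the phone body and the
#' field-of-view boundary ray that meets the table at B. The food's position
#' in the image is summarized by `k = a/b`, where `a` is the distance from the
#' food to the bottom of the photo and `b` the total image length. From these
#' the shooting distance `l_OC` (origin to the food's table point C) follows.
#'
#' @name photo_geometry
NULL

#' Phone specification
#'
#' @param p bottom-of-phone to camera length in metres (> 0).
#' @param beta camera field-offset angle in radians (0 < beta < pi/2);
#'   a phone-model constant.
#' @return object of class `phone_spec`.
#' @export
phone_spec <- function(p = 0.15, beta = pi / 6) {
  if (!is.numeric(p) || p <= 0) dk_stop("dk_input_error", "p must be > 0")
  if (!is.numeric(beta) || beta <= 0 || beta >= pi / 2)
    dk_stop("dk_input_error", "beta must be in (0, pi/2)")
  structure(list(p = p, beta = beta), class = "phone_spec")
}

check_alpha <- function(alpha) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha > pi / 2)
    dk_stop("dk_input_error", "alpha must be in (0, pi/2]")
  invisible(alpha)
}

#' Camera position
#'
#' `A = (p cos(alpha), p sin(alpha))` in the table frame.
#'
#' @param spec a [phone_spec()].
#' @param alpha tilt angle from the table, radians.
#' @return numeric `c(x, y)` in metres.
#' @export
camera_position <- function(spec, alpha) {
  check_alpha(alpha)
  c(x = spec$p * cos(alpha), y = spec$p * sin(alpha))
}

#' Table intersection of the field boundary ray
#'
#' `l_OB = p sin(beta) / sin(alpha + beta)`: the distance from the origin to
#' the point B where the image-bottom boundary ray meets the table.
#'
#' @inheritParams camera_position
#' @return length in metres.
#' @export
base_intersection <- function(spec, alpha) {
  check_alpha(alpha)
  s <- sin(alpha + spec$beta)
  if (abs(s) < 1e-12)
    dk_stop("dk_singular_geometry", "alpha + beta = pi: singular geometry")
  spec$p * sin(spec$beta) / s
}

#' Image-plane point for a food at fractional image height k
#'
#' The food's image-plane point sits at distance
#' `d = 2 p k sin(alpha) cos(beta) / sin(alpha+beta)` from the origin along
#' the virtual-image line — the phone body reflected across the table plane —
#' so `D = d * (cos(alpha), -sin(alpha))`. The reflection is what makes the
#' camera-to-image-point ray sweep the table as `k` grows: a point at the
#' same distance on the phone-body line itself would be collinear with the
#' camera and the origin for every `k`, and the shooting distance would
#' degenerate to zero. `k = 0` maps to the origin ray.
#'
#' @inheritParams camera_position
#' @param k fractional food height in the image, `a/b`, in `[0, 1]`.
#' @return numeric `c(x, y)` in metres, with attribute `degenerate = TRUE`
#'   when `alpha == pi/2` (vertical phone).
#' @export
image_point <- function(spec, alpha, k) {
  check_alpha(alpha)
  if (!is.numeric(k) || k < 0 || k > 1)
    dk_stop("dk_input_error", "k must be in [0, 1]")
  s <- sin(alpha + spec$beta)
  if (abs(s) < 1e-12)
    dk_stop("dk_singular_geometry", "alpha + beta = pi: singular geometry")
  d <- 2 * spec$p * k * sin(alpha) * cos(spec$beta) / s
  out <- c(x = d * cos(alpha), y = -d * sin(alpha))
  if (isTRUE(all.equal(alpha, pi / 2))) attr(out, "degenerate") <- TRUE
  out
}

#' Shooting distance from camera and image points
#'
#' Default mode intersects the line through the camera A and the image-plane
#' point D with the table (y = 0):
#' `l_OC = x_A - y_A (x_D - x_A) / (y_D - y_A)`.
#' The `literal` mode evaluates the alternative closed form
#' `l_OC = y_D (x_D - x_A) / (y_D - x_A) + x_A` exactly as written, for
#' audit; its denominator mixes a y- with an x-coordinate and it disagrees
#' with the ray-cast construction except at special configurations.
#'
#' @param A camera position `c(x, y)` (see [camera_position()]).
#' @param D image-plane point `c(x, y)` (see [image_point()]).
#' @param mode `"default"` (line--table intersection) or `"literal"`.
#' @return distance `l_OC` in metres; attribute `degenerate = TRUE` for a
#'   vertical ray (C coincides with O's vertical line).
#' @export
shooting_distance <- function(A, D, mode = c("default", "literal")) {
  mode <- match.arg(mode)
  if (isTRUE(all.equal(unname(A), unname(D))))
    dk_stop("dk_input_error", "A and D coincide")
  if (mode == "literal") {
    den <- D[2] - A[1]
    if (abs(den) < 1e-12)
      dk_stop("dk_singular_geometry", "literal-mode denominator vanishes")
    return(unname(D[2] * (D[1] - A[1]) / den + A[1]))
  }
  dy <- D[2] - A[2]
  if (abs(dy) < 1e-12)
    dk_stop("dk_parallel_ray", "ray A-D is parallel to the table")
  l <- unname(A[1] - A[2] * (D[1] - A[1]) / dy)
  if (abs(D[1] - A[1]) < 1e-12) attr(l, "degenerate") <- TRUE
  l
}

#' End-to-end shooting distance from phone geometry
#'
#' Convenience wrapper: camera position, image point, and line--table
#' intersection in one call.
#'
#' @inheritParams image_point
#' @param mode see [shooting_distance()].
#' @return `l_OC` in metres.
#' @export
shot_distance <- function(spec, alpha, k, mode = "default") {
  A <- camera_position(spec, alpha)
  D <- image_point(spec, alpha, k)
  if (mode == "literal") D[2] <- -D[2]   # the printed form's upward-y point
  shooting_distance(A, D, mode = mode)
}

#' Projected food area from a binary mask
#'
#' `S = (number of set pixels) * pitch^2`. Also reports the geometry inputs
#' `a` (distance in pixels from the mask centroid to the bottom image row)
#' and `b` (image length in pixels, rows), as needed for `k = a/b`.
#'
#' @param mask logical or 0/1 numeric matrix; rows run top to bottom.
#' @param pitch pixel pitch in metres per pixel at table scale.
#' @return list with `S` (m^2), `a`, `b` (pixels), `n_pixels`.
#' @export
projected_area <- function(mask, pitch) {
  if (is.character(mask) && length(mask) == 1) mask <- read_mask(mask)
  m <- mask > 0
  n <- sum(m)
  if (n == 0) dk_stop("dk_empty_mask", "mask contains no set pixels")
  if (!is.numeric(pitch) || pitch <= 0) dk_stop("dk_input_error", "pitch must be > 0")
  rows <- row(m)[m]
  centroid_row <- mean(rows - 0.5)      # pixel-centre convention
  list(S = n * pitch^2, a = nrow(m) - centroid_row, b = nrow(m), n_pixels = n)
}

#' Read a binary mask from a PNG file or run-length text fixture
#'
#' PNG: first channel, nonzero = food. Run-length text: first line
#' `rows cols`, following lines `row start_col end_col` (inclusive).
#'
#' @param path file path; `.png` or anything else treated as run-length text.
#' @return logical matrix.
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) dk_stop("dk_io_error", "mask file not found: %s", path)
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    img <- png::readPNG(path)
    if (length(dim(img)) == 3) img <- img[, , 1]
    return(img > 0)
  }
  lines <- readLines(path)
  hdr <- as.integer(strsplit(trimws(lines[1]), "[[:space:]]+")[[1]])
  m <- matrix(FALSE, hdr[1], hdr[2])
  for (ln in lines[-1]) {
    if (!nzchar(trimws(ln))) next
    v <- as.integer(strsplit(trimws(ln), "[[:space:]]+")[[1]])
    m[v[1], v[2]:v[3]] <- TRUE
  }
  m
}

#' Write a binary mask as a run-length text fixture
#'
#' @param mask logical matrix.
#' @param path output path.
#' @export
write_mask <- function(mask, path) {
  lines <- sprintf("%d %d", nrow(mask), ncol(mask))
  for (r in seq_len(nrow(mask))) {
    v <- which(mask[r, ])
    if (length(v) == 0) next
    runs <- split(v, cumsum(c(1, diff(v) != 1)))
    lines <- c(lines, vapply(runs, function(rr)
      sprintf("%d %d %d", r, min(rr), max(rr)), character(1)))
  }
  writeLines(lines, path)
  invisible(path)
}
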