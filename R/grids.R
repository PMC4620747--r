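#' Translation grid of candidate anchor images
#'
#' Vertices of a cubic lattice of side `side`, anchored so that `center` is
#' itself a vertex, restricted to the open ball `B(center, radius)`. With
#' `side` slightly smaller than `sqrt(3) * eps / 9` the half-diagonal of a
#' lattice cell is just under `eps/6`, so every point of
#' `B(center, radius - eps/6)` has a grid point within `eps/6` — the
#' covering contract that makes the anchored search near-optimal.
#'
#' @param center 3-vector (the target atom a_k).
#' @param radius ball radius in Angstrom (`theta + eps/6`).
#' @param side lattice side in Angstrom (must be < sqrt(3)*eps/9 for the
#'   covering contract at resolution eps).
#' @return List of class `translation_grid` with `points` (matrix, sorted by
#'   distance from the center), `center`, `radius`, `side`.
#' @export
build_translation_grid <- function(center, radius, side) {
  if (side <= 0) stop("side must be positive")
  pts <- cpp_translation_grid(as.numeric(center), radius, side)
  structure(list(points = pts, center = as.numeric(center),
                 radius = radius, side = side),
            class = "translation_grid")
}

#' @export
print.translation_grid <- function(x, ...) {
  cat(sprintf("translation_grid: %d points, radius %.3f, side %.4f\n",
              nrow(x$points), x$radius, x$side))
  invisible(x)
}

#' Spherical-cap grid of candidate second-anchor images
#'
#' Geodesic grid on the sphere `S(sphere_center, sphere_radius)` (the
#' possible images of b_l once b_k is pinned: the chord length is rigid)
#' restricted to the ball `B(ball_center, ball_radius)` around the target
#' atom a_l, plus a one-spacing margin so the covering contract survives the
#' discretized ball test. Latitude bands at angular step
#' `spacing/sphere_radius` from the pole facing `ball_center`, each band
#' sampled in longitude at arc step at most `spacing`. With
#' `spacing <= eps/6`, any point of the exact cap has a grid point within
#' `eps/6` in chord distance.
#'
#' @param sphere_center,sphere_radius candidate image a^k and chord length
#'   `||b_k - b_l||`.
#' @param ball_center,ball_radius target atom a_l and `theta + eps/3`.
#' @param spacing grid spacing in Angstrom (<= eps/6).
#' @return List of class `cap_grid` with `points` and the construction
#'   parameters. Empty intersection yields zero points.
#' @export
build_cap_grid <- function(sphere_center, sphere_radius, ball_center,
                           ball_radius, spacing) {
  if (sphere_radius <= 0) stop("sphere_radius must be positive")
  if (spacing <= 0) stop("spacing must be positive")
  pts <- cpp_cap_grid(as.numeric(sphere_center), sphere_radius,
                      as.numeric(ball_center), ball_radius, spacing)
  structure(list(points = pts, sphere_center = as.numeric(sphere_center),
                 sphere_radius = sphere_radius,
                 ball_center = as.numeric(ball_center),
                 ball_radius = ball_radius, spacing = spacing),
            class = "cap_grid")
}

#' @export
print.cap_grid <- function(x, ...) {
  cat(sprintf("cap_grid: %d points on sphere r=%.3f within ball r=%.3f\n",
              nrow(x$points), x$sphere_radius, x$ball_radius))
  invisible(x)
}
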