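cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# deterministic unit vector perpendicular to u
perpendicular_unit <- function(u) {
  p <- if (abs(u[1]) <= abs(u[2]) && abs(u[1]) <= abs(u[3])) c(1, 0, 0)
       else if (abs(u[2]) <= abs(u[3])) c(0, 1, 0) else c(0, 0, 1)
  p <- p - sum(p * u) * u
  p / sqrt(sum(p^2))
}

# Vectorized feasibility arcs for rotating `points` about the axis
# (axis_point, axis_dir) toward `targets` under `cutoff`.
# For each residue the squared distance as a function of the rotation angle
# phi is d^2(phi) = A - B cos(phi - center) with A = wpar^2 + q^2 + rho^2 and
# B = 2 rho q, where rho is the circle radius of the rotating point, q the
# in-plane distance of the target from the circle center and wpar its axial
# offset. The condition d^2 <= cutoff^2 is empty, full, or one closed arc.
axis_arcs <- function(points, targets, axis_point, axis_dir, cutoff,
                      tol = 1e-9) {
  u <- axis_dir / sqrt(sum(axis_dir^2))
  d <- sweep(as.matrix(points), 2L, axis_point)
  alpha <- as.numeric(d %*% u)
  e <- d - outer(alpha, u)
  rho <- sqrt(rowSums(e^2))
  w <- sweep(as.matrix(targets), 2L, axis_point) - outer(alpha, u)
  wpar <- as.numeric(w %*% u)
  wperp <- w - outer(wpar, u)
  q <- sqrt(rowSums(wperp^2))
  A <- wpar^2 + q^2 + rho^2
  B <- 2 * rho * q
  c2 <- (cutoff + tol)^2
  e1 <- perpendicular_unit(u)
  e2 <- cross3(u, e1)
  kind <- character(length(A))
  degen <- B < 1e-15                      # point on axis or target on axis
  kind[degen & A <= c2] <- "full"
  kind[degen & A > c2] <- "empty"
  kappa <- ifelse(degen, NA_real_, (A - c2) / B)
  kind[!degen & kappa <= -1] <- "full"
  kind[!degen & kappa > 1] <- "empty"
  proper <- kind == ""
  kind[proper] <- "proper"
  psi <- rep(NA_real_, length(A))
  centre <- rep(NA_real_, length(A))
  if (any(proper)) {
    psi[proper] <- acos(pmin(1, pmax(-1, kappa[proper])))
    phip <- atan2(e[proper, , drop = FALSE] %*% e2,
                  e[proper, , drop = FALSE] %*% e1)
    phit <- atan2(wperp[proper, , drop = FALSE] %*% e2,
                  wperp[proper, , drop = FALSE] %*% e1)
    centre[proper] <- (as.numeric(phit) - as.numeric(phip)) %% (2 * pi)
  }
  list(kind = kind, centre = centre, half_width = psi)
}

#' Feasible rotation arc of one point about an axis
#'
#' The set of rotation angles phi for which rotating `point` about the line
#' through `axis_point` with direction `axis_dir` brings it within `cutoff`
#' of `target`. The set is empty, the full circle, or one closed arc
#' (wraparound `start > end` means the arc crosses angle 0). Arcs are closed
#' to match the closed "<= cutoff" convention.
#'
#' @param point,target 3-vectors.
#' @param axis_point point on the rotation axis.
#' @param axis_dir axis direction (unit within 1e-9).
#' @param cutoff distance cutoff in Angstrom (>= 0).
#' @param tol boundary tolerance (default 1e-9).
#' @return A list of class `sweep_arc` with `kind` ("empty", "full",
#'   "proper") and, for proper arcs, `start` and `end` angles in \[0, 2*pi).
#' @export
angular_feasible_arc <- function(point, target, axis_point, axis_dir, cutoff,
                                 tol = 1e-9) {
  stopifnot(cutoff >= 0, abs(sqrt(sum(axis_dir^2)) - 1) < 1e-9)
  a <- axis_arcs(matrix(point, 1L), matrix(target, 1L), axis_point, axis_dir,
                 cutoff, tol)
  out <- list(kind = a$kind[1], start = NA_real_, end = NA_real_)
  if (a$kind[1] == "proper") {
    out$start <- (a$centre[1] - a$half_width[1]) %% (2 * pi)
    out$end <- (a$centre[1] + a$half_width[1]) %% (2 * pi)
  }
  class(out) <- "sweep_arc"
  out
}

# core event sweep over proper arcs [centre - psi, centre + psi];
# returns maximal simultaneous overlap and the midpoint of a maximal
# interval. Entry events are processed before exit events at equal angles so
# tangent (closed) arcs are counted.
sweep_max_overlap <- function(centre, psi) {
  if (length(centre) == 0L) return(list(count = 0L, angle = 0))
  s <- (centre - psi) %% (2 * pi)
  e <- (centre + psi) %% (2 * pi)
  wraps <- s > e
  init <- sum(wraps)
  ang <- c(s, e)
  typ <- c(rep(1L, length(s)), rep(-1L, length(e)))
  o <- order(ang, -typ)
  ang <- ang[o]
  typ <- typ[o]
  run <- init + cumsum(typ)
  best <- max(init, max(run))
  if (best == init && init >= max(run)) {
    # maximal on [0, first event)
    return(list(count = as.integer(best), angle = ang[1] / 2))
  }
  j <- which.max(run)
  nxt <- if (j < length(ang)) ang[j + 1] else ang[1] + 2 * pi
  list(count = as.integer(best), angle = ((ang[j] + nxt) / 2) %% (2 * pi))
}

#' Optimal rotation about an anchored axis
#'
#' Given an anchored frame (a transform pinning model residues k and l to
#' candidate image points), finds the rotation angle about the axis through
#' the two images that maximizes the number of residues within `cutoff` of
#' their targets. The feasibility set of each residue is an arc on the
#' rotation circle; sorting the at most 2n arc endpoints and sweeping them
#' with a running overlap counter finds the maximum in O(n log n). The
#' reported angle is the midpoint of a maximal-count interval, robustly
#' inside the feasible set. Residues whose arc is the full circle are added
#' to a base counter and excluded from event sorting.
#'
#' @param pair a `structure_pair`.
#' @param frame an `anchored_frame` from [anchored_transform()].
#' @param cutoff distance cutoff in Angstrom.
#' @param tol boundary tolerance (default 1e-9).
#' @return List with `angle` (radians), `count` (residues fitted), and
#'   `transform` (the full `rigid_transform`, rotation composed with the
#'   frame's base transform).
#' @export
best_axis_rotation <- function(pair, frame, cutoff, tol = 1e-9) {
  stopifnot(inherits(pair, "structure_pair"), inherits(frame, "anchored_frame"),
            cutoff >= 0)
  axis_dir <- frame$image_l - frame$image_k
  axis_dir <- axis_dir / sqrt(sum(axis_dir^2))
  pts <- apply_transform(frame$base_transform, pair$model$xyz)
  arcs <- axis_arcs(pts, pair$target$xyz, frame$image_k, axis_dir, cutoff, tol)
  n_full <- sum(arcs$kind == "full")
  pr <- arcs$kind == "proper"
  sw <- sweep_max_overlap(arcs$centre[pr], arcs$half_width[pr])
  rot <- rotation_about_axis(frame$image_k, axis_dir, sw$angle)
  list(angle = sw$angle, count = n_full + sw$count,
       transform = transform_compose(rot, frame$base_transform))
}
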