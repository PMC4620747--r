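#' Count residues fitted under a distance cutoff
#'
#' Number of residues i with `||a_i - T(b_i)|| <= theta` (closed inequality,
#' absorbed float noise via a +tol slack), the quantity MAX(T, theta) whose
#' maximum over rigid T defines the Hubbard function.
#'
#' @param pair a `structure_pair`.
#' @param transform a `rigid_transform` applied to the model.
#' @param theta cutoff in Angstrom (>= 0).
#' @param tol boundary tolerance in Angstrom (default 1e-9).
#' @return Integer count; divide by `pair$n` for the fraction.
#' @export
count_within <- function(pair, transform, theta, tol = 1e-9) {
  stopifnot(inherits(pair, "structure_pair"), theta >= 0)
  d <- residue_distances(pair, transform)
  sum(d <= theta + tol)
}

# per-residue distances ||a_i - T(b_i)||
residue_distances <- function(pair, transform) {
  tb <- apply_transform(transform, pair$model$xyz)
  sqrt(rowSums((pair$target$xyz - tb)^2))
}

#' Rigid transform anchored at two residues
#'
#' Constructs a rigid transform that maps model residues k and l onto the
#' candidate image points `image_k` and `image_l`. The images must be
#' congruent with the model chord (`||image_k - image_l|| = ||b_k - b_l||`
#' within 1e-6 Angstrom); the residual degree of freedom — the twist about
#' the axis through the images — is arbitrary here and is optimized
#' separately by [best_axis_rotation()].
#'
#' @param pair a `structure_pair`.
#' @param k,l distinct residue indices (1-based).
#' @param image_k,image_l target-space image points for b_k, b_l.
#' @return An object of class `anchored_frame` with elements `k`, `l`,
#'   `image_k`, `image_l` and `base_transform`.
#' @export
anchored_transform <- function(pair, k, l, image_k, image_l) {
  stopifnot(inherits(pair, "structure_pair"), k != l,
            k >= 1, l >= 1, k <= pair$n, l <= pair$n)
  image_k <- as.numeric(image_k); image_l <- as.numeric(image_l)
  bk <- pair$model$xyz[k, ]; bl <- pair$model$xyz[l, ]
  v <- bl - bk
  r <- sqrt(sum(v^2))
  if (r < 1e-9) stop("degenerate anchor: coincident model residues")
  w <- image_l - image_k
  rp <- sqrt(sum(w^2))
  if (abs(rp - r) > 1e-6)
    stop(sprintf("chord-length mismatch: %.3g Angstrom", abs(rp - r)))
  R <- rotation_between(v / r, w / rp)
  tr <- rigid_transform(R, image_k - as.numeric(R %*% bk))
  structure(list(k = k, l = l, image_k = image_k, image_l = image_l,
                 base_transform = tr),
            class = "anchored_frame")
}

# minimal rotation taking unit vector u onto unit vector w
rotation_between <- function(u, w) {
  c_ <- sum(u * w)
  ax <- c(u[2] * w[3] - u[3] * w[2],
          u[3] * w[1] - u[1] * w[3],
          u[1] * w[2] - u[2] * w[1])
  s <- sqrt(sum(ax^2))
  if (s < 1e-12) {
    if (c_ > 0) return(diag(3))
    # antiparallel: rotate pi about any axis perpendicular to u
    p <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    ax <- p - sum(p * u) * u
    ax <- ax / sqrt(sum(ax^2))
    return(rotation_from_axis_angle(ax * pi))
  }
  rotation_from_axis_angle(ax / s * atan2(s, c_))
}

#' Candidate radial pairs
#'
#' All ordered index pairs (k, l), k != l, explored as candidate radial
#' pairs of the (unknown) optimal residue subset. The true radial pair
#' cannot be identified in advance, so all n(n-1) ordered pairs are
#' enumerated in a deterministic order (k ascending, then l).
#'
#' @param n number of residues (>= 2).
#' @return Integer matrix with columns `k`, `l` and n(n-1) rows.
#' @export
candidate_radial_pairs <- function(n) {
  if (n < 2L) stop("need at least 2 residues for a radial pair")
  k <- rep(seq_len(n), each = n)
  l <- rep(seq_len(n), times = n)
  cbind(k = k[k != l], l = l[k != l])
}

# Reduced anchor set for large instances: for each selected k, its two
# farthest partners in the model (the radial-pair heuristic). Deterministic.
reduced_anchor_pairs <- function(model_xyz, n_residues) {
  n <- nrow(model_xyz)
  ks <- unique(round(seq(1L, n, length.out = min(n_residues, n))))
  out <- lapply(ks, function(k) {
    d <- colSums((t(model_xyz) - model_xyz[k, ])^2)
    d[k] <- -Inf
    far <- order(d, decreasing = TRUE)[seq_len(min(2L, n - 1L))]
    cbind(k = k, l = far)
  })
  do.call(rbind, out)
}
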