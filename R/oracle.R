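# Brute-force ground truth for tiny instances.
#
# The key reduction: for a fixed rotation R, the translation minimizing
# max_i ||a_i - R b_i - t|| is the center of the smallest enclosing ball of
# the points v_i = a_i - R b_i, and the minimax value is that ball's radius.
# The 6-DOF minimax therefore collapses to a 3-DOF search over rotations,
# attacked by multi-start Nelder-Mead over rotation vectors with
# deterministic quasi-random starts.

# --- exact smallest enclosing ball (Welzl, n tiny) ----------------------

ball_of_boundary <- function(P) {
  k <- nrow(P)
  if (k == 0L) return(list(center = c(0, 0, 0), radius = -1))
  if (k == 1L) return(list(center = P[1, ], radius = 0))
  if (k == 2L) {
    cen <- (P[1, ] + P[2, ]) / 2
    return(list(center = cen, radius = sqrt(sum((P[1, ] - cen)^2))))
  }
  p1 <- P[1, ]
  U <- sweep(P[-1, , drop = FALSE], 2L, p1)
  G <- U %*% t(U)
  rhs <- rowSums(U^2) / 2
  sol <- tryCatch(solve(G, rhs), error = function(e) NULL)
  if (is.null(sol) || abs(det(G)) < 1e-10) {
    # degenerate boundary set: fall back to the best pair/triple ball
    best <- NULL
    for (drop_i in seq_len(k)) {
      b <- ball_of_boundary(P[-drop_i, , drop = FALSE])
      d <- sqrt(colSums((t(P) - b$center)^2))
      if (max(d) <= b$radius + 1e-9 && (is.null(best) || b$radius < best$radius))
        best <- b
    }
    if (!is.null(best)) return(best)
    cen <- colMeans(P)
    return(list(center = cen, radius = max(sqrt(colSums((t(P) - cen)^2)))))
  }
  cen <- p1 + as.numeric(t(U) %*% sol)
  list(center = cen, radius = sqrt(sum((P[1, ] - cen)^2)))
}

welzl <- function(P, idx, boundary) {
  if (length(idx) == 0L || nrow(boundary) == 4L)
    return(ball_of_boundary(boundary))
  i <- idx[length(idx)]
  b <- welzl(P, idx[-length(idx)], boundary)
  p <- P[i, ]
  if (sqrt(sum((p - b$center)^2)) <= b$radius + 1e-10) return(b)
  welzl(P, idx[-length(idx)], rbind(boundary, p))
}

# exact 1-center of a small point set (n x 3)
enclosing_ball <- function(P) {
  P <- as.matrix(P)
  if (nrow(P) == 1L) return(list(center = P[1, ], radius = 0))
  welzl(P, seq_len(nrow(P)), P[0, , drop = FALSE])
}

# --- deterministic rotation starts --------------------------------------

# quasi-random rotation vectors: Fibonacci-sphere axes, golden-ratio angles
fibonacci_rotvecs <- function(k) {
  j <- seq_len(k)
  z <- 1 - 2 * (j - 0.5) / k
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- 2 * pi * j * (sqrt(5) - 1) / 2
  ang <- pi * ((j * (sqrt(2) - 1)) %% 1)
  cbind(r * cos(phi) * ang, r * sin(phi) * ang, z * ang)
}

# --- operations ---------------------------------------------------------

#' Exact bottleneck (minimax) superposition of a residue subset
#'
#' The minimum over rigid transforms T of `max_{i in subset}
#' ||a_i - T(b_i)||`, with a certificate transform achieving the value.
#' Intended for tiny subsets (the exact-curve oracle enumerates subsets of
#' pairs with n <= 6). For a fixed rotation the optimal translation is the
#' exact 1-center of the residual point set, so only the 3 rotation degrees
#' of freedom are searched (multi-start Nelder-Mead: identity, the Kabsch
#' rotation, and deterministic quasi-random starts, then a polish from the
#' best).
#'
#' @param pair a `structure_pair`.
#' @param subset integer indices (length >= 1).
#' @param starts number of quasi-random starts (default 32).
#' @param tol value tolerance of the certificate check (default 1e-4).
#' @return List of class `subset_bottleneck` with `subset`, `value`
#'   (Angstrom) and `certificate_transform`.
#' @export
subset_bottleneck <- function(pair, subset, starts = 32L, tol = 1e-4) {
  stopifnot(inherits(pair, "structure_pair"), length(subset) >= 1,
            all(subset >= 1), all(subset <= pair$n))
  a <- pair$target$xyz[subset, , drop = FALSE]
  b <- pair$model$xyz[subset, , drop = FALSE]
  if (length(subset) == 1L) {
    tr <- rigid_transform(diag(3), a[1, ] - b[1, ])
    return(structure(list(subset = subset, value = 0,
                          certificate_transform = tr),
                     class = "subset_bottleneck"))
  }
  obj <- function(rv) {
    R <- rotation_from_axis_angle(rv)
    enclosing_ball(a - b %*% t(R))$radius
  }
  kb <- kabsch_transform(a, b)
  kb_rv <- rotvec_from_matrix(kb$R)
  starts_rv <- rbind(c(0, 0, 0), kb_rv, fibonacci_rotvecs(max(1L, starts - 2L)))
  best <- NULL
  for (s in seq_len(nrow(starts_rv))) {
    fit <- optim(starts_rv[s, ], obj, method = "Nelder-Mead",
                 control = list(reltol = 1e-12, maxit = 400))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  # polish
  fit <- optim(best$par, obj, method = "Nelder-Mead",
               control = list(reltol = 1e-14, maxit = 1000))
  if (fit$value < best$value) best <- fit
  R <- rotation_from_axis_angle(best$par)
  cen <- enclosing_ball(a - b %*% t(R))
  tr <- rigid_transform(R, cen$center)
  structure(list(subset = subset, value = cen$radius,
                 certificate_transform = tr),
            class = "subset_bottleneck")
}

rotvec_from_matrix <- function(R) {
  c_ <- (sum(diag(R)) - 1) / 2
  ax <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
  s <- sqrt(sum(ax^2)) / 2
  th <- atan2(s, c_)
  if (s < 1e-9) {
    if (c_ > 0) return(c(0, 0, 0))
    # angle pi: axis from R + I
    M <- (R + diag(3)) / 2
    u <- sqrt(pmax(0, diag(M)))
    i <- which.max(u)
    if (u[i] > 0) {
      u <- M[, i] / u[i]
      u <- u / sqrt(sum(u^2))
    } else u <- c(1, 0, 0)
    return(u * pi)
  }
  ax / (2 * s) * th
}

#' @export
print.subset_bottleneck <- function(x, ...) {
  cat(sprintf("subset_bottleneck: |S|=%d, value %.5f A\n",
              length(x$subset), x$value))
  invisible(x)
}

# minimax values f_j = min over subsets of size j; f_1 = 0
subset_minimax_values <- function(pair, starts = 32L) {
  n <- pair$n
  if (n > 6L) stop("oracle limit: exact enumeration supports n <= 6")
  f <- numeric(n)
  for (j in seq_len(n)[-1]) {
    subs <- combn(n, j)
    f[j] <- min(apply(subs, 2L, function(s)
      subset_bottleneck(pair, s, starts = starts)$value))
  }
  cummax(f)
}

#' Exact Hubbard step curve by subset enumeration
#'
#' Ground-truth curve for tiny pairs: for each subset size j the exact
#' bottleneck value f_j is the smallest cutoff at which j residues fit, so
#' H(theta) = max\{j/n : f_j <= theta\}. The curve has at most n-1 steps and
#' values in multiples of 1/n.
#'
#' @param pair a `structure_pair` with n <= 6.
#' @param theta_max domain end (default 10).
#' @param starts multi-start count passed to [subset_bottleneck()].
#' @return A [step_curve()] with attribute `minimax_values` (the f_j).
#' @export
exact_curve <- function(pair, theta_max = 10, starts = 32L) {
  f <- subset_minimax_values(pair, starts = starts)
  n <- pair$n
  zero <- f <= 1e-9
  base <- max(which(zero)) / n
  jumps <- which(!zero & f <= theta_max)
  # highest j at each distinct value; merge numerically coincident levels
  th <- f[jumps]
  keep <- if (length(th)) rev(c(TRUE, diff(rev(th)) < -1e-6)) else logical(0)
  curve <- step_curve(step_thetas = th[keep],
                      step_values = jumps[keep] / n,
                      theta_max = theta_max, base_value = base)
  attr(curve, "minimax_values") <- f
  curve
}

#' Exact area under the Hubbard function
#'
#' Layer-cake integral of the exact step curve:
#' `sum_j (1/n) * max(0, theta_max - f_j)`.
#'
#' @inheritParams exact_curve
#' @return Area in Angstrom x fraction.
#' @export
exact_area <- function(pair, theta_max = 10, starts = 32L) {
  f <- subset_minimax_values(pair, starts = starts)
  sum(pmax(0, theta_max - f)) / pair$n
}

# layer-cake area from a curve produced by exact_curve (avoids recompute)
exact_area_from_curve <- function(curve) {
  f <- attr(curve, "minimax_values")
  sum(pmax(0, curve$theta_max - f)) / length(f)
}
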