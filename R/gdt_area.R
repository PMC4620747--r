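#' Algorithm parameters for the near-optimal GDT search
#'
#' @param epsilon grid resolution in Angstrom (> 0); controls both the
#'   discretization density and the 4*epsilon area-error guarantee.
#' @param theta_max maximum cutoff of the curve domain in Angstrom
#'   (default 10, the CASP convention).
#' @param cutoffs_ts,cutoffs_ha fixed cutoff lists for GDT_TS (1,2,4,8) and
#'   GDT_HA (0.5,1,2,4).
#' @param cube_side_factor fraction of `sqrt(3)*epsilon/9` used as the
#'   translation-lattice side; must be < 1 strictly (default 0.99).
#' @param cap_spacing cap-grid spacing in Angstrom (default `epsilon/6`).
#' @param distance_tol boundary tolerance for the closed "<= theta" test.
#' @return List of class `gdt_params`.
#' @export
gdt_params <- function(epsilon = 0.5, theta_max = 10,
                       cutoffs_ts = c(1, 2, 4, 8),
                       cutoffs_ha = c(0.5, 1, 2, 4),
                       cube_side_factor = 0.99,
                       cap_spacing = epsilon / 6,
                       distance_tol = 1e-9) {
  stopifnot(epsilon > 0, theta_max > 0,
            cube_side_factor > 0, cube_side_factor < 1,
            cap_spacing > 0, cap_spacing <= epsilon / 6 + 1e-12)
  structure(list(epsilon = epsilon, theta_max = theta_max,
                 cutoffs_ts = cutoffs_ts, cutoffs_ha = cutoffs_ha,
                 cube_side_factor = cube_side_factor,
                 cap_spacing = cap_spacing,
                 distance_tol = distance_tol),
            class = "gdt_params")
}

#' Search-effort options
#'
#' The default options run the full guaranteed enumeration: all n(n-1)
#' ordered anchor pairs and grids at the density required for the
#' near-optimality proof. For large structures that enumeration is
#' astronomically expensive (the method's complexity is
#' O(n^3 log n / eps^6)), so a reduced search can be requested: a
#' deterministic subset of anchor pairs (for each of `max_anchor_residues`
#' evenly spaced residues k, its two farthest partners — the radial-pair
#' heuristic) and integer thinning factors applied to the translation
#' lattice and cap grid. The reduced search still reports genuine fitted
#' counts of genuine anchored transforms (every reported H_i is a valid
#' lower bound on H(theta_i + epsilon)), but the near-optimality lower
#' bracket H_i >= H(theta_i) is only guaranteed for the full enumeration.
#'
#' @param max_anchor_residues number of anchor residues k to explore, or
#'   NULL for all ordered pairs.
#' @param thin_translation,thin_cap integer factors (>= 1) multiplying the
#'   lattice side and cap spacing.
#' @param warm_start seed incumbents with the Kabsch fit (area mode only;
#'   never affects validity of the sandwich brackets).
#' @param max_candidates abort guard on the number of candidate image pairs.
#' @export
gdt_search_options <- function(max_anchor_residues = NULL,
                               thin_translation = 1L, thin_cap = 1L,
                               warm_start = TRUE,
                               max_candidates = 2e9) {
  stopifnot(thin_translation >= 1, thin_cap >= 1)
  structure(list(max_anchor_residues = max_anchor_residues,
                 thin_translation = as.integer(thin_translation),
                 thin_cap = as.integer(thin_cap),
                 warm_start = isTRUE(warm_start),
                 max_candidates = max_candidates),
            class = "gdt_search_options")
}

anchor_set <- function(pair, search) {
  if (is.null(search$max_anchor_residues)) {
    candidate_radial_pairs(pair$n)
  } else {
    reduced_anchor_pairs(pair$model$xyz, search$max_anchor_residues)
  }
}

# counts of a transform at a vector of cutoffs
counts_at <- function(pair, transform, cutoffs, tol) {
  d <- residue_distances(pair, transform)
  vapply(cutoffs, function(cc) sum(d <= cc + tol), integer(1))
}

#' Near-optimal H values on the epsilon grid
#'
#' The one-pass algorithm: thresholds theta_i = (i-1)*epsilon,
#' i = 1..m = ceiling(theta_max/epsilon), are accumulated simultaneously
#' while enumerating candidate anchored transforms once. Each returned H_i
#' is bracketed as H((i-1)*epsilon) <= H_i <= H(i*epsilon) by the Hubbard
#' function of the pair (full enumeration; see [gdt_search_options()] for
#' the reduced search). Finalization enforces monotone non-decrease
#' (cummax) and floors at 1/n — a single residue always superimposes
#' exactly.
#'
#' @param pair a `structure_pair`.
#' @param params a `gdt_params`.
#' @param search a `gdt_search_options`.
#' @return List of class `gdt_accumulator`: `epsilon`, `theta_max`,
#'   `thetas`, `H` (fractions), `counts`, `witnesses` (per-slot anchored
#'   candidates or warm-start transforms), `n`, `stats`.
#' @export
compute_H_values <- function(pair, params = gdt_params(),
                             search = gdt_search_options()) {
  stopifnot(inherits(pair, "structure_pair"), inherits(params, "gdt_params"))
  eps <- params$epsilon
  m <- ceiling(params$theta_max / eps)
  thetas <- (seq_len(m) - 1) * eps
  n <- pair$n
  if (n < 2L) {
    return(finalize_accumulator(pair, params, thetas, counts = rep(1L, m),
                                witnesses = rep(list(NULL), m),
                                stats = list(n_candidates = 0, n_sweeps = 0)))
  }
  H0 <- rep(0L, m)
  warm <- NULL
  if (search$warm_start) {
    warm <- kabsch_transform(pair$target$xyz, pair$model$xyz)
    H0 <- counts_at(pair, warm, thetas + eps, params$distance_tol)
  }
  res <- cpp_gdt_search(pair$target$xyz, pair$model$xyz, eps, thetas,
                        as.integer(H0),
                        anchor_set(pair, search),
                        side = search$thin_translation *
                          params$cube_side_factor * sqrt(3) * eps / 9,
                        spacing = search$thin_cap * params$cap_spacing,
                        tol = params$distance_tol,
                        max_candidates = search$max_candidates)
  witnesses <- lapply(seq_len(m), function(i) {
    if (!is.na(res$wit_k[i])) {
      list(source = "anchored", k = res$wit_k[i], l = res$wit_l[i],
           image_k = res$wit_ak[i, ], image_l = res$wit_al[i, ])
    } else if (!is.null(warm) && H0[i] > 0L) {
      list(source = "warm", transform = warm)
    } else NULL
  })
  finalize_accumulator(pair, params, thetas, res$H, witnesses,
                       stats = list(n_candidates = res$n_candidates,
                                    n_sweeps = res$n_sweeps))
}

finalize_accumulator <- function(pair, params, thetas, counts, witnesses,
                                 stats) {
  counts <- cummax(pmax(as.integer(counts), 1L))
  structure(list(epsilon = params$epsilon, theta_max = params$theta_max,
                 thetas = thetas, n = pair$n,
                 counts = counts, H = counts / pair$n,
                 witnesses = witnesses, stats = stats,
                 params = params),
            class = "gdt_accumulator")
}

#' @export
print.gdt_accumulator <- function(x, ...) {
  cat(sprintf("gdt_accumulator: n=%d, eps=%.3g, m=%d, H in [%.3f, %.3f]\n",
              x$n, x$epsilon, length(x$H), min(x$H), max(x$H)))
  invisible(x)
}

#' Reconstruct the witness transform of one H slot
#'
#' Rebuilds the rigid transform realizing `acc$H[i]`: for an anchored
#' witness, the anchored transform is reconstructed from the stored image
#' pair and the optimal axis rotation at the slot's sweep cutoff is
#' recomputed. `count_within` of the result at cutoff `theta_i + epsilon`
#' reproduces the stored count.
#'
#' @param pair the `structure_pair` the accumulator came from.
#' @param acc a `gdt_accumulator`.
#' @param i slot index.
#' @return A `rigid_transform`, or NULL when the slot has no witness (the
#'   1/n floor; any single-residue translation realizes it).
#' @export
witness_transform <- function(pair, acc, i) {
  w <- acc$witnesses[[i]]
  if (is.null(w)) return(NULL)
  if (w$source == "warm") return(w$transform)
  frame <- anchored_transform(pair, w$k, w$l, w$image_k, w$image_l)
  best_axis_rotation(pair, frame, acc$thetas[i] + acc$epsilon,
                     acc$params$distance_tol)$transform
}

#' Riemann-sum area estimate
#'
#' The area estimate `sum(epsilon * H_i)` over the grid, with the
#' percent-scale score `100 * area / theta_max` matching the 100 x
#' theta_max rectangle convention. The estimate is a 4*epsilon
#' approximation of the exact area under the Hubbard function (full
#' enumeration). The grid may overshoot theta_max by up to one cell
#' (m = ceiling(theta_max/epsilon)); the overshoot is part of the error
#' budget and the last cell is deliberately not clipped.
#'
#' @param acc a `gdt_accumulator` from [compute_H_values()].
#' @return List of class `gdt_area_estimate` with `epsilon`, `theta_max`,
#'   `m`, `H_values`, `area`, `normalized`.
#' @export
area_estimate <- function(acc) {
  stopifnot(inherits(acc, "gdt_accumulator"))
  area <- sum(acc$epsilon * acc$H)
  structure(list(epsilon = acc$epsilon, theta_max = acc$theta_max,
                 m = length(acc$H), n = acc$n, H_values = acc$H,
                 area = area,
                 normalized = 100 * area / acc$theta_max),
            class = "gdt_area_estimate")
}

#' @export
print.gdt_area_estimate <- function(x, ...) {
  cat(sprintf("GDT area estimate: %.4f A (normalized %.2f), eps=%.3g, n=%d\n",
              x$area, x$normalized, x$epsilon, x$n))
  invisible(x)
}

#' Near-optimal GDT fractions at fixed cutoffs
#'
#' For each cutoff theta the anchored-grid + plane-sweep machinery is run
#' restricted to that single threshold, reporting the fraction fitted at
#' sweep cutoff theta + epsilon by the best qualified candidate (anchor
#' images within theta + eps/6 resp. theta + eps/3 of their target atoms).
#' The result lies in [H(theta), H(theta + epsilon)]. No warm start is
#' used: the output is exactly the anchored search's, as the fixed-cutoff
#' scores are defined by it.
#'
#' @param pair a `structure_pair`.
#' @param cutoffs positive ascending cutoffs in Angstrom.
#' @param params a `gdt_params`.
#' @param search a `gdt_search_options`.
#' @return List of class `gdt_fixed` with `cutoffs`, `fractions`,
#'   `aggregate` (100 x mean fraction).
#' @export
gdt_fixed_cutoffs <- function(pair, cutoffs, params = gdt_params(),
                              search = gdt_search_options()) {
  stopifnot(inherits(pair, "structure_pair"),
            all(cutoffs > 0), !is.unsorted(cutoffs))
  n <- pair$n
  if (n < 2L) {
    fr <- rep(1, length(cutoffs))
  } else {
    anchors <- anchor_set(pair, search)
    fr <- vapply(cutoffs, function(theta) {
      res <- cpp_gdt_search(pair$target$xyz, pair$model$xyz, params$epsilon,
                            theta, 0L, anchors,
                            side = search$thin_translation *
                              params$cube_side_factor * sqrt(3) *
                              params$epsilon / 9,
                            spacing = search$thin_cap * params$cap_spacing,
                            tol = params$distance_tol,
                            max_candidates = search$max_candidates)
      max(res$H[1], 1L) / n
    }, numeric(1))
  }
  structure(list(cutoffs = cutoffs, fractions = fr,
                 aggregate = 100 * mean(fr), epsilon = params$epsilon),
            class = "gdt_fixed")
}

#' @export
print.gdt_fixed <- function(x, ...) {
  cat(sprintf("GDT at cutoffs (%s): fractions (%s), aggregate %.2f\n",
              paste(x$cutoffs, collapse = ", "),
              paste(sprintf("%.3f", x$fractions), collapse = ", "),
              x$aggregate))
  invisible(x)
}

#' GDT_TS and GDT_HA scores
#'
#' GDT_TS is 100 times the mean fitted fraction at cutoffs 1, 2, 4, 8
#' Angstrom; GDT_HA halves the cutoffs (0.5, 1, 2, 4). Fractions come from
#' the near-optimal fixed-cutoff search at resolution `params$epsilon`.
#'
#' @inheritParams gdt_fixed_cutoffs
#' @return A `gdt_fixed` object; its `aggregate` is the score on the 0-100
#'   scale.
#' @export
gdt_ts <- function(pair, params = gdt_params(), search = gdt_search_options())
  gdt_fixed_cutoffs(pair, params$cutoffs_ts, params, search)

#' @rdname gdt_ts
#' @export
gdt_ha <- function(pair, params = gdt_params(), search = gdt_search_options())
  gdt_fixed_cutoffs(pair, params$cutoffs_ha, params, search)

#' Curve records of an accumulator
#'
#' @param acc a `gdt_accumulator`.
#' @return data.frame with columns theta, fraction, source, suitable for
#'   [write_curve_tsv()].
#' @export
as_curve_records <- function(acc) {
  stopifnot(inherits(acc, "gdt_accumulator"))
  data.frame(theta = acc$thetas, fraction = acc$H, source = "near_optimal",
             stringsAsFactors = FALSE)
}
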