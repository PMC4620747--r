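# Deterministic generators for structure pairs with known GDT behavior.
# All generators are pure functions of their arguments (seed included); no
# generator touches the global RNG state.

with_preserved_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Collinear C-alpha chain
#'
#' Points at `((i-1)*spacing, 0, 0)`. The 3.8 Angstrom default mimics
#' consecutive C-alpha geometry.
#'
#' @param n number of residues (>= 1).
#' @param spacing inter-residue spacing in Angstrom.
#' @return A `protein_structure`.
#' @export
make_chain <- function(n, spacing = 3.8) {
  stopifnot(n >= 1)
  protein_structure(cbind((seq_len(n) - 1) * spacing, 0, 0))
}

#' Split-shift pair with a known step curve
#'
#' Target = collinear chain; model = the same chain with even-numbered
#' residues displaced by +delta in z and odd-numbered residues by -delta.
#' By construction half the residues can be zeroed out by a translation
#' while the opposed displacement prevents any compromise transform from
#' fitting more than half below theta = delta, so the Hubbard function is
#' 0.5 for theta < delta and 1 at and above delta (confirmed against the
#' subset-bottleneck oracle at n = 6 rather than assumed).
#'
#' @param n even number of residues (>= 2).
#' @param spacing chain spacing in Angstrom.
#' @param delta displacement magnitude in Angstrom (>= 0).
#' @return A `structure_pair`.
#' @export
make_split_shift_pair <- function(n, spacing = 3.8, delta) {
  stopifnot(n >= 2, delta >= 0)
  if (n %% 2 != 0) stop("n must be even for the split-shift construction")
  target <- make_chain(n, spacing)
  xyz <- target$xyz
  xyz[, 3] <- ifelse(seq_len(n) %% 2 == 0, delta, -delta)
  pair_structures(target, protein_structure(xyz))
}

#' Randomly perturbed pair
#'
#' Target = collinear chain; model = target plus iid Gaussian displacement
#' (sd `noise_sd` per coordinate), then an arbitrary seeded rigid motion
#' applied to the whole model — exercising the rigid invariance of all GDT
#' quantities. Pure function of its arguments.
#'
#' @param n number of residues (>= 2).
#' @param spacing chain spacing in Angstrom.
#' @param noise_sd per-coordinate displacement sd in Angstrom (>= 0).
#' @param seed integer seed fixing all randomness.
#' @return A `structure_pair`.
#' @export
make_random_perturb_pair <- function(n, spacing = 3.8, noise_sd, seed) {
  stopifnot(n >= 2, noise_sd >= 0)
  target <- make_chain(n, spacing)
  with_preserved_seed(seed, {
    xyz <- target$xyz + matrix(rnorm(3 * n, sd = noise_sd), ncol = 3)
    mot <- random_rigid_transform()
    pair_structures(target, apply_transform(mot, protein_structure(xyz)))
  })
}

# uniform random rotation (quaternion method) + uniform translation;
# consumes the current RNG stream
random_rigid_transform <- function(translation_range = 10) {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  R <- matrix(c(
    1 - 2 * (q[3]^2 + q[4]^2), 2 * (q[2] * q[3] - q[4] * q[1]),
    2 * (q[2] * q[4] + q[3] * q[1]),
    2 * (q[2] * q[3] + q[4] * q[1]), 1 - 2 * (q[2]^2 + q[4]^2),
    2 * (q[3] * q[4] - q[2] * q[1]),
    2 * (q[2] * q[4] - q[3] * q[1]), 2 * (q[3] * q[4] + q[2] * q[1]),
    1 - 2 * (q[2]^2 + q[3]^2)), 3, 3, byrow = TRUE)
  rigid_transform(R, runif(3, -translation_range, translation_range))
}
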