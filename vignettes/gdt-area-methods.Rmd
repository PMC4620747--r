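---
title: "Scoring protein models by the area under the GDT curve"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring protein models by the area under the GDT curve}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gdtarea)
```

## The model quality problem

Given an experimentally determined protein structure `a = (a_1, ..., a_n)`
and a predicted model `b = (b_1, ..., b_n)` of the same length (one point per
residue, conventionally the C-alpha atom), the Global Distance Test asks:
for a distance cutoff theta, what is the largest fraction of model residues
that *some* rigid motion places within theta of the corresponding target
residues? Formally the Hubbard (GDT) function is

    H(theta) = max_T |{ i : ||a_i - T(b_i)|| <= theta }| / n

with the maximum over all rotations-plus-translations T. Because H only
takes values in {1/n, ..., 1} and is monotone, it is a step function with at
most n - 1 steps. The familiar GDT_TS score samples it at four arbitrary
cutoffs (1, 2, 4, 8 Angstrom) and averages; this package instead targets the
*area* under H on [0, theta_max] (theta_max = 10 Angstrom by the CASP
convention), which uses the whole curve: small areas would mean a poor
model, and the score `100 * area / theta_max` lives on the usual 0-100
scale. A smaller sampling artifact also disappears: GDT_TS can rank a
clearly worse model above a better one when the interesting part of the
curve falls between two of the four cutoffs.

Computing even one exact value H(theta) is prohibitively expensive (the best
exact algorithms are high-degree polynomial), so the area is approximated by
a Riemann sum of *near-optimal* values: lower bounds `H_i` on a grid
`theta_i = (i-1)*eps`, each bracketed as

    H((i-1)*eps)  <=  H_i  <=  H(i*eps).

Summing `eps * H_i` over `i = 1..m`, `m = ceiling(theta_max/eps)`, gives an
estimate within `4*eps` of the true area: up to `2*eps` from bracketed
sampling of a monotone function, and up to another `2*eps` shared between
the Riemann error proper and the last grid cell overshooting theta_max
(we deliberately do not clip that cell; the overshoot is part of the error
budget and vanishes when theta_max/eps is integer).

## The search over rigid motions

The bracket for `H_i` is established by discretizing candidate rigid
motions anchored at residue pairs:

1. **Anchor pairs.** For the unknown optimal residue subset there is always
   a "radial pair" (a residue and the subset's farthest residue from it)
   whose two positions pin the subset's placement up to a rotation about
   their axis. Since the subset is unknown, all n(n-1) ordered pairs (k, l)
   are tried, in a fixed deterministic order.
2. **Translation grid.** Candidate images of `b_k` are the vertices of a
   cubic lattice of side just below `sqrt(3)*eps/9` (so a cell half-diagonal
   is just under `eps/6`), anchored so that the target atom `a_k` is itself
   a vertex, restricted to the open ball of radius `theta_i + eps/6` around
   `a_k`. Anchoring the lattice at `a_k` makes runs deterministic and
   translation-reproducible; the covering contract — any admissible image
   position has a grid point within `eps/6` — is what the tests assert, not
   any particular boundary convention (the open-ball test uses a 1e-12
   slack).
3. **Cap grid.** Once `b_k` is pinned at a candidate `a^k`, the image of
   `b_l` must lie on the sphere around `a^k` of radius `||b_k - b_l||` (the
   chord is rigid) and within `theta_i + eps/3` of `a_l`. That spherical cap
   is sampled by latitude bands of angular step `spacing/radius` with
   longitude step at most `spacing` (`spacing = eps/6`), plus a one-spacing
   margin band so the covering contract survives the discretized ball test.
4. **Plane sweep.** The remaining degree of freedom is the twist about the
   axis through the two images. For each residue the feasible twist angles
   form a closed arc (possibly empty or the full circle): the squared
   distance to the target is `A - B cos(phi - phi_0)`. Sorting the at most
   2n arc endpoints and sweeping with a running counter finds the maximum
   overlap — the best count — in O(n log n). Arcs are closed to match the
   closed `<= theta` convention, entry events are processed before exit
   events at equal angles (so tangent arcs count), and the reported angle is
   the midpoint of a maximal interval, robustly inside the feasible set.

A candidate image pair updates slot i exactly when `||a_k - a^k|| <
theta_i + eps/6` and `||a_l - a^l|| < theta_i + eps/3`, with sweep cutoff
`theta_i + eps`; all m slots are accumulated in a single pass over
candidates, and the translation grid around each `a_k` is built once rather
than once per threshold. The loop structure (anchor pairs, then grid-point
pairs, then applicable thresholds, each calling one sweep) gives the
O(n^3 log n / eps^6) complexity; with n^2 anchor pairs and O(1/eps^5)
image pairs each, the constants are large, which is why the
exactness-preserving accelerations below matter.

### Exactness-preserving accelerations

Three prunings never change the result:

* **Certification at 1.** Any transform whose count at cutoff `i*eps`
  reaches n proves `H(i*eps) = 1`, so slot i and all later slots are final.
  The enumeration radius shrinks accordingly as incumbents improve. The
  RMSD-optimal (Kabsch) fit seeds the incumbents for the area computation —
  any transform's count at `i*eps` is a valid value inside the bracket, so
  this warm start cannot violate either side of it. The Kabsch fit is used
  (rather than, say, the identity) because it is equivariant under rigid
  motion of the model, preserving exact rigid invariance of all H values.
* **Sphere-feasibility bound.** With `b_k` pinned at `a^k`, residue i lies
  on a sphere of known radius, so
  `|dist(a_i, a^k) - ||b_i - b_k||| <= cutoff` is necessary for fitting;
  when the count of residues passing this test cannot beat the incumbent,
  the whole cap enumeration for `a^k` is skipped.
* **Arc-count bound.** The number of non-empty arcs bounds the sweep
  result; sorting is skipped when it cannot beat the incumbent.

### The reduced search for large structures

The full enumeration is the guaranteed algorithm and the default, but at
n = 100 and eps = 0.25 it needs ~10^13 elementary operations — far beyond
any desk machine. For large inputs `gdt_search_options()` can request a
documented reduced search: a deterministic anchor subset (for each of a few
evenly spaced residues k, its two farthest partners — the radial-pair
heuristic, robust to near-ties) and integer thinning factors on the two
grids. Every number the reduced search reports is still the genuine count
of a genuine anchored transform found by the same machinery — a valid lower
bound on `H(theta_i + eps)` — but the lower bracket `H_i >= H(theta_i)` is
no longer formally guaranteed. Thinning by factors (t, c) degrades the
effective anchor precision from `eps/3` to about `t*eps/6 + c*eps/6 (plus
the projection term)`, so fits whose geometric margin exceeds roughly three
times that are still found; the worked fixtures below are engineered with
margins far above it.

## Fixed-cutoff scores (GDT_TS / GDT_HA)

`gdt_fixed_cutoffs()` runs the same machinery restricted to a single
threshold per cutoff, reporting the best qualified candidate's fraction at
sweep cutoff `theta + eps` — a value inside `[H(theta), H(theta + eps)]`.
Two conventions are worth stating. First, no warm start is used here: the
score is *defined* as the anchored search's output, whose qualification
radii (`theta + eps/6`, `theta + eps/3`) are part of the method. Second,
the aggregate is 100 times the *mean* of the four fractions (cutoffs 1, 2,
4, 8 for GDT_TS; 0.5, 1, 2, 4 for GDT_HA) — the score is an average, not a
sum.

## The exact oracle

For pairs with n <= 6 residues the package computes ground truth by brute
force. The key reduction: for a residue subset S and a *fixed* rotation R,
the translation minimizing `max_{i in S} ||a_i - R b_i - t||` is the center
of the smallest enclosing ball of the residuals `{a_i - R b_i}`, computed
exactly (Welzl's algorithm; at most four support points). The 6-DOF minimax
therefore collapses to a 3-DOF search over rotation vectors, handled by
multi-start Nelder-Mead (identity, the Kabsch rotation, and 30
quasi-random starts from a Fibonacci-sphere/golden-ratio sequence —
deterministic, so oracle runs are exactly reproducible), followed by a
polish from the best start. An independent dense rotation-grid cross-check
in the test suite agrees to within 0.05 Angstrom.

Enumerating all subsets of each size j gives the exact minimax values
`f_j` (non-decreasing in j by subset monotonicity), from which the exact
step curve follows: `H(theta) = max{ j/n : f_j <= theta }`, and the exact
area is the layer-cake sum `sum_j max(0, theta_max - f_j)/n`. Oracle values
carry a ~1e-3 Angstrom optimization tolerance, which all acceptance
comparisons propagate (bounds are checked with `+ 2 * 1e-3` slack). Because
a numerical minimax can only overestimate the true minimum, oracle error
can never make the lower-bracket check spuriously pass.

## Synthetic study pairs

`make_chain(n, spacing)` builds a collinear chain at 3.8 Angstrom spacing
(C-alpha geometry; the spacing is cosmetic, not load-bearing).
`make_split_shift_pair(n, spacing, delta)` displaces even-numbered residues
by `+delta` in z and odd-numbered ones by `-delta`: either parity class can
be zeroed by a translation, so H is 0.5 below delta... *almost*. Working
through this package exposed a subtlety worth recording: a perfectly
straight chain has a continuous axial symmetry, and slightly screwed
("helical") rigid motions can redistribute the two offset classes, fitting
more than half the residues at cutoffs within about 10% below delta. At
n = 6 end effects are strong enough that the exact oracle finds a tilted
4-of-6 fit at 1.01 Angstrom for delta = 1.5 — the exact curve has a genuine
intermediate step there. At n = 100 the compromise fits max out well below
half + 1 as long as the cutoff (plus the search's eps inflation) stays a
comfortable factor below delta.

The two worked fixtures are therefore engineered with wide margins:

* *blue-type* (a good model whose errors sit just above the smallest
  cutoff): delta = 1.5, so half the residues fit under 1 Angstrom and all
  fit under 2, 4 and 8 — per-cutoff fractions (0.5, 1, 1, 1), GDT_TS
  exactly 87.5;
* *red-type* (an almost identical model whose errors sit just above the
  second cutoff): delta = 3.0, so half fit under 1 and 2 and all fit under
  4 and 8 — fractions (0.5, 0.5, 1, 1), GDT_TS exactly 75. A misfit
  distance barely above 2 (say 2.2) would *not* realize this profile under
  a search with eps = 0.25: the inflated cutoff 2.25 crosses the misfit
  distance and qualified helical fits appear that fit well over half the
  residues; 3.0 sits safely in the open interval the profile actually
  requires.

The four-cutoff aggregate drops by a fixed 12.5 points the moment the
misfit distance crosses a cutoff, no matter how small the crossing; the
area score instead degrades continuously with the misfit distance — the
sampling artifact the area measure is designed to remove.

`make_random_perturb_pair(n, spacing, noise_sd, seed)` adds iid Gaussian
noise to every coordinate and then applies a seeded random rigid motion to
the whole model, exercising rigid invariance. What these generators do
*not* emulate: realistic backbone geometry (bond angles, excluded volume),
correlated domain motions, alignment gaps, or experimental coordinate
error in the target. Passing tests on them validates the optimization
machinery and its guarantees, not biological realism of any scoring
threshold.

## Numerical choices

* Distance comparisons use a closed inequality with a +1e-9 Angstrom slack,
  so residues exactly at a cutoff count and float noise cannot flip them.
* Anchored transforms require chord congruence within 1e-6 Angstrom and
  reproduce both anchors to 1e-9; coincident model residues (< 1e-9 apart)
  cannot define an axis and the anchor pair is skipped — harmless, because
  any subset of two or more distinct points has a non-degenerate radial
  pair.
* Degenerate arcs (residue on the axis, or target on the axis) have
  constant distance and are classified full/empty before any inverse
  trigonometry.
* Step-curve evaluation at a jump returns the post-jump value: H(theta) is
  attained at theta because its defining maximum uses a closed inequality.
* Monotone finalization (cummax over slots, floor at 1/n) is a safety net:
  per-candidate maxima are already monotone across slots in exact
  arithmetic, and a single residue always superimposes exactly.
* n = 1 pairs are legal with the constant-1 curve; the oracle refuses
  n > 6 (subset enumeration grows combinatorially).

## Validation problem sizes

The validation suite (`area_bound_trials()`) runs 20 seeded random pairs —
n in {3, 4, 5}, per-coordinate noise 1-3 Angstrom, eps in {1.0, 0.5} —
with the *full* guaranteed enumeration against the exact oracle. Sizes are
matched to the enumeration cost, which grows like `(f_max/eps)^5` per
anchor pair (f_max being the full-set bottleneck radius, driven by the
noise level): the finer resolution is paired with the smallest instances
and the strongest noise with the coarser resolution, keeping the suite at
desk scale while still covering both resolutions and the full noise range.
Across seeds the observed worst-case area error is about 0.3*eps (bound: 4)
and the worst-case exact-H Riemann error about 0.55*eps (bound: 2).

## Known limitations

* The guaranteed enumeration is practical only for small n or coarse eps;
  the reduced search drops the formal lower bracket (scores remain genuine
  lower bounds).
* Correspondence is positional (or by label intersection); there is no
  sequence alignment, so target and model must describe the same residues.
* The oracle's multi-start optimization is not a formal global-optimality
  proof; it is cross-checked by an independent rotation-grid search and by
  certificate transforms, and its tolerance is propagated into every
  comparison that uses it.
* PDB input follows evaluation practice: first model only, ATOM/CA records
  only, altlocs resolved by occupancy.
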