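test_that("identical structures give a constant-1 accumulator and full area", {
  p <- pair_structures(make_chain(5), make_chain(5))
  acc <- compute_H_values(p, gdt_params(epsilon = 0.5))
  expect_true(all(acc$H == 1))
  est <- area_estimate(acc)
  expect_equal(est$area, 10)
  expect_equal(est$normalized, 100)

  # m = ceiling(theta_max/eps) may overshoot: eps = 0.3 gives 34 cells
  acc <- compute_H_values(p, gdt_params(epsilon = 0.3))
  est <- area_estimate(acc)
  expect_equal(est$m, 34L)
  expect_equal(est$area, 10.2)

  # single-residue pairs are legal and constant 1
  p1 <- pair_structures(make_chain(1), make_chain(1))
  expect_true(all(compute_H_values(p1, gdt_params(epsilon = 1))$H == 1))
})

test_that("split-shift H values step from one half to one at delta", {
  # H_i must be 0.5 wherever the sweep cutoff i*eps is below delta and 1
  # wherever theta_i = (i-1)*eps is at or beyond delta; slots whose bracket
  # straddles delta may take either value
  ss <- make_split_shift_pair(6, 3.8, 1.5)
  params <- gdt_params(epsilon = 0.5)
  acc <- compute_H_values(ss, params)
  below <- acc$thetas + params$epsilon < 1.5
  above <- acc$thetas >= 1.5
  expect_true(all(acc$H[below] == 0.5))
  expect_true(all(acc$H[above] == 1))

  # oracle sandwich on every slot
  cv <- exact_curve(ss, 10)
  H_lo <- evaluate_step_curve(cv, pmax(acc$thetas - 2e-3, 0))
  H_hi <- evaluate_step_curve(cv, pmin(acc$thetas + params$epsilon + 2e-3, 10))
  expect_true(all(acc$H >= H_lo - 1e-12))
  expect_true(all(acc$H <= H_hi + 1e-12))
})

test_that("every H slot is realized exactly by its witness transform", {
  pair <- make_random_perturb_pair(4, 3.8, 1.5, seed = 3)
  params <- gdt_params(epsilon = 1)
  acc <- compute_H_values(pair, params)
  for (i in seq_along(acc$H)) {
    tr <- witness_transform(pair, acc, i)
    if (is.null(tr)) next
    expect_gte(count_within(pair, tr, acc$thetas[i] + params$epsilon),
               acc$counts[i])
  }
  # at least the certified-full slots must have witnesses
  expect_true(any(!vapply(acc$witnesses, is.null, logical(1))))
})

test_that("H values are rigid-invariant in the model frame", {
  pair <- make_random_perturb_pair(4, 3.8, 1.2, seed = 14)
  params <- gdt_params(epsilon = 1)
  acc1 <- compute_H_values(pair, params)
  motion <- with_seed(77, gdtarea:::random_rigid_transform())
  moved <- pair_structures(pair$target, apply_transform(motion, pair$model))
  acc2 <- compute_H_values(moved, params)
  expect_identical(acc1$counts, acc2$counts)
})

test_that("area of the blue-type fixture is within 4*eps of the step integral", {
  # analytic step integral: 0.5 * 1.5 + 1 * 8.5 = 9.25
  pair <- make_split_shift_pair(100, 3.8, 1.5)
  params <- gdt_params(epsilon = 0.25)
  search <- gdt_search_options(max_anchor_residues = 8, thin_translation = 4,
                               thin_cap = 3)
  est <- area_estimate(compute_H_values(pair, params, search))
  expect_lte(abs(est$area - 9.25), 4 * 0.25)
})

test_that("fixed-cutoff scores are exact for identical structures", {
  p <- pair_structures(make_chain(8), make_chain(8))
  g <- gdt_ts(p, gdt_params(epsilon = 0.5))
  expect_equal(g$fractions, rep(1, 4))
  expect_equal(g$aggregate, 100)
  h <- gdt_ha(p, gdt_params(epsilon = 0.5))
  expect_equal(h$aggregate, 100)
})
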