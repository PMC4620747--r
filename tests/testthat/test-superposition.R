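test_that("rigid transforms compose, invert and apply correctly", {
  expect_equal(apply_transform(transform_identity(), make_chain(3))$xyz,
               make_chain(3)$xyz)
  tr <- rigid_transform(diag(3), c(1, 2, 3))
  expect_equal(unname(apply_transform(tr, matrix(0, 1, 3))[1, ]), c(1, 2, 3))
  rot <- rotation_about_axis(c(0, 0, 0), c(0, 0, 1), pi)
  expect_equal(unname(apply_transform(rot, matrix(c(1, 0, 0), 1))[1, ]),
               c(-1, 0, 0), tolerance = 1e-12)
  with_seed(11, {
    t1 <- random_frame(random_cloud_pair(4, 1), 2)$base_transform
    t2 <- rotation_about_axis(rnorm(3), random_unit(), runif(1, 0, 2 * pi))
    x <- matrix(rnorm(9), 3)
    expect_equal(apply_transform(transform_compose(t2, t1), x),
                 apply_transform(t2, apply_transform(t1, x)))
    inv <- transform_inverse(t2)
    expect_equal(apply_transform(inv, apply_transform(t2, x)), x,
                 tolerance = 1e-12)
  })
  expect_error(rigid_transform(diag(c(1, 1, -1)), c(0, 0, 0)), "proper")
})

test_that("count_within matches a naive per-residue distance check", {
  p <- pair_structures(make_chain(6), make_chain(6))
  expect_equal(count_within(p, transform_identity(), 0), 6L)

  shifted <- pair_structures(
    make_chain(4),
    apply_transform(rigid_transform(diag(3), c(0, 0, 5)), make_chain(4)))
  expect_equal(count_within(shifted, transform_identity(), 1), 0L)
  expect_equal(count_within(shifted, rigid_transform(diag(3), c(0, 0, -5)), 0),
               4L)

  for (seed in 1:10) {
    pair <- random_cloud_pair(7, seed)
    tr <- with_seed(seed + 100,
                    rotation_about_axis(rnorm(3), random_unit(), runif(1)))
    theta <- with_seed(seed + 200, runif(1, 0, 5))
    naive <- 0L
    for (i in seq_len(pair$n)) {
      bi <- as.numeric(tr$R %*% pair$model$xyz[i, ]) + tr$t
      if (sqrt(sum((pair$target$xyz[i, ] - bi)^2)) <= theta + 1e-9)
        naive <- naive + 1L
    }
    expect_identical(count_within(pair, tr, theta), naive)
  }
})

test_that("count_within is congruence-invariant and monotone in theta", {
  pair <- random_cloud_pair(6, 42)
  tr <- with_seed(1, rotation_about_axis(rnorm(3), random_unit(), 0.7))
  motion <- with_seed(2, rotation_about_axis(rnorm(3), random_unit(), 1.3))
  moved <- pair_structures(apply_transform(motion, pair$target), pair$model)
  for (theta in c(0.5, 1, 2, 4))
    expect_identical(count_within(pair, tr, theta),
                     count_within(moved, transform_compose(motion, tr), theta))
  counts <- vapply(seq(0, 6, by = 0.25),
                   function(th) count_within(pair, tr, th), integer(1))
  expect_true(all(diff(counts) >= 0L))
})

test_that("anchored transforms satisfy both anchor equations", {
  pair <- pair_structures(make_chain(3), make_chain(3))
  fr <- anchored_transform(pair, 1, 2, c(5, 5, 5), c(8.8, 5, 5))
  expect_equal(fr$base_transform$t, c(5, 5, 5))

  expect_error(anchored_transform(pair, 1, 2, c(0, 0, 0), c(3.9, 0, 0)),
               "chord-length mismatch")

  for (seed in 1:20) {
    pair <- random_cloud_pair(6, seed)
    fr <- random_frame(pair, seed + 500)
    img <- apply_transform(fr$base_transform, pair$model$xyz)
    expect_lt(sqrt(sum((img[fr$k, ] - fr$image_k)^2)), 1e-9)
    expect_lt(sqrt(sum((img[fr$l, ] - fr$image_l)^2)), 1e-9)
  }

  dup <- pair_structures(
    make_chain(3),
    protein_structure(matrix(c(0, 0, 0, 0, 0, 0, 1, 1, 1), 3, byrow = TRUE)))
  expect_error(anchored_transform(dup, 1, 2, c(0, 0, 0), c(0, 0, 0)),
               "degenerate anchor")
})

test_that("axis rotations keep the anchors fixed", {
  pair <- random_cloud_pair(5, 7)
  fr <- random_frame(pair, 8)
  dir <- (fr$image_l - fr$image_k) / sqrt(sum((fr$image_l - fr$image_k)^2))
  for (ang in c(0.3, 1.7, 4.4)) {
    tr <- transform_compose(rotation_about_axis(fr$image_k, dir, ang),
                            fr$base_transform)
    img <- apply_transform(tr, pair$model$xyz)
    expect_lt(sqrt(sum((img[fr$k, ] - fr$image_k)^2)), 1e-9)
    expect_lt(sqrt(sum((img[fr$l, ] - fr$image_l)^2)), 1e-9)
  }
})

test_that("candidate radial pairs enumerate all ordered pairs", {
  expect_equal(nrow(candidate_radial_pairs(3)), 6L)
  expect_equal(nrow(candidate_radial_pairs(2)), 2L)
  p10 <- candidate_radial_pairs(10)
  expect_equal(nrow(p10), 90L)
  expect_equal(anyDuplicated(paste(p10[, 1], p10[, 2])), 0L)
  expect_error(candidate_radial_pairs(1), "at least 2")
})

test_that("Kabsch fit recovers an exact rigid motion", {
  with_seed(5, {
    a <- matrix(rnorm(15, sd = 5), ncol = 3)
    mot <- rotation_about_axis(rnorm(3), random_unit(), 1.1)
    b <- apply_transform(transform_inverse(mot), a)
    fit <- kabsch_transform(a, b)
    expect_equal(apply_transform(fit, b), a, tolerance = 1e-9)
  })
})
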