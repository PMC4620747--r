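test_that("degenerate arcs (point on axis) are constant-distance cases", {
  # point on the axis: rotation leaves it fixed, distance to target constant
  arc <- angular_feasible_arc(point = c(0, 0, 3), target = c(0.5, 0, 3),
                              axis_point = c(0, 0, 0), axis_dir = c(0, 0, 1),
                              cutoff = 1)
  expect_equal(arc$kind, "full")
  arc <- angular_feasible_arc(point = c(0, 0, 3), target = c(2, 0, 3),
                              axis_point = c(0, 0, 0), axis_dir = c(0, 0, 1),
                              cutoff = 1)
  expect_equal(arc$kind, "empty")
})

test_that("feasibility arcs agree with a dense angular scan", {
  for (seed in 1:20) {
    with_seed(seed, {
      axis_point <- rnorm(3)
      axis_dir <- random_unit()
      point <- rnorm(3, sd = 3)
      target <- rnorm(3, sd = 3)
      cutoff <- runif(1, 0.5, 4)
    })
    arc <- angular_feasible_arc(point, target, axis_point, axis_dir, cutoff)
    phis <- (seq_len(1e5) - 1) * 2 * pi / 1e5
    # explicit circle parameterization: o + alpha*u + cos(phi)*e + sin(phi)*(u x e)
    u <- axis_dir
    dvec <- point - axis_point
    alpha <- sum(dvec * u)
    e <- dvec - alpha * u
    uxe <- gdtarea:::cross3(u, e)
    centre_pt <- axis_point + alpha * u
    pos <- outer(cos(phis), e) + outer(sin(phis), uxe) +
      matrix(centre_pt, length(phis), 3, byrow = TRUE)
    feas <- sqrt(rowSums(sweep(pos, 2, target)^2)) <= cutoff + 1e-9
    in_arc <- switch(arc$kind,
      empty = rep(FALSE, length(phis)),
      full = rep(TRUE, length(phis)),
      proper = if (arc$start <= arc$end) phis >= arc$start & phis <= arc$end
               else phis >= arc$start | phis <= arc$end)
    if (arc$kind == "proper") {
      # endpoints agree with the scan boundary to the scan resolution
      flips <- which(diff(feas) != 0)
      expect_equal(sum(diff(in_arc) != 0), length(flips))
      dist_to_end <- pmin(
        abs(((phis - arc$start + pi) %% (2 * pi)) - pi),
        abs(((phis - arc$end + pi) %% (2 * pi)) - pi))
      ok <- feas == in_arc | dist_to_end < 1e-4
      expect_true(all(ok))
    } else {
      expect_true(all(feas == in_arc))
    }
  }
})

test_that("plane sweep equals the dense-scan maximum on random instances", {
  for (seed in 1:25) {
    n <- with_seed(seed, sample(3:12, 1))
    pair <- random_cloud_pair(n, seed, noise = 2)
    fr <- random_frame(pair, seed + 1000)
    cutoff <- with_seed(seed + 2000, runif(1, 1, 6))
    sw <- best_axis_rotation(pair, fr, cutoff)
    expect_equal(sw$count, dense_scan_max(pair, fr, cutoff))
    # the reported angle reproduces the reported count exactly
    expect_identical(count_within(pair, sw$transform, cutoff), sw$count)
    # the sweep can only improve on the arbitrary initial twist
    expect_gte(sw$count, count_within(pair, fr$base_transform, cutoff))
  }
})

test_that("sweep count is monotone in cutoff and axis-reversal invariant", {
  pair <- random_cloud_pair(8, 99, noise = 2)
  fr <- random_frame(pair, 100)
  counts <- vapply(seq(0.5, 6, by = 0.5),
                   function(cc) best_axis_rotation(pair, fr, cc)$count,
                   integer(1))
  expect_true(all(diff(counts) >= 0L))

  rev_fr <- anchored_transform(pair, fr$l, fr$k, fr$image_l, fr$image_k)
  # re-anchor so both residues are pinned identically, axis reversed
  expect_equal(best_axis_rotation(pair, rev_fr, 2)$count,
               best_axis_rotation(pair, fr, 2)$count)
})

test_that("anchored pair always lies inside the swept count", {
  # anchors are pinned to their images, so when the images are within the
  # cutoff of the targets both anchors are always counted
  pair <- random_cloud_pair(6, 17, noise = 1)
  k <- 1L; l <- 4L
  r <- sqrt(sum((pair$model$xyz[l, ] - pair$model$xyz[k, ])^2))
  dirkl <- (pair$target$xyz[l, ] - pair$target$xyz[k, ])
  dirkl <- dirkl / sqrt(sum(dirkl^2))
  fr <- anchored_transform(pair, k, l, pair$target$xyz[k, ],
                           pair$target$xyz[k, ] + r * dirkl)
  sw <- best_axis_rotation(pair, fr, max(1, abs(r - sqrt(sum((pair$target$xyz[l, ] - pair$target$xyz[k, ])^2)))) + 0.5)
  expect_gte(sw$count, 2L)
})
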