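test_that("translation grid contains the center and respects the open ball", {
  g <- build_translation_grid(c(1, 2, 3), radius = 0.1, side = 0.5)
  expect_equal(nrow(g$points), 1L)           # radius < side/2: center only
  expect_equal(unname(g$points[1, ]), c(1, 2, 3))

  # eps = 3, theta = 0: radius eps/6 = 0.5, side just under sqrt(3)*3/9
  side <- 0.99 * sqrt(3) * 3 / 9
  g <- build_translation_grid(c(0, 0, 0), radius = 0.5, side = side)
  expect_equal(nrow(g$points), 1L)           # half-diagonal ~0.495 < 0.5

  g <- build_translation_grid(c(0, 0, 0), radius = 2, side = 0.3)
  d <- sqrt(rowSums(g$points^2))
  expect_true(all(d < 2))
  expect_true(any(d == 0))                   # the center is a lattice vertex
  expect_error(build_translation_grid(c(0, 0, 0), 1, -0.1), "positive")
})

test_that("translation grid covers the shrunken ball within eps/6", {
  eps <- 0.8
  side <- 0.99 * sqrt(3) * eps / 9
  radius <- 2 + eps / 6
  centre <- c(0.3, -0.7, 1.1)
  g <- build_translation_grid(centre, radius, side)
  probes <- with_seed(4, {
    v <- matrix(rnorm(3000), ncol = 3)
    v <- v / sqrt(rowSums(v^2)) * runif(1000)^(1/3) * 2
    sweep(v, 2, centre, "+")
  })
  nearest <- apply(probes, 1, function(q)
    min(sqrt(colSums((t(g$points) - q)^2))))
  expect_true(all(nearest <= eps / 6))
})

test_that("cap grid lies on the sphere and covers the exact cap", {
  eps <- 0.8
  spacing <- eps / 6
  sc <- c(0, 0, 0); r <- 5
  bc <- c(0, 0, 6); brad <- 2.5
  g <- build_cap_grid(sc, r, bc, brad, spacing)
  expect_gt(nrow(g$points), 0)
  on_sphere <- abs(sqrt(rowSums(sweep(g$points, 2, sc)^2)) - r)
  expect_true(all(on_sphere < 1e-9))
  din <- sqrt(rowSums(sweep(g$points, 2, bc)^2))
  expect_true(all(din <= brad + spacing + 1e-12))

  # probe the exact cap: points of the sphere within the ball
  probes <- with_seed(9, {
    out <- matrix(NA_real_, 0, 3)
    while (nrow(out) < 1000) {
      v <- matrix(rnorm(9000), ncol = 3)
      v <- v / sqrt(rowSums(v^2)) * r
      keep <- sqrt(rowSums(sweep(v, 2, bc)^2)) < brad
      out <- rbind(out, v[keep, , drop = FALSE])
    }
    out[seq_len(1000), ]
  })
  nearest <- apply(probes, 1, function(q)
    min(sqrt(colSums((t(g$points) - q)^2))))
  expect_true(all(nearest <= eps / 6))
})

test_that("cap grid band structure and degenerate intersections", {
  # ball containing the whole sphere: full-sphere grid
  r <- 2; spacing <- 0.3
  g <- build_cap_grid(c(0, 0, 0), r, c(0, 0, 0.5), 5, spacing)
  lat <- round(sweep(g$points, 2, c(0, 0, 0)) %*%
                 matrix(c(0, 0, 1) / 1, ncol = 1), 9)
  # latitude bands measured along the axis toward the ball center
  axis <- c(0, 0, 1)
  coslat <- round(as.numeric(g$points %*% axis) / r, 7)
  expect_equal(length(unique(coslat)), ceiling(pi * r / spacing) + 1)

  # external tangency: only points near the tangent point, within margin
  g2 <- build_cap_grid(c(0, 0, 0), 2, c(0, 0, 4.05), 2, 0.3)
  expect_true(nrow(g2$points) < 30)
  if (nrow(g2$points) > 0) {
    din <- sqrt(rowSums(sweep(g2$points, 2, c(0, 0, 4.05))^2))
    expect_true(all(din <= 2 + 0.3 + 1e-12))
  }

  # empty intersection
  g3 <- build_cap_grid(c(0, 0, 0), 1, c(0, 0, 10), 2, 0.3)
  expect_equal(nrow(g3$points), 0L)
})

test_that("grid cardinalities scale as 1/eps^3 and 1/eps^2", {
  sizes_t <- vapply(c(0.8, 0.4), function(eps)
    nrow(build_translation_grid(c(0, 0, 0), 2 + eps / 6,
                                0.99 * sqrt(3) * eps / 9)$points), numeric(1))
  expect_gt(sizes_t[2] / sizes_t[1], 8 / 3)
  expect_lt(sizes_t[2] / sizes_t[1], 8 * 3)

  sizes_c <- vapply(c(0.8, 0.4), function(eps)
    nrow(build_cap_grid(c(0, 0, 0), 5, c(0, 0, 5.5), 2 + eps / 3,
                        eps / 6)$points), numeric(1))
  expect_gt(sizes_c[2] / sizes_c[1], 4 / 3)
  expect_lt(sizes_c[2] / sizes_c[1], 4 * 3)
})
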