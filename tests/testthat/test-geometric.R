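test_that("minimum convex polygon matches an independent hull construction", {
  sq <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))
  expect_equal(mcp(sq)$area, 1.0)
  with_center <- rbind(sq, c(0.5, 0.5))
  expect_equal(nrow(mcp(with_center)$vertices), 4)   # interior point ignored
  expect_error(mcp(cbind(0:4, 0:4)), "degenerate")
  expect_error(mcp(cbind(c(0, 1), c(0, 1))), "degenerate")
  set.seed(11)
  for (i in 1:5) {
    xy <- matrix(rnorm(100), 50, 2)
    expect_equal(mcp(xy)$area, shoelace(giftwrap_hull(xy)), tolerance = 1e-12)
  }
})

test_that("LoCoH with k = n collapses to the minimum convex polygon", {
  set.seed(12)
  xy <- matrix(rnorm(60, sd = 300), 30, 2)
  lo <- locoh_k(xy, k = nrow(xy))
  m <- mcp(xy)
  # all hulls identical to the MCP, coverage complete in one step
  expect_equal(sort(lo$areas)[1], m$area, tolerance = 1e-12)
  expect_equal(lo$percents[1], 100)
  # covered cells identical to the MCP field on the same grid
  grid <- reference_grid(xy, grain = 20)
  f_lo <- locoh_k(xy, k = nrow(xy), grid = grid)$field
  f_m <- estimate_field(hr_trajectory("a", seq_len(nrow(xy)) * 60,
                                      xy[, 1], xy[, 2]), "mcp", grid = grid)
  expect_equal(is.finite(f_lo$score), is.finite(f_m$score))
})

test_that("LoCoH defaults k to the square root of n and orders its unions", {
  set.seed(13)
  xy <- matrix(rnorm(200, sd = 500), 100, 2)
  lo <- locoh_k(xy)
  expect_equal(lo$field$params$k, 10L)
  expect_true(all(diff(lo$percents) >= 0))
  expect_equal(lo$percents[length(lo$percents)], 100)
  expect_true(all(diff(lo$areas) >= 0))
  expect_error(locoh_k(xy, k = 2), "k must be >= 3")
  expect_error(locoh_k(xy, k = 101), "k must be <= n")
})

test_that("LoCoH hull-union coverage matches exact inclusion-exclusion areas", {
  # crafted 5-point set, k = 3: every 3-NN hull enumerated by the oracle
  xy <- cbind(c(0, 100, 60, 10, 90), c(0, 10, 90, 70, 80))
  grid <- reference_grid(xy, grain = 1, buffer = 2)
  lo <- locoh_k(xy, k = 3, grid = grid)
  hull_oracle <- lapply(1:5, function(i) {
    d <- colSums((t(xy) - xy[i, ])^2)
    idx <- order(d)[1:3]
    giftwrap_hull(xy[idx, , drop = FALSE])
  })
  exact <- union_area_incl_excl(hull_oracle)
  grid_area <- sum(is.finite(lo$field$score)) * grid$grain^2
  expect_lt(abs(grid_area / exact - 1), 0.05)   # fine-grain rasterization
  # and per-hull areas agree exactly with the oracle's hull areas
  expect_equal(sort(lo$areas), sort(vapply(hull_oracle, shoelace, 1)),
               tolerance = 1e-12)
})

test_that("SLCA seeds on the tightest triad and matches a step-by-step oracle", {
  tri <- cbind(c(0, 3, 1.5), c(0, 0, 2))
  s <- slca(tri, grid = reference_grid(tri, grain = 0.2, buffer = 0.5))
  expect_setequal(s$order, 1:3)
  expect_equal(s$percents, rep(100, 3))

  # two well-separated triads: the tighter one is exhausted first
  tight <- cbind(c(0, 1, 0.5), c(0, 0, 0.8))
  loose <- cbind(c(100, 104, 102), c(100, 100, 103))
  xy <- rbind(loose, tight)    # tighter triad listed second on purpose
  s2 <- slca(xy, grid = reference_grid(xy, grain = 5))
  expect_setequal(s2$order[1:3], 4:6)
  expect_setequal(s2$order, 1:6)

  # crafted 8-point and random sets: full assignment order equals the
  # from-scratch recomputation of the same step rule
  xy8 <- cbind(c(0, 1, 0.5, 10, 11, 10.5, 5, 5.2),
               c(0, 0, 0.9, 0, 0, 0.9, 5, 5.3))
  s8 <- slca(xy8, grid = reference_grid(xy8, grain = 1))
  expect_equal(s8$order, slca_oracle_order(xy8))
  for (seed in 1:4) {
    set.seed(seed)
    xy_r <- matrix(runif(60, 0, 1000), 30, 2)
    s_r <- slca(xy_r, grid = reference_grid(xy_r, grain = 50))
    expect_equal(s_r$order, slca_oracle_order(xy_r))
  }
  expect_error(slca(tri[1:2, ]), "at least 3")
})

test_that("characteristic hull orders Delaunay triangles and tends to the MCP", {
  tri <- cbind(c(0, 3, 1.5), c(0, 0, 2))
  ch <- char_hull(tri)
  expect_equal(nrow(ch$triangles), 1)
  expect_equal(ch$total_area, mcp(tri)$area, tolerance = 1e-12)

  sq <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))
  ch_sq <- char_hull(sq)
  expect_equal(nrow(ch_sq$triangles), 2)
  expect_equal(ch_sq$total_area, 1.0, tolerance = 1e-12)
  expect_equal(ch_sq$percents[nrow(ch_sq$triangles)], 100)

  expect_error(char_hull(cbind(0:5, 0:5)), "collinear")

  set.seed(14)
  for (i in 1:5) {
    xy <- matrix(rnorm(2 * (20 + 10 * i), sd = 400), ncol = 2)
    ch_r <- char_hull(xy)
    expect_lt(abs(ch_r$total_area / mcp(xy)$area - 1), 1e-9)
    expect_true(all(diff(ch_r$areas) >= 0))
    expect_true(all(diff(ch_r$percents) >= 0))
  }
})

test_that("duplicate relocations are tolerated by the hull estimators", {
  set.seed(15)
  base <- matrix(rnorm(40, sd = 200), 20, 2)
  xy <- rbind(base, base[1:8, ])   # 40% duplicated rows
  lo <- locoh_k(xy, k = 4)
  expect_equal(lo$percents[length(lo$percents)], 100)
  expect_equal(lo$areas[1], 0)     # duplicate-degenerate hulls sort first
  ch <- char_hull(xy)
  expect_lt(abs(ch$total_area / mcp(xy)$area - 1), 1e-9)
  expect_equal(ch$percents[nrow(ch$triangles)], 100)
})
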