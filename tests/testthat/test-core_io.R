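test_that("trajectories round-trip through delimited text, sorted per animal", {
  f <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(animal_id = c("a", "a", "a"),
                   timestamp = c(7200, 0, 3600),
                   x = c(3e5, 1e5, 2e5), y = c(3e5, 1e5, 2e5), err_sd = 34)
  write.csv(df, f, row.names = FALSE)
  tr <- read_trajectories(f)
  expect_length(tr, 1)
  expect_equal(length(tr$a), 3)
  expect_equal(tr$a$x, c(1e5, 2e5, 3e5))   # sorted by time

  df2 <- data.frame(animal_id = c("a", "b", "a", "b"),
                    timestamp = c(0, 0, 3600, 3600),
                    x = 1:4 * 1e5, y = 1:4 * 1e5)
  write.csv(df2, f, row.names = FALSE)
  tr2 <- read_trajectories(f, columns = c(animal_id = "animal_id",
                                          timestamp = "timestamp",
                                          x = "x", y = "y"))
  expect_named(tr2, c("a", "b"))
  expect_equal(tr2$b$x, c(2e5, 4e5))
})

test_that("geographic-looking coordinates and duplicate timestamps are flagged", {
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(animal_id = "a", timestamp = c(0, 3600),
                       x = c(-81.4, -81.5), y = c(26.1, 26.2)),
            f, row.names = FALSE)
  expect_warning(read_trajectories(f), "projected CRS")

  write.csv(data.frame(animal_id = "a", timestamp = c(0, 0),
                       x = c(1e5, 2e5), y = c(1e5, 2e5)),
            f, row.names = FALSE)
  expect_error(suppressWarnings(read_trajectories(f)), "duplicate timestamp.*'a'")
})

test_that("annual filter keeps years with strictly more than the threshold", {
  t2009 <- as.numeric(as.POSIXct("2009-03-01", tz = "UTC")) +
    3600 * seq_len(51)
  tr <- hr_trajectory("a", t2009, seq_along(t2009), seq_along(t2009))
  expect_length(filter_min_annual(tr), 1)          # 51 > 50: retained

  tr50 <- hr_trajectory("a", t2009[1:50], 1:50, 1:50)
  expect_length(filter_min_annual(tr50), 0)        # exactly 50: dropped

  # 60 fixes in 2009, 40 in 2010: only the first year survives
  t2009b <- as.numeric(as.POSIXct("2009-03-01", tz = "UTC")) +
    3600 * seq_len(60)
  t2010 <- as.numeric(as.POSIXct("2010-03-01", tz = "UTC")) +
    3600 * seq_len(40)
  tr2 <- hr_trajectory("a", c(t2009b, t2010), 1:100, 1:100)
  out <- filter_min_annual(tr2)
  expect_length(out, 1)
  expect_equal(attr(out[[1]], "year"), 2009L)
  expect_equal(length(out[[1]]), 60)

  empty <- hr_trajectory("a", 0, 0, 0)
  expect_length(filter_min_annual(empty), 0)
})

test_that("reference grid snaps its origin and covers the buffered extent", {
  # 1050 m span, zero buffer: 11 columns of 100 m
  g <- reference_grid(cbind(c(0, 1050), c(0, 100)), grain = 100, buffer = 0)
  expect_equal(g$ncols, 11L)
  # single fix at (500, 500) with 300 m buffer: origin snapped to 200, 6 cols
  g2 <- reference_grid(cbind(500, 500), grain = 100, buffer = 300)
  expect_equal(g2$x0, 200)
  expect_equal(g2$ncols, 6L)
  # single point, no buffer: a legal 1x1 grid
  g3 <- reference_grid(cbind(550, 550), grain = 100, buffer = 0)
  expect_equal(c(g3$ncols, g3$nrows), c(1L, 1L))
  # default grain is the 100 m reference grain
  expect_equal(reference_grid(cbind(c(0, 500), c(0, 500)))$grain, 100)
})

test_that("half-open cells partition the extent", {
  g <- reference_grid(cbind(c(0, 499), c(0, 299)), grain = 100, buffer = 0)
  expect_equal(point_to_cell(g, g$x0, g$y0), cbind(row = 0L, col = 0L))
  expect_equal(unname(point_to_cell(g, g$x0 + 100, g$y0)[, "col"]), 1L)
  expect_true(all(is.na(point_to_cell(g, g$x0 - 1, g$y0))))
  # max edge belongs to the last cell
  expect_equal(unname(point_to_cell(g, g$x0 + g$ncols * 100, g$y0)[, "col"]),
               g$ncols - 1L)
  # partition: each random in-extent point lands in exactly the cell whose
  # half-open bounds contain it
  set.seed(42)
  px <- runif(500, g$x0, g$x0 + g$ncols * 100)
  py <- runif(500, g$y0, g$y0 + g$nrows * 100)
  rc <- point_to_cell(g, px, py)
  expect_false(anyNA(rc))
  expect_true(all(px >= g$x0 + rc[, "col"] * 100 &
                  px < g$x0 + (rc[, "col"] + 1) * 100))
  expect_true(all(py >= g$y0 + rc[, "row"] * 100 &
                  py < g$y0 + (rc[, "row"] + 1) * 100))
})

test_that("normalization to a UD divides by the total mass", {
  g <- reference_grid(cbind(c(0, 199), c(0, 99)), grain = 100, buffer = 0)
  ud <- normalize_to_ud(cell_field(g, matrix(c(2, 2), 1, 2)))
  expect_equal(as.vector(ud$score), c(0.5, 0.5))
  u2 <- normalize_to_ud(cell_field(g, matrix(c(0.7, 0.3), 1, 2)))
  expect_equal(as.vector(u2$score), c(0.7, 0.3))
  set.seed(1)
  u3 <- random_ud(1)
  expect_equal(sum(u3$score), 1, tolerance = 1e-12)
  expect_error(normalize_to_ud(cell_field(g, matrix(0, 1, 2))), "all-zero")
})

test_that("volume-contour levels accumulate sorted mass with grouped ties", {
  g <- reference_grid(cbind(c(0, 299), c(0, 99)), grain = 100, buffer = 0)
  ud <- normalize_to_ud(cell_field(g, matrix(c(0.5, 0.3, 0.2), 1, 3)))
  expect_equal(sort(as.vector(volume_contour_levels(ud)$score)),
               c(50, 80, 100))
  g1 <- reference_grid(cbind(50, 50), grain = 100, buffer = 0)
  u1 <- normalize_to_ud(cell_field(g1, matrix(1)))
  expect_equal(as.vector(volume_contour_levels(u1)$score), 100)
  g4 <- reference_grid(cbind(c(0, 399), c(0, 99)), grain = 100, buffer = 0)
  u4 <- normalize_to_ud(cell_field(g4, matrix(0.25, 1, 4)))
  expect_equal(as.vector(volume_contour_levels(u4)$score), rep(100, 4))
})

test_that("volume-contour levels are permutation- and scale-invariant", {
  set.seed(7)
  for (i in 1:5) {
    m <- matrix(rexp(24), 4, 6)
    g <- reference_grid(cbind(c(0, 599), c(0, 399)), grain = 100, buffer = 0)
    lev <- volume_contour_levels(normalize_to_ud(cell_field(g, m)))$score
    perm <- sample(24)
    mp <- matrix(as.vector(m)[perm], 4, 6)
    levp <- volume_contour_levels(normalize_to_ud(cell_field(g, mp)))$score
    expect_equal(as.vector(levp), as.vector(lev)[perm])
    levs <- volume_contour_levels(normalize_to_ud(cell_field(g, 7 * m)))$score
    expect_equal(levs, lev)
  }
})

test_that("isopleths are nested unions of covered cells", {
  g <- reference_grid(cbind(c(0, 299), c(0, 99)), grain = 100, buffer = 0)
  ud <- normalize_to_ud(cell_field(g, matrix(c(0.5, 0.3, 0.2), 1, 3)))
  iso <- extract_isopleths(ud, c(50, 95, 100))
  expect_equal(iso$areas, c(1, 2, 3) * 100^2)   # 95% level holds 2 cells
  expect_error(extract_isopleths(ud, c(0, 50)), "levels")
  expect_error(extract_isopleths(ud, 101), "levels")
  # nestedness on random UDs, including the all-positive 100% region
  for (s in 1:5) {
    u <- random_ud(s)
    iso <- extract_isopleths(u, c(30, 50, 95, 100))
    for (i in seq_along(iso$levels)[-1])
      expect_true(all(iso$cells[[i]][iso$cells[[i - 1]]]))
    expect_equal(sum(iso$cells[[length(iso$cells)]]), sum(u$score > 0))
  }
})

test_that("raster, GeoJSON and CSV writers round-trip", {
  ud <- random_ud(3)
  f <- withr::local_tempfile(fileext = ".asc")
  write_ascii_grid(ud, f)
  back <- read_ascii_grid(f)
  expect_lt(max(abs(back$score - ud$score)), 1e-9)
  expect_equal(back$grid$ncols, ud$grid$ncols)

  iso <- extract_isopleths(ud, c(50, 95, 100))
  fj <- withr::local_tempfile(fileext = ".geojson")
  write_isopleths_geojson(iso, fj)
  gj <- jsonlite::read_json(fj)
  expect_equal(length(gj$features), 3)
  expect_equal(gj$features[[1]]$properties$level, 50)

  tab <- data.frame(animal_id = "a", estimator = "bbmm", auc = 0.97)
  fc <- withr::local_tempfile(fileext = ".csv")
  write_table_csv(tab, fc)
  expect_equal(names(read.csv(fc)), c("animal_id", "estimator", "auc"))
})

test_that("hull sequences export with step and percent attributes", {
  set.seed(9)
  xy <- matrix(rnorm(40, sd = 300), 20, 2)
  fh <- withr::local_tempfile(fileext = ".geojson")
  lo <- locoh_k(xy, k = 5)
  write_hulls_geojson(lo, fh)
  gj <- jsonlite::read_json(fh)
  expect_lte(length(gj$features), 20)
  expect_equal(gj$features[[1]]$properties$step, 1)
  expect_equal(gj$features[[1]]$properties$percent, lo$percents[1])
  ch <- char_hull(xy)
  write_hulls_geojson(ch, fh)
  expect_equal(length(jsonlite::read_json(fh)$features), nrow(ch$triangles))
})
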