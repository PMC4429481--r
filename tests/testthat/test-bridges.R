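test_that("single-bridge variance MLE matches the closed form", {
  # alpha = 0.5, T = 2 s, delta = 0, deviation d from the midpoint:
  # the likelihood is maximized at sigma2 = d^2 / (2 T alpha (1 - alpha))
  tr <- hr_trajectory("a", c(0, 1, 2), c(0, 3, 0), c(0, 0, 0), err_sd = 0)
  expect_equal(as.numeric(bbmm_fit_variance(tr)), 9 / (2 * 2 * 0.25),
               tolerance = 1e-6)
  # asymmetric alpha = 1/3 (T = 3 s): same stationarity condition
  tr2 <- hr_trajectory("a", c(0, 1, 3), c(0, 0, 0), c(0, 2, 0), err_sd = 0)
  a <- 1 / 3
  expect_equal(as.numeric(bbmm_fit_variance(tr2)),
               4 / (2 * 3 * a * (1 - a)), tolerance = 1e-6)
})

test_that("fixes on the interpolation lines give a zero-boundary variance", {
  n <- 11
  tr <- hr_trajectory("a", (0:(n - 1)) * 10, seq(0, 100, length.out = n),
                      rep(0, n), err_sd = 10)
  expect_warning(s2 <- bbmm_fit_variance(tr), "zero boundary")
  expect_lt(as.numeric(s2), 1e-6)
})

test_that("Brownian-motion variance is recovered from noisy hourly fixes", {
  est <- vapply(1:5, function(s)
    as.numeric(bbmm_fit_variance(sim_bm_track(s))), numeric(1))
  expect_lt(abs(median(est) / 0.25 - 1), 0.25)
})

test_that("bridge UDs are normalized, symmetric and quadrature-stable", {
  g <- reference_grid(cbind(c(-800, 800), c(-500, 500)), grain = 50,
                      buffer = 300)
  seg <- hr_trajectory("a", c(0, 3600), c(-400, 400), c(0, 0), err_sd = 30)
  ud <- bbmm_ud(seg, sigma2_m = 0.3, default_err_sd = 30, grid = g)
  expect_equal(sum(ud$score), 1, tolerance = 1e-6)
  # symmetric about the perpendicular bisector of the segment
  expect_lt(max(abs(ud$score - ud$score[, rev(seq_len(g$ncols))])), 1e-9)

  tr <- sim_bm_track(31, n = 11, err = 20)
  fine <- bbmm_ud(tr, sigma2_m = 0.25, default_err_sd = 20, n_steps = 200)
  tv <- vapply(c(10, 20, 40), function(m) {
    u <- bbmm_ud(tr, sigma2_m = 0.25, default_err_sd = 20,
                 grid = fine$grid, n_steps = m)
    sum(abs(u$score - fine$score)) / 2
  }, numeric(1))
  expect_true(all(diff(tv) < 0))     # refinement converges monotonically
  expect_lt(tv[2], 1e-4)             # 20 steps vs 10x finer quadrature
})

test_that("windowed variances need enough fixes and center on the global fit", {
  tr <- sim_bm_track(32, n = 20)
  expect_error(dbbmm_variances(tr), "use the global BBMM")
  expect_error(dbbmm_variances(sim_bm_track(33, n = 100), window_size = 21,
                               margin = 11), "window_size")
  # homogeneous track: windowed values scatter around the global estimate
  # (each 31-fix window scores ~15 bridges, a ~25% noise floor)
  for (s in 1:3) {
    tr <- sim_bm_track(40 + s, n = 400, err = 0)
    v <- dbbmm_variances(tr)
    g <- as.numeric(bbmm_fit_variance(tr))
    expect_lt(abs(median(v) / g - 1), 0.4)
    expect_gt(mean(abs(v / g - 1) < 0.5), 0.7)
  }
})

test_that("two-phase tracks show the variance jump; constant reduces to BBMM", {
  ok <- vapply(1:5, function(s) {
    v <- dbbmm_variances(sim_two_phase_track(s))
    mean(v[201:400]) > mean(v[1:200])
  }, logical(1))
  expect_true(all(ok))
  # constant variance sequence: dBBMM UD equals the BBMM UD exactly
  tr <- sim_bm_track(34, n = 60)
  g <- reference_grid(tr)
  ub <- bbmm_ud(tr, sigma2_m = 0.25, default_err_sd = 30, grid = g)
  ud <- dbbmm_ud(tr, variances = rep(0.25, 60), default_err_sd = 30, grid = g)
  expect_lt(sum(abs(ub$score - ud$score)) / 2, 1e-9)
  # two-phase: the high-variance phase spreads its conditional mass wider
  tp <- sim_two_phase_track(3)
  vtp <- dbbmm_variances(tp)
  gtp <- reference_grid(tp)
  bridge_spread <- function(idx) {
    sub <- tp; sub$time <- tp$time[idx]; sub$x <- tp$x[idx]
    sub$y <- tp$y[idx]; sub$err_sd <- tp$err_sd[idx]
    ud <- dbbmm_ud(sub, variances = vtp[idx], default_err_sd = 20, grid = gtp)
    # mean bridge SD proxy: mass-weighted spread around the path is wider
    sum(ud$score * ud$score)  # concentration (inverse-spread) proxy
  }
  expect_gt(bridge_spread(1:200), bridge_spread(201:400))
})

test_that("diffusion is estimated by mean squared displacement over 4T", {
  seg <- hr_trajectory("a", c(0, 3600, 7200), c(0, 200, 200), c(0, 0, 1),
                       err_sd = 0)
  d_hat <- estimate_diffusion(seg)
  expect_equal(d_hat, mean(c(200^2 / (4 * 3600), 1 / (4 * 3600))))
  still <- hr_trajectory("a", c(0, 60, 120), c(0, 0, 0), c(0, 0, 0))
  expect_equal(estimate_diffusion(still), 0)
  est <- vapply(1:10, function(s) {
    tr <- sim_bm_track(s, sigma2 = 0.4, n = 1000, err = 0)
    estimate_diffusion(tr)
  }, numeric(1))
  # for 2-D Brownian motion E d^2 = 4 D T with D = sigma2 / 2
  expect_lt(abs(median(est) / 0.2 - 1), 0.2)
})

test_that("biased-random-bridge kernels inflate mid-segment as prescribed", {
  # one segment, tau = T: a single kernel at the midpoint with
  # h^2 = hmin^2 + 2 * 0.5 * 0.5 * D * T = 34^2 + 0.5 * 0.1 * 3600 = 1336
  g <- reference_grid(cbind(c(-600, 600), c(-400, 400)), grain = 50,
                      buffer = 200)
  tr <- hr_trajectory("a", c(0, 3600), c(-200, 200), c(0, 0))
  ud <- mkde_brb_ud(tr, hmin = 34, D = 0.1, tau = 3600, lmin = 10, grid = g)
  h2 <- 34^2 + 0.5 * 0.1 * 3600
  cx <- rangeselect:::grid_centers_x(g)
  cy <- rangeselect:::grid_centers_y(g)
  dens <- outer(dnorm(cy, 0, sqrt(h2)), dnorm(cx, 0, sqrt(h2)))
  expect_lt(max(abs(ud$score - dens / sum(dens))), 1e-12)

  # short segments are stationary: two hmin kernels at the endpoints
  tr2 <- hr_trajectory("a", c(0, 3600), c(-10, 10), c(0, 0))
  ud2 <- mkde_brb_ud(tr2, hmin = 34, D = 0.1, lmin = 50, grid = g)
  dens2 <- outer(dnorm(cy, 0, 34),
                 dnorm(cx, -10, 34) + dnorm(cx, 10, 34))
  expect_lt(max(abs(ud2$score - dens2 / sum(dens2))), 1e-12)
})

test_that("MKDE refuses VHF-like schedules where no segment fits tmax", {
  # 3 fixes/week: every gap is ~2 days >> 12 h
  tt <- c(0, 2, 4, 7, 9, 11, 14) * 86400
  tr <- hr_trajectory("v", tt, rnorm(7, sd = 500), rnorm(7, sd = 500),
                      err_sd = 124, schedule_class = "vhf",
                      technology = "VHF")
  expect_error(mkde_brb_ud(tr), "not estimable.*VHF")
})
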