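## per-fix squared location-error, falling back to a default
fix_err2 <- function(traj, default_err_sd) {
  e <- traj$err_sd
  e[!is.finite(e)] <- default_err_sd
  e^2
}

## leave-one-out bridge statistics: fixes at even 1-based positions are
## scored against the bridge through their (odd-position) neighbours
bridge_stats <- function(traj, default_err_sd) {
  n <- length(traj$time)
  if (n < 3) stop("need at least 3 fixes")
  e2 <- fix_err2(traj, default_err_sd)
  ev <- seq(2, n - 1, by = 2)
  T <- traj$time[ev + 1] - traj$time[ev - 1]
  a <- (traj$time[ev] - traj$time[ev - 1]) / T
  mx <- traj$x[ev - 1] + a * (traj$x[ev + 1] - traj$x[ev - 1])
  my <- traj$y[ev - 1] + a * (traj$y[ev + 1] - traj$y[ev - 1])
  list(T = T, a = a,
       d2 = (traj$x[ev] - mx)^2 + (traj$y[ev] - my)^2,
       c = e2[ev] + (1 - a)^2 * e2[ev - 1] + a^2 * e2[ev + 1])
}

#' Fit the Brownian-motion variance of a Brownian bridge movement model
#'
#' Maximizes the leave-one-out likelihood: odd-indexed fixes define bridges
#' and each even-indexed fix at relative time `alpha` in its bracketing gap
#' `T` is scored under a bivariate normal centered on the linear
#' interpolation with per-axis variance
#' `T alpha (1-alpha) sigma2_m + delta_e^2 + (1-alpha)^2 delta1^2 +
#' alpha^2 delta2^2` -- the bridge variance plus the location error of the
#' scored fix itself and the interpolation-weighted errors of its
#' bracketing fixes (all fixes are observed with error, so omitting the
#' scored fix's error would inflate `sigma2_m` by `delta^2 / (T alpha
#' (1-alpha))`).
#'
#' @param traj An [hr_trajectory] with at least 3 fixes.
#' @param default_err_sd Location-error SD (m) used where a fix lacks
#'   `err_sd`.
#' @return The fitted `sigma2_m` in m^2/s (scalar, with the number of scored
#'   bridges as attribute `n_bridges`).
#' @export
bbmm_fit_variance <- function(traj, default_err_sd = 0) {
  st <- bridge_stats(traj, default_err_sd)
  ok <- st$T > 0
  if (!any(ok)) stop("no bridges with positive duration")
  hi <- 4 * max(st$d2[ok] / (2 * st$T[ok] * st$a[ok] * (1 - st$a[ok])),
                1e-12)
  e2 <- fix_err2(traj, default_err_sd)
  fit <- cpp_bbmm_mle(traj$time, traj$x, traj$y, e2, hi)
  s2 <- fit$sigma2
  if (s2 <= max(hi * 1e-8, 1e-8))
    warning("Brownian-motion variance estimated at the zero boundary ",
            "(fixes fall on the interpolation lines)")
  structure(s2, n_bridges = fit$n_bridges)
}

## shared bridge rasterizer: per segment, average the bridge density over
## n_steps interior alpha values (midpoint rule), weight by duration
bridge_accumulate <- function(traj, seg_sigma2, default_err_sd, grid,
                              n_steps) {
  n <- length(traj$time)
  e2 <- fix_err2(traj, default_err_sd)
  T <- diff(traj$time)
  keep <- T > 0
  if (!all(keep)) warning(sum(!keep), " zero-duration segment(s) skipped")
  segs <- which(keep)
  if (!length(segs)) stop("no usable segments")
  al <- (seq_len(n_steps) - 0.5) / n_steps
  i <- rep(segs, each = n_steps)
  a <- rep(al, times = length(segs))
  px <- traj$x[i] + a * (traj$x[i + 1] - traj$x[i])
  py <- traj$y[i] + a * (traj$y[i + 1] - traj$y[i])
  v <- T[i] * a * (1 - a) * seg_sigma2[i] +
    (1 - a)^2 * e2[i] + a^2 * e2[i + 1]
  v <- pmax(v, 1e-9)
  w <- T[i] / n_steps
  dens <- cpp_accumulate_gaussian(grid$x0, grid$y0, grid$grain,
                                  grid$nrows, grid$ncols,
                                  px, py, v, v, rep(0, length(v)), w)
  dens
}

#' Brownian bridge movement model utilization distribution
#'
#' @param traj An [hr_trajectory].
#' @param sigma2_m Brownian-motion variance in m^2/s; fitted with
#'   [bbmm_fit_variance()] when `NULL`.
#' @param default_err_sd Location-error SD (m) where a fix lacks one.
#' @param grid A [reference_grid()]; built with defaults when `NULL`.
#' @param n_steps Integration steps per segment (default 10, minimum 5).
#' @return An `hr_ud`.
#' @export
bbmm_ud <- function(traj, sigma2_m = NULL, default_err_sd = 0, grid = NULL,
                    n_steps = 10) {
  stopifnot(n_steps >= 5)
  if (is.null(grid)) grid <- reference_grid(traj)
  if (is.null(sigma2_m)) sigma2_m <- bbmm_fit_variance(traj, default_err_sd)
  n <- length(traj$time)
  dens <- bridge_accumulate(traj, rep(as.numeric(sigma2_m), n - 1),
                            default_err_sd, grid, n_steps)
  normalize_to_ud(cell_field(grid, dens * grid$grain^2, estimator = "bbmm",
                             params = list(sigma2_m = as.numeric(sigma2_m),
                                           default_err_sd = default_err_sd,
                                           n_steps = n_steps)))
}

#' Windowed Brownian-motion variances for the dynamic BBMM
#'
#' Slides a window of `window_size` fixes along the path; within each window
#' a single-variance model competes by BIC against two-variance models split
#' at every interior breakpoint at least `margin` fixes from the window
#' edges (each variance is the leave-one-out bridge MLE on its sub-track).
#' Every fix is assigned the average of the selected-model variances over all
#' windows covering it; the first and last `margin` fixes inherit the nearest
#' interior value.
#'
#' @param traj An [hr_trajectory] with at least `window_size` fixes.
#' @param window_size Odd window length in fixes (default 31).
#' @param margin Minimum distance of a breakpoint from the window edge
#'   (default 11); requires `window_size >= 2 * margin + 3`.
#' @param default_err_sd Location-error SD (m) where a fix lacks one.
#' @return Numeric vector of per-fix `sigma2_m` (m^2/s).
#' @export
dbbmm_variances <- function(traj, window_size = 31, margin = 11,
                            default_err_sd = 0) {
  stopifnot(margin >= 3, window_size >= 2 * margin + 3)
  n <- length(traj$time)
  if (n < window_size)
    stop("fewer fixes (", n, ") than the window (", window_size,
         "); use the global BBMM instead")
  st <- bridge_stats(traj, default_err_sd)
  ok <- st$T > 0
  hi <- 4 * max(st$d2[ok] / (2 * st$T[ok] * st$a[ok] * (1 - st$a[ok])),
                1e-12)
  e2 <- fix_err2(traj, default_err_sd)
  cpp_dbbmm_variances(traj$time, traj$x, traj$y, e2,
                      as.integer(window_size), as.integer(margin), hi)
}

#' Dynamic Brownian bridge movement model utilization distribution
#'
#' As [bbmm_ud()], but each segment uses the mean of its two endpoint
#' per-fix variances. With a constant variance sequence this reduces exactly
#' to the global BBMM surface.
#'
#' @param traj An [hr_trajectory].
#' @param variances Per-fix variance vector from [dbbmm_variances()]; fitted
#'   with defaults when `NULL`.
#' @param default_err_sd,grid,n_steps As in [bbmm_ud()].
#' @return An `hr_ud`.
#' @export
dbbmm_ud <- function(traj, variances = NULL, default_err_sd = 0,
                     grid = NULL, n_steps = 10) {
  stopifnot(n_steps >= 5)
  if (is.null(grid)) grid <- reference_grid(traj)
  if (is.null(variances)) variances <- dbbmm_variances(traj,
                                                       default_err_sd = default_err_sd)
  n <- length(traj$time)
  stopifnot(length(variances) == n)
  seg_s2 <- (variances[-n] + variances[-1]) / 2
  dens <- bridge_accumulate(traj, seg_s2, default_err_sd, grid, n_steps)
  normalize_to_ud(cell_field(grid, dens * grid$grain^2, estimator = "dbbmm",
                             params = list(default_err_sd = default_err_sd,
                                           n_steps = n_steps)))
}

#' Method-of-moments diffusion coefficient
#'
#' For pure Brownian motion the expected squared displacement over a gap T is
#' `4 D T`, so `D` is estimated as the mean over segments of `d^2 / (4 T)`.
#'
#' @param traj An [hr_trajectory] with at least 3 fixes.
#' @return Estimated diffusion `D` in m^2/s.
#' @export
estimate_diffusion <- function(traj) {
  n <- length(traj$time)
  if (n < 3) stop("need at least 3 fixes")
  T <- diff(traj$time)
  d2 <- diff(traj$x)^2 + diff(traj$y)^2
  ok <- T > 0
  mean(d2[ok] / (4 * T[ok]))
}

#' Movement-based kernel density estimator (biased random bridges)
#'
#' Interpolates each segment every `tau` seconds and places a normal kernel
#' at each interpolated point whose squared bandwidth inflates away from the
#' fixes in a bridge shape: `h^2(p) = hmin^2 + 2 p (1-p) D T` at relative
#' time `p` in a segment of duration `T`. Segments longer than `tmax` are
#' skipped (with a count reported); segments shorter than `lmin` are treated
#' as stationary, contributing kernels of SD `hmin` at both endpoints.
#' Sparse schedules in which *no* segment is shorter than `tmax` (typical of
#' VHF flight data) are not estimable and raise an error.
#'
#' @param traj An [hr_trajectory].
#' @param hmin Minimum kernel SD in meters (default 34, the GPS error scale).
#' @param D Diffusion coefficient in m^2/s; estimated with
#'   [estimate_diffusion()] when `NULL`.
#' @param tmax Maximum usable segment duration in seconds (default 12 h).
#' @param lmin Minimum segment length in meters below which the segment is
#'   treated as stationary (default 50).
#' @param tau Interpolation step in seconds (default 300).
#' @param grid A [reference_grid()]; built with defaults when `NULL`.
#' @return An `hr_ud` (attribute `n_skipped` counts dropped segments).
#' @export
mkde_brb_ud <- function(traj, hmin = 34, D = NULL, tmax = 12 * 3600,
                        lmin = 50, tau = 300, grid = NULL) {
  stopifnot(hmin > 0, tmax > 0, lmin >= 0, tau > 0)
  if (is.null(grid)) grid <- reference_grid(traj)
  n <- length(traj$time)
  if (n < 2) stop("need at least 2 fixes")
  T <- diff(traj$time)
  len <- sqrt(diff(traj$x)^2 + diff(traj$y)^2)
  usable <- T > 0 & T <= tmax
  n_skipped <- sum(!usable)
  if (!any(usable))
    stop("no segment has duration <= tmax (", tmax, " s): the movement-based ",
         "kernel density estimator is not estimable for this sparse ",
         "(VHF-like) collection schedule")
  if (is.null(D)) D <- estimate_diffusion(traj)
  parts <- lapply(which(usable), function(i) {
    if (len[i] < lmin) {
      cbind(px = c(traj$x[i], traj$x[i + 1]),
            py = c(traj$y[i], traj$y[i + 1]),
            h2 = hmin^2, w = T[i] / 2)
    } else {
      m <- max(1L, round(T[i] / tau))
      p <- (seq_len(m) - 0.5) / m
      cbind(px = traj$x[i] + p * (traj$x[i + 1] - traj$x[i]),
            py = traj$y[i] + p * (traj$y[i + 1] - traj$y[i]),
            h2 = hmin^2 + 2 * p * (1 - p) * D * T[i],
            w = T[i] / m)
    }
  })
  ev <- do.call(rbind, parts)
  px <- ev[, "px"]; py <- ev[, "py"]; h2 <- ev[, "h2"]; w <- ev[, "w"]
  dens <- cpp_accumulate_gaussian(grid$x0, grid$y0, grid$grain,
                                  grid$nrows, grid$ncols,
                                  px, py, h2, h2, rep(0, length(h2)), w)
  ud <- normalize_to_ud(cell_field(grid, dens * grid$grain^2,
                                   estimator = "mkde",
                                   params = list(hmin = hmin, D = D,
                                                 tmax = tmax, lmin = lmin,
                                                 tau = tau)))
  attr(ud, "n_skipped") <- n_skipped
  ud
}
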