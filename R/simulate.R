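#' Ornstein-Uhlenbeck movement parameters
#'
#' The simulator's stand-in for home-ranging movement is a mean-reverting
#' (Ornstein-Uhlenbeck) process per coordinate: stationary, centered on a
#' range center, with long-run standard deviation `sigma / sqrt(2 * beta)`.
#' Defaults emulate a large terrestrial carnivore: a stationary SD of 3 km
#' (a home range spanning roughly 10-15 km) and a reversion time scale of
#' one day, which gives hourly displacements of several hundred meters and
#' daily travel around 15 km -- fast sub-daily movement within a range that
#' is revisited on the daily scale. (A much shorter reversion scale would
#' make the animal cross its whole range between hourly fixes, i.e. move
#' implausibly fast for a terrestrial mammal.)
#'
#' @param center Numeric length-2: range-center coordinates in meters.
#' @param beta Reversion rate in 1/s (default `1 / 86400`).
#' @param sigma Noise intensity in m/sqrt(s) (default chosen so the
#'   stationary SD is 3000 m).
#' @param duration_days Span of the simulated path in days (default 365).
#' @param start Start time in seconds since epoch (default 2010-01-04
#'   00:00 UTC, a Monday, so VHF flight weekdays are well defined).
#' @return A list of class `ou_params`.
#' @export
ou_params <- function(center = c(0, 0), beta = 1 / 86400,
                      sigma = 3000 * sqrt(2 / 86400),
                      duration_days = 365,
                      start = 1262563200) {
  stopifnot(beta > 0, sigma > 0, duration_days > 0)
  structure(list(center = center, beta = beta, sigma = sigma,
                 duration_days = duration_days, start = start),
            class = "ou_params")
}

## one exact OU increment block: vectorized over a time grid
ou_axis <- function(n_steps, dt, mu, beta, sigma, x0) {
  rho <- exp(-beta * dt)
  sd_step <- sqrt(sigma^2 / (2 * beta) * (1 - rho^2))
  eps <- stats::rnorm(n_steps, 0, sd_step)
  x <- numeric(n_steps + 1)
  x[1] <- x0
  for (i in seq_len(n_steps)) x[i + 1] <- mu + rho * (x[i] - mu) + eps[i]
  x
}

#' Simulate a home-ranging movement path
#'
#' Uses the exact OU transition
#' `X_{t+dt} = mu + e^(-beta dt) (X_t - mu) + N(0, sigma^2/(2 beta) (1 - e^(-2 beta dt)))`
#' per axis, starting from the stationary distribution.
#'
#' @param params An [ou_params()] object.
#' @param dt Simulation step in seconds (default 60).
#' @param seed Integer seed (optional; the current RNG state is used when
#'   `NULL`).
#' @return A list of class `hr_path` with `time`, `x`, `y`, `params`.
#' @export
simulate_ou <- function(params, dt = 60, seed = NULL) {
  stopifnot(inherits(params, "ou_params"), dt > 0)
  if (!is.null(seed)) set.seed(seed)
  n_steps <- ceiling(params$duration_days * 86400 / dt)
  sd_stat <- params$sigma / sqrt(2 * params$beta)
  x0 <- stats::rnorm(1, params$center[1], sd_stat)
  y0 <- stats::rnorm(1, params$center[2], sd_stat)
  x <- ou_axis(n_steps, dt, params$center[1], params$beta, params$sigma, x0)
  y <- ou_axis(n_steps, dt, params$center[2], params$beta, params$sigma, y0)
  structure(list(time = params$start + dt * (0:n_steps), x = x, y = y,
                 dt = dt, params = params),
            class = "hr_path")
}

#' Simulate a two-state movement path
#'
#' Concatenates two OU regimes with a parameter switch at `switch_time`
#' seconds after the start; the path is continuous at the switch. Used as the
#' fixture for windowed-variance (dBBMM) behavior-change tests.
#'
#' @param params_a,params_b [ou_params()] for the first and second regime;
#'   the total duration comes from `params_a`.
#' @param switch_time Seconds after the start at which the regime changes;
#'   must lie inside the duration.
#' @param dt Simulation step in seconds.
#' @param seed Integer seed (optional).
#' @return An `hr_path`.
#' @export
simulate_two_state <- function(params_a, params_b, switch_time, dt = 60,
                               seed = NULL) {
  stopifnot(inherits(params_a, "ou_params"), inherits(params_b, "ou_params"))
  total <- params_a$duration_days * 86400
  if (switch_time <= 0 || switch_time >= total)
    stop("switch_time must lie strictly inside the path duration")
  if (!is.null(seed)) set.seed(seed)
  n1 <- floor(switch_time / dt)
  n_all <- ceiling(total / dt)
  n2 <- n_all - n1
  sd_stat <- params_a$sigma / sqrt(2 * params_a$beta)
  x0 <- stats::rnorm(1, params_a$center[1], sd_stat)
  y0 <- stats::rnorm(1, params_a$center[2], sd_stat)
  # draw all x innovations before the y innovations so that, with identical
  # regimes, the path is bit-identical to simulate_ou under the same seed
  xa <- ou_axis(n1, dt, params_a$center[1], params_a$beta, params_a$sigma, x0)
  xb <- ou_axis(n2, dt, params_b$center[1], params_b$beta, params_b$sigma,
                xa[n1 + 1])
  ya <- ou_axis(n1, dt, params_a$center[2], params_a$beta, params_a$sigma, y0)
  yb <- ou_axis(n2, dt, params_b$center[2], params_b$beta, params_b$sigma,
                ya[n1 + 1])
  structure(list(time = params_a$start + dt * (0:n_all),
                 x = c(xa, xb[-1]), y = c(ya, yb[-1]),
                 dt = dt, params = list(a = params_a, b = params_b,
                                        switch_time = switch_time)),
            class = "hr_path")
}

## nearest path sample at requested times
path_at <- function(path, times) {
  i <- round((times - path$time[1]) / path$dt) + 1
  i <- pmin(pmax(i, 1), length(path$time))
  list(x = path$x[i], y = path$y[i])
}

#' Observe a path under a GPS duty cycle
#'
#' Samples the path at the collar schedule (`hourly` = 3600 s, `four` =
#' 14400 s, `seven` = 25200 s between attempts), drops each attempt
#' independently with probability `1 - fix_success`, and adds independent
#' `N(0, err_sd^2)` location error per axis. The realized fix-success
#' proportion is recorded on the trajectory.
#'
#' @param path An `hr_path`.
#' @param schedule_class `"hourly"`, `"four"` or `"seven"`.
#' @param fix_success Probability each scheduled attempt yields a fix
#'   (default 0.74, the overall GPS success rate emulated here).
#' @param err_sd GPS location-error SD in meters (default 34).
#' @param animal_id Identifier for the resulting trajectory.
#' @param seed Integer seed (optional).
#' @return An [hr_trajectory] with `technology = "GPS"`.
#' @export
observe_gps <- function(path, schedule_class = c("hourly", "four", "seven"),
                        fix_success = 0.74, err_sd = 34,
                        animal_id = "sim", seed = NULL) {
  schedule_class <- match.arg(schedule_class)
  stopifnot(fix_success > 0, fix_success <= 1, err_sd >= 0)
  if (!is.null(seed)) set.seed(seed)
  step <- c(hourly = 3600, four = 14400, seven = 25200)[[schedule_class]]
  t0 <- path$time[1]
  tmax <- path$time[length(path$time)]
  attempts <- seq(t0, tmax, by = step)
  keep <- stats::runif(length(attempts)) < fix_success
  if (!any(keep)) stop("no fixes survived the fix-success dropout")
  tt <- attempts[keep]
  p <- path_at(path, tt)
  hr_trajectory(animal_id, tt,
                p$x + stats::rnorm(length(tt), 0, err_sd),
                p$y + stats::rnorm(length(tt), 0, err_sd),
                err_sd = err_sd, schedule_class = schedule_class,
                technology = "GPS",
                fix_success = mean(keep))
}

#' Observe a path under a VHF flight schedule
#'
#' At most one location per Monday, Wednesday and Friday, at a uniformly
#' random time in the 0700-1100 UTC flight window, with `N(0, err_sd^2)`
#' error per axis. Each scheduled flight locates the animal with probability
#' `p_flight` (cancelled flights, failure to home in on the beacon); the
#' default 0.67 puts a year of monitoring at roughly 105 locations, the
#' regime typical of aerial VHF tracking of large carnivores.
#'
#' @param path An `hr_path` spanning at least one week.
#' @param err_sd VHF location-error SD in meters (default 124).
#' @param p_flight Probability a scheduled flight yields a location
#'   (default 0.67).
#' @param animal_id Identifier for the resulting trajectory.
#' @param seed Integer seed (optional).
#' @return An [hr_trajectory] with `technology = "VHF"`, schedule `"vhf"`.
#' @export
vhf_subsample <- function(path, err_sd = 124, p_flight = 0.67,
                          animal_id = "sim", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(p_flight > 0, p_flight <= 1)
  t0 <- path$time[1]
  tmax <- path$time[length(path$time)]
  if (tmax - t0 < 7 * 86400) stop("path must span at least one week")
  day0 <- floor(t0 / 86400) * 86400
  days <- seq(day0, tmax, by = 86400)
  wd <- as.integer(format(as.POSIXct(days, origin = "1970-01-01", tz = "UTC"),
                          "%u"))
  flight_days <- days[wd %in% c(1L, 3L, 5L)]
  located <- stats::runif(length(flight_days)) < p_flight
  tt <- flight_days[located] +
    (7 + 4 * stats::runif(sum(located))) * 3600
  tt <- tt[tt >= t0 & tt <= tmax]
  if (!length(tt)) stop("no flight-window times fall inside the path span")
  p <- path_at(path, tt)
  hr_trajectory(animal_id, tt,
                p$x + stats::rnorm(length(tt), 0, err_sd),
                p$y + stats::rnorm(length(tt), 0, err_sd),
                err_sd = err_sd, schedule_class = "vhf",
                technology = "VHF", fix_success = mean(located))
}

#' Simulate a benchmark cohort of animals observed by GPS and VHF
#'
#' Each animal follows an independent OU path and is observed under both a
#' GPS duty cycle and the VHF flight schedule, so the full estimator
#' comparison can run end to end with known truth. Per-animal seeds are
#' derived deterministically from the master seed; changing only the error
#' SDs leaves movement and timestamps unchanged.
#'
#' @param n_animals Number of animals (default 10).
#' @param days Path span in days (default 365; a full year reproduces the
#'   ~105 VHF locations/year regime).
#' @param schedule_class GPS duty cycle (default `"hourly"`).
#' @param fix_success GPS fix success (default 0.74).
#' @param gps_err,vhf_err Location-error SDs in meters (defaults 34 and 124).
#' @param beta,sd_stationary OU reversion rate (1/s) and stationary SD (m).
#' @param seed Master seed (default 1).
#' @return A list of class `hr_cohort`: one element per animal with `gps`,
#'   `vhf` trajectories and `truth` (the OU parameters used).
#' @export
make_benchmark_cohort <- function(n_animals = 10, days = 365,
                                  schedule_class = "hourly",
                                  fix_success = 0.74,
                                  gps_err = 34, vhf_err = 124,
                                  beta = 1 / 86400,
                                  sd_stationary = 3000,
                                  seed = 1) {
  areas <- c("south", "north")
  out <- lapply(seq_len(n_animals), function(i) {
    sd_i <- (seed * 1009 + i * 7919) %% 2147483647
    prm <- ou_params(center = c(0, 0), beta = beta,
                     sigma = sd_stationary * sqrt(2 * beta),
                     duration_days = days)
    path <- simulate_ou(prm, dt = 60, seed = sd_i)
    gps <- observe_gps(path, schedule_class, fix_success, gps_err,
                       animal_id = sprintf("A%02d", i), seed = sd_i + 1)
    vhf <- vhf_subsample(path, vhf_err, animal_id = sprintf("A%02d", i),
                         seed = sd_i + 2)
    gps$study_area <- vhf$study_area <- areas[(i %% 2) + 1]
    list(gps = gps, vhf = vhf, truth = prm, seed = sd_i)
  })
  names(out) <- sprintf("A%02d", seq_len(n_animals))
  structure(out, class = "hr_cohort")
}

#' @export
print.hr_cohort <- function(x, ...) {
  cat(sprintf("<hr_cohort> %d animals, GPS + VHF trajectories\n", length(x)))
  invisible(x)
}
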