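#' Fit a home-range estimator to a trajectory
#'
#' The modelling front end of the package: fits one of the suite's
#' estimators on the animal's reference grid and returns a classed object
#' bundling the score field / utilization distribution, the isopleths, and
#' the AUC goodness of fit, with the usual methods (`print`, `summary`,
#' `plot`, `area`).
#'
#' @param traj An [hr_trajectory].
#' @param estimator Estimator tag (see [estimate_field()]).
#' @param grain,buffer Reference-grid parameters in meters.
#' @param levels Isopleth levels (percent) extracted for UD-producing
#'   estimators.
#' @param ... Passed on to the estimator.
#' @return An object of class `homerange`.
#' @examples
#' \donttest{
#' prm <- ou_params(duration_days = 20)
#' tr <- observe_gps(simulate_ou(prm, seed = 7), seed = 8)
#' hr <- homerange(tr, "lkde")
#' hr
#' }
#' @export
homerange <- function(traj, estimator = "bbmm", grain = 100,
                      buffer = 3 * grain, levels = c(50, 95, 100), ...) {
  stopifnot(inherits(traj, "hr_trajectory"))
  grid <- reference_grid(traj, grain = grain, buffer = buffer)
  field <- estimate_field(traj, estimator, grid = grid, ...)
  iso <- if (inherits(field, "hr_ud")) extract_isopleths(field, levels)
         else NULL
  auc <- tryCatch(compute_auc(field, traj), error = function(e) NA_real_)
  structure(list(trajectory = traj, estimator = estimator, grid = grid,
                 field = field, isopleths = iso, auc = auc),
            class = "homerange")
}

#' @export
print.homerange <- function(x, ...) {
  cat(sprintf("<homerange> %s for animal %s (%d fixes, %s)\n",
              x$estimator, x$trajectory$animal_id,
              length(x$trajectory$time), x$trajectory$technology))
  cat(sprintf("  AUC = %.4f\n", as.numeric(x$auc)))
  if (!is.null(x$isopleths))
    for (i in seq_along(x$isopleths$levels))
      cat(sprintf("  %5.1f%% isopleth: %.2f km^2\n",
                  x$isopleths$levels[i], x$isopleths$areas[i] / 1e6))
  invisible(x)
}

#' @export
summary.homerange <- function(object, ...) {
  print(object)
  invisible(object)
}

#' Isopleth areas of a fitted home range
#'
#' @param x A `homerange` object.
#' @param levels Percent levels; defaults to those extracted at fit time.
#' @return Named numeric vector of areas in m^2.
#' @export
area <- function(x, levels = NULL) UseMethod("area")

#' @export
area.homerange <- function(x, levels = NULL) {
  if (inherits(x$field, "hr_ud")) {
    iso <- if (is.null(levels)) x$isopleths
           else extract_isopleths(x$field, levels)
    stats::setNames(iso$areas, paste0(iso$levels, "%"))
  } else {
    # hull-family fields: area of cells covered at each level
    lv <- if (is.null(levels)) c(50, 95, 100) else levels
    s <- x$field$score
    vapply(lv, function(L)
      sum(is.finite(s) & (100 - s) <= L + 1e-9) * x$grid$grain^2,
      numeric(1)) |> stats::setNames(paste0(lv, "%"))
  }
}

#' @export
plot.homerange <- function(x, y, ...) {
  g <- x$grid
  s <- x$field$score
  s[!is.finite(s)] <- NA
  graphics::image(grid_centers_x(g), grid_centers_y(g), t(s),
                  asp = 1, xlab = "x (m)", ylab = "y (m)",
                  main = sprintf("%s, AUC = %.3f", x$estimator,
                                 as.numeric(x$auc)),
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE), ...)
  graphics::points(x$trajectory$x, x$trajectory$y, pch = ".", col = "blue")
  if (!is.null(x$isopleths))
    for (rings in x$isopleths$polygons)
      for (r in rings) graphics::lines(r, col = "black", lwd = 0.7)
  invisible(x)
}
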