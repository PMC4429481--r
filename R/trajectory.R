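#' Construct a telemetry trajectory
#'
#' A trajectory is one animal's time-ordered sequence of relocations in a
#' projected planar coordinate system (meters), with an optional per-fix
#' location-error standard deviation and the collar duty-cycle class the
#' fixes were collected under.
#'
#' @param animal_id Character scalar identifying the animal.
#' @param time Numeric vector of fix times in seconds since epoch (or a
#'   `POSIXct` vector). Must be strictly increasing after sorting; duplicate
#'   times are an error.
#' @param x,y Numeric vectors of projected planar coordinates in meters.
#' @param err_sd Optional numeric vector (or scalar, recycled) of per-fix
#'   location-error standard deviations in meters; `NA` where unknown.
#' @param schedule_class One of `"hourly"`, `"four"`, `"seven"`, `"vhf"`:
#'   the collection-schedule category (fixes every <=1 h, 2-4 h, 7-14 h, or
#'   VHF flight schedule).
#' @param technology `"GPS"` or `"VHF"`.
#' @param fix_success Optional proportion in (0, 1]: fraction of scheduled
#'   fix attempts that produced a location (a covariate in the AUC analysis).
#' @param study_area Optional character label used as a covariate.
#' @return An object of class `hr_trajectory`.
#' @examples
#' tr <- hr_trajectory("A1", time = c(0, 3600, 7200),
#'                     x = c(0, 50, 100), y = c(0, 10, 0), err_sd = 34)
#' tr
#' @export
hr_trajectory <- function(animal_id, time, x, y, err_sd = NA_real_,
                          schedule_class = c("hourly", "four", "seven", "vhf"),
                          technology = c("GPS", "VHF"),
                          fix_success = NA_real_, study_area = NA_character_) {
  schedule_class <- match.arg(schedule_class)
  technology <- match.arg(technology)
  if (inherits(time, "POSIXct")) time <- as.numeric(time)
  n <- length(time)
  if (n < 1L) stop("a trajectory needs at least one fix")
  if (length(x) != n || length(y) != n)
    stop("time, x and y must have equal length")
  err_sd <- rep_len(as.numeric(err_sd), n)
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("coordinates must be finite")
  if (any(err_sd < 0, na.rm = TRUE)) stop("err_sd must be >= 0")
  o <- order(time)
  time <- time[o]; x <- x[o]; y <- y[o]; err_sd <- err_sd[o]
  if (anyDuplicated(time))
    stop("duplicate timestamps for animal '", animal_id, "' at row(s) ",
         paste(which(duplicated(time))[1L], collapse = ", "))
  structure(
    list(animal_id = as.character(animal_id), time = time, x = x, y = y,
         err_sd = err_sd, schedule_class = schedule_class,
         technology = technology, fix_success = as.numeric(fix_success),
         study_area = as.character(study_area)),
    class = "hr_trajectory")
}

#' @export
print.hr_trajectory <- function(x, ...) {
  span_d <- diff(range(x$time)) / 86400
  cat(sprintf("<hr_trajectory> animal %s: %d fixes over %.1f days (%s, %s)\n",
              x$animal_id, length(x$time), span_d, x$technology,
              x$schedule_class))
  invisible(x)
}

#' @export
length.hr_trajectory <- function(x) length(x$time)

#' Read trajectories from delimited text
#'
#' Reads a delimited file with one relocation per row and returns one
#' [hr_trajectory] per animal, fixes sorted by time. Coordinates must be in a
#' projected meter CRS; if every row looks geographic (|x| <= 180 and
#' |y| <= 90) a warning is raised because all distances and areas downstream
#' are metric.
#'
#' @param path Path to a delimited text file.
#' @param columns Named character vector mapping the roles
#'   `animal_id`, `timestamp`, `x`, `y` (and optionally `err_sd`) to column
#'   names in the file.
#' @param sep Field separator (default `","`).
#' @param schedule_class,technology Passed to [hr_trajectory()] for every
#'   animal in the file.
#' @param tz Timezone used to parse ISO-8601 timestamps (default `"UTC"`).
#' @return A named list of [hr_trajectory] objects, one per animal.
#' @export
read_trajectories <- function(path,
                              columns = c(animal_id = "animal_id",
                                          timestamp = "timestamp",
                                          x = "x", y = "y",
                                          err_sd = "err_sd"),
                              sep = ",",
                              schedule_class = "hourly",
                              technology = "GPS",
                              tz = "UTC") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("animal_id", "timestamp", "x", "y")
  if (!all(need %in% names(columns)))
    stop("columns must map at least ", paste(need, collapse = ", "))
  for (role in need)
    if (!columns[[role]] %in% names(df))
      stop("column '", columns[[role]], "' (role ", role, ") not in file")
  tcol <- df[[columns[["timestamp"]]]]
  tnum <- if (is.numeric(tcol)) as.numeric(tcol)
          else as.numeric(as.POSIXct(tcol, tz = tz))
  if (anyNA(tnum)) stop("unparseable timestamps in ", path)
  xs <- as.numeric(df[[columns[["x"]]]])
  ys <- as.numeric(df[[columns[["y"]]]])
  if (all(abs(xs) <= 180) && all(abs(ys) <= 90))
    warning("coordinates look geographic (lon/lat); a projected CRS in ",
            "meters is required for all distance and area computations")
  es <- if ("err_sd" %in% names(columns) && columns[["err_sd"]] %in% names(df))
    as.numeric(df[[columns[["err_sd"]]]]) else NA_real_
  es <- rep_len(es, nrow(df))
  ids <- as.character(df[[columns[["animal_id"]]]])
  out <- lapply(split(seq_len(nrow(df)), ids), function(i) {
    ti <- tnum[i]
    if (anyDuplicated(ti)) {
      dup <- which(duplicated(ti))[1L]
      stop("duplicate timestamp for animal '", ids[i[1L]],
           "' at input row ", i[dup])
    }
    hr_trajectory(ids[i[1L]], ti, xs[i], ys[i], es[i],
                  schedule_class = schedule_class, technology = technology)
  })
  out[order(names(out))]
}

#' Split a trajectory into calendar years with enough fixes
#'
#' Annual home ranges are only estimated for animal-years with strictly more
#' than `threshold` locations; the year is the calendar year (1 January to
#' 31 December, UTC). Years at or below the threshold are dropped.
#'
#' @param traj An [hr_trajectory].
#' @param threshold Minimum count; a year is retained when its number of
#'   fixes is strictly greater than this (default 50).
#' @return A list of [hr_trajectory] objects, one per retained calendar year
#'   (possibly empty).
#' @export
filter_min_annual <- function(traj, threshold = 50) {
  stopifnot(inherits(traj, "hr_trajectory"), threshold >= 1)
  yr <- as.integer(format(as.POSIXct(traj$time, origin = "1970-01-01",
                                     tz = "UTC"), "%Y"))
  keep_years <- names(which(table(yr) > threshold))
  out <- lapply(keep_years, function(y) {
    i <- which(yr == as.integer(y))
    tr <- traj
    tr$time <- traj$time[i]; tr$x <- traj$x[i]; tr$y <- traj$y[i]
    tr$err_sd <- traj$err_sd[i]
    attr(tr, "year") <- as.integer(y)
    tr
  })
  out
}

## xy matrix helper used across estimators
traj_xy <- function(traj) cbind(traj$x, traj$y)
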