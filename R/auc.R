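#' Area-under-the-curve goodness of fit for a home-range surface
#'
#' Scores how well an estimator's cell scores rank the cells that actually
#' contain relocations above those that do not. The response is binary per
#' cell (1 if the cell holds at least one fix), the predictor is the cell
#' score, and the statistic is the tie-corrected rank-sum AUC:
#' `(pairs where the presence cell scores higher + 0.5 * tied pairs) /
#' (n1 * n0)` -- identical to the trapezoidal ROC area. 0.5 means no
#' discrimination, 1.0 a perfect fit of the isopleths to the relocations.
#'
#' @param field An `hr_field` or `hr_ud` on the trajectory's reference grid.
#' @param traj The [hr_trajectory] the field was estimated from.
#' @return AUC in `[0, 1]` (attributes `n_presence`, `n_absence`).
#' @export
compute_auc <- function(field, traj) {
  stopifnot(inherits(field, "hr_field"), inherits(traj, "hr_trajectory"))
  idx <- cell_index(field$grid, traj$x, traj$y)
  idx <- idx[!is.na(idx)]
  if (!length(idx)) stop("no fix falls inside the grid extent")
  n_cells <- length(field$score)
  presence <- logical(n_cells)
  presence[idx] <- TRUE
  n1 <- sum(presence); n0 <- n_cells - n1
  if (n1 == 0 || n0 == 0)
    stop("AUC undefined: need at least one presence and one absence cell")
  r <- rank(as.vector(field$score))   # midranks handle ties, -Inf sorts low
  auc <- (sum(r[presence]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  structure(auc, n_presence = n1, n_absence = n0)
}

## the eight estimators of the suite, in canonical order
HR_ESTIMATORS <- c("locoh", "slca", "char", "lkde", "pkde",
                   "bbmm", "dbbmm", "mkde")

#' Estimate one home-range score field
#'
#' Dispatches to the estimator implementations on a shared reference grid.
#' Estimator tags: `mcp`, `locoh`, `slca`, `char` (hull family), `lkde`,
#' `pkde`, `lscv` (location-based KDE), `bbmm`, `dbbmm`, `mkde` (movement
#' family).
#'
#' @param traj An [hr_trajectory].
#' @param estimator One of the tags above.
#' @param grid A [reference_grid()]; built with defaults when `NULL`.
#' @param ... Passed on to the underlying estimator.
#' @return An `hr_field` (hull family) or `hr_ud` (kernel and movement
#'   families).
#' @export
estimate_field <- function(traj, estimator, grid = NULL, ...) {
  if (is.null(grid)) grid <- reference_grid(traj)
  xy <- traj_xy(traj)
  switch(estimator,
    mcp = {
      poly <- mcp(xy)
      lm <- mark_cells_in_poly(grid, poly$vertices, 100,
                               matrix(NA_real_, grid$nrows, grid$ncols))
      level_to_field(grid, lm, "mcp", list())
    },
    locoh = locoh_k(xy, grid = grid, ...)$field,
    slca = slca(xy, grid = grid)$field,
    char = char_hull(xy, grid = grid)$field,
    lkde = kde_ud(xy, href_bandwidth(xy), grid),
    pkde = kde_ud(xy, plugin_bandwidth(xy), grid),
    lscv = kde_ud(xy, lscv_bandwidth(xy, grain = grid$grain), grid),
    bbmm = bbmm_ud(traj, grid = grid,
                   default_err_sd = default_err(traj), ...),
    dbbmm = dbbmm_ud(traj, grid = grid,
                     default_err_sd = default_err(traj), ...),
    mkde = mkde_brb_ud(traj, grid = grid, ...),
    stop("unknown estimator '", estimator, "'")
  )
}

default_err <- function(traj) {
  e <- traj$err_sd[is.finite(traj$err_sd)]
  if (length(e)) stats::median(e) else 0
}

n_locations_class <- function(n) {
  cut(n, breaks = c(0, 100, 500, 1000, Inf),
      labels = c("<100", "101-500", "501-1000", ">1000"), right = TRUE)
}

#' AUC records for a set of trajectories and estimators
#'
#' Runs every estimator on every trajectory (each on that animal's shared
#' reference grid) and computes the AUC with covariates filled. Estimators
#' that cannot run on a trajectory (e.g. the movement-based KDE on VHF
#' schedules) are recorded with `NA` AUC and the failure message, never as
#' zero.
#'
#' @param trajs A list of [hr_trajectory] objects (or an `hr_cohort`, whose
#'   GPS and VHF trajectories are both used).
#' @param estimators Character vector of estimator tags (default the 8-
#'   estimator suite).
#' @param grain,buffer Reference-grid parameters (meters).
#' @param ... Passed to [estimate_field()].
#' @return A data frame with one row per (animal, estimator) combination.
#' @export
auc_table <- function(trajs, estimators = HR_ESTIMATORS, grain = 100,
                      buffer = 3 * grain, ...) {
  if (inherits(trajs, "hr_cohort"))
    trajs <- unlist(lapply(trajs, function(a) list(a$gps, a$vhf)),
                    recursive = FALSE)
  rows <- lapply(trajs, function(tr) {
    grid <- reference_grid(tr, grain = grain, buffer = buffer)
    n_cells <- grid$nrows * grid$ncols
    do.call(rbind, lapply(estimators, function(est) {
      res <- tryCatch({
        f <- estimate_field(tr, est, grid = grid, ...)
        a <- compute_auc(f, tr)
        list(auc = as.numeric(a), note = "")
      }, error = function(e) list(auc = NA_real_,
                                  note = conditionMessage(e)))
      data.frame(animal_id = tr$animal_id, estimator = est,
                 technology = tr$technology, auc = res$auc,
                 n_locations = length(tr$time),
                 n_locations_class = as.character(
                   n_locations_class(length(tr$time))),
                 fix_success = tr$fix_success,
                 schedule_class = tr$schedule_class,
                 study_area = tr$study_area,
                 n_cells = n_cells,
                 note = res$note,
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Kruskal-Wallis rank test across groups
#'
#' Tie-corrected rank-based H with `df = groups - 1` and a chi-squared
#' p-value (wraps `stats::kruskal.test`).
#'
#' @param groups A list (possibly named) of numeric vectors, each nonempty.
#' @return A list with `H`, `df`, `p`.
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2) stop("need at least 2 groups")
  if (any(lengths(groups) == 0)) stop("all groups must be nonempty")
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  kt <- stats::kruskal.test(x, g)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p = kt$p.value)
}

#' Pairwise Welch t-tests with Bonferroni correction
#'
#' One Welch two-sample t-test per group pair; each p-value is multiplied by
#' the number of comparisons `g (g - 1) / 2` and capped at 1.
#'
#' @param groups A named list of numeric vectors with at least 2 values each.
#' @return A symmetric matrix of adjusted p-values (`NA` on the diagonal).
#' @export
pairwise_t_bonferroni <- function(groups) {
  gnames <- names(groups)
  if (is.null(gnames)) gnames <- paste0("g", seq_along(groups))
  k <- length(groups)
  if (k < 2) stop("need at least 2 groups")
  if (any(lengths(groups) < 2)) stop("each group needs at least 2 values")
  m <- k * (k - 1) / 2
  p <- matrix(NA_real_, k, k, dimnames = list(gnames, gnames))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      a <- groups[[i]]; b <- groups[[j]]
      raw <- tryCatch(stats::t.test(a, b)$p.value,
                      error = function(e) {
                        # both groups constant: identical means give p = 1,
                        # different means are infinitely separated
                        if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0
                      })
      p[i, j] <- p[j, i] <- min(1, raw * m)
    }
  }
  p
}

#' Logit transform
#'
#' `ln(x / (1 - x))` for proportions strictly inside (0, 1).
#'
#' @param x Numeric vector in (0, 1).
#' @return The logit of `x`.
#' @export
logit <- function(x) {
  if (any(x <= 0 | x >= 1)) stop("logit is defined on (0, 1) only")
  log(x / (1 - x))
}

## AUC of exactly 1 happens for hull estimators on tiny grids; clamp just
## inside 1 (by half a cell's worth of rank mass) so the logit stays finite
clamp_auc <- function(auc, n_cells) {
  hit <- auc >= 1
  if (any(hit)) {
    warning(sum(hit), " AUC value(s) of exactly 1 clamped below 1 ",
            "for the logit transform")
    auc[hit] <- 1 - 1 / (2 * n_cells[hit])
  }
  lo <- auc <= 0
  if (any(lo)) auc[lo] <- 1 / (2 * n_cells[lo])
  auc
}

#' Small-sample corrected Akaike information criterion
#'
#' `AICc = -2 loglik + 2K + 2K(K+1)/(n - K - 1)`; requires `n > K + 1`.
#'
#' @param loglik Maximized log-likelihood.
#' @param K Number of estimated parameters.
#' @param n Sample size.
#' @return The AICc value.
#' @export
aicc <- function(loglik, K, n) {
  if (n <= K + 1) stop("AICc requires n > K + 1")
  -2 * loglik + 2 * K + 2 * K * (K + 1) / (n - K - 1)
}

#' Rank a candidate model set by AICc
#'
#' Computes `delta = AICc - min(AICc)`, Akaike weights
#' `exp(-delta/2) / sum(exp(-delta/2))`, and flags candidates with
#' `delta < 4`. Rows are returned sorted by AICc.
#'
#' @param rows A data frame with columns `terms`, `K`, `AICc`.
#' @return The data frame with `delta`, `weight`, `candidate` columns added.
#' @export
model_selection <- function(rows) {
  stopifnot(nrow(rows) >= 1, all(c("terms", "K", "AICc") %in% names(rows)))
  rows <- rows[order(rows$AICc), , drop = FALSE]
  rows$delta <- rows$AICc - rows$AICc[1]
  w <- exp(-rows$delta / 2)
  rows$weight <- w / sum(w)
  rows$candidate <- rows$delta < 4.0
  rownames(rows) <- NULL
  rows
}
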