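#' Cell score fields and utilization distributions
#'
#' A cell score field attaches a real-valued score to every cell of a
#' reference grid; all estimators in the suite ultimately produce one, and
#' the AUC statistic operates on it. Scores must be ordered so that larger
#' means more intensely used (cells a hull estimator never covers carry
#' `-Inf`). A utilization distribution (UD) is the special case where the
#' scores are non-negative probability masses summing to one.
#'
#' @param grid An [reference_grid()] object.
#' @param score Numeric matrix (`nrows` x `ncols`; row 1 is the southernmost
#'   row) of per-cell scores.
#' @param estimator Short tag naming the estimator that produced the field.
#' @param params Named list of estimator parameters (recorded, not used).
#' @return An object of class `hr_field` (and `hr_ud` once normalized).
#' @export
cell_field <- function(grid, score, estimator = "unknown", params = list()) {
  stopifnot(inherits(grid, "hr_grid"))
  score <- as.matrix(score)
  if (nrow(score) != grid$nrows || ncol(score) != grid$ncols)
    stop("score matrix shape does not match the grid")
  if (any(is.nan(score)))
    stop("scores must not be NaN")
  structure(list(grid = grid, score = score, estimator = estimator,
                 params = params),
            class = "hr_field")
}

#' @export
print.hr_field <- function(x, ...) {
  kind <- if (inherits(x, "hr_ud")) "utilization distribution" else "score field"
  cat(sprintf("<%s> %s on %d x %d grid (grain %g m), estimator %s\n",
              class(x)[1L], kind, x$grid$nrows, x$grid$ncols, x$grid$grain,
              x$estimator))
  invisible(x)
}

#' Normalize a score field to a utilization distribution
#'
#' Divides non-negative cell scores by their total so the masses sum to one.
#'
#' @param field An `hr_field` with non-negative scores, at least one positive.
#' @return An object of classes `hr_ud`, `hr_field`.
#' @export
normalize_to_ud <- function(field) {
  stopifnot(inherits(field, "hr_field"))
  s <- field$score
  if (any(s < 0)) stop("scores must be >= 0 to normalize to a UD")
  tot <- sum(s)
  if (tot <= 0) stop("all-zero score field cannot be normalized")
  field$score <- s / tot
  class(field) <- unique(c("hr_ud", class(field)))
  field
}

#' Per-cell volume-contour levels of a UD
#'
#' The volume-contour level of a cell is the percent of total UD mass held by
#' cells at least as heavy as it: sort cells by mass descending, accumulate,
#' and let equal-mass cells share one level (the accumulated mass of the whole
#' tie group). The k% home-range isopleth is then the set of cells with level
#' `<= k`. Zero-mass cells get level `Inf` so they never enter an isopleth.
#'
#' @param ud An `hr_ud`.
#' @return An `hr_field` whose scores are levels in percent (plus `Inf` for
#'   zero-mass cells).
#' @export
volume_contour_levels <- function(ud) {
  stopifnot(inherits(ud, "hr_ud"))
  m <- as.vector(ud$score)
  lev <- rep(Inf, length(m))
  pos <- which(m > 0)
  if (length(pos)) {
    mp <- m[pos]
    o <- order(mp, decreasing = TRUE)
    sm <- mp[o]
    cum <- cumsum(sm)
    # ties share the level reached at the end of their tie group
    grp_last <- rev(!duplicated(rev(sm)))   # TRUE at last member of each group
    last_idx <- which(grp_last)
    group_id <- findInterval(seq_along(sm), c(0, last_idx), left.open = TRUE)
    lev[pos[o]] <- 100 * cum[last_idx][group_id]
  }
  out <- ud
  out$score <- matrix(lev, nrow = ud$grid$nrows)
  class(out) <- "hr_field"
  out$estimator <- paste0(ud$estimator, "_levels")
  out
}

#' Extract nested isopleths from a UD
#'
#' The region at level L is the union of all cells with volume-contour level
#' `<= L`; its area is the cell count times the squared grain. Regions are
#' polygonized along cell edges for export.
#'
#' @param ud An `hr_ud`.
#' @param levels Percent levels in (0, 100].
#' @return An object of class `hr_isopleths`: a list with `levels`, `areas`
#'   (m^2), `cells` (list of logical matrices) and `polygons` (list of ring
#'   lists, each ring a closed two-column coordinate matrix; clockwise rings
#'   are holes).
#' @export
extract_isopleths <- function(ud, levels = c(50, 95, 100)) {
  stopifnot(inherits(ud, "hr_ud"))
  if (any(levels <= 0 | levels > 100)) stop("levels must lie in (0, 100]")
  levels <- sort(levels)
  lev <- volume_contour_levels(ud)$score
  g <- ud$grid
  cells <- lapply(levels, function(L) lev <= L + 1e-9)
  areas <- vapply(cells, function(cm) sum(cm) * g$grain^2, numeric(1))
  polys <- lapply(cells, function(cm) cells_to_rings(g, cm))
  structure(list(levels = levels, areas = areas, cells = cells,
                 polygons = polys, grid = g, estimator = ud$estimator),
            class = "hr_isopleths")
}

#' @export
print.hr_isopleths <- function(x, ...) {
  cat("<hr_isopleths>", x$estimator, "\n")
  for (i in seq_along(x$levels))
    cat(sprintf("  %5.1f%%  %12.0f m^2  (%d rings)\n", x$levels[i],
                x$areas[i], length(x$polygons[[i]])))
  invisible(x)
}

## Polygonize a logical cell mask into boundary rings by directed-edge
## cancellation: each TRUE cell contributes its four edges counterclockwise;
## edges shared by two TRUE cells cancel; the survivors chain into rings.
## With the CCW convention, outer shells come out CCW (positive signed area)
## and holes CW.
cells_to_rings <- function(grid, mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(list())
  g <- grid$grain
  r <- idx[, 1] - 1L; c <- idx[, 2] - 1L
  # vertex keys: (col, row) lattice points, encoded as col + row * (ncols+2)
  W <- grid$ncols + 2L
  enc <- function(cc, rr) cc + rr * W
  # directed edges CCW: bottom (c,r)->(c+1,r), right, top, left
  from <- c(enc(c, r),     enc(c + 1L, r),     enc(c + 1L, r + 1L), enc(c, r + 1L))
  to   <- c(enc(c + 1L, r), enc(c + 1L, r + 1L), enc(c, r + 1L),     enc(c, r))
  # cancel edge pairs that appear in both directions
  key_f <- paste(from, to); key_r <- paste(to, from)
  drop <- key_f %in% key_r
  from <- from[!drop]; to <- to[!drop]
  if (!length(from)) return(list())
  rings <- list()
  # chain edges: map from-vertex -> edge index (boundary vertices can carry
  # two outgoing edges only at pinch points; resolve by taking any unused one)
  ord <- order(from)
  lookup <- split(ord, from[ord])
  used <- rep(FALSE, length(from))
  for (e0 in seq_along(from)) {
    if (used[e0]) next
    ring_v <- integer(0)
    e <- e0
    repeat {
      used[e] <- TRUE
      ring_v <- c(ring_v, from[e])
      nxt_cands <- lookup[[as.character(to[e])]]
      nxt <- nxt_cands[!used[nxt_cands]]
      if (!length(nxt)) break
      e <- nxt[1L]
    }
    cc <- ring_v %% W; rr <- ring_v %/% W
    xs <- grid$x0 + cc * g; ys <- grid$y0 + rr * g
    rings[[length(rings) + 1L]] <- cbind(x = c(xs, xs[1L]), y = c(ys, ys[1L]))
  }
  rings
}

## shoelace signed area of a closed ring
ring_signed_area <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  n <- length(x)
  sum(x[-n] * y[-1] - x[-1] * y[-n]) / 2
}
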