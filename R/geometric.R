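## ---- shared polygon helpers -------------------------------------------

## convex hull as a CCW polygon matrix (vertices, no closing row);
## returns NULL for degenerate (collinear / duplicate) input
convex_hull_poly <- function(xy) {
  xy <- unique(as.matrix(xy))
  if (nrow(xy) < 3) return(NULL)
  h <- grDevices::chull(xy)
  poly <- xy[h, , drop = FALSE]
  a <- poly_signed_area(poly)
  if (abs(a) < 1e-12 * max(1, diff(range(xy[, 1])), diff(range(xy[, 2])))^2)
    return(NULL)
  if (a < 0) poly <- poly[rev(seq_len(nrow(poly))), , drop = FALSE]
  poly
}

poly_signed_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  j <- c(seq_len(nrow(poly))[-1], 1L)
  sum(x * y[j] - x[j] * y) / 2
}

## vectorized point-in-convex-polygon test (poly CCW); boundary counts inside
points_in_convex <- function(poly, px, py) {
  if (is.null(poly)) return(rep(FALSE, length(px)))
  n <- nrow(poly)
  scale <- max(abs(poly)) + 1
  eps <- -1e-9 * scale^2
  inside <- rep(TRUE, length(px))
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    cr <- (poly[j, 1] - poly[i, 1]) * (py - poly[i, 2]) -
          (poly[j, 2] - poly[i, 2]) * (px - poly[i, 1])
    inside <- inside & cr >= eps
    if (!any(inside)) break
  }
  inside
}

## mark grid cells whose centers fall in a convex polygon, assigning `level`
## where no level is set yet; returns the updated level matrix
mark_cells_in_poly <- function(grid, poly, level, level_mat) {
  if (is.null(poly)) return(level_mat)
  g <- grid$grain
  c0 <- max(1L, floor((min(poly[, 1]) - grid$x0) / g - 0.5) + 1L)
  c1 <- min(grid$ncols, ceiling((max(poly[, 1]) - grid$x0) / g + 0.5))
  r0 <- max(1L, floor((min(poly[, 2]) - grid$y0) / g - 0.5) + 1L)
  r1 <- min(grid$nrows, ceiling((max(poly[, 2]) - grid$y0) / g + 0.5))
  if (c0 > c1 || r0 > r1) return(level_mat)
  cols <- c0:c1; rows <- r0:r1
  sub <- level_mat[rows, cols, drop = FALSE]
  todo <- which(is.na(sub))        # only cells not yet covered need testing
  if (!length(todo)) return(level_mat)
  cx <- grid$x0 + (cols[(todo - 1) %/% length(rows) + 1] - 0.5) * g
  cy <- grid$y0 + (rows[(todo - 1) %% length(rows) + 1] - 0.5) * g
  ins <- points_in_convex(poly, cx, cy)
  if (any(ins)) {
    sub[todo[ins]] <- level
    level_mat[rows, cols] <- sub
  }
  level_mat
}

## turn a per-cell covering-level matrix (NA = never covered) into the score
## field AUC uses: larger = more intensely used, uncovered = -Inf
level_to_field <- function(grid, level_mat, estimator, params) {
  s <- 100 - level_mat
  s[is.na(s)] <- -Inf
  cell_field(grid, s, estimator = estimator, params = params)
}

#' Minimum convex polygon
#'
#' Convex hull of the relocations; the building block the hull-based
#' estimators generalize.
#'
#' @param xy Two-column matrix of coordinates (meters) or an
#'   [hr_trajectory].
#' @return A list of class `hr_poly` with `vertices` (CCW matrix) and
#'   `area` (m^2).
#' @examples
#' mcp(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)))$area
#' @export
mcp <- function(xy) {
  if (inherits(xy, "hr_trajectory")) xy <- traj_xy(xy)
  poly <- convex_hull_poly(xy)
  if (is.null(poly))
    stop("degenerate geometry: need >= 3 non-collinear points")
  structure(list(vertices = poly, area = poly_signed_area(poly)),
            class = "hr_poly")
}

#' @export
print.hr_poly <- function(x, ...) {
  cat(sprintf("<hr_poly> %d vertices, area %.6g m^2\n",
              nrow(x$vertices), x$area))
  invisible(x)
}

## ---- local convex hull (LoCoH) ----------------------------------------

#' k-nearest-neighbour local convex hull estimator
#'
#' For each relocation, the convex hull of the point and its k-1 nearest
#' neighbours is built; hulls are sorted by area ascending and progressively
#' unioned. The percent of points covered after each union defines the
#' isopleth levels, and each grid cell is scored by `100 - (level at first
#' coverage)`, so more intensely used cells score higher; cells never covered
#' score `-Inf`. The default k is the square root of the number of
#' relocations (rounded, minimum 3).
#'
#' @param xy Coordinates matrix or [hr_trajectory].
#' @param k Neighbourhood size, `3 <= k <= n` (default `round(sqrt(n))`).
#' @param grid Optional [reference_grid()]; built with defaults when `NULL`.
#' @return A list of class `hr_hullseq` with elements `percents` (after each
#'   union), `areas` (hull areas, sorted order), `order` (hull root point
#'   indices), and `field` (the `hr_field` for AUC).
#' @export
locoh_k <- function(xy, k = NULL, grid = NULL) {
  if (inherits(xy, "hr_trajectory")) xy <- traj_xy(xy)
  xy <- as.matrix(xy)
  n <- nrow(xy)
  if (is.null(k)) k <- max(3L, as.integer(round(sqrt(n))))
  if (k < 3) stop("k must be >= 3")
  if (k > n) stop("k must be <= n")
  if (is.null(grid)) grid <- reference_grid(xy)
  nb <- if (k > 1) cpp_knn(xy[, 1], xy[, 2], k - 1L) else NULL
  hulls <- vector("list", n)
  areas <- numeric(n)
  members <- vector("list", n)
  for (i in seq_len(n)) {
    idx <- c(i, if (!is.null(nb)) nb[i, ])
    members[[i]] <- idx
    p <- convex_hull_poly(xy[idx, , drop = FALSE])
    hulls[i] <- list(p)    # may be NULL for degenerate neighbourhoods
    areas[i] <- if (is.null(p)) 0 else poly_signed_area(p)
  }
  ord <- order(areas, seq_len(n))
  covered <- rep(FALSE, n)
  level_mat <- matrix(NA_real_, grid$nrows, grid$ncols)
  percents <- numeric(n)
  for (s in seq_len(n)) {
    i <- ord[s]
    covered[members[[i]]] <- TRUE
    if (!is.null(hulls[[i]])) {
      inb <- which(!covered)
      if (length(inb)) {
        ins <- points_in_convex(hulls[[i]], xy[inb, 1], xy[inb, 2])
        covered[inb[ins]] <- TRUE
      }
    }
    percents[s] <- 100 * sum(covered) / n
    level_mat <- mark_cells_in_poly(grid, hulls[[i]], percents[s], level_mat)
  }
  structure(list(source = "locoh", percents = percents,
                 areas = areas[ord], order = ord, hulls = hulls[ord],
                 field = level_to_field(grid, level_mat, "locoh",
                                        list(k = k))),
            class = "hr_hullseq")
}

#' @export
print.hr_hullseq <- function(x, ...) {
  cat(sprintf("<hr_hullseq> %s: %d hulls, final coverage %.1f%%\n",
              x$source, length(x$percents), max(x$percents)))
  invisible(x)
}

## ---- single-linkage cluster analysis (SLCA) ---------------------------

#' Single-linkage cluster home-range estimator
#'
#' Clusters relocations by a stepwise single-linkage process: the seed
#' cluster is the 3-point set with smallest mean pairwise distance (among
#' triples formed by a point and its two nearest neighbours); each subsequent
#' step either (a) assigns the unassigned point closest to an existing
#' cluster (single-linkage distance), (b) forms a new 3-point cluster from an
#' unassigned point and its two nearest unassigned neighbours (mean pairwise
#' distance), or (c) merges the two closest clusters -- whichever candidate
#' has the smallest distance (ties: assign < new < merge, then lowest index).
#' The process stops when all relocations sit in one cluster. The isopleth at
#' P% is the union of the convex hulls of the clusters restricted to the
#' first `ceiling(P% * n)` assigned points; cells are scored by `100 -
#' (percent assigned at first coverage)`.
#'
#' @param xy Coordinates matrix or [hr_trajectory].
#' @param grid Optional [reference_grid()].
#' @return A list of class `hr_hullseq` with `order` (point indices in
#'   assignment order), `percents`, `steps` (step log) and `field`.
#' @export
slca <- function(xy, grid = NULL) {
  if (inherits(xy, "hr_trajectory")) xy <- traj_xy(xy)
  xy <- as.matrix(xy)
  n <- nrow(xy)
  if (n < 3) stop("SLCA needs at least 3 points")
  if (is.null(grid)) grid <- reference_grid(xy)
  dist_to <- function(i) sqrt((xy[, 1] - xy[i, 1])^2 + (xy[, 2] - xy[i, 2])^2)

  assigned <- rep(FALSE, n)
  clusters <- list()          # active clusters: member index vectors
  dmin <- list()              # per cluster: min distance from every point
  cand_val <- numeric(0)      # cached best unassigned candidate per cluster
  cand_pt <- integer(0)
  cross <- matrix(numeric(0), 0, 0)  # min inter-cluster distances
  level_mat <- matrix(NA_real_, grid$nrows, grid$ncols)
  ord <- integer(0)
  percents <- numeric(0)
  steps <- character(0)

  # candidate new-cluster triples: a point plus its two nearest unassigned
  # neighbours, at mean pairwise distance; cached lazily (a cached cost can
  # only be too low when a cached neighbour has since been assigned, and a
  # refresh never lowers it, so stale entries are validated on selection)
  triple_cost <- rep(NA_real_, n)
  triple_of <- vector("list", n)
  refresh_triple <- function(p) {
    un <- which(!assigned)
    un <- un[un != p]
    if (length(un) < 2) {
      triple_cost[p] <<- Inf; triple_of[[p]] <<- NULL; return(invisible())
    }
    d <- dist_to(p)[un]
    o <- un[order(d, un)][1:2]
    tri <- c(p, o)
    triple_cost[p] <<- mean(stats::dist(xy[tri, , drop = FALSE]))
    triple_of[[p]] <<- tri
  }
  best_triple <- function() {
    repeat {
      un <- which(!assigned)
      if (length(un) < 3) return(list(cost = Inf, tri = NULL))
      p <- un[which.min(triple_cost[un])]
      if (!is.finite(triple_cost[p])) return(list(cost = Inf, tri = NULL))
      tri <- triple_of[[p]]
      if (!any(assigned[tri])) return(list(cost = triple_cost[p], tri = tri))
      refresh_triple(p)
    }
  }

  recompute_cand <- function(ci) {
    d <- dmin[[ci]]
    d[assigned] <- Inf
    j <- which.min(d)
    if (length(j) && is.finite(d[j])) {
      cand_val[ci] <<- d[j]; cand_pt[ci] <<- j
    } else {
      cand_val[ci] <<- Inf; cand_pt[ci] <<- NA_integer_
    }
  }

  rasterize_cluster <- function(ci, pct) {
    poly <- convex_hull_poly(xy[clusters[[ci]], , drop = FALSE])
    level_mat <<- mark_cells_in_poly(grid, poly, pct, level_mat)
  }

  add_cluster <- function(members) {
    ci <- length(clusters) + 1L
    clusters[[ci]] <<- members
    assigned[members] <<- TRUE
    dmin[[ci]] <<- do.call(pmin, lapply(members, dist_to))
    k <- length(clusters)
    newcross <- matrix(Inf, k, k)
    if (k > 1) {
      newcross[-k, -k] <- cross
      for (cj in seq_len(k - 1L))
        if (length(clusters[[cj]]))
          newcross[k, cj] <- newcross[cj, k] <- min(dmin[[cj]][members])
    }
    cross <<- newcross
    cand_val[ci] <<- Inf; cand_pt[ci] <<- NA_integer_
    recompute_cand(ci)
    for (cj in which(cand_pt %in% members)) recompute_cand(cj)
    ci
  }

  for (p in seq_len(n)) refresh_triple(p)
  seed <- best_triple()
  ci <- add_cluster(seed$tri)
  ord <- sort(seed$tri)   # members of one step are recorded in index order
  percents <- rep(100 * 3 / n, 3)
  rasterize_cluster(ci, 100 * length(ord) / n)
  steps <- sprintf("new c%d {%s}", ci, paste(seed$tri, collapse = ","))

  repeat {
    active <- which(lengths(clusters) > 0)
    n_assigned <- length(ord)
    if (n_assigned == n && length(active) <= 1) break
    # (a) closest unassigned point to an existing cluster
    best_add <- Inf; add_p <- NA; add_c <- NA
    if (length(active)) {
      j <- active[which.min(cand_val[active])]
      best_add <- cand_val[j]; add_p <- cand_pt[j]; add_c <- j
    }
    # (b) best new triple among unassigned
    nt <- best_triple()
    # (c) closest cluster pair
    best_mrg <- Inf; mrg <- c(NA, NA)
    if (length(active) > 1) {
      sub <- cross[active, active, drop = FALSE]
      jj <- which(sub == min(sub), arr.ind = TRUE)[1, ]
      best_mrg <- min(sub); mrg <- active[jj]
    }
    pick <- which.min(c(best_add, nt$cost, best_mrg))
    if (pick == 1L) {
      ci <- add_c
      clusters[[ci]] <- c(clusters[[ci]], add_p)
      assigned[add_p] <- TRUE
      ord <- c(ord, add_p)
      pct <- 100 * length(ord) / n
      percents <- c(percents, pct)
      d <- dist_to(add_p)
      dmin[[ci]] <- pmin(dmin[[ci]], d)
      for (cj in setdiff(which(lengths(clusters) > 0), ci))
        cross[ci, cj] <- cross[cj, ci] <-
          min(cross[ci, cj], dmin[[cj]][add_p])
      recompute_cand(ci)
      for (cj in which(cand_pt == add_p)) recompute_cand(cj)
      rasterize_cluster(ci, pct)
      steps <- c(steps, sprintf("add %d -> c%d", add_p, ci))
    } else if (pick == 2L) {
      tri <- nt$tri
      ci <- add_cluster(tri)
      ord <- c(ord, sort(tri))
      pct <- 100 * length(ord) / n
      percents <- c(percents, rep(pct, 3))
      rasterize_cluster(ci, pct)
      steps <- c(steps, sprintf("new c%d {%s}", ci,
                                paste(tri, collapse = ",")))
    } else {
      a <- min(mrg); b <- max(mrg)
      clusters[[a]] <- c(clusters[[a]], clusters[[b]])
      clusters[[b]] <- integer(0)
      dmin[[a]] <- pmin(dmin[[a]], dmin[[b]])
      act <- setdiff(which(lengths(clusters) > 0), a)
      for (cj in act)
        cross[a, cj] <- cross[cj, a] <- min(cross[a, cj], cross[b, cj])
      cross[b, ] <- Inf; cross[, b] <- Inf
      cand_val[b] <- Inf; cand_pt[b] <- NA_integer_
      recompute_cand(a)
      pct <- 100 * length(ord) / n
      rasterize_cluster(a, pct)
      steps <- c(steps, sprintf("merge c%d + c%d", a, b))
    }
  }
  structure(list(source = "slca", percents = percents, order = ord,
                 steps = steps,
                 field = level_to_field(grid, level_mat, "slca", list())),
            class = "hr_hullseq")
}

## ---- characteristic hull (CHAR) ---------------------------------------

#' Characteristic hull estimator
#'
#' Delaunay triangulation of the relocations with triangles ordered smallest
#' to largest; the isopleth at P% is the union of the shortest prefix of
#' triangles containing at least P% of the points, and the 100% region (all
#' triangles) is exactly the minimum convex polygon. Duplicate relocations
#' are collapsed for the triangulation and counted through their
#' representative.
#'
#' @param xy Coordinates matrix or [hr_trajectory].
#' @param grid Optional [reference_grid()].
#' @return A list of class `hr_hullseq` with `triangles` (index matrix in
#'   sorted order), `areas`, `percents`, `total_area` (= MCP area) and
#'   `field`.
#' @export
char_hull <- function(xy, grid = NULL) {
  if (inherits(xy, "hr_trajectory")) xy <- traj_xy(xy)
  xy <- as.matrix(xy)
  n <- nrow(xy)
  if (n < 3) stop("need at least 3 points")
  if (is.null(grid)) grid <- reference_grid(xy)
  key <- paste(xy[, 1], xy[, 2])
  rep_idx <- match(key, key)              # representative of each duplicate
  uniq <- which(rep_idx == seq_len(n))
  ux <- xy[uniq, 1]; uy <- xy[uniq, 2]
  if (length(uniq) < 3) stop("degenerate geometry: fewer than 3 distinct points")
  tri <- cpp_delaunay(ux, uy)
  if (nrow(tri) == 0) stop("degenerate geometry: points are collinear")
  tri_area <- vapply(seq_len(nrow(tri)), function(i) {
    p <- cbind(ux[tri[i, ]], uy[tri[i, ]])
    abs(poly_signed_area(p))
  }, numeric(1))
  if (sum(tri_area) <= 0) stop("degenerate geometry: points are collinear")
  tri_sorted <- t(apply(tri, 1, sort))
  o <- order(tri_area, tri_sorted[, 1], tri_sorted[, 2], tri_sorted[, 3])
  tri <- tri[o, , drop = FALSE]
  tri_area <- tri_area[o]
  # multiplicity of each unique point (duplicates count through representative)
  mult <- tabulate(match(rep_idx, uniq), nbins = length(uniq))
  covered_u <- rep(FALSE, length(uniq))
  percents <- numeric(nrow(tri))
  level_mat <- matrix(NA_real_, grid$nrows, grid$ncols)
  for (i in seq_len(nrow(tri))) {
    covered_u[tri[i, ]] <- TRUE
    percents[i] <- 100 * sum(mult[covered_u]) / n
    poly <- cbind(ux[tri[i, ]], uy[tri[i, ]])
    if (poly_signed_area(poly) < 0) poly <- poly[3:1, , drop = FALSE]
    level_mat <- mark_cells_in_poly(grid, poly, percents[i], level_mat)
  }
  structure(list(source = "char", percents = percents, areas = tri_area,
                 triangles = tri, total_area = sum(tri_area),
                 xy_unique = cbind(ux, uy),
                 field = level_to_field(grid, level_mat, "char", list())),
            class = "hr_hullseq")
}
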