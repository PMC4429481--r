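## Independent oracles and fixture builders used across the suite.

## shoelace area of a (non-closed) polygon matrix
shoelace <- function(p) {
  n <- nrow(p)
  j <- c(2:n, 1)
  abs(sum(p[, 1] * p[j, 2] - p[j, 1] * p[, 2])) / 2
}

## convex hull by gift wrapping (independent of grDevices::chull)
giftwrap_hull <- function(xy) {
  xy <- unique(as.matrix(xy))
  n <- nrow(xy)
  start <- which.min(xy[, 1] + 1e-9 * xy[, 2])
  hull <- start
  repeat {
    p <- hull[length(hull)]
    cand <- setdiff(seq_len(n), p)
    q <- cand[1]
    for (r in cand[-1]) {
      cr <- (xy[q, 1] - xy[p, 1]) * (xy[r, 2] - xy[p, 2]) -
            (xy[q, 2] - xy[p, 2]) * (xy[r, 1] - xy[p, 1])
      d_q <- sum((xy[q, ] - xy[p, ])^2)
      d_r <- sum((xy[r, ] - xy[p, ])^2)
      if (cr < 0 || (abs(cr) < 1e-12 && d_r > d_q)) q <- r
    }
    if (q == start) break
    hull <- c(hull, q)
    if (length(hull) > n) stop("gift wrap failed")
  }
  xy[hull, , drop = FALSE]
}

## brute-force pair-counting AUC: response per cell, score per cell
auc_bruteforce <- function(score, presence) {
  s1 <- score[presence]; s0 <- score[!presence]
  tot <- 0
  for (a in s1) tot <- tot + sum(a > s0) + 0.5 * sum(a == s0)
  tot / (length(s1) * length(s0))
}

## Sutherland-Hodgman intersection of two convex CCW polygons
clip_convex <- function(subject, clip) {
  out <- subject
  n <- nrow(clip)
  for (i in seq_len(n)) {
    if (is.null(out) || nrow(out) < 3) return(NULL)
    a <- clip[i, ]; b <- clip[if (i == n) 1 else i + 1, ]
    side <- (b[1] - a[1]) * (out[, 2] - a[2]) -
            (b[2] - a[2]) * (out[, 1] - a[1])
    m <- nrow(out)
    res <- NULL
    for (j in seq_len(m)) {
      k <- if (j == m) 1 else j + 1
      ci <- side[j] >= -1e-12; ni <- side[k] >= -1e-12
      if (ci) res <- rbind(res, out[j, ])
      if (xor(ci, ni)) {
        t <- side[j] / (side[j] - side[k])
        res <- rbind(res, out[j, ] + t * (out[k, ] - out[j, ]))
      }
    }
    out <- res
  }
  out
}

## union area of convex polygons by inclusion-exclusion (small sets only)
union_area_incl_excl <- function(polys) {
  polys <- polys[!vapply(polys, is.null, logical(1))]
  k <- length(polys)
  total <- 0
  for (mask in seq_len(2^k - 1)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(k) - 1)) > 0)
    inter <- polys[[idx[1]]]
    for (j in idx[-1]) {
      inter <- clip_convex(inter, polys[[j]])
      if (is.null(inter)) break
    }
    if (!is.null(inter) && nrow(inter) >= 3)
      total <- total + (-1)^(length(idx) + 1) * shoelace(inter)
  }
  total
}

## from-scratch recomputation of the SLCA step rule (no incremental caches)
slca_oracle_order <- function(xy) {
  xy <- as.matrix(xy)
  n <- nrow(xy)
  D <- as.matrix(stats::dist(xy))
  assigned <- rep(FALSE, n)
  clusters <- list()
  ord <- integer(0)
  best_new <- function() {
    un <- which(!assigned)
    if (length(un) < 3) return(list(cost = Inf))
    best <- list(cost = Inf)
    for (p in un) {
      others <- setdiff(un, p)
      o <- others[order(D[p, others], others)][1:2]
      tri <- c(p, o)
      cost <- mean(c(D[tri[1], tri[2]], D[tri[1], tri[3]],
                     D[tri[2], tri[3]]))
      if (cost < best$cost - 1e-12) best <- list(cost = cost, tri = tri)
    }
    best
  }
  s <- best_new()
  clusters[[1]] <- s$tri; assigned[s$tri] <- TRUE; ord <- sort(s$tri)
  repeat {
    active <- which(lengths(clusters) > 0)
    un <- which(!assigned)
    if (!length(un) && length(active) <= 1) break
    b_add <- Inf; ap <- ac <- NA
    for (ci in active) for (p in un) {
      d <- min(D[p, clusters[[ci]]])
      if (d < b_add - 1e-12) { b_add <- d; ap <- p; ac <- ci }
    }
    b_new <- best_new()
    b_mrg <- Inf; pair <- NULL
    if (length(active) > 1)
      for (i in active) for (j in active) if (i < j) {
        d <- min(D[clusters[[i]], clusters[[j]]])
        if (d < b_mrg - 1e-12) { b_mrg <- d; pair <- c(i, j) }
      }
    pick <- which.min(c(b_add, b_new$cost, b_mrg))
    if (pick == 1) {
      clusters[[ac]] <- c(clusters[[ac]], ap)
      assigned[ap] <- TRUE; ord <- c(ord, ap)
    } else if (pick == 2) {
      clusters[[length(clusters) + 1]] <- b_new$tri
      assigned[b_new$tri] <- TRUE; ord <- c(ord, sort(b_new$tri))
    } else {
      clusters[[pair[1]]] <- c(clusters[[pair[1]]], clusters[[pair[2]]])
      clusters[[pair[2]]] <- integer(0)
    }
  }
  ord
}

## simulated Brownian-motion track observed with error
sim_bm_track <- function(seed, sigma2 = 0.25, n = 500, dt = 3600,
                         err = 30) {
  set.seed(seed)
  x <- cumsum(c(0, stats::rnorm(n - 1, 0, sqrt(sigma2 * dt))))
  y <- cumsum(c(0, stats::rnorm(n - 1, 0, sqrt(sigma2 * dt))))
  if (err > 0) {
    x <- x + stats::rnorm(n, 0, err)
    y <- y + stats::rnorm(n, 0, err)
  }
  hr_trajectory("bm", (0:(n - 1)) * dt, x, y, err_sd = err)
}

## two-phase Brownian track: variance jumps at the midpoint
sim_two_phase_track <- function(seed, s2_a = 0.05, s2_b = 0.5, n = 400,
                                dt = 3600, err = 20) {
  set.seed(seed)
  s2 <- rep(c(s2_a, s2_b), each = n / 2)
  x <- cumsum(c(0, stats::rnorm(n - 1, 0, sqrt(s2[-1] * dt))))
  y <- cumsum(c(0, stats::rnorm(n - 1, 0, sqrt(s2[-1] * dt))))
  hr_trajectory("tp", (0:(n - 1)) * dt,
                x + stats::rnorm(n, 0, err), y + stats::rnorm(n, 0, err),
                err_sd = err)
}

## small OU GPS trajectory for estimator smoke tests
sim_small_gps <- function(seed, days = 15, schedule = "hourly") {
  prm <- ou_params(duration_days = days)
  path <- simulate_ou(prm, seed = seed)
  observe_gps(path, schedule, seed = seed + 1000)
}

## random UD on a small grid
random_ud <- function(seed, nr = 6, nc = 5) {
  set.seed(seed)
  g <- reference_grid(cbind(c(0, nc * 100 - 1), c(0, nr * 100 - 1)),
                      grain = 100, buffer = 0)
  normalize_to_ud(cell_field(g, matrix(stats::rexp(nr * nc), nr, nc),
                             estimator = "rand"))
}
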