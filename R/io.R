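#' Write and read a cell field as an ESRI ASCII grid
#'
#' The ESRI ASCII grid format is plain text (`ncols`/`nrows`/`xllcorner`/
#' `yllcorner`/`cellsize`/`NODATA_value` header followed by rows north to
#' south), readable by every desktop GIS. `-Inf` scores are stored as NODATA.
#'
#' @param field An `hr_field` or `hr_ud`.
#' @param path Output file path.
#' @param digits Significant digits written (default 12; round-trips doubles
#'   to ~1e-12 relative).
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(field, path, digits = 12) {
  stopifnot(inherits(field, "hr_field"))
  g <- field$grid
  con <- file(path, "w")
  on.exit(close(con))
  nodata <- -9999
  writeLines(c(paste("ncols", g$ncols), paste("nrows", g$nrows),
               paste("xllcorner", format(g$x0, digits = 15)),
               paste("yllcorner", format(g$y0, digits = 15)),
               paste("cellsize", format(g$grain, digits = 15)),
               paste("NODATA_value", nodata)), con)
  s <- field$score
  s[!is.finite(s)] <- nodata
  # rows written north to south
  for (r in rev(seq_len(g$nrows)))
    writeLines(paste(format(s[r, ], digits = digits, trim = TRUE,
                            scientific = TRUE), collapse = " "), con)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @param estimator Tag attached to the field read back.
#' @export
read_ascii_grid <- function(path, estimator = "file") {
  hdr <- readLines(path, n = 6)
  kv <- strsplit(hdr, "\\s+")
  vals <- stats::setNames(vapply(kv, function(p) as.numeric(p[2]), numeric(1)),
                          vapply(kv, `[`, character(1), 1))
  grid <- structure(list(x0 = vals[["xllcorner"]], y0 = vals[["yllcorner"]],
                         grain = vals[["cellsize"]],
                         ncols = as.integer(vals[["ncols"]]),
                         nrows = as.integer(vals[["nrows"]])),
                    class = "hr_grid")
  dat <- scan(path, skip = 6, quiet = TRUE)
  s <- matrix(dat, nrow = grid$nrows, ncol = grid$ncols, byrow = TRUE)
  s <- s[rev(seq_len(grid$nrows)), , drop = FALSE]
  s[s == vals[["NODATA_value"]]] <- -Inf
  cell_field(grid, s, estimator = estimator)
}

#' Write isopleths as GeoJSON
#'
#' One feature per level, each a MultiPolygon whose counterclockwise rings are
#' shells and clockwise rings holes (assigned to the shell that contains
#' them). Coordinates are written in the projected CRS of the input.
#'
#' @param iso An `hr_isopleths` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_isopleths_geojson <- function(iso, path) {
  stopifnot(inherits(iso, "hr_isopleths"))
  features <- lapply(seq_along(iso$levels), function(i) {
    rings <- iso$polygons[[i]]
    geom <- if (!length(rings)) {
      list(type = "MultiPolygon", coordinates = list())
    } else {
      sa <- vapply(rings, ring_signed_area, numeric(1))
      shells <- which(sa > 0); holes <- which(sa < 0)
      polys <- lapply(shells, function(s) list(ring_coords(rings[[s]])))
      for (h in holes) {
        # attach hole to the smallest shell whose bbox contains it
        hb <- apply(rings[[h]], 2, range)
        cand <- shells[vapply(shells, function(s) {
          sb <- apply(rings[[s]], 2, range)
          all(sb[1, ] <= hb[1, ]) && all(sb[2, ] >= hb[2, ])
        }, logical(1))]
        if (length(cand)) {
          s <- cand[which.min(abs(sa[cand]))]
          k <- match(s, shells)
          polys[[k]] <- c(polys[[k]], list(ring_coords(rings[[h]])))
        }
      }
      list(type = "MultiPolygon", coordinates = polys)
    }
    list(type = "Feature",
         properties = list(level = iso$levels[i], area_m2 = iso$areas[i],
                           estimator = iso$estimator),
         geometry = geom)
  })
  obj <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

ring_coords <- function(ring) lapply(seq_len(nrow(ring)),
                                     function(i) c(ring[i, 1], ring[i, 2]))

#' Write a hull sequence as GeoJSON
#'
#' One polygon feature per hull (local convex hulls in union order, or
#' Delaunay triangles in area order) with `step` and `percent` (points
#' covered after that step) attributes. Degenerate hulls are skipped.
#'
#' @param hs An `hr_hullseq` from [locoh_k()] or [char_hull()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_hulls_geojson <- function(hs, path) {
  stopifnot(inherits(hs, "hr_hullseq"))
  polys <- if (!is.null(hs$hulls)) {
    hs$hulls
  } else if (!is.null(hs$triangles)) {
    lapply(seq_len(nrow(hs$triangles)), function(i)
      hs$xy_unique[hs$triangles[i, ], , drop = FALSE])
  } else {
    stop("this hull sequence does not retain polygon geometry")
  }
  keep <- which(!vapply(polys, is.null, logical(1)))
  features <- lapply(keep, function(i) {
    p <- polys[[i]]
    ring <- rbind(p, p[1, , drop = FALSE])
    list(type = "Feature",
         properties = list(step = i, percent = hs$percents[i],
                           source = hs$source),
         geometry = list(type = "Polygon",
                         coordinates = list(ring_coords(ring))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a table of AUC records or model rows as CSV
#'
#' @param x A data frame (e.g. from [auc_table()] or [model_selection()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}
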