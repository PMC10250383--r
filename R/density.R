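# Trajectory probability-density maps and extraction of high-density
# (primary settlement) areas.

#' Trajectory probability density
#'
#' Bins the recorded trajectory samples whose age falls in `age_window`
#' onto a regular grid over `bbox` (default 299 x 299 cells, ~0.14 km^2
#' per cell on a desk-scale domain) and normalises the counts to sum to 1.
#' Samples outside the bounding box are dropped with a count warning.
#'
#' Particles carrying an individual lag can be windowed per particle: with
#' `lag_extends_window = TRUE` the upper bound becomes
#' `age_window[2] + lag`, matching an analysis that follows older spat for
#' proportionally longer.
#'
#' @param traj a `trajectories` object (or a per-year list of them).
#' @param bbox `c(xmin, xmax, ymin, ymax)` in meters.
#' @param n_cells integer pair, cells per axis (default `c(299, 299)`).
#' @param age_window `c(min, max)` age window in seconds.
#' @param lag_extends_window extend the window's upper bound by each
#'   particle's lag.
#' @return Object of class `density_grid`: `prob` (nx x ny matrix summing
#'   to 1), `bbox`, `n_cells`, `cell_area_km2`, `n_samples`,
#'   `n_particles`, `empty` flag.
#' @export
trajectory_density <- function(traj, bbox, n_cells = c(299, 299),
                               age_window = c(10, 25.5) * 86400,
                               lag_extends_window = FALSE) {
  trajs <- if (inherits(traj, "trajectories")) list(traj) else traj
  n_cells <- rep(as.integer(n_cells), length.out = 2)
  cw <- (bbox[2] - bbox[1]) / n_cells[1]
  ch <- (bbox[4] - bbox[3]) / n_cells[2]
  counts <- matrix(0, n_cells[1], n_cells[2])
  n_in <- 0; n_out <- 0; n_particles <- 0
  for (tr in trajs) {
    ages <- trajectory_ages(tr)
    hi <- if (lag_extends_window) age_window[2] + tr$lag else age_window[2]
    sel <- !is.na(ages) & ages >= age_window[1] & ages <= hi
    n_particles <- n_particles + nrow(tr$x)
    if (!any(sel)) next
    xs <- tr$x[sel]; ys <- tr$y[sel]
    ix <- floor((xs - bbox[1]) / cw) + 1
    iy <- floor((ys - bbox[3]) / ch) + 1
    ok <- ix >= 1 & ix <= n_cells[1] & iy >= 1 & iy <= n_cells[2]
    n_out <- n_out + sum(!ok)
    n_in <- n_in + sum(ok)
    if (any(ok)) {
      tab <- table(factor(ix[ok], levels = seq_len(n_cells[1])),
                   factor(iy[ok], levels = seq_len(n_cells[2])))
      counts <- counts + unclass(tab)
    }
  }
  if (n_out > 0)
    warning(sprintf("%d trajectory samples outside the bounding box dropped",
                    n_out))
  empty <- n_in == 0
  prob <- if (empty) counts else counts / n_in
  out <- list(prob = prob, bbox = as.numeric(bbox), n_cells = n_cells,
              cell_area_km2 = (cw / 1000) * (ch / 1000),
              n_samples = n_in, n_particles = n_particles, empty = empty)
  class(out) <- "density_grid"
  out
}

#' Extract high-density settlement areas
#'
#' Thresholds a [trajectory_density()] grid at an expected particle
#' density (default 0.6 particles km^-2: per-cell probability times the
#' released-particle count, divided by the cell area), labels the retained
#' cells into 4-connected components, and dilates each component by a
#' buffer (default 500 m) to absorb model uncertainty. Component areas are
#' reported in km^2 using the closed-form area of a rectilinear polygon
#' dilated by a disk (cells + perimeter strips + corner terms). Components
#' whose buffers overlap are merged under the earlier label, with the
#' merged area measured by fine-grid sampling.
#'
#' @param density a `density_grid`.
#' @param threshold_per_km2 particle-density threshold, particles km^-2.
#' @param buffer_m dilation radius, m.
#' @param n_particles particle count converting probabilities to expected
#'   particle numbers (default: the count recorded in `density`).
#' @return Object of class `settlement_areas`: list `areas` of components
#'   (each `label`, `cells`, `rects`, `area_km2`), plus `buffer_m` and the
#'   thresholding parameters.
#' @export
extract_settlement_areas <- function(density, threshold_per_km2 = 0.6,
                                     buffer_m = 500, n_particles = NULL) {
  stopifnot(inherits(density, "density_grid"))
  if (is.null(n_particles)) n_particles <- density$n_particles
  dens <- density$prob * n_particles / density$cell_area_km2
  keep <- dens >= threshold_per_km2
  labels <- label_components(keep)
  nlab <- max(labels)
  bbox <- density$bbox
  cw <- (bbox[2] - bbox[1]) / density$n_cells[1]
  ch <- (bbox[4] - bbox[3]) / density$n_cells[2]
  areas <- list()
  if (nlab > 0) {
    for (l in seq_len(nlab)) {
      idx <- which(labels == l, arr.ind = TRUE)
      rects <- cbind(bbox[1] + (idx[, 1] - 1) * cw,
                     bbox[1] + idx[, 1] * cw,
                     bbox[3] + (idx[, 2] - 1) * ch,
                     bbox[3] + idx[, 2] * ch)
      colnames(rects) <- c("xmin", "xmax", "ymin", "ymax")
      areas[[l]] <- list(label = sprintf("A%02d", l), cells = idx,
                         rects = rects,
                         area_km2 = buffered_cell_area(idx, cw, ch, buffer_m))
    }
    areas <- merge_overlapping(areas, buffer_m, cw, ch)
  }
  out <- list(areas = areas, buffer_m = buffer_m,
              threshold_per_km2 = threshold_per_km2,
              n_particles = n_particles)
  class(out) <- "settlement_areas"
  out
}

#' @export
print.settlement_areas <- function(x, ...) {
  cat("settlement_areas:", length(x$areas), "area(s)\n")
  for (a in x$areas)
    cat(sprintf("  %s: %d cell(s), %.3f km2\n", a$label, nrow(a$cells),
                a$area_km2))
  invisible(x)
}

# Internal: 4-connected component labelling of a logical matrix
# (iterative flood fill; diagonal contact does not connect).
label_components <- function(keep) {
  labels <- matrix(0L, nrow(keep), ncol(keep))
  nxt <- 0L
  todo <- which(keep & labels == 0L)
  nr <- nrow(keep)
  for (start in todo) {
    if (labels[start] != 0L) next
    nxt <- nxt + 1L
    stack <- start
    while (length(stack)) {
      cur <- stack[length(stack)]
      stack <- stack[-length(stack)]
      if (labels[cur] != 0L) next
      labels[cur] <- nxt
      i <- (cur - 1L) %% nr + 1L
      j <- (cur - 1L) %/% nr + 1L
      nb <- c(if (i > 1) cur - 1L, if (i < nr) cur + 1L,
              if (j > 1) cur - nr, if (j < ncol(keep)) cur + nr)
      nb <- nb[keep[nb] & labels[nb] == 0L]
      stack <- c(stack, nb)
    }
  }
  labels
}

# Internal: area (km^2) of a 4-connected cell set dilated by a disk of
# radius r. Closed form for a rectilinear polygon: A + P*r + (pi r^2 / 4)
# per convex corner - r^2 per reflex corner, counted from 2x2 windows of
# the padded cell raster. Exact while r stays below half the minimum
# feature separation (diagonal cell contacts are approximated as two
# convex corners).
buffered_cell_area <- function(idx, cw, ch, r) {
  i0 <- min(idx[, 1]); j0 <- min(idx[, 2])
  m <- matrix(FALSE, max(idx[, 1]) - i0 + 3, max(idx[, 2]) - j0 + 3)
  m[cbind(idx[, 1] - i0 + 2, idx[, 2] - j0 + 2)] <- TRUE
  A <- nrow(idx) * cw * ch
  # perimeter: exposed cell edges
  P <- 0
  P <- P + sum(m[-1, ] & !m[-nrow(m), ]) * ch + sum(!m[-1, ] & m[-nrow(m), ]) * ch
  P <- P + sum(m[, -1] & !m[, -ncol(m)]) * cw + sum(!m[, -1] & m[, -ncol(m)]) * cw
  # corners from 2x2 windows
  s <- m[-nrow(m), -ncol(m)] + m[-1, -ncol(m)] + m[-nrow(m), -1] + m[-1, -1]
  diagpair <- (m[-nrow(m), -ncol(m)] & m[-1, -1] & !m[-1, -ncol(m)] & !m[-nrow(m), -1]) |
    (!m[-nrow(m), -ncol(m)] & !m[-1, -1] & m[-1, -ncol(m)] & m[-nrow(m), -1])
  n_convex <- sum(s == 1) + 2 * sum(diagpair)
  n_reflex <- sum(s == 3)
  (A + P * r + n_convex * pi * r^2 / 4 - n_reflex * r^2) / 1e6
}

# Internal: merge components whose buffered outlines overlap; the merged
# component keeps the earlier label and its area is measured numerically.
merge_overlapping <- function(areas, r, cw, ch) {
  n <- length(areas)
  if (n < 2) return(areas)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  closer_than <- function(ra, rb, thr) {
    # bounding-box lower bound first; exact cell-to-cell scan only if needed
    bdx <- max(min(ra[, 1]) - max(rb[, 2]), min(rb[, 1]) - max(ra[, 2]), 0)
    bdy <- max(min(ra[, 3]) - max(rb[, 4]), min(rb[, 3]) - max(ra[, 4]), 0)
    if (sqrt(bdx^2 + bdy^2) >= thr) return(FALSE)
    for (a in seq_len(nrow(ra))) {
      ddx <- pmax(ra[a, 1] - rb[, 2], rb[, 1] - ra[a, 2], 0)
      ddy <- pmax(ra[a, 3] - rb[, 4], rb[, 3] - ra[a, 4], 0)
      if (min(ddx^2 + ddy^2) < thr^2) return(TRUE)
    }
    FALSE
  }
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (closer_than(areas[[i]]$rects, areas[[j]]$rects, 2 * r)) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  out <- list()
  for (rt in unique(roots)) {
    members <- which(roots == rt)
    if (length(members) == 1) {
      out[[length(out) + 1L]] <- areas[[members]]
    } else {
      cells <- do.call(rbind, lapply(areas[members], `[[`, "cells"))
      rects <- do.call(rbind, lapply(areas[members], `[[`, "rects"))
      out[[length(out) + 1L]] <- list(
        label = areas[[members[1]]]$label, cells = cells, rects = rects,
        area_km2 = sampled_buffer_area(rects, r))
    }
  }
  out
}

# Internal: numeric area of the union of rectangles dilated by r
# (midpoint sampling at ~r/20 resolution, capped at a 500 x 500 grid for
# very large merged components).
sampled_buffer_area <- function(rects, r) {
  ext <- max(max(rects[, 2]) - min(rects[, 1]),
             max(rects[, 4]) - min(rects[, 3])) + 2 * r
  step <- max(r / 20, ext / 500, 1)
  xs <- seq(min(rects[, 1]) - r, max(rects[, 2]) + r, by = step)
  ys <- seq(min(rects[, 3]) - r, max(rects[, 4]) + r, by = step)
  gx <- rep(xs, times = length(ys))
  gy <- rep(ys, each = length(xs))
  inside <- rep(FALSE, length(gx))
  for (a in seq_len(nrow(rects))) {
    ddx <- pmax(rects[a, 1] - gx, gx - rects[a, 2], 0)
    ddy <- pmax(rects[a, 3] - gy, gy - rects[a, 4], 0)
    inside <- inside | (ddx^2 + ddy^2 <= r^2)
  }
  sum(inside) * step^2 / 1e6
}

#' Write settlement areas as GeoJSON
#'
#' Each area becomes a MultiPolygon of its member cells, with properties
#' `label`, `area_km2` (buffered) and `buffer_m`.
#'
#' @param areas a `settlement_areas` object.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_settlement_areas <- function(areas, path) {
  feats <- lapply(areas$areas, function(a) {
    polys <- lapply(seq_len(nrow(a$rects)), function(i) {
      rc <- a$rects[i, ]
      list(list(c(rc[1], rc[3]), c(rc[2], rc[3]),
                c(rc[2], rc[4]), c(rc[1], rc[4]), c(rc[1], rc[3])))
    })
    list(type = "Feature",
         properties = list(label = a$label, area_km2 = a$area_km2,
                           buffer_m = areas$buffer_m),
         geometry = list(type = "MultiPolygon", coordinates = polys))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
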