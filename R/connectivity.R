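# Connectivity matrices (primary, secondary, total), dispersal kernels and
# the EOF decomposition of inter-annual variability.

#' Connectivity matrix from settlement records
#'
#' `values[source, sink]` is the fraction of particles released from
#' `source` that settled at `sink` (settler count divided by the source's
#' total release); the diagonal is local retention. Rows are sources,
#' columns sinks. The sink set may differ from the source set (e.g. sites
#' as sources, primary settlement areas as sinks), giving the rectangular
#' matrices from which secondary connectivity is assembled.
#'
#' @param records settlement records (columns `source_id`, `status`,
#'   `settle_target_id`).
#' @param source_ids,sink_ids row / column identities.
#' @param released named vector: particles released per source (defaults
#'   to the per-source record counts).
#' @param kind `"primary"`, `"secondary"` or `"total"` (metadata).
#' @return A `connectivity_matrix` (numeric matrix with dimnames and
#'   attributes `kind` and `released`).
#' @export
connectivity_matrix <- function(records, source_ids, sink_ids = source_ids,
                                released = NULL, kind = "primary") {
  if (is.null(released)) {
    tab <- table(records$source_id)
    released <- stats::setNames(as.numeric(tab), names(tab))
  }
  if (any(!records$source_id %in% source_ids))
    stop("data error: unknown source id: ",
         setdiff(unique(records$source_id), source_ids)[1])
  st <- records[records$status == "settled", ]
  if (nrow(st) && any(!st$settle_target_id %in% sink_ids))
    stop("data error: unknown sink id: ",
         setdiff(unique(st$settle_target_id), sink_ids)[1])
  m <- matrix(0, length(source_ids), length(sink_ids),
              dimnames = list(source_ids, sink_ids))
  if (nrow(st)) {
    tab <- table(factor(st$source_id, levels = source_ids),
                 factor(st$settle_target_id, levels = sink_ids))
    m <- unclass(tab) * 1
  }
  rel <- stats::setNames(rep(0, length(source_ids)), source_ids)
  rel[names(released)] <- released
  nz <- rel > 0
  m[nz, ] <- m[nz, , drop = FALSE] / rel[nz]
  structure(m, kind = kind, released = rel, class = c("connectivity_matrix", "matrix"))
}

#' Connectivity matrices from an experiment result
#'
#' Convenience wrapper around [connectivity_matrix()] for
#' [run_experiment()] output: restricts settlement to the requested sink
#' set (e.g. the 49 sites, or the primary settlement areas — settlers on
#' other targets count as unsettled for that matrix) and optionally returns
#' one matrix per year, release counts taken from the per-year records.
#'
#' @param result an `experiment_result`.
#' @param sink_ids sink identity set (default: the source set).
#' @param source_ids source identity set (default: the scenario's site ids
#'   when releasing from sites, else the ids present in the records).
#' @param yearly return a list of per-year matrices instead of one pooled
#'   matrix.
#' @param kind metadata label, see [connectivity_matrix()].
#' @return A `connectivity_matrix`, or a named list of them (`yearly = TRUE`).
#' @export
connectivity_from_experiment <- function(result, sink_ids = NULL,
                                         source_ids = NULL, yearly = FALSE,
                                         kind = "primary") {
  rec <- result$records
  if (is.null(source_ids)) {
    source_ids <- if (result$config$release_area == "sites" &&
                        !is.null(result$scenario$sites))
      result$scenario$sites$site_id
    else sort(unique(rec$source_id))
  }
  if (is.null(sink_ids)) sink_ids <- source_ids
  out <- rec$status == "settled" & !(rec$settle_target_id %in% sink_ids)
  rec$status[out] <- "expired"
  rec$settle_target_id[out] <- NA_character_
  one <- function(r) {
    tab <- table(factor(r$source_id, levels = source_ids))
    connectivity_matrix(r, source_ids, sink_ids,
                        released = stats::setNames(as.numeric(tab),
                                                   source_ids),
                        kind = kind)
  }
  if (yearly) lapply(split(rec, rec$year), one) else one(rec)
}

#' Average yearly connectivity matrices
#'
#' Element-wise mean over years (the decadal regional matrix when applied
#' to ten yearly matrices).
#'
#' @param yearly list of `connectivity_matrix` with identical dimnames.
#' @return The averaged `connectivity_matrix`.
#' @export
average_matrices <- function(yearly) {
  stopifnot(length(yearly) >= 1)
  d <- dim(yearly[[1]])
  for (m in yearly)
    if (!identical(dim(m), d) || !identical(dimnames(m), dimnames(yearly[[1]])))
      stop("invalid argument: matrices must share dimensions and ids")
  out <- Reduce(`+`, lapply(yearly, unclass)) / length(yearly)
  rel <- Reduce(`+`, lapply(yearly, attr, "released")) / length(yearly)
  structure(out, kind = attr(yearly[[1]], "kind"), released = rel,
            years = length(yearly),
            class = c("connectivity_matrix", "matrix"))
}

#' Secondary and total connectivity
#'
#' Secondary connectivity is the product of two rectangular matrices: the
#' site-to-primary-area matrix of the larval (forward) run and the
#' area-to-site matrix of the spat run — site-to-site transport via the
#' primary settlement areas. Total connectivity is the element-wise sum of
#' the primary and secondary matrices.
#'
#' @param sites_to_areas `n_sites x n_areas` connectivity matrix.
#' @param areas_to_sites `n_areas x n_sites` connectivity matrix.
#' @return `secondary_connectivity()`: their product (kind
#'   `"secondary"`); `total_connectivity()`: the sum (kind `"total"`).
#' @export
secondary_connectivity <- function(sites_to_areas, areas_to_sites) {
  if (ncol(sites_to_areas) != nrow(areas_to_sites))
    stop("invalid argument: inner (primary-area) dimensions do not match")
  out <- unclass(sites_to_areas) %*% unclass(areas_to_sites)
  structure(out, kind = "secondary",
            released = attr(sites_to_areas, "released"),
            class = c("connectivity_matrix", "matrix"))
}

#' @rdname secondary_connectivity
#' @param primary,secondary site-to-site matrices of identical shape.
#' @export
total_connectivity <- function(primary, secondary) {
  if (!identical(dim(primary), dim(secondary)))
    stop("invalid argument: dimension mismatch")
  structure(unclass(primary) + unclass(secondary), kind = "total",
            released = attr(primary, "released"),
            class = c("connectivity_matrix", "matrix"))
}

#' Dispersal kernel
#'
#' Distribution of settlement probability with straight-line (Euclidean)
#' distance from the release point: per-bin settled proportion relative to
#' all releases of the group, so the kernel mass equals the group's total
#' settlement fraction.
#'
#' `dispersal_kernel()` works from individual settlement records;
#' `kernel_from_matrix()` from a connectivity matrix and site centroids
#' (release-weighted), which is how kernels are segregated by
#' primary/secondary/total connectivity.
#'
#' @param records settlement records with release and settlement positions.
#' @param n_released total releases of the group (default `nrow(records)`).
#' @param bin_km bin width, km.
#' @param group label carried into the result.
#' @return Object of class `dispersal_kernel`: `breaks_km`, `proportion`,
#'   `group`, `total_fraction`.
#' @export
dispersal_kernel <- function(records, n_released = nrow(records),
                             bin_km = 20, group = "all") {
  st <- records[records$status == "settled", ]
  dist_km <- if (nrow(st)) {
    sqrt((st$settle_x - st$release_x)^2 +
           (st$settle_y - st$release_y)^2) / 1000
  } else numeric(0)
  kernel_from_distances(dist_km, rep(1, length(dist_km)), n_released,
                        bin_km, group)
}

#' @rdname dispersal_kernel
#' @param C a `connectivity_matrix`.
#' @param source_xy,sink_xy two-column centroid matrices with rownames
#'   matching the matrix dimnames.
#' @param released per-source release counts (default: the matrix's
#'   `released` attribute, else equal weights).
#' @export
kernel_from_matrix <- function(C, source_xy, sink_xy = source_xy,
                               released = NULL, bin_km = 20, group = "all") {
  if (is.null(released)) released <- attr(C, "released")
  if (is.null(released)) released <- stats::setNames(rep(1, nrow(C)), rownames(C))
  released <- released[rownames(C)]
  d <- outer(seq_len(nrow(C)), seq_len(ncol(C)), function(i, j) {
    sqrt((source_xy[rownames(C)[i], 1] - sink_xy[colnames(C)[j], 1])^2 +
           (source_xy[rownames(C)[i], 2] - sink_xy[colnames(C)[j], 2])^2)
  }) / 1000
  w <- unclass(C) * as.numeric(released)
  kernel_from_distances(as.numeric(d), as.numeric(w), sum(released),
                        bin_km, group)
}

kernel_from_distances <- function(dist_km, weight, n_released, bin_km, group) {
  keep <- weight > 0
  dist_km <- dist_km[keep]; weight <- weight[keep]
  n_bins <- max(1, ceiling(max(dist_km, bin_km / 2) / bin_km + 1e-9))
  breaks <- seq(0, n_bins * bin_km, by = bin_km)
  prop <- numeric(n_bins)
  if (length(dist_km)) {
    bi <- pmin(floor(dist_km / bin_km) + 1, n_bins)
    prop <- as.numeric(tapply(weight, factor(bi, levels = seq_len(n_bins)), sum))
    prop[is.na(prop)] <- 0
    prop <- prop / n_released
  }
  out <- list(breaks_km = breaks, proportion = prop, group = group,
              total_fraction = sum(prop))
  class(out) <- "dispersal_kernel"
  out
}

#' Kernel summary statistics
#'
#' Mode bin and distance quantiles (linear within bins) of a
#' [dispersal_kernel()], relative to its own settled mass.
#'
#' @param kernel a `dispersal_kernel`.
#' @param q quantile level (e.g. 0.95).
#' @return `kernel_mode_km`: midpoint of the most-massive bin;
#'   `kernel_quantile_km`: the `q` distance quantile in km.
#' @export
kernel_mode_km <- function(kernel) {
  i <- which.max(kernel$proportion)
  (kernel$breaks_km[i] + kernel$breaks_km[i + 1]) / 2
}

#' @rdname kernel_mode_km
#' @export
kernel_quantile_km <- function(kernel, q = 0.95) {
  if (kernel$total_fraction <= 0) return(NA_real_)
  cum <- cumsum(kernel$proportion) / kernel$total_fraction
  i <- which(cum >= q)[1]
  lo <- if (i == 1) 0 else cum[i - 1]
  frac <- (q - lo) / (cum[i] - lo)
  kernel$breaks_km[i] + frac * diff(kernel$breaks_km[i:(i + 1)])
}

#' EOF decomposition of inter-annual connectivity variance
#'
#' Flattens each yearly matrix to a vector, removes the across-year mean,
#' and decomposes the anomaly stack by SVD. Modes are returned in matrix
#' form with their explained-variance fractions (singular values squared
#' over total). Identical years (zero variance) yield an empty mode list
#' flagged `degenerate`.
#'
#' @param yearly list of >= 2 `connectivity_matrix` objects.
#' @return List: `modes` (list of matrices), `variance_fraction`,
#'   `amplitudes` (years x modes), `degenerate`.
#' @export
eof_interannual <- function(yearly) {
  if (length(yearly) < 2)
    stop("invalid argument: need at least two years")
  d <- dim(yearly[[1]])
  X <- do.call(rbind, lapply(yearly, function(m) as.numeric(unclass(m))))
  anom <- sweep(X, 2, colMeans(X))
  tot <- sum(anom^2)
  if (tot < 1e-300)
    return(list(modes = list(), variance_fraction = numeric(0),
                amplitudes = matrix(0, length(yearly), 0), degenerate = TRUE))
  sv <- svd(anom)
  keep <- which(sv$d^2 / tot > 1e-12)
  modes <- lapply(keep, function(k) matrix(sv$v[, k], d[1], d[2],
                                           dimnames = dimnames(yearly[[1]])))
  list(modes = modes,
       variance_fraction = sv$d[keep]^2 / sum(sv$d^2),
       amplitudes = sv$u[, keep, drop = FALSE] %*% diag(sv$d[keep], length(keep)),
       degenerate = FALSE)
}

#' Write a connectivity matrix to CSV
#'
#' @param C a `connectivity_matrix`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_connectivity_csv <- function(C, path) {
  utils::write.csv(as.data.frame(unclass(C)), path, row.names = TRUE)
  invisible(path)
}
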