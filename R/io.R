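#' Write / read a flow field
#'
#' Serialises a [flow_field()] to the package's plain-text exchange format:
#' a header with the grid geometry (dims `time, z, y, x`, SI units), then one
#' block per variable (`mask`, `bathymetry`, `u`, `v`, `w`), values in x-fastest
#' order at full `%.17g` precision so `read_flow(write_flow(f))` reproduces
#' `f` to floating-point identity.
#'
#' @param field a `flow_field`.
#' @param path file path.
#' @return `write_flow` returns `path` invisibly; `read_flow` a `flow_field`.
#' @export
write_flow <- function(field, path) {
  g <- field$grid
  num <- function(x) paste(sprintf("%.17g", as.numeric(x)), collapse = " ")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "musselflow_flow 1",
    sprintf("dims nx %d ny %d nz %d nt %d", g$nx, g$ny, length(g$z_levels), g$nt),
    paste("origin", num(c(g$x_origin, g$y_origin))),
    paste("resolution", num(c(g$dx, g$dy))),
    paste("z_levels", num(g$z_levels)),
    paste("time_axis", num(c(g$t0, g$dt_field))),
    "units x m y m z m time s velocity m.s-1"
  ), con)
  wv <- function(name, x) writeLines(c(paste("var", name), num(x)), con)
  wv("mask", as.integer(field$mask))
  wv("bathymetry", field$bathymetry)
  wv("u", field$u); wv("v", field$v); wv("w", field$w)
  invisible(path)
}

#' @rdname write_flow
#' @export
read_flow <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 7 || !startsWith(lines[1], "musselflow_flow"))
    stop("format error: not a musselflow flow file")
  fields <- strsplit(lines, " +")
  key <- vapply(fields, `[[`, "", 1)
  get_line <- function(k) {
    i <- which(key == k)
    if (length(i) != 1) stop("format error: missing dimension line '", k, "'")
    as.numeric(fields[[i]][-1])
  }
  di <- which(key == "dims")
  if (length(di) != 1) stop("format error: missing dimension line 'dims'")
  dl <- fields[[di]]
  dims <- as.numeric(dl[c(3, 5, 7, 9)])
  names(dims) <- dl[c(2, 4, 6, 8)]
  if (!identical(names(dims), c("nx", "ny", "nz", "nt")) || any(is.na(dims)))
    stop("format error: malformed dims line")
  dims <- unname(dims)
  origin <- get_line("origin")
  res <- get_line("resolution")
  z <- get_line("z_levels")
  ta <- get_line("time_axis")
  if (length(z) != dims[3]) stop("format error: z_levels length mismatch")
  grid <- build_grid(c(dims[1] * res[1], dims[2] * res[2]), res, z,
                     t0 = ta[1], dt_field = ta[2], nt = dims[4],
                     origin = origin)
  vars <- list()
  vi <- which(key == "var")
  for (i in vi) {
    nm <- fields[[i]][2]
    vars[[nm]] <- as.numeric(fields[[i + 1]])
  }
  for (nm in c("mask", "bathymetry", "u", "v", "w"))
    if (is.null(vars[[nm]])) stop("format error: missing variable ", nm)
  nxy <- dims[1] * dims[2]
  n4 <- nxy * dims[3] * dims[4]
  for (nm in c("u", "v", "w"))
    if (length(vars[[nm]]) != n4)
      stop("format error: variable ", nm, " has wrong length")
  flow_field(grid,
             array(vars$u, dims), array(vars$v, dims), array(vars$w, dims),
             mask = matrix(vars$mask != 0, dims[1], dims[2]),
             bathymetry = matrix(vars$bathymetry, dims[1], dims[2]))
}

#' Write / read habitat sites as GeoJSON
#'
#' Habitat sites are exchanged as a GeoJSON FeatureCollection of square
#' polygons in the local projected plane (meters), with properties
#' `site_id`, `population_id` and `area_km2`.
#'
#' @param sites a `habitat_sites` frame ([generate_habitat()]).
#' @param path file path.
#' @return `write_habitat` returns `path` invisibly; `read_habitat` a
#'   `habitat_sites` frame.
#' @export
write_habitat <- function(sites, path) {
  feats <- lapply(seq_len(nrow(sites)), function(i) {
    s <- sites[i, ]
    ring <- list(
      c(s$xmin, s$ymin), c(s$xmax, s$ymin),
      c(s$xmax, s$ymax), c(s$xmin, s$ymax), c(s$xmin, s$ymin)
    )
    list(
      type = "Feature",
      properties = list(site_id = s$site_id,
                        population_id = s$population_id,
                        area_km2 = s$area_km2),
      geometry = list(type = "Polygon", coordinates = list(ring))
    )
  })
  fc <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_habitat
#' @export
read_habitat <- function(path) {
  fc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(fc$type) || fc$type != "FeatureCollection")
    stop("format error: expected a GeoJSON FeatureCollection")
  rows <- lapply(fc$features, function(f) {
    ring <- f$geometry$coordinates[[1]]
    xs <- vapply(ring, function(p) as.numeric(p[[1]]), numeric(1))
    ys <- vapply(ring, function(p) as.numeric(p[[2]]), numeric(1))
    data.frame(site_id = f$properties$site_id,
               population_id = f$properties$population_id,
               xmin = min(xs), xmax = max(xs),
               ymin = min(ys), ymax = max(ys),
               area_km2 = as.numeric(f$properties$area_km2),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("habitat_sites", "data.frame")
  out
}

#' Read a scenario configuration from YAML
#'
#' Reads a structured text (YAML) file whose keys mirror the arguments of
#' [coastal_config()] and returns the corresponding `scenario_config`.
#' Unknown keys raise an error naming them.
#'
#' @param path YAML file path.
#' @return A `scenario_config`.
#' @export
read_scenario_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(coastal_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("invalid argument: unknown scenario keys: ", paste(bad, collapse = ", "))
  for (nm in intersect(names(vals), c("extent", "resolution", "z_levels", "gap_y")))
    vals[[nm]] <- as.numeric(unlist(vals[[nm]]))
  do.call(coastal_config, vals)
}

#' Read a pairwise F_ST matrix
#'
#' Square CSV with a population-id header row and first column. The matrix
#' is validated as symmetric with a zero diagonal; small negative estimates
#' (a common artefact of unbiased F_ST estimators) are clamped to 0 with a
#' warning.
#'
#' @param path CSV file path.
#' @return A symmetric numeric matrix with population-id dimnames.
#' @export
read_fst_matrix <- function(path) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(df)
  if (nrow(m) != ncol(m) || any(rownames(m) != colnames(m)))
    stop("format error: F_ST matrix must be square with matching ids")
  if (max(abs(m - t(m))) > 1e-8)
    stop("format error: F_ST matrix must be symmetric")
  m <- (m + t(m)) / 2
  diag(m) <- 0
  if (any(m < 0)) {
    warning("negative F_ST estimates clamped to 0")
    m[m < 0] <- 0
  }
  m
}
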