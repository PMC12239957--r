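#' Parameters for the synthetic climate landscape
#'
#' Describes a regular lon/lat grid (WGS84 decimal degrees, rows addressed
#' from the northern edge) carrying one or more climate variables, each a
#' smooth spatial gradient plus noise, and future scenarios obtained by
#' shifting the present layers.
#'
#' @param grid_extent named vector `lon_min, lon_max, lat_min, lat_max`.
#' @param grid_resolution cell size in degrees (> 0).
#' @param variables character vector of variable names; the first is the
#'   focal clinal variable.
#' @param cline_axis `"lon"` or `"lat"`: axis of the main gradient.
#' @param future_shift named list: per scenario, a named numeric vector of
#'   per-variable additive shifts (variables missing from the vector shift
#'   by 0).
#' @param gradient_range total change of the focal variable across the cline
#'   axis (units of the variable).
#' @param noise_sd standard deviation of the smooth spatial noise field.
#' @param n_causal_loci default causal-locus count used by cline embedding.
#' @param cline_steepness default logistic steepness for cline embedding.
#' @param seed RNG seed for the noise fields.
#' @return an object of class `landscape_params`.
#' @export
landscape_params <- function(grid_extent = c(lon_min = 100, lon_max = 110,
                                             lat_min = 25, lat_max = 35),
                             grid_resolution = 0.5,
                             variables = c("BIO7", "BIO15"),
                             cline_axis = "lon",
                             future_shift = list(ssp126 = c(BIO7 = 1),
                                                 ssp585 = c(BIO7 = 2.5)),
                             gradient_range = 10,
                             noise_sd = 0.5,
                             n_causal_loci = 20,
                             cline_steepness = 2,
                             seed = 1L) {
  if (grid_resolution <= 0) stop("grid_resolution must be > 0")
  if (grid_extent["lon_max"] <= grid_extent["lon_min"] ||
      grid_extent["lat_max"] <= grid_extent["lat_min"])
    stop("degenerate grid extent")
  if (!cline_axis %in% c("lon", "lat")) stop("cline_axis must be lon or lat")
  structure(list(grid_extent = grid_extent,
                 grid_resolution = grid_resolution,
                 variables = variables, cline_axis = cline_axis,
                 future_shift = future_shift,
                 gradient_range = gradient_range, noise_sd = noise_sd,
                 n_causal_loci = n_causal_loci,
                 cline_steepness = cline_steepness,
                 seed = as.integer(seed)),
            class = "landscape_params")
}

# smooth random surface on [0,1]^2 grid coordinates: low-order Fourier mix
.smooth_noise <- function(u, v, sd) {
  z <- matrix(0, length(v), length(u))
  for (k in 1:3) {
    a <- stats::rnorm(4)
    z <- z + outer(sin(2 * pi * (k * v + a[1])), sin(2 * pi * (k * u + a[2]))) * a[3] / k +
      outer(cos(2 * pi * (k * v + a[4])), cos(2 * pi * (k * u + a[1]))) * a[2] / k
  }
  if (stats::sd(z) > 0) z <- z / stats::sd(z)
  z * sd
}

.new_climate_grid <- function(lon, lat, layers, scenario) {
  structure(list(lon = lon, lat = lat, layers = layers, scenario = scenario),
            class = "climate_grid")
}

#' @export
print.climate_grid <- function(x, ...) {
  cat("climate_grid [", x$scenario, "]: ", length(x$lat), " x ", length(x$lon),
      " cells, variables: ", paste(names(x$layers), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' Simulate present and future climate layers on a regular grid
#'
#' Each variable is a linear gradient along the cline axis plus a smooth
#' seeded noise field; future scenarios add the configured per-variable shift
#' to the present layer (identical geometry). Optionally extracts per-sample
#' environmental values by bilinear interpolation.
#'
#' @param params a [landscape_params()] object.
#' @param samples optional data.frame with `lon`, `lat` columns; when given,
#'   the returned list carries an `env` matrix (samples x variables).
#' @return list of class `climate_layer_set`: `present` (a `climate_grid`),
#'   `futures` (named list of `climate_grid`), and optionally `env`.
#' @export
simulate_landscape <- function(params, samples = NULL) {
  stopifnot(inherits(params, "landscape_params"))
  set.seed(params$seed)
  ex <- params$grid_extent
  res <- params$grid_resolution
  lon <- seq(ex["lon_min"] + res / 2, ex["lon_max"] - res / 2, by = res)
  lat <- rev(seq(ex["lat_min"] + res / 2, ex["lat_max"] - res / 2, by = res))
  u <- (lon - ex["lon_min"]) / (ex["lon_max"] - ex["lon_min"])
  v <- (lat - ex["lat_min"]) / (ex["lat_max"] - ex["lat_min"])
  layers <- list()
  for (j in seq_along(params$variables)) {
    # first variable climbs along the cline axis; the rest get a weak
    # gradient along the other axis so they are mostly noise
    along_lon <- (params$cline_axis == "lon") == (j == 1)
    grad <- if (along_lon) outer(rep(1, length(lat)), u)
      else outer(v, rep(1, length(lon)))
    if (j > 1) grad <- grad * 0.3
    base <- 10 * j + params$gradient_range * grad
    layers[[params$variables[j]]] <-
      base + .smooth_noise(u, v, params$noise_sd)
  }
  present <- .new_climate_grid(lon, lat, layers, "present")
  futures <- lapply(names(params$future_shift), function(sc) {
    sh <- params$future_shift[[sc]]
    ly <- lapply(names(layers), function(nm) {
      d <- if (nm %in% names(sh)) sh[[nm]] else 0
      layers[[nm]] + d
    })
    names(ly) <- names(layers)
    .new_climate_grid(lon, lat, ly, sc)
  })
  names(futures) <- names(params$future_shift)
  out <- list(present = present, futures = futures, params = params)
  if (!is.null(samples))
    out$env <- extract_env(present, samples$lon, samples$lat)
  structure(out, class = "climate_layer_set")
}

#' Extract environmental values at point coordinates
#'
#' Bilinear interpolation of every layer of a climate grid at the given
#' lon/lat points. Points outside the grid extent are an error.
#'
#' @param grid a `climate_grid`.
#' @param lon,lat numeric vectors of point coordinates (decimal degrees).
#' @return numeric matrix, points x variables.
#' @export
extract_env <- function(grid, lon, lat) {
  stopifnot(inherits(grid, "climate_grid"), length(lon) == length(lat))
  res_lon <- abs(diff(grid$lon[1:2]))
  res_lat <- abs(diff(grid$lat[1:2]))
  lo_min <- min(grid$lon) - res_lon / 2
  lo_max <- max(grid$lon) + res_lon / 2
  la_min <- min(grid$lat) - res_lat / 2
  la_max <- max(grid$lat) + res_lat / 2
  bad <- lon < lo_min | lon > lo_max | lat < la_min | lat > la_max
  if (any(bad))
    stop("sample coordinates outside grid extent: point(s) ",
         paste(which(bad), collapse = ", "))
  lon_asc <- grid$lon
  lat_asc <- rev(grid$lat)              # ascending for interpolation
  out <- matrix(NA_real_, length(lon), length(grid$layers),
                dimnames = list(NULL, names(grid$layers)))
  ix <- pmin(pmax(findInterval(lon, lon_asc), 1L), length(lon_asc) - 1L)
  iy <- pmin(pmax(findInterval(lat, lat_asc), 1L), length(lat_asc) - 1L)
  tx <- pmin(pmax((lon - lon_asc[ix]) / (lon_asc[ix + 1] - lon_asc[ix]), 0), 1)
  ty <- pmin(pmax((lat - lat_asc[iy]) / (lat_asc[iy + 1] - lat_asc[iy]), 0), 1)
  nlat <- length(grid$lat)
  for (nm in names(grid$layers)) {
    z <- grid$layers[[nm]]
    r1 <- nlat - iy + 1L                # row of lat_asc[iy] (south)
    r2 <- nlat - iy                     # row of lat_asc[iy+1] (north)
    z11 <- z[cbind(r1, ix)]; z21 <- z[cbind(r1, ix + 1L)]
    z12 <- z[cbind(r2, ix)]; z22 <- z[cbind(r2, ix + 1L)]
    out[, nm] <- (1 - tx) * (1 - ty) * z11 + tx * (1 - ty) * z21 +
      (1 - tx) * ty * z12 + tx * ty * z22
  }
  out
}

#' Cell-centre coordinates of a climate grid
#'
#' @param grid a `climate_grid`.
#' @return data.frame with `lon`, `lat` for every cell, in row-major order
#'   (row 1 = northernmost row), matching `as.vector(t(layer))` ordering used
#'   by the offset maps.
#' @export
grid_coords <- function(grid) {
  data.frame(lon = rep(grid$lon, times = length(grid$lat)),
             lat = rep(grid$lat, each = length(grid$lon)))
}

#' Simulate occurrence records from a Gaussian climatic niche
#'
#' Defines true habitat suitability as a Gaussian response to the focal
#' climate variable (optimum and niche breadth in the variable's units) and
#' samples occurrence points from grid cells with probability proportional
#' to suitability, jittered within the cell. This gives the
#' presence/background stage a climatically structured species to recover.
#'
#' @param grid a `climate_grid` (present climate).
#' @param n number of occurrence records.
#' @param variable focal variable (defaults to the first layer).
#' @param optimum niche optimum; default the 35% quantile of the layer.
#' @param breadth Gaussian niche SD; default 12% of the layer's range.
#' @param seed RNG seed.
#' @return data.frame with `lon`, `lat` and attribute `suitability_truth`
#'   (the per-cell true suitability, grid layout).
#' @export
simulate_occurrences <- function(grid, n = 400, variable = NULL,
                                 optimum = NULL, breadth = NULL, seed = 1L) {
  stopifnot(inherits(grid, "climate_grid"))
  set.seed(seed)
  if (is.null(variable)) variable <- names(grid$layers)[1]
  z <- grid$layers[[variable]]
  if (is.null(optimum)) optimum <- stats::quantile(z, 0.35, names = FALSE)
  if (is.null(breadth)) breadth <- 0.12 * diff(range(z))
  suit <- exp(-0.5 * ((z - optimum) / breadth)^2)
  cells <- grid_coords(grid)
  w <- as.vector(t(suit))
  idx <- sample.int(nrow(cells), n, replace = TRUE, prob = w)
  res <- abs(diff(grid$lon[1:2]))
  occ <- data.frame(
    lon = cells$lon[idx] + stats::runif(n, -res / 2, res / 2),
    lat = cells$lat[idx] + stats::runif(n, -res / 2, res / 2))
  attr(occ, "suitability_truth") <- suit
  attr(occ, "optimum") <- optimum
  attr(occ, "breadth") <- breadth
  occ
}

#' Write one climate layer in the CSV-grid dialect
#'
#' Plain-text raster: a 6-line header (`ncols`, `nrows`, `xllcorner`,
#' `yllcorner`, `cellsize`, `nodata_value`) followed by one row of values per
#' grid row, north to south.
#'
#' @param grid a `climate_grid`.
#' @param variable layer name.
#' @param file output path.
#' @param nodata value written for NA cells.
#' @export
write_csv_grid <- function(grid, variable, file, nodata = -9999) {
  z <- grid$layers[[variable]]
  if (is.null(z)) stop("no layer named ", variable)
  res <- abs(diff(grid$lon[1:2]))
  hdr <- c(paste("ncols", ncol(z)), paste("nrows", nrow(z)),
           paste("xllcorner", min(grid$lon) - res / 2),
           paste("yllcorner", min(grid$lat) - res / 2),
           paste("cellsize", res), paste("nodata_value", nodata))
  z[is.na(z)] <- nodata
  body <- apply(z, 1, paste, collapse = " ")
  writeLines(c(hdr, body), file)
}

#' Read a CSV-grid file back into a single-layer climate grid
#'
#' @param file path written by [write_csv_grid()].
#' @param variable layer name to assign.
#' @param scenario scenario tag.
#' @return a `climate_grid` with one layer.
#' @export
read_csv_grid <- function(file, variable = "layer", scenario = "present") {
  lines <- readLines(file)
  hdr <- strsplit(trimws(lines[1:6]), "\\s+")
  vals <- stats::setNames(as.numeric(vapply(hdr, `[`, "", 2)),
                          tolower(vapply(hdr, `[`, "", 1)))
  z <- do.call(rbind, lapply(lines[-(1:6)], function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
  z[z == vals["nodata_value"]] <- NA
  res <- vals["cellsize"]
  lon <- vals["xllcorner"] + res / 2 + res * (seq_len(vals["ncols"]) - 1)
  lat <- rev(vals["yllcorner"] + res / 2 + res * (seq_len(vals["nrows"]) - 1))
  .new_climate_grid(lon, lat, stats::setNames(list(z), variable), scenario)
}
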