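# Spatial containers and IO: daily temperature cubes (NetCDF), quarter-degree
# grid cells, seagrass polygons, EEZ maps, and score-map serialization.

#' Construct a daily temperature cube
#'
#' The in-memory container for gridded daily sea temperature. Values are
#' stored in degrees Celsius on a regular lon/lat pixel grid defined by its
#' edges (pixel registration by edges, WGS84 lon/lat). Missing values are NA.
#'
#' @param lon_edges,lat_edges ascending numeric vectors of pixel edges
#'   (length = number of pixels + 1)
#' @param dates `Date` vector, strictly increasing with a daily step
#' @param values numeric array of dim (days, lat pixels, lon pixels), degrees C
#' @param crs_tag coordinate reference tag, informational
#' @return an object of class `raster_cube`
#' @export
raster_cube <- function(lon_edges, lat_edges, dates, values, crs_tag = "WGS84") {
  lon_edges <- as.numeric(lon_edges); lat_edges <- as.numeric(lat_edges)
  dates <- as.Date(dates)
  if (any(diff(lon_edges) <= 0) || any(diff(lat_edges) <= 0)) {
    stop_mesa("lon_edges and lat_edges must be strictly ascending")
  }
  if (length(dates) > 1 && any(as.integer(diff(dates)) != 1L)) {
    stop_mesa("dates must have a daily step with no gaps")
  }
  dv <- dim(values)
  if (length(dv) != 3 || dv[1] != length(dates) ||
      dv[2] != length(lat_edges) - 1 || dv[3] != length(lon_edges) - 1) {
    stop_mesa("values must be an array of dim (n_days, n_lat, n_lon) matching edges/dates")
  }
  if (any(!is.finite(values) & !is.na(values))) {
    stop_mesa("values must be finite where not missing (NA)")
  }
  structure(
    list(lon_edges = lon_edges, lat_edges = lat_edges, dates = dates,
         values = values, crs_tag = crs_tag),
    class = "raster_cube"
  )
}

#' @export
print.raster_cube <- function(x, ...) {
  cat(sprintf(
    "raster_cube: %d x %d pixels, %d days (%s .. %s), lon [%g, %g], lat [%g, %g]\n",
    length(x$lat_edges) - 1, length(x$lon_edges) - 1, length(x$dates),
    format(min(x$dates)), format(max(x$dates)),
    min(x$lon_edges), max(x$lon_edges), min(x$lat_edges), max(x$lat_edges)))
  invisible(x)
}

#' Pixel centers and identifiers of a cube
#'
#' @param cube a `raster_cube`
#' @return data.frame with one row per pixel: `pixel_id`, integer indices
#'   `ix` (lon) and `iy` (lat), and center coordinates `lon`, `lat`
#' @export
cube_pixels <- function(cube) {
  stopifnot(inherits(cube, "raster_cube"))
  lon_c <- (cube$lon_edges[-1] + cube$lon_edges[-length(cube$lon_edges)]) / 2
  lat_c <- (cube$lat_edges[-1] + cube$lat_edges[-length(cube$lat_edges)]) / 2
  g <- expand.grid(iy = seq_along(lat_c), ix = seq_along(lon_c))
  data.frame(
    pixel_id = sprintf("px%03d_%03d", g$ix, g$iy),
    ix = g$ix, iy = g$iy,
    lon = lon_c[g$ix], lat = lat_c[g$iy],
    stringsAsFactors = FALSE
  )
}

#' Extract one pixel's daily series from a cube
#'
#' @param cube a `raster_cube`
#' @param ix,iy lon and lat pixel indices
#' @return a [daily_series()]
#' @export
cube_series <- function(cube, ix, iy) {
  stopifnot(inherits(cube, "raster_cube"))
  daily_series(cube$dates, cube$values[, iy, ix],
               pixel_id = sprintf("px%03d_%03d", ix, iy))
}

#' Write a temperature cube to NetCDF (Kelvin)
#'
#' Serializes the cube the way ocean-model products distribute daily
#' potential temperature: a CF-style (lon, lat, time) variable in Kelvin
#' with a "days since" time axis. [read_sst_cube()] inverts this exactly.
#'
#' @param cube a `raster_cube` (values in degrees C)
#' @param path output file path
#' @param variable_name NetCDF variable name (default `"thetao"`)
#' @return `path`, invisibly
#' @export
write_sst_cube <- function(cube, path, variable_name = "thetao") {
  stopifnot(inherits(cube, "raster_cube"))
  px <- cube_pixels(cube)
  lon_c <- sort(unique(px$lon)); lat_c <- sort(unique(px$lat))
  dim_lon <- ncdf4::ncdim_def("lon", "degrees_east", lon_c)
  dim_lat <- ncdf4::ncdim_def("lat", "degrees_north", lat_c)
  origin <- cube$dates[1]
  dim_time <- ncdf4::ncdim_def(
    "time", sprintf("days since %s", format(origin)),
    as.numeric(cube$dates - origin), unlim = TRUE)
  var <- ncdf4::ncvar_def(variable_name, "K", list(dim_lon, dim_lat, dim_time),
                          missval = 1e20, prec = "double")
  nc <- ncdf4::nc_create(path, var)
  on.exit(ncdf4::nc_close(nc), add = TRUE)
  vals_k <- aperm(cube$values + 273.15, c(3, 2, 1))  # -> (lon, lat, time)
  vals_k[is.na(vals_k)] <- 1e20
  ncdf4::ncvar_put(nc, var, vals_k)
  invisible(path)
}

#' Read a daily temperature cube from NetCDF
#'
#' Reads a CF-style (lon/lat/time) daily temperature variable stored in
#' Kelvin, converts to degrees Celsius (x - 273.15), normalizes both spatial
#' axes to ascending order, and masks the variable's fill value as NA.
#'
#' @param path NetCDF file path
#' @param variable_name name of the temperature variable
#' @return a [raster_cube()] in degrees Celsius
#' @export
read_sst_cube <- function(path, variable_name = "thetao") {
  if (!file.exists(path)) stop_mesa("SST file not found: ", path)
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc), add = TRUE)
  if (!variable_name %in% names(nc$var)) {
    stop_mesa("variable '", variable_name, "' not found in ", path,
              "; available: ", paste(names(nc$var), collapse = ", "))
  }
  var <- nc$var[[variable_name]]
  dnames <- vapply(var$dim, function(d) d$name, character(1))
  ax <- function(cands) {
    hit <- which(tolower(dnames) %in% cands)
    if (length(hit) != 1) {
      stop_mesa("variable '", variable_name, "' must have lon/lat/time axes; found: ",
                paste(dnames, collapse = ", "))
    }
    hit
  }
  i_lon <- ax(c("lon", "longitude", "x"))
  i_lat <- ax(c("lat", "latitude", "y"))
  i_time <- ax(c("time", "t"))

  lon_c <- as.numeric(var$dim[[i_lon]]$vals)
  lat_c <- as.numeric(var$dim[[i_lat]]$vals)
  tvals <- as.numeric(var$dim[[i_time]]$vals)
  tunits <- var$dim[[i_time]]$units
  m <- regmatches(tunits, regexec("days since ([0-9]{4}-[0-9]{2}-[0-9]{2})", tunits))[[1]]
  if (length(m) != 2) stop_mesa("unsupported time units '", tunits, "' (need 'days since YYYY-MM-DD')")
  dates <- as.Date(m[2]) + tvals
  if (length(dates) > 1 && any(diff(tvals) != 1)) {
    stop_mesa("non-daily time step in '", path, "'")
  }

  vals <- ncdf4::ncvar_get(nc, variable_name, collapse_degen = FALSE)
  vals <- aperm(vals, order(c(i_time, i_lat, i_lon)))  # -> (time, lat, lon)
  # normalize ascending axes
  if (is.unsorted(lat_c)) { vals <- vals[, rev(seq_along(lat_c)), , drop = FALSE]; lat_c <- rev(lat_c) }
  if (is.unsorted(lon_c)) { vals <- vals[, , rev(seq_along(lon_c)), drop = FALSE]; lon_c <- rev(lon_c) }
  vals[!is.na(vals) & abs(vals - var$missval) < 1e-5 * abs(var$missval)] <- NA

  edges <- function(centers) {
    if (length(centers) == 1) return(c(centers - 0.05, centers + 0.05))
    d <- diff(centers)
    c(centers[1] - d[1] / 2, centers[-length(centers)] + d / 2,
      centers[length(centers)] + d[length(d)] / 2)
  }
  raster_cube(edges(lon_c), edges(lat_c), dates, vals - 273.15)
}

#' Generate a quarter-degree grid-cell (QDGC) lattice over a bounding box
#'
#' QDGC cells form a hierarchical lon/lat lattice anchored at integer
#' degrees; the cell width at level L is 0.5 / 2^(L-1) degrees (level 1 =
#' 0.5 deg, level 3 = 0.125 deg). Every lattice cell intersecting the box is
#' returned whole (snapped to the anchor lattice, not clipped to the box),
#' so cell identities are reproducible across runs with different extents.
#'
#' @param level integer 1-7
#' @param bbox numeric vector `c(lon_min, lon_max, lat_min, lat_max)`
#' @return data.frame of class `qdgc_grid`: `cell_id`, `lon_min`, `lon_max`,
#'   `lat_min`, `lat_max`; attribute `cell_size_deg`
#' @examples
#' g <- generate_qdgc_grid(3, c(10, 11, 35, 36))
#' nrow(g)            # 64 cells
#' attr(g, "cell_size_deg")  # 0.125
#' @export
generate_qdgc_grid <- function(level, bbox) {
  if (!is.numeric(level) || length(level) != 1 || level != as.integer(level) ||
      level < 1 || level > 7) {
    stop_mesa("level must be an integer in 1..7, got: ", format(level))
  }
  size <- 0.5 / 2^(level - 1)
  bbox <- as.numeric(bbox)
  stopifnot(length(bbox) == 4)
  empty <- data.frame(cell_id = character(0), lon_min = numeric(0),
                      lon_max = numeric(0), lat_min = numeric(0),
                      lat_max = numeric(0), stringsAsFactors = FALSE)
  if (bbox[1] >= bbox[2] || bbox[3] >= bbox[4]) {
    return(structure(empty, cell_size_deg = size, level = level, class = c("qdgc_grid", "data.frame")))
  }
  eps <- 1e-9
  ci <- seq(floor(bbox[1] / size + eps), ceiling(bbox[2] / size - eps) - 1)
  ri <- seq(floor(bbox[3] / size + eps), ceiling(bbox[4] / size - eps) - 1)
  g <- expand.grid(ri = ri, ci = ci)
  out <- data.frame(
    cell_id = sprintf("L%d_%d_%d", level, g$ci, g$ri),
    lon_min = g$ci * size, lon_max = (g$ci + 1) * size,
    lat_min = g$ri * size, lat_max = (g$ri + 1) * size,
    stringsAsFactors = FALSE
  )
  structure(out, cell_size_deg = size, level = level, class = c("qdgc_grid", "data.frame"))
}

#' Construct a seagrass patch set
#'
#' @param polygons a single two-column (lon, lat) matrix or a list of them;
#'   rings are repaired (closing vertex and duplicate vertices dropped) and
#'   degenerate rings rejected
#' @param source_tag provenance string
#' @return object of class `seagrass_patches`
#' @export
seagrass_patches <- function(polygons, source_tag = "synthetic") {
  if (is.matrix(polygons)) polygons <- list(polygons)
  polygons <- lapply(polygons, repair_ring)
  structure(list(polygons = polygons, source_tag = source_tag),
            class = "seagrass_patches")
}

#' Construct an EEZ map
#'
#' @param polygons named list: country code -> two-column (lon, lat) matrix
#'   or list of such rings
#' @return object of class `eez_map`
#' @export
eez_map <- function(polygons) {
  codes <- names(polygons)
  if (is.null(codes) || anyDuplicated(codes) || any(codes == "")) {
    stop_mesa("eez_map needs uniquely named polygons (country codes)")
  }
  polys <- lapply(polygons, function(p) {
    if (is.matrix(p)) p <- list(p)
    lapply(p, repair_ring)
  })
  structure(list(polygons = polys), class = "eez_map")
}

#' Select the cube pixels that contain seagrass
#'
#' A pixel is selected iff its rectangle overlaps at least one seagrass
#' polygon with positive area (which covers polygons wholly inside the
#' pixel). No buffer is applied and any positive coverage, however small,
#' selects the pixel.
#'
#' @param cube a `raster_cube`
#' @param patches a [seagrass_patches()] set
#' @return subset of [cube_pixels()] rows for the selected pixels
#' @export
select_seagrass_pixels <- function(cube, patches) {
  stopifnot(inherits(cube, "raster_cube"), inherits(patches, "seagrass_patches"))
  px <- cube_pixels(cube)
  if (length(patches$polygons) == 0) {
    warn_mesa("empty seagrass patch set: no pixels selected")
    return(px[0, ])
  }
  le <- cube$lon_edges; la <- cube$lat_edges
  sel <- rep(FALSE, nrow(px))
  for (ring in patches$polygons) {
    bb <- c(range(ring[, 1]), range(ring[, 2]))
    cand <- which(!sel &
                    le[px$ix] < bb[2] & le[px$ix + 1] > bb[1] &
                    la[px$iy] < bb[4] & la[px$iy + 1] > bb[3])
    for (k in cand) {
      a <- rect_ring_overlap(ring, le[px$ix[k]], le[px$ix[k] + 1],
                             la[px$iy[k]], la[px$iy[k] + 1])
      if (a > 0) sel[k] <- TRUE
    }
  }
  px[sel, , drop = FALSE]
}

point_in_country <- function(px, py, rings) {
  on_edge <- function(ring) {
    n <- nrow(ring)
    x <- ring[, 1]; y <- ring[, 2]
    xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
    cross <- (xn - x) * (py - y) - (yn - y) * (px - x)
    within <- px >= pmin(x, xn) - 1e-12 & px <= pmax(x, xn) + 1e-12 &
      py >= pmin(y, yn) - 1e-12 & py <= pmax(y, yn) + 1e-12
    any(abs(cross) < 1e-12 & within)
  }
  any(vapply(rings, function(r) point_in_ring(px, py, r) || on_edge(r), logical(1)))
}

#' Assign grid cells to EEZs by centroid
#'
#' Each cell inherits the country whose EEZ polygon contains the cell
#' centroid (boundary inclusive). A centroid claimed by several countries
#' (shared border) is resolved to the lexicographically smallest country
#' code, with a warning. Centroids in no EEZ are left unassigned (NA).
#'
#' @param cells a `qdgc_grid`
#' @param eez an [eez_map()]
#' @return data.frame: `cell_id`, `country_code` (NA when unassigned)
#' @export
assign_cells_to_eez <- function(cells, eez) {
  stopifnot(inherits(cells, "qdgc_grid"), inherits(eez, "eez_map"))
  if (nrow(cells) == 0 || length(eez$polygons) == 0) {
    stop_mesa("assign_cells_to_eez needs non-empty cells and EEZ map")
  }
  codes <- sort(names(eez$polygons))
  cx <- (cells$lon_min + cells$lon_max) / 2
  cy <- (cells$lat_min + cells$lat_max) / 2
  ties <- character(0)
  country <- rep(NA_character_, nrow(cells))
  for (i in seq_len(nrow(cells))) {
    hit <- codes[vapply(codes, function(cc)
      point_in_country(cx[i], cy[i], eez$polygons[[cc]]), logical(1))]
    if (length(hit) >= 1) country[i] <- hit[1]
    if (length(hit) > 1) ties <- c(ties, cells$cell_id[i])
  }
  if (length(ties) > 0) {
    warn_mesa("EEZ tie at cell centroid(s) ", paste(ties, collapse = ", "),
              "; assigned lexicographically smallest country code")
  }
  data.frame(cell_id = cells$cell_id, country_code = country,
             stringsAsFactors = FALSE)
}

#' Write a per-cell score map to GeoJSON or CSV
#'
#' @param cells a `qdgc_grid`
#' @param values either a named vector (cell_id -> value, written as column
#'   `score`) or a data.frame with a `cell_id` column and one or more
#'   attribute columns; every cell in `cells` must have a value
#' @param path output path
#' @param format `"vector"` (GeoJSON FeatureCollection of cell polygons) or
#'   `"table"` (CSV, one row per cell with its bounds)
#' @return `path`, invisibly
#' @export
write_score_map <- function(cells, values, path, format = c("vector", "table")) {
  stopifnot(inherits(cells, "qdgc_grid"))
  format <- match.arg(format)
  if (!is.data.frame(values)) {
    values <- data.frame(cell_id = names(values), score = unname(values),
                         stringsAsFactors = FALSE)
  }
  if (!"cell_id" %in% names(values)) stop_mesa("values needs a cell_id column")
  missing <- setdiff(cells$cell_id, values$cell_id)
  if (length(missing) > 0) {
    stop_mesa("no value for cell(s): ", paste(missing, collapse = ", "))
  }
  values <- values[match(cells$cell_id, values$cell_id), , drop = FALSE]
  attrs <- values[, setdiff(names(values), "cell_id"), drop = FALSE]

  if (format == "table") {
    out <- cbind(cells[, c("cell_id", "lon_min", "lon_max", "lat_min", "lat_max")],
                 attrs)
    utils::write.csv(out, path, row.names = FALSE)
  } else {
    features <- lapply(seq_len(nrow(cells)), function(i) {
      ring <- list(
        c(cells$lon_min[i], cells$lat_min[i]),
        c(cells$lon_max[i], cells$lat_min[i]),
        c(cells$lon_max[i], cells$lat_max[i]),
        c(cells$lon_min[i], cells$lat_max[i]),
        c(cells$lon_min[i], cells$lat_min[i]))
      props <- c(list(cell_id = cells$cell_id[i]),
                 lapply(attrs, function(col) col[i]))
      list(type = "Feature",
           geometry = list(type = "Polygon", coordinates = list(ring)),
           properties = props)
    })
    gj <- list(type = "FeatureCollection", features = features)
    jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read back a score map written by [write_score_map()]
#'
#' @param path file path
#' @param format `"vector"` or `"table"`
#' @return data.frame with `cell_id` and the attribute columns
#' @export
read_score_map <- function(path, format = c("vector", "table")) {
  format <- match.arg(format)
  if (format == "table") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    return(df[, setdiff(names(df), c("lon_min", "lon_max", "lat_min", "lat_max")),
              drop = FALSE])
  }
  gj <- jsonlite::read_json(path)
  rows <- lapply(gj$features, function(f) as.data.frame(f$properties,
                                                        stringsAsFactors = FALSE))
  do.call(rbind, rows)
}
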