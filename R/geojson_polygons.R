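# Minimal GeoJSON polygon IO for seagrass patch sets and EEZ maps. Only
# single-ring Polygon features are produced and consumed, which is all the
# synthetic geography and the pipeline contracts use.

polygons_to_geojson <- function(rings, props, path) {
  features <- lapply(seq_along(rings), function(i) {
    ring <- rings[[i]]
    closed <- rbind(ring, ring[1, ])
    list(type = "Feature",
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(closed)),
                                                   function(j) closed[j, ]))),
         properties = as.list(props[i, , drop = FALSE]))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

geojson_to_polygons <- function(path) {
  gj <- jsonlite::read_json(path)
  rings <- lapply(gj$features, function(f) {
    ring <- f$geometry$coordinates[[1]]
    do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
  })
  props <- lapply(gj$features, function(f)
    as.data.frame(f$properties, stringsAsFactors = FALSE))
  list(rings = rings, props = do.call(rbind, props))
}

#' Write / read a seagrass patch set as GeoJSON
#'
#' @param patches a [seagrass_patches()]
#' @param path file path
#' @return `path` (write) or a [seagrass_patches()] (read)
#' @export
write_seagrass_geojson <- function(patches, path) {
  stopifnot(inherits(patches, "seagrass_patches"))
  props <- data.frame(patch_id = seq_along(patches$polygons),
                      source_tag = patches$source_tag)
  polygons_to_geojson(patches$polygons, props, path)
}

#' @rdname write_seagrass_geojson
#' @export
read_seagrass_geojson <- function(path) {
  if (!file.exists(path)) stop_mesa("seagrass file not found: ", path)
  p <- geojson_to_polygons(path)
  seagrass_patches(p$rings, source_tag = p$props$source_tag[1] %||% "file")
}

#' Write / read an EEZ map as GeoJSON
#'
#' Each feature carries a `country_code` property; several features may share
#' a code (multi-part EEZs).
#'
#' @param eez an [eez_map()]
#' @param path file path
#' @return `path` (write) or an [eez_map()] (read)
#' @export
write_eez_geojson <- function(eez, path) {
  stopifnot(inherits(eez, "eez_map"))
  rings <- list(); codes <- character(0)
  for (cc in names(eez$polygons)) {
    for (r in eez$polygons[[cc]]) {
      rings[[length(rings) + 1]] <- r
      codes <- c(codes, cc)
    }
  }
  polygons_to_geojson(rings, data.frame(country_code = codes), path)
}

#' @rdname write_eez_geojson
#' @export
read_eez_geojson <- function(path) {
  if (!file.exists(path)) stop_mesa("EEZ file not found: ", path)
  p <- geojson_to_polygons(path)
  codes <- unique(p$props$country_code)
  eez_map(stats::setNames(
    lapply(codes, function(cc) p$rings[p$props$country_code == cc]), codes))
}
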