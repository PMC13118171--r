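# Planar polygon utilities for cluster-to-area assignment.
#
# Polygons are closed rings of lon/lat pairs (planar arithmetic; GPS jitter and
# admin-area scales make projection effects negligible for containment tests).
# A polygon is a list with elements `outer` (n x 2 matrix, closed or open ring)
# and optionally `holes` (list of rings). An "area polygon set" is a list of
# such polygons with attributes `ids` (external labels) carried alongside.

close_ring <- function(ring) {
  ring <- as.matrix(ring)
  if (!all(ring[1, ] == ring[nrow(ring), ])) ring <- rbind(ring, ring[1, ])
  ring
}

# ray-casting containment with explicit boundary detection.
# returns "inside", "boundary" or "outside".
point_ring_position <- function(x, y, ring, tol = 1e-12) {
  ring <- close_ring(ring)
  n <- nrow(ring) - 1L
  inside <- FALSE
  for (k in seq_len(n)) {
    x1 <- ring[k, 1]; y1 <- ring[k, 2]
    x2 <- ring[k + 1, 1]; y2 <- ring[k + 1, 2]
    # boundary: point within tol of the segment
    if (point_segment_distance(x, y, x1, y1, x2, y2) <= tol) {
      return("boundary")
    }
    # crossing test (half-open rule avoids double counting at vertices)
    if ((y1 > y) != (y2 > y)) {
      xint <- x1 + (y - y1) / (y2 - y1) * (x2 - x1)
      if (x < xint) inside <- !inside
    }
  }
  if (inside) "inside" else "outside"
}

point_segment_distance <- function(x, y, x1, y1, x2, y2) {
  dx <- x2 - x1; dy <- y2 - y1
  len2 <- dx * dx + dy * dy
  if (len2 == 0) return(sqrt((x - x1)^2 + (y - y1)^2))
  t <- ((x - x1) * dx + (y - y1) * dy) / len2
  t <- min(1, max(0, t))
  px <- x1 + t * dx; py <- y1 + t * dy
  sqrt((x - px)^2 + (y - py)^2)
}

point_in_polygon <- function(x, y, polygon, tol = 1e-12) {
  pos <- point_ring_position(x, y, polygon$outer, tol)
  if (pos == "outside") return("outside")
  if (pos == "boundary") return("boundary")
  for (h in polygon$holes %||% list()) {
    hp <- point_ring_position(x, y, h, tol)
    if (hp == "boundary") return("boundary")
    if (hp == "inside") return("outside")
  }
  "inside"
}

# minimum distance from a point to a polygon boundary (0 if on the boundary)
point_polygon_distance <- function(x, y, polygon) {
  if (point_in_polygon(x, y, polygon) != "outside") return(0)
  rings <- c(list(polygon$outer), polygon$holes %||% list())
  dmin <- Inf
  for (ring in rings) {
    ring <- close_ring(ring)
    for (k in seq_len(nrow(ring) - 1L)) {
      d <- point_segment_distance(
        x, y, ring[k, 1], ring[k, 2], ring[k + 1, 1], ring[k + 1, 2]
      )
      if (d < dmin) dmin <- d
    }
  }
  dmin
}

#' Read area polygons from a GeoJSON FeatureCollection
#'
#' Features must carry `admin1` (and optionally `admin2`) properties. Polygon
#' and MultiPolygon geometries are supported; rings are taken as lon/lat pairs.
#'
#' @param path path to a GeoJSON file.
#' @return a list of polygons (each a list of `outer`/`holes` parts, a feature
#'   possibly contributing several parts) with a data.frame attribute
#'   `properties` (one row per polygon part: `admin1`, `admin2`, `feature`).
#' @export
read_geojson_areas <- function(path) {
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(gj$features)) {
    stop_prevmapr("not a GeoJSON FeatureCollection: ", path,
                  class = "prevmapr_schema_error")
  }
  polys <- list()
  props <- list()
  ring_to_matrix <- function(ring) {
    do.call(rbind, lapply(ring, function(xy) c(xy[[1]], xy[[2]])))
  }
  for (f in seq_along(gj$features)) {
    feat <- gj$features[[f]]
    geom <- feat$geometry
    pr <- feat$properties
    parts <- switch(geom$type,
      Polygon = list(geom$coordinates),
      MultiPolygon = geom$coordinates,
      stop_prevmapr("unsupported geometry type: ", geom$type,
                    class = "prevmapr_schema_error")
    )
    for (part in parts) {
      outer <- ring_to_matrix(part[[1]])
      holes <- lapply(part[-1], ring_to_matrix)
      polys[[length(polys) + 1L]] <- list(outer = outer, holes = holes)
      props[[length(props) + 1L]] <- data.frame(
        admin1 = as.character(pr$admin1 %||% NA_character_),
        admin2 = as.character(pr$admin2 %||% NA_character_),
        feature = f,
        stringsAsFactors = FALSE
      )
    }
  }
  attr(polys, "properties") <- do.call(rbind, props)
  polys
}

polygon_properties <- function(area_polygons) {
  pr <- attr(area_polygons, "properties")
  if (is.null(pr)) {
    pr <- data.frame(
      admin1 = as.character(seq_along(area_polygons)),
      admin2 = as.character(seq_along(area_polygons)),
      feature = seq_along(area_polygons)
    )
  }
  pr
}
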