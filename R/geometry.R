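#' @title Range geometry: polygons, centroids, distances and areas
#' @name range-geometry
#' @description
#' Species ranges are handled as lon/lat polygons on the WGS84 sphere.
#' Distances are great circles on the mean radius 6371.0088 km; areas are
#' spherical polygon areas in km²; centroids are planar area centroids
#' computed in a frame recentered on the polygon's longitudinal midpoint so
#' ranges straddling the antimeridian are handled correctly.
NULL

validate_lonlat <- function(lon, lat, what = "coordinate") {
  if (!all(is.finite(lon)) || !all(is.finite(lat)))
    stopf("non-finite %s values", what, class = "abundicentre_invalid_argument")
  if (any(lon < -180 | lon > 180) || any(lat < -90 | lat > 90))
    stopf("%s out of bounds: lon must be in [-180,180], lat in [-90,90]",
          what, class = "abundicentre_invalid_argument")
  invisible(TRUE)
}

# Choose a longitude frame in which the point set is contiguous.  Returns
# `to` (map into the frame, centred on 0) and `from` (map back to [-180,180]).
lon_frame <- function(lon) {
  span0 <- diff(range(lon))
  lon360 <- lon %% 360
  mid <- if (span0 > 180 && diff(range(lon360)) < span0)
    mean(range(lon360)) else mean(range(lon))
  list(
    to   = function(l) ((l - mid + 180) %% 360) - 180,
    from = function(x) {
      l <- ((x + mid + 180) %% 360) - 180
      # keep +180 as +180 rather than wrapping to -180 when it was positive
      l
    },
    mid = mid
  )
}

#' Construct a range polygon
#'
#' @param rings list of vertex matrices/data.frames with columns `lon`,
#'   `lat`; the first ring is the outer boundary, any others are holes.
#'   Rings are closed automatically.
#' @param source provenance of the geometry: an expert range map or a
#'   minimum convex polygon.
#' @return object of class `range_polygon`.
#' @export
new_range_polygon <- function(rings, source = c("expert_map", "mcp")) {
  source <- match.arg(source)
  rings <- lapply(rings, function(r) {
    r <- as.matrix(r)
    colnames(r) <- c("lon", "lat")
    validate_lonlat(r[, 1], r[, 2], "polygon vertex")
    # normalise: close the ring
    if (any(r[1, ] != r[nrow(r), ])) r <- rbind(r, r[1, ])
    if (nrow(unique(r[-nrow(r), , drop = FALSE])) < 3)
      stopf("polygon ring needs >= 3 distinct vertices",
            class = "abundicentre_degenerate_geometry")
    r
  })
  structure(list(rings = rings, source = source), class = "range_polygon")
}

#' @export
print.range_polygon <- function(x, ...) {
  cat(sprintf("<range_polygon> %d ring(s), %d outer vertices, source=%s\n",
              length(x$rings), nrow(x$rings[[1]]) - 1L, x$source))
  invisible(x)
}

#' Minimum convex polygon of occurrence points
#'
#' Convex hull of a set of lon/lat occurrence points, used as a range proxy
#' when expert range maps are unavailable. If the points span more than 180
#' degrees of longitude they are recentered before hull construction and
#' the hull is mapped back, so ranges straddling the antimeridian work.
#'
#' @param points data.frame or matrix with columns `lon`, `lat` (degrees).
#' @return A `range_polygon` with counter-clockwise outer ring and
#'   `source = "mcp"`.
#' @examples
#' pts <- data.frame(lon = c(0, 1, 1, 0, 0.5), lat = c(0, 0, 1, 1, 0.5))
#' minimum_convex_polygon(pts)
#' @export
minimum_convex_polygon <- function(points) {
  points <- as.matrix(as.data.frame(points)[, c("lon", "lat")])
  validate_lonlat(points[, 1], points[, 2], "occurrence point")
  points <- unique(points)
  if (nrow(points) < 3)
    stopf("minimum convex polygon needs >= 3 distinct points (got %d)",
          nrow(points), class = "abundicentre_degenerate_geometry")
  fr <- lon_frame(points[, 1])
  x <- fr$to(points[, 1]); y <- points[, 2]
  idx <- grDevices::chull(x, y)          # clockwise order
  if (length(idx) < 3)
    stopf("all points are collinear; hull is degenerate",
          class = "abundicentre_degenerate_geometry")
  idx <- rev(idx)                        # counter-clockwise
  ring <- cbind(lon = fr$from(x[idx]), lat = y[idx])
  new_range_polygon(list(ring), source = "mcp")
}

# signed shoelace area and centroid of one closed ring in planar coords
ring_area_centroid <- function(x, y) {
  n <- length(x)
  i <- seq_len(n - 1L); j <- i + 1L
  cross <- x[i] * y[j] - x[j] * y[i]
  a <- sum(cross) / 2
  if (abs(a) < .Machine$double.eps * 100)
    return(list(area = 0, cx = NA_real_, cy = NA_real_))
  list(area = a,
       cx = sum((x[i] + x[j]) * cross) / (6 * a),
       cy = sum((y[i] + y[j]) * cross) / (6 * a))
}

#' Planar area centroid of a range polygon
#'
#' Area-weighted centroid (shoelace formula) of the outer ring minus any
#' holes, computed in a longitude frame recentered on the polygon's
#' longitudinal midpoint (antimeridian-safe) and mapped back to
#' `[-180, 180]`. This is the planar centroid on geographic coordinates,
#' matching the common desktop-GIS default, not a spherical centre of mass.
#'
#' @param polygon a `range_polygon` (first ring outer, others holes).
#' @return Named numeric `c(lon =, lat =)`.
#' @export
range_centroid <- function(polygon) {
  stopifnot(inherits(polygon, "range_polygon"))
  all_lon <- unlist(lapply(polygon$rings, function(r) r[, 1]))
  fr <- lon_frame(all_lon)
  parts <- lapply(polygon$rings, function(r)
    ring_area_centroid(fr$to(r[, 1]), r[, 2]))
  a <- abs(parts[[1]]$area)
  if (a == 0)
    stopf("zero-area polygon has no centroid",
          class = "abundicentre_degenerate_geometry")
  cx <- parts[[1]]$cx * a
  cy <- parts[[1]]$cy * a
  if (length(parts) > 1) for (h in parts[-1]) {
    ah <- abs(h$area)
    a <- a - ah
    cx <- cx - h$cx * ah
    cy <- cy - h$cy * ah
  }
  if (a <= 0)
    stopf("holes cover the whole polygon; centroid undefined",
          class = "abundicentre_degenerate_geometry")
  c(lon = fr$from(cx / a), lat = cy / a)
}

#' Great-circle distance in kilometres
#'
#' Haversine great-circle distance on a sphere of radius 6371.0088 km
#' (the WGS84 mean radius). Vectorised over both arguments.
#'
#' @param a,b points as `c(lon, lat)` vectors or two-column
#'   matrices/data.frames with columns `lon`, `lat` (degrees).
#' @return Distance(s) in km, `>= 0`, zero iff the points coincide.
#' @examples
#' geodesic_distance_km(c(0, 0), c(0, 90))   # quarter great circle
#' @export
geodesic_distance_km <- function(a, b) {
  as_mat <- function(p) {
    if (is.null(dim(p))) matrix(as.numeric(p), ncol = 2,
                                dimnames = list(NULL, c("lon", "lat")))
    else as.matrix(as.data.frame(p)[, c("lon", "lat")])
  }
  a <- as_mat(a); b <- as_mat(b)
  validate_lonlat(a[, 1], a[, 2]); validate_lonlat(b[, 1], b[, 2])
  to_rad <- pi / 180
  dlat <- (b[, 2] - a[, 2]) * to_rad
  dlon <- (b[, 1] - a[, 1]) * to_rad
  h <- sin(dlat / 2)^2 +
    cos(a[, 2] * to_rad) * cos(b[, 2] * to_rad) * sin(dlon / 2)^2
  h <- pmin(pmax(h, 0), 1)
  unname(2 * EARTH_RADIUS_KM * asin(sqrt(h)))
}

#' Spherical polygon area in km squared
#'
#' Area of a range polygon on the sphere of radius 6371.0088 km, holes
#' subtracted. Computation delegates to [geosphere::areaPolygon()] with a
#' spherical figure (flattening 0).
#'
#' @param polygon a `range_polygon`.
#' @return Area in km².
#' @export
range_area_km2 <- function(polygon) {
  stopifnot(inherits(polygon, "range_polygon"))
  r_m <- EARTH_RADIUS_KM * 1000
  one <- function(ring)
    geosphere::areaPolygon(ring[-nrow(ring), , drop = FALSE], a = r_m, f = 0) / 1e6
  areas <- vapply(polygon$rings, one, numeric(1))
  total <- areas[1] - sum(areas[-1])
  if (!is.finite(total) || total <= 0)
    stopf("degenerate polygon: nonpositive spherical area",
          class = "abundicentre_degenerate_geometry")
  total
}

#' Summarise a range polygon
#'
#' Computes the range centroid, range size (km²) and the absolute latitude
#' of the centroid — the per-species geographic covariates used downstream.
#'
#' @param polygon a `range_polygon`.
#' @return A `range_summary` list: `centroid`, `range_size_km2`,
#'   `abs_latitude_deg`.
#' @export
range_summary <- function(polygon) {
  centroid <- range_centroid(polygon)
  structure(list(centroid = centroid,
                 range_size_km2 = range_area_km2(polygon),
                 abs_latitude_deg = abs(unname(centroid["lat"]))),
            class = "range_summary")
}

#' @export
print.range_summary <- function(x, ...) {
  cat(sprintf("<range_summary> centroid (%.3f, %.3f), %.0f km2, |lat| %.2f\n",
              x$centroid["lon"], x$centroid["lat"],
              x$range_size_km2, x$abs_latitude_deg))
  invisible(x)
}

#' Annotate observations with distance to the range centroid
#'
#' @param observations data.frame with columns `lon`, `lat`.
#' @param summary a `range_summary`, or a centroid `c(lon, lat)`.
#' @return `observations` with a `distance_km` column filled.
#' @export
distance_to_centroid <- function(observations, summary) {
  centroid <- if (inherits(summary, "range_summary")) summary$centroid
              else summary
  observations$distance_km <- geodesic_distance_km(
    observations[, c("lon", "lat")],
    matrix(centroid, nrow = nrow(observations), ncol = 2, byrow = TRUE,
           dimnames = list(NULL, c("lon", "lat"))))
  observations
}

## ---- GeoJSON / WKT interchange ---------------------------------------

#' Write species range polygons to GeoJSON
#'
#' @param ranges named list of `range_polygon` (names = species ids).
#' @param path output file.
#' @export
write_ranges_geojson <- function(ranges, path) {
  features <- lapply(names(ranges), function(sp) {
    poly <- ranges[[sp]]
    coords <- lapply(poly$rings, function(r)
      lapply(seq_len(nrow(r)), function(i) c(r[i, 1], r[i, 2])))
    list(type = "Feature",
         properties = list(species = sp, source = poly$source),
         geometry = list(type = "Polygon", coordinates = coords))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read species range polygons from GeoJSON
#'
#' @param path a GeoJSON FeatureCollection of Polygon features carrying a
#'   `species` property.
#' @return Named list of `range_polygon`.
#' @export
read_ranges_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  if (!identical(gj$type, "FeatureCollection"))
    stopf("expected a GeoJSON FeatureCollection",
          class = "abundicentre_invalid_argument")
  out <- list()
  for (f in gj$features) {
    sp <- f$properties$species
    rings <- lapply(f$geometry$coordinates, function(ring)
      do.call(rbind, lapply(ring, function(pt)
        c(lon = as.numeric(pt[[1]]), lat = as.numeric(pt[[2]])))))
    out[[sp]] <- new_range_polygon(rings, source = f$properties$source %||% "expert_map")
  }
  out
}

#' Convert between `range_polygon` and WKT POLYGON strings
#'
#' @param polygon a `range_polygon`.
#' @return `polygon_to_wkt()`: a WKT string; `wkt_to_polygon()`: a
#'   `range_polygon`.
#' @export
polygon_to_wkt <- function(polygon) {
  stopifnot(inherits(polygon, "range_polygon"))
  rings <- vapply(polygon$rings, function(r)
    paste0("(", paste(sprintf("%.10g %.10g", r[, 1], r[, 2]), collapse = ", "), ")"),
    character(1))
  paste0("POLYGON (", paste(rings, collapse = ", "), ")")
}

#' @param wkt a `POLYGON (...)` well-known-text string.
#' @param source ring provenance label for the result.
#' @rdname polygon_to_wkt
#' @export
wkt_to_polygon <- function(wkt, source = "expert_map") {
  wkt <- trimws(wkt)
  if (!grepl("^POLYGON", wkt, ignore.case = TRUE))
    stopf("only POLYGON WKT is supported", class = "abundicentre_invalid_argument")
  body <- sub("^POLYGON\\s*\\(", "", wkt, ignore.case = TRUE)
  body <- sub("\\)$", "", body)
  ring_strings <- strsplit(body, "\\)\\s*,\\s*\\(")[[1]]
  ring_strings <- gsub("[()]", "", ring_strings)
  rings <- lapply(ring_strings, function(rs) {
    pts <- strsplit(trimws(strsplit(rs, ",")[[1]]), "\\s+")
    do.call(rbind, lapply(pts, function(p)
      c(lon = as.numeric(p[1]), lat = as.numeric(p[2]))))
  })
  new_range_polygon(rings, source = source)
}
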