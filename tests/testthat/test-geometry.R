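R_KM <- 6371.0088

test_that("minimum convex polygon excludes interior points and rejects degenerate input", {
  pts <- data.frame(lon = c(10, 11, 11, 10, 10.5), lat = c(20, 20, 21, 21, 20.5))
  hull <- minimum_convex_polygon(pts)
  ring <- hull$rings[[1]]
  verts <- unique(ring[-nrow(ring), , drop = FALSE])
  expect_equal(nrow(verts), 4)
  expect_setequal(paste(verts[, 1], verts[, 2]),
                  paste(pts$lon[1:4], pts$lat[1:4]))
  expect_error(minimum_convex_polygon(data.frame(lon = c(0, 1, 2), lat = c(0, 1, 2))),
               class = "abundicentre_degenerate_geometry")
  expect_error(minimum_convex_polygon(data.frame(lon = c(0, 1), lat = c(0, 0))),
               class = "abundicentre_degenerate_geometry")
})

test_that("minimum convex polygon agrees with a brute-force hull and is idempotent", {
  set.seed(11)
  for (rep in 1:5) {
    pts <- data.frame(lon = runif(200, -20, 20), lat = runif(200, -10, 30))
    hull <- minimum_convex_polygon(pts)
    ring <- hull$rings[[1]][-1, , drop = FALSE]   # drop duplicated closure vertex
    oracle_idx <- brute_force_hull_vertices(pts$lon, pts$lat)
    expect_setequal(paste(ring[, 1], ring[, 2]),
                    paste(pts$lon[oracle_idx], pts$lat[oracle_idx]))
    # every input point inside or on the hull: re-hulling the union adds nothing
    again <- minimum_convex_polygon(as.data.frame(ring))
    expect_setequal(paste(again$rings[[1]][, 1], again$rings[[1]][, 2]),
                    paste(hull$rings[[1]][, 1], hull$rings[[1]][, 2]))
    with_pt <- minimum_convex_polygon(rbind(as.data.frame(ring),
                                            data.frame(lon = mean(ring[, 1]),
                                                       lat = mean(ring[, 2]))))
    expect_equal(nrow(with_pt$rings[[1]]), nrow(hull$rings[[1]]))
  }
})

test_that("range centroid matches closed forms and handles the antimeridian", {
  sq <- new_range_polygon(list(cbind(lon = c(9.5, 10.5, 10.5, 9.5),
                                     lat = c(19.5, 19.5, 20.5, 20.5))))
  expect_equal(unname(range_centroid(sq)), c(10, 20), tolerance = 1e-12)
  tri <- new_range_polygon(list(cbind(lon = c(0, 3, 0), lat = c(0, 0, 3))))
  expect_equal(unname(range_centroid(tri)), c(1, 1), tolerance = 1e-12)
  # polygon straddling 180E/W: square from 179E to 179W
  am <- new_range_polygon(list(cbind(lon = c(179, -179, -179, 179),
                                     lat = c(-1, -1, 1, 1))))
  ctr <- range_centroid(am)
  expect_gte(abs(ctr["lon"]), 179)
  # oracle: shift into a frame centred on 180, compute there, map back
  lon_shifted <- c(-1, 1, 1, -1)   # 179 -> -1, -179 -> +1 about 180
  oracle_lon <- mean(range(lon_shifted)) + 180
  oracle_lon <- ((oracle_lon + 180) %% 360) - 180
  expect_equal(unname(ctr["lat"]), 0, tolerance = 1e-12)
  expect_equal(abs(unname(ctr["lon"])), abs(oracle_lon), tolerance = 1e-9)
  sliver <- cbind(lon = c(0, 1, 2), lat = c(0, 0, 0))
  expect_error(range_centroid(new_range_polygon(list(rbind(sliver)))),
               class = "abundicentre_degenerate_geometry")
})

test_that("great-circle distances match closed forms and are metric", {
  expect_identical(geodesic_distance_km(c(12, -3), c(12, -3)), 0)
  expect_equal(geodesic_distance_km(c(0, 0), c(180, 0)), pi * R_KM, tolerance = 1e-3 / 20015)
  expect_equal(geodesic_distance_km(c(0, 0), c(0, 90)), pi * R_KM / 2, tolerance = 1e-3 / 10007)
  expect_error(geodesic_distance_km(c(NA, 0), c(0, 0)),
               class = "abundicentre_invalid_argument")
  set.seed(5)
  pts <- cbind(lon = runif(30, -180, 180), lat = runif(30, -90, 90))
  for (k in 1:30) {
    i <- sample(30, 3)
    d_ab <- geodesic_distance_km(pts[i[1], ], pts[i[2], ])
    d_bc <- geodesic_distance_km(pts[i[2], ], pts[i[3], ])
    d_ac <- geodesic_distance_km(pts[i[1], ], pts[i[3], ])
    expect_equal(d_ab, geodesic_distance_km(pts[i[2], ], pts[i[1], ]))
    expect_lte(d_ac, d_ab + d_bc + 1e-6)
  }
})

test_that("spherical areas match closed forms, subtract holes, and ignore rotation", {
  # hemisphere bounded by the equator, traversed counter-clockwise
  eq <- cbind(lon = seq(-180, 179, by = 1), lat = 0)
  hemi <- new_range_polygon(list(eq))
  expect_equal(range_area_km2(hemi), 2 * pi * R_KM^2, tolerance = 1e-3)
  quad <- new_range_polygon(list(cbind(lon = c(0, 1, 1, 0), lat = c(0, 0, 1, 1))))
  closed_form <- R_KM^2 * (pi / 180) * (sin(pi / 180) - 0)
  expect_equal(range_area_km2(quad), closed_form, tolerance = 5e-3)
  outer <- cbind(lon = c(0, 4, 4, 0), lat = c(0, 0, 4, 4))
  hole <- cbind(lon = c(1, 2, 2, 1), lat = c(1, 1, 2, 2))
  with_hole <- new_range_polygon(list(outer, hole))
  expect_equal(range_area_km2(with_hole),
               range_area_km2(new_range_polygon(list(outer))) -
                 range_area_km2(new_range_polygon(list(hole))),
               tolerance = 1e-9)
  rot <- new_range_polygon(list(cbind(lon = outer[, 1] + 57, lat = outer[, 2])))
  expect_equal(range_area_km2(rot),
               range_area_km2(new_range_polygon(list(outer))),
               tolerance = 1e-4)
})

test_that("range summaries expose centroid, area and absolute latitude", {
  sq <- new_range_polygon(list(cbind(lon = c(-1, 1, 1, -1), lat = c(-31, -31, -29, -29))))
  s <- range_summary(sq)
  expect_equal(s$abs_latitude_deg, 30, tolerance = 1e-9)
  expect_true(s$range_size_km2 > 0)
  expect_true(s$abs_latitude_deg >= 0 && s$abs_latitude_deg <= 90)
})

test_that("distance to centroid is zero at the centroid and matches an independent haversine", {
  sq <- new_range_polygon(list(cbind(lon = c(9, 11, 11, 9), lat = c(19, 19, 21, 21))))
  s <- range_summary(sq)
  obs <- data.frame(lon = c(10, 10, 10), lat = c(20, 20.5, 19.5))
  out <- distance_to_centroid(obs, s)
  expect_equal(out$distance_km[1], 0)
  expect_equal(out$distance_km[2], out$distance_km[3], tolerance = 1e-9)
  set.seed(9)
  rnd <- data.frame(lon = runif(50, -180, 180), lat = runif(50, -85, 85))
  got <- distance_to_centroid(rnd, s)$distance_km
  want <- oracle_distance_km(as.matrix(rnd[, c("lon", "lat")]),
                             matrix(s$centroid, 50, 2, byrow = TRUE))
  expect_equal(got, want, tolerance = 1e-9)
})

test_that("GeoJSON and WKT round-trip a polygon set", {
  sq <- new_range_polygon(list(cbind(lon = c(9, 11, 11, 9), lat = c(19, 19, 21, 21))))
  tri <- minimum_convex_polygon(data.frame(lon = c(0, 2, 1), lat = c(0, 0, 2)))
  path <- withr::local_tempfile(fileext = ".geojson")
  write_ranges_geojson(list(spA = sq, spB = tri), path)
  back <- read_ranges_geojson(path)
  expect_named(back, c("spA", "spB"))
  expect_equal(back$spA$rings[[1]], sq$rings[[1]], ignore_attr = TRUE)
  expect_identical(back$spB$source, "mcp")
  wkt <- polygon_to_wkt(sq)
  expect_match(wkt, "^POLYGON")
  expect_equal(wkt_to_polygon(wkt)$rings[[1]], sq$rings[[1]], ignore_attr = TRUE)
})
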