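test_that("UTM projection round-trips lon/lat within 1e-6 degrees", {
  withr::with_seed(11, {
    crs <- crs_utm(15)
    lon <- runif(200, -94.5, -91.5)
    lat <- runif(200, 47, 49)
    xy <- project_lonlat(lon, lat, crs)
    ll <- unproject_xy(xy[, 1], xy[, 2], crs)
    expect_lt(max(abs(ll[, "lon"] - lon)), 1e-6)
    expect_lt(max(abs(ll[, "lat"] - lat)), 1e-6)
    # central meridian of the zone maps to the 500 km false easting
    expect_equal(unname(project_lonlat(-93, 48, crs)[1, "x"]), 5e5)
  })
  expect_error(as_fw_crs("mercator"), class = "fishwolf_config_error")
  expect_s3_class(as_fw_crs("utm:15N"), "fw_crs")
})

test_that("read_fixes projects, sorts, and enforces the schema", {
  path <- withr::local_tempfile(fileext = ".csv")
  # out-of-order rows, lon/lat input, one animal
  writeLines(c(
    "animal_id,timestamp,lon,lat,fix_interval_min",
    "W1,2021-05-01 00:40:00,-93.001,48.0002,20",
    "W1,2021-05-01 00:00:00,-93.000,48.0000,20",
    "W1,2021-05-01 00:20:00,-93.0005,48.0001,20"), path)
  trajs <- read_fixes(path, crs = "utm:15N", tz = LOCAL_TZ)
  expect_named(trajs, "W1")
  tr <- trajs$W1
  expect_equal(nrow(tr), 3)
  expect_false(is.unsorted(tr$t, strictly = TRUE))
  # planar metres: ~74 m west-shift for 0.001 degrees of longitude at 48N
  expect_equal(tr$x[[1]] - tr$x[[3]], 74.5, tolerance = 0.01)
  ll <- unproject_xy(tr$x, tr$y, crs_utm(15))
  expect_equal(unname(ll[1, "lon"]), -93, tolerance = 1e-6)

  # shuffled rows give an identical sorted structure
  lines <- readLines(path)
  writeLines(c(lines[1], lines[c(4, 2, 3)]), path)
  expect_identical(read_fixes(path, crs = "utm:15N", tz = LOCAL_TZ)$W1, tr)
})

test_that("read_fixes surfaces schema problems instead of guessing", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("animal_id,timestamp,fix_interval_min", "W1,2021-05-01,20"), path)
  expect_error(read_fixes(path), class = "fishwolf_schema_error")

  writeLines(c("animal_id,timestamp,x,y,fix_interval_min",
               "W1,not-a-time,1,2,20"), path)
  expect_error(read_fixes(path, crs = "planar"), regexp = "row 1",
               class = "fishwolf_schema_error")

  # duplicate (animal, timestamp) is an error, not a dedup
  writeLines(c("animal_id,timestamp,x,y,fix_interval_min",
               "W1,2021-05-01 00:00:00,1,2,20",
               "W1,2021-05-01 00:00:00,3,4,20"), path)
  expect_error(read_fixes(path, crs = "planar"), class = "fishwolf_schema_error")

  writeLines("animal_id,timestamp,x,y,fix_interval_min", path)
  expect_warning(out <- read_fixes(path, crs = "planar"), "empty")
  expect_length(out, 0)
})

test_that("water features read from GeoJSON and WKT with geometry checks", {
  path <- withr::local_tempfile(fileext = ".geojson")
  gj <- list(type = "FeatureCollection", features = list(
    list(type = "Feature", properties = list(feature_id = "creek_a"),
         geometry = list(type = "LineString",
                         coordinates = list(list(0, 0), list(0, 1000)))),
    list(type = "Feature", properties = list(feature_id = "creek_b"),
         geometry = list(type = "LineString",
                         coordinates = list(list(500, 0), list(500, 400), list(900, 400)))),
    list(type = "Feature", properties = list(kind = "dam"),
         geometry = list(type = "Point", coordinates = list(0, 500)))
  ))
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  feats <- read_water_features(path)
  expect_named(feats, c("creek_a", "creek_b"))
  expect_equal(feature_length(feats$creek_a), 1000)
  expect_equal(feature_length(feats$creek_b), 800)
  # the dam point attaches to the nearest line
  expect_equal(feats$creek_a$dam_points[1, ], c(0, 500))
  expect_null(feats$creek_b$dam_points)

  wkt <- withr::local_tempfile(fileext = ".wkt")
  writeLines("LINESTRING (0 0, 300 400)", wkt)
  fw <- read_water_features(wkt)
  expect_equal(feature_length(fw[[1]]), 500)

  # degenerate and wrong-type geometries are rejected
  expect_error(water_feature("bad", cbind(c(0, 0), c(5, 5))),
               class = "fishwolf_geometry_error")
  gj$features <- list(list(type = "Feature", properties = NULL,
                           geometry = list(type = "Polygon", coordinates = list())))
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  expect_error(read_water_features(path), class = "fishwolf_geometry_error")
})

test_that("camera records enforce the seven-code ethogram vocabulary", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("camera_id,timestamp,media,n_wolves,collar_status,behaviour",
               "CAM01,2018-05-07 21:00:00,video,1,collared,wading"), path)
  rec <- read_camera_records(path, tz = LOCAL_TZ)
  expect_equal(rec$behaviour, "wading")

  writeLines(c("camera_id,timestamp,media,n_wolves,collar_status,behaviour",
               "CAM01,2018-05-07 21:00:00,video,1,collared,swimming"), path)
  expect_error(read_camera_records(path), regexp = "on_creek_bank",
               class = "fishwolf_vocabulary_error")

  # identity count on a 59-record fixture, with sorting by (camera, time)
  recs <- event_fixture_59()
  shuffled <- recs[withr::with_seed(3, sample(nrow(recs))), ]
  f2 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(
    dplyr::mutate(shuffled, timestamp = format(t, "%Y-%m-%d %H:%M:%S"),
                  .keep = "unused"), f2)
  back <- read_camera_records(f2, tz = LOCAL_TZ)
  expect_equal(nrow(back), 59)
  expect_equal(back$t, recs$t)
})

test_that("annotations reject contradictory remains flags", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("cluster_id,fresh_fish_remains,wolf_sign_abundant,other_predator_sign,remains_old",
               "c1,TRUE,TRUE,FALSE,TRUE"), path)
  expect_error(read_annotations(path), class = "fishwolf_schema_error")
  writeLines(c("cluster_id,fresh_fish_remains,wolf_sign_abundant,other_predator_sign,remains_old",
               "c1,TRUE,TRUE,FALSE,FALSE"), path)
  ann <- read_annotations(path)
  expect_true(is_fishing_cluster(ann))
})
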