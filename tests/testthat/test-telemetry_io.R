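test_that("fix tables round-trip through CSV unchanged", {
  ds <- small_dataset()
  path <- withr::local_tempfile(fileext = ".csv")
  write_fixes(ds$fixes, path)
  back <- read_fixes(path)
  expect_identical(back$individual_id, ds$fixes$individual_id)
  expect_identical(back$sex, ds$fixes$sex)
  expect_equal(as.numeric(back$timestamp), as.numeric(ds$fixes$timestamp))
  expect_identical(back$x, ds$fixes$x)
  expect_identical(back$y, ds$fixes$y)
  expect_identical(back$survey_round, ds$fixes$survey_round)
})

test_that("read_fixes enforces its schema", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,sex,timestamp,x,y",
               "a,F,2015-10-10T01:00:00,0,0",
               "a,F,2015-10-10T02:00:00,1,1",
               "b,M,2015-10-10T01:00:00,5,5"), path)
  fx <- read_fixes(path)
  expect_equal(nrow(fx), 3L)
  expect_true(!is.unsorted(fx$timestamp[fx$individual_id == "a"],
                           strictly = TRUE))
  # survey round from calendar month, October -> 1
  expect_equal(unique(fx$survey_round), 1L)

  writeLines(c("id,sex,timestamp,x,y",
               "a,F,2015-10-10T01:00:00,0,0",
               "a,F,2015-10-10T01:00:00,1,1"), path)
  expect_error(read_fixes(path), "duplicated.*a")

  writeLines(c("id,sex,when,x,y", "a,F,2015-10-10T01:00:00,0,0"), path)
  expect_error(read_fixes(path), "missing required column.*timestamp")

  writeLines(c("id,sex,timestamp,x,y", "a,F,not-a-time,0,0"), path)
  expect_error(read_fixes(path), "unparseable timestamp.*1")
})

test_that("timestamps with offsets normalise to UTC", {
  expect_equal(parse_timestamp("2016-01-01T12:00:00+09:00"),
               as.POSIXct("2016-01-01 03:00:00", tz = "UTC"))
  expect_equal(parse_timestamp("2016-01-01T03:00:00Z"),
               parse_timestamp("2016-01-01 03:00:00"))
})

test_that("habitat annotation matches a ray-casting oracle", {
  ds <- small_dataset()
  set.seed(42)
  ext <- ds$map$extent
  pts <- data.frame(
    individual_id = sprintf("P%03d", 1:100), sex = "F",
    timestamp = as.POSIXct("2015-10-10", tz = "UTC") + (1:100) * 3600,
    x = runif(100, ext["xmin"] - 50, ext["xmax"] + 50),
    y = runif(100, ext["ymin"] - 50, ext["ymax"] + 50),
    survey_round = 1L)
  ann <- suppressWarnings(annotate_habitat(pts, ds$map))
  labs <- vapply(ds$map$patches, `[[`, "", "label")
  for (i in seq_len(100)) {
    hits <- vapply(ds$map$patches, function(p)
      oracle_point_in_polygon(pts$x[i], pts$y[i], p$ring), NA)
    for (lab in HABITAT_LABELS) {
      expected <- as.integer(any(hits & labs == lab))
      got <- ann[i, lab]
      # the package keeps one membership per category on exact ties;
      # the oracle has no tie rule, so only the any-membership agrees
      if (expected == 0) expect_equal(got, 0L)
    }
    veg_hit <- any(hits & labs %in% VEGETATION_LABELS)
    expect_equal(sum(ann[i, VEGETATION_LABELS]), as.integer(veg_hit))
  }
  # category indicators never exceed one
  expect_true(all(rowSums(ann[, VEGETATION_LABELS]) <= 1))
  expect_true(all(rowSums(ann[, LANDCOVER_LABELS]) <= 1))
})

test_that("containment and empty cases annotate as expected", {
  map <- habitat_map(c("TG", "OA"),
                     list(cbind(c(0, 100, 100, 0), c(0, 0, 100, 100)),
                          cbind(c(200, 300, 300, 200), c(0, 0, 100, 100))))
  fx <- make_fixes(c("a", "b"), c("F", "M"), 1:2, c(50, 150), c(50, 50))
  ann <- annotate_habitat(fx, map)
  expect_equal(unname(unlist(ann[1, HABITAT_LABELS])),
               as.integer(HABITAT_LABELS == "TG"))
  expect_equal(sum(ann[2, HABITAT_LABELS]), 0L)
  # outside the extent: warning, all zero
  far <- make_fixes("c", "F", 1, 1e6, 1e6)
  expect_warning(ann2 <- annotate_habitat(far, map), "outside")
  expect_equal(sum(ann2[1, HABITAT_LABELS]), 0L)
})

test_that("habitat map validation rejects bad geometry and labels", {
  expect_error(habitat_map("XX", list(cbind(c(0, 1, 1), c(0, 0, 1)))),
               "unknown habitat label")
  bowtie <- cbind(c(0, 1, 1, 0), c(0, 1, 0, 1))
  expect_error(habitat_map("TG", list(bowtie)), "self-intersecting")
  # two overlapping vegetation patches are invalid ...
  sq <- function(x0, y0, s) cbind(c(x0, x0 + s, x0 + s, x0),
                                  c(y0, y0, y0 + s, y0 + s))
  expect_error(habitat_map(c("TG", "FL"), list(sq(0, 0, 10), sq(5, 5, 10))),
               "vegetation patches overlap")
  # ... but vegetation over land cover is fine, as are shared edges
  expect_s3_class(habitat_map(c("TG", "OA"),
                              list(sq(0, 0, 10), sq(5, 5, 10))),
                  "habitat_map")
  expect_s3_class(habitat_map(c("TG", "FL"),
                              list(sq(0, 0, 10), sq(10, 0, 10))),
                  "habitat_map")
})

test_that("habitat maps round-trip through GeoJSON", {
  ds <- small_dataset()
  path <- withr::local_tempfile(fileext = ".geojson")
  write_habitat_map(ds$map, path)
  back <- read_habitat_map(path)
  expect_equal(length(back$patches), length(ds$map$patches))
  expect_equal(vapply(back$patches, `[[`, "", "label"),
               vapply(ds$map$patches, `[[`, "", "label"))
  expect_equal(back$patches[[3]]$ring, ds$map$patches[[3]]$ring,
               ignore_attr = TRUE)
})

test_that("temperature join equals a per-row lookup and errors on gaps", {
  temps <- reference_temperatures()
  fx <- make_fixes(c("a", "a", "b"), c("F", "F", "M"), 1:3,
                   1:3, 1:3)
  fx$survey_round <- c(1L, 2L, 1L)
  out <- attach_temperature(fx, temps)
  lookup <- setNames(temps$wt, temps$month_index)
  expect_equal(out$wt, unname(lookup[as.character(fx$survey_round)]))
  expect_equal(nrow(out), nrow(fx))
  fx$survey_round[1] <- 99L
  expect_error(attach_temperature(fx, temps), "99")
})

test_that("local planar projection is metric near the centroid", {
  # two points ~111 m apart in latitude
  pl <- lonlat_to_planar(c(126.5, 126.5), c(37.25, 37.251))
  expect_equal(pl$y[2] - pl$y[1], 111.2, tolerance = 0.01)
})
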