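test_that("simulation is bit-identical for a fixed seed and config", {
  a <- small_dataset(seed = 5L)
  b <- small_dataset(seed = 5L)
  expect_identical(a$fixes, b$fixes)
  expect_identical(lapply(a$map$patches, `[[`, "ring"),
                   lapply(b$map$patches, `[[`, "ring"))
  c <- small_dataset(seed = 6L)
  expect_false(identical(a$fixes$x, c$fixes$x))
})

test_that("generated maps cover all labels without vegetation overlap", {
  cfg <- sim_config(seed = 3L)
  map <- generate_habitat_map(cfg)
  labs <- vapply(map$patches, `[[`, "", "label")
  expect_true(all(HABITAT_LABELS %in% labs))
  expect_gte(length(map$patches), 8L)
  # validate_habitat_map ran at construction; re-run explicitly
  expect_silent(validate_habitat_map(map))
  # vegetation tiles the rectangle: shoelace areas sum to the extent area
  veg_area <- sum(vapply(map$patches[labs %in% VEGETATION_LABELS],
                         function(p) oracle_ring_area(p$ring), 0))
  # rings are emitted at cm precision, hence the loose tolerance
  expect_equal(veg_area, unname(cfg$extent["length"] * cfg$extent["width"]),
               tolerance = 1e-4)
  expect_error(generate_habitat_map(sim_config(extent = c(80, 40))),
               "too small")
})

test_that("degenerate movement settings behave as documented", {
  cfg <- sim_config(seed = 2L, n_females = 2L, n_males = 2L,
                    n_rounds = 1L,
                    extent = c(length = 2000, width = 374),
                    speed_model = list(p_move = 0, meanlog = 4.9,
                                       sdlog = 0.8, rest_speed = 0,
                                       p_stay_move = 0.7),
                    home = list(strength = 0, radius = 120),
                    avoid = list(strength = 0, radius = 260))
  sim <- simulate_trajectories(cfg, generate_habitat_map(cfg))
  st <- steps_by_individual(sim$fixes)
  expect_true(all(st$linear_speed == 0))
  expect_error(simulate_trajectories(sim_config(n_females = 0, n_males = 0)),
               "empty population")
})

test_that("turning concentration follows the kappa parameter", {
  base <- function(kappa) {
    cfg <- sim_config(seed = 9L, n_females = 3L, n_males = 3L,
                      n_rounds = 2L, turn_kappa = kappa,
                      extent = c(length = 50000, width = 50000),
                      home = list(strength = 0, radius = 100),
                      avoid = list(strength = 0, radius = 100),
                      dropout = 0)
    sim <- simulate_trajectories(cfg, generate_habitat_map(cfg))
    st <- steps_by_individual(sim$fixes)
    ta <- st$turning_angle[is.finite(st$turning_angle)]
    mean(cos(ta * pi / 180))
  }
  conc_high <- base(20)
  conc_low <- base(0.1)
  expect_gt(conc_high, 0.8)   # headings concentrate near 0 degrees
  expect_lt(conc_low, 0.4)
  expect_gt(conc_high, conc_low)
})

test_that("planted attraction raises in-habitat co-occurrence above the null", {
  run_one <- function(strength) {
    cfg <- sim_config(
      seed = 21L, n_females = 4L, n_males = 4L, n_rounds = 3L,
      extent = c(length = 2500, width = 374),
      association_plan = list(
        list(pair_class = "FM", habitat = "TG", rounds = 1:3,
             strength = strength, n_pairs = 2L)))
    map <- generate_habitat_map(cfg)
    sim <- simulate_trajectories(cfg, map)
    ann <- annotate_habitat(sim$fixes, map)
    sn <- build_snapshots(ann)
    ev <- detect_cooccurrences(sn, 250)
    ev <- ev[ev$pair_class == "FM", ]
    if (!nrow(ev)) return(c(frac = NA_real_, null = mean(sn$TG)))
    key <- paste(as.numeric(sn$snapshot_time), sn$individual_id)
    ia <- match(paste(as.numeric(ev$snapshot_time), ev$id_a), key)
    c(frac = mean(sn$TG[ia]), null = mean(sn$TG))
  }
  strong <- run_one(0.9)
  weak <- run_one(0)
  # with planting, F-M co-occurrences concentrate in the target habitat
  expect_gt(strong["frac"], strong["null"] + 0.2)
  # without planting the rate stays near the areal null
  if (is.finite(weak["frac"])) {
    expect_lt(abs(weak["frac"] - weak["null"]), 0.35)
  }
})

test_that("the reference dataset matches the study design", {
  ds <- get_reference_dataset()
  ids <- unique(ds$fixes$individual_id)
  expect_length(ids, 24L)
  expect_equal(sum(grepl("^F", ids)), 12L)
  expect_equal(sum(grepl("^M", ids)), 12L)
  expect_equal(sort(unique(ds$fixes$survey_round)), 1:12)
  expect_equal(nrow(ds$temps), 12L)

  # fixes fall inside the (rotated) site rectangle
  uv <- nutrisom:::.xy_to_uv(ds$fixes$x, ds$fixes$y)
  expect_true(all(uv[, 1] >= -1 & uv[, 1] <= 6901))
  expect_true(all(uv[, 2] >= -1 & uv[, 2] <= 375))

  # strictly increasing timestamps per individual
  expect_silent(validate_fixes(ds$fixes))

  # marginal speed within the calibration band around 48.3 / 96.2 m/h
  s <- movement_summary(steps_by_individual(ds$fixes))
  expect_gt(s$mean_speed, 36.2)
  expect_lt(s$mean_speed, 60.4)
  expect_gt(s$sd_speed, 0.75 * 96.2)
  expect_lt(s$sd_speed, 1.25 * 96.2)
})

test_that("written datasets are byte-stable and readable", {
  ds <- small_dataset()
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_dataset(ds, d1)
  write_dataset(small_dataset(), d2)
  for (f in c("fixes.csv", "habitat.geojson", "temps.csv", "truth.json")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  expect_error(write_dataset(ds, d1), "exist")
  fx <- read_fixes(file.path(d1, "fixes.csv"))
  expect_equal(nrow(fx), nrow(ds$fixes))
})
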