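# End-to-end workflow: movement stats -> snapshots -> neighbour
# distances (imputed, filtered) -> co-occurrence sweep + stable radius
# -> Geo-SOM trainings (female-target, male-target, all) -> clustering
# + statistics -> association table, with a reproducibility manifest.

#' Pipeline configuration
#'
#' Defaults match the reference settings throughout: snapshot tolerance
#' 30 min on a 1 h grid, 3 h maximum step gap, 50-2000 m radius sweep,
#' 250 m co-occurrence radius, a 9 x 6 map with geographic tolerance
#' k = 3 trained rough 200/4/0.2 + fine 20/10/0.1, k-means over 2..10,
#' and the sex-specific eligibility thresholds (54/80 for the distance
#' analysis, 38/34 for the co-occurrence analysis).
#'
#' @param seed run seed (all stages derive their randomness from it).
#' @param snapshot_tolerance minutes; `interval` hours.
#' @param max_gap hours.
#' @param radii sweep radii (m); `base_radius` the sweep's base.
#' @param cooccur_radius radius for the co-occurrence analysis (m).
#' @param rows,cols,k,phases map geometry, geographic tolerance and
#'   training schedule.
#' @param k_range,restarts codebook clustering settings.
#' @param dist_min_f,dist_min_m,cooc_min_f,cooc_min_m eligibility
#'   thresholds.
#' @param targets which training targets to run.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            snapshot_tolerance = 30, interval = 1,
                            max_gap = 3,
                            radii = seq(50, 2000, by = 50),
                            base_radius = 50,
                            cooccur_radius = 250,
                            rows = 9L, cols = 6L, k = 3L,
                            phases = som_phases(),
                            k_range = 2:10, restarts = 20L,
                            dist_min_f = 54L, dist_min_m = 80L,
                            cooc_min_f = 38L, cooc_min_m = 34L,
                            targets = c("F", "M", "all")) {
  structure(as.list(environment()), class = "pipeline_config")
}

.training_variables <- function(kind = c("distance", "cooccurrence")) {
  kind <- match.arg(kind)
  base <- c("X", "Y", "WT", HABITAT_LABELS, "LiS", "AnS")
  if (kind == "distance") c(base, "DAS", "DSS", "DDS")
  else c(base, "FM", "FF", "MM")
}

# assemble per-(individual, snapshot) training samples; returns the raw
# (unnormalised) sample table with a sex column alongside
.build_samples <- function(snapshots, records, kind) {
  key_s <- paste(as.numeric(snapshots$snapshot_time),
                 snapshots$individual_id)
  out <- data.frame(individual_id = snapshots$individual_id,
                    sex = snapshots$sex,
                    snapshot_time = snapshots$snapshot_time,
                    X = snapshots$x, Y = snapshots$y,
                    WT = snapshots$wt)
  for (h in HABITAT_LABELS) out[[h]] <- snapshots[[h]]
  out$LiS <- snapshots$LiS
  out$AnS <- snapshots$AnS
  if (kind == "distance") {
    key_r <- paste(as.numeric(records$snapshot_time), records$individual_id)
    m <- match(key_s, key_r)
    out$DAS <- records$das[m]
    out$DSS <- records$dss[m]
    out$DDS <- records$dds[m]
  } else {
    out$FM <- snapshots$inc_FM
    out$FF <- snapshots$inc_FF
    out$MM <- snapshots$inc_MM
  }
  out
}

# mean-impute LiS/AnS per individual (sparse step-undefined samples),
# then drop rows that still carry NA in any training variable
.complete_samples <- function(samples, vars) {
  for (v in c("LiS", "AnS")) {
    if (!v %in% vars) next
    samples[[v]] <- ave(samples[[v]], samples$individual_id,
                        FUN = function(z) {
                          z[is.na(z)] <- mean(z, na.rm = TRUE)
                          z
                        })
  }
  keep <- complete.cases(samples[, vars, drop = FALSE])
  samples[keep, , drop = FALSE]
}

.train_target <- function(samples, vars, config, target, seed_offset) {
  sub <- if (target == "all") samples else
    samples[samples$sex == target, , drop = FALSE]
  if (nrow(sub) < 10L) return(NULL)
  sc <- som_scale(sub[, vars, drop = FALSE])
  grid <- som_grid(config$rows, config$cols, variables = vars,
                   seed = config$seed + seed_offset)
  grid <- som_train(grid, sc$x, phases = config$phases, k = config$k,
                    seed = config$seed + seed_offset)
  grid$norm <- list(min = sc$min, range = sc$range)
  bmu <- bmu_map(grid, sc$x)
  list(grid = grid, samples = sub, scaled = sc$x, bmu = bmu,
       target = target)
}

#' Run the full analysis pipeline
#'
#' @param fixes fix table ([read_fixes()] dialect).
#' @param map `habitat_map` in the same planar frame.
#' @param temps monthly water-temperature table.
#' @param config [pipeline_config()].
#' @return list of class `pipeline_result` with stages: movement
#'   (`steps`, `movement_summary`), `snapshots`, neighbour `records`
#'   (+ imputation summary, eligible ids), co-occurrence (`profiles`,
#'   `events`, `stable_radius`), trainings (`distance`,
#'   `cooccurrence`: one entry per target with grid, samples, bmu),
#'   `clustering` + `cluster_stats` + `cluster_tests`, `sr_plane`,
#'   `association` (ranks per class and the tally table), and
#'   `manifest`.
#' @export
run_pipeline <- function(fixes, map, temps, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  validate_fixes(fixes)
  counts <- list(n_fixes = nrow(fixes),
                 n_individuals = length(unique(fixes$individual_id)))

  fixes <- annotate_habitat(fixes, map)
  fixes <- attach_temperature(fixes, temps)

  steps <- steps_by_individual(fixes, max_gap = config$max_gap)
  mv <- movement_summary(steps)
  # join per-step metrics back to the fix ending each step
  key_f <- paste(fixes$individual_id, as.numeric(fixes$timestamp))
  key_s <- paste(steps$individual_id, as.numeric(steps$t1))
  m <- match(key_f, key_s)
  fixes$LiS <- steps$linear_speed[m]
  fixes$AnS <- steps$angular_speed[m]

  snapshots <- build_snapshots(fixes, tolerance = config$snapshot_tolerance,
                               interval = config$interval)
  counts$n_snapshots <- length(unique(snapshots$snapshot_time))

  records <- neighbor_records(snapshots)
  eligible_dist <- eligibility_filter(records, config$dist_min_f,
                                      config$dist_min_m)
  records_el <- records[records$individual_id %in% eligible_dist, ,
                        drop = FALSE]
  records_el <- impute_missing(records_el)
  counts$n_records <- nrow(records)
  counts$n_eligible_distance <- length(eligible_dist)

  sweep <- radius_sweep(snapshots, radii = config$radii)
  sr_m <- stable_radius(sweep$profiles, base_radius = config$base_radius)
  events <- sweep$events[sweep$events$distance <= config$cooccur_radius, ,
                         drop = FALSE]
  events$radius <- config$cooccur_radius
  counts$n_events <- nrow(events)
  snapshots <- cooccurrence_incidence(snapshots, events)

  dist_vars <- .training_variables("distance")
  cooc_vars <- .training_variables("cooccurrence")
  dist_samples <- .build_samples(snapshots, records_el, "distance")
  dist_samples <- dist_samples[dist_samples$individual_id %in%
                                 eligible_dist, , drop = FALSE]
  dist_samples <- .complete_samples(dist_samples, dist_vars)

  eligible_cooc <- eligibility_filter(records, config$cooc_min_f,
                                      config$cooc_min_m)
  cooc_samples <- .build_samples(snapshots, records_el, "cooccurrence")
  cooc_samples <- cooc_samples[cooc_samples$individual_id %in%
                                 eligible_cooc, , drop = FALSE]
  cooc_samples <- .complete_samples(cooc_samples, cooc_vars)
  counts$n_distance_samples <- nrow(dist_samples)
  counts$n_cooccurrence_samples <- nrow(cooc_samples)

  trainings <- list(distance = list(), cooccurrence = list())
  off <- 10L
  for (tg in config$targets) {
    trainings$distance[[tg]] <-
      .train_target(dist_samples, dist_vars, config, tg, off)
    off <- off + 1L
    trainings$cooccurrence[[tg]] <-
      .train_target(cooc_samples, cooc_vars, config, tg, off)
    off <- off + 1L
  }

  # clustering + distance statistics on the all-individuals distance map
  clustering <- NULL; cstats <- NULL; ctests <- NULL; sr_plane <- NULL
  tr_all <- trainings$distance[["all"]]
  if (!is.null(tr_all)) {
    clustering <- kmeans_codebook(tr_all$grid, k_range = config$k_range,
                                  seed = config$seed,
                                  restarts = config$restarts)
    samp <- tr_all$samples
    samp$das <- samp$DAS; samp$dss <- samp$DSS; samp$dds <- samp$DDS
    samp$dss_f <- ifelse(samp$sex == "F", samp$DSS, NA_real_)
    samp$dss_m <- ifelse(samp$sex == "M", samp$DSS, NA_real_)
    cstats <- cluster_distance_stats(
      clustering, samp, tr_all$bmu,
      variables = c("das", "dss", "dds", "dss_f", "dss_m"))
    cl <- attr(cstats, "cluster_of_sample")
    ctests <- compare_clusters(samp$dds, cl)
    sr_plane <- sex_ratio_plane(tr_all$grid, tr_all$bmu, samp$sex)
  }

  # association scoring on the all-individuals co-occurrence map
  association <- NULL
  tr_cooc <- trainings$cooccurrence[["all"]]
  if (!is.null(tr_cooc)) {
    planes <- component_planes(tr_cooc$grid)
    class_planes <- lapply(c(FM = "FM", FF = "FF", MM = "MM"),
                           function(v) plane_vector(planes, v))
    habitat_planes <- lapply(setNames(nm = HABITAT_LABELS),
                             function(v) plane_vector(planes, v))
    ranks <- lapply(class_planes, function(p)
      rank_plane_associations(habitat_planes, p))
    association <- list(
      planes = planes,
      ranks = ranks,
      table = association_table(class_planes, habitat_planes))
  }

  manifest <- list(
    package = "nutrisom",
    version = as.character(utils::packageVersion("nutrisom")),
    seed = config$seed,
    settings = list(
      snapshot_tolerance = config$snapshot_tolerance,
      interval = config$interval, max_gap = config$max_gap,
      radii = range(config$radii), base_radius = config$base_radius,
      cooccur_radius = config$cooccur_radius,
      grid = c(config$rows, config$cols), k = config$k,
      phases = config$phases, k_range = range(config$k_range),
      restarts = config$restarts,
      eligibility = c(dist_f = config$dist_min_f,
                      dist_m = config$dist_min_m,
                      cooc_f = config$cooc_min_f,
                      cooc_m = config$cooc_min_m)),
    counts = counts)

  structure(list(steps = steps, movement_summary = mv,
                 snapshots = snapshots, records = records,
                 records_eligible = records_el,
                 eligible_distance = eligible_dist,
                 eligible_cooccurrence = eligible_cooc,
                 profiles = sweep$profiles, events = events,
                 stable_radius = sr_m,
                 trainings = trainings,
                 clustering = clustering, cluster_stats = cstats,
                 cluster_tests = ctests, sr_plane = sr_plane,
                 association = association,
                 manifest = manifest),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result\n")
  cat(sprintf("  fixes: %d (%d individuals), snapshots: %d\n",
              x$manifest$counts$n_fixes, x$manifest$counts$n_individuals,
              x$manifest$counts$n_snapshots))
  cat(sprintf("  mean speed %.1f m/h (SD %.1f), stable radius %d m, %d events\n",
              x$movement_summary$mean_speed, x$movement_summary$sd_speed,
              x$stable_radius, x$manifest$counts$n_events))
  if (!is.null(x$clustering)) {
    cat(sprintf("  codebook clusters: k = %d\n", x$clustering$selected_k))
  }
  invisible(x)
}

#' Write pipeline outputs to a directory
#'
#' Deterministic text outputs: the manifest is written first, then the
#' per-stage CSVs (steps, neighbour records, co-occurrence profiles and
#' events, component planes per training, node clusters, cluster
#' statistics, pairwise tests, association scores and tally).
#' Re-running the pipeline with the same inputs and config reproduces
#' the files byte for byte.
#'
#' @param result `pipeline_result`.
#' @param dir output directory.
#' @param force overwrite existing files.
#' @return `dir`, invisibly.
#' @export
write_pipeline_outputs <- function(result, dir, force = FALSE) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wcsv <- function(df, name) {
    path <- file.path(dir, name)
    if (file.exists(path) && !force) {
      stop("output exists: ", path, " (use force = TRUE)")
    }
    df <- as.data.frame(df)
    for (nm in names(df)) {
      if (inherits(df[[nm]], "POSIXct")) {
        df[[nm]] <- format(df[[nm]], "%Y-%m-%dT%H:%M:%S", tz = "UTC")
      }
    }
    write.csv(df, path, row.names = FALSE, quote = FALSE)
  }
  jsonlite::write_json(result$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  wcsv(result$steps, "steps.csv")
  wcsv(result$records, "neighbor_records.csv")
  wcsv(result$profiles, "cooccurrence_profiles.csv")
  wcsv(result$events, "cooccurrence_events.csv")
  for (kind in names(result$trainings)) {
    for (tg in names(result$trainings[[kind]])) {
      tr <- result$trainings[[kind]][[tg]]
      if (is.null(tr)) next
      wcsv(component_planes(tr$grid),
           sprintf("planes_%s_%s.csv", kind, tg))
    }
  }
  if (!is.null(result$clustering)) {
    tr <- result$trainings$distance[["all"]]
    wcsv(data.frame(node = seq_along(result$clustering$labels),
                    row = tr$grid$coords[, 1], col = tr$grid$coords[, 2],
                    cluster = result$clustering$labels), "clusters.csv")
    wcsv(result$cluster_stats, "cluster_stats.csv")
    wcsv(result$cluster_tests, "cluster_tests.csv")
    wcsv(result$sr_plane, "sr_plane.csv")
  }
  if (!is.null(result$association)) {
    tab <- result$association$table
    wcsv(cbind(pair_class = rownames(tab), as.data.frame(tab)),
         "association_table.csv")
    ranks <- do.call(rbind, lapply(names(result$association$ranks),
      function(cl) cbind(pair_class = cl, result$association$ranks[[cl]])))
    wcsv(ranks, "association_ranks.csv")
  }
  invisible(dir)
}
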