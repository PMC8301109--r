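# Time-matched snapshots and sex-stratified nearest-neighbour distances:
# DAS (any neighbour), DSS (same sex), DDS (different sex).

#' Build time-matched multi-individual snapshots
#'
#' The snapshot grid is the union of fix times rounded to the nominal
#' fix interval. Each individual contributes, per snapshot, its
#' temporally closest fix within `tolerance` minutes, or is absent.
#'
#' @param fixes multi-individual fix table (any extra columns are
#'   carried through).
#' @param tolerance half-window in minutes (default 30, half the minimum
#'   1 h fix interval).
#' @param interval nominal fix interval in hours used for rounding.
#' @return long data.frame: one row per (snapshot_time, individual)
#'   membership, with `snapshot_time` prepended to the fix columns.
#' @export
build_snapshots <- function(fixes, tolerance = 30, interval = 1) {
  if (tolerance <= 0) stop("tolerance must be positive (minutes)")
  if (interval <= 0) stop("interval must be positive (hours)")
  step <- interval * 3600
  tol <- tolerance * 60
  tms <- as.numeric(fixes$timestamp)
  grid <- sort(unique(round(tms / step) * step))
  parts <- lapply(split(seq_len(nrow(fixes)), fixes$individual_id),
                  function(idx) {
    ft <- tms[idx]
    # nearest fix per grid time
    pos <- findInterval(grid, ft)
    lo <- pmax(pos, 1L)
    hi <- pmin(pos + 1L, length(ft))
    d_lo <- abs(grid - ft[lo])
    d_hi <- abs(grid - ft[hi])
    nearest <- ifelse(d_hi < d_lo, hi, lo)
    dmin <- pmin(d_lo, d_hi)
    keep <- dmin <= tol
    if (!any(keep)) return(NULL)
    out <- fixes[idx[nearest[keep]], , drop = FALSE]
    out$snapshot_time <- as.POSIXct(grid[keep], origin = "1970-01-01",
                                    tz = "UTC")
    out
  })
  out <- do.call(rbind, parts)
  if (is.null(out)) {
    stop("no snapshot memberships within tolerance")
  }
  out <- out[order(out$snapshot_time, out$individual_id), , drop = FALSE]
  rownames(out) <- NULL
  out[, c("snapshot_time", setdiff(names(out), "snapshot_time"))]
}

#' Nearest-neighbour distances for one target in one snapshot
#'
#' @param snapshot data.frame of one snapshot's members (columns
#'   `individual_id`, `sex`, `x`, `y`).
#' @param target_id id of the target individual (must be a member).
#' @return one-row data.frame with `das`, `dss`, `dds` (meters; NA when
#'   the category is empty) and the nearest neighbour id per category.
#'   Ties are broken by lowest individual id.
#' @export
neighbor_distances <- function(snapshot, target_id) {
  i <- which(snapshot$individual_id == target_id)
  if (!length(i)) stop("target ", target_id, " absent from snapshot")
  i <- i[1]
  others <- snapshot[-i, , drop = FALSE]
  # deterministic tie-break on equal distances
  others <- others[order(others$individual_id), , drop = FALSE]
  d <- sqrt((others$x - snapshot$x[i])^2 + (others$y - snapshot$y[i])^2)
  pick <- function(mask) {
    if (!any(mask)) return(c(NA_real_, NA_character_))
    j <- which(mask)[which.min(d[mask])]
    c(d[j], others$individual_id[j])
  }
  same <- pick(others$sex == snapshot$sex[i])
  diff_ <- pick(others$sex != snapshot$sex[i])
  all_ <- pick(rep(TRUE, nrow(others)))
  data.frame(individual_id = target_id,
             sex = snapshot$sex[i],
             das = as.numeric(all_[1]), nearest_any = all_[2],
             dss = as.numeric(same[1]), nearest_same = same[2],
             dds = as.numeric(diff_[1]), nearest_diff = diff_[2],
             stringsAsFactors = FALSE)
}

#' Neighbour records for every member of every snapshot
#'
#' @param snapshots long snapshot table from [build_snapshots()].
#' @return data.frame with one record per (snapshot_time, individual):
#'   `snapshot_time`, `individual_id`, `sex`, `das`, `dss`, `dds` and
#'   nearest ids. `das = min(dss, dds)` whenever both exist.
#' @export
neighbor_records <- function(snapshots) {
  parts <- lapply(split(snapshots, snapshots$snapshot_time), function(sn) {
    recs <- do.call(rbind, lapply(sn$individual_id, neighbor_distances,
                                  snapshot = sn))
    recs$snapshot_time <- sn$snapshot_time[1]
    recs
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out[, c("snapshot_time", "individual_id", "sex", "das", "dss", "dds",
          "nearest_any", "nearest_same", "nearest_diff")]
}

#' Impute sparsely missing neighbour distances by individual mean
#'
#' For each (individual, variable), if the missing fraction is below
#' `max_missing_fraction` the missing entries are replaced by that
#' individual's mean of the observed values; otherwise they are left
#' missing and flagged. An all-missing variable is flagged, never
#' imputed.
#'
#' @param records neighbour records from [neighbor_records()].
#' @param variables which distance columns to treat (default das, dss,
#'   dds).
#' @param max_missing_fraction imputation domain boundary (default 0.05,
#'   i.e. the rule applies only when less than 5% is missing).
#' @return the records with imputed values, logical `<var>_imputed`
#'   columns, and an `imputation` attribute summarising each
#'   (individual, variable): `n`, `n_missing`, `fraction`, `imputed`.
#' @export
impute_missing <- function(records, variables = c("das", "dss", "dds"),
                           max_missing_fraction = 0.05) {
  stopifnot(all(variables %in% names(records)))
  summary_rows <- list()
  for (v in variables) {
    records[[paste0(v, "_imputed")]] <- FALSE
  }
  for (id in unique(records$individual_id)) {
    sel <- records$individual_id == id
    for (v in variables) {
      vals <- records[[v]][sel]
      n_miss <- sum(is.na(vals))
      frac <- n_miss / length(vals)
      do_impute <- n_miss > 0 && frac < max_missing_fraction &&
        n_miss < length(vals)
      if (do_impute) {
        m <- mean(vals, na.rm = TRUE)
        miss_idx <- which(sel)[is.na(vals)]
        records[[v]][miss_idx] <- m
        records[[paste0(v, "_imputed")]][miss_idx] <- TRUE
      }
      summary_rows[[length(summary_rows) + 1L]] <- data.frame(
        individual_id = id, variable = v, n = length(vals),
        n_missing = n_miss, fraction = frac, imputed = do_impute)
    }
  }
  attr(records, "imputation") <- do.call(rbind, summary_rows)
  records
}

#' Select individuals with enough samples for training
#'
#' Mirrors the study's eligibility rule: sex-specific minimum sample
#' counts (reference thresholds 54 for females and 80 for males in the
#' distance analysis; 38 and 34 in the co-occurrence analysis).
#'
#' @param records neighbour records (or any table with `individual_id`
#'   and `sex`, one row per sample).
#' @param min_f,min_m sex-specific minimum record counts.
#' @return character vector of included individual ids.
#' @export
eligibility_filter <- function(records, min_f = 54L, min_m = 80L) {
  cnt <- table(records$individual_id)
  sex <- vapply(split(records$sex, records$individual_id), `[`, "", 1)
  thr <- ifelse(sex == "F", min_f, min_m)
  keep <- names(cnt)[as.vector(cnt) >= thr[names(cnt)]]
  if (!length(keep)) {
    warning("no individual meets the eligibility thresholds")
  }
  sort(keep)
}
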