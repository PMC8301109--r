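#' @useDynLib nutrisom, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats aggregate ave complete.cases cor dist kmeans p.adjust
#'   rbinom rlnorm runif sd setNames t.test quantile rexp
#' @importFrom utils read.csv write.csv head
NULL

#' Habitat label vocabulary
#'
#' Vegetation types: hydric herbaceous vegetation (HHV), tall grassland
#' (TG), xeric herbaceous vegetation (XHV), hydric woody vegetation (HWV),
#' floating-leaved hydrophytes (FL). Land-cover states: open area (OA),
#' road (R), artificial structure (AS). Vegetation patches must not
#' overlap each other; a vegetation patch may overlap a land-cover patch.
#'
#' @format Character vectors.
#' @name habitat_labels
NULL

#' @rdname habitat_labels
#' @export
VEGETATION_LABELS <- c("HHV", "TG", "XHV", "HWV", "FL")

#' @rdname habitat_labels
#' @export
LANDCOVER_LABELS <- c("OA", "R", "AS")

#' @rdname habitat_labels
#' @export
HABITAT_LABELS <- c(VEGETATION_LABELS, LANDCOVER_LABELS)

.default_dialect <- c(id = "id", sex = "sex", timestamp = "timestamp",
                      x = "x", y = "y", round = "round")

#' Parse ISO-8601 timestamps to timezone-naive UTC
#'
#' Accepts `YYYY-MM-DD HH:MM:SS` or the `T`-separated form, optionally
#' suffixed with `Z` or a `+hh:mm`/`-hhmm` offset; offsets are normalised
#' away so the internal representation is UTC throughout.
#'
#' @param x character vector of timestamps.
#' @return POSIXct vector (UTC); NA where unparseable.
#' @keywords internal
parse_timestamp <- function(x) {
  x <- trimws(as.character(x))
  x <- sub("T", " ", x, fixed = TRUE)
  off_min <- rep(0, length(x))
  has_z <- grepl("Z$", x)
  x[has_z] <- sub("Z$", "", x[has_z])
  m <- regexpr("[+-][0-9]{2}:?[0-9]{2}$", x)
  has_off <- m > 0
  if (any(has_off)) {
    off <- regmatches(x, m)
    sign <- ifelse(substr(off, 1, 1) == "-", -1, 1)
    digits <- gsub("[^0-9]", "", off)
    off_min[has_off] <- sign * (as.numeric(substr(digits, 1, 2)) * 60 +
                                as.numeric(substr(digits, 3, 4)))
    x[has_off] <- substr(x[has_off], 1, nchar(x[has_off]) - nchar(off))
    x <- trimws(x)
  }
  # bare dates get midnight
  bare <- !grepl(" ", x) & nzchar(x)
  x[bare] <- paste(x[bare], "00:00:00")
  out <- as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01",
                    tz = "UTC")
  for (fmt in c("%Y-%m-%d %H:%M:%OS", "%Y-%m-%d %H:%M")) {
    idx <- which(is.na(out))
    if (!length(idx)) break
    out[idx] <- as.POSIXct(strptime(x[idx], fmt, tz = "UTC"), tz = "UTC")
  }
  out - off_min * 60
}

#' Derive the survey-round index from calendar months
#'
#' Rounds number the monthly survey campaigns 1..12. With the reference
#' layout (start month October) October maps to 1 and September to 12.
#'
#' @param timestamp POSIXct vector.
#' @param start_month first calendar month of the survey year (default 10).
#' @return integer vector in 1..12.
#' @export
survey_round_of <- function(timestamp, start_month = 10L) {
  mon <- as.integer(format(timestamp, "%m"))
  ((mon - start_month) %% 12L) + 1L
}

#' Read a telemetry fix table from CSV
#'
#' One row per radio-tracking observation: individual id, sex (F/M),
#' ISO-8601 timestamp, planar easting/northing in meters. Rows are sorted
#' by (individual, time); duplicated (individual, timestamp) keys are an
#' error, as are non-increasing timestamps within an individual.
#'
#' @param path CSV file path.
#' @param dialect named character vector mapping the canonical names
#'   `id`, `sex`, `timestamp`, `x`, `y` (optionally `round`) to the file's
#'   column names.
#' @param start_month calendar month mapped to survey round 1.
#' @return data.frame with columns `individual_id`, `sex`, `timestamp`,
#'   `x`, `y`, `survey_round`.
#' @export
read_fixes <- function(path, dialect = NULL, start_month = 10L) {
  dia <- .default_dialect
  if (!is.null(dialect)) dia[names(dialect)] <- dialect
  # colClasses keeps a single-sex column ("F"/"T") from becoming logical
  raw <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                  colClasses = "character")
  need <- dia[c("id", "sex", "timestamp", "x", "y")]
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols)) {
    stop("fix table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  ts <- parse_timestamp(raw[[dia[["timestamp"]]]])
  if (anyNA(ts)) {
    bad <- which(is.na(ts))
    stop("unparseable timestamp at data line(s): ",
         paste(head(bad, 5L), collapse = ", "),
         if (length(bad) > 5L) " ..." else "")
  }
  fixes <- data.frame(
    individual_id = as.character(raw[[dia[["id"]]]]),
    sex = as.character(raw[[dia[["sex"]]]]),
    timestamp = ts,
    x = as.numeric(raw[[dia[["x"]]]]),
    y = as.numeric(raw[[dia[["y"]]]]),
    stringsAsFactors = FALSE
  )
  if (dia[["round"]] %in% names(raw)) {
    fixes$survey_round <- as.integer(raw[[dia[["round"]]]])
  } else {
    fixes$survey_round <- survey_round_of(ts, start_month)
  }
  validate_fixes(fixes)
  fixes[order(fixes$individual_id, fixes$timestamp), , drop = FALSE] |>
    `rownames<-`(NULL)
}

#' Validate a fix table
#'
#' @param fixes data.frame as returned by [read_fixes()].
#' @return the table, invisibly; errors describe the first violation.
#' @export
validate_fixes <- function(fixes) {
  stopifnot(is.data.frame(fixes))
  need <- c("individual_id", "sex", "timestamp", "x", "y", "survey_round")
  miss <- setdiff(need, names(fixes))
  if (length(miss)) stop("fix table lacks column(s): ", paste(miss, collapse = ", "))
  if (!all(fixes$sex %in% c("F", "M"))) {
    stop("sex must be 'F' or 'M' for every fix")
  }
  if (!all(is.finite(fixes$x)) || !all(is.finite(fixes$y))) {
    stop("fix coordinates must be finite")
  }
  key <- paste(fixes$individual_id, format(fixes$timestamp, "%Y-%m-%d %H:%M:%OS3"))
  if (anyDuplicated(key)) {
    dup <- unique(key[duplicated(key)])
    stop("duplicated (individual, timestamp) key(s): ",
         paste(head(dup, 5L), collapse = "; "))
  }
  ord <- order(fixes$individual_id, fixes$timestamp)
  f <- fixes[ord, ]
  same <- f$individual_id[-1] == f$individual_id[-nrow(f)]
  if (nrow(f) > 1 && any(same & diff(as.numeric(f$timestamp)) <= 0)) {
    stop("timestamps must be strictly increasing within an individual")
  }
  invisible(fixes)
}

#' Write a fix table to CSV
#'
#' Emits the dialect that [read_fixes()] consumes:
#' `id,sex,timestamp,x,y,round` with ISO-8601 UTC timestamps. Writing then
#' reading a valid table is the identity.
#'
#' @param fixes fix table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fixes <- function(fixes, path) {
  validate_fixes(fixes)
  out <- data.frame(
    id = fixes$individual_id,
    sex = fixes$sex,
    timestamp = format(fixes$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    x = fixes$x,
    y = fixes$y,
    round = fixes$survey_round
  )
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct a habitat map
#'
#' A habitat map is a list of labelled simple polygons in planar meter
#' coordinates. Labels come from the fixed eight-member vocabulary
#' ([HABITAT_LABELS]); two vegetation patches must not overlap, while a
#' vegetation patch and a land-cover patch may.
#'
#' @param labels character vector, one per patch.
#' @param rings list of two-column numeric matrices (x, y), one ring per
#'   patch; rings need not repeat the first vertex.
#' @return object of class `habitat_map`.
#' @export
habitat_map <- function(labels, rings) {
  stopifnot(length(labels) == length(rings), length(labels) >= 1L)
  labels <- as.character(labels)
  bad <- setdiff(labels, HABITAT_LABELS)
  if (length(bad)) stop("unknown habitat label(s): ", paste(bad, collapse = ", "))
  rings <- lapply(rings, function(r) {
    r <- as.matrix(r)
    stopifnot(ncol(r) == 2, nrow(r) >= 3)
    # drop a duplicated closing vertex
    if (all(r[1, ] == r[nrow(r), ])) r <- r[-nrow(r), , drop = FALSE]
    storage.mode(r) <- "double"
    colnames(r) <- c("x", "y")
    r
  })
  patches <- Map(function(l, r) list(label = l, ring = r), labels, rings)
  names(patches) <- NULL
  xs <- unlist(lapply(rings, function(r) r[, 1]))
  ys <- unlist(lapply(rings, function(r) r[, 2]))
  map <- structure(
    list(patches = patches,
         extent = c(xmin = min(xs), xmax = max(xs),
                    ymin = min(ys), ymax = max(ys))),
    class = "habitat_map"
  )
  validate_habitat_map(map)
  map
}

#' @export
print.habitat_map <- function(x, ...) {
  labs <- vapply(x$patches, `[[`, "", "label")
  cat("habitat_map:", length(x$patches), "patches;",
      "labels:", paste(sort(unique(labs)), collapse = " "), "\n")
  cat(sprintf("extent: x [%.1f, %.1f]  y [%.1f, %.1f] m\n",
              x$extent["xmin"], x$extent["xmax"],
              x$extent["ymin"], x$extent["ymax"]))
  invisible(x)
}

# segment intersection test used by the simplicity / overlap checks
.segments_cross <- function(p1, p2, q1, q2) {
  o <- function(a, b, c) {
    v <- (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
    sign(v)
  }
  o1 <- o(p1, p2, q1); o2 <- o(p1, p2, q2)
  o3 <- o(q1, q2, p1); o4 <- o(q1, q2, p2)
  (o1 != o2 && o3 != o4 && o1 != 0 && o2 != 0 && o3 != 0 && o4 != 0)
}

.ring_simple <- function(r) {
  n <- nrow(r)
  seg <- function(i) list(r[i, ], r[if (i == n) 1L else i + 1L, ])
  for (i in seq_len(n - 2L)) {
    for (j in (i + 2L):n) {
      if (i == 1L && j == n) next  # adjacent through the wrap
      a <- seg(i); b <- seg(j)
      if (.segments_cross(a[[1]], a[[2]], b[[1]], b[[2]])) return(FALSE)
    }
  }
  TRUE
}

.rings_overlap <- function(a, b) {
  # strict interior overlap of simple rings: any proper edge crossing, or
  # one ring's vertex strictly inside the other
  na <- nrow(a); nb <- nrow(b)
  for (i in seq_len(na)) {
    p1 <- a[i, ]; p2 <- a[if (i == na) 1L else i + 1L, ]
    for (j in seq_len(nb)) {
      q1 <- b[j, ]; q2 <- b[if (j == nb) 1L else j + 1L, ]
      if (.segments_cross(p1, p2, q1, q2)) return(TRUE)
    }
  }
  strict_in <- function(px, py, ring) {
    point_in_ring(px, py, ring, boundary = FALSE) &
      !.on_ring_boundary(px, py, ring, eps = 1e-6)
  }
  any(strict_in(a[, 1], a[, 2], b)) || any(strict_in(b[, 1], b[, 2], a))
}

#' Validate a habitat map
#'
#' Checks the label vocabulary, ring simplicity and the
#' vegetation/vegetation non-overlap invariant.
#'
#' @param map `habitat_map`.
#' @return the map, invisibly.
#' @export
validate_habitat_map <- function(map) {
  stopifnot(inherits(map, "habitat_map"))
  labs <- vapply(map$patches, `[[`, "", "label")
  bad <- setdiff(labs, HABITAT_LABELS)
  if (length(bad)) stop("unknown habitat label(s): ", paste(bad, collapse = ", "))
  for (p in map$patches) {
    if (!.ring_simple(p$ring)) {
      stop("self-intersecting polygon for label ", p$label)
    }
  }
  veg <- which(labs %in% VEGETATION_LABELS)
  if (length(veg) > 1L) {
    for (i in seq_along(veg)[-length(veg)]) {
      for (j in (i + 1L):length(veg)) {
        if (.rings_overlap(map$patches[[veg[i]]]$ring,
                           map$patches[[veg[j]]]$ring)) {
          stop("vegetation patches overlap: ", labs[veg[i]], " and ",
               labs[veg[j]])
        }
      }
    }
  }
  invisible(map)
}

#' Point-in-polygon test for a single ring
#'
#' Crossing-parity test with an explicit boundary rule: points on the
#' boundary count as inside (closed polygons), which keeps habitat
#' annotation deterministic.
#'
#' @param x,y point coordinates.
#' @param ring two-column matrix of ring vertices (unclosed).
#' @param boundary logical; if `TRUE` boundary points are inside.
#' @param eps boundary snap distance in meters.
#' @return logical vector.
#' @export
point_in_ring <- function(x, y, ring, boundary = TRUE, eps = 1e-9) {
  pts <- cbind(x, y)
  inside <- as.logical(mgcv::in.out(rbind(ring, ring[1, ]), pts))
  if (boundary) {
    on_b <- .on_ring_boundary(x, y, ring, eps)
    inside <- inside | on_b
  }
  inside
}

.on_ring_boundary <- function(x, y, ring, eps = 1e-9) {
  n <- nrow(ring)
  res <- rep(FALSE, length(x))
  for (i in seq_len(n)) {
    a <- ring[i, ]; b <- ring[if (i == n) 1L else i + 1L, ]
    ab <- b - a
    len2 <- sum(ab^2)
    if (len2 == 0) next
    t <- ((x - a[1]) * ab[1] + (y - a[2]) * ab[2]) / len2
    t <- pmin(1, pmax(0, t))
    dx <- a[1] + t * ab[1] - x
    dy <- a[2] + t * ab[2] - y
    res <- res | (dx * dx + dy * dy <= eps * eps)
  }
  res
}

#' Annotate fixes with habitat membership indicators
#'
#' Adds one 0/1 column per habitat label by point-in-polygon membership
#' (boundary points count as inside). A fix outside every patch has all
#' indicators 0; fixes outside the map extent additionally trigger a
#' warning but are kept.
#'
#' @param fixes fix table.
#' @param map `habitat_map` in the same planar frame.
#' @return the fix table with eight indicator columns appended.
#' @export
annotate_habitat <- function(fixes, map) {
  stopifnot(inherits(map, "habitat_map"))
  ind <- matrix(0L, nrow(fixes), length(HABITAT_LABELS),
                dimnames = list(NULL, HABITAT_LABELS))
  # one membership per category; boundary points touching two patches of
  # the same category go to the earliest patch (deterministic tie-break)
  taken_veg <- rep(FALSE, nrow(fixes))
  taken_cov <- rep(FALSE, nrow(fixes))
  for (p in map$patches) {
    hit <- point_in_ring(fixes$x, fixes$y, p$ring)
    if (p$label %in% VEGETATION_LABELS) {
      hit <- hit & !taken_veg
      taken_veg <- taken_veg | hit
    } else {
      hit <- hit & !taken_cov
      taken_cov <- taken_cov | hit
    }
    ind[hit, p$label] <- 1L
  }
  ext <- map$extent
  outside <- fixes$x < ext["xmin"] | fixes$x > ext["xmax"] |
    fixes$y < ext["ymin"] | fixes$y > ext["ymax"]
  if (any(outside)) {
    warning(sum(outside), " fix(es) outside the habitat map extent; ",
            "indicators set to 0")
  }
  cbind(fixes, as.data.frame(ind))
}

#' Write a habitat map as GeoJSON
#'
#' FeatureCollection of Polygon features, each carrying a `label`
#' property; coordinates in the map's planar meter frame.
#'
#' @param map `habitat_map`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_habitat_map <- function(map, path) {
  feats <- lapply(map$patches, function(p) {
    ring <- rbind(p$ring, p$ring[1, , drop = FALSE])
    coords <- lapply(seq_len(nrow(ring)), function(i) c(ring[i, 1], ring[i, 2]))
    list(type = "Feature",
         properties = list(label = p$label),
         geometry = list(type = "Polygon", coordinates = list(coords)))
  })
  fc <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a habitat map from GeoJSON
#'
#' @param path GeoJSON FeatureCollection with Polygon features carrying a
#'   `label` property.
#' @return `habitat_map`.
#' @export
read_habitat_map <- function(path) {
  fc <- jsonlite::read_json(path)
  if (is.null(fc$type) || fc$type != "FeatureCollection") {
    stop("expected a GeoJSON FeatureCollection in ", path)
  }
  labels <- character(0)
  rings <- list()
  for (ft in fc$features) {
    if (ft$geometry$type != "Polygon") {
      stop("unsupported geometry type: ", ft$geometry$type)
    }
    lab <- ft$properties$label
    if (is.null(lab)) stop("feature without a 'label' property")
    ring <- do.call(rbind, lapply(ft$geometry$coordinates[[1]],
                                  function(c2) c(c2[[1]], c2[[2]])))
    labels <- c(labels, lab)
    rings <- c(rings, list(ring))
  }
  habitat_map(labels, rings)
}

#' Read / write the monthly water-temperature table
#'
#' CSV with columns `month,wt`: one mean water temperature (degrees C) per
#' survey month 1..12.
#'
#' @param path CSV path.
#' @return data.frame with columns `month_index`, `wt`.
#' @export
read_temperature <- function(path) {
  raw <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("month", "wt") %in% names(raw))) {
    stop("temperature table needs columns 'month' and 'wt'")
  }
  out <- data.frame(month_index = as.integer(raw$month),
                    wt = as.numeric(raw$wt))
  if (anyDuplicated(out$month_index)) {
    stop("temperature table has duplicated months")
  }
  out[order(out$month_index), , drop = FALSE] |> `rownames<-`(NULL)
}

#' @rdname read_temperature
#' @param temps temperature table.
#' @export
write_temperature <- function(temps, path) {
  write.csv(data.frame(month = temps$month_index, wt = temps$wt),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Join water temperature onto fixes by survey month
#'
#' @param fixes fix table with `survey_round`.
#' @param temps temperature table from [read_temperature()].
#' @return fixes with a `wt` column.
#' @export
attach_temperature <- function(fixes, temps) {
  miss <- setdiff(unique(fixes$survey_round), temps$month_index)
  if (length(miss)) {
    stop("no water temperature for survey month(s): ",
         paste(sort(miss), collapse = ", "))
  }
  fixes$wt <- temps$wt[match(fixes$survey_round, temps$month_index)]
  fixes
}

#' Project lon/lat to a local planar frame
#'
#' Equirectangular projection about the data centroid: adequate for a
#' site a few kilometers across, documented as an approximation.
#'
#' @param lon,lat coordinates in degrees.
#' @return data.frame with planar `x`, `y` in meters.
#' @export
lonlat_to_planar <- function(lon, lat) {
  R <- 6371008.8
  lat0 <- mean(lat) * pi / 180
  lon0 <- mean(lon) * pi / 180
  data.frame(x = R * cos(lat0) * (lon * pi / 180 - lon0),
             y = R * (lat * pi / 180 - lat0))
}
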