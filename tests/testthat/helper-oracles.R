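# Independent brute-force oracles used across the suite. These stay
# deliberately naive (loops, exhaustive search) so they cannot share a
# defect with the implementation paths they check.

# crossing-parity point-in-polygon with the same closed-boundary rule
# as the package (boundary points inside)
oracle_point_in_polygon <- function(px, py, ring, eps = 1e-9) {
  n <- nrow(ring)
  # boundary check
  for (i in seq_len(n)) {
    a <- ring[i, ]; b <- ring[if (i == n) 1L else i + 1L, ]
    ab <- b - a
    len2 <- sum(ab^2)
    if (len2 == 0) next
    t <- ((px - a[1]) * ab[1] + (py - a[2]) * ab[2]) / len2
    t <- min(1, max(0, t))
    if ((a[1] + t * ab[1] - px)^2 + (a[2] + t * ab[2] - py)^2 <= eps^2) {
      return(TRUE)
    }
  }
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    if ((ring[i, 2] > py) != (ring[j, 2] > py)) {
      xint <- ring[i, 1] + (py - ring[i, 2]) *
        (ring[j, 1] - ring[i, 1]) / (ring[j, 2] - ring[i, 2])
      if (px < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

# exhaustive geo-tolerant BMU search by explicit loops
oracle_find_bmu <- function(sample, grid, k) {
  n <- nrow(grid$weights)
  gi <- match(grid$geo_vars, grid$variables)
  best_g <- Inf; g <- NA_integer_
  for (i in seq_len(n)) {
    d <- sum((sample[gi] - grid$weights[i, gi])^2)
    if (d < best_g) { best_g <- d; g <- i }
  }
  best <- Inf; bmu <- NA_integer_
  for (i in seq_len(n)) {
    if (lattice_distance(grid, i, g) > k) next
    d <- sum((sample - grid$weights[i, ])^2)
    if (d < best) { best <- d; bmu <- i }
  }
  bmu
}

# nearest-neighbour distances from a full distance matrix
oracle_neighbor_distances <- function(snapshot, target_id) {
  dm <- as.matrix(dist(cbind(snapshot$x, snapshot$y)))
  i <- which(snapshot$individual_id == target_id)
  d <- dm[i, ]
  d[i] <- Inf
  same <- snapshot$sex == snapshot$sex[i]
  same[i] <- FALSE
  diff_ <- snapshot$sex != snapshot$sex[i]
  pick <- function(mask) if (any(mask)) min(d[mask]) else NA_real_
  c(das = pick(d < Inf), dss = pick(same), dds = pick(diff_))
}

# all-pairs co-occurrence by explicit double loop
oracle_detect <- function(snapshot, radius) {
  n <- nrow(snapshot)
  out <- NULL
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- sqrt((snapshot$x[i] - snapshot$x[j])^2 +
                  (snapshot$y[i] - snapshot$y[j])^2)
      if (d <= radius) {
        ids <- sort(c(snapshot$individual_id[i], snapshot$individual_id[j]))
        out <- rbind(out, data.frame(id_a = ids[1], id_b = ids[2],
                                     distance = d))
      }
    }
  }
  out
}

# Rayleigh mean resultant length for bearings in degrees
oracle_rayleigh_r <- function(deg) {
  rad <- deg * pi / 180
  sqrt(mean(cos(rad))^2 + mean(sin(rad))^2)
}

# polygon area by the shoelace formula
oracle_ring_area <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  n <- nrow(ring)
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

# adjusted Rand index from the contingency table
oracle_ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  expected <- sum_a * sum_b / n
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

# simple fix-table constructor for unit tests
make_fixes <- function(id, sex, t_hours, x, y, origin = "2015-10-10") {
  data.frame(
    individual_id = id,
    sex = sex,
    timestamp = as.POSIXct(origin, tz = "UTC") + t_hours * 3600,
    x = x, y = y,
    survey_round = 1L,
    stringsAsFactors = FALSE
  )
}
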