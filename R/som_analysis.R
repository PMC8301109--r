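# Post-training analysis of the codebook: k-means clustering with
# Davies-Bouldin model selection, per-cluster distance statistics with
# pairwise Welch tests, the sex-ratio plane, and quantitative
# component-plane association scoring.

#' Davies-Bouldin index
#'
#' Mean over clusters of the worst ratio (S_i + S_j) / M_ij, where S is
#' the mean within-cluster distance to the centroid and M the distance
#' between centroids; smaller is better.
#'
#' @param x numeric matrix of observations.
#' @param labels integer cluster labels.
#' @return nonnegative scalar (Inf if two centroids coincide).
#' @export
davies_bouldin <- function(x, labels) {
  x <- as.matrix(x)
  ks <- sort(unique(labels))
  cent <- t(vapply(ks, function(k) colMeans(x[labels == k, , drop = FALSE]),
                   numeric(ncol(x))))
  s <- vapply(seq_along(ks), function(i) {
    xi <- x[labels == ks[i], , drop = FALSE]
    mean(sqrt(rowSums(sweep(xi, 2, cent[i, ])^2)))
  }, 0)
  r <- vapply(seq_along(ks), function(i) {
    max(vapply(seq_along(ks)[-i], function(j) {
      m <- sqrt(sum((cent[i, ] - cent[j, ])^2))
      if (m == 0) Inf else (s[i] + s[j]) / m
    }, 0))
  }, 0)
  mean(r)
}

#' Cluster the codebook with k-means
#'
#' Best-of-restarts k-means on the node weight vectors for each
#' candidate cluster count; the selected count minimises the
#' Davies-Bouldin index (ties to the smaller k). Deterministic given
#' the seed.
#'
#' @param grid trained `som_grid`.
#' @param k_range candidate cluster counts (default 2..10; the minimum
#'   candidate is 2 by construction).
#' @param seed RNG seed.
#' @param restarts k-means restarts per candidate (default 20).
#' @return object of class `codebook_clustering`: `selected_k`,
#'   `labels` (per node), `centers`, `scores` (per candidate k),
#'   `sizes`.
#' @export
kmeans_codebook <- function(grid, k_range = 2:10, seed = 1L,
                            restarts = 20L) {
  X <- grid$weights
  if (any(k_range < 2L)) stop("cluster counts below 2 are not candidates")
  if (max(k_range) > nrow(X)) {
    stop("k_range exceeds the number of nodes (", nrow(X), ")")
  }
  fits <- list()
  scores <- numeric(length(k_range))
  .with_seed(seed, {
    for (i in seq_along(k_range)) {
      k <- k_range[i]
      fit <- suppressWarnings(
        kmeans(X, centers = k, nstart = restarts, iter.max = 100L))
      fits[[i]] <- fit
      scores[i] <- davies_bouldin(X, fit$cluster)
    }
  })
  best <- which.min(scores)
  fit <- fits[[best]]
  structure(list(selected_k = k_range[best],
                 labels = unname(fit$cluster),
                 centers = fit$centers,
                 scores = data.frame(k = k_range, davies_bouldin = scores),
                 sizes = unname(fit$size)),
            class = "codebook_clustering")
}

#' @export
print.codebook_clustering <- function(x, ...) {
  cat("codebook_clustering: selected k =", x$selected_k,
      "(Davies-Bouldin), cluster sizes:",
      paste(x$sizes, collapse = " "), "\n")
  invisible(x)
}

#' Per-cluster distance statistics
#'
#' Maps each sample to its BMU's cluster and summarises the requested
#' variables per cluster: mean, SD, n. Also identifies the clusters
#' with the smallest and largest mean of `rank_by` (reference: the
#' different-sex distance DDS, the criterion by which the minimum- and
#' maximum-distance clusters are described).
#'
#' @param clustering `codebook_clustering`.
#' @param samples data.frame of samples in raw units.
#' @param bmu BMU node index per sample (from [bmu_map()]).
#' @param variables columns of `samples` to summarise.
#' @param rank_by variable used to rank clusters (default `"dds"`).
#' @return data.frame (cluster x variable): `cluster`, `variable`, `n`,
#'   `mean`, `sd`; attributes `min_cluster` and `max_cluster`. Empty
#'   clusters appear with `n = 0` and no statistics.
#' @export
cluster_distance_stats <- function(clustering, samples, bmu,
                                   variables = c("das", "dss", "dds"),
                                   rank_by = "dds") {
  stopifnot(inherits(clustering, "codebook_clustering"),
            nrow(samples) == length(bmu),
            all(variables %in% names(samples)))
  cl <- clustering$labels[bmu]
  ks <- seq_len(clustering$selected_k)
  rows <- list()
  for (k in ks) {
    in_k <- which(cl == k)
    for (v in variables) {
      vals <- samples[[v]][in_k]
      vals <- vals[!is.na(vals)]
      rows[[length(rows) + 1L]] <- data.frame(
        cluster = k, variable = v, n = length(vals),
        mean = if (length(vals)) mean(vals) else NA_real_,
        sd = if (length(vals) > 1) sd(vals) else
          if (length(vals) == 1) 0 else NA_real_)
    }
  }
  out <- do.call(rbind, rows)
  if (rank_by %in% variables) {
    mk <- out[out$variable == rank_by & out$n > 0, ]
    attr(out, "min_cluster") <- mk$cluster[which.min(mk$mean)]
    attr(out, "max_cluster") <- mk$cluster[which.max(mk$mean)]
  }
  attr(out, "cluster_of_sample") <- cl
  out
}

#' Pairwise Welch t-tests with Holm correction
#'
#' Compares a variable across groups with all pairwise Welch t-tests,
#' adjusting the p-values by Holm's method over the whole comparison
#' family. Pairs involving a degenerate group (fewer than 2 values, or
#' zero variance in both groups) are skipped and flagged.
#'
#' @param values numeric vector.
#' @param groups grouping vector of the same length.
#' @return data.frame: `group_a`, `group_b`, `statistic`, `p_raw`,
#'   `p_adjusted`, `skipped`.
#' @export
compare_clusters <- function(values, groups) {
  g <- split(values[!is.na(values)], groups[!is.na(values)])
  ks <- names(g)
  if (length(ks) < 2L) stop("need at least two groups to compare")
  pairs <- utils::combn(ks, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    a <- g[[pairs[1, j]]]; b <- g[[pairs[2, j]]]
    if (length(a) < 2L || length(b) < 2L ||
        (sd(a) == 0 && sd(b) == 0)) {
      return(data.frame(group_a = pairs[1, j], group_b = pairs[2, j],
                        statistic = NA_real_, p_raw = NA_real_,
                        skipped = TRUE))
    }
    tt <- t.test(a, b)  # Welch by default
    data.frame(group_a = pairs[1, j], group_b = pairs[2, j],
               statistic = unname(tt$statistic), p_raw = tt$p.value,
               skipped = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- NA_real_
  ok <- !out$skipped
  out$p_adjusted[ok] <- p.adjust(out$p_raw[ok], method = "holm")
  out
}

#' Sex ratio of a group
#'
#' Mean of the member sex codes (+1 for female, -1 for male); +1 iff
#' all members are female, and the normalised value
#' `sr_norm = (sr_raw + 1) / 2` is 0.5 exactly for equal counts.
#'
#' @param sexes character vector of "F"/"M".
#' @return list with `sr_raw` in `[-1, 1]` and `sr_norm` in `[0, 1]`.
#' @export
sex_ratio <- function(sexes) {
  if (!length(sexes)) stop("empty member list")
  if (!all(sexes %in% c("F", "M"))) stop("sexes must be 'F' or 'M'")
  code <- ifelse(sexes == "F", 1, -1)
  sr <- mean(code)
  list(sr_raw = sr, sr_norm = (sr + 1) / 2)
}

#' Sex-ratio plane of a trained map
#'
#' Per node, the mean sex code of the samples mapping to that node via
#' the BMU; nodes with no mapped samples are NA.
#'
#' @param grid trained `som_grid`.
#' @param bmu BMU index per sample.
#' @param sexes sample sexes ("F"/"M").
#' @return data.frame: `node`, `row`, `col`, `n`, `sr_raw`, `sr_norm`.
#' @export
sex_ratio_plane <- function(grid, bmu, sexes) {
  stopifnot(length(bmu) == length(sexes))
  code <- ifelse(sexes == "F", 1, -1)
  n_nodes <- nrow(grid$weights)
  sr <- rep(NA_real_, n_nodes)
  n <- integer(n_nodes)
  agg <- tapply(code, factor(bmu, levels = seq_len(n_nodes)), mean)
  cnt <- tapply(code, factor(bmu, levels = seq_len(n_nodes)), length)
  sr[!is.na(agg)] <- agg[!is.na(agg)]
  n[!is.na(cnt)] <- cnt[!is.na(cnt)]
  data.frame(node = seq_len(n_nodes), row = grid$coords[, 1],
             col = grid$coords[, 2], n = n, sr_raw = sr,
             sr_norm = (sr + 1) / 2)
}

#' Association score between two component planes
#'
#' A quantitative surrogate for visually matching component maps. Three
#' complementary statistics are computed: the Spearman rank correlation
#' of the two planes over nodes (`score`, symmetric in its arguments)
#' with its polarity (`inverse` when negative); the Jaccard overlap
#' between the top-decile node set of plane A and the top (match) or
#' bottom (inverse) decile of plane B (`extremum_overlap`); and the
#' directional `enrichment` of plane B in plane A's high region -- the
#' A-weighted mean of B divided by the plain mean of B, so values above
#' 1 mean B is over-represented where A is high. Enrichment is the
#' statistic that mirrors reading a component map by eye: locate the
#' peak region of one plane and ask what the other plane shows there.
#'
#' @param plane_a,plane_b numeric vectors over the same nodes (NA nodes
#'   are dropped pairwise).
#' @param decile extremum fraction (default 0.1).
#' @return object of class `association_score`: `score`, `polarity`,
#'   `extremum_overlap`, `enrichment`, `n_nodes`; `score` is NA
#'   (flagged constant) for a constant plane.
#' @export
plane_association <- function(plane_a, plane_b, decile = 0.1) {
  stopifnot(length(plane_a) == length(plane_b))
  ok <- is.finite(plane_a) & is.finite(plane_b)
  a <- plane_a[ok]; b <- plane_b[ok]
  if (length(a) < 3L) stop("too few nodes with values on both planes")
  out <- list(score = NA_real_, polarity = NA_character_,
              extremum_overlap = NA_real_, enrichment = NA_real_,
              n_nodes = length(a), constant = FALSE)
  if (sum(a) > 0 && mean(b) > 0) {
    out$enrichment <- (sum(a * b) / sum(a)) / mean(b)
  }
  if (sd(a) == 0 || sd(b) == 0) {
    out$constant <- TRUE
    return(structure(out, class = "association_score"))
  }
  out$score <- suppressWarnings(cor(a, b, method = "spearman"))
  out$polarity <- if (out$score < 0) "inverse" else "match"
  m <- max(1L, ceiling(decile * length(a)))
  top <- function(v) order(v, seq_along(v), decreasing = TRUE)[seq_len(m)]
  bottom <- function(v) order(v, seq_along(v))[seq_len(m)]
  set_a <- top(a)
  set_b <- if (out$polarity == "inverse") bottom(b) else top(b)
  out$extremum_overlap <- length(intersect(set_a, set_b)) /
    length(union(set_a, set_b))
  structure(out, class = "association_score")
}

#' @export
print.association_score <- function(x, ...) {
  if (x$constant) {
    cat("association_score: constant plane (score undefined)\n")
  } else {
    cat(sprintf("association_score: %.3f (%s), extremum overlap %.2f, enrichment %.2f over %d nodes\n",
                x$score, x$polarity, x$extremum_overlap, x$enrichment,
                x$n_nodes))
  }
  invisible(x)
}

#' Rank habitat planes by association with a target plane
#'
#' Habitats are ordered by the enrichment of their plane in the
#' target's high-incidence region (the map-reading criterion), with the
#' Spearman score as tie-break; both are reported.
#'
#' @param planes plane table from [component_planes()] (or a named list
#'   of node-value vectors).
#' @param target numeric plane vector (e.g. a co-occurrence incidence
#'   plane), used as the weighting plane.
#' @param habitat_vars habitat plane names to rank.
#' @return data.frame sorted by decreasing enrichment: `variable`,
#'   `enrichment`, `score`, `polarity`, `extremum_overlap`.
#' @export
rank_plane_associations <- function(planes, target,
                                    habitat_vars = HABITAT_LABELS) {
  get_plane <- function(v) {
    if (is.data.frame(planes)) plane_vector(planes, v) else planes[[v]]
  }
  rows <- lapply(habitat_vars, function(v) {
    sc <- plane_association(target, get_plane(v))
    data.frame(variable = v,
               enrichment = sc$enrichment,
               score = sc$score,
               polarity = if (is.na(sc$score)) NA_character_ else sc$polarity,
               extremum_overlap = sc$extremum_overlap)
  })
  out <- do.call(rbind, rows)
  out[order(-out$enrichment, -out$score, out$variable), ] |>
    `rownames<-`(NULL)
}

#' Association table of pair classes versus habitats
#'
#' Tallies, for each pair-class incidence plane, the habitat planes
#' whose association score reaches `threshold` -- a reproducible
#' criterion replacing visual inspection of matched component maps.
#'
#' @param class_planes named list of incidence plane vectors (names
#'   FF/FM/MM or similar).
#' @param habitat_planes named list of habitat plane vectors.
#' @param threshold minimum Spearman score for a cell to count
#'   (default 0.5).
#' @return integer matrix pair-class x habitat of 0/1 tallies, with a
#'   `scores` attribute carrying the underlying score matrix.
#' @export
association_table <- function(class_planes, habitat_planes,
                              threshold = 0.5) {
  scores <- matrix(NA_real_, length(class_planes), length(habitat_planes),
                   dimnames = list(names(class_planes),
                                   names(habitat_planes)))
  for (i in seq_along(class_planes)) {
    for (j in seq_along(habitat_planes)) {
      sc <- plane_association(class_planes[[i]], habitat_planes[[j]])
      scores[i, j] <- sc$score
    }
  }
  tab <- ifelse(!is.na(scores) & scores >= threshold, 1L, 0L)
  attr(tab, "scores") <- scores
  tab
}
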