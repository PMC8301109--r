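planted_codebook <- function(seed = 31, centers = c(0.1, 0.5, 0.9)) {
  g <- som_grid(9, 6, variables = c("X", "Y", "p", "q", "r"), seed = seed)
  set.seed(seed)
  group <- rep(seq_along(centers), length.out = 54)
  g$weights[] <- centers[group] + rnorm(54 * 5, 0, 0.01)
  list(grid = g, truth = group)
}

test_that("codebook clustering recovers planted groups and selects k", {
  pc <- planted_codebook()
  cl <- kmeans_codebook(pc$grid, k_range = 2:8, seed = 4)
  expect_equal(cl$selected_k, 3L)
  expect_gte(oracle_ari(pc$truth, cl$labels), 0.95)
  # duplicate nodes always share a cluster
  dup <- which(pc$truth == 1)
  expect_equal(length(unique(cl$labels[dup])), 1L)
  expect_error(kmeans_codebook(pc$grid, k_range = 2:60), "exceeds")
  expect_error(kmeans_codebook(pc$grid, k_range = 1:3), "below 2")
  # deterministic given the seed
  cl2 <- kmeans_codebook(pc$grid, k_range = 2:8, seed = 4)
  expect_identical(cl$labels, cl2$labels)
  expect_identical(cl$scores, cl2$scores)
})

test_that("cluster statistics match hand arithmetic and conserve n", {
  pc <- planted_codebook()
  cl <- kmeans_codebook(pc$grid, k_range = 2:4, seed = 4)
  samples <- data.frame(das = c(1, 2, 3, 4, 5, 6),
                        dss = c(2, 2, 4, 4, 6, 6),
                        dds = c(10, 20, 30, 40, 50, 60))
  bmu <- c(1, 1, 2, 2, 3, 3)
  st <- cluster_distance_stats(cl, samples, bmu)
  lab <- cl$labels
  for (v in c("das", "dss", "dds")) {
    for (k in unique(lab[1:3])) {
      sel <- which(lab[bmu] == k)
      row <- st[st$cluster == k & st$variable == v, ]
      if (length(sel)) {
        expect_equal(row$mean, mean(samples[[v]][sel]))
        expect_equal(row$n, length(sel))
      }
    }
  }
  expect_equal(sum(st$n[st$variable == "das"]), 6L)

  same <- samples; same[] <- 5
  st2 <- cluster_distance_stats(cl, same, bmu)
  expect_true(all(st2$sd[st2$n > 0] == 0))
  # min/max clusters ranked by mean different-sex distance
  expect_equal(attr(st, "min_cluster"),
               st$cluster[st$variable == "dds" &
                            st$mean == min(st$mean[st$variable == "dds"],
                                           na.rm = TRUE)][1])
})

test_that("pairwise Welch tests with Holm behave at the null and alternative", {
  set.seed(41)
  base <- rnorm(50)
  same <- compare_clusters(c(base, base), rep(c("a", "b"), each = 50))
  expect_gt(same$p_adjusted[1], 0.9)

  far <- compare_clusters(c(rnorm(50), rnorm(50, 10)),
                          rep(c("a", "b"), each = 50))
  expect_lt(far$p_adjusted[1], 0.001)

  three <- compare_clusters(c(rnorm(30), rnorm(30, 0.5), rnorm(30, 3)),
                            rep(c("a", "b", "c"), each = 30))
  expect_true(all(three$p_adjusted >= three$p_raw, na.rm = TRUE))

  degen <- compare_clusters(c(1, 2, 3, 4, 5), c("a", "a", "a", "a", "b"))
  expect_true(degen$skipped[1])
})

test_that("sex ratio codes females +1 and males -1", {
  expect_equal(sex_ratio(rep("F", 5))$sr_raw, 1)
  expect_equal(sex_ratio(c("F", "F", "M", "M"))$sr_norm, 0.5)
  r <- sex_ratio(c("F", "M", "M", "M"))
  expect_equal(r$sr_raw, -0.5)
  expect_equal(r$sr_norm, 0.25)
  expect_error(sex_ratio(character(0)), "empty")
  expect_error(sex_ratio(c("F", "x")), "'F' or 'M'")
  # relabelling equivariance: swapping sexes negates the raw ratio
  set.seed(42)
  for (i in 1:20) {
    s <- sample(c("F", "M"), 10, replace = TRUE)
    flipped <- ifelse(s == "F", "M", "F")
    expect_equal(sex_ratio(flipped)$sr_raw, -sex_ratio(s)$sr_raw)
  }
})

test_that("the sex-ratio plane averages codes per node", {
  g <- som_grid(3, 3, variables = c("X", "Y", "v"), seed = 1)
  bmu <- c(1, 1, 2, 2, 2, 5)
  sexes <- c("F", "M", "F", "F", "M", "M")
  pl <- sex_ratio_plane(g, bmu, sexes)
  expect_equal(pl$sr_raw[1], 0)      # 1 F + 1 M
  expect_equal(pl$sr_norm[1], 0.5)   # equal proportions -> 0.5
  expect_equal(pl$sr_raw[2], 1 / 3)
  expect_equal(pl$sr_raw[5], -1)
  expect_true(is.na(pl$sr_raw[9]))
  expect_equal(pl$n[2], 3L)
})

test_that("plane association scores identity, inversion and enrichment", {
  set.seed(43)
  p <- runif(54)
  self <- plane_association(p, p)
  expect_equal(self$score, 1)
  expect_equal(self$extremum_overlap, 1)
  expect_equal(self$polarity, "match")

  anti <- plane_association(p, 1 - p)
  expect_equal(anti$score, -1)
  expect_equal(anti$polarity, "inverse")
  expect_equal(anti$extremum_overlap, 1)

  cst <- plane_association(p, rep(0.4, 54))
  expect_true(cst$constant)
  expect_true(is.na(cst$score))
  expect_equal(cst$enrichment, 1)

  # symmetry of the rank correlation
  q <- runif(54)
  expect_equal(plane_association(p, q)$score,
               plane_association(q, p)$score)

  # enrichment: binary habitat confined to the peak region scores > 1
  inc <- c(rep(1, 6), rep(0.05, 48))
  hab <- c(rep(1, 6), rep(0, 48))
  expect_gt(plane_association(inc, hab)$enrichment, 5)
  expect_lt(plane_association(inc, rev(hab))$enrichment, 1)
})

test_that("association tables honour thresholds and planted dominance", {
  set.seed(44)
  planes <- list(FM = c(rep(1, 6), runif(48, 0, 0.2)))
  habs <- list(TG = c(rep(1, 6), rep(0, 48)),
               FL = c(rep(0, 48), rep(1, 6)),
               HHV = runif(54))
  tab <- association_table(planes, habs, threshold = 1.01)
  expect_true(all(tab == 0L))
  tab2 <- association_table(planes, habs, threshold = -1)
  expect_true(all(tab2 == 1L))
  scores <- attr(association_table(planes, habs), "scores")
  expect_equal(colnames(scores), c("TG", "FL", "HHV"))
  expect_equal(unname(which.max(scores["FM", ])), 1L)

  rk <- rank_plane_associations(habs, planes$FM,
                                habitat_vars = names(habs))
  expect_equal(rk$variable[1], "TG")
})
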