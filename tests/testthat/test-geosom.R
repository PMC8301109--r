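vars5 <- c("X", "Y", "a", "b", "c")

rand_grid <- function(seed, rows = 4, cols = 4, vars = vars5) {
  g <- som_grid(rows, cols, variables = vars, seed = seed)
  # spread the weights over [0,1] so searches are non-trivial
  set.seed(seed + 1000)
  g$weights[] <- runif(length(g$weights))
  g
}

test_that("grid initialisation is seeded, small and sized correctly", {
  g1 <- som_grid(9, 6, variables = vars5, seed = 7)
  g2 <- som_grid(9, 6, variables = vars5, seed = 7)
  expect_identical(g1$weights, g2$weights)
  expect_equal(nrow(g1$weights), 54L)
  expect_true(all(g1$weights >= 0 & g1$weights <= 0.1))
  g3 <- som_grid(9, 6, variables = vars5, seed = 8)
  expect_false(identical(g1$weights, g3$weights))
  expect_error(som_grid(9, 6, variables = character(0)), "empty")
  expect_error(som_grid(9, 6, variables = c("a", "b"), geo_vars = c("X")),
               "subset")
})

test_that("node distance is the summed squared difference", {
  expect_equal(node_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(node_distance(c(1, 0), c(0, 0)), 1)
  set.seed(8)
  for (i in 1:20) {
    x <- runif(5); w <- runif(5)
    acc <- 0
    for (j in 1:5) acc <- acc + (x[j] - w[j])^2
    expect_equal(node_distance(x, w), acc)
  }
  expect_error(node_distance(1:3, 1:4), "length")
})

test_that("lattice distances are Chebyshev (rect) and cube (hex)", {
  g <- som_grid(4, 4, variables = vars5, seed = 1)
  # node 1 = (1,1); node 16 = (4,4); node 4 = (1,4)
  expect_equal(lattice_distance(g, 1, 16), 3)
  expect_equal(lattice_distance(g, 1, 4), 3)
  expect_equal(lattice_distance(g, 1, 6), 1)
  gh <- som_grid(4, 4, variables = vars5, seed = 1, lattice = "hexagonal")
  expect_equal(lattice_distance(gh, 1, 1), 0)
  expect_equal(lattice_distance(gh, 1, 2), 1)
  # hex rows shift: (1,1)->(2,1) are adjacent
  expect_equal(lattice_distance(gh, 1, 5), 1)
})

test_that("saturated tolerance reduces the BMU to the global argmin", {
  set.seed(9)
  for (i in 1:200) {
    g <- rand_grid(i)
    x <- setNames(runif(5), vars5)
    full <- colSums((t(g$weights) - x)^2)
    expect_equal(find_bmu(x, g, k = 10), which.min(full))
  }
})

test_that("zero tolerance forces the geographic winner", {
  set.seed(10)
  for (i in 1:50) {
    g <- rand_grid(100 + i)
    x <- setNames(runif(5), vars5)
    geo <- colSums((t(g$weights[, 1:2]) - x[1:2])^2)
    expect_equal(find_bmu(x, g, k = 0), which.min(geo))
  }
})

test_that("intermediate tolerance matches exhaustive constrained search", {
  set.seed(11)
  for (i in 1:100) {
    g <- rand_grid(200 + i, rows = 3, cols = 3)
    x <- setNames(runif(5), vars5)
    for (k in 0:2) {
      expect_equal(find_bmu(x, g, k = k), oracle_find_bmu(x, g, k))
    }
  }
})

test_that("crafted weights show the geographic constraint binding", {
  g <- som_grid(3, 3, variables = c("X", "Y", "v"), seed = 1)
  g$weights[] <- 0.5
  # node 1 is the geo-winner; node 9 wins the full distance but lies
  # outside the k = 1 disc of node 1
  g$weights[1, ] <- c(0, 0, 0)
  g$weights[9, ] <- c(0.4, 0.4, 1)
  x <- c(X = 0, Y = 0, v = 1)
  unconstrained <- find_bmu(x, g, k = 4)
  constrained <- find_bmu(x, g, k = 1)
  expect_equal(unconstrained, 9L)
  expect_false(constrained == 9L)
  expect_lte(lattice_distance(g, constrained, 1), 1)
  expect_equal(constrained, oracle_find_bmu(x, g, 1))
})

test_that("bubble updates move only the neighbourhood, by eta", {
  g <- rand_grid(12)
  x <- setNames(runif(5), vars5)
  expect_identical(update_weights(g, 6, x, eta = 0, radius = 2)$weights,
                   g$weights)
  g1 <- update_weights(g, 6, x, eta = 1, radius = 0)
  expect_equal(unname(g1$weights[6, ]), unname(x))
  moved <- which(rowSums(g1$weights != g$weights) > 0)
  expect_equal(moved, 6L)

  # hand arithmetic: w = 0.5, x = 1.0, eta = 0.2 -> 0.6
  g2 <- g; g2$weights[] <- 0.5
  g3 <- update_weights(g2, 1, setNames(rep(1, 5), vars5),
                       eta = 0.2, radius = 0)
  expect_equal(unname(g3$weights[1, ]), rep(0.6, 5))

  # strict contraction for 0 < eta <= 1 whenever the distance is nonzero
  set.seed(13)
  for (i in 1:50) {
    g <- rand_grid(300 + i)
    x <- setNames(runif(5), vars5)
    bmu <- find_bmu(x, g, k = 10)
    d0 <- node_distance(x, g$weights[bmu, ])
    if (d0 == 0) next
    eta <- runif(1, 0.01, 1)
    g2 <- update_weights(g, bmu, x, eta = eta, radius = 1)
    expect_lt(node_distance(x, g2$weights[bmu, ]), d0)
  }
})

test_that("training is deterministic, validated, and converges on one sample", {
  X <- matrix(runif(20), 4, 5, dimnames = list(NULL, vars5))
  g <- som_grid(3, 3, variables = vars5, seed = 3)
  t1 <- som_train(g, X, k = 1, seed = 5)
  t2 <- som_train(g, X, k = 1, seed = 5)
  expect_identical(t1$weights, t2$weights)
  expect_identical(t1$qe_history, t2$qe_history)

  expect_error(som_train(g, X * 3, k = 1, seed = 5), "normalised")

  one <- X[1, , drop = FALSE]
  ph <- som_phases(rough_iter = 50, rough_radius = 0, rough_rate = 0.5,
                   fine_iter = 50, fine_radius = 0, fine_rate = 0.5)
  tr <- som_train(g, one, phases = ph, k = 5, seed = 1)
  bmu <- find_bmu(one[1, ], tr, k = 5)
  expect_lt(max(abs(tr$weights[bmu, ] - one[1, ])), 1e-6)
})

test_that("one training pass equals the step-by-step R update sequence", {
  X <- matrix(runif(40), 8, 5, dimnames = list(NULL, vars5))
  g0 <- som_grid(3, 3, variables = vars5, seed = 21)
  ph <- som_phases(rough_iter = 1, rough_radius = 2, rough_rate = 0.3,
                   fine_iter = 1, fine_radius = 1, fine_rate = 0.1)
  trained <- som_train(g0, X, phases = ph, k = 1, seed = 9)

  # replicate: same shuffles, R-level BMU search + bubble update
  ref <- g0
  set.seed(9)
  for (cfg in list(c(2, 0.3), c(1, 0.1))) {
    ord <- sample.int(nrow(X))
    for (s in ord) {
      bmu <- find_bmu(X[s, ], ref, k = 1)
      ref <- update_weights(ref, bmu, X[s, ], eta = cfg[2],
                            radius = cfg[1])
    }
  }
  expect_equal(trained$weights, ref$weights, tolerance = 1e-12)
})

test_that("trained maps separate well-separated clouds", {
  set.seed(14)
  n <- 120
  cloud <- rep(1:2, each = n / 2)
  X <- cbind(X = runif(n), Y = runif(n),
             a = ifelse(cloud == 1, 0.1, 0.9) + rnorm(n, 0, 0.02),
             b = ifelse(cloud == 1, 0.9, 0.1) + rnorm(n, 0, 0.02),
             c = runif(n))
  X <- pmin(pmax(X, 0), 1)
  g <- som_grid(4, 4, variables = colnames(X), seed = 2)
  tr <- som_train(g, X, k = 6, seed = 2)
  bmu <- bmu_map(tr, X, k = 6)
  side <- tr$weights[bmu, "a"] > 0.5
  expect_gte(oracle_ari(cloud, side), 0.9)
})

test_that("quantization error matches a loop oracle and its edge cases", {
  g <- rand_grid(15)
  X <- g$weights[c(2, 5, 9), ]
  expect_equal(quantization_error(g, X, k = 10), 0)

  set.seed(16)
  X <- matrix(runif(50), 10, 5, dimnames = list(NULL, vars5))
  qe <- quantization_error(g, X, k = 10)
  acc <- 0
  for (i in 1:10) {
    best <- Inf
    for (j in seq_len(nrow(g$weights))) {
      best <- min(best, sum((X[i, ] - g$weights[j, ])^2))
    }
    acc <- acc + sqrt(best)
  }
  expect_equal(qe, acc / 10)
  expect_equal(quantization_error(g, X[sample(10), ], k = 10), qe)
})

test_that("component planes normalise to [0,1] with the 0.5 convention", {
  g <- rand_grid(17)
  planes <- component_planes(g)
  for (v in vars5) {
    p <- plane_vector(planes, v)
    expect_equal(min(p), 0)
    expect_equal(max(p), 1)
  }
  g$weights[, "c"] <- 0.37
  pc <- plane_vector(component_planes(g), "c")
  expect_true(all(pc == 0.5))
})

test_that("trained models survive JSON serialisation", {
  X <- matrix(runif(40), 8, 5, dimnames = list(NULL, vars5))
  g <- som_train(som_grid(3, 3, variables = vars5, seed = 1), X,
                 phases = som_phases(rough_iter = 5, fine_iter = 2),
                 k = 1, seed = 1)
  g$norm <- list(min = setNames(rep(0, 5), vars5),
                 range = setNames(rep(2, 5), vars5))
  path <- withr::local_tempfile(fileext = ".json")
  write_som(g, path)
  back <- read_som(path)
  expect_equal(back$weights, g$weights)
  expect_equal(back$geo_vars, g$geo_vars)
  expect_equal(back$k, g$k)
  expect_equal(bmu_map(back, X), bmu_map(g, X))
})
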