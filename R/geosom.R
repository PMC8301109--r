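# From-scratch SOM / Geo-SOM.
#
# The map is a rows x cols lattice of nodes, each carrying a weight
# vector over the named input variables. A designated subset of the
# variables (reference: X and Y) is geographic: the best-matching unit
# (BMU) is found in two phases -- first the node nearest the sample in
# the geographic components alone (the geo-winner), then the node
# minimising the full summed squared distance among nodes within
# lattice radius k (the geographic tolerance) of the geo-winner. k = 0
# forces the geo-winner; k at or beyond the lattice diameter recovers
# the standard SOM. Weight updates use the bubble neighbourhood:
# w <- w + eta * (x - w) for nodes within the current radius of the
# BMU, all other nodes unchanged.

#' Initialise a SOM grid
#'
#' Weights start i.i.d. uniform on [0, 0.1] (random small values),
#' deterministic for a given seed. The reference map is 9 x 6 = 54
#' nodes on a rectangular lattice with Chebyshev lattice distance; a
#' hexagonal (odd-r offset) lattice is available as an option.
#'
#' @param rows,cols grid dimensions (reference 9 x 6; both at least 2).
#' @param variables character vector of input variable names.
#' @param seed RNG seed for the weight initialisation.
#' @param geo_vars names of the geographic variables (default
#'   `c("X", "Y")`); must be a subset of `variables`.
#' @param lattice `"rectangular"` (default) or `"hexagonal"`.
#' @return object of class `som_grid`: weights matrix (nodes x
#'   variables, row-major node order), lattice coordinates, metadata.
#' @export
som_grid <- function(rows = 9L, cols = 6L, variables, seed = 1L,
                     geo_vars = c("X", "Y"),
                     lattice = c("rectangular", "hexagonal")) {
  lattice <- match.arg(lattice)
  if (length(variables) == 0L) stop("empty variable list")
  stopifnot(rows >= 2L, cols >= 2L)
  if (rows * cols < 4L) stop("grid needs at least 4 nodes")
  if (!all(geo_vars %in% variables)) {
    stop("geo_vars must be a subset of variables")
  }
  n <- rows * cols
  w <- .with_seed(seed, matrix(runif(n * length(variables), 0, 0.1),
                               nrow = n))
  colnames(w) <- variables
  coords <- cbind(row = rep(seq_len(rows), each = cols),
                  col = rep(seq_len(cols), times = rows))
  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 lattice = lattice, variables = variables,
                 geo_vars = geo_vars, weights = w,
                 coords = coords, seed = as.integer(seed),
                 norm = NULL),
            class = "som_grid")
}

#' @export
print.som_grid <- function(x, ...) {
  cat(sprintf("som_grid: %d x %d (%s lattice), %d variables (%s geographic)\n",
              x$rows, x$cols, x$lattice, length(x$variables),
              paste(x$geo_vars, collapse = "/")))
  invisible(x)
}

#' Summed squared distance between a sample and a node weight
#'
#' `d = sum_i (x_i - w_i)^2` -- squared Euclidean with no root, the
#' response each node computes for an input vector.
#'
#' @param sample,node numeric vectors of equal length.
#' @return nonnegative scalar.
#' @export
node_distance <- function(sample, node) {
  if (length(sample) != length(node)) {
    stop("sample and node weight have different lengths")
  }
  sum((sample - node)^2)
}

#' Lattice distance between two nodes
#'
#' Chebyshev distance on the rectangular lattice; hexagonal cube
#' distance (odd-r offset rows) on the hexagonal lattice.
#'
#' @param grid `som_grid`.
#' @param i,j node indices (1-based, row-major).
#' @return integer distance in lattice units.
#' @export
lattice_distance <- function(grid, i, j) {
  a <- grid$coords[i, ]; b <- grid$coords[j, ]
  if (grid$lattice == "rectangular") {
    return(max(abs(a[1] - b[1]), abs(a[2] - b[2])))
  }
  qa <- a[2] - (a[1] - a[1] %% 2) / 2
  qb <- b[2] - (b[1] - b[1] %% 2) / 2
  dq <- qa - qb; dr <- a[1] - b[1]
  max(abs(dq), abs(dr), abs(dq + dr))
}

.geo_idx <- function(grid) match(grid$geo_vars, grid$variables)

.align_sample <- function(sample, grid) {
  if (!is.null(names(sample))) {
    miss <- setdiff(grid$variables, names(sample))
    if (length(miss)) stop("sample lacks variable(s): ",
                           paste(miss, collapse = ", "))
    sample <- sample[grid$variables]
  } else if (length(sample) != length(grid$variables)) {
    stop("sample length does not match the grid's variables")
  }
  if (anyNA(sample)) stop("sample contains missing values")
  as.numeric(sample)
}

#' Two-phase geographically tolerant BMU search
#'
#' Phase 1 finds the geo-winner: the node minimising the summed squared
#' distance restricted to the geographic variables. Phase 2 returns the
#' node minimising the full distance among nodes within lattice
#' distance `k` of the geo-winner. Ties break to the lowest node index
#' in both phases.
#'
#' @param sample named numeric vector (or unnamed in the grid's
#'   variable order).
#' @param grid `som_grid`.
#' @param k geographic tolerance in lattice units; `k = 0` forces the
#'   geo-winner, `k` at or beyond the grid diameter gives the standard
#'   unconstrained SOM search.
#' @return BMU node index (1-based).
#' @export
find_bmu <- function(sample, grid, k = 3L) {
  stopifnot(k >= 0)
  x <- .align_sample(sample, grid)
  gi <- .geo_idx(grid)
  d_geo <- colSums((t(grid$weights[, gi, drop = FALSE]) - x[gi])^2)
  g <- which.min(d_geo)
  allowed <- which(vapply(seq_len(nrow(grid$weights)),
                          function(i) lattice_distance(grid, i, g) <= k,
                          NA))
  d_full <- colSums((t(grid$weights[allowed, , drop = FALSE]) - x)^2)
  allowed[which.min(d_full)]
}

#' Bubble-neighbourhood weight update
#'
#' Nodes within lattice distance `radius` of the BMU (the winner and
#' its neighbours, indicator 1) move toward the sample:
#' `w <- w + eta * (x - w)`; all other nodes (indicator 0) are
#' unchanged.
#'
#' @param grid `som_grid`.
#' @param bmu winning node index.
#' @param sample input vector.
#' @param eta learning rate in `[0, 1]`.
#' @param radius neighbourhood radius in lattice units.
#' @return the updated grid.
#' @export
update_weights <- function(grid, bmu, sample, eta, radius) {
  stopifnot(eta >= 0, eta <= 1, radius >= 0)
  x <- .align_sample(sample, grid)
  for (i in seq_len(nrow(grid$weights))) {
    if (lattice_distance(grid, i, bmu) <= radius) {
      grid$weights[i, ] <- grid$weights[i, ] + eta * (x - grid$weights[i, ])
    }
  }
  grid
}

#' Training schedule
#'
#' Defaults reproduce the reference settings verbatim: a rough phase of
#' 200 iterations starting at radius 4 and rate 0.2, then a fine phase
#' of 20 iterations starting at radius 10 and rate 0.1. (The printed
#' fine radius exceeds both the rough radius and the small side of a
#' 9 x 6 grid; it is accepted as configured. `corrected = TRUE` swaps
#' in a monotone fine phase starting at radius 2.) Within a phase, the
#' radius decays linearly to 1 and the rate to a tenth of its initial
#' value.
#'
#' @param rough_iter,rough_radius,rough_rate rough-phase settings.
#' @param fine_iter,fine_radius,fine_rate fine-phase settings.
#' @param corrected use the monotone fine radius.
#' @return list of two phases, each `list(iterations, radius, rate)`.
#' @export
som_phases <- function(rough_iter = 200L, rough_radius = 4, rough_rate = 0.2,
                       fine_iter = 20L, fine_radius = 10, fine_rate = 0.1,
                       corrected = FALSE) {
  if (corrected) fine_radius <- 2
  stopifnot(rough_iter >= 1, fine_iter >= 1, rough_radius >= 0,
            fine_radius >= 0, rough_rate > 0, rough_rate <= 1,
            fine_rate > 0, fine_rate <= 1)
  list(rough = list(iterations = as.integer(rough_iter),
                    radius = rough_radius, rate = rough_rate),
       fine = list(iterations = as.integer(fine_iter),
                   radius = fine_radius, rate = fine_rate))
}

#' Min-max normalise training samples to [0, 1]
#'
#' Per-variable min-max scaling, as required before training; the
#' normaliser (min and range per variable) is returned so component
#' planes can be reported in raw units. Constant variables scale to
#' 0.5.
#'
#' @param samples data.frame or matrix of training samples.
#' @return list with `x` (scaled matrix), `min`, `range`.
#' @export
som_scale <- function(samples) {
  x <- as.matrix(samples)
  storage.mode(x) <- "double"
  if (anyNA(x)) stop("training samples contain missing values")
  mins <- apply(x, 2, min)
  rngs <- apply(x, 2, max) - mins
  scaled <- sweep(sweep(x, 2, mins), 2, ifelse(rngs > 0, rngs, 1), "/")
  scaled[, rngs == 0] <- 0.5
  list(x = scaled, min = mins, range = rngs)
}

.check_normalized <- function(X, tol = 1e-9) {
  if (min(X) < -tol || max(X) > 1 + tol) {
    stop("training samples must be min-max normalised to [0, 1]; ",
         "see som_scale()")
  }
}

#' Train a Geo-SOM
#'
#' Sequential training over the phases of [som_phases()]: in each
#' phase, the neighbourhood radius decays linearly from its initial
#' value to 1 and the learning rate to a tenth of its initial value
#' across the phase's iterations. One iteration is one full pass
#' through the samples in a seeded-shuffled order, each sample pulling
#' its geo-tolerant BMU's bubble neighbourhood toward it. The
#' quantization error is recorded after every iteration. Training is
#' deterministic given (grid, samples, phases, k, seed).
#'
#' @param grid `som_grid` from [som_grid()].
#' @param samples matrix or data.frame of samples over the grid's
#'   variables, min-max normalised to `[0, 1]` (error otherwise).
#' @param phases training schedule (default [som_phases()]).
#' @param k geographic tolerance (reference default 3).
#' @param seed seed for the per-pass sample shuffling.
#' @return the trained grid, with `qe_history` (data.frame phase,
#'   iteration, qe) and `qe_initial` attached, plus the training
#'   settings.
#' @export
som_train <- function(grid, samples, phases = som_phases(), k = 3L,
                      seed = 1L) {
  stopifnot(inherits(grid, "som_grid"), k >= 0)
  X <- as.matrix(samples)
  storage.mode(X) <- "double"
  if (!is.null(colnames(X))) X <- X[, grid$variables, drop = FALSE]
  if (ncol(X) != length(grid$variables)) {
    stop("samples do not match the grid's variables")
  }
  if (nrow(X) < 1L) stop("need at least one training sample")
  if (anyNA(X)) stop("training samples contain missing values")
  .check_normalized(X)
  gi <- .geo_idx(grid) - 1L
  hex <- grid$lattice == "hexagonal"
  nrow_i <- as.integer(grid$coords[, 1])
  ncol_i <- as.integer(grid$coords[, 2])
  Wt <- t(grid$weights)
  Xt <- t(X)
  qe0 <- cpp_quantization_error(Wt, nrow_i, ncol_i, Xt, gi,
                                as.integer(k), hex)
  hist_rows <- list()
  .with_seed(seed, {
    for (ph_name in names(phases)) {
      ph <- phases[[ph_name]]
      Tn <- ph$iterations
      for (t in seq_len(Tn)) {
        frac <- if (Tn > 1) (t - 1) / (Tn - 1) else 0
        radius_t <- ph$radius + frac * (1 - ph$radius)
        eta_t <- ph$rate + frac * (ph$rate / 10 - ph$rate)
        ord <- sample.int(nrow(X)) - 1L
        Wt <- cpp_som_pass(Wt, nrow_i, ncol_i, Xt, ord, gi,
                           as.integer(k), eta_t, radius_t, hex)
        qe <- cpp_quantization_error(Wt, nrow_i, ncol_i, Xt, gi,
                                     as.integer(k), hex)
        hist_rows[[length(hist_rows) + 1L]] <-
          data.frame(phase = ph_name, iteration = t, qe = qe)
      }
    }
  })
  grid$weights <- t(Wt)
  colnames(grid$weights) <- grid$variables
  grid$trained <- TRUE
  grid$k <- as.integer(k)
  grid$train_seed <- as.integer(seed)
  grid$phases <- phases
  grid$qe_initial <- qe0
  grid$qe_history <- do.call(rbind, hist_rows)
  grid
}

#' BMU indices for a sample matrix
#'
#' @param grid `som_grid`.
#' @param samples normalised sample matrix over the grid's variables.
#' @param k geographic tolerance (defaults to the tolerance the grid
#'   was trained with, else the saturating diameter).
#' @return integer vector of node indices, one per sample.
#' @export
bmu_map <- function(grid, samples, k = NULL) {
  if (is.null(k)) k <- if (!is.null(grid$k)) grid$k else
    max(grid$rows, grid$cols)
  X <- as.matrix(samples)
  storage.mode(X) <- "double"
  if (!is.null(colnames(X))) X <- X[, grid$variables, drop = FALSE]
  if (anyNA(X)) stop("samples contain missing values")
  cpp_bmu_map(t(grid$weights), as.integer(grid$coords[, 1]),
              as.integer(grid$coords[, 2]), t(X), .geo_idx(grid) - 1L,
              as.integer(k), grid$lattice == "hexagonal")
}

#' Quantization error of a grid on samples
#'
#' Mean over samples of the Euclidean distance (square root of the
#' summed squared distance) to the geo-tolerant BMU. Zero exactly when
#' every sample coincides with its BMU's weight vector.
#'
#' @param grid `som_grid`.
#' @param samples sample matrix.
#' @param k geographic tolerance (see [bmu_map()]).
#' @return nonnegative scalar.
#' @export
quantization_error <- function(grid, samples, k = NULL) {
  if (is.null(k)) k <- if (!is.null(grid$k)) grid$k else
    max(grid$rows, grid$cols)
  X <- as.matrix(samples)
  storage.mode(X) <- "double"
  if (!is.null(colnames(X))) X <- X[, grid$variables, drop = FALSE]
  cpp_quantization_error(t(grid$weights), as.integer(grid$coords[, 1]),
                         as.integer(grid$coords[, 2]), t(X),
                         .geo_idx(grid) - 1L, as.integer(k),
                         grid$lattice == "hexagonal")
}

#' Component planes
#'
#' One per-variable view of the trained map: node values min-max
#' rescaled to `[0, 1]` over nodes (a constant plane maps to 0.5
#' everywhere by convention). With `normalized = FALSE` and a stored
#' normaliser, values are reported in raw data units instead.
#'
#' @param grid trained `som_grid`.
#' @param normalized rescale each plane to `[0, 1]` (default).
#' @return data.frame: `node`, `row`, `col`, `variable`, `value`.
#' @export
component_planes <- function(grid, normalized = TRUE) {
  W <- grid$weights
  out <- lapply(grid$variables, function(v) {
    vals <- W[, v]
    if (normalized) {
      rng <- max(vals) - min(vals)
      vals <- if (rng < 1e-12) rep(0.5, length(vals)) else
        (vals - min(vals)) / rng
    } else if (!is.null(grid$norm)) {
      vals <- vals * grid$norm$range[[v]] + grid$norm$min[[v]]
    }
    data.frame(node = seq_len(nrow(W)), row = grid$coords[, 1],
               col = grid$coords[, 2], variable = v, value = vals)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Extract one plane as a numeric vector over nodes
#'
#' @param planes output of [component_planes()].
#' @param variable plane name.
#' @return numeric vector in node order.
#' @export
plane_vector <- function(planes, variable) {
  p <- planes[planes$variable == variable, ]
  if (!nrow(p)) stop("no plane named ", variable)
  p$value[order(p$node)]
}

#' Serialise / restore a trained map as JSON
#'
#' @param grid `som_grid`.
#' @param path output path.
#' @return `path` (write) or a `som_grid` (read).
#' @export
write_som <- function(grid, path) {
  obj <- list(rows = grid$rows, cols = grid$cols, lattice = grid$lattice,
              variables = grid$variables, geo_vars = grid$geo_vars,
              weights = apply(grid$weights, 1, as.list),
              seed = grid$seed, k = grid$k,
              norm = if (!is.null(grid$norm))
                list(min = as.list(grid$norm$min),
                     range = as.list(grid$norm$range)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_som
#' @export
read_som <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  g <- som_grid(obj$rows, obj$cols, variables = obj$variables,
                seed = if (!is.null(obj$seed)) obj$seed else 1L,
                geo_vars = obj$geo_vars, lattice = obj$lattice)
  W <- as.matrix(obj$weights)
  dimnames(W) <- list(NULL, obj$variables)
  g$weights <- W
  if (!is.null(obj$k)) g$k <- as.integer(obj$k)
  if (!is.null(obj$norm)) {
    g$norm <- list(min = unlist(obj$norm$min),
                   range = unlist(obj$norm$range))
  }
  g$trained <- TRUE
  g
}

#' Heatmap panels of component planes
#'
#' Base-graphics image panels, one per variable, values on the shared
#' [0, 1] scale.
#'
#' @param grid trained `som_grid`.
#' @param variables which planes to draw (default all).
#' @return invisibly, the plane table.
#' @export
plot_component_planes <- function(grid, variables = grid$variables) {
  planes <- component_planes(grid)
  nv <- length(variables)
  nc <- ceiling(sqrt(nv))
  nr <- ceiling(nv / nc)
  op <- graphics::par(mfrow = c(nr, nc), mar = c(1, 1, 2, 1))
  on.exit(graphics::par(op))
  pal <- grDevices::hcl.colors(64, "viridis")
  for (v in variables) {
    vals <- plane_vector(planes, v)
    m <- matrix(NA_real_, grid$rows, grid$cols)
    m[cbind(grid$coords[, 1], grid$coords[, 2])] <- vals
    graphics::image(seq_len(grid$cols), seq_len(grid$rows),
                    t(m[grid$rows:1, , drop = FALSE]),
                    col = pal, zlim = c(0, 1), axes = FALSE,
                    xlab = "", ylab = "", main = v)
  }
  invisible(planes)
}
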