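#' Construct a two-coordinate conformational energy landscape
#'
#' The ground-truth landscape is a sum of negative Gaussian wells on a flat
#' background, defined over a rectangular conformational-coordinate domain
#' (by default the unit square). Energies are expressed in units of kT. The
#' default landscape carries twelve wells of uneven depths arranged on a
#' 3 x 4 grid, the configuration used throughout the benchmark.
#'
#' The energy at a point \eqn{c} is
#' \deqn{E(c) = E_0 - \sum_i d_i \exp(-\|c - \mu_i\|^2 / (2 w_i^2))}
#' where \eqn{d_i > 0} is the depth (kT), \eqn{\mu_i} the center and
#' \eqn{w_i} the width (standard deviation) of well \eqn{i}. Equilibrium
#' occupancy follows the Boltzmann factor \eqn{p(c) \propto \exp(-E(c)/kT)}.
#'
#' @param wells data frame with columns `id`, `cc1`, `cc2`, `depth`, `width`.
#'   Ids must be unique and contiguous 1..n; depths and widths positive;
#'   centers inside the domain. Defaults to [default_wells()].
#' @param kT energy scale (default 1; all energies are reported in kT units).
#' @param domain 2x2 matrix of domain bounds, rows = (min, max), columns =
#'   (cc1, cc2). Default unit square.
#' @param background_energy constant baseline energy (default 0).
#' @return An object of class `energy_landscape`.
#' @examples
#' ls <- energy_landscape()
#' energy_at(ls, c(0.125, 1/6))
#' @seealso [occupancy_density()], [sample_conformations()],
#'   [label_conformation()]
#' @export
energy_landscape <- function(wells = default_wells(), kT = 1,
                             domain = rbind(c(0, 0), c(1, 1)),
                             background_energy = 0) {
  wells <- as.data.frame(wells)
  req <- c("id", "cc1", "cc2", "depth", "width")
  if (!all(req %in% names(wells)))
    stop("wells must have columns: ", paste(req, collapse = ", "))
  wells <- wells[order(wells$id), req, drop = FALSE]
  n <- nrow(wells)   # n = 0 gives a flat landscape at the background energy
  if (!identical(as.integer(wells$id), seq_len(n)))
    stop("well ids must be unique and contiguous 1..n")
  if (any(wells$depth <= 0)) stop("well depths must be positive (kT)")
  if (any(wells$width <= 0)) stop("well widths must be positive")
  domain <- matrix(as.numeric(domain), 2, 2)
  if (any(domain[1, ] >= domain[2, ])) stop("domain bounds must be increasing")
  inside <- wells$cc1 >= domain[1, 1] & wells$cc1 <= domain[2, 1] &
    wells$cc2 >= domain[1, 2] & wells$cc2 <= domain[2, 2]
  if (!all(inside)) stop("all well centers must lie inside the domain")
  if (kT <= 0) stop("kT must be positive")
  structure(list(wells = wells, kT = kT, domain = domain,
                 background_energy = background_energy),
            class = "energy_landscape")
}

#' Default 12-well ground-truth well table
#'
#' Twelve Gaussian wells of uneven depths on a 3 x 4 grid: columns along
#' cc1 at 0.13, 0.38, 0.63, 0.88 and rows along cc2 at 0.17, 0.49, 0.83.
#' Ids are raster-ordered, left to right then bottom to top.
#'
#' The centers sit slightly off grid-commensurate positions (such as
#' 0.125 or 0.5) on purpose: a peak exactly on a lattice-cell boundary of
#' the discretized occupancy produces exact ties between adjacent cells,
#' making the strict-local-maximum count of the lattice density
#' ill-defined at common resolutions.
#'
#' Depths (10 to 12.5 kT, a fixed uneven vector) together with the common
#' width 0.022 concentrate the equilibrium occupancy in the wells, so
#' Boltzmann samples form twelve well-separated clusters with only a
#' trace continuum between them, while the Gaussian tails keep the
#' landscape smooth and continuous.
#'
#' @return data frame with columns `id`, `cc1`, `cc2`, `depth`, `width`.
#' @export
default_wells <- function() {
  g <- expand.grid(cc1 = c(0.13, 0.38, 0.63, 0.88),
                   cc2 = c(0.17, 0.49, 0.83))
  data.frame(id = 1:12, cc1 = g$cc1, cc2 = g$cc2,
             depth = c(10.0, 11.5, 10.5, 12.0, 11.0, 10.2,
                       12.5, 10.8, 11.8, 10.4, 11.2, 12.2),
             width = 0.022)
}

in_domain <- function(landscape, cc) {
  cc[, 1] >= landscape$domain[1, 1] & cc[, 1] <= landscape$domain[2, 1] &
    cc[, 2] >= landscape$domain[1, 2] & cc[, 2] <= landscape$domain[2, 2]
}

as_cc_matrix <- function(cc) {
  if (is.null(dim(cc))) cc <- matrix(cc, ncol = 2, byrow = length(cc) == 2)
  cc <- as.matrix(cc)
  if (ncol(cc) != 2) stop("conformational coordinates must have 2 columns")
  storage.mode(cc) <- "double"
  cc
}

# Unchecked vectorized energy evaluation (m points x n wells).
energy_at_impl <- function(landscape, cc) {
  w <- landscape$wells
  e <- rep(landscape$background_energy, nrow(cc))
  for (i in seq_len(nrow(w))) {
    d2 <- (cc[, 1] - w$cc1[i])^2 + (cc[, 2] - w$cc2[i])^2
    e <- e - w$depth[i] * exp(-d2 / (2 * w$width[i]^2))
  }
  e
}

#' Evaluate the landscape energy at conformational coordinates
#'
#' @param landscape an [energy_landscape()].
#' @param cc a length-2 vector or an m x 2 matrix of coordinates inside the
#'   domain.
#' @return numeric vector of energies in kT units.
#' @export
energy_at <- function(landscape, cc) {
  stopifnot(inherits(landscape, "energy_landscape"))
  cc <- as_cc_matrix(cc)
  if (!all(in_domain(landscape, cc)))
    stop("coordinates outside the landscape domain")
  energy_at_impl(landscape, cc)
}

#' Discretized Boltzmann occupancy density on a lattice
#'
#' Evaluates \eqn{p(c) \propto \exp(-E(c)/kT)} at cell midpoints of a
#' `grid_resolution` x `grid_resolution` lattice over the domain and
#' normalizes the cell masses to sum to one.
#'
#' @param landscape an [energy_landscape()].
#' @param grid_resolution lattice cells per axis (>= 8).
#' @return An object of class `occupancy_grid`: list with midpoint vectors
#'   `cc1`, `cc2`, matrices `p` (cell masses summing to 1) and `E` (kT),
#'   indexed `[cc1, cc2]`, plus `grid_resolution` and `cell_area`.
#' @export
occupancy_density <- function(landscape, grid_resolution = 128L) {
  stopifnot(inherits(landscape, "energy_landscape"))
  grid_resolution <- as.integer(grid_resolution)
  if (grid_resolution < 8L) stop("grid_resolution must be at least 8")
  d <- landscape$domain
  step1 <- (d[2, 1] - d[1, 1]) / grid_resolution
  step2 <- (d[2, 2] - d[1, 2]) / grid_resolution
  cc1 <- d[1, 1] + (seq_len(grid_resolution) - 0.5) * step1
  cc2 <- d[1, 2] + (seq_len(grid_resolution) - 0.5) * step2
  g <- as.matrix(expand.grid(cc1 = cc1, cc2 = cc2))
  E <- matrix(energy_at_impl(landscape, g), grid_resolution, grid_resolution)
  w <- exp(-(E - min(E)) / landscape$kT)   # shift before exp for stability
  p <- w / sum(w)
  structure(list(cc1 = cc1, cc2 = cc2, p = p, E = E,
                 grid_resolution = grid_resolution,
                 cell_area = step1 * step2),
            class = "occupancy_grid")
}

#' Count strict local maxima of a lattice density
#'
#' A cell counts as a strict local maximum when its value exceeds all of its
#' existing (up to 8) neighbors. On the default landscape at sufficient
#' resolution this recovers exactly the twelve energy minima.
#'
#' @param grid an `occupancy_grid` from [occupancy_density()], or a matrix.
#' @return data frame of maxima with columns `cc1`, `cc2`, `p` (coordinates
#'   are lattice indices when a bare matrix is supplied).
#' @export
local_maxima <- function(grid) {
  if (inherits(grid, "occupancy_grid")) {
    m <- grid$p
    cc1 <- grid$cc1
    cc2 <- grid$cc2
  } else {
    m <- as.matrix(grid)
    cc1 <- seq_len(nrow(m))
    cc2 <- seq_len(ncol(m))
  }
  nr <- nrow(m); nc <- ncol(m)
  out <- NULL
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    ni <- max(1, i - 1):min(nr, i + 1)
    nj <- max(1, j - 1):min(nc, j + 1)
    nb <- m[ni, nj, drop = FALSE]
    if (sum(nb < m[i, j]) == length(nb) - 1L)
      out <- rbind(out, data.frame(cc1 = cc1[i], cc2 = cc2[j], p = m[i, j]))
  }
  if (is.null(out)) out <- data.frame(cc1 = numeric(), cc2 = numeric(),
                                      p = numeric())
  out
}

#' Label a conformation by its ground-truth well
#'
#' Assigns the id of the nearest well center (Euclidean distance in
#' conformational coordinates); ties break to the lowest id. This is the
#' Voronoi-basin ground-truth labeling used for all recall computations.
#'
#' @param landscape an [energy_landscape()].
#' @param cc length-2 vector or m x 2 matrix inside the domain.
#' @return integer vector of well ids.
#' @export
label_conformation <- function(landscape, cc) {
  stopifnot(inherits(landscape, "energy_landscape"))
  cc <- as_cc_matrix(cc)
  if (!all(in_domain(landscape, cc)))
    stop("coordinates outside the landscape domain")
  w <- landscape$wells
  if (nrow(w) == 0L) stop("cannot label conformations: landscape has no wells")
  d2 <- outer(cc[, 1], w$cc1, "-")^2 + outer(cc[, 2], w$cc2, "-")^2
  # max.col on negated distances returns the first (lowest-id) minimum
  as.integer(w$id[max.col(-d2, ties.method = "first")])
}

#' Sample Boltzmann-distributed conformations
#'
#' Draws exact samples from the equilibrium occupancy density by rejection
#' sampling: proposals uniform over the domain, envelope set from the
#' maximum Boltzmann weight found on a fine lattice and at the well centers
#' (with a small safety factor). Deterministic for a given seed.
#'
#' @param landscape an [energy_landscape()].
#' @param n number of samples (>= 0).
#' @param seed integer RNG seed.
#' @return data frame of class `conformation_sample` with columns `index`
#'   (0-based), `cc1`, `cc2`, `well_label`.
#' @export
sample_conformations <- function(landscape, n, seed = 1L) {
  stopifnot(inherits(landscape, "energy_landscape"))
  n <- as.integer(n)
  if (n < 0L) stop("n must be non-negative")
  d <- landscape$domain
  out <- matrix(numeric(0), 0, 2)
  if (n > 0L) {
    # Envelope: max unnormalized weight over well centers and a 512^2 lattice.
    centers <- as.matrix(landscape$wells[, c("cc1", "cc2")])
    grid <- occupancy_density(landscape, 512L)
    emin <- min(min(grid$E), min(energy_at_impl(landscape, centers)))
    wmax <- exp(-(emin - emin) / landscape$kT) * 1.000001  # = 1 + safety
    # Acceptance rate = Z / (domain area * wmax); use it to size batches.
    rate <- max(sum(grid$p / max(grid$p)) / grid$grid_resolution^2, 1e-6)
    out <- with_seed(seed, {
      acc <- matrix(numeric(0), 0, 2)
      while (nrow(acc) < n) {
        m <- min(ceiling(1.2 * (n - nrow(acc)) / rate) + 1024, 8e6)
        prop <- cbind(runif(m, d[1, 1], d[2, 1]), runif(m, d[1, 2], d[2, 2]))
        w <- exp(-(energy_at_impl(landscape, prop) - emin) / landscape$kT)
        keep <- runif(m) < w / wmax
        acc <- rbind(acc, prop[keep, , drop = FALSE])
      }
      acc[seq_len(n), , drop = FALSE]
    })
  }
  res <- data.frame(index = seq_len(n) - 1L, cc1 = out[, 1], cc2 = out[, 2])
  res$well_label <- if (n == 0L) integer(0)
    else if (nrow(landscape$wells) > 0L) label_conformation(landscape, out)
    else NA_integer_
  class(res) <- c("conformation_sample", "data.frame")
  res
}

#' @describeIn energy_landscape `simulate` method: draws `nsim` Boltzmann
#'   samples via [sample_conformations()].
#' @param object,nsim,... standard [stats::simulate()] arguments.
#' @param seed integer RNG seed.
#' @export
simulate.energy_landscape <- function(object, nsim = 1, seed = 1L, ...) {
  sample_conformations(object, nsim, seed)
}

#' @export
print.energy_landscape <- function(x, ...) {
  cat("Conformational energy landscape\n")
  cat(sprintf("  wells: %d (depths %.2f..%.2f kT, widths %.3g..%.3g)\n",
              nrow(x$wells), min(x$wells$depth), max(x$wells$depth),
              min(x$wells$width), max(x$wells$width)))
  cat(sprintf("  domain: [%g, %g] x [%g, %g], kT = %g\n",
              x$domain[1, 1], x$domain[2, 1], x$domain[1, 2], x$domain[2, 2],
              x$kT))
  invisible(x)
}

#' @export
plot.energy_landscape <- function(x, grid_resolution = 128L, ...) {
  g <- occupancy_density(x, grid_resolution)
  graphics::image(g$cc1, g$cc2, g$E, col = grDevices::hcl.colors(64, "viridis"),
                  xlab = "conformational coordinate 1",
                  ylab = "conformational coordinate 2",
                  main = "Energy landscape (kT)", useRaster = TRUE, ...)
  graphics::points(x$wells$cc1, x$wells$cc2, pch = 3, col = "white")
  graphics::text(x$wells$cc1, x$wells$cc2, labels = x$wells$id,
                 pos = 3, col = "white", cex = 0.8)
  invisible(g)
}
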