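# Shared fixtures, all built in code at test time.

# Two deep wells whose basin free energies differ by exactly kT*ln(2), so
# the equilibrium occupancy ratio is 2:1 (background mass negligible).
# For a Gaussian well the basin density is ~ exp(d) * 2*pi*sigma^2/d (the
# effective width of exp(-E) shrinks as sigma/sqrt(d)), so the deeper
# well's width is scaled by sqrt(d1/d2) to keep the entropic terms equal
# and leave only the kT*ln(2) energy gap.
two_well_landscape <- function(depth = 12) {
  d1 <- depth + log(2)
  energy_landscape(wells = data.frame(
    id = 1:2, cc1 = c(0.3, 0.7), cc2 = 0.5,
    depth = c(d1, depth), width = 0.03 * c(sqrt(d1 / depth), 1)))
}

# One isolated well far from the domain edge.
single_well_landscape <- function(depth = 3, width = 0.02) {
  energy_landscape(wells = data.frame(
    id = 1L, cc1 = 0.5, cc2 = 0.5, depth = depth, width = width))
}

# 12 tight, widely separated clusters (n_per points each) on a 3 x 4 grid
# in a synthetic embedding space, plus their labels.
clustered_embedding <- function(n_per = 10, spread = 0.01, seed = 99) {
  centers <- expand.grid(x = c(0, 3, 6, 9), y = c(0, 4, 8))
  lab <- rep(1:12, each = n_per)
  emb <- with_seed_test(seed, {
    cbind(centers$x[lab] + rnorm(length(lab), 0, spread),
          centers$y[lab] + rnorm(length(lab), 0, spread))
  })
  list(embedding = emb, labels = lab, centers = as.matrix(centers))
}

# Seed scoping for test-local randomness.
with_seed_test <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# Small phantom for imaging tests (cheap projections).
small_phantom <- function() build_default_phantom(32L, 3.0)

# Basin masses of a landscape by midpoint integration of the Boltzmann
# density over the Voronoi cell of each well center (independent oracle
# for sampling-recovery checks; labeling by explicit distance scan).
basin_masses_oracle <- function(landscape, res = 256L) {
  g <- occupancy_density(landscape, res)
  pts <- as.matrix(expand.grid(cc1 = g$cc1, cc2 = g$cc2))
  w <- landscape$wells
  lab <- apply(pts, 1, function(p) {
    d2 <- (p[1] - w$cc1)^2 + (p[2] - w$cc2)^2
    which(d2 == min(d2))[1]
  })
  as.numeric(tapply(as.numeric(g$p), factor(lab, levels = w$id), sum))
}
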