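# Internal helpers: seeded RNG scoping, derived streams, rotations.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state. All stochastic operations in the package go through this.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Derived per-item stream: independent of generation order, so per-particle
# noise can be reproduced in isolation. Kept below 2^31 - 1.
derive_seed <- function(seed, index) {
  s <- (as.numeric(seed) %% 2147483647) * 48271 + as.numeric(index) * 1664525
  as.integer(s %% 2147483647)
}

# Rodrigues rotation matrix for a unit axis and angle in degrees,
# counter-clockwise positive looking down the axis (right-handed).
rotation_matrix <- function(axis, angle_deg) {
  stopifnot(length(axis) == 3)
  n <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, n[3], -n[2],
                -n[3], 0, n[1],
                n[2], -n[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# ZYZ Euler rotation (Relion-style rot, tilt, psi in degrees):
# R = Rz(psi) %*% Ry(tilt) %*% Rz(rot), applied to column vectors.
euler_matrix <- function(rot, tilt, psi) {
  rz <- function(a) rotation_matrix(c(0, 0, 1), a)
  ry <- function(a) rotation_matrix(c(0, 1, 0), a)
  rz(psi) %*% ry(tilt) %*% rz(rot)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
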