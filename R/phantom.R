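#' Construct a two-body ribosome-like phantom
#'
#' The phantom is a Gaussian-blob density model of a ribosome-like object
#' with a fixed large subunit (LSU) and a mobile small subunit (SSU). The
#' SSU rotates rigidly, ratchet-like, about two mutually orthogonal axes
#' through a pivot at the LSU-SSU interface; the two rotation angles are
#' the physical realization of the two conformational coordinates.
#'
#' Using an analytic Gaussian-mixture density (rather than an atomic-model
#' map) makes volume rendering and projection closed-form and keeps the
#' total mass exactly invariant under the rigid SSU rotation.
#'
#' @param lsu,ssu blob sets: data frames with columns `x`, `y`, `z` (voxel
#'   units, origin at the box center), `sigma` (isotropic width, voxels,
#'   > 0) and `amplitude` (> 0).
#' @param pivot length-3 rotation origin (voxel units).
#' @param axis1,axis2 orthonormal rotation axes (3-vectors).
#' @param max_angle1,max_angle2 full ratchet half-ranges in degrees
#'   (default 10 each); conformational coordinate 0 maps to -max, 1 to +max.
#' @param box_size voxels per edge (even, >= 32).
#' @param voxel_size voxel edge in Angstrom.
#' @return An object of class `two_body_phantom`.
#' @seealso [build_default_phantom()], [render_volume()], [project_particle()]
#' @export
two_body_phantom <- function(lsu, ssu, pivot, axis1, axis2,
                             max_angle1 = 10, max_angle2 = 10,
                             box_size = 64L, voxel_size = 3.0) {
  box_size <- as.integer(box_size)
  if (box_size < 32L) stop("box_size must be at least 32")
  if (box_size %% 2L != 0L) stop("box_size must be even")
  check_blobs <- function(b, what) {
    b <- as.data.frame(b)
    req <- c("x", "y", "z", "sigma", "amplitude")
    if (!all(req %in% names(b)))
      stop(what, " blobs must have columns: ", paste(req, collapse = ", "))
    if (any(b$sigma <= 0) || any(b$amplitude <= 0))
      stop(what, " blob sigma and amplitude must be positive")
    b[, req]
  }
  lsu <- check_blobs(lsu, "lsu")
  ssu <- check_blobs(ssu, "ssu")
  axis1 <- axis1 / sqrt(sum(axis1^2))
  axis2 <- axis2 / sqrt(sum(axis2^2))
  if (abs(sum(axis1 * axis2)) > 1e-10)
    stop("rotation axes must be orthogonal")
  half <- box_size / 2
  support <- function(b) {
    r <- cbind(b$x, b$y, b$z)
    max(abs(r) + 3 * b$sigma)
  }
  if (max(support(lsu), support(ssu)) > half)
    stop("box too small: a blob exceeds the box at 3 sigma")
  structure(list(lsu = lsu, ssu = ssu, pivot = as.numeric(pivot),
                 axis1 = axis1, axis2 = axis2,
                 max_angle1 = max_angle1, max_angle2 = max_angle2,
                 box_size = box_size, voxel_size = voxel_size),
            class = "two_body_phantom")
}

#' Default ribosome-like phantom
#'
#' A deterministic two-body blob model: a large LSU cluster occupying
#' roughly the lower half of the box, a smaller SSU cluster above it, the
#' pivot at their interface, and rotation axes along x (axis 1) and y
#' (axis 2). Blob geometry scales with `box_size` so the object fills the
#' box comparably at any size.
#'
#' @param box_size voxels per edge (even, >= 32; default 64).
#' @param voxel_size voxel edge in Angstrom (default 3).
#' @return A [two_body_phantom()].
#' @export
build_default_phantom <- function(box_size = 64L, voxel_size = 3.0) {
  s <- box_size / 64  # geometry scale factor
  lsu <- data.frame(
    x = s * c(0, 7, -7, 3, -4, 0),
    y = s * c(0, 3, 4, -6, -5, 6),
    z = s * c(-10, -8, -9, -12, -6, -14),
    sigma = s * c(6.5, 4.5, 4.5, 4.0, 4.0, 3.5),
    amplitude = c(1.0, 0.8, 0.8, 0.7, 0.7, 0.6))
  ssu <- data.frame(
    x = s * c(0, 6, -5, 2),
    y = s * c(0, -3, 2, 5),
    z = s * c(10, 12, 13, 16),
    sigma = s * c(4.5, 3.2, 3.0, 2.6),
    amplitude = c(0.9, 0.7, 0.6, 0.5))
  two_body_phantom(lsu, ssu, pivot = s * c(0, 0, 3),
                   axis1 = c(1, 0, 0), axis2 = c(0, 1, 0),
                   box_size = box_size, voxel_size = voxel_size)
}

#' Map conformational coordinates to SSU rotation angles
#'
#' Linear, monotone map of each coordinate in \[0, 1\] onto
#' \[-max_angle, +max_angle\]: `alpha = max_angle1 * (2 cc1 - 1)` about
#' axis 1 and `beta = max_angle2 * (2 cc2 - 1)` about axis 2; the domain
#' midpoint (0.5, 0.5) is the unrotated rest pose.
#'
#' @param phantom a [two_body_phantom()].
#' @param cc length-2 vector or m x 2 matrix in \[0, 1\]^2.
#' @return m x 2 matrix with columns `alpha`, `beta` (degrees).
#' @export
conformation_to_angles <- function(phantom, cc) {
  stopifnot(inherits(phantom, "two_body_phantom"))
  cc <- as_cc_matrix(cc)
  if (any(cc < 0) || any(cc > 1))
    stop("conformational coordinates must lie in [0, 1]^2")
  cbind(alpha = phantom$max_angle1 * (2 * cc[, 1] - 1),
        beta = phantom$max_angle2 * (2 * cc[, 2] - 1))
}

# All blobs (LSU fixed, SSU rotated about the pivot) for one conformation.
# Rotation composition R(axis2, beta) %*% R(axis1, alpha): axis1 applied
# first. At <= 10 degrees the commutator is second-order; the order is
# fixed and documented.
conformed_blobs <- function(phantom, cc) {
  ang <- conformation_to_angles(phantom, cc)
  R <- rotation_matrix(phantom$axis2, ang[1, "beta"]) %*%
    rotation_matrix(phantom$axis1, ang[1, "alpha"])
  ssu <- phantom$ssu
  ctr <- t(R %*% (t(as.matrix(ssu[, c("x", "y", "z")])) - phantom$pivot) +
             phantom$pivot)
  ssu$x <- ctr[, 1]; ssu$y <- ctr[, 2]; ssu$z <- ctr[, 3]
  rbind(phantom$lsu, ssu)
}

# Total analytic mass of a blob set: sum amplitude * (2 pi)^(3/2) sigma^3.
blob_mass <- function(blobs) {
  sum(blobs$amplitude * (2 * pi)^1.5 * blobs$sigma^3)
}

#' Render the phantom density volume at a conformation
#'
#' Rotates the SSU blob centers rigidly about the pivot (Rodrigues
#' rotations, axis 1 applied first) and evaluates the Gaussian-mixture
#' density analytically on the voxel grid; no voxel resampling or
#' interpolation is involved, so the analytic mass is exactly
#' conformation-independent.
#'
#' @param phantom a [two_body_phantom()].
#' @param cc length-2 conformational coordinate in \[0, 1\]^2.
#' @return An object of class `volume_grid`: list with `data` (array
#'   `dim c(nx, ny, nz)`, x fastest, origin at the box center),
#'   `voxel_size`, and `analytic_mass`.
#' @export
render_volume <- function(phantom, cc = c(0.5, 0.5)) {
  stopifnot(inherits(phantom, "two_body_phantom"))
  blobs <- conformed_blobs(phantom, cc)
  bs <- phantom$box_size
  ax <- seq_len(bs) - 1 - bs / 2   # voxel center coordinates
  vol <- array(0, dim = c(bs, bs, bs))
  half <- bs / 2
  for (i in seq_len(nrow(blobs))) {
    if (max(abs(c(blobs$x[i], blobs$y[i], blobs$z[i])) + 3 * blobs$sigma[i]) >
        half)
      warning("blob ", i, " falls outside the 3-sigma box support")
    s2 <- 2 * blobs$sigma[i]^2
    gx <- exp(-(ax - blobs$x[i])^2 / s2)
    gy <- exp(-(ax - blobs$y[i])^2 / s2)
    gz <- exp(-(ax - blobs$z[i])^2 / s2)
    # separable outer product, scaled by amplitude
    vol <- vol + blobs$amplitude[i] * (gx %o% gy %o% gz)
  }
  structure(list(data = vol, voxel_size = phantom$voxel_size,
                 analytic_mass = blob_mass(blobs)),
            class = "volume_grid")
}

#' @export
print.two_body_phantom <- function(x, ...) {
  cat("Two-body ribosome-like phantom\n")
  cat(sprintf("  LSU: %d blobs (fixed); SSU: %d blobs (mobile)\n",
              nrow(x$lsu), nrow(x$ssu)))
  cat(sprintf("  box: %d^3 voxels at %.2f A/voxel\n", x$box_size,
              x$voxel_size))
  cat(sprintf("  ratchet range: +/-%g deg (axis 1), +/-%g deg (axis 2)\n",
              x$max_angle1, x$max_angle2))
  invisible(x)
}
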