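#' Analytic projection of the phantom at one conformation and orientation
#'
#' Forms the orthographic line-integral projection of the conformed blob
#' density along the viewing z axis after orienting the blob set by a ZYZ
#' Euler rotation (Relion-style `rot`, `tilt`, `psi`, applied about the box
#' center). A 3-D isotropic Gaussian blob projects analytically to a 2-D
#' Gaussian of the same sigma with line-integral amplitude
#' `amplitude * sigma * sqrt(2 pi)`, so no volume is voxelized.
#'
#' @param phantom a [two_body_phantom()].
#' @param cc length-2 conformational coordinate in \[0, 1\]^2.
#' @param euler length-3 `c(rot, tilt, psi)` in degrees (ZYZ).
#' @return `box_size` x `box_size` numeric matrix (x fastest), pixel grid
#'   matching the voxel grid of [render_volume()].
#' @export
project_particle <- function(phantom, cc = c(0.5, 0.5),
                             euler = c(0, 0, 0)) {
  stopifnot(inherits(phantom, "two_body_phantom"), length(euler) == 3)
  blobs <- conformed_blobs(phantom, cc)
  R <- euler_matrix(euler[1], euler[2], euler[3])
  ctr <- t(R %*% t(as.matrix(blobs[, c("x", "y", "z")])))
  bs <- phantom$box_size
  ax <- seq_len(bs) - 1 - bs / 2
  img <- matrix(0, bs, bs)
  for (i in seq_len(nrow(blobs))) {
    s2 <- 2 * blobs$sigma[i]^2
    gx <- exp(-(ax - ctr[i, 1])^2 / s2)
    gy <- exp(-(ax - ctr[i, 2])^2 / s2)
    img <- img + blobs$amplitude[i] * blobs$sigma[i] * sqrt(2 * pi) *
      (gx %o% gy)
  }
  img
}

#' Apply a phase contrast transfer function to an image
#'
#' Multiplies the image by a two-parameter phase CTF in Fourier space,
#' `CTF(k) = -sin(pi * lambda * dz * |k|^2)` with defocus `dz` and the
#' electron wavelength set by the acceleration voltage. Optional stage of
#' the forward model, off by default.
#'
#' @param image numeric matrix.
#' @param defocus_um defocus in micrometres (underfocus positive).
#' @param pixel_size pixel edge in Angstrom.
#' @param kv acceleration voltage in kilovolt (default 300).
#' @return CTF-modulated image (real part of the inverse transform).
#' @export
ctf_apply <- function(image, defocus_um, pixel_size, kv = 300) {
  n <- nrow(image)
  stopifnot(ncol(image) == n)
  # relativistic electron wavelength, Angstrom
  v <- kv * 1000
  lambda <- 12.2639 / sqrt(v + 0.97845e-6 * v^2)
  f <- c(seq(0, floor(n / 2)), seq(-ceiling(n / 2) + 1, -1)) / (n * pixel_size)
  k2 <- outer(f^2, f^2, "+")
  ctf <- -sin(pi * lambda * (defocus_um * 1e4) * k2)
  Re(stats::fft(stats::fft(image) * ctf, inverse = TRUE)) / n^2
}

#' Calibrate the noise standard deviation for a target SNR
#'
#' SNR is defined as pooled signal variance divided by noise variance over
#' whole frames (no particle mask): `sigma = sqrt(Var(signal) / snr)`,
#' with the variance pooled over every pixel of every noise-free image.
#' One global sigma keeps the noise stationary across conformations.
#'
#' @param noise_free_images array `c(box, box, n)` or a list of matrices of
#'   noise-free projections.
#' @param snr_target target signal-to-noise ratio (> 0; `Inf` gives 0).
#' @return noise standard deviation in image-intensity units.
#' @export
calibrate_noise_sigma <- function(noise_free_images, snr_target = 1) {
  if (is.list(noise_free_images))
    noise_free_images <- simplify2array(noise_free_images)
  if (snr_target <= 0) stop("snr_target must be positive")
  v <- stats::var(as.numeric(noise_free_images))
  if (v == 0) stop("signal has zero variance; cannot calibrate noise")
  if (is.infinite(snr_target)) return(0)
  sqrt(v / snr_target)
}

#' Add white Gaussian noise to an image
#'
#' i.i.d. zero-mean Gaussian noise of standard deviation `sigma` per pixel;
#' deterministic for a given seed.
#'
#' @param image numeric matrix.
#' @param sigma noise standard deviation (>= 0).
#' @param seed integer RNG seed.
#' @return noisy image of the same dimensions.
#' @export
add_noise <- function(image, sigma, seed = 1L) {
  if (sigma < 0) stop("sigma must be non-negative")
  if (sigma == 0) return(image)
  image + with_seed(seed, matrix(stats::rnorm(length(image), 0, sigma),
                                 nrow(image), ncol(image)))
}

#' Generate a synthetic single-particle dataset
#'
#' The full forward model: conformations are Boltzmann-sampled from the
#' landscape, orientations are drawn uniformly over SO(3) (or held at a
#' single fixed view), each particle is projected analytically, the noise
#' sigma is calibrated on the noise-free pass to hit `snr_target`, and
#' per-particle Gaussian noise is added from streams derived from
#' `(seed, index)` so generation is order-independent. Fully deterministic
#' given `seed`.
#'
#' @param landscape an [energy_landscape()].
#' @param phantom a [two_body_phantom()].
#' @param n number of particles (>= 1).
#' @param snr_target target SNR (default 1, the benchmark condition).
#' @param seed integer global seed.
#' @param orientation_mode `"uniform"` (Haar over SO(3)) or `"fixed"`
#'   (identity view for every particle).
#' @param keep_clean keep the noise-free images in the result (`$clean`);
#'   off by default to bound memory for large stacks.
#' @param ctf apply a per-particle phase CTF ([ctf_apply()]) before noise;
#'   off by default. Defoci are drawn uniformly from `defocus_range` and
#'   recorded in the metadata.
#' @param defocus_range defocus range in micrometres when `ctf = TRUE`.
#' @return An object of class `particle_stack`: list with `images` (array
#'   `c(box, box, n)`), `pixel_size` (Angstrom), `metadata` (data frame:
#'   `index`, `rot`, `tilt`, `psi`, `cc1`, `cc2`, `well_label`,
#'   `noise_sigma`, `seed_offset`), `snr_target`, `global_seed`.
#' @export
generate_dataset <- function(landscape, phantom, n, snr_target = 1,
                             seed = 1L,
                             orientation_mode = c("uniform", "fixed"),
                             keep_clean = FALSE, ctf = FALSE,
                             defocus_range = c(0.5, 2.5)) {
  stopifnot(inherits(landscape, "energy_landscape"),
            inherits(phantom, "two_body_phantom"))
  n <- as.integer(n)
  if (n < 1L) stop("n must be at least 1")
  orientation_mode <- match.arg(orientation_mode)
  conf <- sample_conformations(landscape, n, seed = derive_seed(seed, 0L))
  eul <- if (orientation_mode == "uniform") {
    with_seed(derive_seed(seed, 1L), {
      cbind(rot = stats::runif(n, -180, 180),
            tilt = acos(stats::runif(n, -1, 1)) * 180 / pi,
            psi = stats::runif(n, -180, 180))
    })
  } else {
    cbind(rot = rep(0, n), tilt = rep(0, n), psi = rep(0, n))
  }
  bs <- phantom$box_size
  clean <- array(0, dim = c(bs, bs, n))
  for (i in seq_len(n)) {
    clean[, , i] <- project_particle(phantom, c(conf$cc1[i], conf$cc2[i]),
                                     eul[i, ])
  }
  defocus <- NULL
  if (ctf) {
    defocus <- with_seed(derive_seed(seed, 2L),
                         stats::runif(n, defocus_range[1], defocus_range[2]))
    for (i in seq_len(n)) {
      clean[, , i] <- ctf_apply(clean[, , i], defocus[i], phantom$voxel_size)
    }
  }
  sigma <- calibrate_noise_sigma(clean, snr_target)
  images <- clean
  offsets <- 2L + seq_len(n)
  if (sigma > 0) {
    for (i in seq_len(n)) {
      images[, , i] <- add_noise(clean[, , i], sigma,
                                 seed = derive_seed(seed, offsets[i]))
    }
  }
  meta <- data.frame(index = conf$index, rot = eul[, "rot"],
                     tilt = eul[, "tilt"], psi = eul[, "psi"],
                     cc1 = conf$cc1, cc2 = conf$cc2,
                     well_label = conf$well_label,
                     noise_sigma = sigma, seed_offset = offsets)
  if (ctf) meta$defocus_um <- defocus
  out <- list(images = images, pixel_size = phantom$voxel_size,
              metadata = meta, snr_target = snr_target, global_seed = seed)
  if (keep_clean) out$clean <- clean
  structure(out, class = "particle_stack")
}

#' Empirical SNR of a generated stack
#'
#' Pooled variance of the noise-free images divided by pooled variance of
#' the added noise, matching the calibration convention.
#'
#' @param stack a [generate_dataset()] result created with
#'   `keep_clean = TRUE`.
#' @return empirical SNR (dimensionless).
#' @export
empirical_snr <- function(stack) {
  stopifnot(inherits(stack, "particle_stack"))
  if (is.null(stack$clean))
    stop("stack was generated without keep_clean = TRUE")
  stats::var(as.numeric(stack$clean)) /
    stats::var(as.numeric(stack$images - stack$clean))
}

#' @export
print.particle_stack <- function(x, ...) {
  d <- dim(x$images)
  cat("Synthetic particle stack\n")
  cat(sprintf("  %d particles, %d x %d px at %.2f A/px\n", d[3], d[1], d[2],
              x$pixel_size))
  cat(sprintf("  target SNR %.3g (noise sigma %.4g), seed %d\n",
              x$snr_target, x$metadata$noise_sigma[1], x$global_seed))
  cat(sprintf("  wells represented: %d of %d\n",
              length(unique(x$metadata$well_label)),
              max(x$metadata$well_label)))
  invisible(x)
}
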