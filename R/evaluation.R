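#' Per-well centers of an embedding
#'
#' The center of each energy minimum in embedding space is the arithmetic
#' mean of the embedding coordinates of all particles carrying that
#' ground-truth label.
#'
#' @param embedding n x d numeric matrix (d >= 1) of per-particle
#'   coordinates, row-aligned to `true_labels`.
#' @param true_labels integer ground-truth well labels (1..n_wells); every
#'   label up to the maximum must occur at least once.
#' @return n_wells x d matrix of class centers (row i = well i).
#' @export
well_centers <- function(embedding, true_labels) {
  embedding <- as_embedding(embedding)
  true_labels <- as.integer(true_labels)
  stopifnot(nrow(embedding) == length(true_labels))
  n_wells <- max(true_labels)
  missing <- setdiff(seq_len(n_wells), unique(true_labels))
  if (length(missing) > 0)
    stop("no particles labeled for well(s): ", paste(missing, collapse = ", "))
  centers <- matrix(NA_real_, n_wells, ncol(embedding))
  for (k in seq_len(n_wells)) {
    centers[k, ] <- colMeans(embedding[true_labels == k, , drop = FALSE])
  }
  centers
}

#' Assign particles to nearest well centers
#'
#' Each particle receives the label of the center with minimal squared
#' Euclidean distance; ties break to the lowest well id.
#'
#' @param embedding n x d numeric matrix.
#' @param centers k x d matrix of well centers (row i = well i).
#' @return integer vector of predicted labels.
#' @export
assign_nearest_center <- function(embedding, centers) {
  embedding <- as_embedding(embedding)
  centers <- as.matrix(centers)
  if (nrow(centers) < 1) stop("at least one center is required")
  stopifnot(ncol(embedding) == ncol(centers))
  # ||x - c||^2 = ||x||^2 + ||c||^2 - 2 x.c ; ||x||^2 constant per row
  d2 <- outer(rep(1, nrow(embedding)), rowSums(centers^2)) -
    2 * embedding %*% t(centers)
  as.integer(max.col(-d2, ties.method = "first"))
}

#' Per-well recall table
#'
#' For each well n, `recall(n) = TP(n) / P(n)` where `P(n)` counts the
#' particles whose ground-truth label is n (the positive class) and
#' `TP(n)` those among them also predicted as n.
#'
#' @param true_labels,predicted_labels integer label vectors of equal
#'   length, values in 1..n_wells; every true label must occur.
#' @return data frame of class `recall_table` with columns `well`, `P`,
#'   `TP`, `recall`.
#' @export
recall_per_well <- function(true_labels, predicted_labels) {
  true_labels <- as.integer(true_labels)
  predicted_labels <- as.integer(predicted_labels)
  stopifnot(length(true_labels) == length(predicted_labels))
  n_wells <- max(true_labels, predicted_labels)
  P <- tabulate(true_labels, nbins = n_wells)
  if (any(P == 0))
    stop("recall undefined: no particles with true label ",
         paste(which(P == 0), collapse = ", "))
  TP <- tabulate(true_labels[true_labels == predicted_labels],
                 nbins = n_wells)
  out <- data.frame(well = seq_len(n_wells), P = P, TP = TP,
                    recall = TP / P)
  class(out) <- c("recall_table", "data.frame")
  out
}

#' Balanced accuracy and recall spread from a recall table
#'
#' Balanced accuracy is the unweighted mean of the per-well recalls,
#' reported in percent. The spread is the standard deviation of the
#' per-well recalls, population convention by default (divide by the
#' number of wells), also in percent.
#'
#' @param recall_table a [recall_per_well()] result.
#' @param sd_convention `"population"` (default) or `"sample"`.
#' @return list with `accuracy` and `recall_std`, both in percent.
#' @export
accuracy <- function(recall_table, sd_convention = c("population", "sample")) {
  sd_convention <- match.arg(sd_convention)
  r <- recall_table$recall
  m <- mean(r)
  s <- if (sd_convention == "population") {
    sqrt(mean((r - m)^2))
  } else {
    stats::sd(r)
  }
  list(accuracy = 100 * m, recall_std = 100 * s)
}

#' Score an embedding against ground-truth well labels
#'
#' The full accuracy metric: per-well centers in embedding space
#' ([well_centers()]), nearest-center assignment
#' ([assign_nearest_center()]), per-well recall ([recall_per_well()]) and
#' balanced accuracy ([accuracy()]). The metric runs in the native
#' dimension of the supplied embedding; no normalization or whitening is
#' applied.
#'
#' @inheritParams well_centers
#' @inheritParams accuracy
#' @return An object of class `benchmark_report`: list with `recall_table`,
#'   `accuracy` (%), `recall_std` (%), `n`, `n_wells`, `sd_convention`.
#' @examples
#' conf <- sample_conformations(energy_landscape(), 2000, seed = 7)
#' report <- evaluate_embedding(cbind(conf$cc1, conf$cc2), conf$well_label)
#' report
#' @export
evaluate_embedding <- function(embedding, true_labels,
                               sd_convention = c("population", "sample")) {
  sd_convention <- match.arg(sd_convention)
  embedding <- as_embedding(embedding)
  true_labels <- as.integer(true_labels)
  centers <- well_centers(embedding, true_labels)
  pred <- assign_nearest_center(embedding, centers)
  tab <- recall_per_well(true_labels, pred)
  acc <- accuracy(tab, sd_convention)
  structure(list(recall_table = tab, accuracy = acc$accuracy,
                 recall_std = acc$recall_std, n = length(true_labels),
                 n_wells = nrow(tab), sd_convention = sd_convention),
            class = "benchmark_report")
}

as_embedding <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.null(dim(x))) x <- matrix(x, ncol = 1)
  storage.mode(x) <- "double"
  if (any(!is.finite(x))) stop("embedding contains non-finite entries")
  x
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat("Embedding benchmark report\n")
  cat(sprintf("  %d particles, %d wells\n", x$n, x$n_wells))
  cat(sprintf("  balanced accuracy: %.2f %%\n", x$accuracy))
  cat(sprintf("  recall std (%s):   %.2f %%\n", x$sd_convention,
              x$recall_std))
  invisible(x)
}

#' @export
summary.benchmark_report <- function(object, ...) {
  print(object)
  cat("  per-well recall:\n")
  print(object$recall_table, row.names = FALSE)
  invisible(object)
}

#' 2-D occupancy map of an embedding
#'
#' Normalized 2-D histogram of the particles over embedding space; the
#' equilibrium occupancy representation of the conformational landscape.
#' Bins span the data range on each axis.
#'
#' @param embedding n x 2 matrix (occupancy maps are 2-D by construction).
#' @param n_bins bins per axis (>= 4; default 40).
#' @return An object of class `occupancy_map`: list with `breaks1`,
#'   `breaks2`, `mid1`, `mid2`, `counts` (n_bins x n_bins), `p`
#'   (probabilities summing to 1), `n`.
#' @export
occupancy_map <- function(embedding, n_bins = 40L) {
  embedding <- as_embedding(embedding)
  if (ncol(embedding) != 2)
    stop("occupancy maps require a 2-dimensional embedding")
  n_bins <- as.integer(n_bins)
  if (n_bins < 4L) stop("n_bins must be at least 4")
  breaks1 <- seq(min(embedding[, 1]), max(embedding[, 1]),
                 length.out = n_bins + 1)
  breaks2 <- seq(min(embedding[, 2]), max(embedding[, 2]),
                 length.out = n_bins + 1)
  i <- findInterval(embedding[, 1], breaks1, rightmost.closed = TRUE,
                    all.inside = TRUE)
  j <- findInterval(embedding[, 2], breaks2, rightmost.closed = TRUE,
                    all.inside = TRUE)
  counts <- matrix(tabulate((j - 1L) * n_bins + i, nbins = n_bins^2),
                   n_bins, n_bins)
  structure(list(breaks1 = breaks1, breaks2 = breaks2,
                 mid1 = (breaks1[-1] + breaks1[-(n_bins + 1)]) / 2,
                 mid2 = (breaks2[-1] + breaks2[-(n_bins + 1)]) / 2,
                 counts = counts, p = counts / nrow(embedding),
                 n = nrow(embedding)),
            class = "occupancy_map")
}

#' Boltzmann-inverted energy surface from an occupancy map
#'
#' Inverts the Boltzmann relation, `E = -kT ln p`, on bins whose counts
#' reach `floor_count`, and shifts the surface so its minimum is zero.
#' Bins below the floor are masked (`NA`), never extrapolated: no energy
#' is invented for unvisited states.
#'
#' @param map an [occupancy_map()].
#' @param kT energy scale (default 1).
#' @param floor_count minimum bin count to invert (>= 1; default 1).
#' @return An object of class `energy_surface`: list with `mid1`, `mid2`,
#'   `E` (kT units, `NA` where masked), `kT`, `floor_count`.
#' @export
energy_from_occupancy <- function(map, kT = 1, floor_count = 1L) {
  stopifnot(inherits(map, "occupancy_map"))
  if (floor_count < 1) stop("floor_count must be at least 1")
  keep <- map$counts >= floor_count
  if (!any(keep)) stop("all bins are below floor_count")
  E <- matrix(NA_real_, nrow(map$counts), ncol(map$counts))
  E[keep] <- -kT * log(map$p[keep])
  E <- E - min(E, na.rm = TRUE)
  structure(list(mid1 = map$mid1, mid2 = map$mid2, E = E, kT = kT,
                 floor_count = as.integer(floor_count)),
            class = "energy_surface")
}

#' @export
plot.occupancy_map <- function(x, ...) {
  graphics::image(x$mid1, x$mid2, x$p,
                  col = grDevices::hcl.colors(64, "viridis"),
                  xlab = "embedding dim 1", ylab = "embedding dim 2",
                  main = "Occupancy map", useRaster = TRUE, ...)
  invisible(x)
}

#' @export
plot.energy_surface <- function(x, ...) {
  graphics::image(x$mid1, x$mid2, x$E,
                  col = grDevices::hcl.colors(64, "viridis", rev = TRUE),
                  xlab = "embedding dim 1", ylab = "embedding dim 2",
                  main = "Energy landscape (kT)", useRaster = TRUE, ...)
  invisible(x)
}

#' Fixed 12-color lineage palette
#'
#' A fixed, documented palette of twelve visually distinct colors, one per
#' energy minimum, used for data-lineage coloring.
#'
#' @return character vector of 12 hex colors.
#' @export
lineage_palette <- function() {
  c("#E6194B", "#3CB44B", "#FFE119", "#4363D8", "#F58231", "#911EB4",
    "#46F0F0", "#F032E6", "#BCF60C", "#008080", "#9A6324", "#800000")
}

#' Data-lineage coloring of an embedding
#'
#' Colors each particle in the embedding by its ground-truth energy
#' minimum through the fixed [lineage_palette()], visualizing how a
#' heterogeneity method mixes or preserves the ground-truth basins.
#'
#' @param embedding n x d matrix (first two dims are plotted).
#' @param true_labels integer ground-truth labels in 1..12.
#' @param png_path optional path; when given, a scatter plot is written as
#'   PNG.
#' @return data frame with the embedding coordinates (`dim1`, `dim2`, ...),
#'   `color_id` (= well label) and `color` (hex).
#' @export
lineage_map <- function(embedding, true_labels, png_path = NULL) {
  embedding <- as_embedding(embedding)
  true_labels <- as.integer(true_labels)
  stopifnot(nrow(embedding) == length(true_labels))
  pal <- lineage_palette()
  if (max(true_labels) > length(pal) || min(true_labels) < 1)
    stop("labels must lie in 1..", length(pal))
  out <- as.data.frame(embedding)
  names(out) <- paste0("dim", seq_len(ncol(embedding)))
  out$color_id <- true_labels
  out$color <- pal[true_labels]
  if (!is.null(png_path)) {
    grDevices::png(png_path, width = 900, height = 800)
    on.exit(grDevices::dev.off(), add = TRUE)
    graphics::plot(out$dim1, out$dim2, col = out$color, pch = 16,
                   cex = 0.5, xlab = "embedding dim 1",
                   ylab = "embedding dim 2",
                   main = "Data lineage (colored by ground-truth minimum)")
    graphics::legend("topright", legend = seq_along(pal), col = pal,
                     pch = 16, ncol = 2, cex = 0.8, title = "well")
  }
  out
}
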