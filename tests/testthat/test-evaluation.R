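test_that("well centers are per-class means", {
  # a single-point class is its own center; a symmetric pair centers at 0
  emb <- rbind(c(2, 3), c(-1, -1), c(1, 1))
  ctr <- well_centers(emb, c(1L, 2L, 2L))
  expect_equal(ctr[1, ], c(2, 3))
  expect_equal(ctr[2, ], c(0, 0))

  # 500 random labeled points against an independent per-class mean
  set <- with_seed_test(12, list(emb = matrix(rnorm(1000), ncol = 2),
                                 lab = sample(1:12, 500, replace = TRUE)))
  ctr <- well_centers(set$emb, set$lab)
  for (k in 1:12) {
    expect_equal(ctr[k, ], colMeans(set$emb[set$lab == k, , drop = FALSE]),
                 tolerance = 1e-12)
  }
  expect_error(well_centers(emb, c(1L, 1L, 3L)), "well\\(s\\): 2")
})

test_that("nearest-center assignment matches the exhaustive distance scan", {
  cl <- clustered_embedding(n_per = 5)
  # points exactly at a center get that center's label
  expect_identical(assign_nearest_center(cl$centers, cl$centers), 1:12)

  # equidistant between centers 2 and 7: lowest id wins
  ctr2 <- rbind(c(-3, -3), c(2, 0), c(4, 4), c(6, 9), c(-3, 2), c(8, 1),
                c(0, 2))  # centers 2 and 7 equidistant from (1, 1)
  expect_identical(assign_nearest_center(rbind(c(1, 1)), ctr2), 2L)

  pts <- with_seed_test(8, matrix(rnorm(2000, sd = 4), ncol = 2))
  brute <- apply(pts, 1, function(p) {
    d2 <- rowSums(sweep(cl$centers, 2, p)^2)
    which(d2 == min(d2))[1]
  })
  expect_identical(assign_nearest_center(pts, cl$centers), as.integer(brute))
})

test_that("recall follows TP(n)/P(n) with the documented edge cases", {
  # perfect assignment: recall 1 everywhere
  lab <- rep(1:12, each = 4)
  tab <- recall_per_well(lab, lab)
  expect_equal(tab$recall, rep(1, 12))
  expect_equal(sum(tab$P), length(lab))

  # a never-recovered well scores 0
  pred <- lab
  pred[lab == 5L] <- 6L
  expect_equal(recall_per_well(lab, pred)$recall[5], 0)

  # hand-counted 5-element confusion
  tab <- recall_per_well(c(1, 1, 1, 2, 2), c(1, 1, 2, 2, 2))
  expect_equal(tab$recall, c(2 / 3, 1))
  expect_equal(tab$P, c(3, 2))
  expect_equal(tab$TP, c(2, 2))

  expect_error(recall_per_well(c(1, 1, 2), c(3, 1, 2)), "true label")
})

test_that("balanced accuracy is the unweighted mean recall, in percent", {
  tab <- data.frame(well = 1:12, P = 10, TP = 8,
                    recall = rep(0.776, 12))
  expect_equal(accuracy(tab)$accuracy, 77.6)
  expect_equal(accuracy(tab)$recall_std, 0)

  tab$recall <- c(1, rep(0, 11))
  expect_equal(accuracy(tab)$accuracy, 100 / 12)

  r <- with_seed_test(5, runif(12))
  tab$recall <- r
  a <- accuracy(tab)
  expect_equal(a$accuracy, mean(r) * 100, tolerance = 1e-12)
  expect_equal(a$recall_std, sqrt(mean((r - mean(r))^2)) * 100,
               tolerance = 1e-12)
  expect_equal(accuracy(tab, "sample")$recall_std, sd(r) * 100,
               tolerance = 1e-12)
})

test_that("evaluation is exact on separated input and chance on noise", {
  # perfectly separated clusters: accuracy 100, recall spread 0
  cl <- clustered_embedding(n_per = 10)
  rep1 <- evaluate_embedding(cl$embedding, cl$labels)
  expect_equal(rep1$accuracy, 100)
  expect_equal(rep1$recall_std, 0)
  expect_true(all(rep1$recall_table$recall == 1))

  # uninformative uniform embedding: accuracy at the 1/12 chance level
  n <- 12000L
  emb <- with_seed_test(33, matrix(runif(2 * n), ncol = 2))
  lab <- rep(1:12, each = n / 12L)
  rep2 <- evaluate_embedding(emb, lab)
  expect_lt(abs(rep2$accuracy - 100 / 12), 1.5)  # ~4 SE at this n

  # accuracy bounds hold for arbitrary inputs
  expect_gte(rep2$accuracy, 0)
  expect_lte(rep2$accuracy, 100)
})

test_that("similarity transforms leave the report invariant", {
  conf <- sample_conformations(energy_landscape(), 1000, seed = 13)
  emb <- cbind(conf$cc1, conf$cc2)
  base <- evaluate_embedding(emb, conf$well_label)

  th <- 0.7
  Rm <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  mapped <- 3.2 * emb %*% Rm + matrix(c(5, -2), 1000, 2, byrow = TRUE)
  same <- evaluate_embedding(mapped, conf$well_label)
  expect_equal(same$recall_table$recall, base$recall_table$recall)
  expect_equal(same$accuracy, base$accuracy)

  # anisotropic scaling can change nearest-center boundaries: the report
  # is NOT guaranteed invariant, only well-defined
  aniso <- emb %*% diag(c(30, 0.05))
  rep_a <- evaluate_embedding(aniso, conf$well_label)
  expect_gte(rep_a$accuracy, 0)
  expect_lte(rep_a$accuracy, 100)
})

test_that("occupancy maps are normalized histograms over the data range", {
  # all points in one bin
  emb <- matrix(rep(c(0.5, 0.5), each = 20), ncol = 2)
  emb <- rbind(emb, c(10, 10))   # stretch the range
  m <- occupancy_map(emb, 4L)
  expect_equal(sum(m$p), 1, tolerance = 1e-12)
  expect_equal(max(m$p), 20 / 21)
  expect_equal(sum(m$counts), 21)

  # uniform cloud: multinomial fluctuation bounds on every bin
  n <- 100000L
  u <- with_seed_test(77, matrix(runif(2 * n), ncol = 2))
  m10 <- occupancy_map(u, 10L)
  p0 <- 1 / 100
  se <- sqrt(p0 * (1 - p0) / n)
  expect_lt(max(abs(m10$p - p0)), 5 * se)

  expect_error(occupancy_map(matrix(rnorm(30), ncol = 3), 8L),
               "2-dimensional")
  expect_error(occupancy_map(matrix(runif(20), ncol = 2), 3L), "n_bins")
})

test_that("energy inversion is -kT log p with masking, floored at zero", {
  # uniform occupancy inverts to a flat zero surface
  grid_pts <- as.matrix(expand.grid(seq(0.05, 0.95, 0.1),
                                    seq(0.05, 0.95, 0.1)))
  m <- occupancy_map(grid_pts, 10L)
  es <- energy_from_occupancy(m)
  expect_equal(max(abs(es$E)), 0, tolerance = 1e-12)

  # two occupied bins at probability 2/3 and 1/3: energy gap kT ln 2
  emb2 <- rbind(matrix(rep(c(0.1, 0.5), each = 40), ncol = 2),
                matrix(rep(c(0.9, 0.5), each = 20), ncol = 2))
  m2 <- occupancy_map(emb2, 4L)
  es2 <- energy_from_occupancy(m2, kT = 1)
  vals <- sort(unique(es2$E[!is.na(es2$E)]))
  expect_equal(vals, c(0, log(2)), tolerance = 1e-12)
  # unvisited bins are masked, not extrapolated
  expect_true(any(is.na(es2$E)))

  expect_error(energy_from_occupancy(m2, floor_count = 99), "floor_count")
  expect_error(energy_from_occupancy(m2, kT = 1, floor_count = 0),
               "floor_count")
})

test_that("degrading an embedding with noise never helps accuracy", {
  conf <- sample_conformations(energy_landscape(), 2000, seed = 19)
  emb <- cbind(conf$cc1, conf$cc2)
  sigmas <- c(0, 0.25, 0.5, 1, 2)
  reps <- 20L
  acc <- matrix(NA_real_, reps, length(sigmas))
  for (r in seq_len(reps)) {
    for (j in seq_along(sigmas)) {
      noisy <- distort_embedding(emb, "noise", magnitude = sigmas[j],
                                 seed = 1000L * r + j)
      acc[r, j] <- evaluate_embedding(noisy, conf$well_label)$accuracy
    }
  }
  mu <- colMeans(acc)
  se <- apply(acc, 2, sd) / sqrt(reps)
  for (j in seq_len(length(sigmas) - 1)) {
    expect_lte(mu[j + 1], mu[j] + sqrt(se[j]^2 + se[j + 1]^2))
  }
})

test_that("lineage coloring is a fixed palette keyed by true label", {
  cl <- clustered_embedding(n_per = 8)
  lin <- lineage_map(cl$embedding, cl$labels)
  expect_identical(length(unique(lin$color)), 12L)
  expect_identical(lin$color_id, cl$labels)
  expect_identical(lin$color, lineage_palette()[cl$labels])

  # permuting particles permutes rows, same multiset
  perm <- with_seed_test(3, sample.int(nrow(lin)))
  lin_p <- lineage_map(cl$embedding[perm, ], cl$labels[perm])
  expect_identical(lin_p[order(lin_p$dim1, lin_p$dim2), ],
                   lin[order(lin$dim1, lin$dim2), ],
                   ignore_attr = TRUE)

  # well-separated clusters: every point in a well's Voronoi cell wears
  # that well's color (100% purity)
  pred <- assign_nearest_center(cl$embedding, cl$centers)
  expect_identical(lin$color, lineage_palette()[pred])

  png_path <- tempfile(fileext = ".png")
  lineage_map(cl$embedding, cl$labels, png_path = png_path)
  expect_true(file.exists(png_path) && file.size(png_path) > 0)
})
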