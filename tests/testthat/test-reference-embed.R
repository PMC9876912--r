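test_that("the oracle embedding is the ground-truth coordinates", {
  ls <- energy_landscape()
  ph <- small_phantom()
  st <- generate_dataset(ls, ph, 30, snr_target = 1, seed = 6)
  emb <- embed_oracle(st)
  expect_identical(nrow(emb), 30L)
  expect_identical(emb[, "dim1"], st$metadata$cc1)
  expect_identical(emb[, "dim2"], st$metadata$cc2)
})

test_that("oracle + evaluate is the fixed point on the default landscape", {
  conf <- sample_conformations(energy_landscape(), 5000, seed = 27)
  meta <- data.frame(cc1 = conf$cc1, cc2 = conf$cc2,
                     well_label = conf$well_label)
  report <- evaluate_embedding(embed_oracle(meta), meta$well_label)
  expect_equal(report$accuracy, 100)
  expect_equal(report$recall_std, 0)
})

test_that("PCA scores of a fixed-view sweep track the conformation", {
  ph <- small_phantom()
  n <- 60L
  cc1 <- seq(0, 1, length.out = n)
  imgs <- array(0, c(ph$box_size, ph$box_size, n))
  for (i in seq_len(n)) {
    imgs[, , i] <- project_particle(ph, c(cc1[i], 0.5), c(0, 0, 0))
  }
  stack <- structure(
    list(images = imgs, pixel_size = ph$voxel_size,
         metadata = data.frame(rot = 0, tilt = 0, psi = 0,
                               cc1 = cc1, cc2 = 0.5)),
    class = "particle_stack")
  sc <- embed_pca(stack, 2)
  expect_gt(abs(cor(sc[, 1], cc1, method = "spearman")), 0.99)

  # duplicated particle yields duplicated score rows
  dup <- stack
  dup$images <- imgs[, , c(seq_len(n), 1L)]
  dup$metadata <- rbind(stack$metadata, stack$metadata[1, ])
  sc_dup <- embed_pca(dup, 2)
  expect_equal(sc_dup[n + 1L, ], sc_dup[1L, ], tolerance = 1e-10)

  # mixed orientations are rejected, not silently embedded
  mixed <- stack
  mixed$metadata$tilt <- seq(0, 90, length.out = n)
  expect_error(embed_pca(mixed, 2), "fixed-orientation")
})

test_that("PCA matches a dense covariance eigendecomposition oracle", {
  ph <- small_phantom()
  n <- 50L
  cc <- with_seed_test(14, cbind(runif(n), runif(n)))
  imgs <- array(0, c(ph$box_size, ph$box_size, n))
  for (i in seq_len(n)) {
    imgs[, , i] <- project_particle(ph, cc[i, ], c(0, 0, 0))
  }
  stack <- structure(
    list(images = imgs, pixel_size = ph$voxel_size,
         metadata = data.frame(rot = 0, tilt = 0, psi = 0,
                               cc1 = cc[, 1], cc2 = cc[, 2])),
    class = "particle_stack")
  sc <- embed_pca(stack, 2)

  X <- t(matrix(imgs, ph$box_size^2, n))
  X <- sweep(X, 2, colMeans(X))
  eC <- eigen(crossprod(X), symmetric = TRUE)
  oracle <- X %*% eC$vectors[, 1:2]
  for (k in 1:2) {
    v <- eC$vectors[, k]
    if (v[which.max(abs(v))] < 0) oracle[, k] <- -oracle[, k]
  }
  expect_lt(max(abs(sc - oracle)), 1e-8)
})

test_that("distortions behave as specified and are seeded", {
  cl <- clustered_embedding(n_per = 20)
  emb <- cl$embedding

  expect_identical(distort_embedding(emb, "identity"), emb)
  expect_identical(distort_embedding(emb, "noise", magnitude = 0), emb)
  expect_identical(distort_embedding(emb, "affine", magnitude = 0), emb)
  expect_identical(distort_embedding(emb, "noise", 0.5, seed = 4),
                   distort_embedding(emb, "noise", 0.5, seed = 4))
  expect_error(distort_embedding(emb, "warp"), "arg")

  # collapse keeps only the first dimension
  col <- distort_embedding(emb, "collapse")
  expect_identical(ncol(col), 1L)
  expect_identical(col[, 1], emb[, 1])

  # affine keeps rows aligned (no permutation), shuffle does not
  aff <- distort_embedding(emb, "affine", magnitude = 1, seed = 2)
  expect_identical(dim(aff), dim(emb))
  shf <- distort_embedding(emb, "shuffle", seed = 2)
  expect_false(identical(shf, emb))
  expect_equal(shf[order(shf[, 1], shf[, 2]), ],
               emb[order(emb[, 1], emb[, 2]), ], ignore_attr = TRUE)
})

test_that("shuffled embeddings score at the 1/12 chance level", {
  n_per <- 1000L
  cl <- clustered_embedding(n_per = n_per)
  shf <- distort_embedding(cl$embedding, "shuffle", seed = 8)
  rep <- evaluate_embedding(shf, cl$labels)
  # 4 SE of the balanced accuracy under random assignment
  se <- 100 * sqrt((1 / 12) * (11 / 12) / n_per) / sqrt(12)
  expect_lt(abs(rep$accuracy - 100 / 12), 4 * se)
})

test_that("discarding the second coordinate costs the predicted accuracy", {
  ls <- energy_landscape()
  conf <- sample_conformations(ls, 6000, seed = 35)
  emb <- cbind(conf$cc1, conf$cc2)
  full <- evaluate_embedding(emb, conf$well_label)
  col <- evaluate_embedding(distort_embedding(emb, "collapse"),
                            conf$well_label)
  expect_lt(col$accuracy, full$accuracy)

  # Voronoi oracle for the expected collapsed accuracy: each class is a
  # Gaussian on cc1 around its column; its recall is the mass of that
  # Gaussian falling in the 1-D Voronoi interval of the class mean.
  centers1 <- as.numeric(well_centers(
    distort_embedding(emb, "collapse"), conf$well_label))
  ord <- order(centers1)
  bounds <- c(-Inf, (centers1[ord][-12] + centers1[ord][-1]) / 2, Inf)
  expected_recall <- numeric(12)
  for (k in 1:12) {
    pos <- which(ord == k)
    mu <- ls$wells$cc1[k]
    sdev <- ls$wells$width[k]
    expected_recall[k] <- pnorm(bounds[pos + 1], mu, sdev) -
      pnorm(bounds[pos], mu, sdev)
  }
  expect_lt(abs(col$accuracy - 100 * mean(expected_recall)), 4)
})
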