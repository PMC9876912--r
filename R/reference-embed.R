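#' Oracle embedding: ground-truth conformational coordinates
#'
#' Returns the ground-truth `(cc1, cc2)` of every particle as the
#' embedding — the output an ideal heterogeneity method would produce.
#' Evaluating it closes the loop: on a well-separated landscape it scores
#' 100 % balanced accuracy by construction.
#'
#' @param metadata a `particle_stack` metadata data frame (or the stack
#'   itself) with `cc1` and `cc2` columns.
#' @return n x 2 matrix with columns `dim1`, `dim2`.
#' @export
embed_oracle <- function(metadata) {
  if (inherits(metadata, "particle_stack")) metadata <- metadata$metadata
  if (!all(c("cc1", "cc2") %in% names(metadata)))
    stop("metadata must carry cc1 and cc2 columns")
  out <- cbind(dim1 = metadata$cc1, dim2 = metadata$cc2)
  rownames(out) <- NULL
  out
}

#' PCA embedding of a fixed-orientation image stack
#'
#' Mean-centers the flattened images and returns the scores on the top
#' principal axes. Restricted to stacks in which every particle shares one
#' orientation: on mixed views, image-space PCA conflates pose with
#' conformation — disentangling the two is exactly the problem the
#' benchmarked heterogeneity methods exist to solve, so the restriction is
#' enforced rather than silently producing a meaningless embedding. The
#' sign of each component is fixed by making its largest-magnitude loading
#' positive.
#'
#' @param stack a [generate_dataset()] `particle_stack`.
#' @param n_components number of components (default 2; <= n).
#' @return n x n_components score matrix.
#' @export
embed_pca <- function(stack, n_components = 2L) {
  stopifnot(inherits(stack, "particle_stack"))
  eul <- as.matrix(stack$metadata[, c("rot", "tilt", "psi")])
  if (max(apply(eul, 2, function(v) diff(range(v)))) > 1e-9)
    stop("embed_pca requires a fixed-orientation stack: ",
         "PCA on mixed views conflates pose and conformation")
  d <- dim(stack$images)
  n <- d[3]
  if (n < n_components) stop("need at least n_components particles")
  X <- t(matrix(stack$images, d[1] * d[2], n))   # n x pixels
  X <- sweep(X, 2, colMeans(X))
  sv <- svd(X, nu = n_components, nv = n_components)
  scores <- sv$u %*% diag(sv$d[seq_len(n_components)], n_components)
  for (k in seq_len(n_components)) {
    load_k <- sv$v[, k]
    if (load_k[which.max(abs(load_k))] < 0) scores[, k] <- -scores[, k]
  }
  colnames(scores) <- paste0("dim", seq_len(n_components))
  scores
}

#' Apply a controlled distortion to an embedding
#'
#' Mimics the failure modes of real heterogeneity methods with five
#' distortion kinds: `identity` (copy), `noise` (adds i.i.d. Gaussian
#' noise with per-dimension sd `magnitude` times that dimension's data
#' sd), `affine` (random rotation followed by anisotropic axis scaling
#' with condition number `1 + magnitude`), `shuffle` (permutes rows,
#' destroying all label information), and `collapse` (keeps only the
#' first dimension, discarding the rest). Deterministic per seed.
#'
#' @param embedding n x d numeric matrix.
#' @param kind one of `"identity"`, `"noise"`, `"affine"`, `"shuffle"`,
#'   `"collapse"`.
#' @param magnitude distortion strength (>= 0; 0 leaves noise/affine
#'   untouched).
#' @param seed integer RNG seed.
#' @return distorted embedding matrix.
#' @export
distort_embedding <- function(embedding,
                              kind = c("identity", "noise", "affine",
                                       "shuffle", "collapse"),
                              magnitude = 0, seed = 1L) {
  kind <- match.arg(kind)
  embedding <- as_embedding(embedding)
  if (magnitude < 0) stop("magnitude must be non-negative")
  d <- ncol(embedding)
  switch(kind,
    identity = embedding,
    noise = {
      if (magnitude == 0) return(embedding)
      sds <- apply(embedding, 2, stats::sd) * magnitude
      embedding + with_seed(seed, {
        matrix(stats::rnorm(length(embedding)), nrow(embedding), d) %*%
          diag(sds, d)
      })
    },
    affine = {
      if (magnitude == 0) return(embedding)
      with_seed(seed, {
        Q <- qr.Q(qr(matrix(stats::rnorm(d * d), d, d)))
        scales <- seq(1, 1 + magnitude, length.out = d)
        embedding %*% Q %*% diag(scales, d)
      })
    },
    shuffle = {
      perm <- with_seed(seed, sample.int(nrow(embedding)))
      embedding[perm, , drop = FALSE]
    },
    collapse = embedding[, 1, drop = FALSE]
  )
}
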