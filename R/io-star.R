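# Relion-dialect STAR metadata I/O. Column names use the _rln namespace
# for orientations so ground truth can feed external cryo-EM tools
# directly; package-specific ground-truth columns are namespaced _elb.

star_columns <- c(
  index = "_rlnImageName", rot = "_rlnAngleRot", tilt = "_rlnAngleTilt",
  psi = "_rlnAnglePsi", cc1 = "_elbCc1", cc2 = "_elbCc2",
  well_label = "_elbWellLabel")

#' Write particle metadata as a Relion-dialect STAR file
#'
#' Emits a `data_particles` loop with `_rlnImageName`, `_rlnAngleRot`,
#' `_rlnAngleTilt`, `_rlnAnglePsi` and the ground-truth columns `_elbCc1`,
#' `_elbCc2`, `_elbWellLabel`. Image names are `NNNNNN@<image_file>`
#' (1-based slice). Floats use fixed 6-decimal formatting so identical
#' metadata yields byte-identical files.
#'
#' @param metadata `particle_stack` metadata data frame (or the stack).
#' @param path output `.star` path.
#' @param image_file stack filename referenced in `_rlnImageName`.
#' @return `path`, invisibly.
#' @export
write_star <- function(metadata, path, image_file = "particles.mrcs") {
  if (inherits(metadata, "particle_stack")) metadata <- metadata$metadata
  need <- setdiff(names(star_columns), "index")
  miss <- setdiff(need, names(metadata))
  if (length(miss) > 0)
    stop("metadata lacks column(s): ", paste(miss, collapse = ", "))
  n <- nrow(metadata)
  idx <- if ("index" %in% names(metadata)) metadata$index else seq_len(n) - 1L
  rows <- sprintf(
    "%06d@%s %12.6f %12.6f %12.6f %12.6f %12.6f %d",
    idx + 1L, image_file, metadata$rot, metadata$tilt, metadata$psi,
    metadata$cc1, metadata$cc2, as.integer(metadata$well_label))
  header <- c("", "data_particles", "", "loop_",
              sprintf("%s #%d", unname(star_columns),
                      seq_along(star_columns)))
  writeLines(c(header, rows, ""), path)
  invisible(path)
}

#' Read a Relion-dialect STAR metadata file
#'
#' Parses the first loop block and returns the particle table. Errors
#' name any required column that is absent.
#'
#' @param path `.star` file path.
#' @return data frame with columns `index` (0-based), `rot`, `tilt`,
#'   `psi`, `cc1`, `cc2`, `well_label`, `image_file`.
#' @export
read_star <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  loop_at <- which(lines == "loop_")
  if (length(loop_at) == 0) stop("malformed STAR file: no loop_ block")
  i <- loop_at[1] + 1L
  cols <- character(0)
  while (i <= length(lines) && startsWith(lines[i], "_")) {
    cols <- c(cols, sub("\\s+#\\d+$", "", lines[i]))
    i <- i + 1L
  }
  miss <- setdiff(unname(star_columns), cols)
  if (length(miss) > 0)
    stop("STAR file lacks required column(s): ", paste(miss, collapse = ", "))
  body <- lines[i:length(lines)]
  body <- body[nzchar(body) & !startsWith(body, "#")]
  if (length(body) == 0) stop("STAR loop block has no data rows")
  fields <- strsplit(body, "\\s+")
  if (any(lengths(fields) != length(cols)))
    stop("STAR data row has wrong number of fields")
  tab <- as.data.frame(do.call(rbind, fields), stringsAsFactors = FALSE)
  names(tab) <- cols
  img <- tab[[star_columns[["index"]]]]
  out <- data.frame(
    index = as.integer(sub("@.*$", "", img)) - 1L,
    rot = as.numeric(tab[[star_columns[["rot"]]]]),
    tilt = as.numeric(tab[[star_columns[["tilt"]]]]),
    psi = as.numeric(tab[[star_columns[["psi"]]]]),
    cc1 = as.numeric(tab[[star_columns[["cc1"]]]]),
    cc2 = as.numeric(tab[[star_columns[["cc2"]]]]),
    well_label = as.integer(tab[[star_columns[["well_label"]]]]),
    image_file = sub("^[0-9]+@", "", img))
  if (any(!is.finite(out$rot) | !is.finite(out$tilt) | !is.finite(out$psi)))
    stop("STAR file contains non-numeric angles")
  out
}

#' Write the CSV mirror of particle metadata
#'
#' Plain CSV with the same columns as the STAR file, for consumers outside
#' the cryo-EM ecosystem. Fixed float formatting keeps the writer
#' deterministic.
#'
#' @inheritParams write_star
#' @return `path`, invisibly.
#' @export
write_meta_csv <- function(metadata, path) {
  if (inherits(metadata, "particle_stack")) metadata <- metadata$metadata
  cols <- intersect(c("index", "rot", "tilt", "psi", "cc1", "cc2",
                      "well_label"), names(metadata))
  m <- metadata[, cols, drop = FALSE]
  for (nm in intersect(cols, c("rot", "tilt", "psi", "cc1", "cc2")))
    m[[nm]] <- sprintf("%.6f", m[[nm]])
  utils::write.csv(m, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an embedding table from CSV
#'
#' Accepts the `index, dim1..dimd` convention (an `index` column is
#' carried through as row alignment; `dim*` columns become the embedding).
#'
#' @param path CSV path.
#' @return n x d embedding matrix ordered by `index` when present.
#' @export
read_embedding_csv <- function(path) {
  tab <- utils::read.csv(path)
  dims <- grep("^dim[0-9]+$", names(tab), value = TRUE)
  if (length(dims) == 0) stop("embedding CSV has no dim1..dimd columns")
  if ("index" %in% names(tab)) tab <- tab[order(tab$index), , drop = FALSE]
  as_embedding(tab[, dims, drop = FALSE])
}

#' Write an embedding table to CSV
#'
#' @param embedding n x d matrix.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_embedding_csv <- function(embedding, path) {
  embedding <- as_embedding(embedding)
  tab <- data.frame(index = seq_len(nrow(embedding)) - 1L)
  for (k in seq_len(ncol(embedding)))
    tab[[paste0("dim", k)]] <- sprintf("%.10g", embedding[, k])
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
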