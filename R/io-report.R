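#' Write a benchmark report as JSON
#'
#' Serializes per-well `P`, `TP` and `recall` together with balanced
#' accuracy and recall standard deviation (both in percent) so reports
#' round-trip exactly.
#'
#' @param report a [evaluate_embedding()] `benchmark_report`.
#' @param path output `.json` path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "benchmark_report"))
  obj <- list(
    n = report$n, n_wells = report$n_wells,
    sd_convention = report$sd_convention,
    accuracy = report$accuracy, recall_std = report$recall_std,
    wells = lapply(seq_len(nrow(report$recall_table)), function(i) {
      r <- report$recall_table[i, ]
      list(well = r$well, P = r$P, TP = r$TP, recall = r$recall)
    }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a benchmark report from JSON
#'
#' Validates the schema and the metric invariants (`0 <= TP <= P`,
#' recalls in `[0, 1]`, accuracy in `[0, 100]`) before reconstructing the
#' `benchmark_report`.
#'
#' @param path `.json` path written by [write_report()].
#' @return a `benchmark_report`.
#' @export
read_report <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  need <- c("n", "n_wells", "sd_convention", "accuracy", "recall_std",
            "wells")
  miss <- setdiff(need, names(obj))
  if (length(miss) > 0)
    stop("report lacks field(s): ", paste(miss, collapse = ", "))
  tab <- do.call(rbind, lapply(obj$wells, function(w) {
    data.frame(well = as.integer(w$well), P = as.integer(w$P),
               TP = as.integer(w$TP), recall = as.numeric(w$recall))
  }))
  if (any(tab$TP < 0 | tab$TP > tab$P))
    stop("invalid report: TP outside [0, P]")
  if (any(tab$recall < 0 | tab$recall > 1))
    stop("invalid report: recall outside [0, 1]")
  acc <- as.numeric(obj$accuracy)
  if (acc < 0 || acc > 100)
    stop("invalid report: accuracy outside [0, 100] %")
  class(tab) <- c("recall_table", "data.frame")
  structure(list(recall_table = tab, accuracy = acc,
                 recall_std = as.numeric(obj$recall_std),
                 n = as.integer(obj$n), n_wells = as.integer(obj$n_wells),
                 sd_convention = obj$sd_convention),
            class = "benchmark_report")
}

#' Write an occupancy lattice as CSV
#'
#' Long-format CSV with columns `cc1`, `cc2`, `p`, `E` — one row per
#' lattice cell of an [occupancy_density()] grid (or per bin of an
#' [occupancy_map()] plus matching [energy_from_occupancy()] surface).
#'
#' @param grid an `occupancy_grid`.
#' @param path output `.csv` path.
#' @return `path`, invisibly.
#' @export
write_occupancy_csv <- function(grid, path) {
  stopifnot(inherits(grid, "occupancy_grid"))
  g <- expand.grid(cc1 = grid$cc1, cc2 = grid$cc2)
  tab <- data.frame(cc1 = sprintf("%.10g", g$cc1),
                    cc2 = sprintf("%.10g", g$cc2),
                    p = sprintf("%.10g", as.numeric(grid$p)),
                    E = sprintf("%.10g", as.numeric(grid$E)))
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
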