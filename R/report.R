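# Run statistics and the benchmark-style result table
# (columns: loop, interval, rmsd, sol, tsecs, max_err).

#' Summarize a solve as a stats record
#'
#' @param sols a `bp_solutions` object.
#' @param loop label for the loop (e.g. `"synth6-s3(1,3,5)"`).
#' @param interval the discretization interval `c(lo, hi)` used.
#' @return list of scalar statistics (class `bp_stats`).
#' @export
solution_stats <- function(sols, loop = "loop", interval = c(NA, NA)) {
  stopifnot(inherits(sols, "bp_solutions"))
  n <- length(sols$solutions)
  structure(list(
    loop = loop,
    interval_lo = unname(interval[1L]),
    interval_hi = unname(interval[2L]),
    kind = sols$kind,
    delta = sols$delta,
    K = sols$K,
    sol = n,
    rmsd_min = if (n && !all(is.na(sols$rmsd))) min(sols$rmsd) else NA_real_,
    rmsd_mean = if (n && !all(is.na(sols$rmsd))) mean(sols$rmsd) else NA_real_,
    rmsd_max = if (n && !all(is.na(sols$rmsd))) max(sols$rmsd) else NA_real_,
    max_err = if (n) max(sols$max_err) else NA_real_,
    nodes = sols$nodes,
    pruned = sols$pruned,
    tsecs = sols$wall_time
  ), class = "bp_stats")
}

#' Write a stats record to JSON
#'
#' @param stats a `bp_stats` record (or plain named list).
#' @param path output path.
#' @export
write_stats <- function(stats, path) {
  jsonlite::write_json(unclass(stats), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Tabulate stats records in the benchmark column layout
#'
#' @param stats list of `bp_stats` records, or character vector of JSON
#'   paths written by [write_stats()].
#' @param path optional TSV output path.
#' @return data.frame with columns `loop`, `interval`, `rmsd`, `sol`,
#'   `tsecs`, `max_err`.
#' @export
report_table <- function(stats, path = NULL) {
  if (is.character(stats))
    stats <- lapply(stats, function(p) jsonlite::read_json(p))
  rows <- lapply(stats, function(s) data.frame(
    loop = s$loop,
    interval = if (is.null(s$interval_lo) || is.na(s$interval_lo)) "" else
      sprintf("[%.2f, %.2f]", s$interval_lo, s$interval_hi),
    rmsd = if (is.null(s$rmsd_min) || is.na(s$rmsd_min)) NA_real_ else
      round(s$rmsd_min, 2L),
    sol = s$sol,
    tsecs = round(s$tsecs, 2L),
    max_err = if (is.null(s$max_err) || is.na(s$max_err)) NA_real_ else
      round(s$max_err, 2L)))
  out <- do.call(rbind, rows)
  if (!is.null(path))
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  out
}
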