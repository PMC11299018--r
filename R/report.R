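# Rendering of summary tables and run manifests.

.fmt <- function(x, digits) {
  ifelse(is.na(x), "", formatC(x, format = "f", digits = digits))
}

#' Render summary rows as a fixed-width text table
#'
#' One row per adjustment set; per-method column blocks with the mean
#' estimate (3 decimals), empirical SE (4 decimals), and relative SE
#' (3 decimals, `referent` for self-referent rows).  The scenario column
#' is suppressed when all rows belong to a single scenario.
#'
#' @param rows summary data.frame from [summarize_estimates()].
#' @return character vector of table lines.
#' @export
render_summary <- function(rows) {
  stopifnot(is.data.frame(rows), nrow(rows) > 0)
  methods <- unique(rows$method)
  scenarios <- unique(rows$scenario)
  one_scenario <- length(scenarios) == 1L
  key <- unique(rows[, c("scenario", "adj_set")])

  tab <- data.frame(adj_set = key$adj_set, stringsAsFactors = FALSE)
  if (!one_scenario) tab <- cbind(scenario = key$scenario, tab)
  for (m in methods) {
    sub <- rows[rows$method == m, ]
    idx <- match(paste(key$scenario, key$adj_set),
                 paste(sub$scenario, sub$adj_set))
    rel <- .fmt(sub$relative_se[idx], 3)
    rel[is.na(sub$relative_se[idx])] <- "referent"
    block <- data.frame(.fmt(sub$mean_estimate[idx], 3),
                        .fmt(sub$empirical_se[idx], 4),
                        rel, stringsAsFactors = FALSE)
    names(block) <- paste0(m, c("_mean", "_se", "_rel_se"))
    tab <- cbind(tab, block)
  }
  widths <- pmax(nchar(names(tab)),
                 apply(tab, 2, function(col) max(nchar(col))))
  pad <- function(v, w) formatC(v, width = w, flag = "-")
  header <- paste(mapply(pad, names(tab), widths), collapse = "  ")
  lines <- apply(tab, 1, function(r)
    paste(mapply(pad, r, widths), collapse = "  "))
  c(header, paste(rep("-", nchar(header)), collapse = ""), lines)
}

#' Write a run manifest
#'
#' Flat key/value text file recording everything needed to reproduce a
#' run exactly: package version, master seed, scenario names, replicate
#' count, timestamp, and the diagnostic counters (clipped outcome
#' probabilities, clipped sampling probabilities, dropped design columns).
#'
#' @param path output file.
#' @param master_seed integer master seed of the run.
#' @param scenarios character vector of scenario names.
#' @param n_replicates replicate count.
#' @param diagnostics named list of counters, as attached to the records
#'   returned by [run_scenario()].
#' @export
write_manifest <- function(path, master_seed, scenarios, n_replicates,
                           diagnostics = list()) {
  lines <- c(
    paste0("tool_version: transportsim ",
           as.character(packageVersion("transportsim"))),
    paste0("master_seed: ", master_seed),
    paste0("scenarios: ", paste(scenarios, collapse = ", ")),
    paste0("n_replicates: ", n_replicates),
    paste0("timestamp: ", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")))
  for (nm in names(diagnostics))
    lines <- c(lines, paste0(nm, ": ", diagnostics[[nm]]))
  writeLines(lines, path)
  invisible(path)
}

#' Write estimate records and summary rows as CSV
#'
#' `estimates.csv` columns: scenario, method, adj_set, replicate,
#' estimate, status.  `summary.csv` columns: the summary-row layout of
#' [summarize_estimates()].
#'
#' @param records estimate records.
#' @param rows summary rows.
#' @param dir output directory (created if absent).
#' @return invisibly, the two file paths.
#' @export
write_run_csv <- function(records, rows, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  est_path <- file.path(dir, "estimates.csv")
  sum_path <- file.path(dir, "summary.csv")
  write.csv(records[, c("scenario", "method", "adj_set", "replicate",
                        "estimate", "status")],
            est_path, row.names = FALSE)
  write.csv(rows, sum_path, row.names = FALSE)
  invisible(c(estimates = est_path, summary = sum_path))
}
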