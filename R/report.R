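#' Write an adhesion analysis report
#'
#' Emits a JSON report (PR, DWI, t*, per-phase totals, classification,
#' study maximum, configuration echo) and a CSV companion with the
#' per-phase table. Numeric CSV fields are written at fixed precision so
#' identical analyses produce byte-identical files.
#'
#' @param scan an [adhesion_scan()] (or [adhesion_metrics()]) result.
#' @param path output path for the JSON report; the CSV is written next to
#'   it with extension `.csv`.
#' @return Invisibly, the two written paths.
#' @export
write_report <- function(scan, path) {
  json_path <- if (grepl("\\.json$", path)) path else paste0(path, ".json")
  csv_path <- sub("\\.json$", ".csv", json_path)
  is_scan <- inherits(scan, "adhesion_scan")
  rep <- list(
    pr = scan$pr,
    dwi = scan$dwi,
    classification = scan$classification,
    t_star_percent = if (is_scan) scan$t_star_percent else NULL,
    d_max_mm = if (is_scan) scan$d_max else NULL,
    m_t = if (is_scan) as.numeric(sprintf("%.6f", scan$m_t)) else NULL,
    phase_percents = if (is_scan) seq(10L, 90L, 10L) else NULL,
    n_roi = if (is_scan) scan$n_roi else NULL,
    histogram = list(n_bins = scan$histogram$n_total,
                     h_max = scan$histogram$h_max,
                     h_alpha = scan$histogram$h_alpha,
                     n_nonzero = scan$histogram$n_nonzero,
                     n_samples = scan$histogram$n_samples),
    config = unclass(scan$config))
  rep <- rep[!vapply(rep, is.null, logical(1))]
  jsonlite::write_json(rep, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  if (is_scan) {
    df <- data.frame(phase_percent = seq(10L, 90L, 10L),
                     m_t = sprintf("%.6f", scan$m_t),
                     n_roi = scan$n_roi,
                     is_t_star = seq_len(9) == scan$t_star)
  } else {
    df <- data.frame(pr = sprintf("%.6f", scan$pr),
                     dwi = sprintf("%.6f", scan$dwi),
                     classification = scan$classification)
  }
  write.csv(df, csv_path, row.names = FALSE)
  invisible(c(json = json_path, csv = csv_path))
}

#' Read a JSON report back
#' @param path the JSON path written by [write_report()].
#' @return Named list of report fields.
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
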