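#' Write a cost-effectiveness result table
#'
#' Formats a [cea_frontier()] table the way published incremental tables
#' are printed: whole-yen money, three-decimal QALYs, columns
#' `Intervention`, `Cost`, `Incremental cost`, `QALYs`,
#' `Incremental QALYs`, `ICER`. Internal arithmetic stays at full
#' precision; rounding happens only here.
#'
#' @param frontier_tb Output of [cea_frontier()].
#' @param path Output path (tab-separated).
#' @return Invisibly, the formatted data frame that was written.
#' @export
write_cea_table <- function(frontier_tb, path) {
  fmt <- data.frame(
    Intervention = gsub("_", "-", frontier_tb$strategy),
    Cost = round(frontier_tb$cost),
    `Incremental cost` = round(frontier_tb$incr_cost),
    QALYs = sprintf("%.3f", frontier_tb$qaly),
    `Incremental QALYs` = sprintf("%.3f", frontier_tb$incr_qaly),
    ICER = round(frontier_tb$icer),
    Status = frontier_tb$status,
    check.names = FALSE)
  write.table(fmt, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(fmt)
}

#' Write any result tibble as a delimited file
#'
#' Money columns (names starting with `cost`, `icer` or `incr_cost`) are
#' rounded to whole yen; QALY columns to three decimals.
#'
#' @param tb A data frame.
#' @param path Output path (tab-separated).
#' @return Invisibly, `path`.
#' @export
write_result_table <- function(tb, path) {
  tb <- as.data.frame(tb)
  tb <- tb[, !vapply(tb, is.list, TRUE), drop = FALSE]
  for (nm in names(tb)) {
    if (grepl("^(cost|icer|incr_cost)", nm) && is.numeric(tb[[nm]])) {
      tb[[nm]] <- round(tb[[nm]])
    } else if (grepl("qaly", nm) && is.numeric(tb[[nm]])) {
      tb[[nm]] <- round(tb[[nm]], 3)
    }
  }
  write.table(tb, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Write a machine-readable run manifest
#'
#' Records everything needed to reproduce a run bit-for-bit: the full
#' configuration, the package version, the MD5 checksum of the parameter
#' file in use, and any counters the caller passes (clamped probabilities,
#' PSA resamples, fallback distributions).
#'
#' @param config A [sim_config()].
#' @param path Output JSON path.
#' @param parameter_file Optional path of the parameter file to checksum.
#' @param extra Optional named list of additional fields.
#' @return Invisibly, the manifest list.
#' @export
write_run_manifest <- function(config, path, parameter_file = NULL, extra = list()) {
  manifest <- c(
    list(package = "hipcea",
         version = as.character(utils::packageVersion("hipcea")),
         config = unclass(config)),
    if (!is.null(parameter_file)) {
      list(parameter_file = basename(parameter_file),
           parameter_md5 = unname(tools::md5sum(parameter_file)))
    },
    extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(manifest)
}
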