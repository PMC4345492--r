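# Plain-text file formats: two-column delimited time series with
# '#'-prefixed header lines carrying units, plus JSON reports/manifests.

#' Write / read a force trace as delimited text
#'
#' Tab-separated `time_s`, `force_N` with `#` header lines naming units;
#' round-trips losslessly at full double precision.
#'
#' @param trace A [force_trace].
#' @param path File path.
#' @return `write_force_trace` returns `path` invisibly; `read_force_trace`
#'   returns a [force_trace].
#' @export
write_force_trace <- function(trace, path) {
  assert_that(inherits(trace, "force_trace"), "`trace` must be a force_trace")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# afplatform force trace", "# columns: time_s\tforce_N"), con)
  utils::write.table(data.frame(time_s = sprintf("%.17g", trace$time),
                                force_N = sprintf("%.17g", trace$force)),
                     con, sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_force_trace
#' @export
read_force_trace <- function(path) {
  d <- utils::read.table(path, comment.char = "#", sep = "\t",
                         col.names = c("time", "force"))
  force_trace(d$time, d$force)
}

#' Write / read a stroke segmentation as delimited text
#'
#' Tab-separated `start_s`, `end_s`, `phase` plus flight bounds in the
#' header.
#'
#' @param seg A [stroke_segmentation].
#' @param path File path.
#' @return `write_segmentation` returns `path` invisibly;
#'   `read_segmentation` returns a [stroke_segmentation].
#' @export
write_segmentation <- function(seg, path) {
  assert_that(inherits(seg, "stroke_segmentation"), "`seg` must be a stroke_segmentation")
  fb <- attr(seg, "flight_bounds")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# afplatform stroke segmentation",
               sprintf("# flight_bounds_s: %.17g\t%.17g", fb[1], fb[2]),
               "# columns: start_s\tend_s\tphase"), con)
  utils::write.table(data.frame(start_s = sprintf("%.17g", seg$start),
                                end_s = sprintf("%.17g", seg$end),
                                phase = seg$phase),
                     con, sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_segmentation
#' @export
read_segmentation <- function(path) {
  hdr <- grep("^#", readLines(path, n = 10L), value = TRUE)
  fb <- NULL
  bl <- grep("flight_bounds_s:", hdr, value = TRUE)
  if (length(bl))
    fb <- as.numeric(strsplit(sub(".*flight_bounds_s:\\s*", "", bl[1]), "\t")[[1]])
  d <- utils::read.table(path, comment.char = "#", sep = "\t",
                         col.names = c("start", "end", "phase"))
  stroke_segmentation(d$start, d$end, d$phase, flight_bounds = fb)
}

#' Write validation metrics or a summary as JSON
#'
#' @param x A `validation_metrics`, `validation_report`, or any list-like
#'   result.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_metrics_json <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

# reproduction manifest: config, seed, package version
write_manifest <- function(config, path) {
  manifest <- list(
    package = "afplatform",
    version = as.character(utils::packageVersion("afplatform")),
    seed = config$seed,
    config = utils::capture.output(utils::str(unclass(config), max.level = 2)))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
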