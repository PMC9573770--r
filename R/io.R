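# CSV readers and writers of the pipeline's fixed dialects (UTF-8, comma
# separator, header row, period decimal; retention times in minutes;
# transitions labelled by nominal neutral-loss mass).

.metadataLines <- function(seed = NULL, config = NULL) {
  ver <- as.character(utils::packageVersion("ohpcb"))
  lines <- paste0("# ohpcb ", ver)
  if (!is.null(seed)) lines <- c(lines, paste0("# seed: ", seed))
  if (!is.null(config))
    lines <- c(lines, paste0("# config: ", configHash(config)))
  lines
}

#' Hash a configuration object
#'
#' Stable MD5 of the deparsed configuration, embedded in every report so
#' reruns are attributable to an exact configuration.
#'
#' @param config any R object.
#' @return character MD5 digest.
#' @export
configHash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(config), f)
  unname(tools::md5sum(f))
}

#' Write a report CSV with embedded metadata
#'
#' @param df data.frame to write.
#' @param file output path.
#' @param seed seed to record.
#' @param config configuration object to hash into the header.
#' @export
writeReportCsv <- function(df, file, seed = NULL, config = NULL) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(.metadataLines(seed, config), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(file)
}

.readCsv <- function(file, required, what) {
  if (!file.exists(file)) stop(what, " file not found: ", file)
  df <- tryCatch(
    utils::read.csv(file, comment.char = "#", stringsAsFactors = FALSE),
    error = function(e) stop("malformed CSV '", file, "': ",
                             conditionMessage(e)))
  missing <- setdiff(required, colnames(df))
  if (length(missing))
    stop("malformed ", what, " CSV '", file, "': missing column(s) ",
         paste(missing, collapse = ", "))
  df
}

#' Read a measured standards table
#'
#' Expected columns: \code{name}, \code{smiles}, \code{rt_min},
#' \code{rrf_loss15} .. \code{rrf_loss66}, \code{concentration},
#' \code{solution_id}.
#'
#' @param file CSV path.
#' @return data.frame.
#' @export
readStandardsCsv <- function(file) {
  .readCsv(file, c("name", "smiles", "rt_min",
                   paste0("rrf_loss", NEUTRAL_LOSSES), "concentration",
                   "solution_id"),
           "standards")
}

#' Read an unknown-peak table
#'
#' Expected columns: \code{peak_id}, \code{rt_min},
#' \code{area_loss15} .. \code{area_loss66}, \code{precursor_mz};
#' an \code{rrt} column is computed from the reference internal standard
#' when absent.
#'
#' @param file CSV path.
#' @param reference optional \code{\link{internalStandard}} used to derive
#'   RRT from \code{rt_min}.
#' @return data.frame.
#' @export
readPeakTable <- function(file, reference = NULL) {
  df <- .readCsv(file, c("peak_id", "rt_min",
                         paste0("area_loss", NEUTRAL_LOSSES),
                         "precursor_mz"),
                 "peak-table")
  if (is.null(df$rrt)) {
    if (is.null(reference))
      stop("peak table lacks an 'rrt' column and no reference internal ",
           "standard was given")
    df$rrt <- computeRrt(df$rt_min, reference)
  }
  df
}
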