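#' SubjectTimeSeries: one subject's regional time courses
#'
#' The universal currency of the pipeline: a timepoints x regions matrix of
#' BOLD-like signals (component time courses), with the repetition time (TR),
#' region labels aligned to a [ModuleAtlas-class], a subject id and the
#' anesthetic dose (% isoflurane) the scan was acquired under.
#'
#' @slot values numeric T x R matrix, column names are region labels.
#' @slot tr repetition time in seconds.
#' @slot subject subject identifier.
#' @slot dose anesthetic dose in percent (NA when not applicable).
#' @slot group free-text group tag (e.g. design arm).
#'
#' @aliases seriesMatrix repetitionTime subjectId dose
#' @export
setClass("SubjectTimeSeries",
  representation(values = "matrix", tr = "numeric", subject = "character",
                 dose = "numeric", group = "character"))

setValidity("SubjectTimeSeries", function(object) {
  msg <- NULL
  v <- object@values
  if (!is.numeric(v)) msg <- c(msg, "values must be numeric")
  if (anyNA(v)) msg <- c(msg, "values must not contain missing entries")
  if (nrow(v) < 2L) msg <- c(msg, "need at least 2 timepoints")
  if (is.null(colnames(v)) || anyDuplicated(colnames(v)))
    msg <- c(msg, "columns must carry unique region labels")
  if (length(object@tr) != 1L || object@tr <= 0) msg <- c(msg, "tr must be a positive scalar")
  if (is.null(msg)) TRUE else msg
})

#' Construct a SubjectTimeSeries
#'
#' @param values T x R numeric matrix with region-label column names.
#' @param tr repetition time in seconds.
#' @param subject subject id.
#' @param dose anesthetic dose (percent).
#' @param group group tag.
#' @return a [SubjectTimeSeries-class].
#' @export
subjectTimeSeries <- function(values, tr = 1, subject = "subj",
                              dose = NA_real_, group = "") {
  new("SubjectTimeSeries", values = values, tr = as.numeric(tr),
      subject = as.character(subject), dose = as.numeric(dose),
      group = as.character(group))
}

#' @rdname SubjectTimeSeries-class
setMethod("seriesMatrix", "SubjectTimeSeries", function(x) x@values)
#' @rdname SubjectTimeSeries-class
setMethod("repetitionTime", "SubjectTimeSeries", function(x) x@tr)
#' @rdname SubjectTimeSeries-class
setMethod("subjectId", "SubjectTimeSeries", function(x) x@subject)
#' @rdname SubjectTimeSeries-class
setMethod("dose", "SubjectTimeSeries", function(x) x@dose)
#' @rdname SubjectTimeSeries-class
setMethod("regionLabels", "SubjectTimeSeries", function(x) colnames(x@values))

setMethod("show", "SubjectTimeSeries", function(object) {
  cat(sprintf("SubjectTimeSeries '%s': %d timepoints x %d regions, TR = %g s",
              object@subject, nrow(object@values), ncol(object@values), object@tr))
  if (!is.na(object@dose)) cat(sprintf(", dose = %g%%", object@dose))
  cat("\n")
})

#' Write / read a subject time-series TSV
#'
#' One row per timepoint, one column per region; the header row carries the
#' region labels. TR, subject id and dose are stored in `# key: value`
#' comment lines so a round trip preserves metadata.
#'
#' @param ts a [SubjectTimeSeries-class].
#' @param path file path.
#' @return `writeTimeSeriesTSV` returns `path` invisibly; `readTimeSeriesTSV`
#'   returns a [SubjectTimeSeries-class].
#' @export
writeTimeSeriesTSV <- function(ts, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# tr: %.10g", ts@tr), con)
  writeLines(sprintf("# subject: %s", ts@subject), con)
  writeLines(sprintf("# dose: %.10g", ts@dose), con)
  writeLines(sprintf("# group: %s", ts@group), con)
  write.table(format(ts@values, digits = 10, trim = TRUE, scientific = FALSE),
              con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTimeSeriesTSV
#' @export
readTimeSeriesTSV <- function(path) {
  hdr <- readLines(path, n = 10L)
  hdr <- hdr[startsWith(hdr, "#")]
  meta <- function(key, default) {
    ln <- grep(paste0("^# ", key, ":"), hdr, value = TRUE)
    if (length(ln) == 0L) default else trimws(sub(paste0("^# ", key, ":"), "", ln[1L]))
  }
  values <- as.matrix(read.table(path, header = TRUE, sep = "\t",
                                 comment.char = "#", check.names = FALSE))
  subjectTimeSeries(values,
                    tr = as.numeric(meta("tr", "1")),
                    subject = meta("subject", basename(path)),
                    dose = as.numeric(meta("dose", "NA")),
                    group = meta("group", ""))
}
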