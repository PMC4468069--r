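#' @include AllClasses.R layout.R
NULL

# Dialect defaults for the tab-delimited ASCII export of MEA acquisition
# tool chains: header "t [ms]<TAB>El 12 [uV]...", one time point per line.
defaultDialect <- function() {
  list(delimiter = NULL,      # NULL = auto-detect among tab/;/,
       commentChar = "#")
}

#' Construct an MEARecording
#'
#' @param samples numeric matrix (time x electrodes, uV); columns in layout
#'   label order.
#' @param samplingRate sampling rate in Hz.
#' @param layout an [ElectrodeLayout-class] (default [standardLayout()]).
#' @param startTime time of the first sample in ms.
#' @return an [MEARecording-class].
#' @export
meaRecording <- function(samples, samplingRate, layout = standardLayout(),
                         startTime = 0) {
  samples <- as.matrix(samples)
  if (ncol(samples) != length(layout@labels))
    stop("sample column count (", ncol(samples),
         ") must equal layout label count (", length(layout@labels), ")")
  colnames(samples) <- layout@labels
  new("MEARecording", samples = samples, samplingRate = samplingRate,
      layout = layout, startTime = startTime)
}

# Split one line on the detected delimiter, trimming whitespace.
splitFields <- function(line, delim) {
  f <- strsplit(line, delim, fixed = TRUE)[[1]]
  trimws(f)
}

detectDelimiter <- function(headerLine) {
  counts <- c("\t" = lengths(regmatches(headerLine, gregexpr("\t", headerLine))),
              ";"  = lengths(regmatches(headerLine, gregexpr(";", headerLine, fixed = TRUE))),
              ","  = lengths(regmatches(headerLine, gregexpr(",", headerLine, fixed = TRUE))))
  if (all(counts == 0)) stop("cannot detect delimiter in header line (no tab, ';' or ',')")
  names(counts)[which.max(counts)]
}

# Parse one header token into "time", an electrode label, or NA.
parseHeaderToken <- function(tok) {
  if (grepl("^t\\b", tok, ignore.case = TRUE) || grepl("\\[(m|u|µ)s\\]", tok))
    return("time")
  m <- regmatches(tok, regexpr("[1-8][1-8]", tok))
  if (length(m)) m else NA_character_
}

#' Read an ASCII MEA recording
#'
#' Reads the tab-delimited ASCII export format: a header line naming the time
#' column and one column per electrode ("El 12 \[uV\]" or a bare label),
#' followed by one time point per line. Semicolon and comma delimiters,
#' leading '#' comment lines, and a time column in us (converted to ms) are
#' also accepted. The sampling rate is inferred as 1000 / median successive
#' time difference (ms); the time column must be strictly increasing and
#' regular to within 1 ppm.
#'
#' @param path file to read.
#' @param layout expected [ElectrodeLayout-class] (default [standardLayout()]).
#' @param dialect list overriding auto-detection; supported keys
#'   \code{delimiter} and \code{commentChar} (see Details).
#' @param smoothing optional [SmoothingConfig-class]; when supplied (and
#'   enabled) the returned recording carries smoothed traces.
#' @return an [MEARecording-class].
#' @seealso [writeAsciiRecording()]
#' @export
readAsciiRecording <- function(path, layout = standardLayout(),
                               dialect = defaultDialect(), smoothing = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  dia <- utils::modifyList(defaultDialect(), dialect)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  isComment <- startsWith(trimws(lines), dia$commentChar)
  lines <- lines[!isComment]
  if (length(lines) < 3L) stop("file has fewer than a header plus 2 data lines")

  delim <- if (is.null(dia$delimiter)) detectDelimiter(lines[1]) else dia$delimiter
  header <- splitFields(lines[1], delim)
  roles <- vapply(header, parseHeaderToken, character(1), USE.NAMES = FALSE)
  timeCol <- which(roles == "time")
  if (length(timeCol) != 1L)
    stop("header must contain exactly one time column; found ", length(timeCol))
  elecCols <- which(!is.na(roles) & roles != "time")
  colLabels <- roles[elecCols]
  if (anyDuplicated(colLabels))
    stop("duplicate electrode column(s): ",
         paste(unique(colLabels[duplicated(colLabels)]), collapse = ", "))
  missing <- setdiff(layout@labels, colLabels)
  if (length(missing))
    stop("missing electrode column(s): ", paste(missing, collapse = ", "))
  timeInUs <- grepl("\\[(u|µ)s\\]", header[timeCol])

  body <- lines[-1]
  fields <- strsplit(body, delim, fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != length(header)))
    stop("row ", which(nf != length(header))[1] + 1L, " has ", nf[nf != length(header)][1],
         " fields, expected ", length(header))
  mat <- matrix(suppressWarnings(as.numeric(trimws(unlist(fields)))),
                nrow = length(body), byrow = TRUE)
  if (anyNA(mat)) {
    bad <- which(is.na(mat), arr.ind = TRUE)[1, ]
    stop("unparsable numeric value at data row ", bad["row"],
         ", column '", header[bad["col"]], "'")
  }
  tvec <- mat[, timeCol]
  if (timeInUs) tvec <- tvec / 1000
  dt <- diff(tvec)
  if (any(dt <= 0)) stop("time column must be strictly increasing (violated at row ",
                         which(dt <= 0)[1] + 1L, ")")
  med <- stats::median(dt)
  if (max(abs(dt - med)) / med > 1e-6)
    stop("time column jitter exceeds 1 ppm; irregular sampling is not supported")

  samples <- mat[, elecCols, drop = FALSE]
  colnames(samples) <- colLabels
  samples <- samples[, layout@labels, drop = FALSE]
  rec <- new("MEARecording", samples = samples, samplingRate = 1000 / med,
             layout = layout, startTime = tvec[1])
  if (!is.null(smoothing) && smoothing@enabled)
    rec <- smoothRecording(rec, smoothing)
  rec
}

#' Write an ASCII MEA recording
#'
#' Writes the default dialect: UTF-8, tab-delimited, header
#' \code{t [ms]<TAB>El 12 [uV]<TAB>...} with electrode columns in ascending
#' label order, one time point per line. Voltages are written with
#' \code{precision} significant digits; the time column is always written
#' with full (12 significant digit) precision so the sampling rate survives a
#' round trip.
#'
#' @param recording an [MEARecording-class].
#' @param path output file.
#' @param precision significant digits for voltage values (default 6).
#' @return invisibly, \code{path}.
#' @seealso [readAsciiRecording()]
#' @export
writeAsciiRecording <- function(recording, path, precision = 6) {
  stopifnot(is(recording, "MEARecording"))
  lab <- recording@layout@labels
  header <- paste(c("t [ms]", sprintf("El %s [µV]", lab)), collapse = "\t")
  tvec <- sampleTimes(recording)
  body <- apply(recording@samples, 1, function(rw)
    paste(sprintf("%.*g", precision, rw), collapse = "\t"))
  lines <- c(header, paste(sprintf("%.12g", tvec), body, sep = "\t"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(enc2utf8(lines), con, useBytes = TRUE)
  invisible(path)
}
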