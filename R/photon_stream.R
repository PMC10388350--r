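#' Construct a photon stream
#'
#' A photon stream is the raw observable of a diffusion-based single-molecule
#' FRET experiment: a time-ordered record of detected photons, each tagged
#' with its detection channel (donor or acceptor emission) and, under pulsed
#' interleaved excitation (PIE), with the excitation slot in which it arrived
#' (donor- or acceptor-excitation pulse).
#'
#' Timestamps are integer multiples of the instrument clock period ("ticks"),
#' stored as doubles so that long recordings exceed the 32-bit integer range
#' without loss (exact up to 2^53 ticks). All durations in seconds are derived
#' as `ticks * clock_period`.
#'
#' @param timestamps numeric vector of arrival times in clock ticks,
#'   non-decreasing.
#' @param channel character vector, one of `"D"` (donor emission channel) or
#'   `"A"` (acceptor emission channel) per photon.
#' @param slot character vector, one of `"Dex"` (donor excitation) or
#'   `"Aex"` (acceptor excitation) per photon.
#' @param clock_period clock period in seconds per tick (> 0).
#' @param metadata free-form named list of provenance information.
#'
#' @return An object of class `"photon_stream"`: a list with fields
#'   `timestamps`, `channel`, `slot`, `clock_period`, `metadata`.
#' @export
photon_stream <- function(timestamps, channel, slot,
                          clock_period = 12.5e-9, metadata = list()) {
  timestamps <- as.numeric(timestamps)
  channel <- as.character(channel)
  slot <- as.character(slot)
  n <- length(timestamps)
  if (length(channel) != n || length(slot) != n) {
    stop("timestamps, channel and slot must have equal length")
  }
  if (n > 1 && any(diff(timestamps) < 0)) {
    stop("photon timestamps must be sorted in non-decreasing order")
  }
  if (!is.numeric(clock_period) || length(clock_period) != 1 ||
      clock_period <= 0) {
    stop("clock_period must be a single positive number")
  }
  bad_ch <- setdiff(unique(channel), c("D", "A"))
  if (length(bad_ch)) {
    stop("unknown channel tag(s): ", paste(bad_ch, collapse = ", "))
  }
  bad_sl <- setdiff(unique(slot), c("Dex", "Aex"))
  if (length(bad_sl)) {
    stop("unknown excitation slot tag(s): ", paste(bad_sl, collapse = ", "))
  }
  structure(
    list(timestamps = timestamps, channel = channel, slot = slot,
         clock_period = clock_period, metadata = metadata),
    class = "photon_stream"
  )
}

#' @export
print.photon_stream <- function(x, ...) {
  n <- length(x$timestamps)
  cat("<photon_stream> ", n, " photons, clock period ",
      format(x$clock_period), " s\n", sep = "")
  if (n) {
    span <- (x$timestamps[n] - x$timestamps[1]) * x$clock_period
    cat("  span ", format(span, digits = 4), " s; Dex ",
        sum(x$slot == "Dex"), " / Aex ", sum(x$slot == "Aex"),
        "; channel D ", sum(x$channel == "D"), " / A ",
        sum(x$channel == "A"), "\n", sep = "")
  }
  invisible(x)
}

#' @export
length.photon_stream <- function(x) length(x$timestamps)

#' Read a photon stream from disk
#'
#' Reads the plain columnar-text dialect: a comma-separated file with header
#' `timestamp,channel,slot`, where `channel` is `D` or `A` and `slot` is
#' `Dex` or `Aex`. An optional comment line of the form
#' `# clock_period_s=<value>` preceding the header sets the clock period;
#' otherwise 12.5 ns is assumed.
#'
#' @param path path to the file.
#' @param format file format; only `"columnar-text"` is supported.
#' @param clock_period clock period in seconds, used when the file does not
#'   carry one.
#' @return A [photon_stream].
#' @seealso [write_photon_stream()]
#' @export
read_photon_stream <- function(path, format = c("columnar-text"),
                               clock_period = 12.5e-9) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  cp <- clock_period
  meta_lines <- grep("^#", lines)
  for (i in meta_lines) {
    m <- regmatches(lines[i],
                    regexec("clock_period_s\\s*=\\s*([0-9.eE+-]+)", lines[i]))[[1]]
    if (length(m) == 2) cp <- as.numeric(m[2])
  }
  body <- if (length(meta_lines)) lines[-meta_lines] else lines
  if (!length(body)) stop("format error: file has no header line")
  header <- strsplit(trimws(body[1]), ",")[[1]]
  required <- c("timestamp", "channel", "slot")
  missing <- setdiff(required, header)
  if (length(missing)) {
    stop("format error: missing required field(s): ",
         paste(missing, collapse = ", "))
  }
  df <- utils::read.csv(text = body, stringsAsFactors = FALSE)
  photon_stream(df$timestamp, df$channel, df$slot, clock_period = cp,
                metadata = list(source = path))
}

#' Write a photon stream to disk
#'
#' Writes the columnar-text dialect read by [read_photon_stream()]. The
#' timestamp/channel/slot records round-trip bit-exactly.
#'
#' @param stream a [photon_stream].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_photon_stream <- function(stream, path) {
  stopifnot(inherits(stream, "photon_stream"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# clock_period_s=%.17g", stream$clock_period), con)
  writeLines("timestamp,channel,slot", con)
  if (length(stream$timestamps)) {
    writeLines(sprintf("%.0f,%s,%s", stream$timestamps, stream$channel,
                       stream$slot), con)
  }
  invisible(path)
}
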