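# File ingestion and serialization: raw 30 Hz CSVs, per-second epoch-count
# CSVs, subject metadata, and metric tables. Plain comma-separated files with
# dot decimals throughout; ActiGraph-style vendor header blocks are detected
# (leading non-numeric lines) and skipped, with the declared sample rate
# parsed out when present.

#' Construct a raw wrist recording
#'
#' A `RawRecording` holds one limb's tri-axial acceleration trace in
#' gravitational units (g), sampled at a constant rate (30 Hz for the
#' supported devices).
#'
#' @param ax,ay,az Numeric vectors of equal length, acceleration in g.
#' @param sample_rate Sampling rate in Hz (> 0).
#' @param subject_id Optional subject identifier.
#' @param limb Limb role: `"paretic_nd"` (paretic / non-dominant) or
#'   `"nonparetic_d"` (non-paretic / dominant).
#' @return An object of class `RawRecording` with elements `ax`, `ay`, `az`,
#'   `sample_rate`, `subject_id`, `limb`.
#' @export
raw_recording <- function(ax, ay, az, sample_rate = 30,
                          subject_id = NA_character_, limb = "paretic_nd") {
  if (length(ax) != length(ay) || length(ay) != length(az))
    stop_ulperf("all three axes must have equal length")
  if (!all(is.finite(ax)) || !all(is.finite(ay)) || !all(is.finite(az)))
    stop_ulperf("non-finite acceleration values")
  if (!is.numeric(sample_rate) || sample_rate <= 0)
    stop_ulperf("sample_rate must be > 0")
  limb <- match.arg(limb, c("paretic_nd", "nonparetic_d"))
  structure(list(ax = as.numeric(ax), ay = as.numeric(ay), az = as.numeric(az),
                 sample_rate = as.numeric(sample_rate),
                 subject_id = subject_id, limb = limb),
            class = "RawRecording")
}

#' @export
length.RawRecording <- function(x) length(x$ax)

#' @export
print.RawRecording <- function(x, ...) {
  cat(sprintf("RawRecording: %d samples at %g Hz (%.1f s), limb %s\n",
              length(x), x$sample_rate, length(x) / x$sample_rate, x$limb))
  invisible(x)
}

#' Construct a bilateral epoch-count series
#'
#' An `EpochSeries` holds aligned per-second vector-magnitude activity counts
#' for both limbs of one subject, in the fixed role order paretic /
#' non-dominant (`vm_p`) vs non-paretic / dominant (`vm_np`).
#'
#' @param vm_p,vm_np Non-negative per-second count vectors of equal length.
#' @param subject_id Optional subject identifier.
#' @return An object of class `EpochSeries`.
#' @export
epoch_series <- function(vm_p, vm_np, subject_id = NA_character_) {
  if (length(vm_p) != length(vm_np))
    stop_ulperf("vm_p and vm_np must have equal length")
  if (any(vm_p < 0) || any(vm_np < 0))
    stop_ulperf("negative counts")
  structure(list(vm_p = as.numeric(vm_p), vm_np = as.numeric(vm_np),
                 epoch_s = 1, count_scale = COUNT_SCALE_G,
                 subject_id = subject_id),
            class = "EpochSeries")
}

#' @export
length.EpochSeries <- function(x) length(x$vm_p)

#' @export
print.EpochSeries <- function(x, ...) {
  cat(sprintf("EpochSeries: %d one-second epochs (%.2f h)\n",
              length(x), length(x) / 3600))
  invisible(x)
}

# Split a CSV file into (header_lines, data_lines). A vendor header is a
# leading block of lines whose first field is not numeric.
split_vendor_header <- function(lines) {
  is_data <- function(l) {
    first <- strsplit(l, ",", fixed = TRUE)[[1]][1]
    suppressWarnings(!is.na(as.numeric(first)))
  }
  i <- 1L
  while (i <= length(lines) && nzchar(trimws(lines[i])) && !is_data(lines[i]))
    i <- i + 1L
  list(header = if (i > 1L) lines[seq_len(i - 1L)] else character(0),
       data = lines[seq(i, length.out = max(0L, length(lines) - i + 1L))])
}

# Parse "... 30 Hz ..." out of a vendor header block, if declared.
header_sample_rate <- function(header) {
  m <- regmatches(header, regexpr("([0-9]+(\\.[0-9]+)?)\\s*Hz", header))
  m <- m[lengths(regmatches(header, regexpr("Hz", header))) > 0]
  if (!length(m)) return(NULL)
  as.numeric(sub("\\s*Hz", "", m[1]))
}

#' Read a raw tri-axial accelerometer CSV
#'
#' Expects three comma-separated axis columns in g (a header row naming them
#' is optional, as is an ActiGraph-style vendor header block). When the
#' vendor header declares a sample rate it overrides the `sample_rate`
#' argument.
#'
#' @param path CSV file path.
#' @param limb Limb role label, see [raw_recording()].
#' @param sample_rate Sampling rate in Hz, used when the file declares none.
#' @param subject_id Optional subject identifier.
#' @return A [raw_recording()] object.
#' @export
read_raw_csv <- function(path, limb = "paretic_nd", sample_rate = 30,
                         subject_id = NA_character_) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop_ulperf("zero-length file: ", path)
  parts <- split_vendor_header(lines)
  hdr_rate <- header_sample_rate(parts$header)
  if (!length(parts$data)) stop_ulperf("no numeric rows in ", path)
  dat <- utils::read.csv(text = paste(parts$data, collapse = "\n"),
                         header = FALSE)
  num <- vapply(dat, is.numeric, logical(1))
  dat <- dat[, num, drop = FALSE]
  if (ncol(dat) < 3) stop_ulperf("missing axis column in ", path)
  if (anyNA(dat)) stop_ulperf("non-numeric rows in ", path)
  # first three numeric columns are the axes (a timestamp column, if
  # present, was non-numeric and already dropped)
  raw_recording(dat[[1]], dat[[2]], dat[[3]],
                sample_rate = hdr_rate %||% sample_rate,
                subject_id = subject_id, limb = limb)
}

#' Read a per-second epoch-count CSV for one limb
#'
#' Accepts either `second_index, vm_counts` columns or `second_index` plus
#' three axis-count columns (combined with [vector_magnitude()]). Gaps in
#' `second_index` (0-based) are zero-filled up to the maximum index.
#'
#' @param path CSV file path.
#' @return Numeric vector of per-second vector-magnitude counts.
#' @export
read_epoch_csv <- function(path) {
  dat <- utils::read.csv(path, header = TRUE)
  if (ncol(dat) < 2) stop_ulperf("expected second_index plus count column(s)")
  idx <- dat[[1]]
  if (anyDuplicated(idx)) stop_ulperf("duplicate second_index")
  if (ncol(dat) >= 4) {
    vm <- vector_magnitude(dat[[2]], dat[[3]], dat[[4]])
  } else {
    vm <- dat[[2]]
  }
  if (any(vm < 0)) stop_ulperf("negative counts")
  out <- numeric(max(idx) + 1L)
  out[idx + 1L] <- vm
  out
}

#' Write / read a metric table
#'
#' A metric table is a data frame with a `subject_id` column followed by
#' upper-limb performance variable columns (canonical names, see
#' [ul_variable_names()]). The CSV round-trips losslessly to double
#' precision.
#'
#' @param table Data frame with `subject_id` plus metric columns.
#' @param path CSV file path.
#' @return `write_metric_table()` returns `path` invisibly;
#'   `read_metric_table()` returns the data frame.
#' @export
write_metric_table <- function(table, path) {
  if (!is.data.frame(table) || nrow(table) == 0)
    stop_ulperf("metric table is empty")
  if (names(table)[1] != "subject_id")
    stop_ulperf("first column must be subject_id")
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_metric_table
#' @export
read_metric_table <- function(path) {
  dat <- utils::read.csv(path, header = TRUE, stringsAsFactors = FALSE)
  dat$subject_id <- as.character(dat$subject_id)
  dat
}

#' Read a subject metadata CSV
#'
#' Columns: `subject_id`, `cohort` (one of `stroke_1`, `stroke_2`,
#' `control`), `paretic_side` (`left`/`right`, stroke only), `dominant_side`
#' (`left`/`right`), optional `arat` (0-57). A `concordant` flag (dominant
#' limb = paretic limb) is derived for stroke subjects.
#'
#' @param path CSV file path.
#' @return Data frame of validated metadata with derived `concordant` column.
#' @export
read_meta_csv <- function(path) {
  meta <- utils::read.csv(path, header = TRUE, stringsAsFactors = FALSE)
  validate_meta(meta)
}

validate_meta <- function(meta) {
  req <- c("subject_id", "cohort", "dominant_side")
  if (!all(req %in% names(meta)))
    stop_ulperf("metadata needs columns: ", paste(req, collapse = ", "))
  if (!all(meta$cohort %in% c("stroke_1", "stroke_2", "control")))
    stop_ulperf("unknown cohort label")
  if (is.null(meta$paretic_side)) meta$paretic_side <- NA_character_
  if (is.null(meta$arat)) meta$arat <- NA_integer_
  if (any(!is.na(meta$arat) & (meta$arat < 0 | meta$arat > 57)))
    stop_ulperf("arat outside [0, 57]")
  stroke <- meta$cohort != "control"
  meta$concordant <- ifelse(stroke,
                            meta$paretic_side == meta$dominant_side, NA)
  meta$subject_id <- as.character(meta$subject_id)
  meta
}
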