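# Readers and writers: a plain-text container for the internal EEG type
# (TSV data + JSON sidecar, lossless round-trip), two-column feature files,
# and a native BrainVision reader for raw recordings.

#' Write an EEG recording to a text container
#'
#' The data matrix goes to `<path>.tsv` (one channel per row, full double
#' precision) and rate, labels and validity masks to `<path>.json`. The
#' round-trip through [read_eeg_txt()] is lossless.
#'
#' @param eeg an [eeg_recording()].
#' @param path base path (without extension).
#' @return `path`, invisibly.
#' @export
write_eeg_txt <- function(eeg, path) {
  stopifnot(inherits(eeg, "eeg_recording"))
  utils::write.table(format(eeg$data, digits = 17, scientific = TRUE, trim = TRUE),
                     paste0(path, ".tsv"), sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invalid <- which(!eeg$valid_samples)
  meta <- list(rate = eeg$rate, channel_labels = eeg$channel_labels,
               valid_channels = eeg$valid_channels,
               n_channels = nrow(eeg$data), n_samples = ncol(eeg$data),
               invalid_sample_index = as.integer(invalid))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an EEG recording written by [write_eeg_txt()]
#'
#' @param path base path (without extension).
#' @return an [eeg_recording()].
#' @export
read_eeg_txt <- function(path) {
  jf <- paste0(path, ".json")
  tf <- paste0(path, ".tsv")
  if (!file.exists(jf) || !file.exists(tf)) {
    stop(sprintf("missing container file(s) for '%s'", path), call. = FALSE)
  }
  meta <- jsonlite::read_json(jf, simplifyVector = TRUE)
  X <- as.matrix(utils::read.table(tf, sep = "\t", header = FALSE,
                                   colClasses = "numeric"))
  dimnames(X) <- NULL
  if (!identical(dim(X), c(meta$n_channels, meta$n_samples))) {
    stop("data shape does not match the JSON sidecar", call. = FALSE)
  }
  vs <- matrix(TRUE, meta$n_channels, meta$n_samples)
  if (length(meta$invalid_sample_index)) vs[meta$invalid_sample_index] <- FALSE
  eeg_recording(X, rate = meta$rate, channel_labels = meta$channel_labels,
                valid_channels = meta$valid_channels, valid_samples = vs)
}

#' Write a stimulus feature as two-column delimited text
#'
#' Columns: `time_s`, `value`.
#'
#' @param feature a [stimulus_feature()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_feature_txt <- function(feature, path) {
  stopifnot(inherits(feature, "stimulus_feature"))
  df <- data.frame(time_s = (seq_along(feature$values) - 1) / feature$rate,
                   value = feature$values)
  utils::write.table(format(df, digits = 17, scientific = TRUE, trim = TRUE),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a two-column feature file
#'
#' @param path file with columns `time_s`, `value` (tab- or
#'   whitespace-delimited, header line).
#' @param feature_name label for the result.
#' @param zscore re-standardise on read (default FALSE: the file is assumed
#'   to hold the analysis-ready series).
#' @return a [stimulus_feature()].
#' @export
read_feature_txt <- function(path, feature_name = "optic_flow", zscore = FALSE) {
  df <- utils::read.table(path, header = TRUE)
  if (!all(c("time_s", "value") %in% names(df))) {
    stop("feature file must have columns time_s and value", call. = FALSE)
  }
  dt <- diff(df$time_s)
  rate <- 1 / stats::median(dt)
  stimulus_feature(df$value, rate, feature_name, zscore = zscore)
}

# parse one INI-style BrainVision section into a named character vector
parse_vhdr_section <- function(lines, section) {
  hdr <- grep(sprintf("^\\[%s\\]", section), lines)
  if (!length(hdr)) return(character(0))
  rest <- lines[(hdr[1] + 1L):length(lines)]
  nxt <- grep("^\\[", rest)
  if (length(nxt)) rest <- rest[seq_len(nxt[1] - 1L)]
  rest <- rest[grepl("=", rest) & !grepl("^;", rest)]
  kv <- regmatches(rest, regexpr("=", rest), invert = TRUE)
  stats::setNames(vapply(kv, function(p) trimws(p[2]), ""),
                  vapply(kv, function(p) trimws(p[1]), ""))
}

#' Read a BrainVision recording
#'
#' Parses the `.vhdr` header (INI format) and reads the binary `.eeg` data
#' file. Supports multiplexed orientation with `IEEE_FLOAT_32` or `INT_16`
#' binary formats; integer data are scaled by the per-channel resolution so
#' the result is in microvolts.
#'
#' @param vhdr_path path to the `.vhdr` header file.
#' @return an [eeg_recording()].
#' @export
read_brainvision <- function(vhdr_path) {
  if (!file.exists(vhdr_path)) stop("header file not found", call. = FALSE)
  lines <- readLines(vhdr_path, warn = FALSE)
  common <- parse_vhdr_section(lines, "Common Infos")
  binary <- parse_vhdr_section(lines, "Binary Infos")
  chans <- parse_vhdr_section(lines, "Channel Infos")
  need <- c("DataFile", "NumberOfChannels", "SamplingInterval")
  miss <- setdiff(need, names(common))
  if (length(miss)) {
    stop(sprintf("malformed BrainVision header: missing field '%s'", miss[1]),
         call. = FALSE)
  }
  if (!is.na(common["DataOrientation"]) &&
      toupper(common[["DataOrientation"]]) != "MULTIPLEXED") {
    stop("only MULTIPLEXED orientation is supported", call. = FALSE)
  }
  D <- as.integer(common[["NumberOfChannels"]])
  rate <- 1e6 / as.numeric(common[["SamplingInterval"]])  # interval is in us
  fmt <- toupper(binary[["BinaryFormat"]])

  labels <- sprintf("ch%03d", seq_len(D))
  resol <- rep(1, D)
  for (i in seq_len(D)) {
    key <- sprintf("Ch%d", i)
    if (key %in% names(chans)) {
      parts <- strsplit(chans[[key]], ",")[[1]]
      if (length(parts) >= 1 && nzchar(trimws(parts[1]))) labels[i] <- trimws(parts[1])
      if (length(parts) >= 3 && nzchar(trimws(parts[3]))) {
        resol[i] <- as.numeric(trimws(parts[3]))
      }
    }
  }

  data_path <- file.path(dirname(vhdr_path), common[["DataFile"]])
  if (!file.exists(data_path)) stop("data file named in header not found", call. = FALSE)
  sz <- file.info(data_path)$size
  if (fmt == "IEEE_FLOAT_32") {
    n_val <- sz / 4
    if (n_val %% D != 0) stop("truncated BrainVision data file", call. = FALSE)
    raw_v <- readBin(data_path, what = "numeric", n = n_val, size = 4,
                     endian = "little")
    X <- matrix(raw_v, nrow = D)
  } else if (fmt == "INT_16") {
    n_val <- sz / 2
    if (n_val %% D != 0) stop("truncated BrainVision data file", call. = FALSE)
    raw_v <- readBin(data_path, what = "integer", n = n_val, size = 2,
                     signed = TRUE, endian = "little")
    X <- matrix(raw_v, nrow = D) * resol
  } else {
    stop(sprintf("unsupported BinaryFormat '%s'", fmt), call. = FALSE)
  }
  eeg_recording(X, rate = rate, channel_labels = labels)
}

#' Trigger-interval consistency check
#'
#' Compares inter-trigger intervals recorded on an auxiliary channel against
#' the expected interval implied by the nominal rate of a periodic marker,
#' returning the mean absolute discrepancy in seconds. Large values flag a
#' misaligned recording.
#'
#' @param trigger_times_s numeric vector of trigger times (seconds).
#' @param expected_interval_s nominal interval between triggers (seconds).
#' @return mean absolute deviation of the intervals, in seconds.
#' @export
trigger_interval_check <- function(trigger_times_s, expected_interval_s) {
  if (length(trigger_times_s) < 2) stop("need at least two triggers", call. = FALSE)
  mean(abs(diff(trigger_times_s) - expected_interval_s))
}
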