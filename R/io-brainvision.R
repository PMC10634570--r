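#' Write a continuous recording as a BrainVision triplet
#'
#' Writes the standard BrainVision file triplet: a `.vhdr` text header, a
#' `.vmrk` marker file with stimulus events, and a `.eeg` binary file with
#' multiplexed IEEE float-32 samples. Files written here load in common
#' EEG toolboxes (MNE, FieldTrip, EEGLAB).
#'
#' @param continuous numeric matrix `[channels, samples]` in microvolts.
#' @param basename output path without extension; the three files get
#'   `.vhdr`, `.vmrk`, `.eeg` appended.
#' @param sample_rate sampling rate, Hz.
#' @param events optional integer vector of stimulus onset samples
#'   (1-based); written as `Stimulus, S<i>` markers.
#' @param event_codes optional integer codes per event (default 1).
#' @param channels optional channel names.
#' @return The `.vhdr` path, invisibly.
#' @export
write_brainvision <- function(continuous, basename, sample_rate,
                              events = integer(0), event_codes = NULL,
                              channels = NULL) {
  continuous <- as.matrix(continuous)
  n_ch <- nrow(continuous)
  channels <- channels %||% paste0("Ch", seq_len(n_ch))
  event_codes <- event_codes %||% rep(1L, length(events))
  stopifnot(length(channels) == n_ch, length(event_codes) == length(events))
  vhdr <- paste0(basename, ".vhdr")
  vmrk <- paste0(basename, ".vmrk")
  eeg <- paste0(basename, ".eeg")

  hdr <- c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "", "[Common Infos]",
    paste0("DataFile=", base::basename(eeg)),
    paste0("MarkerFile=", base::basename(vmrk)),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    paste0("NumberOfChannels=", n_ch),
    sprintf("SamplingInterval=%g", 1e6 / sample_rate),
    "", "[Binary Infos]",
    "BinaryFormat=IEEE_FLOAT_32",
    "", "[Channel Infos]",
    sprintf("Ch%d=%s,,1,%s", seq_len(n_ch), channels, "µV")
  )
  writeLines(hdr, vhdr)

  mrk <- c(
    "Brain Vision Data Exchange Marker File, Version 1.0",
    "", "[Common Infos]",
    paste0("DataFile=", base::basename(eeg)),
    "", "[Marker Infos]",
    "Mk1=New Segment,,1,1,0,0"
  )
  if (length(events) > 0L) {
    mrk <- c(mrk, sprintf("Mk%d=Stimulus,S%3d,%d,1,0",
                          seq_along(events) + 1L, event_codes, events))
  }
  writeLines(mrk, vmrk)

  con <- file(eeg, "wb")
  on.exit(close(con))
  writeBin(as.numeric(continuous), con, size = 4, endian = "little")
  invisible(vhdr)
}

# Minimal ini-style section parser for .vhdr/.vmrk files.
parse_bv_sections <- function(lines) {
  sec <- NULL
  out <- list()
  for (ln in lines) {
    ln <- sub(";.*$", "", ln)
    if (grepl("^\\[", ln)) {
      sec <- gsub("\\[|\\]", "", trimws(ln))
      out[[sec]] <- character(0)
    } else if (!is.null(sec) && nzchar(trimws(ln))) {
      out[[sec]] <- c(out[[sec]], trimws(ln))
    }
  }
  out
}

bv_value <- function(section, key) {
  hit <- grep(paste0("^", key, "="), section, value = TRUE)
  if (length(hit) == 0L) return(NULL)
  sub(paste0("^", key, "="), "", hit[1])
}

#' Read a BrainVision recording
#'
#' Reads the `.vhdr` header, the multiplexed binary data (IEEE float-32 or
#' 16-bit integer with per-channel resolution), and stimulus markers from
#' the `.vmrk` file.
#'
#' @param vhdr_path path to the `.vhdr` header file.
#' @return List with `data` (`[channels, samples]`), `sample_rate`,
#'   `channels`, and `events` (data.frame `sample`, `code`).
#' @export
read_brainvision <- function(vhdr_path) {
  hdr <- parse_bv_sections(readLines(vhdr_path, warn = FALSE))
  common <- hdr[["Common Infos"]]
  if (!identical(bv_value(common, "DataOrientation") %||% "MULTIPLEXED",
                 "MULTIPLEXED")) {
    stop("only MULTIPLEXED data orientation is supported", call. = FALSE)
  }
  n_ch <- as.integer(bv_value(common, "NumberOfChannels"))
  sample_rate <- 1e6 / as.numeric(bv_value(common, "SamplingInterval"))
  fmt <- bv_value(hdr[["Binary Infos"]], "BinaryFormat") %||% "IEEE_FLOAT_32"
  ch_lines <- hdr[["Channel Infos"]]
  ch_fields <- strsplit(sub("^Ch[0-9]+=", "", ch_lines), ",")
  channels <- vapply(ch_fields, `[`, character(1), 1)
  resolution <- vapply(ch_fields, function(f) {
    r <- suppressWarnings(as.numeric(f[3]))
    if (is.na(r)) 1 else r
  }, numeric(1))

  dir <- dirname(vhdr_path)
  eeg_path <- file.path(dir, bv_value(common, "DataFile"))
  sz <- file.info(eeg_path)$size
  con <- file(eeg_path, "rb")
  on.exit(close(con))
  if (fmt == "IEEE_FLOAT_32") {
    raw_vals <- readBin(con, "numeric", n = sz / 4, size = 4, endian = "little")
  } else if (fmt == "INT_16") {
    raw_vals <- readBin(con, "integer", n = sz / 2, size = 2, signed = TRUE,
                        endian = "little")
  } else {
    stop("unsupported BinaryFormat: ", fmt, call. = FALSE)
  }
  n_samp <- length(raw_vals) %/% n_ch
  data <- matrix(raw_vals[seq_len(n_ch * n_samp)], n_ch, n_samp)
  data <- data * resolution

  events <- data.frame(sample = integer(0), code = integer(0))
  mrk_file <- bv_value(common, "MarkerFile")
  mrk_path <- if (!is.null(mrk_file)) file.path(dir, mrk_file) else NULL
  if (!is.null(mrk_path) && file.exists(mrk_path)) {
    mrk <- parse_bv_sections(readLines(mrk_path, warn = FALSE))
    for (ln in mrk[["Marker Infos"]]) {
      f <- strsplit(sub("^Mk[0-9]+=", "", ln), ",")[[1]]
      if (length(f) >= 3 && trimws(f[1]) == "Stimulus") {
        events <- rbind(events, data.frame(
          sample = as.integer(f[3]),
          code = as.integer(gsub("[^0-9]", "", f[2]))))
      }
    }
  }
  list(data = data, sample_rate = sample_rate, channels = channels,
       events = events)
}
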