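## Minimal EDF+ writer/reader (16-bit European Data Format with an
## "EDF Annotations" signal carrying trial markers as TALs). Implemented
## in-package because no EDF library ships with the target environment.
## Only continuous ("EDF+C") files with 1-s data records are produced;
## the reader handles the same subset and fails loudly on anything else.

pad_field <- function(x, width) {
  s <- as.character(x)
  if (nchar(s) > width) abort("EDF header field too wide: '%s' (> %d)", s, width)
  formatC(s, width = -width)           # left-justified, space padded
}

# Format a physical bound into <= 8 EDF chars, then re-parse it so the
# value used for quantisation is exactly the value stored in the header.
edf_phys <- function(x) {
  s <- formatC(x, digits = 6, width = 1, format = "g")
  if (nchar(s) > 8) s <- formatC(x, digits = 4, width = 1, format = "g")
  as.numeric(s)
}

#' Write a recording to an EDF+ file
#'
#' Samples are stored as 16-bit integers against a per-channel physical
#' range (default +/-200 microvolts, auto-widened per channel when the data
#' exceed it), in 1-s data records; annotations are stored as EDF+ TALs in
#' an "EDF Annotations" signal. The recording must therefore be a whole
#' number of seconds at an integer sampling rate.
#'
#' @param recording an `eeg_recording`.
#' @param path output file path.
#' @param physical_range default physical bounds in microvolts.
#' @return `path`, invisibly.
#' @export
write_edf <- function(recording, path, physical_range = c(-200, 200)) {
  fs <- recording$sampling_rate
  if (fs != round(fs)) abort("EDF writer needs an integer sampling rate")
  n <- ncol(recording$samples)
  if (n %% fs != 0)
    abort("EDF writer needs a whole number of seconds (%d samples at %g Hz)",
          n, fs)
  n_rec <- n %/% fs
  nch <- nrow(recording$samples)

  pmin_d <- rep(edf_phys(physical_range[1]), nch)
  pmax_d <- rep(edf_phys(physical_range[2]), nch)
  for (ch in seq_len(nch)) {
    mx <- max(abs(recording$samples[ch, ]), 1e-6)
    if (mx > pmax_d[ch] || -mx < pmin_d[ch]) {   # auto-range fallback
      pmax_d[ch] <- edf_phys(mx * 1.05)
      pmin_d[ch] <- edf_phys(-mx * 1.05)
    }
  }
  dmin <- -32768; dmax <- 32767

  # per-record annotation byte payloads (timestamp TAL + event TALs)
  ann <- recording$annotations
  rec_ann <- lapply(seq_len(n_rec) - 1L, function(t0) {
    s <- sprintf("+%d\x14\x14", t0)
    if (!is.null(ann) && nrow(ann)) {
      here <- which(floor(ann$onset) == t0)
      for (i in here)
        s <- paste0(s, sprintf("+%s\x15%s\x14%s\x14",
                               format(ann$onset[i]), format(ann$duration[i]),
                               ann$label[i]))
    }
    c(charToRaw(s), as.raw(0))   # TAL terminator (nul byte)
  })
  ann_bytes <- max(vapply(rec_ann, length, integer(1)))
  ann_nsamp <- as.integer(ceiling(ann_bytes / 2))
  ns <- nch + 1L

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad_field("0", 8),
    pad_field(recording$participant_id, 80),
    pad_field("Startdate 01-JAN-2000 synthetic", 80),
    pad_field("01.01.00", 8),
    pad_field("00.00.00", 8),
    pad_field(256 * (ns + 1), 8),
    pad_field("EDF+C", 44),
    pad_field(n_rec, 8),
    pad_field(1, 8),
    pad_field(ns, 4))
  sig <- function(values, width) paste(vapply(values, pad_field, "",
                                              width = width), collapse = "")
  hdr <- paste0(hdr,
    sig(c(recording$channel_labels, "EDF Annotations"), 16),
    sig(rep("", ns), 80),
    sig(c(rep("uV", nch), ""), 8),
    sig(c(pmin_d, -1), 8),
    sig(c(pmax_d, 1), 8),
    sig(c(rep(dmin, nch), dmin), 8),
    sig(c(rep(dmax, nch), dmax), 8),
    sig(rep("", ns), 80),
    sig(c(rep(fs, nch), ann_nsamp), 8),
    sig(rep("", ns), 32))
  writeChar(hdr, con, eos = NULL)

  scale <- (dmax - dmin) / (pmax_d - pmin_d)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * fs + 1L):(r * fs)
    for (ch in seq_len(nch)) {
      d <- round((recording$samples[ch, idx] - pmin_d[ch]) * scale[ch] + dmin)
      writeBin(as.integer(pmin(pmax(d, dmin), dmax)), con, size = 2L,
               endian = "little")
    }
    payload <- rec_ann[[r]]
    writeBin(c(payload, raw(2L * ann_nsamp - length(payload))), con)
  }
  invisible(path)
}

read_edf_field <- function(raw_hdr, offset, width, name, numeric = FALSE) {
  s <- trimws(rawToChar(raw_hdr[(offset + 1):(offset + width)]))
  if (numeric) {
    v <- suppressWarnings(as.numeric(s))
    if (is.na(v)) abort("malformed EDF header field '%s': '%s'", name, s)
    return(v)
  }
  s
}

#' Read an EDF/EDF+ file
#'
#' Supports the continuous 16-bit subset produced by [write_edf()]:
#' uniform digital range per signal, optional "EDF Annotations" signal
#' parsed into trial annotations.
#'
#' @param path EDF file path.
#' @return an `eeg_recording`.
#' @export
read_edf <- function(path) {
  sz <- file.info(path)$size
  if (is.na(sz) || sz < 256) abort("not an EDF file (shorter than one header)")
  con <- file(path, "rb")
  on.exit(close(con))
  h <- readBin(con, "raw", 256L)
  patient <- read_edf_field(h, 8, 80, "patient")
  hdr_bytes <- read_edf_field(h, 184, 8, "header bytes", numeric = TRUE)
  n_rec <- read_edf_field(h, 236, 8, "number of data records", numeric = TRUE)
  rec_dur <- read_edf_field(h, 244, 8, "record duration", numeric = TRUE)
  ns <- read_edf_field(h, 252, 4, "number of signals", numeric = TRUE)
  if (hdr_bytes != 256 * (ns + 1))
    abort("malformed EDF header field 'header bytes': %g (expected %g)",
          hdr_bytes, 256 * (ns + 1))
  sh <- readBin(con, "raw", 256L * ns)
  if (length(sh) < 256L * ns) abort("truncated EDF file: signal headers missing")
  fld <- function(base, width, name, numeric = FALSE)
    vapply(seq_len(ns), function(i)
      read_edf_field(sh, base * ns + (i - 1) * width, width,
                     name, numeric = numeric),
      if (numeric) numeric(1) else character(1))
  labels <- fld(0, 16, "label")
  pmin_d <- fld(96 + 8, 8, "physical minimum", numeric = TRUE)
  pmax_d <- fld(96 + 16, 8, "physical maximum", numeric = TRUE)
  dmin <- fld(96 + 24, 8, "digital minimum", numeric = TRUE)
  dmax <- fld(96 + 32, 8, "digital maximum", numeric = TRUE)
  nsamp <- fld(96 + 40 + 80, 8, "samples per record", numeric = TRUE)

  is_ann <- labels == "EDF Annotations"
  rec_words <- sum(nsamp)
  expected <- hdr_bytes + 2 * rec_words * n_rec
  if (sz < expected)
    abort("truncated EDF file: %g bytes, expected %g", sz, expected)

  data <- readBin(con, "integer", n = rec_words * n_rec, size = 2L,
                  signed = TRUE, endian = "little")
  sig_idx <- which(!is_ann)
  fs <- nsamp[sig_idx][1] / rec_dur
  samples <- matrix(0, length(sig_idx), nsamp[sig_idx][1] * n_rec)
  ann_text <- character(0)
  offs <- cumsum(c(0, nsamp))
  for (r in seq_len(n_rec)) {
    base <- (r - 1) * rec_words
    for (k in seq_along(sig_idx)) {
      i <- sig_idx[k]
      d <- data[(base + offs[i] + 1):(base + offs[i] + nsamp[i])]
      g <- (pmax_d[i] - pmin_d[i]) / (dmax[i] - dmin[i])
      samples[k, ((r - 1) * nsamp[i] + 1):(r * nsamp[i])] <-
        (d - dmin[i]) * g + pmin_d[i]
    }
    for (i in which(is_ann)) {
      words <- data[(base + offs[i] + 1):(base + offs[i] + nsamp[i])] %% 65536L
      bytes <- as.raw(as.vector(rbind(words %% 256L, words %/% 256L)))
      ann_text <- c(ann_text, rawToChar(bytes[bytes != as.raw(0)]))
    }
  }
  ann <- parse_tals(ann_text)
  new_recording(participant_id = patient,
                channel_labels = labels[sig_idx],
                sampling_rate = fs, samples = samples, annotations = ann)
}

# Parse TAL strings into an annotation data.frame. A part starting with
# +/- opens a new onset[/duration]; any following non-empty part is a label
# at that onset. Timekeeping TALs (no label) are dropped.
parse_tals <- function(chunks) {
  onset <- dur <- numeric(0); lab <- character(0)
  for (chunk in chunks) {
    cur_on <- NA_real_; cur_dur <- 0
    for (p in strsplit(chunk, "\x14", fixed = TRUE)[[1]]) {
      if (!nzchar(p)) next
      if (grepl("^[+-][0-9.]", p)) {
        od <- strsplit(p, "\x15", fixed = TRUE)[[1]]
        cur_on <- as.numeric(od[1])
        cur_dur <- if (length(od) > 1) as.numeric(od[2]) else 0
      } else if (!is.na(cur_on)) {
        onset <- c(onset, cur_on); dur <- c(dur, cur_dur); lab <- c(lab, p)
      }
    }
  }
  data.frame(onset = onset, duration = dur, label = lab)
}
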