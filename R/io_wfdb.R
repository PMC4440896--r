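# WFDB (PhysioNet) reader/writer, MIT-BIH dialect.
# Supported signal storage: format 212 (packed 12-bit pairs) and format 16
# (16-bit little-endian); anything else is rejected explicitly.

# MIT annotation code -> mnemonic (beat and common non-beat codes).
.WFDB_ANN_CODES <- c(
  "1" = "N", "2" = "L", "3" = "R", "4" = "a", "5" = "V", "6" = "F",
  "7" = "J", "8" = "A", "9" = "S", "10" = "E", "11" = "j", "12" = "/",
  "13" = "Q", "14" = "~", "16" = "|", "18" = "s", "19" = "T", "20" = "*",
  "21" = "D", "22" = '"', "23" = "=", "24" = "p", "25" = "B", "26" = "^",
  "27" = "t", "28" = "+", "29" = "u", "30" = "?", "31" = "!", "32" = "[",
  "33" = "]", "34" = "e", "35" = "n", "36" = "@", "37" = "x", "38" = "f",
  "39" = "(", "40" = ")", "41" = "r"
)

.parse_hea_signal_line <- function(line, record_dir) {
  tok <- strsplit(trimws(line), "[ \t]+")[[1L]]
  if (length(tok) < 2L) stop("WFDB header: malformed signal line: ", line)
  fmt_tok <- tok[2L]
  fmt <- sub("^([0-9]+).*$", "\\1", fmt_tok)
  gain <- 200; baseline <- NA_real_; adc_zero <- 0; adc_res <- NA_integer_
  if (length(tok) >= 3L) {
    g <- tok[3L]
    g <- sub("/.*$", "", g)            # strip units
    if (grepl("\\(", g)) {
      baseline <- as.numeric(sub("^.*\\(([-0-9]+)\\).*$", "\\1", g))
      g <- sub("\\(.*$", "", g)
    }
    gv <- suppressWarnings(as.numeric(g))
    if (is.finite(gv) && gv != 0) gain <- gv
  }
  if (length(tok) >= 4L) adc_res <- suppressWarnings(as.integer(tok[4L]))
  if (length(tok) >= 5L) {
    z <- suppressWarnings(as.numeric(tok[5L]))
    if (is.finite(z)) adc_zero <- z
  }
  if (is.na(baseline)) baseline <- adc_zero
  list(file = file.path(record_dir, tok[1L]), format = fmt, gain = gain,
       baseline = baseline, adc_res = adc_res)
}

.decode_fmt212 <- function(raw_bytes, n_values) {
  b <- as.integer(raw_bytes)
  n_triplets <- length(b) %/% 3L
  b <- b[seq_len(3L * n_triplets)]
  b0 <- b[seq(1L, by = 3L, length.out = n_triplets)]
  b1 <- b[seq(2L, by = 3L, length.out = n_triplets)]
  b2 <- b[seq(3L, by = 3L, length.out = n_triplets)]
  s1 <- b0 + bitwShiftL(bitwAnd(b1, 0x0FL), 8L)
  s2 <- b2 + bitwShiftL(bitwShiftR(b1, 4L), 8L)
  # 12-bit two's complement
  s1 <- ifelse(s1 > 2047L, s1 - 4096L, s1)
  s2 <- ifelse(s2 > 2047L, s2 - 4096L, s2)
  out <- as.vector(rbind(s1, s2))
  out[seq_len(min(n_values, length(out)))]
}

.decode_fmt16 <- function(raw_bytes, n_values) {
  v <- readBin(raw_bytes, what = "integer", size = 2L, n = n_values,
               signed = TRUE, endian = "little")
  v
}

#' Read a WFDB record (MIT-BIH dialect)
#'
#' Parses a PhysioNet `.hea`/`.dat` pair (and, when present, the binary
#' `.atr` annotation file) and returns the first signal channel converted to
#' millivolts via the header gain and baseline:
#' `amplitude_mV = (raw - baseline) / gain`. Storage formats 212 and 16 are
#' supported; other formats raise an explicit unsupported-format error.
#'
#' @param path Record path without extension (e.g. `"data/100"`).
#' @return A list with elements `record` (an [ecg_record]) and
#'   `annotations` (a [beat_annotations] data frame, empty when no `.atr`
#'   file exists). Annotation indices are 0-based.
#' @seealso [write_wfdb()]
#' @export
read_wfdb <- function(path) {
  hea <- paste0(path, ".hea")
  if (!file.exists(hea)) stop("WFDB format error: missing header file ", hea)
  lines <- readLines(hea, warn = FALSE)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (!length(lines)) stop("WFDB format error: empty header ", hea)
  head_tok <- strsplit(trimws(lines[1L]), "[ \t]+")[[1L]]
  if (length(head_tok) < 2L) {
    stop("WFDB format error: record line lacks signal count in ", hea)
  }
  record_id <- sub("/.*$", "", head_tok[1L])
  n_sig <- suppressWarnings(as.integer(head_tok[2L]))
  if (is.na(n_sig) || n_sig < 1L) {
    stop("WFDB format error: bad signal count field '", head_tok[2L], "'")
  }
  fs <- if (length(head_tok) >= 3L) suppressWarnings(as.numeric(sub("/.*$", "", head_tok[3L]))) else 250
  if (!is.finite(fs) || fs <= 0) {
    stop("WFDB format error: bad sampling frequency field '", head_tok[3L], "'")
  }
  n_samp <- if (length(head_tok) >= 4L) suppressWarnings(as.numeric(head_tok[4L])) else NA_real_
  if (length(lines) < 1L + n_sig) {
    stop("WFDB format error: header declares ", n_sig,
         " signals but has ", length(lines) - 1L, " signal lines")
  }
  sig <- .parse_hea_signal_line(lines[2L], dirname(path))
  if (!sig$format %in% c("212", "16")) {
    stop("WFDB unsupported-format error: storage format ", sig$format,
         " not supported (only 212 and 16)")
  }
  if (!file.exists(sig$file)) {
    stop("WFDB format error: missing signal file ", sig$file)
  }
  raw_bytes <- readBin(sig$file, what = "raw", n = file.info(sig$file)$size)
  total_vals <- if (is.finite(n_samp)) n_samp * n_sig else Inf
  vals <- switch(sig$format,
    "212" = .decode_fmt212(raw_bytes, total_vals),
    "16"  = .decode_fmt16(raw_bytes, min(total_vals, length(raw_bytes) %/% 2L))
  )
  # de-interleave: channel 0 only
  ch0 <- vals[seq(1L, length(vals), by = n_sig)]
  if (is.finite(n_samp)) ch0 <- ch0[seq_len(min(n_samp, length(ch0)))]
  mv <- (ch0 - sig$baseline) / sig$gain
  rec <- ecg_record(mv, fs = fs, record_id = record_id, lead = "ch0",
                    adc_resolution_bits = if (is.na(sig$adc_res)) NULL else sig$adc_res)
  atr <- paste0(path, ".atr")
  ann <- if (file.exists(atr)) .read_atr(atr, n_samples(rec)) else
    beat_annotations(integer(0))
  list(record = rec, annotations = ann)
}

# MIT annotation file: stream of 16-bit little-endian words,
# code = word >> 10, time increment = word & 0x3FF; (0,0) terminates.
.read_atr <- function(path, n_samples_rec = NULL) {
  raw_bytes <- readBin(path, what = "raw", n = file.info(path)$size)
  words <- readBin(raw_bytes, what = "integer", size = 2L,
                   n = length(raw_bytes) %/% 2L, signed = FALSE,
                   endian = "little")
  idx <- integer(0); lab <- character(0)
  t_cur <- 0; i <- 1L
  while (i <= length(words)) {
    w <- words[i]
    code <- bitwShiftR(w, 10L)
    tinc <- bitwAnd(w, 0x3FFL)
    if (code == 0L && tinc == 0L) break
    if (code == 59L) {            # SKIP: 4-byte interval in next two words
      if (i + 2L > length(words)) break
      interval <- bitwShiftL(words[i + 1L], 16L) + words[i + 2L]
      t_cur <- t_cur + interval
      i <- i + 3L
      next
    }
    if (code %in% c(60L, 61L, 62L)) {   # NUM / SUB / CHN modifiers
      i <- i + 1L
      next
    }
    if (code == 63L) {            # AUX: tinc = byte count, padded to even
      i <- i + 1L + (tinc + tinc %% 2L) %/% 2L
      next
    }
    t_cur <- t_cur + tinc
    idx <- c(idx, t_cur)
    key <- as.character(code)
    lab <- c(lab, if (key %in% names(.WFDB_ANN_CODES)) .WFDB_ANN_CODES[[key]] else key)
    i <- i + 1L
  }
  keep <- if (is.null(n_samples_rec)) rep(TRUE, length(idx)) else idx < n_samples_rec
  # guard: duplicate times would break strict monotonicity
  ok <- keep & !duplicated(idx)
  beat_annotations(idx[ok], label = lab[ok], source = "reference")
}

#' Write a WFDB record (format 16, single channel)
#'
#' Emits a `.hea`/`.dat` pair readable by [read_wfdb()] and by standard WFDB
#' tools. Samples are quantized with the given gain (default 200 adu/mV,
#' the MIT-BIH convention); quantization error is bounded by `1/(2*gain)` mV.
#'
#' @param record An [ecg_record].
#' @param path Output record path without extension.
#' @param gain ADC gain in adu/mV.
#' @param adc_zero ADC zero level (also used as baseline).
#' @return Invisibly, `path`.
#' @export
write_wfdb <- function(record, path, gain = 200, adc_zero = 0) {
  stopifnot(inherits(record, "ecg_record"))
  raw_vals <- as.integer(round(record$samples * gain + adc_zero))
  if (any(raw_vals > 32767L | raw_vals < -32768L)) {
    stop("write_wfdb: sample out of 16-bit range at this gain")
  }
  dat <- paste0(path, ".dat")
  hea <- paste0(path, ".hea")
  con <- file(dat, "wb")
  on.exit(close(con))
  writeBin(raw_vals, con, size = 2L, endian = "little")
  bits <- if (is.null(record$adc_resolution_bits)) 16L else record$adc_resolution_bits
  writeLines(c(
    sprintf("%s 1 %g %d", record$record_id, record$fs, n_samples(record)),
    sprintf("%s 16 %g(%d)/mV %d %d 0 0 0 %s",
            basename(dat), gain, as.integer(adc_zero), bits,
            as.integer(adc_zero), record$lead)
  ), hea)
  invisible(path)
}
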