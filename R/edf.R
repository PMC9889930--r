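# Minimal European Data Format (EDF) support: fixed 256-byte main header,
# 256 bytes of per-signal header fields, 16-bit little-endian samples.
# The whole recording is written as a single data record; physical ranges are
# symmetric per channel (+/- max|value|), which maximizes the 16-bit
# quantization resolution.

DIG_MAX <- 32767L

pad_field <- function(s, width) {
  s <- as.character(s)
  raw_s <- charToRaw(s)
  if (length(raw_s) > width) raw_s <- raw_s[seq_len(width)]
  c(raw_s, rep(charToRaw(" "), width - length(raw_s)))
}

num_field <- function(x, width) {
  s <- formatC(x, width = 1, format = "g", digits = 8)
  if (nchar(s) > width) s <- formatC(x, width = 1, format = "g", digits = 4)
  pad_field(s, width)
}

write_edf <- function(rec, path) {
  ns <- length(rec$channels)
  n <- length(rec$data[[1L]])
  header_bytes <- 256L + 256L * ns
  duration <- n / rec$sampling_rate

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(pad_field("0", 8L), con)
  writeBin(pad_field(rec$subject_id, 80L), con)
  writeBin(pad_field("eegdr recording", 80L), con)
  writeBin(pad_field("01.01.00", 8L), con)
  writeBin(pad_field("00.00.00", 8L), con)
  writeBin(num_field(header_bytes, 8L), con)
  writeBin(pad_field("", 44L), con)
  writeBin(num_field(1L, 8L), con)          # one data record
  writeBin(num_field(duration, 8L), con)
  writeBin(num_field(ns, 4L), con)

  # The physical range is stored as 8 ASCII chars (incl. sign); quantize it
  # upward to 6 significant digits and scale with the exact stored value so
  # the round-trip error stays within one digital step.
  pmax_ch <- vapply(rec$data, function(v) {
    p <- max(abs(v), 1e-12)
    q <- signif(p, 6)
    if (q < p) q <- q + 10^(floor(log10(p)) - 5)
    q
  }, numeric(1))
  for (ch in rec$channels) writeBin(pad_field(ch, 16L), con)
  for (i in seq_len(ns)) writeBin(pad_field("", 80L), con)          # transducer
  for (i in seq_len(ns)) writeBin(pad_field("uV", 8L), con)
  for (i in seq_len(ns)) writeBin(num_field(-pmax_ch[i], 8L), con)  # phys min
  for (i in seq_len(ns)) writeBin(num_field(pmax_ch[i], 8L), con)   # phys max
  for (i in seq_len(ns)) writeBin(num_field(-DIG_MAX, 8L), con)
  for (i in seq_len(ns)) writeBin(num_field(DIG_MAX, 8L), con)
  for (i in seq_len(ns)) writeBin(pad_field("", 80L), con)          # prefilter
  for (i in seq_len(ns)) writeBin(num_field(n, 8L), con)
  for (i in seq_len(ns)) writeBin(pad_field("", 32L), con)

  for (i in seq_len(ns)) {
    dig <- as.integer(round(rec$data[[i]] / pmax_ch[i] * DIG_MAX))
    writeBin(dig, con, size = 2L, endian = "little")
  }
  invisible(path)
}

read_edf_field <- function(con, width) {
  trimws(rawToChar(readBin(con, "raw", n = width)))
}

read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  version <- read_edf_field(con, 8L)
  if (version != "0") stop("not an EDF file (bad version field)", call. = FALSE)
  subject_id <- read_edf_field(con, 80L)
  read_edf_field(con, 80L)  # recording id
  read_edf_field(con, 8L); read_edf_field(con, 8L)  # date, time
  read_edf_field(con, 8L)   # header bytes
  read_edf_field(con, 44L)
  n_records <- as.integer(read_edf_field(con, 8L))
  duration <- as.numeric(read_edf_field(con, 8L))
  ns <- as.integer(read_edf_field(con, 4L))
  if (is.na(ns) || ns < 1L) stop("EDF: invalid signal count", call. = FALSE)

  labels <- vapply(seq_len(ns), function(i) read_edf_field(con, 16L), character(1))
  for (i in seq_len(ns)) read_edf_field(con, 80L)
  for (i in seq_len(ns)) read_edf_field(con, 8L)
  phys_min <- vapply(seq_len(ns), function(i) as.numeric(read_edf_field(con, 8L)), numeric(1))
  phys_max <- vapply(seq_len(ns), function(i) as.numeric(read_edf_field(con, 8L)), numeric(1))
  dig_min <- vapply(seq_len(ns), function(i) as.numeric(read_edf_field(con, 8L)), numeric(1))
  dig_max <- vapply(seq_len(ns), function(i) as.numeric(read_edf_field(con, 8L)), numeric(1))
  for (i in seq_len(ns)) read_edf_field(con, 80L)
  spr <- vapply(seq_len(ns), function(i) as.integer(read_edf_field(con, 8L)), integer(1))
  for (i in seq_len(ns)) read_edf_field(con, 32L)

  data <- stats::setNames(vector("list", ns), labels)
  for (r in seq_len(n_records)) {
    for (i in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[i], size = 2L, endian = "little",
                     signed = TRUE)
      phys <- phys_min[i] + (dig - dig_min[i]) *
        (phys_max[i] - phys_min[i]) / (dig_max[i] - dig_min[i])
      data[[i]] <- c(data[[i]], phys)
    }
  }
  fs <- spr[1L] * n_records / (duration * n_records)
  eeg_recording(data, sampling_rate = fs,
                subject_id = if (nzchar(subject_id)) subject_id else "subject")
}
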