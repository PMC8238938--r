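# Minimal WFDB (header + format-16 signal) I/O for intrapartum archives.
#
# Only what the CTU-UHB dialect needs: one .hea file, one interleaved
# little-endian int16 .dat file, gain/baseline per channel, channel
# descriptions naming FHR and UC.

parse_wfdb_header <- function(hea_path) {
  lines <- readLines(hea_path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 2L) rlang::abort(sprintf("WFDB header %s is empty.", hea_path))
  top <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  record <- top[1]
  nsig <- as.integer(top[2])
  fs <- if (length(top) >= 3) as.numeric(top[3]) else 250
  nsamp <- if (length(top) >= 4) as.integer(top[4]) else NA_integer_
  sig <- lapply(lines[1 + seq_len(nsig)], function(line) {
    f <- strsplit(trimws(line), "\\s+")[[1]]
    fmt <- sub("x.*$", "", sub(":.*$", "", sub("\\+.*$", "", f[2])))
    gain_field <- if (length(f) >= 3) f[3] else "200"
    units <- sub("^[^/]*/?", "", gain_field)
    gain_num <- sub("/.*$", "", gain_field)
    baseline <- NA_real_
    if (grepl("\\(", gain_num)) {
      baseline <- as.numeric(sub("^.*\\(([-0-9.]+)\\).*$", "\\1", gain_num))
      gain_num <- sub("\\(.*$", "", gain_num)
    }
    gain <- as.numeric(gain_num)
    if (!is.finite(gain) || gain == 0) gain <- 200
    adc_zero <- if (length(f) >= 5) suppressWarnings(as.numeric(f[5])) else 0
    if (!is.finite(adc_zero)) adc_zero <- 0
    if (!is.finite(baseline)) baseline <- adc_zero
    desc <- if (length(f) >= 9) paste(f[9:length(f)], collapse = " ") else ""
    list(
      file = f[1], format = fmt, gain = gain, baseline = baseline,
      units = units, description = desc
    )
  })
  list(record = record, nsig = nsig, fs = fs, nsamp = nsamp, signals = sig)
}

#' Read a CTG record stored in WFDB format
#'
#' Reads a WFDB header/signal pair (the dialect used by the public CTU-UHB
#' intrapartum database: interleaved little-endian 16-bit samples, format
#' 16) and returns the FHR and UC channels as a [ctg_trace()]. Channels
#' are matched by a description containing "FHR" or "UC"
#' (case-insensitive). Digital values are converted to physical units via
#' each channel's gain and baseline; zero FHR samples -- the archive's
#' dropout convention -- are marked invalid by the trace constructor.
#'
#' @param path Path to the record, with or without the `.hea` extension.
#' @return A [ctg_trace()] at the header's sampling rate.
#' @export
read_wfdb_record <- function(path) {
  hea_path <- if (grepl("\\.hea$", path)) path else paste0(path, ".hea")
  hdr <- parse_wfdb_header(hea_path)
  fmts <- vapply(hdr$signals, `[[`, "", "format")
  if (!all(fmts == "16")) {
    rlang::abort(sprintf(
      "Only WFDB format 16 is supported (header declares: %s).",
      paste(unique(fmts), collapse = ", ")
    ))
  }
  descs <- vapply(hdr$signals, `[[`, "", "description")
  find_channel <- function(key) {
    hit <- grep(key, descs, ignore.case = TRUE)
    if (length(hit) == 0L) {
      rlang::abort(sprintf(
        "No channel description matches '%s'; available channels: %s.",
        key, paste(sprintf("'%s'", descs), collapse = ", ")
      ))
    }
    hit[1]
  }
  i_fhr <- find_channel("FHR")
  i_uc <- find_channel("UC")
  dat_path <- file.path(dirname(hea_path), hdr$signals[[1]]$file)
  n_bytes <- file.info(dat_path)$size
  raw_vals <- readBin(
    dat_path, what = "integer", n = n_bytes %/% 2L,
    size = 2L, signed = TRUE, endian = "little"
  )
  n_frames <- length(raw_vals) %/% hdr$nsig
  m <- matrix(raw_vals[seq_len(n_frames * hdr$nsig)], nrow = hdr$nsig)
  to_physical <- function(i) {
    s <- hdr$signals[[i]]
    (m[i, ] - s$baseline) / s$gain
  }
  ctg_trace(
    fhr = to_physical(i_fhr), uc = to_physical(i_uc), fs = hdr$fs,
    meta = list(record = hdr$record, source = hea_path)
  )
}

#' Write a trace as a WFDB format-16 record
#'
#' Companion writer used to build round-trip fixtures and to export
#' simulated records in the CTU-UHB dialect. Physical values are
#' quantized to `round(value * gain)` 16-bit integers (baseline 0).
#'
#' @param trace A [ctg_trace()].
#' @param path Record path without extension; `.hea` and `.dat` are added.
#' @param gain ADC gain applied to both channels (units per physical unit).
#' @return `path` invisibly.
#' @export
write_wfdb_record <- function(trace, path, gain = 100) {
  assert_ctg_trace(trace)
  record <- basename(path)
  n <- nrow(trace)
  dig <- function(x) {
    x[!is.finite(x)] <- 0
    as.integer(pmax(pmin(round(x * gain), 32767), -32768))
  }
  interleaved <- as.vector(rbind(dig(trace$fhr_bpm), dig(trace$uc_units)))
  writeBin(interleaved, paste0(path, ".dat"), size = 2L, endian = "little")
  hea <- c(
    sprintf("%s 2 %g %d", record, ctg_fs(trace), n),
    sprintf("%s.dat 16 %g(0)/bpm 16 0 0 0 0 FHR", record, gain),
    sprintf("%s.dat 16 %g(0)/nd 16 0 0 0 0 UC", record, gain)
  )
  writeLines(hea, paste0(path, ".hea"))
  invisible(path)
}
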