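#' Read a PCM WAV file
#'
#' Minimal RIFF/WAVE reader for uncompressed audio. Integer PCM (8, 16, 24 or
#' 32 bit) and IEEE float (32 or 64 bit) data are supported; anything else
#' (e.g. ADPCM, mu-law) raises an unsupported-format error. Samples are
#' normalized to `[-1, 1]` doubles and multi-channel files are averaged to a
#' single mono waveform.
#'
#' @param path Path to a `.wav` file.
#' @return A list with elements `sample_rate` (Hz), `waveform` (numeric vector
#'   in `[-1, 1]`), `n_channels` (channel count before mono mixdown) and
#'   `bits` (bits per sample in the file).
#' @seealso [write_wav()]
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) stop("WAV file not found: ", path)
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 44 ||
      rawToChar(raw[1:4]) != "RIFF" || rawToChar(raw[9:12]) != "WAVE") {
    stop("not a RIFF/WAVE file: ", path)
  }

  u16 <- function(at) readBin(raw[at:(at + 1L)], "integer", size = 2,
                              signed = FALSE, endian = "little")
  u32 <- function(at) {
    b <- as.integer(raw[at:(at + 3L)])
    b[1] + b[2] * 256 + b[3] * 65536 + b[4] * 16777216
  }

  # walk chunks after the 12-byte RIFF header
  pos <- 13L
  fmt <- NULL
  data_raw <- NULL
  while (pos + 7L <= length(raw)) {
    id <- rawToChar(raw[pos:(pos + 3L)])
    sz <- u32(pos + 4L)
    body_at <- pos + 8L
    if (id == "fmt ") {
      fmt <- list(
        format     = u16(body_at),
        channels   = u16(body_at + 2L),
        rate       = u32(body_at + 4L),
        bits       = u16(body_at + 14L)
      )
    } else if (id == "data") {
      data_raw <- if (sz > 0) raw[body_at:(body_at + sz - 1L)] else raw(0)
    }
    pos <- body_at + sz + (sz %% 2L)  # chunks are word-aligned
  }
  if (is.null(fmt)) stop("WAV file has no fmt chunk: ", path)
  if (is.null(data_raw)) stop("WAV file has no data chunk: ", path)
  if (!fmt$format %in% c(1L, 3L)) {
    stop("unsupported WAV format code ", fmt$format,
         " (only PCM = 1 and IEEE float = 3 are supported)")
  }

  x <- if (fmt$format == 3L) {
    if (!fmt$bits %in% c(32L, 64L)) stop("float WAV must be 32 or 64 bit")
    readBin(data_raw, "double", size = fmt$bits / 8L,
            n = length(data_raw) / (fmt$bits / 8L), endian = "little")
  } else if (fmt$bits == 8L) {
    # 8-bit PCM is unsigned
    (as.integer(readBin(data_raw, "raw", n = length(data_raw))) - 128) / 128
  } else if (fmt$bits == 16L) {
    readBin(data_raw, "integer", size = 2, signed = TRUE,
            n = length(data_raw) / 2L, endian = "little") / 32768
  } else if (fmt$bits == 24L) {
    b <- as.integer(data_raw)
    n <- length(b) %/% 3L
    v <- b[seq(1L, 3L * n, 3L)] + b[seq(2L, 3L * n, 3L)] * 256 +
      b[seq(3L, 3L * n, 3L)] * 65536
    v <- ifelse(v >= 8388608, v - 16777216, v)
    v / 8388608
  } else if (fmt$bits == 32L) {
    readBin(data_raw, "integer", size = 4,
            n = length(data_raw) / 4L, endian = "little") / 2147483648
  } else {
    stop("unsupported PCM bit depth: ", fmt$bits)
  }

  nch <- fmt$channels
  if (nch > 1L) {
    n <- length(x) %/% nch
    x <- rowMeans(matrix(x[seq_len(n * nch)], ncol = nch, byrow = TRUE))
  }
  list(sample_rate = fmt$rate, waveform = x, n_channels = nch,
       bits = fmt$bits)
}

#' Write a mono waveform as 16-bit PCM WAV
#'
#' Values outside `[-1, 1]` are clipped before quantization.
#'
#' @param waveform Numeric vector of samples in `[-1, 1]`.
#' @param sample_rate Sampling rate in Hz.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(waveform, sample_rate, path) {
  stopifnot(is.numeric(waveform), sample_rate > 0)
  x <- pmin(1, pmax(-1, waveform))
  pcm <- as.integer(round(x * 32767))
  n_bytes <- length(pcm) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  w32 <- function(v) writeBin(as.integer(v), con, size = 4, endian = "little")
  w16 <- function(v) writeBin(as.integer(v), con, size = 2, endian = "little")
  writeChar("RIFF", con, eos = NULL); w32(36L + n_bytes)
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL); w32(16L)
  w16(1L); w16(1L)                     # PCM, mono
  w32(sample_rate); w32(sample_rate * 2L)
  w16(2L); w16(16L)                    # block align, bits
  writeChar("data", con, eos = NULL); w32(n_bytes)
  if (length(pcm)) writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}
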