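#' Peak frequency of a waveform segment
#'
#' The segment is windowed (Hann by default), zero-padded to `pad_factor`
#' times the next power of two, and Fourier-transformed; the returned value is
#' the frequency of the largest-magnitude bin inside `[fmin, fmax]`, refined
#' by three-point parabolic interpolation on the magnitude spectrum. The DC
#' bin is eligible when `fmin = 0` (a constant segment peaks at 0 Hz).
#'
#' @param segment Numeric waveform samples (length >= 2).
#' @param sample_rate Sampling rate in Hz.
#' @param window `"hann"` or `"rectangular"`.
#' @param pad_factor Zero-padding multiple of the next power of two
#'   (default 4).
#' @param fmin,fmax Analysis band in Hz; defaults 0 and Nyquist. Raising
#'   `fmin` (e.g. to 100 Hz) suppresses low-frequency recording noise.
#' @return Peak frequency in Hz, or `NA` for an all-zero segment. The
#'   spectrum parameters used are attached as attribute `params`.
#' @export
peak_frequency <- function(segment, sample_rate, window = c("hann", "rectangular"),
                           pad_factor = 4, fmin = 0, fmax = NULL) {
  window <- match.arg(window)
  n <- length(segment)
  if (n < 2) stop("segment must have >= 2 samples")
  if (is.null(fmax)) fmax <- sample_rate / 2
  if (all(segment == 0)) {
    return(structure(NA_real_, params = list(window = window, n = n,
                                             pad_factor = pad_factor)))
  }
  w <- if (window == "hann") {
    0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))
  } else rep(1, n)
  nfft <- pad_factor * 2^ceiling(log2(n))
  x <- c(segment * w, rep(0, nfft - n))
  mag <- Mod(fft(x))[1:(nfft %/% 2 + 1)]
  freqs <- (seq_along(mag) - 1) * sample_rate / nfft
  band <- which(freqs >= fmin & freqs <= fmax)
  if (!length(band)) stop("empty analysis band [", fmin, ", ", fmax, "] Hz")
  k <- band[which.max(mag[band])]
  # parabolic refinement on the raw magnitude; skip at spectrum edges
  delta <- 0
  if (k > 1 && k < length(mag)) {
    a <- mag[k - 1]; b <- mag[k]; c <- mag[k + 1]
    den <- a - 2 * b + c
    if (den < 0) delta <- 0.5 * (a - c) / den
  }
  structure((k - 1 + delta) * sample_rate / nfft,
            params = list(window = window, n = n, nfft = nfft,
                          pad_factor = pad_factor, fmin = fmin, fmax = fmax))
}

#' Extract per-element peak frequencies from an annotated recording
#'
#' Cuts each annotated element out of the waveform and measures its peak
#' frequency. By default the analysis band starts at 100 Hz to suppress
#' low-frequency recording noise; set `fmin = 0` to make the DC bin eligible.
#'
#' @param waveform Mono waveform in `[-1, 1]` (see [read_wav()]).
#' @param sample_rate Sampling rate in Hz.
#' @param annotations Element annotations (see [read_annotations()]); onsets
#'   and offsets must lie inside the recording.
#' @param fmin Lower edge of the analysis band in Hz (default 100).
#' @param ... Passed on to [peak_frequency()].
#' @return data.frame: `recording_id`, `species`, `onset_s`, `offset_s`,
#'   `peak_hz`.
#' @export
extract_peak_frequencies <- function(waveform, sample_rate, annotations,
                                     fmin = 100, ...) {
  validate_annotations(annotations)
  dur <- length(waveform) / sample_rate
  bad <- which(annotations$onset_s < 0 | annotations$offset_s > dur + 1e-9)
  if (length(bad)) {
    stop("element(s) outside the recording at row(s) ",
         paste(bad, collapse = ", "))
  }
  peaks <- vapply(seq_len(nrow(annotations)), function(i) {
    from <- max(1L, floor(annotations$onset_s[i] * sample_rate) + 1L)
    to <- min(length(waveform), ceiling(annotations$offset_s[i] * sample_rate))
    as.numeric(peak_frequency(waveform[from:to], sample_rate,
                              fmin = fmin, ...))
  }, 0)
  data.frame(annotations[c("recording_id", "species", "onset_s", "offset_s")],
             peak_hz = peaks, stringsAsFactors = FALSE, row.names = NULL)
}

#' Per-recording mean peak frequency
#'
#' For within-community analyses each recording is one sample: the arithmetic
#' mean of its element peak frequencies per (recording, species).
#'
#' @param spectra data.frame from [extract_peak_frequencies()].
#' @return data.frame: `recording_id`, `species`, `n_elements`,
#'   `mean_peak_hz`.
#' @export
summarize_recordings <- function(spectra) {
  stopifnot(all(c("recording_id", "species", "peak_hz") %in% names(spectra)))
  agg <- aggregate(peak_hz ~ recording_id + species, data = spectra,
                   FUN = mean)
  cnt <- aggregate(peak_hz ~ recording_id + species, data = spectra,
                   FUN = length)
  out <- merge(agg, cnt, by = c("recording_id", "species"),
               suffixes = c("_mean", "_n"))
  data.frame(recording_id = out$recording_id, species = out$species,
             n_elements = out$peak_hz_n, mean_peak_hz = out$peak_hz_mean,
             stringsAsFactors = FALSE)
}

#' Test frequency partitioning within one multi-species chorus recording
#'
#' Compares per-element peak frequencies of species vocalizing in the same
#' recording (each element is one unit; elements must not overlap in time).
#' Two species: two-tailed Mann-Whitney U test, exact when the combined
#' sample is <= 20 and tie-free, otherwise the tie-corrected normal
#' approximation. More than two: one-way fixed-effects ANOVA, followed by all
#' pairwise pooled-variance t tests with Bonferroni correction (multiplier =
#' number of pairs, capped at 1).
#'
#' @param spectra data.frame from [extract_peak_frequencies()] for a single
#'   recording (one `recording_id`).
#' @param alpha Per-pair significance level after correction (default 0.05).
#' @param min_elements Species with fewer elements are excluded with a
#'   warning (default 2).
#' @return Object of class `chorus_test`: `recording_id`, `method`
#'   (`"mann-whitney"` or `"anova+bonferroni"`), `statistic`, `p` (overall
#'   test), `pairs` (data.frame: `species_i`, `species_j`, `p_raw`, `p_adj`,
#'   `significant`), `excluded` species.
#' @export
compare_chorus <- function(spectra, alpha = 0.05, min_elements = 2) {
  rid <- unique(spectra$recording_id)
  if (length(rid) != 1) {
    stop("compare_chorus works on one recording at a time; got: ",
         paste(rid, collapse = ", "))
  }
  # elements entering one test must not overlap in time
  o <- spectra[order(spectra$onset_s), ]
  if (nrow(o) > 1 && any(o$onset_s[-1] < o$offset_s[-nrow(o)] - 1e-9)) {
    stop("elements overlap in time within recording ", rid,
         "; only non-overlapping elements are statistically comparable")
  }
  counts <- table(spectra$species)
  excluded <- names(counts)[counts < min_elements]
  if (length(excluded)) {
    warning("excluding species with < ", min_elements, " elements: ",
            paste(excluded, collapse = ", "))
    spectra <- spectra[!spectra$species %in% excluded, , drop = FALSE]
  }
  groups <- split(spectra$peak_hz, spectra$species)
  ns <- length(groups)
  if (ns < 2) stop("need >= 2 species with enough elements in recording ", rid)

  if (ns == 2) {
    x <- groups[[1]]; y <- groups[[2]]
    exact <- (length(x) + length(y) <= 20) && !anyDuplicated(c(x, y))
    wt <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = TRUE))
    pairs <- data.frame(species_i = names(groups)[1],
                        species_j = names(groups)[2],
                        p_raw = wt$p.value, p_adj = wt$p.value,
                        significant = wt$p.value < alpha,
                        stringsAsFactors = FALSE)
    res <- list(recording_id = rid, method = "mann-whitney",
                statistic = unname(wt$statistic), p = wt$p.value,
                pairs = pairs, excluded = excluded)
  } else {
    df <- data.frame(f = spectra$peak_hz, sp = factor(spectra$species))
    fit <- aov(f ~ sp, data = df)
    an <- anova(fit)
    cmb <- combn(names(groups), 2)
    n_pairs <- ncol(cmb)
    p_raw <- vapply(seq_len(n_pairs), function(k) {
      t.test(groups[[cmb[1, k]]], groups[[cmb[2, k]]],
             var.equal = TRUE)$p.value
    }, 0)
    p_adj <- pmin(1, p_raw * n_pairs)
    pairs <- data.frame(species_i = cmb[1, ], species_j = cmb[2, ],
                        p_raw = p_raw, p_adj = p_adj,
                        significant = p_adj < alpha,
                        stringsAsFactors = FALSE)
    res <- list(recording_id = rid, method = "anova+bonferroni",
                statistic = an$`F value`[1], p = an$`Pr(>F)`[1],
                pairs = pairs, excluded = excluded)
  }
  structure(res, class = "chorus_test")
}

#' @export
print.chorus_test <- function(x, ...) {
  cat("Chorus frequency partitioning, recording ", x$recording_id,
      " (", x$method, ")\n", sep = "")
  cat(sprintf("  overall statistic %.3f, p = %.4g\n", x$statistic, x$p))
  print(x$pairs, row.names = FALSE)
  invisible(x)
}
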