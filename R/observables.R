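#' Canonical EEG frequency bands
#'
#' delta (0.5-4 Hz), theta (4-8 Hz), alpha (8-13 Hz) and beta (13-30 Hz);
#' together they tile the 0.5-30 Hz analysis range.
#'
#' @param names Optional subset of band names to return.
#' @return data.frame with columns `name`, `low`, `high` (Hz).
#' @export
eeg_bands <- function(names = NULL) {
  b <- data.frame(name = c("delta", "theta", "alpha", "beta"),
                  low = c(0.5, 4, 8, 13),
                  high = c(4, 8, 13, 30),
                  stringsAsFactors = FALSE)
  if (!is.null(names)) {
    idx <- match(names, b$name)
    if (anyNA(idx)) stop("unknown band name(s): ",
                         paste(names[is.na(idx)], collapse = ", "))
    b <- b[idx, , drop = FALSE]
  }
  b
}

#' Band-pass filter a signal (3rd-order Bessel, zero-phase)
#'
#' @param x Signal (vector) or time-by-channels matrix.
#' @param fs Sampling rate (Hz).
#' @param band Either a row of [eeg_bands()] (or any list with `low`/`high`)
#'   or a numeric length-2 vector of cut-offs (Hz).
#' @param order Filter order of the analog prototype. Default 3.
#' @return Filtered signal, same shape as `x`.
#' @export
bandpass <- function(x, fs, band, order = 3) {
  w <- if (is.numeric(band)) band else c(band$low, band$high)
  stopifnot(length(w) == 2, w[1] > 0, w[1] < w[2])
  if (w[2] >= fs / 2) stop("upper band edge at or above the Nyquist frequency")
  f <- iir_design(order, w, fs, type = "pass", family = "bessel")
  apply_cols(x, function(col) filtfilt(f$b, f$a, col))
}

apply_cols <- function(x, fun) {
  if (is.matrix(x)) {
    out <- apply(x, 2, fun)
    dimnames(out) <- dimnames(x)
    out
  } else fun(x)
}

#' Amplitude envelope of a band-limited signal
#'
#' Magnitude of the analytic signal followed by a 3rd-order Butterworth
#' high-pass (cut-off 0.5 Hz by default, zero-phase) that removes the
#' envelope's DC level and slow drift.
#'
#' @param x Band-passed signal (vector or time-by-channels matrix).
#' @param fs Sampling rate (Hz).
#' @param highpass High-pass cut-off (Hz); `NULL` skips the filter and
#'   returns the raw envelope.
#' @return Envelope signal, same shape as `x`.
#' @export
envelope <- function(x, fs, highpass = 0.5) {
  one <- function(col) {
    env <- hilbert_envelope(col)
    if (is.null(highpass)) return(env)
    f <- iir_design(3, highpass, fs, type = "high", family = "butterworth")
    filtfilt(f$b, f$a, env)
  }
  apply_cols(x, one)
}

#' Amplitude-envelope-correlation functional connectivity
#'
#' Band-pass (Bessel), Hilbert envelope, 0.5 Hz high-pass, then Pearson
#' correlation between all channel pairs. The first and last `edge` seconds
#' of the envelopes are trimmed before correlating to suppress end effects
#' of the analytic signal.
#'
#' @param x Time-by-channels signal matrix (>= 2 channels).
#' @param fs Sampling rate (Hz).
#' @param band Band specification as in [bandpass()].
#' @param edge Seconds trimmed from each end of the envelopes. Default 1.
#' @return An `fc_matrix`: symmetric correlation matrix with unit diagonal,
#'   attributes `band` and `modality = "EEG-envelope"`.
#' @export
envelope_fc <- function(x, fs, band, edge = 1) {
  stopifnot(is.matrix(x), ncol(x) >= 2)
  if (any(apply(x, 2, sd) == 0))
    stop("constant channel(s) in the input: envelope correlation undefined")
  env <- envelope(bandpass(x, fs, band), fs)
  k <- round(edge * fs)
  if (nrow(env) <= 2 * k + 2) stop("signal too short after edge trimming")
  env <- env[(k + 1):(nrow(env) - k), , drop = FALSE]
  fc_from_series(env, band_tag(band), "EEG-envelope")
}

band_tag <- function(band) {
  if (is.numeric(band)) paste0(band[1], "-", band[2], "Hz")
  else as.character(band$name)
}

fc_from_series <- function(x, band, modality) {
  sds <- apply(x, 2, sd)
  if (any(sds == 0))
    stop("constant channel(s): correlation undefined for column(s) ",
         paste(which(sds == 0), collapse = ", "))
  fc <- stats::cor(x)
  fc <- (fc + t(fc)) / 2
  diag(fc) <- 1
  structure(fc, band = band, modality = modality, class = c("fc_matrix", "matrix"))
}

#' BOLD functional connectivity
#'
#' Band-pass the BOLD series between 0.01 and 0.08 Hz (3rd-order Bessel,
#' zero-phase) and correlate all region pairs.
#'
#' @param x Time-by-regions BOLD matrix.
#' @param tr Repetition time (s). Default 2.08.
#' @param band Pass band (Hz). Default `c(0.01, 0.08)`.
#' @return An `fc_matrix` with `modality = "BOLD"`.
#' @export
bold_fc <- function(x, tr = 2.08, band = c(0.01, 0.08)) {
  stopifnot(is.matrix(x), ncol(x) >= 2)
  fs <- 1 / tr
  if (nrow(x) * tr < 2 / band[1])
    stop("BOLD series too short for ", band[1], " Hz filtering (need >= ",
         round(2 / band[1]), " s)")
  filt <- bandpass(x, fs, band)
  fc_from_series(filt, paste0(band[1], "-", band[2], "Hz"), "BOLD")
}

#' Welch power spectral density
#'
#' Hann-windowed (periodic), mean-detrended segments of `window_sec` seconds
#' with 50% overlap; one-sided density normalisation. With the default 2-s
#' windows the frequency resolution is 0.5 Hz.
#'
#' @param x Signal (vector).
#' @param fs Sampling rate (Hz).
#' @param window_sec Segment length (s). Default 2.
#' @param overlap Fractional overlap. Default 0.5.
#' @return An object of class `psd`: list with `freq` (Hz) and `power`
#'   (density, unit^2/Hz).
#' @export
welch_psd <- function(x, fs, window_sec = 2, overlap = 0.5) {
  nper <- round(window_sec * fs)
  n <- length(x)
  if (n < 2 * nper) stop("signal must be at least twice the window length")
  step <- nper - round(nper * overlap)
  starts <- seq(1, n - nper + 1, by = step)
  k <- 0:(nper - 1)
  w <- 0.5 - 0.5 * cos(2 * pi * k / nper)   # periodic Hann
  scale <- 1 / (fs * sum(w^2))
  nfreq <- nper %/% 2 + 1
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- x[s:(s + nper - 1)]
    seg <- (seg - mean(seg)) * w
    sp <- fft(seg)[1:nfreq]
    acc <- acc + (Mod(sp)^2) * scale
  }
  p <- acc / length(starts)
  # one-sided: double everything except DC and (for even nper) Nyquist
  dbl <- rep(2, nfreq)
  dbl[1] <- 1
  if (nper %% 2 == 0) dbl[nfreq] <- 1
  structure(list(freq = (0:(nfreq - 1)) * fs / nper, power = p * dbl),
            class = "psd")
}

#' Normalised power spectrum
#'
#' Divides a PSD by its maximum so that the peak equals 1 (shape-preserving;
#' ties are preserved).
#'
#' @param psd A `psd` object from [welch_psd()].
#' @return A `psd` object with `max(power) == 1`.
#' @export
normalized_psd <- function(psd) {
  m <- max(psd$power)
  if (m <= 0) stop("cannot normalise an all-zero spectrum")
  psd$power <- psd$power / m
  psd
}

#' Relative band power
#'
#' Integrates the PSD over each requested band (trapezoidal rule) and
#' divides by the integral over `total_range`. When the bands tile the full
#' range the entries sum to 1.
#'
#' @param psd A `psd` object.
#' @param bands A data.frame as returned by [eeg_bands()].
#' @param total_range Normalisation range (Hz). Default `c(0.5, 30)`.
#' @return Named numeric vector of band-power fractions (class
#'   `spectral_vector`).
#' @export
relative_band_power <- function(psd, bands = eeg_bands(),
                                total_range = c(0.5, 30)) {
  if (min(psd$freq) > total_range[1] || max(psd$freq) < total_range[2])
    stop("PSD does not cover the total normalisation range")
  total <- band_integral(psd, total_range[1], total_range[2])
  vals <- mapply(function(lo, hi) {
    v <- band_integral(psd, lo, hi)
    if (is.na(v)) stop("band ", lo, "-", hi, " Hz is empty after discretisation")
    v
  }, bands$low, bands$high)
  structure(as.numeric(vals) / total, names = bands$name,
            class = "spectral_vector")
}

# trapezoidal integral of the PSD between lo and hi, with linear
# interpolation at the band edges so tiling bands sum exactly to the total
band_integral <- function(psd, lo, hi) {
  f <- psd$freq; p <- psd$power
  if (hi <= min(f) || lo >= max(f)) return(NA_real_)
  grid <- sort(unique(c(lo, hi, f[f > lo & f < hi])))
  vals <- approx(f, p, xout = grid)$y
  sum(diff(grid) * (head_(vals) + tail_(vals)) / 2)
}
head_ <- function(x) x[-length(x)]
tail_ <- function(x) x[-1]

#' Dominant frequency of a spectrum
#'
#' Frequency of the global PSD maximum within a search range; ties are
#' broken towards the lower frequency.
#'
#' @param psd A `psd` object.
#' @param range Search range (Hz). Default `c(0.5, 60)`.
#' @return Frequency (Hz).
#' @export
dominant_frequency <- function(psd, range = c(0.5, 60)) {
  keep <- psd$freq >= range[1] & psd$freq <= range[2]
  if (!any(keep)) stop("no PSD bins inside the search range")
  f <- psd$freq[keep]; p <- psd$power[keep]
  f[which.max(p)]   # which.max returns the first (lowest-frequency) maximum
}
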