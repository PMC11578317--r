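# Waveform container, CSV I/O, signal conditioning and beat segmentation.

#' PPG recording container
#'
#' @param times Sample times in seconds: strictly increasing, uniform grid
#'   (within 1e-9 s).
#' @param intensities Transmitted-light intensities (a.u.), finite.
#' @param sampling_rate Hz; inferred from the median time step when `NULL`
#'   (snapped to an integer when within 1e-6).
#' @param subject_id Optional subject identifier.
#' @return Object of class `ppg_record`.
#' @export
ppg_record <- function(times, intensities, sampling_rate = NULL,
                       subject_id = NA_character_) {
  if (length(times) < 2L)
    ppg_stop("a ppg_record needs at least 2 samples", "ppg_parse_error")
  if (length(times) != length(intensities))
    ppg_stop("'times' and 'intensities' must have equal length", "ppg_parse_error")
  if (!all(is.finite(intensities)))
    ppg_stop("'intensities' must be finite", "ppg_parse_error")
  dt <- diff(times)
  if (any(dt <= 0))
    ppg_stop("'times' must be strictly increasing (non-monotone time axis)",
             "ppg_parse_error")
  dt_med <- median(dt)
  if (max(abs(dt - dt_med)) > 1e-9)
    ppg_stop("'times' must lie on a uniform grid (within 1e-9 s)", "ppg_parse_error")
  if (is.null(sampling_rate)) {
    sampling_rate <- 1 / dt_med
    if (abs(sampling_rate - round(sampling_rate)) < 1e-6)
      sampling_rate <- round(sampling_rate)
  }
  structure(list(times = as.numeric(times),
                 intensities = as.numeric(intensities),
                 sampling_rate = sampling_rate,
                 subject_id = subject_id),
            class = "ppg_record")
}

#' @export
print.ppg_record <- function(x, ...) {
  cat(sprintf("<ppg_record> %d samples @ %g Hz (%.2f s), subject %s\n",
              length(x$times), x$sampling_rate,
              length(x$times) / x$sampling_rate, x$subject_id))
  invisible(x)
}

#' Read a PPG waveform CSV
#'
#' Expects a comma-separated file with header columns `time_s` and
#' `intensity` ('.' decimal, UTF-8).
#'
#' @param path File path.
#' @param subject_id Optional subject identifier to attach.
#' @return A [ppg_record()] with the sampling rate inferred from the median
#'   time step.
#' @export
read_ppg_csv <- function(path, subject_id = NA_character_) {
  if (!file.exists(path))
    ppg_stop(sprintf("file not found: %s", path), "ppg_parse_error")
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "intensity")
  miss <- setdiff(need, names(df))
  if (length(miss))
    ppg_stop(sprintf("missing column(s): %s", paste(miss, collapse = ", ")),
             "ppg_parse_error")
  if (nrow(df) < 2L)
    ppg_stop("waveform CSV needs at least 2 rows", "ppg_parse_error")
  ppg_record(df$time_s, df$intensity, subject_id = subject_id)
}

#' Write a PPG waveform CSV (full double precision, round-trips bit-exactly)
#'
#' @param record A [ppg_record()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ppg_csv <- function(record, path) {
  stopifnot(inherits(record, "ppg_record"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("time_s,intensity", con)
  writeLines(sprintf("%.17g,%.17g", record$times, record$intensities), con)
  invisible(path)
}

#' Band-limit a PPG recording (zero-phase spectral projection)
#'
#' Conditioning is a frequency-domain projection: the discrete spectrum is
#' computed, bins outside `band` (including DC, which removes the baseline)
#' are zeroed, and the signal is reconstructed. Being a projection the
#' operation is exactly idempotent and strictly zero-phase. The default
#' 0.5-20 Hz band keeps the beat fundamental (1-3 Hz) and the harmonics that
#' carry the dicrotic notch while suppressing drift and wideband noise.
#'
#' @param record A [ppg_record()].
#' @param band Length-2 passband in Hz, inside (0, sampling_rate/2).
#' @return A conditioned [ppg_record()] on the same grid.
#' @export
condition_signal <- function(record, band = c(0.5, 20)) {
  stopifnot(inherits(record, "ppg_record"))
  nyq <- record$sampling_rate / 2
  if (length(band) != 2L || !all(is.finite(band)) || band[1] <= 0 ||
      band[1] >= band[2] || band[2] >= nyq)
    ppg_stop(sprintf("band must satisfy 0 < low < high < Nyquist (%g Hz)", nyq),
             "ppg_band_error")
  x <- record$intensities
  n <- length(x)
  freqs <- (seq_len(n) - 1) * record$sampling_rate / n
  freqs <- pmin(freqs, record$sampling_rate - freqs)  # two-sided
  X <- fft(x)
  X[freqs < band[1] | freqs > band[2]] <- 0
  y <- Re(fft(X, inverse = TRUE)) / n
  ppg_record(record$times, y, sampling_rate = record$sampling_rate,
             subject_id = record$subject_id)
}

# Beat-boundary troughs. Candidates are local minima of a lightly smoothed
# copy, restricted to the deepest depth band (dicrotic-notch dips sit well
# above the inter-beat troughs and are excluded by depth), thinned to a
# minimum separation deepest-first, then snapped to the deepest sample-level
# local minimum of the raw input nearby so every boundary is a local
# minimum of the signal handed in. Returns sorted indices.
find_troughs <- function(x, min_sep_samples, smooth_samples = 9L,
                         depth_frac = 0.2) {
  s <- moving_average(x, smooth_samples)
  cand <- local_minima(s)
  if (!length(cand)) return(integer())
  cand <- cand[s[cand] <= min(s[cand]) + depth_frac * (max(s) - min(s))]
  cand <- cand[order(s[cand], cand)]
  kept <- integer()
  for (i in cand)
    if (!length(kept) || all(abs(kept - i) >= min_sep_samples))
      kept <- c(kept, i)
  kept <- sort(kept)
  raw_min <- local_minima(x)
  if (!length(raw_min)) return(kept)
  half <- max(smooth_samples, 3L)
  snapped <- vapply(kept, function(i) {
    near <- raw_min[abs(raw_min - i) <= half]
    if (!length(near)) i else near[which.min(x[near])]
  }, 0L)
  sort(unique(snapped))
}

# Does this beat exhibit the double-peak (SP then DP) morphology?
# Tested on a lightly smoothed copy so noise ripple does not vote: the beat
# qualifies if it has >= 2 local maxima with adjacent-valley prominence
# >= prominence_frac of the beat's peak-to-trough span.
is_double_peak <- function(x, prominence_frac = 0.1, smooth_samples = 9L) {
  x <- moving_average(x, smooth_samples)
  span <- max(x) - min(x)
  if (span <= 0) return(FALSE)
  pk <- local_maxima(x)
  if (length(pk) < 2L) return(FALSE)
  sum(peak_prominences(x, pk) >= prominence_frac * span) >= 2L
}

#' Segment a conditioned recording into beats
#'
#' Troughs are local minima of the signal separated by at least
#' `min_separation` seconds (default 1/3 s, the period of the 3 Hz upper
#' heart-rate bound). The first segment starts at the lowest trough
#' preceding the first beat showing the double-peak morphology; subsequent
#' segments run trough-to-trough.
#'
#' @param record A [ppg_record()] (normally after [condition_signal()]).
#' @param min_separation Minimum trough separation, seconds.
#' @param prominence_frac Peak prominence threshold for the double-peak
#'   test, as a fraction of the beat span.
#' @return A data.frame of class `beat_segments` with 0-based, half-open
#'   `start_index`, `end_index` columns (ordered, non-overlapping, every
#'   boundary a local minimum).
#' @export
segment_beats <- function(record, min_separation = 1 / 3,
                          prominence_frac = 0.1) {
  stopifnot(inherits(record, "ppg_record"))
  x <- record$intensities
  troughs <- find_troughs(x, round(min_separation * record$sampling_rate),
                          smooth_samples = max(3L, round(0.016 * record$sampling_rate)))
  if (length(troughs) < 2L)
    ppg_stop("recording too short to segment (fewer than two troughs found)",
             "ppg_segmentation_error")
  # locate the first double-peak beat
  first <- NA_integer_
  for (k in seq_len(length(troughs) - 1L)) {
    seg <- x[troughs[k]:troughs[k + 1L]]
    if (is_double_peak(seg, prominence_frac,
                       max(3L, round(0.016 * record$sampling_rate)))) {
      first <- k; break
    }
  }
  if (is.na(first))
    ppg_stop("no valid start point: no double-peak beat found",
             "ppg_segmentation_error")
  troughs <- troughs[first:length(troughs)]
  segs <- data.frame(start_index = troughs[-length(troughs)] - 1L,
                     end_index = troughs[-1L] - 1L)
  class(segs) <- c("beat_segments", "data.frame")
  segs
}

#' Extract one beat's samples from a recording
#'
#' @param record A [ppg_record()].
#' @param segment One row of [segment_beats()] output (0-based half-open).
#' @return Numeric vector of intensities for that beat.
#' @export
beat_slice <- function(record, segment) {
  record$intensities[(segment$start_index + 1L):segment$end_index]
}
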