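# Fiducial-point location (SP/DP/DN/Bot), the eleven-feature summary and
# per-recording aggregation.

#' Locate the four fiducial points within one beat
#'
#' Extrema are detected on a lightly smoothed copy of the beat (a
#' `smooth_ms` moving average) so that noise ripple cannot masquerade as
#' fiducials, but amplitudes are read from the original samples at the
#' detected indices, keeping noiseless extraction exact. Bot is the
#' minimum of the pre-systolic limb (the beat's starting trough), SP the
#' global maximum, DP the highest local maximum after SP with
#' adjacent-valley prominence at least `prominence_frac` of the beat span,
#' and DN the deepest local minimum between SP and DP. When no prominent
#' diastolic peak exists (a notchless, single-humped beat) a fallback
#' locates DN and DP from a smoothed first-derivative estimate: its first
#' upward / downward zero crossings after SP or, failing that, its
#' steepest-descent and slowest-decline points on the diastolic limb;
#' `notch_fallback_used` is then set (amplitude ordering between DN and DP
#' is not guaranteed on such beats).
#'
#' @param beat Numeric vector of one beat's samples (from [beat_slice()]),
#'   or a `ppg_beat` from [simulate_beat()].
#' @param sampling_rate Hz (taken from the `ppg_beat` if given).
#' @param smooth_ms Detection smoothing window, milliseconds.
#' @param prominence_frac Minimum DP prominence as a fraction of the beat
#'   peak-to-trough span.
#' @return Object of class `fiducial_set`: indices (1-based), times
#'   (seconds from beat start) and amplitudes for `bot`, `sp`, `dn`, `dp`,
#'   plus `notch_fallback_used`.
#' @export
locate_fiducials <- function(beat, sampling_rate = NULL, smooth_ms = 16,
                             prominence_frac = 0.05) {
  if (inherits(beat, "ppg_beat")) {
    sampling_rate <- beat$sampling_rate
    beat <- beat$intensities
  }
  if (is.null(sampling_rate))
    ppg_stop("'sampling_rate' is required when 'beat' is a bare vector",
             "ppg_validation_error")
  n <- length(beat)
  if (n < 5L || (max(beat) - min(beat)) < 1e-12 * max(1, abs(mean(beat))))
    ppg_stop("degenerate beat: flat or too short", "ppg_degenerate_beat")
  s <- moving_average(beat, round(smooth_ms / 1000 * sampling_rate))
  i_sp <- which.max(s)
  if (i_sp <= 1L || i_sp >= n)
    ppg_stop("degenerate beat: no interior systolic peak", "ppg_degenerate_beat")
  i_bot <- which.min(s[seq_len(i_sp)])
  span <- max(s) - min(s)

  fallback <- FALSE
  i_dn <- i_dp <- NA_integer_
  pk <- local_maxima(s); pk <- pk[pk > i_sp]
  if (length(pk)) {
    prom <- peak_prominences(s, pk)
    pk <- pk[prom >= prominence_frac * span]
    if (length(pk)) {
      i_dp <- pk[which.max(s[pk])]
      between <- local_minima(s)
      between <- between[between > i_sp & between < i_dp]
      if (length(between)) i_dn <- between[which.min(s[between])]
    }
  }
  if (is.na(i_dn) || is.na(i_dp)) {
    fallback <- TRUE
    d <- moving_average(diff(s), max(3L, round(0.02 * n)))
    after <- seq.int(i_sp, length(d))
    up <- after[which(d[after] < 0 & c(d[-1], NA)[after] >= 0)]
    i_dn <- i_dp <- NA_integer_
    if (length(up)) {
      i_dn <- up[1L] + 1L
      dn_on <- after[after > (i_dn - 1L)]
      down <- dn_on[which(d[dn_on] > 0 & c(d[-1], NA)[dn_on] <= 0)]
      i_dp <- if (length(down)) down[1L] + 1L else NA_integer_
    }
    if (is.na(i_dn) || is.na(i_dp)) {
      # shoulder: decline is slowest where the smoothed derivative peaks
      i_dp <- after[which.max(d[after])] + 1L
      pre <- seq.int(i_sp, max(i_sp, i_dp - 1L))
      i_dn <- pre[which.min(d[pre])] + 1L
    }
    if (i_dn <= i_sp || i_dp <= i_dn || i_dp > n)
      ppg_stop("degenerate beat: no diastolic structure after the systolic peak",
               "ppg_degenerate_beat")
  }
  idx <- c(bot = i_bot, sp = i_sp, dn = i_dn, dp = i_dp)
  structure(list(index = idx,
                 time = (idx - 1L) / sampling_rate,
                 amplitude = stats::setNames(beat[idx], names(idx)),
                 sampling_rate = sampling_rate,
                 notch_fallback_used = fallback),
            class = "fiducial_set")
}

#' Names and order of the eleven PPG features
#' @return Character vector of length 11.
#' @export
feature_names <- function() {
  c("f01_sp_bot", "f02_dp_bot", "f03_dn_bot",
    "f04_t_sp", "f05_t_dn", "f06_t_dp",
    "f07_beat_period", "f08_dp_sp_ratio", "f09_dn_sp_ratio",
    "f10_systolic_slope", "f11_spectral_ratio")
}

# Feature registry: each entry maps (fiducials, beat, sampling_rate) to one
# number. Isolating the definitions here lets alternate feature sets be
# swapped in without touching the extraction pipeline.
ppg_feature_registry <- function() {
  amp <- function(f, which) unname(f$amplitude[which] - f$amplitude["bot"])
  list(
    f01_sp_bot = function(f, beat, fs) amp(f, "sp"),
    f02_dp_bot = function(f, beat, fs) amp(f, "dp"),
    f03_dn_bot = function(f, beat, fs) amp(f, "dn"),
    f04_t_sp = function(f, beat, fs) unname(f$time["sp"]),
    f05_t_dn = function(f, beat, fs) unname(f$time["dn"]),
    f06_t_dp = function(f, beat, fs) unname(f$time["dp"]),
    f07_beat_period = function(f, beat, fs) length(beat) / fs,
    f08_dp_sp_ratio = function(f, beat, fs) amp(f, "dp") / amp(f, "sp"),
    f09_dn_sp_ratio = function(f, beat, fs) amp(f, "dn") / amp(f, "sp"),
    f10_systolic_slope = function(f, beat, fs) {
      if (f$time[["sp"]] <= 0)
        ppg_stop("systolic rise slope undefined: t_SP = 0", "ppg_degenerate_beat")
      amp(f, "sp") / unname(f$time["sp"])
    },
    f11_spectral_ratio = function(f, beat, fs) {
      x <- beat - mean(beat)
      p <- Mod(fft(x))^2
      bins <- 2:(floor(length(x) / 2) + 1L)
      p[2L] / sum(p[bins])
    })
}

#' Extract the eleven-feature vector from one beat
#'
#' Fixed, documented order: (1) SP-Bot, (2) DP-Bot, (3) DN-Bot amplitudes
#' (a.u., anchored at the starting trough); (4) t_SP, (5) t_DN, (6) t_DP
#' seconds from beat start; (7) beat period; (8) (DP-Bot)/(SP-Bot); (9)
#' (DN-Bot)/(SP-Bot); (10) systolic rise slope (SP-Bot)/t_SP; (11) spectral
#' ratio: periodogram power at the beat fundamental over total power. The
#' amplitude ratios are Bot-anchored so features 8, 9 and 11 are invariant
#' under amplitude scaling and features depend only on beat-relative times.
#'
#' @param fiducials A [locate_fiducials()] result.
#' @param beat The beat's samples.
#' @param sampling_rate Hz.
#' @return Named numeric vector of length 11, all finite.
#' @export
extract_features <- function(fiducials, beat, sampling_rate = NULL) {
  if (inherits(beat, "ppg_beat")) {
    sampling_rate <- beat$sampling_rate
    beat <- beat$intensities
  }
  stopifnot(inherits(fiducials, "fiducial_set"))
  if (is.null(sampling_rate)) sampling_rate <- fiducials$sampling_rate
  reg <- ppg_feature_registry()
  x <- vapply(reg, function(fn) fn(fiducials, beat, sampling_rate), 0.0)
  if (!all(is.finite(x)))
    ppg_stop("non-finite feature value (degenerate beat)", "ppg_degenerate_beat")
  x
}

#' Encode subject covariates as numeric P-features
#'
#' @param profile A [subject_profile()] (or `NULL` for all-`NA`).
#' @return Named vector `p_age`, `p_sex` (F = 0, M = 1), `p_height`,
#'   `p_weight`.
#' @export
encode_profile <- function(profile) {
  if (is.null(profile))
    return(c(p_age = NA_real_, p_sex = NA_real_,
             p_height = NA_real_, p_weight = NA_real_))
  c(p_age = profile$age, p_sex = if (profile$sex == "M") 1 else 0,
    p_height = profile$height, p_weight = profile$weight)
}

#' Aggregate a recording into one feature row
#'
#' Conditions the signal (unless `condition = FALSE`), segments it into
#' beats, extracts the eleven features from every non-degenerate beat and
#' averages them. Beats raising degenerate-beat errors are skipped and
#' counted.
#'
#' @param record A [ppg_record()].
#' @param profile Optional [subject_profile()] for the P-features.
#' @param glucose Optional reference glucose (mmol/L) for the y-label.
#' @param condition Apply [condition_signal()] first? The band limit
#'   slightly attenuates the narrow dicrotic notch; disable for noiseless
#'   fidelity checks.
#' @param band Passband handed to [condition_signal()].
#' @return Object of class `feature_row`: `x` (11 feature means), `p`
#'   (encoded covariates), `y`, `n_beats_used`, `n_beats_skipped`.
#' @export
aggregate_recording <- function(record, profile = NULL, glucose = NA_real_,
                                condition = TRUE, band = c(0.5, 20)) {
  stopifnot(inherits(record, "ppg_record"))
  work <- if (condition) condition_signal(record, band) else record
  segs <- segment_beats(work)
  fs <- work$sampling_rate
  rows <- list(); skipped <- 0L
  for (i in seq_len(nrow(segs))) {
    beat <- beat_slice(work, segs[i, ])
    ft <- tryCatch(
      extract_features(locate_fiducials(beat, fs), beat, fs),
      ppg_degenerate_beat = function(e) NULL)
    if (is.null(ft)) skipped <- skipped + 1L else rows[[length(rows) + 1L]] <- ft
  }
  if (!length(rows))
    ppg_stop("all beats degenerate: no features extracted", "ppg_degenerate_beat")
  x <- colMeans(do.call(rbind, rows))
  structure(list(x = x, p = encode_profile(profile), y = glucose,
                 n_beats_used = length(rows), n_beats_skipped = skipped),
            class = "feature_row")
}

#' Feature table for a whole cohort
#'
#' @param cohort A [simulate_cohort()] result.
#' @param condition,band Passed to [aggregate_recording()].
#' @return data.frame with columns `record`, `subject_id`,
#'   `f01_sp_bot` ... `f11_spectral_ratio`, `p_age`, `p_sex`, `p_height`,
#'   `p_weight`, `y_glucose`. Recordings whose extraction fails outright
#'   are skipped with a warning (mirroring the per-beat skip-and-log
#'   policy); the number skipped is attached as attribute `n_failed`.
#' @export
extract_cohort_features <- function(cohort, condition = TRUE,
                                    band = c(0.5, 20)) {
  stopifnot(inherits(cohort, "ppg_cohort"))
  rows <- lapply(seq_along(cohort$sims), function(i) {
    sim <- cohort$sims[[i]]
    fr <- tryCatch(
      aggregate_recording(sim$record, sim$profile, sim$glucose,
                          condition = condition, band = band),
      ppgglucose_error = function(e) {
        warning(sprintf("record %d skipped: %s", i, conditionMessage(e)),
                call. = FALSE)
        NULL
      })
    if (is.null(fr)) return(NULL)
    data.frame(record = i, subject_id = sim$profile$subject_id,
               as.list(fr$x), as.list(fr$p), y_glucose = fr$y)
  })
  failed <- sum(vapply(rows, is.null, TRUE))
  out <- do.call(rbind, rows)
  if (is.null(out))
    ppg_stop("feature extraction failed for every recording", "ppg_degenerate_beat")
  attr(out, "n_failed") <- failed
  out
}

#' Per-feature Pearson correlation with the glucose label
#'
#' @param rows A feature data.frame (as from [extract_cohort_features()])
#'   with the eleven feature columns and `y_glucose`.
#' @return data.frame with `feature`, `r` (`NA` where the feature has zero
#'   variance, flagged in `defined` rather than silently 0).
#' @export
correlation_report <- function(rows) {
  if (nrow(rows) < 3L)
    ppg_stop("correlation_report needs >= 3 rows", "ppg_validation_error")
  y <- rows$y_glucose
  out <- lapply(feature_names(), function(fn) {
    v <- rows[[fn]]
    if (sd(v) == 0 || sd(y) == 0)
      data.frame(feature = fn, r = NA_real_, defined = FALSE)
    else
      data.frame(feature = fn, r = cor(v, y), defined = TRUE)
  })
  do.call(rbind, out)
}
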