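# Synthetic PPG generation: beats, recordings and cohorts whose morphology
# carries a known, recoverable glucose signal.

#' Beat-shape parameters
#'
#' Describes one PPG pulse as the sum of a systolic and a diastolic Gaussian
#' pulse minus a narrow Gaussian dicrotic notch. Amplitudes are *targets*:
#' the generator calibrates the three Gaussian coefficients so that the
#' realized fiducial amplitudes (SP-Bot, DP-Bot, DN-Bot) match
#' `systolic_amplitude`, `diastolic_amplitude` and
#' `diastolic_amplitude - notch_depth` exactly.
#'
#' @param systolic_amplitude Target SP-Bot amplitude (a.u., > 0).
#' @param diastolic_amplitude Target DP-Bot amplitude (a.u., > 0).
#' @param notch_depth How far the dicrotic notch dips below the diastolic
#'   peak (a.u., >= 0). `0` produces a degenerate single-hump beat with a
#'   diastolic shoulder and no interior minimum.
#' @param beat_period Beat length in seconds.
#' @param systolic_time,diastolic_time Pulse centres in seconds from beat
#'   start; defaults are fixed fractions (0.18, 0.40) of the period.
#' @param pulse_widths Named numeric vector with Gaussian standard
#'   deviations `systolic`, `diastolic`, `notch` in seconds. Defaults scale
#'   with the period; the degenerate `notch_depth = 0` case uses wider
#'   pulses so the beat is genuinely single-humped.
#' @return An object of class `beat_params`.
#' @export
beat_params <- function(systolic_amplitude = 1.0,
                        diastolic_amplitude = 0.55,
                        notch_depth = 0.25,
                        beat_period = 0.8,
                        systolic_time = 0.18 * beat_period,
                        diastolic_time = 0.40 * beat_period,
                        pulse_widths = NULL) {
  check_positive_scalar(beat_period, "beat_period")
  check_positive_scalar(systolic_amplitude, "systolic_amplitude")
  check_positive_scalar(diastolic_amplitude, "diastolic_amplitude")
  check_scalar(notch_depth, "notch_depth")
  check_scalar(systolic_time, "systolic_time")
  check_scalar(diastolic_time, "diastolic_time")
  if (notch_depth < 0)
    ppg_stop("field 'notch_depth' must be >= 0", "ppg_validation_error")
  if (notch_depth >= min(systolic_amplitude, diastolic_amplitude))
    ppg_stop("field 'notch_depth' must be < min(systolic_amplitude, diastolic_amplitude)",
             "ppg_validation_error")
  if (!(0 < systolic_time && systolic_time < diastolic_time &&
        diastolic_time < beat_period))
    ppg_stop("fields must satisfy 0 < systolic_time < diastolic_time < beat_period",
             "ppg_validation_error")
  if (is.null(pulse_widths)) {
    pulse_widths <- if (notch_depth > 0) {
      c(systolic = 0.05, diastolic = 0.12, notch = 0.03) * beat_period
    } else {
      c(systolic = 0.10, diastolic = 0.14, notch = 0.03) * beat_period
    }
  }
  if (length(pulse_widths) != 3L || any(!is.finite(pulse_widths)) ||
      any(pulse_widths <= 0))
    ppg_stop("field 'pulse_widths' must be three positive widths", "ppg_validation_error")
  names(pulse_widths) <- c("systolic", "diastolic", "notch")
  structure(list(systolic_amplitude = systolic_amplitude,
                 diastolic_amplitude = diastolic_amplitude,
                 notch_depth = notch_depth,
                 beat_period = beat_period,
                 systolic_time = systolic_time,
                 diastolic_time = diastolic_time,
                 notch_time = (systolic_time + diastolic_time) / 2,
                 pulse_widths = pulse_widths),
            class = "beat_params")
}

# Gaussian basis of the beat model evaluated at times t.
beat_basis <- function(t, p) {
  w <- p$pulse_widths
  cbind(exp(-(t - p$systolic_time)^2 / (2 * w[["systolic"]]^2)),
        exp(-(t - p$diastolic_time)^2 / (2 * w[["diastolic"]]^2)),
        -exp(-(t - p$notch_time)^2 / (2 * w[["notch"]]^2)))
}

# Locate Bot/SP/DN/DP indices on a densely sampled noiseless beat. Bot is
# the global minimum: in a concatenated recording consecutive beats meet at
# the inter-beat trough, and the narrow leading systolic tail makes the
# beat's own endpoints agree with it to ~0.1% of the pulse amplitude.
locate_shape_fiducials <- function(s) {
  i_sp <- which.max(s)
  i_bot <- which.min(s)
  lmin <- local_minima(s)
  lmin <- lmin[lmin > i_sp]
  if (!length(lmin)) return(list(bot = i_bot, sp = i_sp, dn = NA, dp = NA))
  i_dn <- lmin[which.min(s[lmin])]
  lmax <- local_maxima(s)
  lmax <- lmax[lmax > i_dn]
  if (!length(lmax)) return(list(bot = i_bot, sp = i_sp, dn = NA, dp = NA))
  list(bot = i_bot, sp = i_sp, dn = i_dn, dp = lmax[which.max(s[lmax])])
}

# Solve for the three Gaussian coefficients so realized fiducial amplitudes
# equal the configured targets. Returns coefficients plus ground truth.
calibrate_beat_shape <- function(params, n_grid = 2048L) {
  t <- seq(0, params$beat_period, length.out = n_grid)
  G <- beat_basis(t, params)
  targets <- c(params$systolic_amplitude,
               params$diastolic_amplitude,
               params$diastolic_amplitude - params$notch_depth)
  degenerate <- params$notch_depth == 0

  if (degenerate) {
    # No notch: 2x2 solve pinning SP-Bot and the shoulder value at the
    # diastolic centre; the wide default pulses keep the beat single-humped.
    i_td <- which.min(abs(t - params$diastolic_time))
    A <- c(targets[1], targets[2], 0)
    for (it in 1:12) {
      s <- as.vector(G %*% A)
      i_sp <- which.max(s)
      i_bot <- which.min(s[seq_len(i_sp)])
      M <- rbind(G[i_sp, 1:2] - G[i_bot, 1:2],
                 G[i_td, 1:2] - G[i_bot, 1:2])
      A_new <- c(solve(M, targets[1:2]), 0)
      if (max(abs(A_new - A)) < 1e-10) { A <- A_new; break }
      A <- A_new
    }
    s <- as.vector(G %*% A)
    f <- list(bot = which.min(s), sp = which.max(s), dn = NA, dp = NA)
  } else {
    A <- c(targets[1], targets[2], params$notch_depth)
    # the diastolic tail pulls the realized maximum slightly past the
    # systolic centre; a centre correction keeps argmax on systolic_time
    p_eff <- params
    for (it in 1:15) {
      s <- as.vector(G %*% A)
      f <- locate_shape_fiducials(s)
      if (is.na(f$dn))
        ppg_stop("beat parameters do not produce a double-peak pulse (check 'notch_depth')",
                 "ppg_validation_error")
      M <- rbind(G[f$sp, ] - G[f$bot, ],
                 G[f$dp, ] - G[f$bot, ],
                 G[f$dn, ] - G[f$bot, ])
      A_new <- as.vector(solve(M, targets))
      shift <- params$systolic_time - t[f$sp]
      converged <- max(abs(A_new - A)) < 1e-8 && abs(shift) <= t[2] - t[1]
      A <- A_new
      if (converged) break
      p_eff$systolic_time <- p_eff$systolic_time + shift
      G <- beat_basis(t, p_eff)
    }
    s <- as.vector(G %*% A)
    f <- locate_shape_fiducials(s)
    params <- p_eff
  }

  amp <- function(i) if (is.na(i)) NA_real_ else s[i]
  tt <- function(i) if (is.na(i)) NA_real_ else t[i]
  # truth reports the starting trough (the "initial lowest point" anchoring
  # extraction); amplitudes were calibrated against the global minimum,
  # which agrees with it to ~0.1% of the pulse amplitude
  i_start <- which.min(s[seq_len(f$sp)])
  list(coefficients = A,
       degenerate = degenerate,
       shape = function(tq) as.vector(beat_basis(tq, params) %*% A),
       truth = list(
         t_bot = tt(i_start), t_sp = tt(f$sp), t_dn = tt(f$dn), t_dp = tt(f$dp),
         a_bot = amp(i_start), a_sp = amp(f$sp), a_dn = amp(f$dn), a_dp = amp(f$dp)))
}

#' Simulate one PPG beat
#'
#' @param params A [beat_params()] object.
#' @param sampling_rate Samples per second (Hz).
#' @return An object of class `ppg_beat`: list with `intensities` (length
#'   `round(beat_period * sampling_rate)`), `sampling_rate`, `params`,
#'   `truth` (noiseless fiducial times/amplitudes) and `degenerate`
#'   (`TRUE` when `notch_depth = 0` suppresses the notch).
#' @export
simulate_beat <- function(params, sampling_rate = 500) {
  if (!inherits(params, "beat_params")) params <- do.call(beat_params, params)
  check_positive_scalar(sampling_rate, "sampling_rate")
  cal <- calibrate_beat_shape(params)
  n <- round(params$beat_period * sampling_rate)
  tq <- (seq_len(n) - 1) / sampling_rate
  structure(list(intensities = cal$shape(tq),
                 sampling_rate = sampling_rate,
                 params = params,
                 truth = cal$truth,
                 degenerate = cal$degenerate),
            class = "ppg_beat")
}

#' Glucose-to-morphology link
#'
#' Affine map from blood glucose (mmol/L) to the three Bot-anchored beat
#' amplitudes, plus a glucose-dependent additive waveform noise level.
#' Noise decreases linearly with glucose (low-glucose recordings are
#' noisier) and is clipped below at `noise_floor`.
#'
#' @param sp_base,dp_base,dn_base Amplitude targets (a.u.) at `ref_glucose`.
#' @param sp_slope,dp_slope,dn_slope Amplitude change per mmol/L.
#' @param ref_glucose Reference glucose (mmol/L) where the bases apply.
#' @param noise_intercept,noise_slope,noise_floor Parameters of
#'   `noise_sd(g) = max(noise_floor, noise_intercept - noise_slope * g)`.
#' @return An object of class `glucose_link` with a `noise_sd(g)` closure.
#' @export
glucose_link <- function(sp_base = 1.0, dp_base = 0.55, dn_base = 0.30,
                         sp_slope = 0.08, dp_slope = 0.05, dn_slope = 0.03,
                         ref_glucose = 5.4,
                         noise_intercept = 0.05, noise_slope = 0.006,
                         noise_floor = 0.005) {
  for (f in c("sp_base", "dp_base", "dn_base", "sp_slope", "dp_slope",
              "dn_slope", "ref_glucose", "noise_intercept", "noise_slope"))
    check_scalar(get(f), f)
  check_positive_scalar(noise_floor, "noise_floor")
  link <- list(sp_base = sp_base, dp_base = dp_base, dn_base = dn_base,
               sp_slope = sp_slope, dp_slope = dp_slope, dn_slope = dn_slope,
               ref_glucose = ref_glucose,
               noise_intercept = noise_intercept, noise_slope = noise_slope,
               noise_floor = noise_floor)
  link$noise_sd <- function(glucose)
    pmax(noise_floor, noise_intercept - noise_slope * glucose)
  structure(link, class = "glucose_link")
}

# Target Bot-anchored amplitudes for a glucose value (optionally scaled by a
# subject-specific factor).
link_amplitudes <- function(link, glucose, scale = 1) {
  d <- glucose - link$ref_glucose
  a <- scale * c(sp = link$sp_base + link$sp_slope * d,
                 dp = link$dp_base + link$dp_slope * d,
                 dn = link$dn_base + link$dn_slope * d)
  if (any(a <= 0) || a[["dn"]] >= a[["dp"]] || a[["dp"]] >= a[["sp"]])
    ppg_stop("glucose value outside the range this link can render (amplitude ordering broken)",
             "ppg_validation_error")
  a
}

#' Subject covariates (P-features)
#'
#' @param subject_id Identifier string.
#' @param age Years. @param sex `"F"` or `"M"`. @param height cm.
#' @param weight kg.
#' @return Object of class `subject_profile`.
#' @export
subject_profile <- function(subject_id, age = 35, sex = "M",
                            height = 172, weight = 70) {
  check_positive_scalar(age, "age")
  check_positive_scalar(height, "height")
  check_positive_scalar(weight, "weight")
  if (!sex %in% c("F", "M"))
    ppg_stop("field 'sex' must be \"F\" or \"M\"", "ppg_validation_error")
  structure(list(subject_id = as.character(subject_id), age = age, sex = sex,
                 height = height, weight = weight),
            class = "subject_profile")
}

random_profile <- function(subject_id) {
  subject_profile(subject_id,
                  age = round(runif(1, 18, 80)),
                  sex = sample(c("F", "M"), 1L),
                  height = round(max(145, rnorm(1, 170, 10))),
                  weight = round(max(40, rnorm(1, 72, 12))))
}

SCENARIO_NAMES <- c("nir_single", "solar_single", "multi_patient")

#' Cohort scenario specification
#'
#' @param name One of `"nir_single"`, `"solar_single"`, `"multi_patient"`.
#' @param n_records Number of recordings.
#' @param glucose_range Closed glucose interval (mmol/L); both endpoints are
#'   always included once so the label min/max are deterministic.
#' @param n_subjects Number of distinct subjects (1 for the single-person
#'   scenarios).
#' @param duration Seconds of waveform per recording.
#' @param sampling_rate Hz (>= 50).
#' @return Object of class `scenario_spec`.
#' @export
scenario_spec <- function(name, n_records, glucose_range, n_subjects = 1L,
                          duration = 10, sampling_rate = 500) {
  if (!is.character(name) || length(name) != 1L || !name %in% SCENARIO_NAMES)
    ppg_stop(sprintf("unknown scenario name; valid names: %s",
                     paste(SCENARIO_NAMES, collapse = ", ")),
             "ppg_scenario_error")
  check_positive_scalar(n_records, "n_records")
  check_positive_scalar(n_subjects, "n_subjects")
  check_positive_scalar(duration, "duration")
  check_positive_scalar(sampling_rate, "sampling_rate")
  if (sampling_rate < 50)
    ppg_stop("field 'sampling_rate' must be >= 50 Hz", "ppg_validation_error")
  if (length(glucose_range) != 2L || !all(is.finite(glucose_range)) ||
      glucose_range[1] <= 0 || glucose_range[1] >= glucose_range[2])
    ppg_stop("field 'glucose_range' must be positive with lower < upper",
             "ppg_validation_error")
  structure(list(name = name, n_records = as.integer(n_records),
                 glucose_range = as.numeric(glucose_range),
                 n_subjects = as.integer(n_subjects),
                 duration = duration, sampling_rate = sampling_rate),
            class = "scenario_spec")
}

#' Named scenario presets mirroring the study's three experiments
#'
#' `"nir_single"`: 292 recordings, one subject, glucose 4.4-6.4 mmol/L
#' (laser illumination). `"nir_single_88"`: the 88-record training-scale
#' variant of the same scenario. `"solar_single"`: 237 recordings, one
#' subject, sunlight illumination. `"multi_patient"`: 626 recordings over
#' 49 subjects, glucose 4.0-15.0 mmol/L.
#'
#' @param name Preset name.
#' @return A [scenario_spec()].
#' @export
scenario_preset <- function(name = c("nir_single", "nir_single_88",
                                     "solar_single", "multi_patient")) {
  name <- match.arg(name)
  switch(name,
    nir_single    = scenario_spec("nir_single", 292L, c(4.4, 6.4)),
    nir_single_88 = scenario_spec("nir_single",  88L, c(4.4, 6.4)),
    solar_single  = scenario_spec("solar_single", 237L, c(4.4, 6.4)),
    multi_patient = scenario_spec("multi_patient", 626L, c(4.0, 15.0),
                                  n_subjects = 49L))
}

#' Simulate one PPG recording with ground-truth fiducials
#'
#' Draws a beat rate uniformly in 60-100 bpm (inside the 1-3 Hz human
#' heart-rate band), renders consecutive beats from the glucose-calibrated
#' pulse shape with mild period jitter, and adds white Gaussian noise with
#' standard deviation `link$noise_sd(glucose)`.
#'
#' @param profile A [subject_profile()].
#' @param glucose Reference blood glucose (mmol/L, > 0).
#' @param link A [glucose_link()].
#' @param duration Recording length in seconds (must cover >= 3 beats).
#' @param sampling_rate Hz.
#' @param seed Integer seed; same seed gives a bit-identical recording.
#' @param amplitude_scale Subject-specific multiplicative amplitude factor.
#' @param hr_jitter Relative beat-to-beat period jitter (uniform half-width).
#' @return Object of class `ppg_simulation`: `record` (a `ppg_record`),
#'   `truth` (per-beat fiducial times/amplitudes, absolute seconds),
#'   `glucose`, `profile`, `beat_rate_bpm`.
#' @export
simulate_recording <- function(profile, glucose, link = glucose_link(),
                               duration = 10, sampling_rate = 500,
                               seed = NULL, amplitude_scale = 1,
                               hr_jitter = 0.01) {
  check_positive_scalar(glucose, "glucose")
  check_positive_scalar(duration, "duration")
  if (!is.null(seed)) set.seed(seed)
  bpm <- runif(1, 60, 100)
  period <- 60 / bpm
  n_beats <- floor(duration / period)
  if (n_beats < 3)
    ppg_stop(sprintf("duration %.2f s too short: covers %d beat(s), need >= 3",
                     duration, n_beats), "ppg_duration_error")

  a <- link_amplitudes(link, glucose, amplitude_scale)
  params <- beat_params(systolic_amplitude = a[["sp"]],
                        diastolic_amplitude = a[["dp"]],
                        notch_depth = a[["dp"]] - a[["dn"]],
                        beat_period = period)
  cal <- calibrate_beat_shape(params)

  periods <- period * (1 + runif(n_beats, -hr_jitter, hr_jitter))
  lens <- round(periods * sampling_rate)
  starts <- c(0L, cumsum(lens))[seq_len(n_beats)]
  segs <- lapply(lens, function(nk) cal$shape((seq_len(nk) - 1) / sampling_rate))
  clean <- unlist(segs, use.names = FALSE)
  noise_sd <- link$noise_sd(glucose)
  intens <- clean + rnorm(length(clean), 0, noise_sd)

  t0 <- starts / sampling_rate
  truth <- data.frame(beat = seq_len(n_beats),
                      start_index = starts,
                      t_bot = t0 + cal$truth$t_bot,
                      t_sp = t0 + cal$truth$t_sp,
                      t_dn = t0 + cal$truth$t_dn,
                      t_dp = t0 + cal$truth$t_dp,
                      a_bot = cal$truth$a_bot, a_sp = cal$truth$a_sp,
                      a_dn = cal$truth$a_dn, a_dp = cal$truth$a_dp)

  record <- ppg_record(times = (seq_along(intens) - 1) / sampling_rate,
                       intensities = intens,
                       sampling_rate = sampling_rate,
                       subject_id = profile$subject_id)
  structure(list(record = record, truth = truth, glucose = glucose,
                 profile = profile, beat_rate_bpm = bpm,
                 noise_sd = noise_sd, params = params),
            class = "ppg_simulation")
}

#' Simulate a cohort of PPG recordings
#'
#' Labels are drawn uniformly on the scenario's closed glucose range with
#' both endpoints inserted deterministically (records 1 and 2), so the
#' empirical label min/max equal the configured range. Multi-patient
#' scenarios draw distinct subject profiles, assign records to subjects in
#' shuffled round-robin (every subject is used), and give each subject a
#' lognormal amplitude factor (sd 0.05).
#'
#' @param spec A [scenario_spec()] or preset name accepted by
#'   [scenario_preset()].
#' @param link A [glucose_link()].
#' @param seed Integer seed; identical (spec, link, seed) give an identical
#'   cohort.
#' @return Object of class `ppg_cohort`: list with `sims` (one
#'   `ppg_simulation` per record), `labels`, `profiles`, `assignment`,
#'   `spec`, `seed`.
#' @export
simulate_cohort <- function(spec, link = glucose_link(), seed = NULL) {
  if (is.character(spec)) spec <- scenario_preset(spec)
  if (!inherits(spec, "scenario_spec"))
    ppg_stop("'spec' must be a scenario_spec or preset name", "ppg_scenario_error")
  if (!is.null(seed)) set.seed(seed)
  n <- spec$n_records
  lo <- spec$glucose_range[1]; hi <- spec$glucose_range[2]
  labels <- if (n == 1L) runif(1, lo, hi)
            else c(lo, hi, runif(n - 2L, lo, hi))

  ns <- spec$n_subjects
  profiles <- lapply(seq_len(ns), function(i)
    random_profile(sprintf("S%03d", i)))
  assignment <- if (ns == 1L) rep(1L, n)
                else sample(rep_len(seq_len(ns), n))
  scales <- if (ns == 1L) 1 else exp(rnorm(ns, 0, 0.05))
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n)

  sims <- vector("list", n)
  for (i in seq_len(n)) {
    s <- assignment[i]
    sims[[i]] <- simulate_recording(profiles[[s]], labels[i], link,
                                    duration = spec$duration,
                                    sampling_rate = spec$sampling_rate,
                                    seed = sub_seeds[i],
                                    amplitude_scale = scales[s])
  }
  structure(list(spec = spec, link = link, seed = seed, labels = labels,
                 profiles = profiles, assignment = assignment,
                 scales = scales, sims = sims),
            class = "ppg_cohort")
}

#' Write a cohort to disk (waveform CSVs, truth sidecars, manifest)
#'
#' Writes one `time_s,intensity` CSV and one ground-truth JSON sidecar per
#' recording, a `manifest.csv` with columns
#' `record_path,subject_id,glucose_mmol_per_l`, and a `subjects.csv`
#' covariate table.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if missing).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "ppg_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- length(cohort$sims)
  paths <- sprintf("record_%04d.csv", seq_len(n))
  for (i in seq_len(n)) {
    sim <- cohort$sims[[i]]
    write_ppg_csv(sim$record, file.path(dir, paths[i]))
    write_json_canonical(list(glucose_mmol_per_l = sim$glucose,
                              beat_rate_bpm = sim$beat_rate_bpm,
                              truth = sim$truth),
                         file.path(dir, sub("\\.csv$", "_truth.json", paths[i])))
  }
  manifest <- data.frame(
    record_path = paths,
    subject_id = vapply(cohort$sims, function(s) s$profile$subject_id, ""),
    glucose_mmol_per_l = cohort$labels)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  subjects <- do.call(rbind, lapply(cohort$profiles, function(p)
    data.frame(subject_id = p$subject_id, age = p$age, sex = p$sex,
               height = p$height, weight = p$weight)))
  write.csv(subjects, file.path(dir, "subjects.csv"), row.names = FALSE)
  invisible(file.path(dir, "manifest.csv"))
}
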