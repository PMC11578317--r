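# Synthetic PPG generator: beat morphology, glucose link, cohorts.

test_that("simulated beats carry the four fiducials in order", {
  for (p in list(beat_params(),
                 beat_params(systolic_amplitude = 1.6, diastolic_amplitude = 0.9,
                             notch_depth = 0.4, beat_period = 0.6),
                 beat_params(beat_period = 1.0))) {
    b <- simulate_beat(p, 500)
    x <- b$intensities
    expect_length(x, round(p$beat_period * 500))
    i_sp <- which.max(x)
    # SP sits at the configured systolic time (overlapping pulses can pull
    # the realized maximum by a sample or two)
    expect_lt(abs((i_sp - 1) / 500 - p$systolic_time), 3 / 500 + 1e-9)
    lmin <- which(diff(sign(diff(x))) > 0) + 1L
    lmin <- lmin[lmin > i_sp]
    expect_gt(length(lmin), 0)
    i_dn <- lmin[which.min(x[lmin])]
    lmax <- which(diff(sign(diff(x))) < 0) + 1L
    lmax <- lmax[lmax > i_dn]
    expect_gt(length(lmax), 0)
    i_dp <- lmax[which.max(x[lmax])]
    expect_true(i_sp < i_dn && i_dn < i_dp)
    # endpoints sit near the beat minimum
    expect_lt(x[1] - min(x), 0.01 * (max(x) - min(x)))
    expect_lt(x[length(x)] - min(x), 0.01 * (max(x) - min(x)))
  }
  # with default parameters the argmax lands on the configured systolic
  # time to within one sample
  bd <- simulate_beat(beat_params(), 500)
  expect_lt(abs((which.max(bd$intensities) - 1) / 500 -
                beat_params()$systolic_time), 1 / 500 + 1e-9)
})

test_that("realized SP-Bot amplitude matches the configured target within 1%", {
  p <- beat_params(systolic_amplitude = 1.25, diastolic_amplitude = 0.7,
                   notch_depth = 0.3, beat_period = 0.85)
  b <- simulate_beat(p, 500)
  sp_bot <- max(b$intensities) - min(b$intensities)
  expect_lt(abs(sp_bot / p$systolic_amplitude - 1), 0.01)
  # the densely sampled generating function agrees (grid-resolution check)
  b_fine <- simulate_beat(p, 20000)
  sp_bot_fine <- max(b_fine$intensities) - min(b_fine$intensities)
  expect_lt(abs(sp_bot / sp_bot_fine - 1), 0.01)
})

test_that("notch_depth = 0 gives a single-humped beat (fallback path)", {
  b <- simulate_beat(beat_params(notch_depth = 0), 500)
  x <- b$intensities
  i_sp <- which.max(x)
  lmin <- which(diff(sign(diff(x))) > 0) + 1L
  expect_length(lmin[lmin > i_sp & lmin < length(x) - 1L], 0)
  expect_true(b$degenerate)
  expect_true(locate_fiducials(b)$notch_fallback_used)
})

test_that("invalid beat parameters raise validation errors naming the field", {
  expect_error(beat_params(systolic_amplitude = -1), "systolic_amplitude",
               class = "ppg_validation_error")
  expect_error(beat_params(notch_depth = 0.6), "notch_depth",
               class = "ppg_validation_error")
  expect_error(beat_params(systolic_time = 0.5, diastolic_time = 0.3),
               "systolic_time", class = "ppg_validation_error")
  expect_error(beat_params(beat_period = 0), "beat_period",
               class = "ppg_validation_error")
})

test_that("same seed reproduces a bit-identical recording", {
  prof <- subject_profile("S1")
  a <- simulate_recording(prof, 5.2, seed = 99)
  b <- simulate_recording(prof, 5.2, seed = 99)
  expect_identical(a$record$intensities, b$record$intensities)
  expect_identical(a$truth, b$truth)
})

test_that("glucose shifts SP-Bot by the configured slope (zero noise)", {
  link <- noiseless_link()
  prof <- subject_profile("S1")
  lo <- simulate_recording(prof, 4.4, link, seed = 5)
  hi <- simulate_recording(prof, 6.4, link, seed = 5)
  d_sp <- (hi$truth$a_sp[1] - hi$truth$a_bot[1]) -
          (lo$truth$a_sp[1] - lo$truth$a_bot[1])
  expect_lt(abs(d_sp / (link$sp_slope * 2.0) - 1), 0.01)
})

test_that("waveform noise decreases with glucose", {
  link <- glucose_link()
  expect_gt(link$noise_sd(4.4), link$noise_sd(6.4))
  # monotone non-increasing across the whole range, positive everywhere
  g <- seq(2, 20, by = 0.5)
  expect_true(all(diff(link$noise_sd(g)) <= 0))
  expect_true(all(link$noise_sd(g) > 0))
})

test_that("beat rate stays inside the 1-3 Hz heart-rate band", {
  for (s in 1:5) {
    sim <- simulate_recording(subject_profile("S1"), 5.5, seed = s)
    expect_gte(sim$beat_rate_bpm / 60, 1)
    expect_lte(sim$beat_rate_bpm / 60, 3)
  }
})

test_that("too-short recordings are rejected", {
  expect_error(simulate_recording(subject_profile("S1"), 5.5, duration = 1,
                                  seed = 1),
               class = "ppg_duration_error")
})

test_that("SP-Bot is strictly increasing in glucose with zero noise", {
  link <- noiseless_link()
  g <- seq(4.4, 6.4, length.out = 7)
  sp_bot <- vapply(g, function(gl) {
    sim <- simulate_recording(subject_profile("S1"), gl, link, seed = 3)
    sim$truth$a_sp[1] - sim$truth$a_bot[1]
  }, 0.0)
  expect_true(all(diff(sp_bot) > 0))
})

test_that("cohorts have exact sizes and deterministic label endpoints", {
  coh <- simulate_cohort(tiny_scenario(8L), seed = 7)
  expect_length(coh$sims, 8L)
  expect_equal(min(coh$labels), 4.4)
  expect_equal(max(coh$labels), 6.4)
  one <- simulate_cohort(tiny_scenario(1L), seed = 7)
  expect_length(one$sims, 1L)
  expect_gte(one$labels, 4.4)
  expect_lte(one$labels, 6.4)
})

test_that("identical (spec, link, seed) give an identical cohort", {
  a <- simulate_cohort(tiny_scenario(4L), seed = 21)
  b <- simulate_cohort(tiny_scenario(4L), seed = 21)
  expect_identical(lapply(a$sims, function(s) s$record$intensities),
                   lapply(b$sims, function(s) s$record$intensities))
  expect_identical(a$labels, b$labels)
})

test_that("multi-patient cohorts use every subject with distinct profiles", {
  spec <- scenario_spec("multi_patient", 12L, c(4.0, 15.0), n_subjects = 5L,
                        duration = 6)
  coh <- simulate_cohort(spec, seed = 7)
  expect_setequal(unique(coh$assignment), 1:5)
  ids <- vapply(coh$profiles, `[[`, "", "subject_id")
  expect_length(unique(ids), 5L)
  expect_equal(min(coh$labels), 4.0)
  expect_equal(max(coh$labels), 15.0)
})

test_that("unknown scenario names are rejected with the valid list", {
  expect_error(scenario_spec("oral_glucose", 10L, c(4, 6)),
               "nir_single.*solar_single.*multi_patient",
               class = "ppg_scenario_error")
  expect_error(simulate_cohort("not_a_preset"))
})

test_that("presets mirror the study cohort shapes", {
  p88 <- scenario_preset("nir_single_88")
  expect_equal(p88$n_records, 88L)
  expect_equal(p88$glucose_range, c(4.4, 6.4))
  expect_equal(scenario_preset("nir_single")$n_records, 292L)
  expect_equal(scenario_preset("solar_single")$n_records, 237L)
  mp <- scenario_preset("multi_patient")
  expect_equal(mp$n_records, 626L)
  expect_equal(mp$n_subjects, 49L)
})

test_that("written cohorts round-trip through the manifest", {
  dir <- withr::local_tempdir()
  coh <- simulate_cohort(tiny_scenario(3L), seed = 2)
  manifest <- write_cohort(coh, dir)
  man <- read.csv(manifest)
  expect_equal(nrow(man), 3L)
  expect_named(man, c("record_path", "subject_id", "glucose_mmol_per_l"))
  rec <- read_ppg_csv(file.path(dir, man$record_path[2]))
  expect_identical(rec$intensities, coh$sims[[2]]$record$intensities)
})
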