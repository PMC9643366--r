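sin_mod <- function(base, amp, f = 0.5) {
  modulation_spec("sinusoid", baseline_rate = base, amplitude = amp, frequency = f)
}

test_that("an unmodulated epoch yields near-zero modulation depth", {
  # amplitude 0: kinetic depth must sit below the noise floor estimated from
  # the resting epoch's own smoothed IFR excursions.
  tr <- modulated_train(mean_isi = 40, cv = 0.3, seed = 13, epoch_dur = 20,
                        kin = sin_mod(25, 0))
  resp <- kinetic_response(tr, "rotation")
  rest_ifr <- instantaneous_firing_rate(tr, "resting")
  sm <- stats::runmed(rest_ifr$rates, 5)
  floor_est <- max(max(sm) - resp$resting_rate, resp$resting_rate - min(sm))
  expect_lte(resp$modulation_depth, 1.5 * floor_est)
})

test_that("sinusoidal peak rate is recovered within 15% for a regular unit", {
  # extreme-value bias of the smoothed-IFR maximum grows with interval CV,
  # so peak recovery is checked at the regular-unit CV of 0.1
  peaks <- vapply(1:8, function(s) {
    tr <- modulated_train(mean_isi = 50, cv = 0.1, seed = 100 + s,
                          epoch_dur = 20, kin = sin_mod(25, 25, f = 0.5))
    kinetic_response(tr, "rotation")$peak_rate
  }, numeric(1))
  expect_lt(abs(mean(peaks) - 50) / 50, 0.15)
})

test_that("modulation depth increases with stimulus amplitude", {
  depth_at <- function(amp) {
    mean(vapply(1:4, function(s) {
      tr <- modulated_train(mean_isi = 40, cv = 0.3, seed = 300 + s,
                            epoch_dur = 20, kin = sin_mod(25, amp))
      kinetic_response(tr, "rotation")$modulation_depth
    }, numeric(1)))
  }
  depths <- vapply(c(0, 8, 16, 24), depth_at, numeric(1))
  expect_true(all(diff(depths) > 0))
  # reported gain is depth normalized by the supplied stimulus amplitude
  tr <- modulated_train(mean_isi = 40, cv = 0.3, seed = 301, epoch_dur = 20,
                        kin = sin_mod(25, 16))
  resp <- kinetic_response(tr, "rotation", stimulus_amplitude = 16)
  expect_equal(resp$gain, resp$modulation_depth / 16)
})

test_that("tonic and phasic GVS responses are classified correctly", {
  tonic <- modulated_train(mean_isi = 50, cv = 0.3, seed = 41, epoch_dur = 16,
                           gvs = modulation_spec("step", baseline_rate = 20,
                                                 amplitude = 30))
  expect_identical(gvs_response(tonic)$gvs_class, "tonic")
  # adapting step decaying from 66 toward 36 spk/s within the epoch
  phasic <- modulated_train(
    mean_isi = 50, cv = 0.3, seed = 42, epoch_dur = 16,
    gvs = modulation_spec("step", baseline_rate = 36, amplitude = 30,
                          adaptation_tau = 4))
  resp <- gvs_response(phasic)
  expect_identical(resp$gvs_class, "phasic")
  expect_gt(resp$adaptation_index, 0.25)
})

test_that("a train without a gvs epoch reports class none", {
  tr <- resting_train(mean_isi = 40, cv = 0.3, dur = 15, seed = 1)
  expect_identical(gvs_response(tr)$gvs_class, "none")
})

test_that("the adaptation index is invariant to translation and rate scaling", {
  tr <- modulated_train(
    mean_isi = 50, cv = 0.3, seed = 55, epoch_dur = 16,
    gvs = modulation_spec("step", baseline_rate = 30, amplitude = 30,
                          adaptation_tau = 4))
  base <- gvs_response(tr)
  shift_scale <- function(times, epochs, shift, scale) {
    as_spike_train(tr$unit_id, (times + shift) / scale,
                   data.frame(label = epochs$label,
                              start = (epochs$start + shift) / scale,
                              end = (epochs$end + shift) / scale),
                   organ = tr$organ, condition = tr$condition)
  }
  shifted <- gvs_response(shift_scale(tr$spike_times, tr$epochs, 500, 1))
  expect_equal(shifted$adaptation_index, base$adaptation_index, tolerance = 1e-9)
  expect_identical(shifted$gvs_class, base$gvs_class)
  # compressing time doubles every rate; AI is a ratio and must not move
  scaled <- gvs_response(shift_scale(tr$spike_times, tr$epochs, 0, 2),
                         resting_window = 5)
  expect_equal(scaled$adaptation_index, base$adaptation_index, tolerance = 1e-9)
  expect_identical(scaled$gvs_class, base$gvs_class)
})

test_that("tonic/phasic recovery exceeds 90% for profile AIs of 0 vs 0.45", {
  # For an adapting step with plateau = baseline b, amplitude A, tau equal to
  # the epoch quarter Q, the rate-profile AI is (E - L)/E with
  # E = b + A (tau/Q)(1 - exp(-Q/tau)), L = b + A (tau/Q)(exp(-3) - exp(-4)).
  b <- 20; A <- 28.4; tau <- 4; Q <- 4
  E <- b + A * (tau / Q) * (1 - exp(-Q / tau))
  L <- b + A * (tau / Q) * (exp(-3 * Q / tau) - exp(-4 * Q / tau))
  profile_ai <- (E - L) / E
  expect_equal(profile_ai, 0.45, tolerance = 0.01)
  cls <- unlist(lapply(c(FALSE, TRUE), function(adapting) {
    vapply(1:50, function(s) {
      gvs <- if (adapting) {
        modulation_spec("step", baseline_rate = b, amplitude = A,
                        adaptation_tau = tau)
      } else {
        modulation_spec("step", baseline_rate = b, amplitude = A)
      }
      tr <- modulated_train(mean_isi = 40, cv = 0.3, seed = 7000 + s +
                              500 * adapting, epoch_dur = 16, gvs = gvs)
      gvs_response(tr)$gvs_class
    }, character(1))
  }))
  truth <- rep(c("tonic", "phasic"), each = 50)
  expect_gte(mean(cls == truth), 0.90)
})

test_that("sparse epochs are rejected", {
  tr <- modulated_train(mean_isi = 400, cv = 0.3, seed = 2, epoch_dur = 2,
                        gvs = modulation_spec("step", baseline_rate = 2,
                                              amplitude = 0))
  expect_error(gvs_response(tr, resting_window = 10), "insufficient spikes")
})
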