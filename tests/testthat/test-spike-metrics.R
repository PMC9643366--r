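test_that("inter-spike intervals follow their definition", {
  tr <- manual_train(c(0.0, 0.1, 0.3))
  expect_equal(interspike_intervals(tr), c(0.1, 0.2))

  per <- resting_train(mean_isi = 50, cv = 0, dur = 10)
  expect_true(all(abs(interspike_intervals(per) - 0.05) < 1e-12))

  g <- resting_train(mean_isi = 40, cv = 0.5, dur = 30, seed = 3)
  expect_length(interspike_intervals(g), length(g$spike_times) - 1L)
})

test_that("epoch-boundary-straddling intervals are excluded, not truncated", {
  tr <- manual_train(c(0.0, 0.1, 0.3, 0.4),
                     epochs = data.frame(label = "resting",
                                         start = 0.05, end = 0.35))
  expect_equal(interspike_intervals(tr), 0.2)
  expect_error(interspike_intervals(manual_train(
    c(0.0, 0.5), epochs = data.frame(label = "resting", start = 0.2, end = 0.4))),
    "insufficient spikes")
})

test_that("IFR is the elementwise reciprocal of the ISI", {
  tr <- manual_train(c(0.0, 0.1, 0.3))
  ifr <- instantaneous_firing_rate(tr)
  expect_equal(ifr$rates, c(10, 5))
  expect_equal(ifr$times, c(0.1, 0.3))

  g <- resting_train(mean_isi = 35, cv = 0.8, dur = 60, seed = 8)
  isi <- interspike_intervals(g)
  ifr <- instantaneous_firing_rate(g)
  expect_equal(ifr$rates * isi, rep(1, length(isi)), tolerance = 1e-15)
  expect_true(all(ifr$rates > 0))
})

test_that("resting rate averages the IFR over the 10-s window", {
  per <- resting_train(mean_isi = 50, cv = 0, dur = 12)
  expect_equal(resting_rate(per), 20)
  # window longer than the epoch errors unless overridden
  short <- resting_train(mean_isi = 50, cv = 0, dur = 5)
  expect_error(resting_rate(short), "shorter than")
  expect_equal(resting_rate(short, window = 4), 20)
})

test_that("mean resting rate matches the reciprocal-gamma expectation", {
  # For gamma ISIs with shape k > 1 and mean mu, E[1/ISI] = k/((k-1) mu).
  cv <- 0.3; mu_s <- 0.05; k <- 1 / cv^2
  expected <- k / ((k - 1) * mu_s)
  rates <- vapply(1:60, function(s) {
    resting_rate(resting_train(mean_isi = 50, cv = cv, dur = 12, seed = s))
  }, numeric(1))
  se <- sd(rates) / sqrt(length(rates))
  expect_lt(abs(mean(rates) - expected), 3 * se)
})

test_that("CV* matches the arbitrary-precision oracle to 10 significant digits", {
  ref <- cv_star_reference()
  got <- mapply(cv_star, ref$mu, ref$cv)
  expect_true(all(abs(got - ref$cv_star) / ref$cv_star < 5e-10))
})

test_that("CV* limiting and error behavior follow the formula", {
  for (mu in c(15, 20, 30, 50, 80)) expect_identical(cv_star(mu, 0), 0)
  # strictly increasing in CV at fixed mu
  for (mu in c(16, 25, 40, 70)) {
    vals <- vapply(seq(0.05, 1.5, by = 0.05), cv_star, numeric(1), mu_isi = mu)
    expect_true(all(diff(vals) > 0))
  }
  # undefined at or below the denominator root (~14.42 ms under log10)
  expect_error(cv_star(14, 0.3), "undefined")
  expect_error(cv_star(cv_star_mu_root(), 0.3), "undefined")
  expect_silent(cv_star(cv_star_mu_root() + 1e-6, 0.3))
  # natural-log variant shifts the domain accordingly
  expect_equal(cv_star_mu_root("ln"), exp(0.8248 / 0.7116))
  expect_error(cv_star(3, 0.3, log_base = "ln"), "undefined")
  expect_gt(cv_star(20, 0.3, log_base = "ln"), 0)
})

test_that("regularity classification is invariant to time translation", {
  tr <- resting_train(mean_isi = 30, cv = 0.4, dur = 20, seed = 21)
  shifted <- as_spike_train(tr$unit_id, tr$spike_times + 123.456,
                            data.frame(label = "resting",
                                       start = tr$epochs$start + 123.456,
                                       end = tr$epochs$end + 123.456),
                            organ = tr$organ, condition = tr$condition)
  a <- classify_regularity(tr)
  b <- classify_regularity(shifted)
  expect_equal(a$cv_star, b$cv_star, tolerance = 1e-9)
  expect_identical(a$label, b$label)
})

test_that("periodic trains are regular; Poisson-like trains are irregular", {
  per <- resting_train(mean_isi = 30, cv = 0, dur = 15)
  expect_identical(classify_regularity(per, threshold = 0.001)$label, "regular")
  pois <- resting_train(mean_isi = 30, cv = 1, dur = 15, seed = 2)
  expect_identical(classify_regularity(pois)$label, "irregular")
})

test_that("units below the CV* domain are flagged unclassifiable", {
  fast <- resting_train(mean_isi = 10, cv = 0.5, dur = 15, seed = 6)
  res <- classify_regularity(fast)
  expect_identical(res$label, "unclassifiable")
  expect_true(is.na(res$cv_star))
})

test_that("simulated regular/irregular populations are recovered at the default threshold", {
  labs <- unlist(lapply(c(0.1, 1.0), function(cv) {
    vapply(1:25, function(i) {
      classify_regularity(resting_train(mean_isi = 30, cv = cv, dur = 15,
                                        seed = 1000 * cv + i))$label
    }, character(1))
  }))
  truth <- rep(c("regular", "irregular"), each = 25)
  expect_gte(mean(labs == truth), 0.95)
})

test_that("the frozen default threshold matches its calibration recipe", {
  th <- calibrate_regularity_threshold(n_units = 40L, duration = 30,
                                       seed = 424242L)
  expect_lt(abs(th - default_regularity_threshold()) / th, 0.05)
})
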