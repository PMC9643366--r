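# Fixture builders shared across test files. All fixtures are generated in
# code; nothing is read from disk.

resting_train <- function(mean_isi = 40, cv = 0.3, dur = 100, seed = 1,
                          organ = "canal", condition = "normal") {
  generate_spike_train(spike_train_spec(
    paste0("fix_", seed), organ, condition, mean_isi = mean_isi, cv = cv,
    epochs = list(epoch_spec("resting", 0, dur)), seed = seed))
}

# Train with resting + one modulated epoch.
modulated_train <- function(mean_isi = 40, cv = 0.3, seed = 1,
                            kin = NULL, gvs = NULL,
                            resting_dur = 15, epoch_dur = 20) {
  eps <- list(epoch_spec("resting", 0, resting_dur))
  t0 <- resting_dur + 2
  if (!is.null(kin)) {
    eps <- c(eps, list(epoch_spec("rotation", t0, t0 + epoch_dur, kin)))
    t0 <- t0 + epoch_dur + 2
  }
  if (!is.null(gvs)) {
    eps <- c(eps, list(epoch_spec("gvs", t0, t0 + epoch_dur, gvs)))
  }
  generate_spike_train(spike_train_spec(
    paste0("mod_", seed), "canal", "normal", mean_isi = mean_isi, cv = cv,
    epochs = eps, seed = seed))
}

# Hand-built train from explicit spike times (single resting epoch spanning
# the data unless epochs given).
manual_train <- function(times, epochs = NULL) {
  if (is.null(epochs)) {
    epochs <- data.frame(label = "resting", start = min(times) - 1e-9,
                         end = max(times) + 1e-9)
  }
  as_spike_train("manual", times, epochs)
}

# Closed-form pooled two-sample t oracle, written independently of the
# implementation path (which delegates to stats::t.test).
pooled_t_oracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  df <- nx + ny - 2
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# High-precision reference values for CV* (mu in ms, CV, CV*), computed
# once with a 50-digit arbitrary-precision evaluation of the printed
# formula (log base 10) and frozen here.
cv_star_reference <- function() {
  data.frame(
    mu = c(15, 15, 18, 20, 20, 20, 25, 30, 30, 30,
           35, 40, 40, 50, 50, 60, 70, 80, 90, 100),
    cv = c(0.1, 0.5, 0.3, 0.1, 0.3, 1.0, 0.5, 0.1, 0.3, 1.0,
           0.7, 0.2, 1.0, 0.5, 1.2, 0.3, 0.8, 0.4, 1.0, 0.6),
    cv_star = c(83.659458852405, 422.38082119306, 42.284510839435,
                9.9028155352248, 28.713457219916, 92.20424952738,
                29.103669542145, 4.205685070166, 13.483349203246,
                48.337271915242, 30.309261700252, 5.3802350376118,
                48.203265325129, 16.517971701215, 87.532353726958,
                4.1428700206939, 23.197805302026, 7.7466028423459,
                13.13364948704, 10.007258689013)
  )
}
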