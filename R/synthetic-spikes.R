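#' Rate-modulation specification for one epoch
#'
#' Describes the instantaneous firing-rate profile of an epoch: none
#' (stationary resting discharge), a sinusoid (head rotation or linear
#' translation), or a current step (GVS) with optional single-exponential
#' adaptation from the step peak toward a plateau.
#'
#' @param kind `"none"`, `"sinusoid"` or `"step"`.
#' @param baseline_rate baseline firing rate in spk/s (ignored for `"none"`,
#'   where the train's resting rate is `1000 / mean_isi`).
#' @param amplitude modulation amplitude in spk/s. For a sinusoid the rate
#'   swings `baseline_rate +/- amplitude`; for a step the rate jumps to
#'   `baseline_rate + amplitude` at epoch onset.
#' @param frequency sinusoid frequency in Hz.
#' @param phase sinusoid phase in radians at epoch onset.
#' @param adaptation_tau for steps, the exponential adaptation time constant
#'   in seconds; `NULL` means a tonic (non-adapting) step.
#' @param plateau_rate for adapting steps, the asymptotic rate in spk/s the
#'   response decays toward; defaults to `baseline_rate`.
#' @return an object of class `modulation_spec`.
#' @export
modulation_spec <- function(kind = c("none", "sinusoid", "step"),
                            baseline_rate = NULL, amplitude = 0,
                            frequency = NULL, phase = 0,
                            adaptation_tau = NULL, plateau_rate = NULL) {
  kind <- match.arg(kind)
  if (kind != "none") {
    stopifnot_scalar_num(baseline_rate, "baseline_rate", nonneg = TRUE)
    stopifnot_scalar_num(amplitude, "amplitude")
    if (baseline_rate + amplitude < 0 || (kind == "sinusoid" && baseline_rate - amplitude < 0)) {
      stop("invalid modulation: instantaneous rate would be negative", call. = FALSE)
    }
  }
  if (kind == "sinusoid") {
    stopifnot_scalar_num(frequency, "frequency", positive = TRUE)
  }
  if (!is.null(adaptation_tau)) {
    if (kind != "step") stop("adaptation_tau applies to step modulation only", call. = FALSE)
    stopifnot_scalar_num(adaptation_tau, "adaptation_tau", positive = TRUE)
  }
  if (!is.null(plateau_rate)) {
    stopifnot_scalar_num(plateau_rate, "plateau_rate", nonneg = TRUE)
  }
  structure(list(kind = kind, baseline_rate = baseline_rate,
                 amplitude = amplitude, frequency = frequency, phase = phase,
                 adaptation_tau = adaptation_tau, plateau_rate = plateau_rate),
            class = "modulation_spec")
}

#' Epoch specification
#'
#' One labeled interval of a recording: resting, rotation (canal stimulus),
#' transmission (otolith linear-translation stimulus) or gvs. Resting epochs
#' carry no modulation; rotation/transmission are sinusoidal; gvs is a step.
#'
#' @param label one of `"resting"`, `"rotation"`, `"transmission"`, `"gvs"`.
#' @param start,end epoch bounds in seconds, `start < end`.
#' @param modulation a [modulation_spec()].
#' @return an object of class `epoch_spec`.
#' @export
epoch_spec <- function(label = c("resting", "rotation", "transmission", "gvs"),
                       start, end, modulation = modulation_spec("none")) {
  label <- match.arg(label)
  stopifnot_scalar_num(start, "start")
  stopifnot_scalar_num(end, "end")
  if (start >= end) stop("epoch must have start < end", call. = FALSE)
  if (!inherits(modulation, "modulation_spec")) {
    stop("modulation must be a modulation_spec", call. = FALSE)
  }
  ok <- switch(label,
               resting = modulation$kind == "none",
               rotation = , transmission = modulation$kind == "sinusoid",
               gvs = modulation$kind == "step")
  if (!ok) {
    stop(sprintf("epoch label '%s' is incompatible with modulation kind '%s'",
                 label, modulation$kind), call. = FALSE)
  }
  structure(list(label = label, start = start, end = end,
                 modulation = modulation), class = "epoch_spec")
}

#' Spike-train specification
#'
#' Target parameters for one simulated vestibular-nucleus unit: the resting
#' inter-spike-interval distribution (gamma renewal with the given mean ISI
#' and coefficient of variation) plus an ordered list of epochs whose rate
#' profiles are realized by time rescaling of the same renewal process.
#'
#' @param unit_id unit identifier.
#' @param organ `"canal"` or `"otolith"`.
#' @param condition `"normal"` or `"PD"`.
#' @param mean_isi mean resting inter-spike interval in milliseconds, > 0.
#' @param cv coefficient of variation of the resting ISI distribution, >= 0.
#'   `cv = 0` yields a perfectly periodic (deterministic) train and is only
#'   supported for resting epochs.
#' @param epochs list of [epoch_spec()], ordered and non-overlapping.
#' @param seed integer seed; the generator is a pure function of (spec, seed).
#' @return an object of class `spike_train_spec`.
#' @export
spike_train_spec <- function(unit_id, organ = c("canal", "otolith"),
                             condition = c("normal", "PD"),
                             mean_isi, cv, epochs, seed) {
  organ <- match.arg(organ)
  condition <- match.arg(condition)
  stopifnot_scalar_num(mean_isi, "mean_isi", positive = TRUE)
  stopifnot_scalar_num(cv, "cv", nonneg = TRUE)
  if (!is.list(epochs) || length(epochs) == 0L ||
      !all(vapply(epochs, inherits, logical(1), "epoch_spec"))) {
    stop("epochs must be a non-empty list of epoch_spec", call. = FALSE)
  }
  starts <- vapply(epochs, `[[`, numeric(1), "start")
  ends <- vapply(epochs, `[[`, numeric(1), "end")
  if (is.unsorted(starts, strictly = TRUE) || any(starts[-1] < ends[-length(ends)])) {
    stop("epochs must be ordered and non-overlapping", call. = FALSE)
  }
  modulated <- vapply(epochs, function(e) e$modulation$kind != "none", logical(1))
  if (cv == 0 && any(modulated)) {
    stop("cv = 0 with modulation: deterministic trains only supported at rest",
         call. = FALSE)
  }
  structure(list(unit_id = unit_id, organ = organ, condition = condition,
                 mean_isi = mean_isi, cv = cv, epochs = epochs, seed = seed),
            class = "spike_train_spec")
}

# Instantaneous-rate function (spk/s) of one epoch, as a function of
# absolute time. Resting epochs discharge at 1000/mean_isi.
epoch_rate_fun <- function(epoch, resting_rate) {
  m <- epoch$modulation
  t0 <- epoch$start
  switch(m$kind,
         none = function(t) rep(resting_rate, length(t)),
         sinusoid = function(t) {
           m$baseline_rate + m$amplitude * sin(2 * pi * m$frequency * (t - t0) + m$phase)
         },
         step = {
           peak <- m$baseline_rate + m$amplitude
           if (is.null(m$adaptation_tau)) {
             function(t) rep(peak, length(t))
           } else {
             plateau <- m$plateau_rate %||% m$baseline_rate
             function(t) plateau + (peak - plateau) * exp(-(t - t0) / m$adaptation_tau)
           }
         })
}

# Stationary gamma-renewal ISI draws (seconds) with mean mu_s and CV cv.
draw_gamma_isis <- function(n, mu_s, cv) {
  shape <- 1 / cv^2
  stats::rgamma(n, shape = shape, scale = mu_s * cv^2)
}

# Spikes of a stationary (ordinary) gamma renewal process on (start, end].
generate_stationary_epoch <- function(start, end, mu_s, cv) {
  dur <- end - start
  if (cv == 0) {
    n <- floor(dur / mu_s)
    if (n < 1) return(numeric(0))
    return(start + mu_s * seq_len(n))
  }
  times <- numeric(0)
  t <- start
  chunk <- max(64L, ceiling(dur / mu_s * 1.5))
  repeat {
    isis <- draw_gamma_isis(chunk, mu_s, cv)
    tt <- t + cumsum(isis)
    times <- c(times, tt[tt <= end])
    if (tt[length(tt)] > end) break
    t <- tt[length(tt)]
  }
  times
}

# Spikes of an inhomogeneous renewal process on (start, end] with rate
# profile rate_fun, by time rescaling: a unit-mean gamma renewal sequence
# is generated on the integrated-rate axis and mapped back through the
# inverse of Lambda(t) = integral of rate.
generate_rescaled_epoch <- function(start, end, rate_fun, cv, dt = 1e-3) {
  grid <- seq(start, end, by = dt)
  if (grid[length(grid)] < end) grid <- c(grid, end)
  r <- rate_fun(grid)
  if (any(r < -1e-9)) stop("invalid modulation: negative instantaneous rate", call. = FALSE)
  r <- pmax(r, 0)
  # cumulative trapezoid of the rate
  lam <- c(0, cumsum((r[-1] + r[-length(r)]) / 2 * diff(grid)))
  lam_tot <- lam[length(lam)]
  if (lam_tot <= 0) return(numeric(0))
  s <- numeric(0)
  acc <- 0
  chunk <- max(64L, ceiling(lam_tot * 1.5))
  repeat {
    isis <- draw_gamma_isis(chunk, 1, cv)
    ss <- acc + cumsum(isis)
    s <- c(s, ss[ss <= lam_tot])
    if (ss[length(ss)] > lam_tot) break
    acc <- ss[length(ss)]
  }
  if (length(s) == 0L) return(numeric(0))
  # invert Lambda by monotone linear interpolation
  stats::approx(x = lam, y = grid, xout = s, ties = "ordered")$y
}

#' Generate a spike train from a specification
#'
#' Resting epochs are drawn from a stationary gamma renewal process with the
#' spec's mean ISI and CV (shape `1/cv^2`; `cv = 0` gives an exactly periodic
#' train). Modulated epochs are generated as inhomogeneous renewal processes
#' by time rescaling of the epoch's rate function, so the local rate follows
#' the target profile while interval dispersion keeps the unit's CV.
#' Reproducible: the output is a pure function of (spec, seed).
#'
#' @param spec a [spike_train_spec()].
#' @return an object of class `spike_train`: list with `unit_id`, `organ`,
#'   `condition`, `spike_times` (seconds, strictly increasing), `epochs`
#'   (data frame of label/start/end), and the generating `mean_isi`, `cv`,
#'   `seed`.
#' @export
#' @examples
#' sp <- spike_train_spec("u1", "canal", "normal", mean_isi = 50, cv = 0.3,
#'                        epochs = list(epoch_spec("resting", 0, 15)), seed = 1)
#' train <- generate_spike_train(sp)
#' length(train$spike_times)
generate_spike_train <- function(spec) {
  if (!inherits(spec, "spike_train_spec")) {
    stop("spec must be a spike_train_spec", call. = FALSE)
  }
  mu_s <- spec$mean_isi / 1000
  resting_rate <- 1 / mu_s
  times <- with_seed(spec$seed, {
    unlist(lapply(spec$epochs, function(ep) {
      if (ep$modulation$kind == "none") {
        generate_stationary_epoch(ep$start, ep$end, mu_s, spec$cv)
      } else {
        rf <- epoch_rate_fun(ep, resting_rate)
        # validate rate non-negativity at epoch bounds analytically too
        generate_rescaled_epoch(ep$start, ep$end, rf, spec$cv)
      }
    }))
  })
  times <- sort(times)
  times <- times[!duplicated(times)]
  epochs <- data.frame(
    label = vapply(spec$epochs, `[[`, character(1), "label"),
    start = vapply(spec$epochs, `[[`, numeric(1), "start"),
    end = vapply(spec$epochs, `[[`, numeric(1), "end"),
    stringsAsFactors = FALSE
  )
  structure(list(unit_id = spec$unit_id, organ = spec$organ,
                 condition = spec$condition, spike_times = times,
                 epochs = epochs, mean_isi = spec$mean_isi, cv = spec$cv,
                 seed = spec$seed),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> unit %s (%s, %s): %d spikes over %d epochs\n",
              x$unit_id, x$organ, x$condition, length(x$spike_times),
              nrow(x$epochs)))
  invisible(x)
}

#' Construct a spike train directly from spike times
#'
#' Used when reading recorded (or previously written) spike/epoch tables
#' rather than simulating.
#'
#' @param unit_id unit identifier.
#' @param spike_times strictly increasing spike times in seconds.
#' @param epochs data frame with columns `label`, `start`, `end`.
#' @param organ,condition unit metadata.
#' @return a `spike_train` object.
#' @export
as_spike_train <- function(unit_id, spike_times, epochs,
                           organ = c("canal", "otolith"),
                           condition = c("normal", "PD")) {
  organ <- match.arg(organ)
  condition <- match.arg(condition)
  if (is.unsorted(spike_times, strictly = TRUE)) {
    stop("spike_times must be strictly increasing", call. = FALSE)
  }
  stopifnot(all(c("label", "start", "end") %in% names(epochs)))
  structure(list(unit_id = unit_id, organ = organ, condition = condition,
                 spike_times = as.numeric(spike_times),
                 epochs = as.data.frame(epochs), mean_isi = NA_real_,
                 cv = NA_real_, seed = NA_integer_),
            class = "spike_train")
}
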