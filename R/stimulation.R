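#' GVS pulse-train protocol
#'
#' Description of a galvanic-vestibular-stimulation schedule: trains of
#' rectangular current pulses (or an arbitrary sampled waveform) organized in
#' sets. Defaults mirror the study protocol: 20 stimuli of 3 s per set, one
#' stimulus every 60 s, three sets separated by 10 min. Electrode polarity
#' (left anode, right cathode) is carried as metadata only — it does not
#' enter the charge magnitude.
#'
#' @param amplitude current amplitude in amperes, >= 0.
#' @param pulse_duration duration of one stimulus in seconds, > 0.
#' @param pulses_per_set stimuli per set, >= 1.
#' @param n_sets number of sets, >= 1.
#' @param inter_pulse_interval seconds between stimulus onsets within a set.
#' @param inter_set_interval seconds between sets.
#' @param waveform `"rect"` for rectangular pulses or `"sampled"` for an
#'   explicit waveform.
#' @param samples for `"sampled"`: data frame or list with `time` (s,
#'   strictly increasing) and `current` (A) describing one stimulus.
#' @param polarity named character vector of electrode polarities (metadata).
#' @return an object of class `gvs_protocol`.
#' @export
gvs_protocol <- function(amplitude, pulse_duration = 3, pulses_per_set = 20L,
                         n_sets = 3L, inter_pulse_interval = 60,
                         inter_set_interval = 600,
                         waveform = c("rect", "sampled"), samples = NULL,
                         polarity = c(left = "anode", right = "cathode")) {
  waveform <- match.arg(waveform)
  stopifnot_scalar_num(amplitude, "amplitude", nonneg = TRUE)
  stopifnot_scalar_num(pulse_duration, "pulse_duration", positive = TRUE)
  if (!is.numeric(pulses_per_set) || pulses_per_set < 1) {
    stop("pulses_per_set must be >= 1", call. = FALSE)
  }
  if (!is.numeric(n_sets) || n_sets < 1) stop("n_sets must be >= 1", call. = FALSE)
  if (waveform == "sampled") {
    if (is.null(samples) || is.null(samples$time) || is.null(samples$current) ||
        length(samples$time) != length(samples$current) || length(samples$time) < 2L) {
      stop("sampled waveform requires parallel `time` and `current` vectors",
           call. = FALSE)
    }
    if (is.unsorted(samples$time, strictly = TRUE)) {
      stop("sampled waveform times must be strictly increasing", call. = FALSE)
    }
  }
  structure(list(amplitude = amplitude, pulse_duration = pulse_duration,
                 pulses_per_set = as.integer(pulses_per_set),
                 n_sets = as.integer(n_sets),
                 inter_pulse_interval = inter_pulse_interval,
                 inter_set_interval = inter_set_interval,
                 waveform = waveform, samples = samples, polarity = polarity),
            class = "gvs_protocol")
}

#' Total delivered electrical charge of a GVS protocol
#'
#' Charge conservation over the whole schedule:
#' \deqn{q = n_{sets} \sum_{1}^{pulses} \int_{t_1}^{t_2} I(t)\,dt}
#' For rectangular pulses this is exactly
#' `n_sets * pulses_per_set * amplitude * pulse_duration`; for a sampled
#' waveform the per-stimulus integral is evaluated by the trapezoidal rule.
#'
#' @param protocol a [gvs_protocol()].
#' @return total charge in coulombs.
#' @export
#' @examples
#' total_charge(gvs_protocol(amplitude = 100e-6))  # 0.018 C
total_charge <- function(protocol) {
  if (!inherits(protocol, "gvs_protocol")) {
    stop("protocol must be a gvs_protocol", call. = FALSE)
  }
  per_pulse <- if (protocol$waveform == "rect") {
    protocol$amplitude * protocol$pulse_duration
  } else {
    t <- protocol$samples$time
    i <- protocol$samples$current
    sum(diff(t) * (i[-1] + i[-length(i)]) / 2)
  }
  protocol$n_sets * protocol$pulses_per_set * per_pulse
}

#' Stimulation amplitudes of the treatment groups
#'
#' @return named numeric vector of amplitudes in amperes for the five
#'   treatment groups (control and untreated PD received no GVS).
#' @export
gvs_group_amplitudes <- function() {
  c(control = 0, PD = 0, PD_100uA = 100e-6, PD_500uA = 500e-6,
    PD_1000uA = 1000e-6)
}

#' Delivered charge per treatment group
#'
#' Applies [total_charge()] with the default study protocol to each group's
#' amplitude. Unstimulated groups (`control`, `PD`) map to 0 C.
#'
#' @param groups named numeric vector of amplitudes in amperes (names are
#'   group labels), or character vector of known group labels; defaults to
#'   [gvs_group_amplitudes()].
#' @param protocol template [gvs_protocol()]; its amplitude is replaced per
#'   group.
#' @return data frame with columns `group`, `amplitude_uA`, `charge_C`,
#'   ordered by ascending charge.
#' @export
#' @examples
#' charge_per_group()
charge_per_group <- function(groups = gvs_group_amplitudes(),
                             protocol = gvs_protocol(amplitude = 0)) {
  if (is.character(groups)) {
    known <- gvs_group_amplitudes()
    bad <- setdiff(groups, names(known))
    if (length(bad) > 0L) {
      stop(sprintf("unknown group label(s): %s", paste(bad, collapse = ", ")),
           call. = FALSE)
    }
    groups <- known[groups]
  }
  if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
    stop("groups must be named amplitudes", call. = FALSE)
  }
  if (any(groups < 0)) stop("amplitudes must be >= 0", call. = FALSE)
  charge <- vapply(groups, function(a) {
    p <- protocol
    p$amplitude <- a
    total_charge(p)
  }, numeric(1))
  out <- data.frame(group = names(groups), amplitude_uA = unname(groups) * 1e6,
                    charge_C = unname(charge), stringsAsFactors = FALSE)
  out[order(out$charge_C, out$group), , drop = FALSE]
}
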