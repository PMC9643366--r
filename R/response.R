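# Stimulus-response characterization: kinetic (rotation/translation)
# modulation depth and tonic/phasic classification of GVS responses.

smooth_rates <- function(rates, width = 5L) {
  width <- as.integer(width)
  if (width < 1L) stop("smooth_width must be >= 1", call. = FALSE)
  if (width %% 2L == 0L) width <- width + 1L
  if (length(rates) <= width) return(rates)
  as.numeric(stats::runmed(rates, k = width, endrule = "median"))
}

response_summary <- function(unit_id, epoch_label, resting_rate = NA_real_,
                             peak_rate = NA_real_, trough_rate = NA_real_,
                             modulation_depth = NA_real_, gvs_class = "none",
                             adaptation_index = NA_real_, gain = NA_real_,
                             ai_threshold = NA_real_) {
  structure(list(unit_id = unit_id, epoch_label = epoch_label,
                 resting_rate = resting_rate, peak_rate = peak_rate,
                 trough_rate = trough_rate, modulation_depth = modulation_depth,
                 gvs_class = gvs_class, adaptation_index = adaptation_index,
                 gain = gain, ai_threshold = ai_threshold),
            class = "response_summary")
}

#' @export
as.data.frame.response_summary <- function(x, ...) {
  data.frame(unit_id = x$unit_id, epoch_label = x$epoch_label,
             resting_rate = x$resting_rate, peak_rate = x$peak_rate,
             trough_rate = x$trough_rate, modulation_depth = x$modulation_depth,
             gvs_class = x$gvs_class, adaptation_index = x$adaptation_index,
             gain = x$gain, ai_threshold = x$ai_threshold,
             stringsAsFactors = FALSE)
}

#' Kinetic (rotation/translation) response summary
#'
#' Peak and trough of the IFR within the kinetic epoch, after a moving-median
#' smooth (raw reciprocal ISIs are heavy-tailed). The modulation depth is the
#' larger of the peak excursion above the resting rate and the trough
#' excursion below it, in spk/s; if the stimulus amplitude is supplied, a
#' gain (depth/amplitude) is also reported.
#'
#' @param train a `spike_train`.
#' @param epoch_label `"rotation"` or `"transmission"`.
#' @param smooth_width moving-median width in intervals (default 5).
#' @param stimulus_amplitude optional stimulus amplitude to normalize by.
#' @param resting_window passed to [resting_rate()].
#' @return a `response_summary`.
#' @export
kinetic_response <- function(train, epoch_label = c("rotation", "transmission"),
                             smooth_width = 5L, stimulus_amplitude = NULL,
                             resting_window = 10) {
  epoch_label <- match.arg(epoch_label)
  ep <- find_epoch(train, epoch_label)
  st <- train$spike_times
  n_inside <- sum(st >= ep$start & st <= ep$end)
  if (n_inside < 10L) {
    stop(sprintf("insufficient spikes in '%s' epoch (%d found, >= 10 required)",
                 epoch_label, n_inside), call. = FALSE)
  }
  rr <- resting_rate(train, window = resting_window)
  ifr <- instantaneous_firing_rate(train, epoch_label)
  sm <- smooth_rates(ifr$rates, smooth_width)
  peak <- max(sm)
  trough <- min(sm)
  depth <- max(peak - rr, rr - trough)
  gain <- if (is.null(stimulus_amplitude)) NA_real_ else depth / stimulus_amplitude
  response_summary(train$unit_id, epoch_label, resting_rate = rr,
                   peak_rate = peak, trough_rate = trough,
                   modulation_depth = depth, gvs_class = "none", gain = gain)
}

#' GVS response summary and tonic/phasic classification
#'
#' Mean IFR in the first and last quarters of the gvs epoch give the
#' adaptation index `AI = (R_early - R_late) / max(R_early, R_late)`, a
#' dimensionless, rate-scale-invariant measure of within-epoch decay. The
#' response is classified phasic when `|AI|` exceeds the threshold (default
#' 0.25), tonic otherwise; a train with no gvs epoch returns class `"none"`.
#'
#' @param train a `spike_train`.
#' @param ai_threshold phasic cutoff on `|AI|`.
#' @param smooth_width moving-median width for peak/trough extraction.
#' @param resting_window passed to [resting_rate()].
#' @return a `response_summary` with `gvs_class` in tonic/phasic/none.
#' @export
gvs_response <- function(train, ai_threshold = 0.25, smooth_width = 5L,
                         resting_window = 10) {
  stopifnot_scalar_num(ai_threshold, "ai_threshold", positive = TRUE)
  if (!"gvs" %in% train$epochs$label) {
    return(response_summary(train$unit_id, "gvs", gvs_class = "none",
                            ai_threshold = ai_threshold))
  }
  ep <- find_epoch(train, "gvs")
  st <- train$spike_times
  n_inside <- sum(st >= ep$start & st <= ep$end)
  if (n_inside < 10L) {
    stop(sprintf("insufficient spikes in 'gvs' epoch (%d found, >= 10 required)",
                 n_inside), call. = FALSE)
  }
  rr <- tryCatch(resting_rate(train, window = resting_window),
                 error = function(e) NA_real_)
  ifr <- instantaneous_firing_rate(train, "gvs")
  q <- (ep$end - ep$start) / 4
  early <- ifr$rates[ifr$times <= ep$start + q]
  late <- ifr$rates[ifr$times >= ep$end - q]
  if (length(early) == 0L || length(late) == 0L) {
    stop("insufficient spikes in the first or last quarter of the gvs epoch",
         call. = FALSE)
  }
  r_early <- mean(early)
  r_late <- mean(late)
  ai <- (r_early - r_late) / max(r_early, r_late)
  sm <- smooth_rates(ifr$rates, smooth_width)
  peak <- max(sm)
  trough <- min(sm)
  depth <- if (is.na(rr)) NA_real_ else max(peak - rr, rr - trough)
  cls <- if (abs(ai) > ai_threshold) "phasic" else "tonic"
  response_summary(train$unit_id, "gvs", resting_rate = rr, peak_rate = peak,
                   trough_rate = trough, modulation_depth = depth,
                   gvs_class = cls, adaptation_index = ai,
                   ai_threshold = ai_threshold)
}

#' Response table for a list of trains
#'
#' Applies [kinetic_response()] (to whichever of rotation/transmission each
#' train has) and [gvs_response()] and binds the rows.
#'
#' @param trains list of `spike_train`.
#' @param ai_threshold,smooth_width,resting_window passed through.
#' @return data frame, one row per (unit, analyzed epoch).
#' @export
response_table <- function(trains, ai_threshold = 0.25, smooth_width = 5L,
                           resting_window = 10) {
  rows <- lapply(trains, function(tr) {
    out <- list()
    for (lab in intersect(c("rotation", "transmission"), tr$epochs$label)) {
      out <- c(out, list(as.data.frame(kinetic_response(
        tr, lab, smooth_width = smooth_width, resting_window = resting_window))))
    }
    out <- c(out, list(as.data.frame(gvs_response(
      tr, ai_threshold = ai_threshold, smooth_width = smooth_width,
      resting_window = resting_window))))
    do.call(rbind, out)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
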