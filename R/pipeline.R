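# End-to-end orchestration: generate the synthetic cohort, measure every
# unit, compute dosimetry and group statistics, and write the report bundle.

#' Default run configuration
#'
#' Fully serializable description of one pipeline run. Cohort sizes default
#' to the study census (32 canal units of which 20 from non-lesioned animals,
#' 33 otolith units of which 21 non-lesioned); resting rates span 14-34
#' spk/s; the receptor design defaults to the five-group histology layout.
#' Normal and PD units share the same resting-rate range by default (the
#' study found no significant resting-rate difference).
#'
#' @param seed integer master seed; all randomness derives from it.
#' @return a `run_config` list.
#' @export
default_run_config <- function(seed = 1L) {
  cohort <- data.frame(
    organ = c("canal", "canal", "otolith", "otolith"),
    condition = c("normal", "PD", "normal", "PD"),
    n = c(20L, 12L, 21L, 12L),
    stringsAsFactors = FALSE
  )
  rec <- default_receptor_specs()
  receptors <- do.call(rbind, lapply(rec, function(sp) {
    data.frame(group = sp$group, receptor = sp$receptor,
               mean_density = sp$mean_density, sem = sp$sem,
               n_animals = sp$n_animals,
               fields_per_animal = sp$fields_per_animal,
               stringsAsFactors = FALSE)
  }))
  structure(list(
    seed = as.integer(seed),
    cohort = cohort,
    spikes = list(
      resting = c(0, 15), kinetic = c(17, 37), gvs = c(39, 55),
      rate_range = c(14, 34),          # resting rates, spk/s
      cv_regular = 0.1, cv_irregular = 1.0, prop_irregular = 0.5,
      sinusoid_frequency = 0.5,        # Hz; stimulus frequency is configurable,
      sinusoid_rel_amplitude = 0.8,    # not a study-reported value
      gvs_step_amplitude = 30,         # spk/s
      prop_phasic = 0.5, adaptation_tau = 4
    ),
    receptors = list(specs = receptors, field_area_mm2 = 0.15,
                     field_noise = "poisson"),
    rotarod = list(n_animals = 9L, phase_means = c(20.78, 71.23, 5.24),
                   phase_sems = c(6.59, 14.06, 1.23)),
    protocol = list(pulse_duration = 3, pulses_per_set = 20L, n_sets = 3L,
                    inter_pulse_interval = 60, inter_set_interval = 600),
    analysis = list(log_base = "log10",
                    regularity_threshold = default_regularity_threshold(),
                    t_variant = "pooled", ai_threshold = 0.25,
                    resting_window = 10, smooth_width = 5L)
  ), class = "run_config")
}

#' Build the spike-train specifications of a cohort
#'
#' Deterministic expansion of a run configuration into one
#' [spike_train_spec()] per unit. Within each (organ, condition) cell,
#' regular/irregular and tonic/phasic assignments alternate so stratum counts
#' are exact; resting mean ISIs are drawn uniformly over the configured rate
#' range with a seed derived from the master seed.
#'
#' @param config a `run_config`.
#' @return list of `spike_train_spec`.
#' @export
build_cohort_specs <- function(config) {
  sp <- config$spikes
  mu_range_ms <- sort(1000 / sp$rate_range)
  specs <- list()
  idx <- 0L
  for (i in seq_len(nrow(config$cohort))) {
    organ <- config$cohort$organ[i]
    condition <- config$cohort$condition[i]
    n <- config$cohort$n[i]
    n_irr <- round(n * sp$prop_irregular)
    n_pha <- round(n * sp$prop_phasic)
    mus <- with_seed(derive_seed(config$seed, 5000L + i),
                     stats::runif(n, mu_range_ms[1], mu_range_ms[2]))
    for (j in seq_len(n)) {
      idx <- idx + 1L
      irregular <- j <= n_irr
      phasic <- j <= n_pha
      cv <- if (irregular) sp$cv_irregular else sp$cv_regular
      baseline <- 1000 / mus[j]
      kin_label <- if (organ == "canal") "rotation" else "transmission"
      kin_mod <- modulation_spec("sinusoid", baseline_rate = baseline,
                                 amplitude = sp$sinusoid_rel_amplitude * baseline,
                                 frequency = sp$sinusoid_frequency)
      gvs_mod <- if (phasic) {
        modulation_spec("step", baseline_rate = baseline,
                        amplitude = sp$gvs_step_amplitude,
                        adaptation_tau = sp$adaptation_tau)
      } else {
        modulation_spec("step", baseline_rate = baseline,
                        amplitude = sp$gvs_step_amplitude)
      }
      specs[[idx]] <- spike_train_spec(
        unit_id = sprintf("u%03d_%s_%s", idx, organ, condition),
        organ = organ, condition = condition,
        mean_isi = mus[j], cv = cv,
        epochs = list(
          epoch_spec("resting", sp$resting[1], sp$resting[2]),
          epoch_spec(kin_label, sp$kinetic[1], sp$kinetic[2], kin_mod),
          epoch_spec("gvs", sp$gvs[1], sp$gvs[2], gvs_mod)
        ),
        seed = derive_seed(config$seed, idx)
      )
    }
  }
  specs
}

#' Generate the cohort's spike trains
#'
#' @param config a `run_config`.
#' @return list of `spike_train`.
#' @export
generate_cohort <- function(config) {
  lapply(build_cohort_specs(config), generate_spike_train)
}

#' Stratum counts and percentages of a metrics table
#'
#' Counts and percentages per (organ x condition) and (organ x regularity)
#' strata; percentages are within-organ and rounded to one decimal place.
#'
#' @param metrics per-unit metrics table (columns `organ`, `condition`,
#'   `label`).
#' @return list with `by_condition` and `by_regularity` data frames and
#'   `n_total`.
#' @export
summarize_cohort <- function(metrics) {
  strata <- function(field, levels_field) {
    out <- expand.grid(organ = c("canal", "otolith"), value = levels_field,
                       stringsAsFactors = FALSE)
    out$n <- mapply(function(o, v) {
      sum(metrics$organ == o & metrics[[field]] == v)
    }, out$organ, out$value)
    tot <- vapply(out$organ, function(o) sum(metrics$organ == o), numeric(1))
    out$pct <- ifelse(tot > 0, round(100 * out$n / tot, 1), 0)
    names(out)[names(out) == "value"] <- field
    out
  }
  list(by_condition = strata("condition", c("normal", "PD")),
       by_regularity = strata("label", c("regular", "irregular")),
       n_total = nrow(metrics))
}

# Order-independent checksum-ish hash of the serialized config (FNV-1a over
# its JSON), recorded in the manifest so a run can be tied to its config.
config_hash <- function(config) {
  s <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  bytes <- utf8ToInt(as.character(s))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

#' Run the full analysis pipeline
#'
#' Generates the synthetic cohort and receptor tables, computes per-unit
#' metrics and stimulus responses, charge dosimetry, and all group
#' comparisons, and writes every table (tab-delimited, one-line headers) plus
#' a JSON run manifest into `out_dir`. Re-running with the same config and
#' seed reproduces the bundle byte-identically.
#'
#' @param config a `run_config`; see [default_run_config()].
#' @param out_dir output directory (created if missing); `NULL` skips writing.
#' @return invisible list with `trains`, `metrics`, `responses`, `charges`,
#'   `receptor_table`, `rotarod`, `cohort_summary`, `side_contrasts`,
#'   `pd_vs_control`, `dose_response`, `fr_contrasts`, `manifest`.
#' @export
run_pipeline <- function(config = default_run_config(), out_dir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  an <- config$analysis

  trains <- stage("generate_spikes", generate_cohort(config))

  metrics <- stage("spike_metrics", {
    do.call(rbind, lapply(trains, spike_train_metrics,
                          threshold = an$regularity_threshold,
                          log_base = an$log_base,
                          resting_window = an$resting_window))
  })

  responses <- stage("responses", response_table(
    trains, ai_threshold = an$ai_threshold, smooth_width = an$smooth_width,
    resting_window = an$resting_window))

  proto <- config$protocol
  charges <- stage("charge", charge_per_group(
    protocol = gvs_protocol(amplitude = 0,
                            pulse_duration = proto$pulse_duration,
                            pulses_per_set = proto$pulses_per_set,
                            n_sets = proto$n_sets,
                            inter_pulse_interval = proto$inter_pulse_interval,
                            inter_set_interval = proto$inter_set_interval)))

  rec_specs <- stage("receptor_specs", {
    rs <- config$receptors$specs
    lapply(seq_len(nrow(rs)), function(i) {
      receptor_group_spec(rs$group[i], rs$receptor[i], rs$mean_density[i],
                          rs$sem[i], rs$n_animals[i], rs$fields_per_animal[i])
    })
  })
  receptor_table <- stage("generate_receptors", generate_receptor_table(
    rec_specs, seed = derive_seed(config$seed, 900001L),
    field_area_mm2 = config$receptors$field_area_mm2,
    field_noise = config$receptors$field_noise))

  rotarod <- stage("rotarod", generate_rotarod(
    n_animals = config$rotarod$n_animals,
    phase_means = config$rotarod$phase_means,
    phase_sds = config$rotarod$phase_sems * sqrt(config$rotarod$n_animals),
    seed = derive_seed(config$seed, 900002L)))

  side_contrasts <- stage("side_contrast", suppressMessages(rbind(
    side_contrast(receptor_table, "AMPA", variant = an$t_variant),
    side_contrast(receptor_table, "NMDA", variant = an$t_variant))))
  pd_ctrl <- stage("pd_vs_control", rbind(
    pd_vs_control(receptor_table, "AMPA", variant = an$t_variant),
    pd_vs_control(receptor_table, "NMDA", variant = an$t_variant)))
  dr <- stage("dose_response", suppressMessages(list(
    AMPA = dose_response(receptor_table, "AMPA", charges, variant = an$t_variant),
    NMDA = dose_response(receptor_table, "NMDA", charges, variant = an$t_variant))))
  fr_contrasts <- stage("fr_contrast", suppressMessages(
    population_fr_contrast(metrics, variant = an$t_variant)))

  cohort_summary <- stage("summarize", summarize_cohort(metrics))

  manifest <- list(
    package = "vnstim",
    seed = config$seed,
    config_hash = config_hash(config),
    n_units = nrow(metrics),
    analysis_options = an,
    charge_table = charges,
    config = unclass(config)
  )

  bundle <- list(trains = trains, metrics = metrics, responses = responses,
                 charges = charges, receptor_table = receptor_table,
                 rotarod = rotarod, cohort_summary = cohort_summary,
                 side_contrasts = side_contrasts, pd_vs_control = pd_ctrl,
                 dose_response = dr, fr_contrasts = fr_contrasts,
                 manifest = manifest)

  if (!is.null(out_dir)) {
    stage("write", {
      if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
      write_spike_tables(trains, out_dir)
      write_delim_table(metrics, file.path(out_dir, "unit_metrics.tsv"))
      write_delim_table(responses, file.path(out_dir, "unit_responses.tsv"))
      write_delim_table(charges, file.path(out_dir, "charge_table.tsv"))
      write_delim_table(receptor_table, file.path(out_dir, "receptor_counts.tsv"))
      write_delim_table(rotarod, file.path(out_dir, "rotarod.tsv"))
      write_delim_table(side_contrasts, file.path(out_dir, "side_contrasts.tsv"))
      write_delim_table(pd_ctrl, file.path(out_dir, "pd_vs_control.tsv"))
      write_delim_table(rbind(cbind(receptor = "AMPA", dr$AMPA$summary),
                              cbind(receptor = "NMDA", dr$NMDA$summary)),
                        file.path(out_dir, "dose_response_summary.tsv"))
      drc <- rbind(dr$AMPA$comparisons, dr$NMDA$comparisons)
      if (!is.null(drc)) {
        write_delim_table(drc, file.path(out_dir, "dose_response_comparisons.tsv"))
      }
      if (!is.null(fr_contrasts)) {
        write_delim_table(fr_contrasts, file.path(out_dir, "fr_contrasts.tsv"))
      }
      write_delim_table(cohort_summary$by_condition,
                        file.path(out_dir, "cohort_by_condition.tsv"))
      write_delim_table(cohort_summary$by_regularity,
                        file.path(out_dir, "cohort_by_regularity.tsv"))
      jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    })
  }
  invisible(bundle)
}
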