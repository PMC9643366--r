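# Group-level statistics on receptor densities and resting firing rates:
# two-sample t contrasts, left/right control comparison, and the
# dose-response of NMDA density against delivered GVS charge.

#' Two-sample t-test comparison
#'
#' Two-sided two-sample t-test (pooled variance by default, Welch optional)
#' packaged with the group summaries. Degenerate inputs (zero variance in
#' both samples) are resolved by convention: equal means give t = 0, p = 1;
#' unequal means give p at the smallest representable positive value with a
#' `degenerate` flag.
#'
#' @param x,y numeric samples, each of length >= 2.
#' @param variant `"pooled"` (default) or `"welch"`.
#' @param group_a,group_b labels carried into the result.
#' @return a `group_comparison`: one-row data frame with columns `group_a`,
#'   `group_b`, `n_a`, `n_b`, `mean_a`, `mean_b`, `sem_a`, `sem_b`, `t_stat`,
#'   `df`, `p_value`, `test`, `degenerate`.
#' @export
#' @examples
#' two_sample_t(1:5, 2:6)  # t = -1, p ~ 0.3466
two_sample_t <- function(x, y, variant = c("pooled", "welch"),
                         group_a = "a", group_b = "b") {
  variant <- match.arg(variant)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 2L || length(y) < 2L) {
    stop("both samples must have n >= 2", call. = FALSE)
  }
  sem <- function(v) stats::sd(v) / sqrt(length(v))
  degenerate <- FALSE
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (mean(x) == mean(y)) {
      t_stat <- 0; p <- 1; df <- length(x) + length(y) - 2
    } else {
      t_stat <- sign(mean(x) - mean(y)) * Inf
      p <- .Machine$double.xmin
      df <- length(x) + length(y) - 2
      degenerate <- TRUE
    }
  } else {
    ht <- stats::t.test(x, y, var.equal = (variant == "pooled"))
    t_stat <- unname(ht$statistic)
    df <- unname(ht$parameter)
    p <- ht$p.value
  }
  out <- data.frame(group_a = group_a, group_b = group_b,
                    n_a = length(x), n_b = length(y),
                    mean_a = mean(x), mean_b = mean(y),
                    sem_a = sem(x), sem_b = sem(y),
                    t_stat = t_stat, df = df, p_value = p,
                    test = variant, degenerate = degenerate,
                    stringsAsFactors = FALSE)
  class(out) <- c("group_comparison", "data.frame")
  out
}

note_multiple_tests <- function(k) {
  if (k > 3L) {
    message(sprintf(
      "note: %d t-tests run in one invocation with no multiple-testing correction",
      k))
  }
}

#' Per-(animal, side) mean receptor density
#'
#' Aggregates the field-level count table to the analysis unit: the mean
#' density (count/area, counts/mm^2) per animal and side.
#'
#' @param table receptor-count table (see [generate_receptor_table()]).
#' @param receptor `"AMPA"` or `"NMDA"`; `NULL` keeps both.
#' @return data frame with columns `group`, `animal_id`, `side`, `receptor`,
#'   `density`.
#' @export
animal_side_density <- function(table, receptor = NULL) {
  req <- c("animal_id", "group", "side", "receptor", "area_mm2", "count")
  miss <- setdiff(req, names(table))
  if (length(miss) > 0L) {
    stop(sprintf("receptor table lacks column(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  if (any(table$area_mm2 <= 0)) stop("area_mm2 must be > 0", call. = FALSE)
  if (any(table$count < 0)) stop("count must be >= 0", call. = FALSE)
  if (!is.null(receptor)) table <- table[table$receptor == receptor, , drop = FALSE]
  if (nrow(table) == 0L) stop("no rows for the requested receptor", call. = FALSE)
  dens <- table$count / table$area_mm2
  agg <- stats::aggregate(
    dens,
    by = list(group = table$group, animal_id = table$animal_id,
              side = table$side, receptor = table$receptor),
    FUN = mean)
  names(agg)[names(agg) == "x"] <- "density"
  agg[order(agg$group, agg$animal_id, agg$side), , drop = FALSE]
}

#' Left/right receptor-density contrast per group
#'
#' Within each treatment group, compares left- versus right-side densities
#' (animal-side means) with a two-sample t-test. Groups where an animal lacks
#' one side are skipped with a warning.
#'
#' @param table receptor-count table.
#' @param receptor receptor subtype to analyze.
#' @param variant t-test variant.
#' @return data frame of `group_comparison` rows (one per group) with an
#'   extra `group` and `receptor` column.
#' @export
side_contrast <- function(table, receptor = c("AMPA", "NMDA"),
                          variant = "pooled") {
  receptor <- match.arg(receptor)
  d <- animal_side_density(table, receptor)
  rows <- list()
  for (g in unique(d$group)) {
    dg <- d[d$group == g, , drop = FALSE]
    sides <- table(dg$animal_id, dg$side)
    if (!all(c("L", "R") %in% colnames(sides)) || any(sides == 0)) {
      warning(sprintf("group '%s' skipped: not every animal has both sides", g),
              call. = FALSE)
      next
    }
    cmp <- two_sample_t(dg$density[dg$side == "L"], dg$density[dg$side == "R"],
                        variant = variant, group_a = "L", group_b = "R")
    cmp$group <- g
    cmp$receptor <- receptor
    rows[[g]] <- cmp
  }
  note_multiple_tests(length(rows))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Receptor-density dose-response across GVS charges
#'
#' Orders the PD-derived groups by delivered electrical charge, summarizes
#' each as mean +/- SEM of animal-side densities, tests each stimulated group
#' against unstimulated PD, and flags whether the group means are monotone
#' non-increasing with charge.
#'
#' @param table receptor-count table.
#' @param receptor receptor subtype.
#' @param charges data frame from [charge_per_group()] mapping group to
#'   charge in coulombs.
#' @param variant t-test variant.
#' @return list with `summary` (group, charge_C, n, mean, sem ordered by
#'   ascending charge), `comparisons` (each GVS group vs PD), and
#'   `monotone_decreasing` (logical; `NA` when any group is missing).
#' @export
dose_response <- function(table, receptor = c("AMPA", "NMDA"),
                          charges = charge_per_group(), variant = "pooled") {
  receptor <- match.arg(receptor)
  d <- animal_side_density(table, receptor)
  dose_groups <- c("PD", "PD_100uA", "PD_500uA", "PD_1000uA")
  ch <- charges$charge_C[match(dose_groups, charges$group)]
  present <- dose_groups %in% d$group
  if (!all(present)) {
    warning(sprintf("missing group(s): %s; partial dose-response returned",
                    paste(dose_groups[!present], collapse = ", ")), call. = FALSE)
  }
  summ <- do.call(rbind, lapply(seq_along(dose_groups), function(i) {
    g <- dose_groups[i]
    v <- d$density[d$group == g]
    data.frame(group = g, charge_C = ch[i], n = length(v),
               mean = if (length(v) > 0) mean(v) else NA_real_,
               sem = if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  summ <- summ[order(summ$charge_C), , drop = FALSE]
  rownames(summ) <- NULL
  pd <- d$density[d$group == "PD"]
  cmp_groups <- dose_groups[-1]
  comparisons <- NULL
  if (length(pd) >= 2L) {
    rows <- list()
    for (g in cmp_groups[cmp_groups %in% d$group]) {
      v <- d$density[d$group == g]
      if (length(v) < 2L) next
      cmp <- two_sample_t(v, pd, variant = variant, group_a = g, group_b = "PD")
      cmp$receptor <- receptor
      rows[[g]] <- cmp
    }
    note_multiple_tests(length(rows))
    comparisons <- do.call(rbind, rows)
    if (!is.null(comparisons)) rownames(comparisons) <- NULL
  }
  monotone <- if (all(present)) all(diff(summ$mean) <= 0) else NA
  list(summary = summ, comparisons = comparisons,
       monotone_decreasing = monotone)
}

#' PD-versus-control receptor contrast
#'
#' Tests whether receptor density increased after PD-model construction
#' (control vs untreated PD), per receptor subtype.
#'
#' @inheritParams dose_response
#' @return a `group_comparison` row (control as group_a, PD as group_b).
#' @export
pd_vs_control <- function(table, receptor = c("AMPA", "NMDA"),
                          variant = "pooled") {
  receptor <- match.arg(receptor)
  d <- animal_side_density(table, receptor)
  ctrl <- d$density[d$group == "control"]
  pd <- d$density[d$group == "PD"]
  if (length(ctrl) < 2L || length(pd) < 2L) {
    stop("need >= 2 animal-side densities in both control and PD", call. = FALSE)
  }
  cmp <- two_sample_t(ctrl, pd, variant = variant,
                      group_a = "control", group_b = "PD")
  cmp$receptor <- receptor
  cmp
}

#' Normal-versus-PD resting-rate contrast per stratum
#'
#' Within each of the four (organ x regularity) strata, compares the resting
#' firing rates of normal versus PD-model units with a two-sample t-test.
#' Strata with fewer than two units on either side are skipped with a
#' warning.
#'
#' @param metrics per-unit metrics table from [spike_train_metrics()] /
#'   [run_pipeline()] (columns `organ`, `label`, `condition`,
#'   `resting_rate_spk_s`).
#' @param variant t-test variant.
#' @return data frame of comparison rows with `organ` and `regularity`
#'   columns (normal as group_a, PD as group_b).
#' @export
population_fr_contrast <- function(metrics, variant = "pooled") {
  req <- c("organ", "label", "condition", "resting_rate_spk_s")
  if (!all(req %in% names(metrics))) {
    stop(sprintf("metrics table needs columns: %s", paste(req, collapse = ", ")),
         call. = FALSE)
  }
  rows <- list()
  for (org in c("canal", "otolith")) {
    for (reg in c("regular", "irregular")) {
      m <- metrics[metrics$organ == org & metrics$label == reg, , drop = FALSE]
      x <- m$resting_rate_spk_s[m$condition == "normal"]
      y <- m$resting_rate_spk_s[m$condition == "PD"]
      if (length(x) < 2L || length(y) < 2L) {
        warning(sprintf("stratum %s/%s skipped: <2 units per condition", org, reg),
                call. = FALSE)
        next
      }
      cmp <- two_sample_t(x, y, variant = variant,
                          group_a = "normal", group_b = "PD")
      cmp$organ <- org
      cmp$regularity <- reg
      rows[[paste(org, reg)]] <- cmp
    }
  }
  note_multiple_tests(length(rows))
  out <- do.call(rbind, rows)
  if (!is.null(out)) rownames(out) <- NULL
  out
}
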