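#' Receptor-group specification
#'
#' Target population parameters for one (treatment group, receptor subtype)
#' cell of the histology design: the group mean density, the printed SEM,
#' and the number of animals. Between-animal variability is reconstructed
#' from the SEM as `sd = sem * sqrt(n_animals)`.
#'
#' @param group one of `"control"`, `"PD"`, `"PD_100uA"`, `"PD_500uA"`,
#'   `"PD_1000uA"`.
#' @param receptor `"AMPA"` or `"NMDA"`.
#' @param mean_density group mean receptor density in counts/mm^2, > 0.
#' @param sem standard error of the group mean, >= 0.
#' @param n_animals animals in the group, >= 2.
#' @param fields_per_animal stained fields counted per animal and side.
#' @param seed optional integer seed for this group's draws.
#' @return an object of class `receptor_group_spec`.
#' @export
receptor_group_spec <- function(group = c("control", "PD", "PD_100uA",
                                          "PD_500uA", "PD_1000uA"),
                                receptor = c("AMPA", "NMDA"),
                                mean_density, sem, n_animals,
                                fields_per_animal = 5L, seed = NULL) {
  group <- match.arg(group)
  receptor <- match.arg(receptor)
  stopifnot_scalar_num(mean_density, "mean_density", positive = TRUE)
  stopifnot_scalar_num(sem, "sem", nonneg = TRUE)
  if (!is.numeric(n_animals) || n_animals < 2) {
    stop("n_animals must be >= 2: group statistics undefined", call. = FALSE)
  }
  structure(list(group = group, receptor = receptor,
                 mean_density = mean_density, sem = sem,
                 n_animals = as.integer(n_animals),
                 fields_per_animal = as.integer(fields_per_animal),
                 seed = seed),
            class = "receptor_group_spec")
}

#' Default receptor-group specifications
#'
#' The five-group histology design (control, untreated PD, and PD stimulated
#' at 100/500/1000 uA) for both glutamate-receptor subtypes, parameterized by
#' the study's group means and SEMs in counts/mm^2. AMPA densities after PD
#' construction are unchanged by stimulation, so the three GVS groups share
#' the PD mean; NMDA densities decrease with delivered charge.
#'
#' @param receptor `"AMPA"`, `"NMDA"`, or `"both"` (default).
#' @param fields_per_animal stained fields per animal and side.
#' @return list of [receptor_group_spec()].
#' @export
default_receptor_specs <- function(receptor = c("both", "AMPA", "NMDA"),
                                   fields_per_animal = 5L) {
  receptor <- match.arg(receptor)
  grp <- c("control", "PD", "PD_100uA", "PD_500uA", "PD_1000uA")
  n <- c(6L, 5L, 3L, 3L, 3L)
  ampa_mean <- c(78.58, 138.34, 138.34, 138.34, 138.34)
  ampa_sem <- c(12.02, 7.22, 7.22, 7.22, 7.22)
  nmda_mean <- c(76.92, 165.86, 160.58, 134.62, 89.21)
  nmda_sem <- c(7.92, 30.40, 39.24, 12.14, 15.50)
  mk <- function(rec, means, sems) {
    lapply(seq_along(grp), function(i) {
      receptor_group_spec(grp[i], rec, means[i], sems[i], n[i],
                          fields_per_animal = fields_per_animal)
    })
  }
  out <- switch(receptor,
                AMPA = mk("AMPA", ampa_mean, ampa_sem),
                NMDA = mk("NMDA", nmda_mean, nmda_sem),
                both = c(mk("AMPA", ampa_mean, ampa_sem),
                         mk("NMDA", nmda_mean, nmda_sem)))
  out
}

#' Generate a receptor-count table
#'
#' For each group spec, each animal and side (left/right of the vestibular
#' nucleus) receives an i.i.d. density draw from a zero-truncated normal with
#' mean `mean_density` and SD `sem * sqrt(n_animals)` (sides are i.i.d.
#' because the study found no left/right difference). Each stained field then
#' contributes a count: Poisson with mean `density * area` under the default
#' `field_noise = "poisson"`, or the rounded expectation under `"none"`.
#'
#' @param specs list of [receptor_group_spec()].
#' @param seed integer seed; per-group child seeds are derived from it unless
#'   a spec carries its own seed.
#' @param field_area_mm2 area of one counted field in mm^2.
#' @param field_noise `"poisson"` (default) or `"none"`.
#' @return data frame with columns `animal_id`, `group`, `side`, `receptor`,
#'   `area_mm2`, `count` (one row per counted field) and attribute `seed`.
#' @export
generate_receptor_table <- function(specs, seed = 1L, field_area_mm2 = 0.15,
                                    field_noise = c("poisson", "none")) {
  field_noise <- match.arg(field_noise)
  if (!is.list(specs) || length(specs) < 1L ||
      !all(vapply(specs, inherits, logical(1), "receptor_group_spec"))) {
    stop("specs must be a non-empty list of receptor_group_spec", call. = FALSE)
  }
  rows <- lapply(seq_along(specs), function(i) {
    sp <- specs[[i]]
    sp_seed <- sp$seed %||% derive_seed(seed, i)
    with_seed(sp_seed, {
      sd_between <- sp$sem * sqrt(sp$n_animals)
      per <- expand.grid(animal = seq_len(sp$n_animals), side = c("L", "R"),
                         stringsAsFactors = FALSE)
      dens <- rnorm_pos(nrow(per), sp$mean_density, sd_between)
      f <- sp$fields_per_animal
      idx <- rep(seq_len(nrow(per)), each = f)
      lambda <- dens[idx] * field_area_mm2
      count <- if (field_noise == "poisson") {
        stats::rpois(length(lambda), lambda)
      } else {
        round(lambda)
      }
      data.frame(
        animal_id = sprintf("%s_a%02d", sp$group, per$animal[idx]),
        group = sp$group,
        side = per$side[idx],
        receptor = sp$receptor,
        area_mm2 = field_area_mm2,
        count = count,
        stringsAsFactors = FALSE
      )
    })
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "seed") <- seed
  out
}

#' Generate rota-rod time-on-rod durations
#'
#' Per-animal durations (seconds) for the three locomotion phases of the
#' behavioral assay: pre-training, trained (before lesioning), and after PD
#' construction. Draws are zero-truncated normal with the given phase means
#' and SDs; defaults reconstruct the study's phase means and SEMs at n = 9
#' (`sd = sem * sqrt(n)`).
#'
#' @param n_animals number of animals, > 0.
#' @param phase_means length-3 means in seconds (pre-training, trained,
#'   post-PD), all > 0.
#' @param phase_sds length-3 SDs in seconds.
#' @param seed integer seed.
#' @return data frame with columns `animal_id`, `pre_training_s`, `trained_s`,
#'   `post_pd_s` and attribute `seed`.
#' @export
generate_rotarod <- function(n_animals = 9L,
                             phase_means = c(20.78, 71.23, 5.24),
                             phase_sds = c(6.59, 14.06, 1.23) * sqrt(9),
                             seed = 1L) {
  if (!is.numeric(n_animals) || length(n_animals) != 1L || n_animals < 1) {
    stop("n_animals must be a positive count", call. = FALSE)
  }
  if (length(phase_means) != 3L || any(phase_means <= 0)) {
    stop("phase_means must be three positive durations", call. = FALSE)
  }
  if (length(phase_sds) != 3L || any(phase_sds < 0)) {
    stop("phase_sds must be three non-negative durations", call. = FALSE)
  }
  n <- as.integer(n_animals)
  out <- with_seed(seed, data.frame(
    animal_id = sprintf("rr_a%02d", seq_len(n)),
    pre_training_s = rnorm_pos(n, phase_means[1], phase_sds[1]),
    trained_s = rnorm_pos(n, phase_means[2], phase_sds[2]),
    post_pd_s = rnorm_pos(n, phase_means[3], phase_sds[3]),
    stringsAsFactors = FALSE
  ))
  attr(out, "seed") <- seed
  out
}
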