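test_that("pooled t matches the closed-form oracle to 1e-10", {
  x <- c(1, 2, 3, 4, 5); y <- c(2, 3, 4, 5, 6)
  got <- two_sample_t(x, y)
  ora <- pooled_t_oracle(x, y)
  expect_equal(got$t_stat, -1, tolerance = 1e-12)
  expect_equal(got$p_value, ora$p, tolerance = 1e-10)
  expect_equal(got$p_value, 0.3466, tolerance = 1e-4)
  # a second, asymmetric fixed pair
  x2 <- c(3.1, 2.7, 4.4, 3.8, 2.9, 3.3, 4.0)
  y2 <- c(5.0, 4.2, 4.8, 5.5)
  got2 <- two_sample_t(x2, y2)
  ora2 <- pooled_t_oracle(x2, y2)
  expect_equal(got2$t_stat, ora2$t, tolerance = 1e-10)
  expect_equal(got2$p_value, ora2$p, tolerance = 1e-10)
  expect_equal(got2$df, ora2$df)
  expect_equal(got2$sem_a, sd(x2) / sqrt(7), tolerance = 1e-12)
})

test_that("identical and degenerate samples follow the conventions", {
  x <- c(1.2, 3.4, 2.2, 5.0)
  same <- two_sample_t(x, x)
  expect_equal(same$t_stat, 0)
  expect_equal(same$p_value, 1)
  flat_eq <- two_sample_t(rep(2, 3), rep(2, 4))
  expect_equal(flat_eq$p_value, 1)
  expect_false(flat_eq$degenerate)
  flat_ne <- two_sample_t(rep(2, 3), rep(3, 4))
  expect_true(flat_ne$degenerate)
  expect_gt(flat_ne$p_value, 0)
  expect_lt(flat_ne$p_value, 1e-100)
  expect_error(two_sample_t(1, 1:3), "n >= 2")
})

test_that("the Welch variant differs from pooled under unequal variances", {
  set.seed(11)
  x <- rnorm(8, 0, 1); y <- rnorm(30, 0.5, 6)
  pooled <- two_sample_t(x, y, "pooled")
  welch <- two_sample_t(x, y, "welch")
  expect_false(isTRUE(all.equal(pooled$p_value, welch$p_value)))
  ref <- t.test(x, y)
  expect_equal(welch$p_value, ref$p.value, tolerance = 1e-12)
})

test_that("density is unit-consistent under joint count/area scaling", {
  tab <- data.frame(animal_id = "a1", group = "PD", side = c("L", "R"),
                    receptor = "NMDA", area_mm2 = 0.2, count = c(30, 40))
  tab2 <- transform(tab, area_mm2 = area_mm2 * 2, count = count * 2)
  expect_equal(animal_side_density(tab, "NMDA")$density,
               animal_side_density(tab2, "NMDA")$density)
})

test_that("side contrast is null-calibrated for i.i.d. sides and exact for mirrored sides", {
  # i.i.d. L/R generation: per-group false-positive rate near alpha
  spec <- list(receptor_group_spec("PD", "AMPA", 130, 10, n_animals = 6))
  p <- vapply(1:120, function(s) {
    suppressMessages(side_contrast(generate_receptor_table(spec, seed = s),
                                   "AMPA"))$p_value
  }, numeric(1))
  expect_gte(mean(p > 0.05), 0.90)
  # literally mirrored sides: p = 1
  tab <- generate_receptor_table(spec, seed = 1)
  mirrored <- tab
  mirrored$side <- ifelse(tab$side == "L", "R", "L")
  both <- rbind(tab[tab$side == "L", ], mirrored[mirrored$side == "R", ])
  cmp <- side_contrast(both, "AMPA")
  expect_equal(cmp$p_value, 1)
  # a group missing one side is skipped with a warning
  onesided <- tab[tab$side == "L", ]
  expect_warning(res <- side_contrast(onesided, "AMPA"), "both sides")
  expect_null(res)
})

test_that("dose-response ordering, trend flag and gaps behave as specified", {
  mk_exact <- function(means) {
    specs <- mapply(function(g, m) {
      receptor_group_spec(g, "NMDA", m, sem = 0, n_animals = 3,
                          fields_per_animal = 2)
    }, c("PD", "PD_100uA", "PD_500uA", "PD_1000uA"), means, SIMPLIFY = FALSE)
    # field area chosen so density * area is integral and rounding is exact
    generate_receptor_table(specs, seed = 1, field_area_mm2 = 0.2,
                            field_noise = "none")
  }
  dr <- suppressMessages(dose_response(mk_exact(c(160, 150, 120, 90)), "NMDA"))
  expect_identical(dr$summary$group, c("PD", "PD_100uA", "PD_500uA", "PD_1000uA"))
  expect_equal(dr$summary$charge_C, c(0, 0.018, 0.09, 0.18))
  expect_true(dr$monotone_decreasing)
  expect_equal(dr$summary$mean, c(160, 150, 120, 90))
  # zero-variance non-monotone means flag FALSE deterministically
  dr2 <- suppressMessages(dose_response(mk_exact(c(160, 170, 120, 90)), "NMDA"))
  expect_false(dr2$monotone_decreasing)
  # missing group: partial output with an explicit gap
  tab <- mk_exact(c(160, 150, 120, 90))
  tab <- tab[tab$group != "PD_500uA", ]
  expect_warning(dr3 <- dose_response(tab, "NMDA"), "missing group")
  expect_true(is.na(dr3$monotone_decreasing))
  expect_true(is.na(dr3$summary$mean[dr3$summary$group == "PD_500uA"]))
  expect_equal(nrow(dr3$summary), 4L)
})

test_that("PD-vs-control contrast recovers the direction of the receptor increase", {
  specs <- c(default_receptor_specs("NMDA")[1:2],
             default_receptor_specs("AMPA")[1:2])
  tab <- generate_receptor_table(specs, seed = 7)
  for (rec in c("NMDA", "AMPA")) {
    cmp <- pd_vs_control(tab, rec)
    expect_lt(cmp$mean_a, cmp$mean_b) # control below PD
  }
})

test_that("population firing-rate contrasts run per stratum and skip sparse ones", {
  mk_metrics <- function(n, shift = 0, seed = 1) {
    set.seed(seed)
    expand.grid(organ = c("canal", "otolith"),
                label = c("regular", "irregular"),
                condition = c("normal", "PD"), unit = seq_len(n),
                stringsAsFactors = FALSE) |>
      transform(resting_rate_spk_s = rnorm(8 * n, 20, 4) +
                  shift * (condition == "PD"))
  }
  null_res <- suppressMessages(population_fr_contrast(mk_metrics(15)))
  expect_equal(nrow(null_res), 4L)
  shifted <- suppressMessages(population_fr_contrast(mk_metrics(50, shift = 10)))
  expect_true(all(shifted$p_value < 0.05))
  expect_true(all(shifted$mean_a < shifted$mean_b))
  sparse <- mk_metrics(2)
  sparse <- sparse[!(sparse$organ == "canal" & sparse$label == "regular" &
                       sparse$condition == "PD" & sparse$unit == 2), ]
  sparse <- sparse[!(sparse$organ == "canal" & sparse$label == "regular" &
                       sparse$condition == "PD" & sparse$unit == 1), ]
  expect_warning(res <- suppressMessages(population_fr_contrast(sparse)),
                 "skipped")
  expect_equal(nrow(res), 3L)
})

test_that("more than three tests in one invocation emits a correction note", {
  specs <- default_receptor_specs("NMDA")
  tab <- generate_receptor_table(specs, seed = 2)
  expect_message(side_contrast(tab, "NMDA"), "no multiple-testing correction")
})
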