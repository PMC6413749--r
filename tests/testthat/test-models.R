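test_that("fit_age_sex_model recovers a known standardized slope", {
  sc <- simulate_dm_scores(n_ids = 200, visits_per_id = 4, age_slope = 0.3,
                           sex_effect = 0.2, seed = 80)
  res <- fit_age_sex_model(sc)
  ct <- res$coefficients
  slope <- ct[ct$term == "age_z", ]
  expect_lt(slope$ci_lower, 0.3)
  expect_gt(slope$ci_upper, 0.3)
  expect_lt(abs(slope$estimate - 0.3), 0.1)
  expect_equal(res$n_ids, 200L)
  expect_match(res$random_effects, "individual_id")
  expect_true(all(ct$ci_lower < ct$ci_upper))
})

test_that("single-sex cohorts drop sex terms (age-only model)", {
  sc <- simulate_dm_scores(n_ids = 100, visits_per_id = 3, age_slope = 0.3,
                           seed = 81, single_sex = TRUE)
  res <- fit_age_sex_model(sc)
  expect_false(any(grepl("sex", res$coefficients$term)))
  expect_true("age_z" %in% res$coefficients$term)
})

test_that("ID random intercept omitted without repeated observations", {
  sc <- simulate_dm_scores(n_ids = 150, visits_per_id = 1, age_slope = 0.3,
                           seed = 82)
  res <- fit_age_sex_model(sc)
  expect_false(grepl("individual_id", res$random_effects))
})

test_that("t-statistics are invariant to positive rescaling of the score", {
  sc <- simulate_dm_scores(n_ids = 80, visits_per_id = 3, age_slope = 0.25,
                           seed = 83)
  r1 <- fit_age_sex_model(sc)
  sc2 <- sc; sc2$dm_z <- sc2$dm_z * 7.3; sc2$dm <- sc2$dm * 7.3
  r2 <- fit_age_sex_model(sc2)
  t1 <- r1$coefficients$estimate / r1$coefficients$std_error
  t2 <- r2$coefficients$estimate / r2$coefficients$std_error
  expect_equal(t1, t2, tolerance = 1e-8)
})

test_that("mass_change_rate computes kg/year between consecutive visits", {
  co <- cohort_table(data.frame(
    species = "A", individual_id = c("i1", "i1", "i1", "i2"),
    sex = "female", age_at_obs = c(10, 10.5, 12, 8),
    body_mass = c(10, 9, 9.6, 30), g = 1), markers = "g")
  rt <- mass_change_rate(co)
  expect_equal(rt$mass_change_rate, c((9 - 10) / 0.5, (9.6 - 9) / 1.5))
  # last observation and single-observation IDs contribute no rate
  expect_false("i2" %in% rt$individual_id)
  expect_equal(nrow(rt), 2L)
  # equal consecutive masses give rate 0
  co2 <- cohort_table(data.frame(
    species = "A", individual_id = "i1", sex = "female",
    age_at_obs = c(5, 6), body_mass = c(4, 4), g = 1), markers = "g")
  expect_equal(mass_change_rate(co2)$mass_change_rate, 0)
})

test_that("fit_mass_model recovers a negative quadratic age term", {
  cf <- sim_config(seed = 84, n_species = 2, n_ids = 150, p_markers = 4,
                   visits_mean = 4, h0 = 0, mass_age_quad = -0.05)
  sim <- simulate_cohort(cf)
  sp <- sim$tree$tip.label[1]
  co <- select_marker_set(sim$cohort, mode = "fixed",
                          fixed_panel = markers(sim$cohort))[[sp]]
  res <- fit_mass_model(co)
  quad <- res$coefficients[res$coefficients$term == "I(age_z^2)", ]
  expect_lt(quad$estimate, 0)
  expect_lt(quad$ci_upper, 0)
})

test_that("fit_mass_model null dm coefficient covers zero", {
  cf <- sim_config(seed = 85, n_species = 2, n_ids = 120, p_markers = 4,
                   h0 = 0, mass_dm_slope = 0)
  sim <- simulate_cohort(cf)
  sp <- sim$tree$tip.label[1]
  co <- select_marker_set(sim$cohort, mode = "fixed",
                          fixed_panel = markers(sim$cohort))[[sp]]
  sc <- score_cohort(co, build_self_reference(co))
  res <- fit_mass_model(co, sc)
  dmrow <- res$coefficients[res$coefficients$term == "dm_z", ]
  expect_lt(dmrow$ci_lower, 0)
  expect_gt(dmrow$ci_upper, 0)
})

test_that("fit_mass_change_model links dm to subsequent mass loss", {
  cf <- sim_config(seed = 86, n_species = 2, n_ids = 250, p_markers = 4,
                   visits_mean = 5, h0 = 0, mass_dm_slope = -0.4,
                   mass_sd = 0.3)
  sim <- simulate_cohort(cf)
  sp <- sim$tree$tip.label[1]
  co <- select_marker_set(sim$cohort, mode = "fixed",
                          fixed_panel = markers(sim$cohort))[[sp]]
  sc <- score_cohort(co, build_self_reference(co))
  rt <- mass_change_rate(co)
  res <- fit_mass_change_model(rt, sc)
  dmrow <- res$coefficients[res$coefficients$term == "dm_z", ]
  expect_lt(dmrow$estimate, 0)
  expect_lt(dmrow$ci_upper, 0)
  # empty rate table errors
  expect_error(fit_mass_change_model(rt[0, ], sc),
               class = "dysregkit_input_error")
})
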