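test_that("read_cohort reads, validates and logs rejected rows", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("species,individual_id,sex,age_at_obs,g1,g2",
               "A,a1,F,5.6,1.0,2.0",
               "A,a2,M,-1,1.1,2.1",
               "A,a3,F,7.2,1.2,2.2",
               "A,a4,M,8.0,1.3,2.3"), f)
  co <- read_cohort(f)
  expect_s3_class(co, "cohort_table")
  expect_equal(nrow(co), 3L)               # negative-age row rejected
  expect_equal(markers(co), c("g1", "g2"))
  expect_equal(validation_report(co)$rows_dropped, 1L)
  expect_match(validation_report(co)$row_log, "age_at_obs", all = FALSE)
  expect_equal(co$sex, c("female", "female", "male"))

  # missing required column -> schema error
  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("species,individual_id,age_at_obs,g1", "A,a1,5,1"), f2)
  expect_error(read_cohort(f2), class = "dysregkit_schema_error")

  # empty table -> input error
  f3 <- withr::local_tempfile(fileext = ".csv")
  writeLines("species,individual_id,sex,age_at_obs,g1", f3)
  expect_error(read_cohort(f3), class = "dysregkit_input_error")
})

test_that("all-missing marker columns are retained but flagged", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("species,individual_id,sex,age_at_obs,g1,g2",
               "A,a1,F,5.6,1.0,", "A,a2,M,6.0,1.1,"), f)
  co <- read_cohort(f)
  expect_true("g2" %in% markers(co))
  expect_equal(validation_report(co)$all_missing_markers, "g2")
})

test_that("cohort round-trips numeric cells bit-exactly", {
  co <- mvn_cohort(n = 20, p = 3, seed = 5)
  f <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, f)
  co2 <- read_cohort(f)
  for (mk in markers(co)) expect_identical(co2[[mk]], co[[mk]])
  expect_identical(co2$age_at_obs, co$age_at_obs)
})

test_that("filter_adults applies an inclusive boundary and is idempotent", {
  meta <- species_meta(c("A", "B"), maturation_age = c(5.0, 6.0))
  co <- tiny_cohort()
  out <- filter_adults(co, meta)
  expect_true(all(out$age_at_obs[out$species == "A"] >= 5.0))
  expect_true(all(out$age_at_obs[out$species == "B"] >= 6.0))
  expect_equal(attr(out, "n_removed"), 2L)      # B rows at 5.0 and 5.5
  # boundary age retained
  expect_true(any(out$species == "B" & out$age_at_obs == 6.0))
  # idempotence
  out2 <- filter_adults(out, meta)
  expect_equal(as.data.frame(out2), as.data.frame(out), ignore_attr = TRUE)
  # all-adult cohort passes through unchanged
  meta0 <- species_meta(c("A", "B"), maturation_age = c(1, 1))
  expect_equal(as.data.frame(filter_adults(co, meta0)), as.data.frame(co),
               ignore_attr = TRUE)
  # missing species -> configuration error
  expect_error(filter_adults(co, species_meta("A", 5)),
               class = "dysregkit_config_error")
  # all juveniles -> empty with warning
  metaJ <- species_meta(c("A", "B"), maturation_age = c(99, 99))
  expect_warning(out3 <- filter_adults(co, metaJ), "every row")
  expect_equal(nrow(out3), 0L)
})

test_that("filter_implausible blanks cells outside open bounds, keeps bounds", {
  bounds <- data.frame(marker = "g2", low = 1.0, high = 2.1)
  meta <- species_meta(c("A", "B"), c(1, 1), bounds = bounds)
  co <- tiny_cohort()
  out <- filter_implausible(co, meta)
  expect_true(is.na(out$g2[co$g2 == 0.9]))     # below low
  expect_true(is.na(out$g2[co$g2 == 2.2]))     # above high
  expect_equal(out$g2[co$g2 == 1.0], 1.0)      # value at bound retained
  expect_equal(out$g2[co$g2 == 2.1], 2.1)
  expect_equal(unname(attr(out, "implausible_counts")["g2"]), 2L)
  expect_equal(nrow(out), nrow(co))            # cell-wise, never row-wise
  # no bounds -> identity
  out0 <- filter_implausible(co, species_meta(c("A", "B"), c(1, 1)))
  expect_equal(as.data.frame(out0), as.data.frame(co), ignore_attr = TRUE)
})

test_that("select_marker_set: fixed mode complete cases, variable thresholds", {
  co <- tiny_cohort()
  co$g2[1] <- NA
  # fixed: row missing one panel marker is excluded
  out <- select_marker_set(co, mode = "fixed", fixed_panel = c("g1", "g2"))
  expect_equal(nrow(out$A), 3L)
  expect_equal(markers(out$A), markers(out$B))  # identical panels
  # fixed panel marker absent for a species -> species dropped with warning
  co2 <- tiny_cohort()
  co2$g2[co2$species == "B"] <- NA
  expect_warning(out2 <- select_marker_set(co2, mode = "fixed",
                                           fixed_panel = c("g1", "g2")),
                 "B dropped")
  expect_named(out2, "A")
  # variable: 50% availability < 0.7 threshold -> marker excluded
  co3 <- tiny_cohort()
  co3$g2[co3$species == "A"][1:2] <- NA
  out3 <- select_marker_set(co3, mode = "variable", min_markers = 1)
  expect_equal(markers(out3$A), "g1")
  # min_markers floor drops under-markered species
  expect_warning(out4 <- select_marker_set(co3, mode = "variable",
                                           min_markers = 2),
                 "A dropped")
  expect_false("A" %in% names(out4))
  # mode=fixed without a panel is a config error
  expect_error(select_marker_set(co, mode = "fixed"),
               class = "dysregkit_config_error")
})

test_that("read_tree parses, validates tips, tolerates extras", {
  f <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((A:10,B:10):20,C:30);", f)
  tr <- read_tree(f, species = c("A", "B", "C"))
  expect_equal(sort(tr$tip.label), c("A", "B", "C"))
  expect_error(read_tree(f, species = c("A", "B", "C", "D")), "D",
               class = "dysregkit_config_error")
  expect_message(read_tree(f, species = c("A", "B")), "ignored")
  f2 <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((A,B),C);", f2)   # no branch lengths
  expect_error(read_tree(f2), class = "dysregkit_format_error")
})
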