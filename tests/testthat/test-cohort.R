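test_that("cohort construction validates the data model and round-trips CSV", {
  df <- rbind(cohort_row("f1", "control", 2), cohort_row("f1", "control", 3))
  st <- cohort_study(df)
  expect_s3_class(st, "cohort_study")
  expect_equal(length(unique(st$group)), 1)
  expect_equal(length(unique(st$individual_id)), 1)
  expect_equal(study_timepoints(st), c(2L, 3L))

  sim <- simulate_cohort(get_scenario("high", seed = 11))
  f <- withr::local_tempfile(fileext = ".csv")
  write_cohort(sim, f)
  back <- read_cohort(f)
  expect_equal(as.data.frame(back), as.data.frame(sim))
  expect_equal(attr(back, "catalog"), attr(sim, "catalog"))

  # byte-stable writes
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_cohort(sim, f2)
  expect_identical(readBin(f, "raw", file.size(f)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("validation failures raise distinct named error classes", {
  base <- rbind(cohort_row("f1", "g", 3, M = 1), cohort_row("f1", "g", 4))

  expect_error(cohort_study(base[setdiff(names(base), "SBI")]),
               class = "dynetox_missing_column")
  expect_error(cohort_study(base), class = "dynetox_mortality_reversal")

  nb <- cohort_row("f1", "g", 2); nb$PE <- 2
  expect_error(cohort_study(nb), class = "dynetox_nonbinary_value")

  dup <- rbind(cohort_row("f1", "g", 2), cohort_row("f1", "g", 2))
  expect_error(cohort_study(dup), class = "dynetox_duplicate_row")

  frac <- cohort_row("f1", "g", 2.5)
  expect_error(cohort_study(frac), class = "dynetox_bad_timepoint")
})

test_that("post-mortality status resolution follows the chosen policy", {
  # PE appears at 3 dpf, death at 4 dpf, observed through 7 dpf
  series <- rbind(
    cohort_row("f1", "g", 2),
    cohort_row("f1", "g", 3, PE = 1),
    cohort_row("f1", "g", 4, PE = 1, M = 1),
    cohort_row("f1", "g", 5, PE = 1, M = 1),
    cohort_row("f1", "g", 6, PE = 1, M = 1),
    cohort_row("f1", "g", 7, PE = 1, M = 1)
  )
  expect_equal(resolve_status(series, "PE", 6, "carry_forward"), 1L)
  expect_true(is.na(resolve_status(series, "PE", 6, "missing_after_death")))
  # at and before the death day the recorded value stands under both rules
  for (pol in c("carry_forward", "missing_after_death")) {
    expect_equal(resolve_status(series, "PE", 3, pol), 1L)
    expect_equal(resolve_status(series, "PE", 4, pol), 1L)
    expect_equal(resolve_status(series, "YSE", 4, pol), 0L)
  }
  # mortality resolves cumulatively
  expect_equal(resolve_status(series, "M", 2), 0L)
  expect_equal(resolve_status(series, "M", 4), 1L)
  expect_equal(resolve_status(series, "M", 7), 1L)
  expect_error(resolve_status(series, "XX", 4),
               class = "dynetox_unknown_endpoint")

  # alive individual: resolution is the recorded value
  alive <- rbind(cohort_row("f2", "g", 2, YSE = 1), cohort_row("f2", "g", 3))
  expect_equal(resolve_status(alive, "YSE", 2), 1L)
  expect_equal(resolve_status(alive, "YSE", 3), 0L)  # reversal permitted

  # carry_forward never yields NA; missing_after_death only strictly after
  # death (checked across a mortality-heavy simulated cohort)
  st <- simulate_cohort(get_scenario("lethal", seed = 4,
                                     groups = c("5uM" = 5)))
  tps <- study_timepoints(st)
  arr_cf <- dynetox:::resolved_group_array(st, "5uM", "carry_forward")
  expect_false(anyNA(arr_cf))
  arr_md <- dynetox:::resolved_group_array(st, "5uM", "missing_after_death")
  for (id in dimnames(arr_md)[[1]]) {
    m_row <- arr_cf[id, , "M"]
    death <- if (any(m_row == 1)) tps[min(which(m_row == 1))] else Inf
    na_tps <- tps[apply(is.na(arr_md[id, , ]), 1, any)]
    expect_true(all(na_tps > death))
  }
})

test_that("incidence summary counts resolved statuses per cell", {
  st <- cohort_study(zero_cohort_df(10))
  inc <- incidence_summary(st)
  expect_true(all(inc$count == 0))
  expect_true(all(inc$denominator == 10))

  df <- zero_cohort_df(10)
  df$PE[df$individual_id %in% c("i01", "i02", "i03", "i04") &
          df$dpf == 3] <- 1
  inc <- incidence_summary(cohort_study(df))
  expect_equal(inc$count[inc$endpoint == "PE" & inc$dpf == 3], 4L)
  expect_equal(inc$denominator[inc$endpoint == "PE" & inc$dpf == 3], 10L)

  # simulator endpoints are absorbing, so incidence is non-decreasing in t
  for (s in c(2, 9)) {
    sim <- simulate_cohort(get_scenario("high", seed = s))
    inc <- incidence_summary(sim)
    for (g in unique(inc$group)) for (e in labels6) {
      counts <- inc$count[inc$group == g & inc$endpoint == e]
      expect_true(all(diff(counts) >= 0))
    }
    # carry_forward keeps every enrolled individual in every denominator
    expect_true(all(inc$denominator == 30))
  }
})
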