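test_that("earliest SMI mention wins, with declared tie-breaks", {
  m <- data.frame(code = c("F20", "F31"),
                  date = as.Date(c("2010-05-01", "2008-02-01")),
                  source = c("MH", "HOSP"))
  expect_equal(resolve_first_smi(m),
               list(code = "F31", date = as.Date("2008-02-01")))
  expect_equal(resolve_first_smi(m[1, ]),
               list(code = "F20", date = as.Date("2010-05-01")))
  tie <- data.frame(code = c("F20", "F31"),
                    date = as.Date(c("2010-05-01", "2010-05-01")),
                    source = c("HOSP", "MH"))
  expect_equal(resolve_first_smi(tie)$code, "F31")  # MH source wins the tie
  expect_error(resolve_first_smi(m[0, ]), "not in the cohort")
})

test_that("event stream applies chapter, mental-health and window filters", {
  pat <- fixture_patients("P1")
  ep <- data.frame(episode_id = "E1", patient_id = "P1",
                   admission_date = REF_DATE + 10,
                   discharge_date = REF_DATE + 12,
                   diagnoses = "F20;Z01;I10", stringsAsFactors = FALSE)
  ev <- build_event_stream(ep, pat)
  expect_equal(ev$code3, c("F20", "I10"))  # Z-chapter dropped
  ev2 <- build_event_stream(ep, pat, exclude_mental = TRUE)
  expect_equal(ev2$code3, "I10")
  # 6-years-pre event excluded by a 5-year window
  ep$admission_date <- REF_DATE - round(6 * 365.25)
  expect_equal(nrow(build_event_stream(ep, pat, window_years = 5)), 0)
  ep$admission_date <- REF_DATE - round(4 * 365.25)
  expect_equal(nrow(build_event_stream(ep, pat, window_years = 5)), 2)
  # orphan patients are an error
  ep$patient_id <- "P9"
  expect_error(build_event_stream(ep, pat), "P9")
})

test_that("within-episode duplicates collapse to the smallest rank", {
  pat <- fixture_patients("P1")
  ep <- data.frame(episode_id = "E1", patient_id = "P1",
                   admission_date = REF_DATE + 1,
                   discharge_date = REF_DATE + 1,
                   diagnoses = "I10;E11;I10.2", stringsAsFactors = FALSE)
  ev <- build_event_stream(ep, pat)
  expect_equal(ev$code3, c("I10", "E11"))
  expect_equal(ev$within_episode_rank[ev$code3 == "I10"], 0L)
})

test_that("filters are monotone and pre/post is a partition", {
  for (seed in 1:3) {
    cfg <- cohort_config(n_patients = 40, seed = seed)
    pat <- generate_cohort(cfg)
    ep <- generate_episodes(pat, cfg)
    n_all <- nrow(build_event_stream(ep, pat, exclude_chapters = character(0)))
    n_chap <- nrow(build_event_stream(ep, pat))
    n_ment <- nrow(build_event_stream(ep, pat, exclude_mental = TRUE))
    n_win <- nrow(build_event_stream(ep, pat, exclude_mental = TRUE,
                                     window_years = 5))
    expect_true(n_all >= n_chap && n_chap >= n_ment && n_ment >= n_win)
    ev <- build_event_stream(ep, pat)
    expect_equal(sum(ev$years_to_smi < 0) + sum(ev$years_to_smi >= 0),
                 nrow(ev))
  }
})

test_that("the new-condition ratio follows its closed form", {
  pat <- fixture_patients("P1")
  ev <- fixture_events(rep("P1", 4), c("A00", "B00", "B00", "C00"),
                       day = c(-30, -20, 10, 20), patients = pat)
  sp <- split_conditions(ev, "F20", REF_DATE)
  expect_equal(sp$pre_existing, c("A00", "B00"))
  expect_equal(sp$new_conditions, "C00")
  expect_equal(sp$re_occurring, "B00")
  expect_equal(sp$new_ratio, 1 / 3)
  expect_equal(unname(sp$first_appearance_years), 20 / 365.25)

  # all-new and no-post limits
  ev2 <- fixture_events(rep("P1", 2), c("C00", "D00"), day = c(5, 6),
                        patients = pat)
  expect_equal(split_conditions(ev2, "F20", REF_DATE)$new_ratio, 1.0)
  ev3 <- fixture_events("P1", "A00", day = -5, patients = pat)
  expect_equal(split_conditions(ev3, "F20", REF_DATE)$new_ratio, 0.0)
  # a patient with only their index code has no conditions at all
  ev4 <- fixture_events("P1", "F20", day = 0, patients = pat)
  expect_true(is.na(split_conditions(ev4, "F20", REF_DATE)$new_ratio))
})

test_that("ratio bounds hold on generated cohorts", {
  cfg <- cohort_config(n_patients = 50, seed = 4)
  pat <- generate_cohort(cfg)
  ep <- generate_episodes(pat, cfg)
  ev <- build_event_stream(ep, pat)
  sp <- condition_splits(ev, pat)
  ok <- !is.na(sp$new_ratio)
  expect_true(all(sp$new_ratio[ok] >= 0 & sp$new_ratio[ok] <= 1))
  for (i in which(ok)) {
    n1 <- sp$pre_existing[[i]]; n2 <- sp$post_set[[i]]
    expect_length(intersect(sp$new_conditions[[i]], sp$re_occurring[[i]]), 0)
    expect_equal(sp$new_ratio[i] == 1,
                 length(n1) == 0 && length(n2) > 0)
    expect_equal(sp$new_ratio[i] == 0, all(n2 %in% n1))
  }
})

test_that("new conditions per year normalise by follow-up and split by type", {
  pat <- fixture_patients("P1")
  splits <- data.frame(patient_id = "P1", stringsAsFactors = FALSE)
  splits$new_conditions <- list(c("A01", "B02", "C03", "D04", "E05"))
  censor <- REF_DATE + round(5 * 365.25)
  r <- new_per_year(splits, pat, censor)
  expect_equal(r$overall, 1.0, tolerance = 1e-3)
  splits$new_conditions <- list(character(0))
  expect_equal(new_per_year(splits, pat, censor)$overall, 0)
  splits$new_conditions <- list(c("F17", "I10", "E11"))
  censor2 <- REF_DATE + round(2 * 365.25)
  r2 <- new_per_year(splits, pat, censor2)
  expect_equal(r2$mental, 0.5, tolerance = 1e-3)
  expect_equal(r2$physical, 1.0, tolerance = 1e-3)
  # death before the index date is an error
  pat$death_date <- REF_DATE - 1
  expect_error(new_per_year(splits, pat, censor), "death_date")
})
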