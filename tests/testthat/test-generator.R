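test_that("invalid config fields are rejected by name", {
  expect_error(cohort_config(p_f20 = 1.2), "p_f20")
  expect_error(cohort_config(n_patients = 0), "n_patients")
  expect_error(cohort_config(episode_rate_pre = -1), "episode_rate_pre")
  expect_error(cohort_config(ethnicity_probs = c(a = 0.5, b = 0.6)),
               "ethnicity_probs")
  expect_error(cohort_config(age_at_smi_bounds = c(90, 5)),
               "age_at_smi_bounds")
})

test_that("generation is fully determined by the seed", {
  cfg <- cohort_config(n_patients = 60, seed = 42)
  p1 <- generate_cohort(cfg); p2 <- generate_cohort(cfg)
  expect_identical(p1, p2)
  m <- disease_model(cfg)
  e1 <- generate_episodes(p1, cfg, m)
  e2 <- generate_episodes(p2, cfg, m)
  expect_identical(e1, e2)
  # a different seed changes the draw
  p3 <- generate_cohort(cohort_config(n_patients = 60, seed = 43))
  expect_false(identical(p1$first_smi_code, p3$first_smi_code))
})

test_that("index-code split and age-at-SMI law match the configured cohort", {
  pat <- generate_cohort(cohort_config(n_patients = 2000, seed = 7))
  n_f20 <- sum(pat$first_smi_code == "F20")
  # central 99.9% interval of Binomial(2000, 0.6), computed independently
  bounds <- qbinom(c(5e-4, 1 - 5e-4), 2000, 0.6)
  expect_gte(n_f20, bounds[1])
  expect_lte(n_f20, bounds[2])

  pat5 <- generate_cohort(cohort_config(n_patients = 5000, seed = 1))
  age <- as.numeric(pat5$first_smi_date - pat5$dob) / 365.25
  expect_lt(abs(mean(age) - 39.5), 1.0)
  expect_true(all(pat5$first_smi_date > pat5$dob))
})

test_that("episode tables satisfy their structural invariants", {
  cfg <- cohort_config(n_patients = 80, seed = 11)
  pat <- generate_cohort(cfg)
  ep <- generate_episodes(pat, cfg)
  expect_true(all(ep$discharge_date >= ep$admission_date))
  ncodes <- lengths(strsplit(ep$diagnoses, ";"))
  expect_true(all(ncodes >= 1 & ncodes <= 20))
  # exactly one index event per patient, on the index date, with the index code
  for (i in seq_len(nrow(pat))) {
    own <- ep[ep$patient_id == pat$patient_id[i], ]
    hits <- grepl(pat$first_smi_code[i], own$diagnoses, fixed = TRUE)
    expect_equal(sum(hits), 1)
    expect_equal(own$admission_date[hits], pat$first_smi_date[i])
  }
  expect_error(generate_episodes(pat[0, ], cfg), "empty")
})

test_that("certain recurrence replays chronic history in every later episode", {
  cfg <- cohort_config(n_patients = 30, seed = 5, recurrence_prob = 1,
                       chronic_fraction = 1, codes_per_episode_mean = 1,
                       episode_rate_pre = 0.4, episode_rate_post = 0.6,
                       n_diseases = 40)
  pat <- generate_cohort(cfg)
  ep <- generate_episodes(pat, cfg)
  for (pid in pat$patient_id) {
    own <- ep[ep$patient_id == pid, ]
    own <- own[order(own$admission_date), ]
    codes <- strsplit(own$diagnoses, ";")
    idx <- own$diagnoses %in% c("F20", "F31")
    seen <- character(0)
    for (j in seq_along(codes)) {
      if (!idx[j]) {
        expect_true(all(seen %in% codes[[j]]), label = pid)
        seen <- union(seen, codes[[j]])
      }
    }
  }
})

test_that("with all mechanisms off, diagnoses are independent of age", {
  # chi-square of top-disease x age-tercile contingency, never significant
  # at alpha = 0.001 across 5 seeds
  for (seed in 1:5) {
    cfg <- cohort_config(n_patients = 500, seed = seed,
                         selection_strength = 0, progression_strength = 0,
                         recurrence_prob = 0)
    pat <- generate_cohort(cfg)
    ep <- generate_episodes(pat, cfg)
    ev <- build_event_stream(ep, pat)
    ev <- ev[!ev$code3 %in% c("F20", "F31"), ]
    age <- as.numeric(pat$first_smi_date - pat$dob) / 365.25
    terc <- cut(age, quantile(age, c(0, 1/3, 2/3, 1)), include.lowest = TRUE,
                labels = c("low", "mid", "high"))
    ev$terc <- terc[match(ev$patient_id, pat$patient_id)]
    top <- names(sort(table(ev$code3), decreasing = TRUE))[1:20]
    tab <- table(ev$code3[ev$code3 %in% top], ev$terc[ev$code3 %in% top])
    p <- suppressWarnings(chisq.test(tab)$p.value)
    expect_gt(p, 0.001)
  }
})

test_that("selection and progression are separable and recoverable", {
  mi <- function(tab) {
    p <- tab / sum(tab)
    px <- rowSums(p); py <- colSums(p)
    sum(p * log(p / outer(px, py)), na.rm = TRUE)
  }
  age_mi <- function(sel, seed) {
    cfg <- cohort_config(n_patients = 300, seed = seed, n_diseases = 60,
                         selection_strength = sel, recurrence_prob = 0)
    pat <- generate_cohort(cfg)
    ep <- generate_episodes(pat, cfg)
    ev <- build_event_stream(ep, pat)
    ev <- ev[!ev$code3 %in% c("F20", "F31"), ]
    age <- as.numeric(pat$first_smi_date - pat$dob) / 365.25
    band <- cut(age, c(0, 30, 45, 60, Inf))
    mi(table(ev$code3, band[match(ev$patient_id, pat$patient_id)]))
  }
  on <- vapply(1:5, function(s) age_mi(5, s), numeric(1))
  off <- vapply(1:5, function(s) age_mi(0, s), numeric(1))
  expect_gt(mean(on), mean(off))

  # progression: partner diseases are lifted above their base rate
  lift <- function(prog, seed) {
    cfg <- cohort_config(n_patients = 300, seed = seed, n_diseases = 200,
                         prevalence_exponent = 0.5,
                         progression_strength = prog, recurrence_prob = 0)
    pat <- generate_cohort(cfg)
    mod <- disease_model(cfg)
    ep <- generate_episodes(pat, cfg, mod)
    ev <- build_event_stream(ep, pat)
    ev <- ev[!ev$code3 %in% c("F20", "F31"), ]
    hit <- 0L; n <- 0L
    for (pid in pat$patient_id) {
      own <- ev[ev$patient_id == pid, ]
      codes <- match(own$code3, mod$codes)
      if (length(codes) < 2) next
      for (j in 2:length(codes)) {
        partner_set <- unique(unlist(mod$partners[codes[seq_len(j - 1)]]))
        n <- n + 1L
        if (codes[j] %in% partner_set) hit <- hit + 1L
      }
    }
    hit / n
  }
  lift_on <- vapply(1:5, function(s) lift(30, s), numeric(1))
  lift_off <- vapply(1:5, function(s) lift(0, s), numeric(1))
  expect_gt(mean(lift_on), 2 * mean(lift_off))
})

test_that("empirical disease frequencies track the planted heavy tail", {
  cfg <- cohort_config(n_patients = 1000, seed = 9)
  pat <- generate_cohort(cfg)
  mod <- disease_model(cfg)
  ep <- generate_episodes(pat, cfg, mod)
  ev <- build_event_stream(ep, pat)
  counts <- table(factor(ev$code3, levels = mod$codes))
  rho <- cor(as.numeric(counts), mod$prevalence, method = "spearman")
  expect_gt(rho, 0.8)
})

test_that("cohort CSVs round-trip exactly, with the declared dialect", {
  cfg <- cohort_config(n_patients = 25, seed = 2)
  pat <- generate_cohort(cfg)
  ep <- generate_episodes(pat, cfg)
  ep$diagnoses[1] <- "F20;I10"
  dir <- withr::local_tempdir()
  write_cohort(pat, ep, dir)
  raw <- readLines(file.path(dir, "episodes.csv"))
  expect_true(any(grepl("F20;I10", raw, fixed = TRUE)))
  back <- read_cohort(dir)
  expect_equal(back$patients, pat)
  expect_equal(back$episodes, ep)
  # empty episode table still writes a valid header-only file
  write_cohort(pat, ep[0, ], dir)
  empty <- read_cohort(dir)
  expect_equal(nrow(empty$episodes), 0)
  expect_equal(names(empty$episodes), names(ep))
})

test_that("the latent disease model round-trips through JSON", {
  cfg <- cohort_config(n_patients = 10, seed = 3, n_diseases = 20)
  mod <- disease_model(cfg)
  path <- withr::local_tempfile(fileext = ".json")
  write_disease_model(mod, path)
  back <- read_disease_model(path)
  expect_equal(back$codes, mod$codes)
  expect_equal(back$prevalence, mod$prevalence)
  expect_equal(back$chronic, mod$chronic)
  expect_equal(back$partners, mod$partners)
})
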