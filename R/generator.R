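# Synthetic SMI cohort generator.
#
# Replaces the non-deposited mental-health/hospital linkage with a
# seed-reproducible stand-in that has the statistical structure the analysis
# assumes: a ~60/40 F20/F31 split, age at first SMI diagnosis approximately
# Normal(39.5, 16.5) truncated to plausible ages, a heavy-tailed disease
# prevalence distribution, and episode streams spanning years before and after
# the index date. Three independently switchable mechanisms shape how
# diagnoses attach to patients:
#   selection   - age homophily: each disease has a latent age centre and is
#                 preferentially drawn by patients of nearby age;
#   progression - conditional progression: diseases already in a patient's
#                 history multiplicatively boost their latent partner diseases;
#   recurrence  - chronic conditions in the history re-appear in later
#                 episodes with a fixed probability.
# All three default to off/neutral so the baseline cohort is a product-form
# (configuration-model-like) world, which is what the null-model tests assume.

#' Configuration for the synthetic SMI cohort generator
#'
#' All arguments have defaults; the epidemiological ones (F20/F31 split, age at
#' first SMI diagnosis) default to the cohort-level values the analysis is
#' anchored to, the mechanism strengths default to off.
#'
#' @param n_patients Number of patients to generate.
#' @param seed Integer seed; the generator is fully deterministic given the
#'   config (the seed is expanded into independent per-stage streams).
#' @param p_f20 Probability that a patient's index SMI diagnosis is
#'   schizophrenia (F20) rather than bipolar disorder (F31). Default 0.6.
#' @param age_at_smi_mean,age_at_smi_sd Mean/SD (years) of the normal law for
#'   age at first SMI diagnosis. Defaults 39.5 and 16.5.
#' @param age_at_smi_bounds Length-2 truncation bounds in years. Default
#'   `c(0, 100)`: the truncation exists to exclude impossible values, and a
#'   loose lower bound keeps the truncated mean within half a year of the
#'   configured mean (tighter clinical bounds bias it upwards).
#' @param n_diseases Size of the (non-SMI) disease vocabulary. Default 150.
#' @param prevalence_exponent Zipf exponent of the planted prevalence weights
#'   `rank^(-exponent)`; larger means heavier concentration on top diseases.
#'   Default 1.2.
#' @param episode_rate_pre,episode_rate_post Poisson rates (episodes/year) of
#'   hospital admissions before/after the index date. Defaults 0.8 and 1.5.
#' @param obs_years_pre,obs_years_post Observation span (years) before/after
#'   the index date. Defaults 12 and 8.
#' @param codes_per_episode_mean Mean number of freshly drawn diagnosis codes
#'   per episode (at least 1, at most 20 including recurrences). Default 2.
#' @param selection_strength Nonnegative age-homophily strength; per-draw
#'   disease weight is multiplied by
#'   `exp(-selection_strength * |patient_age - age_centre| / 10)`. Default 0.
#' @param progression_strength Nonnegative progression strength; per-draw
#'   weight is multiplied by `1 + progression_strength * (number of history
#'   diseases that list this disease as a progression partner)`. Default 0.
#' @param recurrence_prob Probability that each chronic disease already in the
#'   history is re-diagnosed in a given later episode. Default 0.25.
#' @param chronic_fraction Fraction of diseases flagged chronic. Default 0.3.
#' @param n_progression_partners Latent progression partners per disease.
#'   Default 3.
#' @param p_female Probability of gender "female". Default 0.5.
#' @param ethnicity_probs Named probability vector over ethnicity categories;
#'   must sum to 1.
#' @param smi_window Length-2 `Date` vector: index SMI dates are uniform over
#'   this window (the cohort-identification decade).
#' @param censor_date Administrative censoring date; post-SMI observation is
#'   truncated here.
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 500L,
                          seed = 1L,
                          p_f20 = 0.6,
                          age_at_smi_mean = 39.5,
                          age_at_smi_sd = 16.5,
                          age_at_smi_bounds = c(0, 100),
                          n_diseases = 150L,
                          prevalence_exponent = 1.2,
                          episode_rate_pre = 0.8,
                          episode_rate_post = 1.5,
                          obs_years_pre = 12,
                          obs_years_post = 8,
                          codes_per_episode_mean = 2,
                          selection_strength = 0,
                          progression_strength = 0,
                          recurrence_prob = 0.25,
                          chronic_fraction = 0.3,
                          n_progression_partners = 3L,
                          p_female = 0.5,
                          ethnicity_probs = c(White = 0.55, Black = 0.25,
                                              Asian = 0.10, Mixed = 0.05,
                                              Other = 0.05),
                          smi_window = as.Date(c("2008-04-01", "2018-03-31")),
                          censor_date = as.Date("2018-03-31")) {
  cfg <- list(n_patients = as.integer(n_patients), seed = as.integer(seed),
              p_f20 = p_f20, age_at_smi_mean = age_at_smi_mean,
              age_at_smi_sd = age_at_smi_sd,
              age_at_smi_bounds = as.numeric(age_at_smi_bounds),
              n_diseases = as.integer(n_diseases),
              prevalence_exponent = prevalence_exponent,
              episode_rate_pre = episode_rate_pre,
              episode_rate_post = episode_rate_post,
              obs_years_pre = obs_years_pre, obs_years_post = obs_years_post,
              codes_per_episode_mean = codes_per_episode_mean,
              selection_strength = selection_strength,
              progression_strength = progression_strength,
              recurrence_prob = recurrence_prob,
              chronic_fraction = chronic_fraction,
              n_progression_partners = as.integer(n_progression_partners),
              p_female = p_female, ethnicity_probs = ethnicity_probs,
              smi_window = as.Date(smi_window),
              censor_date = as.Date(censor_date))
  validate_cohort_config(cfg)
  class(cfg) <- "cohort_config"
  cfg
}

validate_cohort_config <- function(cfg) {
  chk <- function(ok, field, msg) {
    if (!isTRUE(ok)) stop("invalid config field '", field, "': ", msg,
                          call. = FALSE)
  }
  prob <- function(p) is.numeric(p) && length(p) == 1 && !is.na(p) &&
    p >= 0 && p <= 1
  chk(is.integer(cfg$n_patients) && cfg$n_patients >= 1L,
      "n_patients", "must be a positive integer")
  chk(is.integer(cfg$seed) && !is.na(cfg$seed), "seed", "must be an integer")
  chk(prob(cfg$p_f20), "p_f20", "must be a probability in [0,1]")
  chk(prob(cfg$p_female), "p_female", "must be a probability in [0,1]")
  chk(prob(cfg$recurrence_prob), "recurrence_prob",
      "must be a probability in [0,1]")
  chk(prob(cfg$chronic_fraction), "chronic_fraction",
      "must be a probability in [0,1]")
  chk(cfg$age_at_smi_sd > 0, "age_at_smi_sd", "must be > 0")
  chk(length(cfg$age_at_smi_bounds) == 2 &&
        cfg$age_at_smi_bounds[1] < cfg$age_at_smi_bounds[2],
      "age_at_smi_bounds", "must be increasing [min, max]")
  chk(cfg$n_diseases >= 1L, "n_diseases", "must be a positive integer")
  chk(cfg$prevalence_exponent > 0, "prevalence_exponent", "must be > 0")
  for (f in c("episode_rate_pre", "episode_rate_post",
              "obs_years_pre", "obs_years_post",
              "selection_strength", "progression_strength")) {
    chk(is.numeric(cfg[[f]]) && cfg[[f]] >= 0, f, "must be nonnegative")
  }
  chk(cfg$codes_per_episode_mean >= 1, "codes_per_episode_mean",
      "must be >= 1")
  chk(is.numeric(cfg$ethnicity_probs) && all(cfg$ethnicity_probs >= 0) &&
        abs(sum(cfg$ethnicity_probs) - 1) < 1e-8 &&
        !is.null(names(cfg$ethnicity_probs)),
      "ethnicity_probs", "must be a named distribution summing to 1")
  chk(!is.na(cfg$censor_date), "censor_date", "must be a calendar date")
  invisible(cfg)
}

# Expand the config seed into an independent per-stage stream; keeps the
# derived seed inside 32-bit integer range.
stage_seed <- function(seed, stage) {
  offs <- c(cohort = 11L, model = 127L, episodes = 1299721L)
  (abs(seed) * 48271L + offs[[stage]]) %% 2147483629L
}

rtruncnorm <- function(n, mean, sd, lo, hi) {
  u <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

#' Generate the patient table of a synthetic SMI cohort
#'
#' Draws demographics and index-diagnosis attributes for `n_patients`
#' patients: index code F20 with probability `p_f20` (else F31), index date
#' uniform over `smi_window`, age at index from the truncated normal, date of
#' birth back-computed from that age. All patients are alive and censored at
#' `censor_date` (`death_date` is `NA`).
#'
#' @param config A [cohort_config()].
#' @return `data.frame` with columns `patient_id`, `gender`, `ethnicity`,
#'   `dob`, `first_smi_code`, `first_smi_date`, `death_date`.
#' @export
generate_cohort <- function(config) {
  validate_cohort_config(config)
  n <- config$n_patients
  set.seed(stage_seed(config$seed, "cohort"))
  code <- ifelse(stats::runif(n) < config$p_f20, "F20", "F31")
  gender <- ifelse(stats::runif(n) < config$p_female, "female", "male")
  ethnicity <- sample(names(config$ethnicity_probs), n, replace = TRUE,
                      prob = config$ethnicity_probs)
  span <- as.integer(config$smi_window[2] - config$smi_window[1])
  smi_date <- config$smi_window[1] + sample.int(span + 1L, n, replace = TRUE) - 1L
  age <- rtruncnorm(n, config$age_at_smi_mean, config$age_at_smi_sd,
                    config$age_at_smi_bounds[1], config$age_at_smi_bounds[2])
  dob <- smi_date - round(age * 365.25)
  data.frame(patient_id = sprintf("P%05d", seq_len(n)),
             gender = gender, ethnicity = ethnicity, dob = dob,
             first_smi_code = code, first_smi_date = smi_date,
             death_date = as.Date(NA), stringsAsFactors = FALSE)
}

#' Frozen generator worlds for mechanism-recovery experiments
#'
#' Returns the [cohort_config()] used by the parameter-recovery analyses. The
#' base world uses a vocabulary of 1000 diseases with a near-flat prevalence
#' law (exponent 0.2), so that cross-patient diagnosis collisions carry
#' information about the planted mechanism rather than about marginal
#' prevalence; `"selection"` turns the age-homophily kernel on at strength 8,
#' `"progression"` turns conditional progression on at strength 30. The
#' `"disassortativity"` world is the selection mechanism with the heavy
#' prevalence tail retained (exponent 1.0), the regime in which degree mixing
#' deviates measurably from the degree-preserving null. These values were
#' fixed once at design time (see the methods vignette).
#'
#' @param mechanism One of `"none"`, `"selection"`, `"progression"`,
#'   `"disassortativity"`.
#' @param n_patients,seed Passed through to [cohort_config()].
#' @return A `cohort_config`.
#' @export
mechanism_config <- function(mechanism = c("none", "selection", "progression",
                                           "disassortativity"),
                             n_patients = 500L, seed = 1L) {
  mechanism <- match.arg(mechanism)
  cohort_config(
    n_patients = n_patients, seed = seed,
    n_diseases = 1000L,
    prevalence_exponent = if (mechanism == "disassortativity") 1.0 else 0.2,
    selection_strength = if (mechanism %in% c("selection",
                                              "disassortativity")) 8 else 0,
    progression_strength = if (mechanism == "progression") 30 else 0)
}

#' Latent disease model (planted ground truth)
#'
#' Draws the disease vocabulary and the latent quantities the generative
#' mechanisms act on: per-disease prevalence weight `rank^(-exponent)`, an age
#' centre for the homophily kernel, a chronic flag, and a sparse progression
#' partner structure (each disease boosts `n_progression_partners` partner
#' diseases). Codes are plausible 3-character ICD-10 categories restricted to
#' the disease chapters I-XIV; F20 and F31 are never in the vocabulary, so the
#' index SMI diagnosis occurs exactly once per patient, at the index date.
#'
#' @param config A [cohort_config()].
#' @return A list of class `disease_model` with elements `codes`, `prevalence`,
#'   `age_center`, `chronic`, `partners` (list of integer vectors).
#' @export
disease_model <- function(config) {
  validate_cohort_config(config)
  set.seed(stage_seed(config$seed, "model"))
  letters10 <- c("A", "B", "C", "D", "E", "F", "G", "H", "I", "J", "K",
                 "L", "M", "N")
  pool <- as.vector(outer(letters10, sprintf("%02d", 0:99), paste0))
  pool <- setdiff(pool, c("F20", "F31"))
  if (config$n_diseases > length(pool)) {
    stop("n_diseases exceeds the available 3-character code pool")
  }
  codes <- sample(pool, config$n_diseases)
  nd <- config$n_diseases
  prevalence <- seq_len(nd)^(-config$prevalence_exponent)
  age_center <- stats::runif(nd, 20, 80)
  chronic <- stats::runif(nd) < config$chronic_fraction
  k <- min(config$n_progression_partners, nd - 1L)
  partners <- lapply(seq_len(nd), function(i) {
    if (k == 0L) integer(0) else sample(setdiff(seq_len(nd), i), k)
  })
  structure(list(codes = codes, prevalence = prevalence,
                 age_center = age_center, chronic = chronic,
                 partners = partners),
            class = "disease_model")
}

# Per-episode diagnosis sampler. history: integer disease indices seen so far.
sample_episode_codes <- function(model, config, age_at_episode, history) {
  nd <- length(model$codes)
  w <- model$prevalence
  if (config$selection_strength > 0) {
    w <- w * exp(-config$selection_strength *
                   abs(age_at_episode - model$age_center) / 10)
  }
  if (config$progression_strength > 0 && length(history)) {
    boost <- tabulate(unlist(model$partners[history]), nbins = nd)
    w <- w * (1 + config$progression_strength * boost)
  }
  n_new <- 1L + stats::rpois(1L, config$codes_per_episode_mean - 1)
  n_new <- min(n_new, nd)
  drawn <- sample.int(nd, n_new, prob = w)
  recur <- integer(0)
  if (config$recurrence_prob > 0 && length(history)) {
    chron <- history[model$chronic[history]]
    if (length(chron)) {
      recur <- chron[stats::runif(length(chron)) < config$recurrence_prob]
    }
  }
  out <- unique(c(recur, drawn))
  out[seq_len(min(length(out), 20L))]
}

#' Generate admission episodes for a synthetic cohort
#'
#' Per patient, admission times follow a Poisson process at
#' `episode_rate_pre` over the `obs_years_pre` years before the index date and
#' `episode_rate_post` over the `obs_years_post` years after it (truncated at
#' `censor_date`); the index SMI diagnosis is materialised as its own episode
#' on `first_smi_date`. Episode diagnosis lists are sampled from the latent
#' disease model with the configured selection/progression/recurrence
#' mechanisms, processing episodes in time order so the history is causal.
#'
#' @param patients Patient table from [generate_cohort()].
#' @param config The same [cohort_config()].
#' @param model A [disease_model()]; defaults to `disease_model(config)`.
#' @return `data.frame` with columns `episode_id`, `patient_id`,
#'   `admission_date`, `discharge_date`, `diagnoses` (semicolon-joined codes).
#' @export
generate_episodes <- function(patients, config, model = disease_model(config)) {
  validate_cohort_config(config)
  if (!is.data.frame(patients) || nrow(patients) == 0) {
    stop("patients table is empty")
  }
  set.seed(stage_seed(config$seed, "episodes"))
  rows <- vector("list", nrow(patients))
  for (i in seq_len(nrow(patients))) {
    p <- patients[i, ]
    smi <- p$first_smi_date
    pre_days <- round(config$obs_years_pre * 365.25)
    post_days <- min(round(config$obs_years_post * 365.25),
                     as.integer(config$censor_date - smi))
    n_pre <- stats::rpois(1L, config$episode_rate_pre * config$obs_years_pre)
    n_post <- if (post_days > 0) {
      stats::rpois(1L, config$episode_rate_post * post_days / 365.25)
    } else 0L
    pre_t <- if (n_pre > 0) {
      smi - sample.int(pre_days, n_pre, replace = TRUE)
    } else smi[0]
    post_t <- if (n_post > 0) {
      smi + sample.int(post_days, n_post, replace = TRUE)
    } else smi[0]
    history <- integer(0)
    adm_all <- c(sort(pre_t), smi, sort(post_t))
    diag_list <- character(length(adm_all))
    is_index <- c(rep(FALSE, length(pre_t)), TRUE, rep(FALSE, length(post_t)))
    age0 <- as.numeric(smi - p$dob) / 365.25
    for (j in seq_along(adm_all)) {
      if (is_index[j]) {
        diag_list[j] <- p$first_smi_code
      } else {
        age_ep <- age0 + as.numeric(adm_all[j] - smi) / 365.25
        idx <- sample_episode_codes(model, config, age_ep, history)
        history <- unique(c(history, idx))
        diag_list[j] <- paste(model$codes[idx], collapse = ";")
      }
    }
    los <- stats::rpois(length(adm_all), 3)
    rows[[i]] <- data.frame(patient_id = p$patient_id,
                            admission_date = adm_all,
                            discharge_date = adm_all + los,
                            diagnoses = diag_list,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$admission_date, out$patient_id), , drop = FALSE]
  out <- data.frame(episode_id = sprintf("E%06d", seq_len(nrow(out))), out,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Write / read a cohort as CSV
#'
#' Dates are ISO-8601; the per-episode diagnosis list is a single cell with
#' codes joined by `";"`. `read_cohort()` round-trips exactly.
#'
#' @param patients,episodes Tables from the generator (or user data in the
#'   same schema).
#' @param dir Directory to write `patients.csv` and `episodes.csv` into
#'   (created if needed).
#' @return `write_cohort()` the directory, invisibly; `read_cohort()` a list
#'   with elements `patients` and `episodes`.
#' @export
write_cohort <- function(patients, episodes, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p <- patients
  for (col in c("dob", "first_smi_date", "death_date")) {
    p[[col]] <- format(p[[col]], "%Y-%m-%d")
  }
  e <- episodes
  for (col in c("admission_date", "discharge_date")) {
    e[[col]] <- format(e[[col]], "%Y-%m-%d")
  }
  utils::write.csv(p, file.path(dir, "patients.csv"), row.names = FALSE,
                   na = "")
  utils::write.csv(e, file.path(dir, "episodes.csv"), row.names = FALSE,
                   na = "")
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  p <- utils::read.csv(file.path(dir, "patients.csv"),
                       stringsAsFactors = FALSE,
                       colClasses = c(patient_id = "character"))
  for (col in c("dob", "first_smi_date", "death_date")) {
    p[[col]] <- as.Date(ifelse(p[[col]] == "" | is.na(p[[col]]),
                               NA, p[[col]]))
  }
  e <- utils::read.csv(file.path(dir, "episodes.csv"),
                       stringsAsFactors = FALSE,
                       colClasses = c(patient_id = "character",
                                      episode_id = "character",
                                      diagnoses = "character"))
  for (col in c("admission_date", "discharge_date")) {
    e[[col]] <- as.Date(e[[col]])
  }
  list(patients = p, episodes = e)
}

#' Dump / load the latent disease model as JSON
#'
#' The ground truth is serialised so parameter-recovery tests can compare
#' empirical structure against the planted model.
#'
#' @param model A [disease_model()].
#' @param path JSON file path.
#' @export
write_disease_model <- function(model, path) {
  jsonlite::write_json(unclass(model), path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_disease_model
#' @export
read_disease_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyMatrix = FALSE)
  x$partners <- lapply(x$partners, as.integer)
  x$chronic <- as.logical(x$chronic)
  structure(x[c("codes", "prevalence", "age_center", "chronic", "partners")],
            class = "disease_model")
}
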