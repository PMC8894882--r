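# Shared fixtures: tiny hand-built cohorts, networks and event streams.

REF_DATE <- as.Date("2010-01-01")

# Patient table with given ids; ages (years at first SMI) optional.
fixture_patients <- function(ids, ages = NULL, smi_code = "F20",
                             smi_date = REF_DATE) {
  n <- length(ids)
  if (is.null(ages)) ages <- rep(40, n)
  smi_date <- rep(as.Date(smi_date), length.out = n)
  data.frame(patient_id = ids,
             gender = rep(c("female", "male"), length.out = n),
             ethnicity = rep("White", n),
             dob = smi_date - round(ages * 365.25),
             first_smi_code = rep(smi_code, length.out = n),
             first_smi_date = smi_date,
             death_date = as.Date(NA),
             stringsAsFactors = FALSE)
}

# Event stream straight from (patient, code, day-offset) triples; offsets are
# days relative to each patient's first SMI date.
fixture_events <- function(p, code, day = seq_along(p), patients = NULL) {
  if (is.null(patients)) patients <- fixture_patients(sort(unique(p)))
  smi <- patients$first_smi_date[match(p, patients$patient_id)]
  ev <- data.frame(patient_id = p, code3 = code, timestamp = smi + day,
                   episode_id = sprintf("E%04d", seq_along(p)),
                   within_episode_rank = 0L,
                   years_to_smi = day / 365.25,
                   stringsAsFactors = FALSE)
  ev <- ev[order(ev$timestamp, ev$episode_id), , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

# Bipartite network from explicit (patient, disease-code) pairs; one event
# per pair occurrence so weights equal pair multiplicities.
fixture_network <- function(p, code, ages = NULL, day = NULL) {
  patients <- fixture_patients(sort(unique(p)), ages = ages)
  if (is.null(day)) day <- seq_along(p)
  ev <- fixture_events(p, code, day = day, patients = patients)
  build_network(ev, patients, label = "ALL")
}

# Random simple bipartite network with n_p patients, n_d diseases, m edges.
random_network <- function(n_p, n_d, m, seed) {
  set.seed(seed)
  all_pairs <- expand.grid(p = seq_len(n_p), d = seq_len(n_d))
  pick <- all_pairs[sample.int(nrow(all_pairs), m), ]
  codes <- sprintf("J%02d", (seq_len(n_d) - 1) %% 100)
  fixture_network(sprintf("P%03d", pick$p), codes[pick$d])
}

# Random diagnosis event stream (days over ~6 years either side of the index
# date), suitable for graphlet-counting oracle checks.
random_stream <- function(n_events, n_p, n_d, seed) {
  set.seed(seed)
  p <- sprintf("P%03d", sample.int(n_p, n_events, replace = TRUE))
  codes <- sprintf("K%02d", (seq_len(n_d) - 1) %% 100)
  d <- codes[sample.int(n_d, n_events, replace = TRUE)]
  day <- sample(-1100:1100, n_events, replace = TRUE)
  fixture_events(p, d, day = day)
}

# Memoised mechanism-world artefacts so acceptance blocks can share cohorts.
.mech_cache <- new.env(parent = emptyenv())
mechanism_artifacts <- function(mechanism, seed, n_patients = 500L) {
  key <- paste(mechanism, seed, n_patients, sep = "_")
  if (is.null(.mech_cache[[key]])) {
    cfg <- mechanism_config(mechanism, n_patients = n_patients, seed = seed)
    patients <- generate_cohort(cfg)
    episodes <- generate_episodes(patients, cfg)
    events <- build_event_stream(episodes, patients)
    .mech_cache[[key]] <- list(config = cfg, patients = patients,
                               events = events)
  }
  .mech_cache[[key]]
}
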