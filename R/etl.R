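# Cohort ETL: raw patient/episode tables -> diagnosis event stream and
# per-patient pre/post-SMI condition splits.

#' Resolve a patient's first SMI diagnosis across sources
#'
#' Given every SMI mention (code F20 or F31) of one patient from the
#' mental-health and hospital sources, returns the earliest one. Date ties are
#' broken by source priority (mental-health register over hospital records),
#' then by code lexicographically.
#'
#' @param mentions `data.frame` with columns `code` (F20/F31), `date` (`Date`)
#'   and `source` (`"MH"` or `"HOSP"`).
#' @return List with elements `code` and `date`.
#' @export
resolve_first_smi <- function(mentions) {
  if (!is.data.frame(mentions) || nrow(mentions) == 0) {
    stop("no SMI mention: patient is not in the cohort")
  }
  if (!all(mentions$code %in% c("F20", "F31"))) {
    stop("SMI mentions must be F20 or F31")
  }
  src_rank <- ifelse(mentions$source == "MH", 0L, 1L)
  o <- order(as.Date(mentions$date), src_rank, mentions$code)
  list(code = mentions$code[o[1]], date = as.Date(mentions$date[o[1]]))
}

#' Build the diagnosis event stream
#'
#' Explodes episode diagnosis lists into one event per (episode, retained
#' 3-character code): codes are normalised ([normalize_icd10()]), invalid codes
#' are dropped, codes in the excluded chapters (by default the non-disease
#' chapters XV-XXII) are dropped, duplicate codes within one episode collapse
#' to a single event keeping the smallest within-episode rank. Each event is
#' timestamped with the admission date and annotated with its signed offset in
#' years from the patient's first SMI diagnosis (negative = pre-SMI). The
#' patient's SMI codes are retained in the stream (network construction
#' excludes them later; graphlet analysis keeps them).
#'
#' @param episodes,patients Tables in the [generate_cohort()] /
#'   [generate_episodes()] schema.
#' @param exclude_chapters Chapters to drop; default [excluded_chapters()].
#' @param exclude_mental If `TRUE`, additionally drop all F-prefixed codes
#'   (sensitivity analysis).
#' @param window_years If finite, keep only events within `window_years` years
#'   before and after the first SMI date (closed on the SMI side:
#'   `[-w, 0)` and `[0, w]`).
#' @return `data.frame` of events sorted by (timestamp, episode_id, rank) with
#'   columns `patient_id`, `code3`, `timestamp`, `episode_id`,
#'   `within_episode_rank`, `years_to_smi`.
#' @export
build_event_stream <- function(episodes, patients,
                               exclude_chapters = excluded_chapters(),
                               exclude_mental = FALSE,
                               window_years = Inf) {
  orphans <- setdiff(unique(episodes$patient_id), patients$patient_id)
  if (length(orphans)) {
    stop("episodes reference unknown patient_id(s): ",
         paste(orphans, collapse = ", "))
  }
  codes <- strsplit(episodes$diagnoses, ";", fixed = TRUE)
  nper <- lengths(codes)
  ev <- data.frame(
    patient_id = rep(episodes$patient_id, nper),
    code3 = normalize_icd10(unlist(codes)),
    timestamp = rep(episodes$admission_date, nper),
    episode_id = rep(episodes$episode_id, nper),
    within_episode_rank = unlist(lapply(nper, seq_len)) - 1L,
    stringsAsFactors = FALSE)
  ev <- ev[!is.na(ev$code3), , drop = FALSE]
  if (nrow(ev)) {
    chap <- icd10_chapter(ev$code3)
    ev <- ev[!(chap %in% exclude_chapters), , drop = FALSE]
  }
  if (exclude_mental && nrow(ev)) {
    ev <- ev[substr(ev$code3, 1, 1) != "F", , drop = FALSE]
  }
  # collapse duplicate codes within an episode, keeping the smallest rank
  ev <- ev[order(ev$episode_id, ev$code3, ev$within_episode_rank), ,
           drop = FALSE]
  dup <- duplicated(ev[c("episode_id", "code3")])
  ev <- ev[!dup, , drop = FALSE]
  smi_date <- patients$first_smi_date[match(ev$patient_id,
                                            patients$patient_id)]
  ev$years_to_smi <- as.numeric(ev$timestamp - smi_date) / 365.25
  if (is.finite(window_years)) {
    ev <- ev[ev$years_to_smi >= -window_years &
               ev$years_to_smi <= window_years, , drop = FALSE]
  }
  ev <- ev[order(ev$timestamp, ev$episode_id, ev$within_episode_rank), ,
           drop = FALSE]
  rownames(ev) <- NULL
  ev
}

#' Split a cohort's events into pre/post-SMI condition sets
#'
#' Per patient, events strictly before the first SMI date feed the
#' pre-existing set N1 and events on/after it feed the post set N2; all events
#' carrying the patient's own index SMI code are excluded from both sets. The
#' ratio of new conditions is `|N2 \\ N1| / |N1 U N2|`, in `[0, 1]`, and is
#' `NA` for patients with no non-SMI conditions at all (such patients are not
#' part of the network models). For every new condition, the years from the
#' index date to its first post-SMI diagnosis are recorded.
#'
#' @param events Event stream from [build_event_stream()].
#' @param patients Patient table.
#' @return `data.frame` with one row per patient: list-columns `pre_existing`,
#'   `post_set`, `new_conditions`, `re_occurring`, `first_appearance_years`
#'   (named numeric), and scalar `new_ratio`.
#' @export
condition_splits <- function(events, patients) {
  out <- vector("list", nrow(patients))
  for (i in seq_len(nrow(patients))) {
    pid <- patients$patient_id[i]
    ev <- events[events$patient_id == pid, , drop = FALSE]
    out[[i]] <- split_conditions(ev, patients$first_smi_code[i],
                                 patients$first_smi_date[i])
    out[[i]]$patient_id <- pid
  }
  data.frame(
    patient_id = vapply(out, `[[`, character(1), "patient_id"),
    pre_existing = I(lapply(out, `[[`, "pre_existing")),
    post_set = I(lapply(out, `[[`, "post_set")),
    new_conditions = I(lapply(out, `[[`, "new_conditions")),
    re_occurring = I(lapply(out, `[[`, "re_occurring")),
    first_appearance_years = I(lapply(out, `[[`, "first_appearance_years")),
    new_ratio = vapply(out, `[[`, numeric(1), "new_ratio"),
    stringsAsFactors = FALSE)
}

#' @rdname condition_splits
#' @param events_one Events of a single patient.
#' @param first_smi_code,first_smi_date The patient's index diagnosis.
#' @export
split_conditions <- function(events_one, first_smi_code, first_smi_date) {
  ev <- events_one[events_one$code3 != first_smi_code, , drop = FALSE]
  pre <- ev$timestamp < first_smi_date
  n1 <- sort(unique(ev$code3[pre]))
  n2 <- sort(unique(ev$code3[!pre]))
  new <- setdiff(n2, n1)
  reoc <- intersect(n1, n2)
  both <- union(n1, n2)
  ratio <- if (length(both) == 0) NA_real_ else length(new) / length(both)
  fay <- numeric(0)
  if (length(new)) {
    post_ev <- ev[!pre & ev$code3 %in% new, , drop = FALSE]
    first_ts <- tapply(as.numeric(post_ev$timestamp), post_ev$code3, min)
    fay <- (first_ts - as.numeric(first_smi_date)) / 365.25
    fay <- fay[new]
  }
  list(pre_existing = n1, post_set = n2, new_conditions = new,
       re_occurring = reoc, first_appearance_years = fay, new_ratio = ratio)
}

#' New conditions per year of post-SMI follow-up
#'
#' Normalises each patient's number of new conditions by the follow-up years
#' from the first SMI date to the death date if present, else to the
#' administrative censoring date. New conditions are split into mental
#' (F-prefixed) and physical (all other chapters).
#'
#' @param splits Output of [condition_splits()].
#' @param patients Patient table (for `first_smi_date` and `death_date`).
#' @param censor_date Administrative censoring date.
#' @return `data.frame` with columns `patient_id`, `followup_years`,
#'   `overall`, `mental`, `physical` (rates per year).
#' @export
new_per_year <- function(splits, patients, censor_date) {
  censor_date <- as.Date(censor_date)
  idx <- match(splits$patient_id, patients$patient_id)
  smi <- patients$first_smi_date[idx]
  death <- patients$death_date[idx]
  if (any(censor_date <= smi)) {
    stop("censor_date must be after every first_smi_date")
  }
  if (any(!is.na(death) & death < smi)) {
    stop("death_date before first_smi_date for: ",
         paste(splits$patient_id[!is.na(death) & death < smi], collapse = ", "))
  }
  end <- as.Date(ifelse(is.na(death), censor_date, death),
                 origin = "1970-01-01")
  yrs <- as.numeric(end - smi) / 365.25
  n_new <- lengths(splits$new_conditions)
  n_mental <- vapply(splits$new_conditions,
                     function(s) sum(substr(s, 1, 1) == "F"), integer(1))
  data.frame(patient_id = splits$patient_id, followup_years = yrs,
             overall = n_new / yrs, mental = n_mental / yrs,
             physical = (n_new - n_mental) / yrs, stringsAsFactors = FALSE)
}
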