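# Claims data model: read claim lines, reconstruct admission episodes,
# apply the prior-stroke washout, and link to the gold-standard registry.
#
# The analysis unit is the admission episode: an index in-hospital claim
# carrying a stroke diagnosis (I60-I64, principal or additional position),
# with all of the patient's claim lines in [index - 7 d, index + 90 d]
# attributed to it (the widest window any key identifier uses) and the full
# pre-index history kept as lookback lines.

.claims_columns <- c(
  "patient_id", "claim_id", "setting", "department", "code", "code_kind",
  "dx_position", "service_date", "claim_start_date"
)
.settings <- c("in_hospital", "outpatient")
.departments <- c("neurology", "neurosurgery", "rehabilitation", "other")
.code_kinds <- c("diagnosis", "procedure", "drug")
.dx_positions <- c("principal", "additional", "none")

# episode attribution window, days relative to the index date
.attribution_window <- c(-7L, 90L)

#' Stroke diagnosis code stems
#'
#' The I60-I64 family used for cohort inclusion and the washout: I60
#' subarachnoid hemorrhage, I61 intracranial hemorrhage, I62 other
#' nontraumatic intracranial hemorrhage, I63 cerebral infarction, I64
#' cerebrovascular disease not otherwise specified. Matched as prefixes.
#'
#' @return Character vector of 3-character code stems.
#' @export
stroke_dx_codes <- function() {
  c("I60", "I61", "I62", "I63", "I64")
}

validate_claim_lines <- function(claims, call = caller_env()) {
  missing_cols <- setdiff(.claims_columns, names(claims))
  if (length(missing_cols) > 0) {
    abort(
      paste0("claims table is missing required column(s): ",
             paste(missing_cols, collapse = ", ")),
      call = call
    )
  }
  claims <- as_tibble(claims)
  for (col in c("service_date", "claim_start_date")) {
    if (!inherits(claims[[col]], "Date")) {
      parsed <- as.Date(as.character(claims[[col]]), format = "%Y-%m-%d")
      bad <- which(is.na(parsed) & !is.na(claims[[col]]))
      if (length(bad) > 0) {
        abort(
          paste0("unparseable ", col, " at row(s): ",
                 paste(head(bad, 10), collapse = ", ")),
          call = call
        )
      }
      claims[[col]] <- parsed
    }
  }
  check_levels <- function(col, levels) {
    bad <- which(!claims[[col]] %in% levels)
    if (length(bad) > 0) {
      abort(
        paste0("invalid ", col, " value(s) at row(s): ",
               paste(head(bad, 10), collapse = ", "),
               " (allowed: ", paste(levels, collapse = ", "), ")"),
        call = call
      )
    }
  }
  check_levels("setting", .settings)
  check_levels("department", .departments)
  check_levels("code_kind", .code_kinds)
  check_levels("dx_position", .dx_positions)
  bad_dx <- which(
    (claims$code_kind == "diagnosis") != (claims$dx_position != "none")
  )
  if (length(bad_dx) > 0) {
    abort(
      paste0("dx_position must be principal/additional exactly for diagnosis ",
             "lines; violated at row(s): ",
             paste(head(bad_dx, 10), collapse = ", ")),
      call = call
    )
  }
  if (any(!nzchar(claims$code) | is.na(claims$code))) {
    abort("claim `code` must be non-empty", call = call)
  }
  claims
}

#' Read claim lines from a delimited file
#'
#' Reads a UTF-8 CSV with one billed code per row and validates the schema:
#' columns `patient_id`, `claim_id`, `setting` (`in_hospital`/`outpatient`),
#' `department` (`neurology`/`neurosurgery`/`rehabilitation`/`other`),
#' `code`, `code_kind` (`diagnosis`/`procedure`/`drug`), `dx_position`
#' (`principal`/`additional`, `none` for non-diagnosis lines), and ISO-8601
#' `service_date` and `claim_start_date`. Extra columns (e.g. a hospital
#' `site`) are preserved but unused.
#'
#' Downstream results never depend on row order.
#'
#' @param path Path to the CSV file.
#' @return A tibble of claim lines.
#' @export
read_claims <- function(path) {
  claims <- readr::read_csv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  validate_claim_lines(claims)
}

#' Read a gold-standard registry table
#'
#' @param path CSV with columns `episode_id` and `true_ais` (0/1).
#' @return A tibble with `episode_id` (character) and `true_ais` (logical).
#' @export
read_registry <- function(path) {
  reg <- readr::read_csv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  if (!all(c("episode_id", "true_ais") %in% names(reg))) {
    abort("registry table must have columns episode_id and true_ais")
  }
  reg %>%
    mutate(true_ais = as.logical(as.integer(true_ais))) %>%
    select(episode_id, true_ais)
}

new_stroke_episodes <- function(meta, lines, lookback) {
  structure(
    meta,
    lines = lines,
    lookback = lookback,
    class = c("stroke_episodes", class(tibble()))
  )
}

#' Reconstruct admission episodes from claim lines
#'
#' An episode is created for every in-hospital claim that carries a stroke
#' diagnosis code (prefix I60-I64) in principal or additional position. The
#' episode id is that claim's id (the claim serial number stands in as the
#' linkage key), the index date is its claim start date, and the principal
#' diagnosis is the claim's principal-position diagnosis code. All of the
#' same patient's lines with a service date within 7 days before to 90 days
#' after the index date are attributed to the episode; everything strictly
#' before the index date is kept as lookback history. A patient readmitted
#' twice yields two episodes.
#'
#' @param claims A tibble of claim lines (see [read_claims()]).
#' @param stroke_codes Character vector of diagnosis code stems defining
#'   cohort entry; default [stroke_dx_codes()].
#' @return A `stroke_episodes` object: a tibble with one row per episode
#'   (`episode_id`, `patient_id`, `index_date`, `principal_dx`), carrying the
#'   attributed lines; see [episode_lines()] and [lookback_lines()].
#' @export
build_episodes <- function(claims, stroke_codes = stroke_dx_codes()) {
  claims <- validate_claim_lines(claims)

  qualifying <- claims %>%
    filter(
      setting == "in_hospital",
      code_kind == "diagnosis",
      dx_position %in% c("principal", "additional"),
      code_in_set(code, stroke_codes, "prefix")
    )

  index_claims <- qualifying %>%
    distinct(claim_id, patient_id, claim_start_date) %>%
    rename(episode_id = claim_id, index_date = claim_start_date)

  principal <- claims %>%
    filter(code_kind == "diagnosis", dx_position == "principal") %>%
    distinct(claim_id, .keep_all = TRUE) %>%
    select(episode_id = claim_id, principal_dx = code)

  meta <- index_claims %>%
    left_join(principal, by = "episode_id") %>%
    select(episode_id, patient_id, index_date, principal_dx) %>%
    arrange(episode_id)

  attributed <- meta %>%
    select(episode_id, patient_id, index_date) %>%
    inner_join(claims, by = "patient_id", relationship = "many-to-many") %>%
    mutate(day_offset = as.integer(service_date - index_date))

  lines <- attributed %>%
    filter(
      day_offset >= .attribution_window[1],
      day_offset <= .attribution_window[2]
    ) %>%
    select(-index_date)
  lookback <- attributed %>%
    filter(day_offset < 0L) %>%
    select(-index_date)

  new_stroke_episodes(meta, lines, lookback)
}

#' Attributed claim lines of episodes
#'
#' @param episodes A `stroke_episodes` object.
#' @return A tibble of claim lines keyed by `episode_id`, with `day_offset`
#'   relative to the episode's index date. `episode_lines()` returns the
#'   lines attributed to the admission (service date within -7 to +90 days);
#'   `lookback_lines()` returns all of the patient's lines strictly before
#'   the index date.
#' @export
episode_lines <- function(episodes) {
  stopifnot(inherits(episodes, "stroke_episodes"))
  attr(episodes, "lines")
}

#' @rdname episode_lines
#' @export
lookback_lines <- function(episodes) {
  stopifnot(inherits(episodes, "stroke_episodes"))
  attr(episodes, "lookback")
}

#' @export
print.stroke_episodes <- function(x, ...) {
  cat("<stroke_episodes>", nrow(x), "episodes,",
      length(unique(x$patient_id)), "patients\n")
  NextMethod()
}

#' Exclude patients with a stroke diagnosis before their index admission
#'
#' Drops every episode of any patient whose claims history contains an
#' I60-I64 diagnosis code strictly before that patient's earliest index
#' date (within `washout_days` of it), so that the surviving first
#' admission is an incident stroke. Later admissions of a surviving patient
#' are retained as readmission episodes. The operation is idempotent.
#'
#' @param episodes A `stroke_episodes` object.
#' @param washout_days Length of the washout window in days; `Inf` (the
#'   default) uses the entire available history.
#' @param stroke_codes Diagnosis code stems; default [stroke_dx_codes()].
#' @return A filtered `stroke_episodes` object. The number of excluded
#'   patients is available as `attr(x, "n_washout_excluded")`.
#' @export
apply_washout <- function(episodes, washout_days = Inf,
                          stroke_codes = stroke_dx_codes()) {
  stopifnot(inherits(episodes, "stroke_episodes"), washout_days > 0)
  meta <- as_tibble(episodes)
  first_index <- meta %>%
    group_by(patient_id) %>%
    summarise(earliest_index = min(index_date), .groups = "drop")

  prior <- lookback_lines(episodes) %>%
    filter(code_kind == "diagnosis",
           code_in_set(code, stroke_codes, "prefix")) %>%
    inner_join(first_index, by = "patient_id") %>%
    filter(
      service_date < earliest_index,
      as.numeric(earliest_index - service_date) <= washout_days
    )
  excluded_patients <- unique(prior$patient_id)

  keep <- meta %>% filter(!patient_id %in% excluded_patients)
  out <- new_stroke_episodes(
    keep,
    episode_lines(episodes) %>% filter(episode_id %in% keep$episode_id),
    lookback_lines(episodes) %>% filter(episode_id %in% keep$episode_id)
  )
  attr(out, "n_washout_excluded") <- length(excluded_patients)
  out
}

#' Link episodes to the gold-standard registry
#'
#' Labels every episode as true AIS or not purely by the existence of a
#' registry linkage: `true_ais` is `TRUE` iff a registry record with
#' `true_ais = TRUE` carries the episode's id. Registry records that match
#' no episode (registry-enrolled patients without claims data) are dropped
#' and tallied.
#'
#' @param episodes A `stroke_episodes` object.
#' @param registry A tibble with columns `episode_id` and `true_ais`
#'   (logical or 0/1); ids must be unique.
#' @return The episodes object with a logical `true_ais` column added.
#'   Attributes: `n_registry_unmatched` (dropped registry records) and
#'   `n_linked` (episodes labelled `TRUE`).
#' @export
link_registry <- function(episodes, registry) {
  stopifnot(inherits(episodes, "stroke_episodes"))
  registry <- as_tibble(registry) %>%
    mutate(true_ais = as.logical(true_ais))
  dup <- registry$episode_id[duplicated(registry$episode_id)]
  if (length(dup) > 0) {
    abort(paste0("duplicate registry episode_id(s): ",
                 paste(head(unique(dup), 10), collapse = ", ")))
  }
  positive <- registry$episode_id[registry$true_ais]
  n_unmatched <- sum(!registry$episode_id %in% episodes$episode_id)

  meta <- as_tibble(episodes) %>%
    mutate(true_ais = episode_id %in% positive)
  out <- new_stroke_episodes(
    meta, episode_lines(episodes), lookback_lines(episodes)
  )
  attr(out, "n_registry_unmatched") <- n_unmatched
  attr(out, "n_linked") <- sum(meta$true_ais)
  out
}
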