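# Evaluation of the 17 key identifiers for admission episodes.
#
# Each identifier is a boolean feature defined by a code set, a closed
# temporal window in days around the index date, and a data scope. Four
# identifiers carry special logic: image follow-up (counting distinct
# imaging events), the new-antithrombotics new-user definition (180-day
# ingredient lookback), anticoagulant presence, and the neurology-to-
# rehabilitation transfer.

# lookback horizon for the antithrombotic new-user definition ("last 6
# months" operationalised as 180 days)
.new_user_lookback_days <- 180L

filter_scope <- function(lines, scope) {
  if (scope == "in_hospital_only") {
    lines %>% filter(setting == "in_hospital")
  } else {
    lines
  }
}

# episode ids with >= 1 line matching a plain windowed code-set definition
match_episode_ids <- function(lines, def) {
  hits <- lines %>%
    filter_scope(def$scope) %>%
    filter(
      day_offset >= def$window[1],
      day_offset <= def$window[2],
      code_kind == def$code_kind,
      code_in_set(code, def$codes, def$match_mode)
    )
  unique(hits$episode_id)
}

# distinct antithrombotic ingredients per episode among `lines`
ingredient_sets <- function(lines, catalog) {
  lines %>%
    filter(code_kind == "drug") %>%
    mutate(ingredient = ingredient_of(code, catalog)) %>%
    filter(ingredient %in% catalog$antithrombotic_ingredients) %>%
    distinct(episode_id, ingredient)
}

#' Evaluate a plain windowed code-set identifier
#'
#' Returns, for each episode, whether at least one attributed claim line
#' matches the identifier's code set within its scope and temporal window
#' (both endpoints inclusive, day offsets relative to the index date).
#' Applies only to identifiers without special logic; the image follow-up,
#' new-antithrombotics, anticoagulants and transfer-to-rehab identifiers
#' have dedicated evaluators.
#'
#' @param episodes A `stroke_episodes` object.
#' @param definition An `identifier_definition`, or the name of one in
#'   `catalog`.
#' @param catalog A `stroke_catalog`.
#' @return A logical vector aligned with the rows of `episodes`.
#' @export
evaluate_code_window <- function(episodes, definition,
                                 catalog = default_catalog()) {
  if (is.character(definition)) {
    definition <- identifier_definition(definition, catalog)
  }
  if (definition$special != "none") {
    abort(paste0("identifier '", definition$name,
                 "' has special logic; use its dedicated evaluator"))
  }
  ids <- match_episode_ids(episode_lines(episodes), definition)
  episodes$episode_id %in% ids
}

#' Evaluate the image follow-up identifier
#'
#' True when an episode has two or more distinct brain-imaging events --
#' distinct (code, service date) pairs over the CT, CT-angiography and MRI
#' code sets -- within -7 to +7 days of the index date, at least one of
#' them a brain CT or MRI code. Two imaging modalities on the same day
#' count as two events; the same code on two dates also counts as two.
#'
#' @inheritParams evaluate_code_window
#' @return A logical vector aligned with the rows of `episodes`.
#' @export
evaluate_image_followup <- function(episodes, catalog = default_catalog()) {
  def <- catalog$identifiers$image_fu
  ct_mri <- unique(c(
    catalog$identifiers$brain_ct$codes, catalog$identifiers$brain_mri$codes
  ))
  events <- episode_lines(episodes) %>%
    filter_scope(def$scope) %>%
    filter(
      day_offset >= def$window[1], day_offset <= def$window[2],
      code_kind == def$code_kind,
      code_in_set(code, def$codes, def$match_mode)
    ) %>%
    distinct(episode_id, code, service_date)
  ids <- events %>%
    group_by(episode_id) %>%
    summarise(
      n_events = n(),
      any_ct_mri = any(code %in% ct_mri),
      .groups = "drop"
    ) %>%
    filter(n_events >= 2L, any_ct_mri) %>%
    pull(episode_id)
  episodes$episode_id %in% ids
}

#' Evaluate a new-antithrombotics (new-user) identifier
#'
#' Implements the new-user definition: with `L` the set of antithrombotic
#' ingredients claimed in the 180 days before the index date and `W` the
#' set claimed in the identifier's window (day 0 to `window_hi`) within its
#' scope, the flag is true iff `W` is non-empty and differs from `L` --
#' first-ever use, a newly added ingredient, or a changed composition all
#' qualify; unchanged therapy and pure discontinuation do not.
#'
#' For the 90-day outpatient-clinic variant, outpatient lines count only
#' when prescribed at a neurology or neurosurgery department; in-hospital
#' lines count regardless of department.
#'
#' @inheritParams evaluate_code_window
#' @param window_hi Upper window bound in days (3, 7 or 90).
#' @param departments Optional department filter applied to outpatient
#'   lines.
#' @return A logical vector aligned with the rows of `episodes`.
#' @export
evaluate_new_antithrombotics <- function(episodes, window_hi = 3L,
                                         departments = NULL,
                                         catalog = default_catalog()) {
  lines <- episode_lines(episodes)
  window_lines <- lines %>%
    filter(day_offset >= 0L, day_offset <= window_hi)
  if (!is.null(departments)) {
    window_lines <- window_lines %>%
      filter(setting == "in_hospital" | department %in% departments)
  }
  W <- ingredient_sets(window_lines, catalog)
  L <- lookback_lines(episodes) %>%
    filter(day_offset >= -.new_user_lookback_days, day_offset <= -1L) %>%
    ingredient_sets(catalog)

  tallies <- full_join(
    W %>% count(episode_id, name = "n_W"),
    full_join(
      L %>% count(episode_id, name = "n_L"),
      inner_join(W, L, by = c("episode_id", "ingredient")) %>%
        count(episode_id, name = "n_WL"),
      by = "episode_id"
    ),
    by = "episode_id"
  ) %>%
    mutate(across(c(n_W, n_L, n_WL), ~ dplyr::coalesce(.x, 0L))) %>%
    filter(n_W > 0L, !(n_W == n_L & n_WL == n_W))

  episodes$episode_id %in% tallies$episode_id
}

#' Evaluate the anticoagulants identifier
#'
#' True when any claim line within day 0 to +7 of the index date (any
#' setting) maps to an anticoagulant ingredient. Presence, not novelty:
#' continued pre-index anticoagulation still counts.
#'
#' @inheritParams evaluate_code_window
#' @return A logical vector aligned with the rows of `episodes`.
#' @export
evaluate_anticoagulants <- function(episodes, catalog = default_catalog()) {
  def <- catalog$identifiers$anticoagulants_7d
  hits <- episode_lines(episodes) %>%
    filter(
      day_offset >= def$window[1], day_offset <= def$window[2],
      code_kind == "drug"
    ) %>%
    mutate(ingredient = ingredient_of(code, catalog)) %>%
    filter(ingredient %in% catalog$anticoagulant_ingredients)
  episodes$episode_id %in% unique(hits$episode_id)
}

#' Evaluate the transfer-to-rehabilitation identifier
#'
#' True when the episode's in-hospital lines within day 0 to +30 include
#' claims from both the neurology and the rehabilitation department (any
#' code), marking an in-admission transfer from neurology to
#' rehabilitation.
#'
#' @inheritParams evaluate_code_window
#' @return A logical vector aligned with the rows of `episodes`.
#' @export
evaluate_transfer_to_rehab <- function(episodes,
                                       catalog = default_catalog()) {
  def <- catalog$identifiers$transfer_to_rehab
  ids <- episode_lines(episodes) %>%
    filter(
      setting == "in_hospital",
      day_offset >= def$window[1], day_offset <= def$window[2],
      department %in% c("neurology", "rehabilitation")
    ) %>%
    distinct(episode_id, department) %>%
    count(episode_id) %>%
    filter(n == 2L) %>%
    pull(episode_id)
  episodes$episode_id %in% ids
}

#' Extract the 17 key-identifier flags for every episode
#'
#' Evaluates all 17 identifiers and returns one row per episode with the
#' flags in catalog order. Deterministic and invariant to claim-line order.
#'
#' @param episodes A `stroke_episodes` object (see [build_episodes()]).
#' @param catalog A `stroke_catalog`.
#' @return A tibble with `episode_id`, `principal_dx` and 17 logical flag
#'   columns named as [identifier_names()]; carries `true_ais` through when
#'   present on `episodes` (see [link_registry()]).
#' @export
#' @examples
#' cohort <- generate_validation_cohort(sim_config(n_episodes = 50, seed = 1))
#' episodes <- build_episodes(cohort$claims)
#' flags <- extract_identifiers(episodes)
#' colMeans(flags[identifier_names()])
extract_identifiers <- function(episodes, catalog = default_catalog()) {
  stopifnot(inherits(episodes, "stroke_episodes"))
  lines <- episode_lines(episodes)
  defs <- catalog$identifiers

  simple <- names(defs)[vapply(defs, function(d) d$special == "none",
                               logical(1))]
  flags <- lapply(simple, function(nm) {
    episodes$episode_id %in% match_episode_ids(lines, defs[[nm]])
  })
  names(flags) <- simple

  flags$image_fu <- evaluate_image_followup(episodes, catalog)
  flags$new_antithrombotics_3d <-
    evaluate_new_antithrombotics(episodes, 3L, catalog = catalog)
  flags$new_antithrombotics_7d <-
    evaluate_new_antithrombotics(episodes, 7L, catalog = catalog)
  flags$new_antithrombotics_90d_nrns_opd <- evaluate_new_antithrombotics(
    episodes, 90L,
    departments = defs$new_antithrombotics_90d_nrns_opd$departments,
    catalog = catalog
  )
  flags$anticoagulants_7d <- evaluate_anticoagulants(episodes, catalog)
  flags$transfer_to_rehab <- evaluate_transfer_to_rehab(episodes, catalog)

  out <- tibble(
    episode_id = episodes$episode_id,
    principal_dx = episodes$principal_dx
  )
  if ("true_ais" %in% names(episodes)) {
    out$true_ais <- episodes$true_ais
  }
  bind_cols_ordered <- flags[identifier_names()]
  dplyr::bind_cols(out, as_tibble(bind_cols_ordered))
}
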