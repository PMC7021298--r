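# Synthetic claims + registry cohort generator.
#
# Emulates the statistical structure the identification algorithm assumes:
# an admission-episode cohort with ~32% AIS prevalence, a principal-
# diagnosis mix with cerebral infarction at one third, and label-
# conditional key-identifier probabilities within the published
# sensitivity/specificity envelopes. Intended flags are drawn first
# (conditionally independent given the label, with structural implications
# enforced), then materialised into concrete, window-consistent claim
# lines; the central guarantee is exactness of the round trip
# extract_identifiers(build_episodes(materialise(blueprints))) == blueprints.

.antiplatelets <- c("aspirin", "clopidogrel", "cilostazol", "triflusal",
                    "ticlopidine")

#' Default label-conditional flag probabilities
#'
#' Per-identifier probabilities of each flag given true AIS status. Values
#' are set inside the published envelopes: imaging identifiers with
#' sensitivity 32-91% and specificity 25-79% (MRI more sensitive and more
#' specific than CT), reperfusion and intervention identifiers with
#' sensitivity below 10% and specificity above 98%, new antithrombotics
#' near 70%/70%, and transfer-to-rehab more specific but less sensitive
#' than rehab. Exact per-identifier values are not published; these
#' defaults are envelope-constrained and tunable.
#'
#' @return A tibble with columns `identifier`, `p_ais`, `p_non`.
#' @export
default_flag_model <- function() {
  tibble::tribble(
    ~identifier,                        ~p_ais, ~p_non,
    "af",                                0.20,   0.10,
    "brain_ct",                          0.65,   0.60,
    "brain_mri",                         0.91,   0.25,
    "cta",                               0.32,   0.21,
    "image_fu",                          0.45,   0.30,
    "holter",                            0.35,   0.15,
    "ivt",                               0.07,   0.004,
    "evt",                               0.03,   0.004,
    "cea",                               0.010,  0.003,
    "carotid_angioplasty",               0.020,  0.004,
    "intracranial_angioplasty",          0.015,  0.004,
    "new_antithrombotics_3d",            0.60,   0.25,
    "new_antithrombotics_7d",            0.70,   0.30,
    "new_antithrombotics_90d_nrns_opd",  0.70,   0.28,
    "anticoagulants_7d",                 0.25,   0.10,
    "rehab",                             0.40,   0.25,
    "transfer_to_rehab",                 0.15,   0.05
  )
}

#' Default principal-diagnosis mixture
#'
#' Label-conditional distribution over principal-diagnosis categories,
#' calibrated so that at 31.7% prevalence the marginal mix matches the
#' admission cohort: cerebral infarction (I63) one third, intracranial
#' hemorrhage 6.1%, subarachnoid hemorrhage 5.7%, TIA about 1.5%, the
#' remainder other diagnoses (other nervous-system and circulatory
#' diseases, neoplasms, ...), with I63 strongly enriched among true AIS.
#'
#' @return A tibble with columns `category`, `p_ais`, `p_non`.
#' @export
default_dx_mix <- function() {
  tibble::tribble(
    ~category, ~p_ais, ~p_non,
    "I63",      0.800,  0.116,
    "I60",      0.005,  0.081,
    "I61",      0.005,  0.087,
    "I62",      0.005,  0.012,
    "I64",      0.050,  0.006,
    "TIA",      0.030,  0.008,
    "other",    0.105,  0.690
  )
}

.dx_code_pools <- list(
  I63 = c("I630", "I633", "I634", "I635", "I638", "I639"),
  I60 = c("I600", "I601", "I609"),
  I61 = c("I610", "I611", "I619"),
  I62 = c("I620", "I629"),
  I64 = "I64",
  TIA = c("G450", "G451", "G458", "G459"),
  other = c("C349", "C719", "G200", "G309", "J189", "I200", "I500",
            "M4806", "R420")
)

#' Configure the synthetic cohort generator
#'
#' @param n_episodes Number of admission episodes to generate.
#' @param prevalence True-AIS prevalence; default 0.317.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @param consent_rate Fraction of true AIS episodes enrolled in the
#'   registry (registry subsampling knob, like a consent rate); default 1.
#' @param flag_model Label-conditional flag probabilities; see
#'   [default_flag_model()].
#' @param dx_mix Label-conditional principal-diagnosis mixture; see
#'   [default_dx_mix()].
#' @param age_mean,age_sd,male_fraction Cohort demographics; defaults 65.6,
#'   15.6 and 0.54.
#' @param start_date,end_date Range from which index admission dates are
#'   drawn; default the 2011-2013 study window.
#' @return A validated `sim_config` object.
#' @export
sim_config <- function(n_episodes, prevalence = 0.317, seed = NULL,
                       consent_rate = 1,
                       flag_model = default_flag_model(),
                       dx_mix = default_dx_mix(),
                       age_mean = 65.6, age_sd = 15.6, male_fraction = 0.54,
                       start_date = as.Date("2011-01-01"),
                       end_date = as.Date("2013-12-31")) {
  stopifnot(
    n_episodes >= 0,
    prevalence >= 0, prevalence <= 1,
    consent_rate >= 0, consent_rate <= 1,
    male_fraction >= 0, male_fraction <= 1,
    age_sd >= 0, start_date <= end_date
  )
  flag_model <- as_tibble(flag_model)
  if (!setequal(flag_model$identifier, identifier_names())) {
    abort("flag_model must cover exactly the 17 identifiers")
  }
  if (any(flag_model$p_ais < 0 | flag_model$p_ais > 1 |
            flag_model$p_non < 0 | flag_model$p_non > 1)) {
    abort("flag_model probabilities must lie in [0, 1]")
  }
  dx_mix <- as_tibble(dx_mix)
  if (!setequal(dx_mix$category, names(.dx_code_pools))) {
    abort(paste0("dx_mix categories must be: ",
                 paste(names(.dx_code_pools), collapse = ", ")))
  }
  if (abs(sum(dx_mix$p_ais) - 1) > 1e-8 || abs(sum(dx_mix$p_non) - 1) > 1e-8) {
    abort("dx_mix probabilities must each sum to 1")
  }
  structure(
    list(
      n_episodes = as.integer(n_episodes), prevalence = prevalence,
      seed = seed, consent_rate = consent_rate, flag_model = flag_model,
      dx_mix = dx_mix, age_mean = age_mean, age_sd = age_sd,
      male_fraction = male_fraction, start_date = start_date,
      end_date = end_date
    ),
    class = "sim_config"
  )
}

# draw one flag per episode from label-conditional probabilities
.draw_flag <- function(true_ais, p_ais, p_non) {
  runif(length(true_ais)) < if_else(true_ais, p_ais, p_non)
}

#' Generate episode blueprints and registry records
#'
#' Draws the latent design of each synthetic episode: the true AIS label
#' (Bernoulli at the configured prevalence), a principal diagnosis from the
#' label-conditional mixture, demographics, and the 17 intended identifier
#' flags from their label-conditional probabilities. Structural
#' implications are enforced coherently: CT angiography implies brain CT
#' (drawn conditional on the parent so the marginal is preserved), a 3-day
#' antithrombotic change implies the 7-day one, and brain CT plus brain MRI
#' force the image-follow-up flag (two imaging events are then inevitable).
#' Registry records carry the true AIS episodes, thinned by the consent
#' rate.
#'
#' @param config A [sim_config()].
#' @return A list with `blueprints` (one row per episode: ids, label,
#'   principal diagnosis, demographics, 17 intended flags) and `registry`.
#' @export
generate_blueprints <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_episodes
  fm <- config$flag_model
  p <- function(id, col) fm[[col]][fm$identifier == id]

  true_ais <- runif(n) < config$prevalence

  # principal diagnosis: label-conditional category, then a concrete code
  mix <- config$dx_mix
  category <- character(n)
  for (lab in c(TRUE, FALSE)) {
    idx <- which(true_ais == lab)
    probs <- if (lab) mix$p_ais else mix$p_non
    if (length(idx) > 0) {
      category[idx] <- sample(mix$category, length(idx), replace = TRUE,
                              prob = probs)
    }
  }
  principal_dx <- character(n)
  for (cat in names(.dx_code_pools)) {
    idx <- which(category == cat)
    if (length(idx) > 0) {
      principal_dx[idx] <- sample(.dx_code_pools[[cat]], length(idx),
                                  replace = TRUE)
    }
  }

  flags <- list()
  for (id in identifier_names()) {
    flags[[id]] <- .draw_flag(true_ais, p(id, "p_ais"), p(id, "p_non"))
  }
  # structural coherence: parent-conditional draws preserve the marginals
  p_cta_g_ct <- function(col) min(1, p("cta", col) / p("brain_ct", col))
  flags$cta <- flags$brain_ct &
    (runif(n) < if_else(true_ais, p_cta_g_ct("p_ais"), p_cta_g_ct("p_non")))
  p_n3_g_n7 <- function(col) {
    min(1, p("new_antithrombotics_3d", col) / p("new_antithrombotics_7d", col))
  }
  flags$new_antithrombotics_3d <- flags$new_antithrombotics_7d &
    (runif(n) < if_else(true_ais, p_n3_g_n7("p_ais"), p_n3_g_n7("p_non")))
  # CT and MRI in the same episode are two distinct imaging events
  flags$image_fu <- flags$image_fu | (flags$brain_ct & flags$brain_mri)

  blueprints <- tibble(
    episode_id = sprintf("CS%07d", seq_len(n)),
    patient_id = sprintf("P%07d", seq_len(n)),
    true_ais = true_ais,
    principal_dx = principal_dx,
    index_date = config$start_date +
      sample.int(as.integer(config$end_date - config$start_date) + 1L, n,
                 replace = TRUE) - 1L,
    age = pmin(pmax(round(rnorm(n, config$age_mean, config$age_sd)), 18), 105),
    sex = if_else(runif(n) < config$male_fraction, "male", "female")
  )
  blueprints <- dplyr::bind_cols(blueprints, as_tibble(flags))

  registry <- blueprints %>%
    filter(true_ais, runif(n()) < config$consent_rate) %>%
    select(episode_id, true_ais)
  list(blueprints = blueprints, registry = registry)
}

# sample one product code for each ingredient in `ing`
.sample_product <- function(ing) {
  vapply(ing, function(i) {
    pool <- .antithrombotic_products[[i]]
    pool[sample.int(length(pool), 1L)]
  }, character(1), USE.NAMES = FALSE)
}

# uniform integer draws in [lo, hi], vectorised over n
.rint <- function(n, lo, hi) {
  lo + sample.int(hi - lo + 1L, n, replace = TRUE) - 1L
}

# pick, per row, an antiplatelet ingredient not among the excluded ones
# (at most two exclusions, so three rotated candidates always suffice)
.pick_antiplatelet <- function(n, excl1 = rep(NA_character_, n),
                               excl2 = rep(NA_character_, n)) {
  k <- length(.antiplatelets)
  r <- sample.int(k, n, replace = TRUE)
  cand1 <- .antiplatelets[r]
  cand2 <- .antiplatelets[(r %% k) + 1L]
  cand3 <- .antiplatelets[((r + 1L) %% k) + 1L]
  ok1 <- (is.na(excl1) | cand1 != excl1) & (is.na(excl2) | cand1 != excl2)
  ok2 <- (is.na(excl1) | cand2 != excl1) & (is.na(excl2) | cand2 != excl2)
  if_else(ok1, cand1, if_else(ok2, cand2, cand3))
}

#' Materialise blueprints into claim lines
#'
#' Turns intended identifier flags into a concrete claims table. For every
#' true flag at least one claim line satisfies that identifier's code set,
#' scope, department and window (codes sampled uniformly from the set, day
#' offsets uniformly within the window); for every false flag no emitted
#' line satisfies it. The subtle interactions are honoured: when
#' anticoagulants are present without a new-antithrombotics flag, the same
#' anticoagulant is also placed in the 180-day lookback so novelty fails;
#' new-antithrombotics lines are emitted at non-specialist outpatient
#' settings so the 90-day neurology/neurosurgery outpatient variant stays
#' independently controllable; extra image-follow-up events are placed
#' outside the CT/MRI windows. Non-catalog filler lines use a reserved
#' "ZZ" code namespace.
#'
#' @param blueprints Blueprint tibble from [generate_blueprints()].
#' @param catalog A `stroke_catalog`.
#' @return A claims tibble in the standard column schema.
#' @export
materialize_claims <- function(blueprints, catalog = default_catalog()) {
  bp <- as_tibble(blueprints)
  needed <- c("episode_id", "patient_id", "principal_dx", "index_date",
              identifier_names())
  missing_cols <- setdiff(needed, names(bp))
  if (length(missing_cols) > 0) {
    abort(paste0("blueprints missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  infeasible <- bp %>%
    filter(
      (cta & !brain_ct) |
        (new_antithrombotics_3d & !new_antithrombotics_7d) |
        (brain_ct & brain_mri & !image_fu)
    )
  if (nrow(infeasible) > 0) {
    abort(paste0(
      "infeasible flag combinations (violating structural implications) ",
      "for blueprint(s): ",
      paste(head(infeasible$episode_id, 10), collapse = ", ")
    ))
  }

  rows <- list()
  inhosp <- function(d, code, kind, dx_pos = "none", dept = "other",
                     data = bp) {
    tibble(
      patient_id = data$patient_id, claim_id = data$episode_id,
      setting = "in_hospital", department = dept, code = code,
      code_kind = kind, dx_position = dx_pos,
      service_date = data$index_date + d,
      claim_start_date = data$index_date
    )
  }
  outpat <- function(d, code, kind, tag, dept = "other", data = bp) {
    tibble(
      patient_id = data$patient_id,
      claim_id = paste0(data$episode_id, "-", tag),
      setting = "outpatient", department = dept, code = code,
      code_kind = kind, dx_position = if_else(kind == "diagnosis",
                                              "additional", "none"),
      service_date = data$index_date + d,
      claim_start_date = data$index_date + d
    )
  }
  add <- function(x) rows[[length(rows) + 1L]] <<- x

  n <- nrow(bp)
  # index in-hospital claim: principal diagnosis at day 0, admitted to
  # neurology (supplies the neurology half of transfer-to-rehab)
  add(inhosp(0L, bp$principal_dx, "diagnosis", "principal", "neurology"))
  # cohort entry for non-I60..64 principal diagnoses: stroke as additional
  no_stroke_dx <- bp %>%
    filter(!code_in_set(principal_dx, stroke_dx_codes(), "prefix"))
  if (nrow(no_stroke_dx) > 0) {
    add(inhosp(0L, "I639", "diagnosis", "additional", "neurology",
               data = no_stroke_dx))
  }

  # atrial fibrillation: additional diagnosis within [0, +30]
  d_af <- bp %>% filter(af)
  if (nrow(d_af) > 0) {
    add(inhosp(.rint(nrow(d_af), 0L, 30L),
               sample(c("I480", "I481", "I482", "I489"), nrow(d_af), TRUE),
               "diagnosis", "additional", data = d_af))
  }

  # imaging: one line per positive modality in [-7, +2]; pre-admission
  # offsets are billed as outpatient visits
  imaging_line <- function(data, code, d) {
    pre <- d < 0L
    bind_rows(
      if (any(!pre)) inhosp(d[!pre], code[!pre], "procedure",
                            data = data[!pre, ]),
      if (any(pre)) outpat(d[pre], code[pre], "procedure", "img",
                           data = data[pre, ])
    )
  }
  d_ct <- bp %>% filter(brain_ct)
  if (nrow(d_ct) > 0) {
    ct_code <- if_else(
      d_ct$cta, "HA471",
      sample(setdiff(.brain_ct_codes, "HA471"), nrow(d_ct), TRUE)
    )
    add(imaging_line(d_ct, ct_code, .rint(nrow(d_ct), -7L, 2L)))
  }
  d_mri <- bp %>% filter(brain_mri)
  if (nrow(d_mri) > 0) {
    add(imaging_line(d_mri, sample(.brain_mri_codes, nrow(d_mri), TRUE),
                     .rint(nrow(d_mri), -7L, 2L)))
  }
  # image follow-up: top up to >= 2 distinct imaging events using days
  # +3..+7, outside every other imaging window
  imaging_codes <- unique(c(.brain_ct_codes, .brain_mri_codes))
  n_events <- as.integer(bp$brain_ct) + as.integer(bp$brain_mri)
  d_fu1 <- bp %>% filter(image_fu & n_events == 1L)
  if (nrow(d_fu1) > 0) {
    add(outpat(.rint(nrow(d_fu1), 3L, 7L),
               sample(imaging_codes, nrow(d_fu1), TRUE),
               "procedure", "fua", data = d_fu1))
  }
  d_fu0 <- bp %>% filter(image_fu & n_events == 0L)
  if (nrow(d_fu0) > 0) {
    m <- nrow(d_fu0)
    d1 <- sample.int(5L, m, replace = TRUE) - 1L        # 0..4
    d2 <- (d1 + sample.int(4L, m, replace = TRUE)) %% 5L # != d1
    add(outpat(3L + d1, sample(imaging_codes, m, TRUE), "procedure", "fua",
               data = d_fu0))
    add(outpat(3L + d2, sample(imaging_codes, m, TRUE), "procedure", "fub",
               data = d_fu0))
  }

  # in-hospital procedure/drug identifiers
  simple_inhosp <- list(
    holter = list(codes = "E6545", kind = "procedure", lo = 0L, hi = 30L),
    ivt = list(codes = .antithrombotic_products$alteplase, kind = "drug",
               lo = 0L, hi = 2L),
    evt = list(codes = catalog$identifiers$evt$codes, kind = "procedure",
               lo = 0L, hi = 2L),
    cea = list(codes = catalog$identifiers$cea$codes, kind = "procedure",
               lo = 0L, hi = 30L),
    carotid_angioplasty = list(
      codes = catalog$identifiers$carotid_angioplasty$codes,
      kind = "procedure", lo = 0L, hi = 30L
    ),
    intracranial_angioplasty = list(
      codes = catalog$identifiers$intracranial_angioplasty$codes,
      kind = "procedure", lo = 0L, hi = 30L
    )
  )
  for (id in names(simple_inhosp)) {
    spec_i <- simple_inhosp[[id]]
    d_id <- bp %>% filter(.data[[id]])
    if (nrow(d_id) > 0) {
      add(inhosp(.rint(nrow(d_id), spec_i$lo, spec_i$hi),
                 sample(spec_i$codes, nrow(d_id), TRUE),
                 spec_i$kind, data = d_id))
    }
  }

  # rehabilitation therapy: outpatient so the transfer identifier stays
  # driven solely by its own department-pair line
  d_rehab <- bp %>% filter(rehab)
  if (nrow(d_rehab) > 0) {
    add(outpat(.rint(nrow(d_rehab), 0L, 30L),
               sample(catalog$identifiers$rehab$codes, nrow(d_rehab), TRUE),
               "procedure", "rhb", data = d_rehab))
  }
  # transfer to rehab: an in-hospital rehabilitation-department line
  # (the index claim provides the neurology line at day 0)
  d_tr <- bp %>% filter(transfer_to_rehab)
  if (nrow(d_tr) > 0) {
    add(inhosp(.rint(nrow(d_tr), 7L, 30L), "ZZTRF", "procedure",
               dept = "rehabilitation", data = d_tr))
  }

  # antithrombotic exposure: lookback set L, window additions, and the
  # anticoagulant line, arranged so each of the four drug flags holds
  # exactly as intended
  ac <- bp$anticoagulants_7d
  n3 <- bp$new_antithrombotics_3d
  n7 <- bp$new_antithrombotics_7d
  n90 <- bp$new_antithrombotics_90d_nrns_opd
  forced <- ac & !n7 # continued pre-index anticoagulation: L = {A}, W = {A}

  nL <- sample(0:2, n, replace = TRUE, prob = c(0.5, 0.3, 0.2))
  L1 <- if_else(nL >= 1L, .pick_antiplatelet(n), NA_character_)
  L2 <- if_else(nL == 2L, .pick_antiplatelet(n, excl1 = L1), NA_character_)
  A <- catalog$anticoagulant_ingredients[
    sample.int(length(catalog$anticoagulant_ingredients), n, replace = TRUE)
  ]
  L1 <- if_else(forced, A, L1)
  L2 <- if_else(forced, NA_character_, L2)

  drug_row <- function(data, ing, d, tag, dept = "other") {
    outpat(d, .sample_product(ing), "drug", tag, dept = dept, data = data)
  }
  has_l1 <- !is.na(L1)
  if (any(has_l1)) {
    add(drug_row(bp[has_l1, ], L1[has_l1],
                 .rint(sum(has_l1), -180L, -10L), "lb1"))
  }
  has_l2 <- !is.na(L2)
  if (any(has_l2)) {
    add(drug_row(bp[has_l2, ], L2[has_l2],
                 .rint(sum(has_l2), -180L, -10L), "lb2"))
  }
  # the novel agent X (an antiplatelet outside L) drives the 3/7-day flags
  X <- .pick_antiplatelet(n, excl1 = L1, excl2 = L2)
  if (any(n7)) {
    d_x <- if_else(n3, .rint(n, 0L, 3L), .rint(n, 4L, 7L))
    add(drug_row(bp[n7, ], X[n7], d_x[n7], "atx"))
  }
  if (any(ac)) {
    # unchanged therapy must keep W == L, so the forced case reuses A from
    # the lookback; with a 7-day change present the anticoagulant may be
    # fresh, but must stay out of days 0-3 unless the 3-day flag is set
    d_a <- if_else(n7 & !n3, .rint(n, 4L, 7L), .rint(n, 0L, 7L))
    add(drug_row(bp[ac, ], A[ac], d_a[ac], "acg"))
  }
  # the 90-day flag is carried by a neurology/neurosurgery outpatient
  # prescription beyond day 7; other antithrombotic lines are emitted at
  # non-specialist outpatient settings and so never reach its scope
  if (any(n90)) {
    Y <- .pick_antiplatelet(n, excl1 = L1, excl2 = L2)
    add(drug_row(bp[n90, ], Y[n90], .rint(n, 8L, 90L)[n90], "n90",
                 dept = sample(c("neurology", "neurosurgery"), n,
                               replace = TRUE)[n90]))
  }

  # filler noise from the reserved non-catalog namespace
  add(outpat(.rint(n, 0L, 60L), sprintf("ZZ%03d", .rint(n, 0L, 999L)),
             "procedure", "flr"))

  bind_rows(rows) %>%
    select(patient_id, claim_id, setting, department, code, code_kind,
           dx_position, service_date, claim_start_date) %>%
    arrange(patient_id, service_date, claim_id, code)
}

#' Generate a complete synthetic validation cohort
#'
#' One-call fixture: draws blueprints, materialises them into claim lines,
#' and returns the claims table, the registry table and a truth-audit table
#' (the blueprints, including the intended flags) for test assertions.
#' Identical seeds give identical tables.
#'
#' @param config A [sim_config()].
#' @return A list with `claims`, `registry` and `truth`.
#' @export
#' @examples
#' cohort <- generate_validation_cohort(sim_config(n_episodes = 20, seed = 42))
#' nrow(cohort$truth)
generate_validation_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  bp <- generate_blueprints(config)
  claims <- materialize_claims(bp$blueprints)
  list(claims = claims, registry = bp$registry, truth = bp$blueprints)
}

#' Generate a cohort with designed classifier performance
#'
#' Builds a cohort whose per-leaf call behaviour is designed: each episode
#' is assigned a target call (AIS with probability `sensitivity` among true
#' AIS, `1 - specificity` among non-AIS) and receives a witness flag
#' pattern that routes the default ruleset to an AIS or non-AIS leaf
#' accordingly, rotating across branches so several trajectories are
#' exercised. Running the full pipeline on such a cohort must recover the
#' designed sensitivity and specificity up to binomial noise.
#'
#' @param n Number of episodes.
#' @param sensitivity,specificity Designed call probabilities; defaults
#'   0.80 and 0.82.
#' @param prevalence True-AIS prevalence; default 0.317.
#' @param seed Integer seed.
#' @return A list with `claims`, `registry` and `truth` (including the
#'   designed `target_call`).
#' @export
design_performance_cohort <- function(n, sensitivity = 0.80,
                                      specificity = 0.82,
                                      prevalence = 0.317, seed = 1L) {
  set.seed(seed)
  true_ais <- runif(n) < prevalence
  target_call <- if_else(true_ais, runif(n) < sensitivity,
                         runif(n) < (1 - specificity))
  variant <- sample.int(4L, n, replace = TRUE)

  f <- matrix(FALSE, nrow = n, ncol = length(identifier_names()),
              dimnames = list(NULL, identifier_names()))
  principal_dx <- rep("I639", n)
  set_f <- function(idx, flags) {
    for (fl in flags) f[idx, fl] <<- TRUE
  }
  # positive witnesses: reperfusion (CT stratum), 3-day change + MRI (no-CT
  # stratum), image follow-up cascade, and reperfusion without I63
  idx <- which(target_call & variant == 1L)
  set_f(idx, c("brain_ct", "ivt"))
  idx <- which(target_call & variant == 2L)
  set_f(idx, c("brain_mri", "new_antithrombotics_3d", "new_antithrombotics_7d"))
  idx <- which(target_call & variant == 3L)
  set_f(idx, c("brain_ct", "brain_mri", "image_fu", "new_antithrombotics_7d"))
  idx <- which(target_call & variant == 4L)
  set_f(idx, "ivt")
  principal_dx[target_call & variant == 4L] <- "C349"
  # negative witnesses: fall-through leaves of each branch
  idx <- which(!target_call & variant == 2L)
  set_f(idx, "brain_mri") # no-CT stratum, empty image-follow-up cascade
  principal_dx[!target_call & variant == 3L] <- "J189"
  idx <- which(!target_call & variant == 4L)
  set_f(idx, "brain_ct") # CT stratum without MRI

  blueprints <- tibble(
    episode_id = sprintf("DP%07d", seq_len(n)),
    patient_id = sprintf("Q%07d", seq_len(n)),
    true_ais = true_ais,
    target_call = target_call,
    principal_dx = principal_dx,
    index_date = as.Date("2011-01-01") + .rint(n, 0L, 1095L)
  )
  blueprints <- dplyr::bind_cols(blueprints, as_tibble(as.data.frame(f)))
  claims <- materialize_claims(blueprints)
  registry <- blueprints %>% filter(true_ais) %>% select(episode_id, true_ais)
  list(claims = claims, registry = registry, truth = blueprints)
}
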