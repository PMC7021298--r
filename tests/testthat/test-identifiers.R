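test_that("plain windowed identifiers respect codes, windows and scope", {
  # CT angiography code inside the CT window sets both CT flags
  eps <- one_episode(claim_row("HA471", -3L, setting = "outpatient"))
  expect_true(evaluate_code_window(eps, "brain_ct"))
  expect_true(evaluate_code_window(eps, "cta"))
  expect_false(evaluate_code_window(eps, "brain_mri"))

  # closed window endpoints: +2 in, +3 out for brain CT
  expect_true(evaluate_code_window(one_episode(claim_row("HA451", 2L)),
                                   "brain_ct"))
  expect_false(evaluate_code_window(one_episode(claim_row("HA451", 3L)),
                                    "brain_ct"))
  expect_true(evaluate_code_window(one_episode(claim_row("HA451", -7L,
                                                         setting = "outpatient")),
                                   "brain_ct"))
  expect_false(evaluate_code_window(one_episode(claim_row("HA451", -8L,
                                                          setting = "outpatient")),
                                    "brain_ct"))

  # Holter at +30 in, +31 out
  expect_true(evaluate_code_window(one_episode(claim_row("E6545", 30L)),
                                   "holter"))
  expect_false(evaluate_code_window(one_episode(claim_row("E6545", 31L)),
                                    "holter"))
  # in-hospital-only scope: an outpatient Holter does not count
  expect_false(evaluate_code_window(
    one_episode(claim_row("E6545", 5L, setting = "outpatient")), "holter"
  ))

  # no matching lines -> false
  expect_false(evaluate_code_window(one_episode(), "ivt"))
  # special-logic identifiers are rejected here
  expect_error(evaluate_code_window(one_episode(), "image_fu"), "special")
  expect_error(evaluate_code_window(one_episode(), "nope"), "unknown")
})

test_that("image follow-up counts distinct (code, date) imaging events", {
  # CT at day -1 plus MRI at day +3: two events
  expect_true(evaluate_image_followup(one_episode(
    claim_row("HA451", -1L, setting = "outpatient"),
    claim_row("HE101", 3L)
  )))
  # a single MRI is not a follow-up
  expect_false(evaluate_image_followup(one_episode(claim_row("HE101", 1L))))
  # same code on two dates counts as two events
  expect_true(evaluate_image_followup(one_episode(
    claim_row("HA451", 0L), claim_row("HA451", 2L)
  )))
  # two modalities on one date count as two events
  expect_true(evaluate_image_followup(one_episode(
    claim_row("HA451", 1L), claim_row("HE101", 1L)
  )))
  # duplicate billing of one (code, date) is one event
  expect_false(evaluate_image_followup(one_episode(
    claim_row("HA451", 1L), claim_row("HA451", 1L)
  )))
  # events must fall inside -7..+7
  expect_false(evaluate_image_followup(one_episode(
    claim_row("HA451", 8L), claim_row("HE101", 9L)
  )))
})

test_that("new-antithrombotics implements the new-user definition", {
  aspirin <- "110701ATB"
  clopidogrel <- "136901ATB"
  warfarin <- "249103ATB"
  rivaroxaban <- "511401ATB"

  # first-ever use
  eps <- one_episode(claim_row(aspirin, 1L, "drug"))
  expect_true(evaluate_new_antithrombotics(eps, 3L))
  expect_true(evaluate_new_antithrombotics(eps, 7L))

  # unchanged therapy: same ingredient in lookback and window
  eps <- one_episode(
    claim_row(aspirin, -60L, "drug", setting = "outpatient"),
    claim_row(aspirin, 1L, "drug")
  )
  expect_false(evaluate_new_antithrombotics(eps, 3L))

  # added ingredient
  eps <- one_episode(
    claim_row(aspirin, -60L, "drug", setting = "outpatient"),
    claim_row(aspirin, 1L, "drug"),
    claim_row(clopidogrel, 2L, "drug")
  )
  expect_true(evaluate_new_antithrombotics(eps, 3L))

  # changed composition (switch)
  eps <- one_episode(
    claim_row(warfarin, -30L, "drug", setting = "outpatient"),
    claim_row(rivaroxaban, 1L, "drug")
  )
  expect_true(evaluate_new_antithrombotics(eps, 3L))

  # pure discontinuation is false
  eps <- one_episode(claim_row(aspirin, -30L, "drug", setting = "outpatient"))
  expect_false(evaluate_new_antithrombotics(eps, 3L))

  # the 6-month lookback horizon: use 181 days ago does not mask novelty
  eps <- one_episode(
    claim_row(aspirin, -181L, "drug", setting = "outpatient"),
    claim_row(aspirin, 1L, "drug")
  )
  expect_true(evaluate_new_antithrombotics(eps, 3L))
  eps <- one_episode(
    claim_row(aspirin, -180L, "drug", setting = "outpatient"),
    claim_row(aspirin, 1L, "drug")
  )
  expect_false(evaluate_new_antithrombotics(eps, 3L))

  # window boundaries: day 4 counts for the 7-day flag only
  eps <- one_episode(claim_row(aspirin, 4L, "drug"))
  expect_false(evaluate_new_antithrombotics(eps, 3L))
  expect_true(evaluate_new_antithrombotics(eps, 7L))
})

test_that("90-day variant restricts outpatient lines to NR/NS departments", {
  aspirin <- "110701ATB"
  depts <- c("neurology", "neurosurgery")
  # outpatient prescription at a non-specialist clinic does not count
  eps <- one_episode(claim_row(aspirin, 10L, "drug", setting = "outpatient",
                               dept = "other"))
  expect_false(evaluate_new_antithrombotics(eps, 90L, departments = depts))
  # neurology outpatient clinic counts
  eps <- one_episode(claim_row(aspirin, 10L, "drug", setting = "outpatient",
                               dept = "neurology"))
  expect_true(evaluate_new_antithrombotics(eps, 90L, departments = depts))
  # in-hospital lines count without department restriction
  eps <- one_episode(claim_row(aspirin, 10L, "drug", dept = "other"))
  expect_true(evaluate_new_antithrombotics(eps, 90L, departments = depts))
  # beyond day 90 is out of window
  eps <- one_episode(claim_row(aspirin, 91L, "drug", setting = "outpatient",
                               dept = "neurology"))
  expect_false(evaluate_new_antithrombotics(eps, 90L, departments = depts))
})

test_that("anticoagulants flag presence, not novelty, within 0..+7", {
  expect_true(evaluate_anticoagulants(one_episode(
    claim_row("168601BIJ", 0L, "drug")
  )))
  # continued pre-index warfarin still counts
  expect_true(evaluate_anticoagulants(one_episode(
    claim_row("249103ATB", -60L, "drug", setting = "outpatient"),
    claim_row("249103ATB", 3L, "drug")
  )))
  # an antiplatelet is not an anticoagulant
  expect_false(evaluate_anticoagulants(one_episode(
    claim_row("110701ATB", 0L, "drug")
  )))
  # day +8 is out of window
  expect_false(evaluate_anticoagulants(one_episode(
    claim_row("249103ATB", 8L, "drug")
  )))
})

test_that("transfer-to-rehab needs both departments in-hospital in 0..+30", {
  expect_true(evaluate_transfer_to_rehab(one_episode(
    claim_row("ZZPHY", 12L, dept = "rehabilitation")
  ))) # index claim supplies the neurology line at day 0
  expect_false(evaluate_transfer_to_rehab(one_episode(
    claim_row("ZZNEU", 5L, dept = "neurology")
  )))
  expect_false(evaluate_transfer_to_rehab(one_episode(
    claim_row("ZZPHY", 31L, dept = "rehabilitation")
  )))
  # outpatient rehabilitation-department visits do not count
  expect_false(evaluate_transfer_to_rehab(one_episode(
    claim_row("ZZPHY", 12L, setting = "outpatient", dept = "rehabilitation")
  )))
})

test_that("extract_identifiers assembles the full 17-flag vector", {
  # an episode with nothing but its index diagnosis: all flags false
  flags <- extract_identifiers(one_episode())
  expect_identical(names(flags),
                   c("episode_id", "principal_dx", identifier_names()))
  expect_false(any(as.logical(flags[identifier_names()])))

  # a lone CTA claim at day 0: brain_ct and cta only
  flags <- extract_identifiers(one_episode(claim_row("HA471", 0L)))
  on <- identifier_names()[as.logical(flags[identifier_names()])]
  expect_setequal(on, c("brain_ct", "cta"))
})

test_that("structural flag implications hold on generated cohorts", {
  cohort <- generate_validation_cohort(sim_config(n_episodes = 400, seed = 21))
  flags <- extract_identifiers(build_episodes(cohort$claims))
  expect_true(all(flags$new_antithrombotics_7d[flags$new_antithrombotics_3d]))
  expect_true(all(flags$brain_ct[flags$cta]))
  expect_true(all(flags$image_fu[flags$brain_ct & flags$brain_mri]))
})
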