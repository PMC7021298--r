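test_that("default ruleset conformance snapshot", {
  rs <- default_ruleset()
  expect_s3_class(rs, "stroke_ruleset")
  expect_identical(rs$version, "CRCS-K-2020")
  # root stratifies on principal diagnosis I63
  expect_identical(rs$nodes[[rs$root]]$test,
                   list(type = "dx_prefix", prefix = "I63"))

  # frozen topology: 50 trajectories (18 in the I63+CT stratum, 17 in
  # I63 without CT, 15 in non-I63), 38 of them AIS leaves
  tr <- enumerate_trajectories(rs)
  expect_equal(nrow(tr), 50L)
  expect_equal(sum(tr$label == "AIS"), 38L)
  prefix <- substr(tr$trajectory_id, 1, 1)
  expect_equal(as.vector(table(prefix)[c("A", "B", "C")]), c(18L, 17L, 15L))
  expect_false(anyDuplicated(tr$trajectory_id) > 0)

  # the hemorrhagic-transformation AIS leaves sit under AF without
  # anticoagulation in each stratum
  hem <- tr[grepl("hemorrhagic", tr$trajectory_id), ]
  expect_equal(nrow(hem), 3L)
  expect_true(all(hem$label == "AIS"))

  # the shipped JSON encodes the same tree
  shipped <- load_ruleset(system.file("extdata", "ruleset-crcsk2020.json",
                                      package = "claimstroke"))
  expect_identical(enumerate_trajectories(shipped), tr)
})

test_that("published example episodes classify as narrated", {
  # I63 principal with CT and IVT: AIS by reperfusion
  res <- classify_episode(flags_row("brain_ct", "ivt"), "I639")
  expect_identical(as.character(res$label), "AIS")
  expect_identical(res$trajectory_id, "A_ivt_ais")

  # non-I63 (ICH code) with EVT: still AIS by reperfusion
  res <- classify_episode(flags_row("evt"), "I619")
  expect_identical(as.character(res$label), "AIS")
  expect_identical(res$trajectory_id, "C_reperfusion_ais")

  # all-false vectors fall through to non-AIS in every stratum
  for (dx in c("I639", "I609", "C349")) {
    expect_identical(
      as.character(classify_episode(flags_row(), dx)$label), "non_AIS"
    )
  }

  # interventions only count combined with a 3-day antithrombotic change
  expect_identical(
    as.character(classify_episode(flags_row("brain_ct", "cea"), "I639")$label),
    "non_AIS"
  )
  res <- classify_episode(
    flags_row("brain_ct", "cea", "new_antithrombotics_3d",
              "new_antithrombotics_7d"), "I639"
  )
  expect_identical(res$trajectory_id, "A_intervention_ais")

  # AF without anticoagulants or late antithrombotics, after positive
  # image follow-up: hemorrhagic transformation, called AIS
  res <- classify_episode(
    flags_row("brain_ct", "brain_mri", "image_fu", "af"), "I639"
  )
  expect_identical(res$trajectory_id, "A_hemorrhagic_transformation")
  expect_identical(as.character(res$label), "AIS")

  # same pattern without image follow-up is non-AIS
  res <- classify_episode(flags_row("brain_mri", "af"), "I639")
  expect_identical(as.character(res$label), "non_AIS")

  # transfer-to-rehab rescues non-I63 cases with a 3-day change
  res <- classify_episode(
    flags_row("new_antithrombotics_3d", "new_antithrombotics_7d",
              "transfer_to_rehab"), "G459"
  )
  expect_identical(res$trajectory_id, "C_n3_transfer_ais")
})

test_that("flags off the taken path never change the result", {
  rs <- default_ruleset()
  tr <- enumerate_trajectories(rs)
  set.seed(31)
  for (i in 1:60) {
    vals <- stats::runif(17) < 0.4
    flags <- flags_row()
    flags[identifier_names()] <- as.list(vals)
    dx <- sample(c("I639", "I609", "C349"), 1)
    base <- classify_episode(flags, dx, rs)
    sig <- tr$signature[tr$trajectory_id == base$trajectory_id]
    for (f in identifier_names()) {
      if (!grepl(f, sig, fixed = TRUE)) {
        flipped <- flags
        flipped[[f]] <- !flipped[[f]]
        expect_identical(classify_episode(flipped, dx, rs), base)
      }
    }
  }
})

test_that("ruleset validation rejects malformed trees", {
  bad_flag <- list(
    version = "x", root = "r",
    nodes = list(r = list(
      test = list(type = "flag", flag = "mri2"),
      if_true = list(leaf = list(label = "AIS", trajectory_id = "t1")),
      if_false = list(leaf = list(label = "non_AIS", trajectory_id = "t2"))
    ))
  )
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(bad_flag, path, auto_unbox = TRUE)
  expect_error(load_ruleset(path), "unknown flag.*mri2")

  cyclic <- bad_flag
  cyclic$nodes$r$test$flag <- "ivt"
  cyclic$nodes$r$if_true <- list(node = "s")
  cyclic$nodes$s <- list(
    test = list(type = "flag", flag = "evt"),
    if_true = list(node = "r"),
    if_false = list(leaf = list(label = "non_AIS", trajectory_id = "t3"))
  )
  jsonlite::write_json(cyclic, path, auto_unbox = TRUE)
  expect_error(load_ruleset(path), "cycle")

  dangling <- bad_flag
  dangling$nodes$r$test$flag <- "ivt"
  dangling$nodes$r$if_true <- list(node = "missing_node")
  jsonlite::write_json(dangling, path, auto_unbox = TRUE)
  expect_error(load_ruleset(path), "missing node")

  unreachable <- bad_flag
  unreachable$nodes$r$test$flag <- "ivt"
  unreachable$nodes$orphan <- list(
    test = list(type = "flag", flag = "evt"),
    if_true = list(leaf = list(label = "AIS", trajectory_id = "t4")),
    if_false = list(leaf = list(label = "non_AIS", trajectory_id = "t5"))
  )
  jsonlite::write_json(unreachable, path, auto_unbox = TRUE)
  expect_error(load_ruleset(path), "unreachable")
})

test_that("classify_episodes records a conserved audit flow", {
  cohort <- generate_validation_cohort(sim_config(n_episodes = 250, seed = 13))
  calls <- cohort$claims |>
    build_episodes() |>
    link_registry(cohort$registry) |>
    extract_identifiers() |>
    classify_episodes()
  expect_equal(nrow(calls), 250L)
  expect_false(any(is.na(calls$label)))

  flow <- flow_counts(calls)
  expect_true(all(flow$n_in == flow$n_true + flow$n_false))
  expect_equal(flow$n_in[flow$node_id == "root"], 250L)
  # labels attached: per-node true-AIS fractions are available
  expect_true(all(!is.na(flow$pct_true_ais_in[flow$n_in > 0])))

  # every trajectory id seen is a real leaf of the tree
  tr <- enumerate_trajectories(default_ruleset())
  expect_true(all(calls$trajectory_id %in% tr$trajectory_id))
})

test_that("every trajectory is reachable and has a claims-level witness", {
  rs <- default_ruleset()
  tr <- enumerate_trajectories(rs)

  # exhaustively enumerate the flags actually tested by the tree (the
  # others cannot steer it) under both diagnosis strata
  tested <- c(
    "brain_ct", "brain_mri", "cta", "image_fu", "holter", "af", "ivt",
    "evt", "cea", "new_antithrombotics_3d", "new_antithrombotics_7d",
    "new_antithrombotics_90d_nrns_opd", "anticoagulants_7d",
    "transfer_to_rehab"
  )
  grid <- do.call(
    tidyr::expand_grid,
    stats::setNames(rep(list(c(FALSE, TRUE)), length(tested)), tested)
  )
  grid$carotid_angioplasty <- FALSE
  grid$intracranial_angioplasty <- FALSE
  grid$rehab <- FALSE
  all_flags <- dplyr::bind_rows(
    grid %>% dplyr::mutate(principal_dx = "I639"),
    grid %>% dplyr::mutate(principal_dx = "C349")
  )
  all_flags$episode_id <- sprintf("W%06d", seq_len(nrow(all_flags)))
  calls <- classify_episodes(all_flags, rs)
  expect_setequal(unique(calls$trajectory_id), tr$trajectory_id)

  # pick, per trajectory, one witness satisfying the structural
  # implications the generator enforces, and materialise it into claims
  feasible <- dplyr::bind_cols(all_flags, label = calls$label,
                               trajectory_id = calls$trajectory_id) %>%
    dplyr::filter(
      !(cta & !brain_ct),
      !(new_antithrombotics_3d & !new_antithrombotics_7d),
      !(brain_ct & brain_mri & !image_fu)
    )
  witnesses <- feasible %>%
    dplyr::group_by(trajectory_id) %>%
    dplyr::slice(1) %>%
    dplyr::ungroup()
  # 45 of the 50 trajectories are claims-realizable; the 5 paths of the
  # I63+CT stratum's no-image-follow-up arm are dead under the shipped
  # catalog, because a CT event plus an MRI event (both needed to enter
  # that stratum's cascade) already constitute an image follow-up
  unrealizable <- setdiff(tr$trajectory_id, witnesses$trajectory_id)
  expect_setequal(
    unrealizable,
    c("A_fu0_ac_ais", "A_fu0_af_n90_ais", "A_fu0_af_non_ais",
      "A_fu0_n90_ais", "A_fu0_non_ais")
  )
  expect_equal(nrow(witnesses), 45L)

  blueprints <- witnesses %>%
    dplyr::mutate(
      patient_id = paste0("PW", dplyr::row_number()),
      index_date = as.Date("2012-03-01")
    )
  claims <- materialize_claims(blueprints)
  got <- claims |>
    build_episodes() |>
    extract_identifiers() |>
    classify_episodes(rs)
  cmp <- dplyr::inner_join(
    witnesses %>% dplyr::select(episode_id, want = trajectory_id),
    tibble::as_tibble(got) %>% dplyr::select(episode_id, got = trajectory_id),
    by = "episode_id"
  )
  expect_equal(nrow(cmp), 45L)
  expect_identical(cmp$got, cmp$want)
})
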