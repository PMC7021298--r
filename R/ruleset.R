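# Diagnosis-stratified decision tree over the 17 key identifiers.
#
# The tree first splits on whether the principal diagnosis is cerebral
# infarction (prefix I63), then -- among I63 admissions -- on brain-CT
# status, and cascades through reperfusion therapy (IVT, EVT),
# interventions combined with new antithrombotics, MRI/CTA combined with
# new antithrombotics, and an image-follow-up cascade (Holter, atrial
# fibrillation, anticoagulants, 90-day outpatient antithrombotic change,
# and a hemorrhagic-transformation leaf). Non-I63 admissions skip the
# intervention steps (clinically irrelevant there) and instead use new
# antithrombotics combined with transfer-to-rehabilitation.
#
# The engine is config-driven: trees are flat node tables, serialisable to
# JSON, so the topology can be amended without code changes.

ruleset_version <- "CRCS-K-2020"

leaf <- function(label, trajectory_id) {
  list(leaf = list(label = label, trajectory_id = trajectory_id))
}
node_ref <- function(node_id) {
  list(node = node_id)
}

test_flag <- function(flag) list(type = "flag", flag = flag)
test_dx_prefix <- function(prefix) list(type = "dx_prefix", prefix = prefix)
test_combo <- function(all_of = character(0), any_of = character(0)) {
  list(type = "combo", all_of = all_of, any_of = any_of)
}

new_stroke_ruleset <- function(nodes, root, version = ruleset_version) {
  structure(
    list(nodes = nodes, root = root, version = version),
    class = "stroke_ruleset"
  )
}

# image-follow-up cascade entered at the brain-MRI test; `p` prefixes node
# and trajectory ids so the subtree can be reused across branches
mri_cascade <- function(p) {
  nd <- function(test, if_true, if_false) {
    list(test = test, if_true = if_true, if_false = if_false)
  }
  ais <- function(id) leaf("AIS", paste0(p, "_", id))
  non <- function(id) leaf("non_AIS", paste0(p, "_", id))
  ref <- function(id) node_ref(paste0(p, "_", id))

  nodes <- list(
    nd(test_flag("brain_mri"), ref("fu"), non("no_mri_non_ais")),
    nd(test_flag("image_fu"), ref("fu1_n7"), ref("fu0_af")),
    # image follow-up present: TIA-like re-imaging pathway
    nd(test_flag("new_antithrombotics_7d"), ais("fu1_n7_ais"), ref("fu1_holter")),
    nd(test_flag("holter"), ais("fu1_holter_ais"), ref("fu1_af")),
    nd(test_flag("af"), ref("fu1_af1_ac"), ref("fu1_af0_n90")),
    nd(test_flag("anticoagulants_7d"), ais("fu1_ac_ais"), ref("fu1_af1_n90")),
    # AF without anticoagulation or antithrombotic change: hemorrhagic
    # transformation assumed, still an AIS call
    nd(test_flag("new_antithrombotics_90d_nrns_opd"),
       ais("fu1_af_n90_ais"), ais("hemorrhagic_transformation")),
    nd(test_flag("new_antithrombotics_90d_nrns_opd"),
       ais("fu1_n90_ais"), non("fu1_non_ais")),
    # no image follow-up
    nd(test_flag("af"), ref("fu0_af1_ac"), ref("fu0_af0_n90")),
    nd(test_flag("anticoagulants_7d"), ais("fu0_ac_ais"), ref("fu0_af1_n90")),
    nd(test_flag("new_antithrombotics_90d_nrns_opd"),
       ais("fu0_af_n90_ais"), non("fu0_af_non_ais")),
    nd(test_flag("new_antithrombotics_90d_nrns_opd"),
       ais("fu0_n90_ais"), non("fu0_non_ais"))
  )
  names(nodes) <- paste0(p, "_", c(
    "mri", "fu", "fu1_n7", "fu1_holter", "fu1_af", "fu1_af1_ac",
    "fu1_af1_n90", "fu1_af0_n90", "fu0_af", "fu0_af1_ac", "fu0_af1_n90",
    "fu0_af0_n90"
  ))
  nodes
}

#' Default stroke identification ruleset ("CRCS-K-2020")
#'
#' Builds the shipped decision tree. The root splits on principal diagnosis
#' prefix I63; I63 admissions are further stratified by brain-CT status.
#' Each stratum cascades, in clinical-flow order: IVT, then EVT (reperfusion
#' first, as the most specific evidence of hyperacute stroke); carotid
#' endarterectomy or carotid/intracranial angioplasty combined with a 3-day
#' antithrombotic change (interventions alone can be elective, so they only
#' count alongside new antithrombotics); a 3-day antithrombotic change
#' combined with brain MRI, then with CT angiography (CT stratum only);
#' and finally an MRI-gated image-follow-up cascade through 7-day
#' antithrombotic change, Holter monitoring, atrial fibrillation,
#' anticoagulants and 90-day outpatient antithrombotic change, with a
#' hemorrhagic-transformation AIS leaf where AF is present but no
#' antithrombotic is given. Non-I63 admissions use reperfusion, then a
#' 3-day antithrombotic change combined with transfer to rehabilitation,
#' then the same MRI cascade.
#'
#' @return A `stroke_ruleset`.
#' @export
#' @examples
#' rs <- default_ruleset()
#' nrow(enumerate_trajectories(rs))
default_ruleset <- function() {
  nd <- function(test, if_true, if_false) {
    list(test = test, if_true = if_true, if_false = if_false)
  }
  interventions <- c("cea", "carotid_angioplasty", "intracranial_angioplasty")

  nodes <- c(
    list(
      root = nd(test_dx_prefix("I63"), node_ref("root_ct"), node_ref("C_reperfusion")),
      root_ct = nd(test_flag("brain_ct"), node_ref("A_ivt"), node_ref("B_ivt")),

      # I63 principal diagnosis, brain CT performed
      A_ivt = nd(test_flag("ivt"), leaf("AIS", "A_ivt_ais"), node_ref("A_evt")),
      A_evt = nd(test_flag("evt"), leaf("AIS", "A_evt_ais"), node_ref("A_intv")),
      A_intv = nd(
        test_combo(all_of = "new_antithrombotics_3d", any_of = interventions),
        leaf("AIS", "A_intervention_ais"), node_ref("A_n3_mri")
      ),
      A_n3_mri = nd(
        test_combo(all_of = c("new_antithrombotics_3d", "brain_mri")),
        leaf("AIS", "A_n3_mri_ais"), node_ref("A_n3_cta")
      ),
      A_n3_cta = nd(
        test_combo(all_of = c("new_antithrombotics_3d", "cta")),
        leaf("AIS", "A_n3_cta_ais"), node_ref("A_mri")
      ),

      # I63 principal diagnosis, no brain CT (no CTA step possible: the
      # CTA code set is a subset of the brain-CT set)
      B_ivt = nd(test_flag("ivt"), leaf("AIS", "B_ivt_ais"), node_ref("B_evt")),
      B_evt = nd(test_flag("evt"), leaf("AIS", "B_evt_ais"), node_ref("B_intv")),
      B_intv = nd(
        test_combo(all_of = "new_antithrombotics_3d", any_of = interventions),
        leaf("AIS", "B_intervention_ais"), node_ref("B_n3_mri")
      ),
      B_n3_mri = nd(
        test_combo(all_of = c("new_antithrombotics_3d", "brain_mri")),
        leaf("AIS", "B_n3_mri_ais"), node_ref("B_mri")
      ),

      # principal diagnosis other than I63: interventions are clinically
      # irrelevant; transfer-to-rehab sharpens the antithrombotic signal
      C_reperfusion = nd(
        test_combo(any_of = c("ivt", "evt")),
        leaf("AIS", "C_reperfusion_ais"), node_ref("C_n3_rehab")
      ),
      C_n3_rehab = nd(
        test_combo(all_of = c("new_antithrombotics_3d", "transfer_to_rehab")),
        leaf("AIS", "C_n3_transfer_ais"), node_ref("C_mri")
      )
    ),
    mri_cascade("A"),
    mri_cascade("B"),
    mri_cascade("C")
  )
  rs <- new_stroke_ruleset(nodes, root = "root")
  validate_ruleset(rs)
  rs
}

#' Validate a ruleset
#'
#' Checks that the tree is single-rooted, acyclic, total and well-formed:
#' every referenced node exists, every test references known identifier
#' flags, every node is reachable from the root, every path ends in a leaf
#' labelled `AIS`/`non_AIS`, and trajectory ids are unique. Violations are
#' reported with the offending node id.
#'
#' @param ruleset A `stroke_ruleset`.
#' @return `ruleset`, invisibly, if valid; otherwise an error.
#' @export
validate_ruleset <- function(ruleset) {
  stopifnot(inherits(ruleset, "stroke_ruleset"))
  nodes <- ruleset$nodes
  known_flags <- identifier_names()
  problems <- character(0)

  if (!ruleset$root %in% names(nodes)) {
    abort(paste0("root node '", ruleset$root, "' not found"))
  }
  check_ref <- function(ref, nid) {
    if (!is.null(ref$node)) {
      if (!ref$node %in% names(nodes)) {
        problems <<- c(problems, paste0(
          "node '", nid, "' references missing node '", ref$node, "'"))
      }
    } else if (!is.null(ref$leaf)) {
      if (!ref$leaf$label %in% c("AIS", "non_AIS")) {
        problems <<- c(problems, paste0(
          "node '", nid, "' has leaf with invalid label '",
          ref$leaf$label, "'"))
      }
    } else {
      problems <<- c(problems, paste0("node '", nid, "' has malformed branch"))
    }
  }
  for (nid in names(nodes)) {
    node <- nodes[[nid]]
    t <- node$test
    flags_used <- switch(
      t$type,
      flag = t$flag,
      dx_prefix = character(0),
      combo = c(t$all_of, t$any_of),
      {
        problems <- c(problems, paste0(
          "node '", nid, "' has unknown test type '", t$type, "'"))
        character(0)
      }
    )
    bad <- setdiff(flags_used, known_flags)
    if (length(bad) > 0) {
      problems <- c(problems, paste0(
        "node '", nid, "' references unknown flag(s): ",
        paste(bad, collapse = ", ")))
    }
    if (t$type == "combo" && length(c(t$all_of, t$any_of)) == 0) {
      problems <- c(problems, paste0("node '", nid, "' has empty combo test"))
    }
    check_ref(node$if_true, nid)
    check_ref(node$if_false, nid)
  }
  if (length(problems) > 0) {
    abort(paste0("invalid ruleset:\n", paste("-", problems, collapse = "\n")))
  }

  # cycle and reachability check by DFS from the root
  visited <- character(0)
  dfs <- function(nid, stack) {
    if (nid %in% stack) {
      abort(paste0("invalid ruleset: cycle involving node '", nid, "'"))
    }
    if (nid %in% visited) {
      return(invisible())
    }
    visited <<- c(visited, nid)
    node <- nodes[[nid]]
    for (ref in list(node$if_true, node$if_false)) {
      if (!is.null(ref$node)) dfs(ref$node, c(stack, nid))
    }
  }
  dfs(ruleset$root, character(0))
  unreachable <- setdiff(names(nodes), visited)
  if (length(unreachable) > 0) {
    abort(paste0("invalid ruleset: unreachable node(s): ",
                 paste(unreachable, collapse = ", ")))
  }
  traj <- enumerate_trajectories(ruleset)$trajectory_id
  if (anyDuplicated(traj)) {
    abort(paste0("invalid ruleset: duplicate trajectory_id(s): ",
                 paste(unique(traj[duplicated(traj)]), collapse = ", ")))
  }
  invisible(ruleset)
}

#' @export
print.stroke_ruleset <- function(x, ...) {
  paths <- enumerate_trajectories(x)
  cat("<stroke_ruleset> version", x$version, "\n")
  cat(" ", length(x$nodes), "decision nodes,", nrow(paths), "trajectories (",
      sum(paths$label == "AIS"), "AIS /", sum(paths$label == "non_AIS"),
      "non-AIS )\n")
  invisible(x)
}

eval_test <- function(test, flags, dx) {
  switch(
    test$type,
    flag = flags[[test$flag]],
    dx_prefix = !is.na(dx) & stringr::str_starts(dx, test$prefix),
    combo = {
      res <- rep(TRUE, length(dx))
      for (f in test$all_of) res <- res & flags[[f]]
      if (length(test$any_of) > 0) {
        any_res <- rep(FALSE, length(dx))
        for (f in test$any_of) any_res <- any_res | flags[[f]]
        res <- res & any_res
      }
      res
    },
    abort(paste0("unknown test type '", test$type, "'"))
  )
}

test_to_string <- function(test) {
  switch(
    test$type,
    flag = test$flag,
    dx_prefix = paste0("principal_dx ~ ", test$prefix, "*"),
    combo = {
      parts <- test$all_of
      if (length(test$any_of) > 0) {
        parts <- c(parts, paste0("(", paste(test$any_of, collapse = " | "), ")"))
      }
      paste(parts, collapse = " & ")
    }
  )
}

#' Classify episodes through a ruleset
#'
#' Routes every episode down the decision tree: each episode reaches exactly
#' one leaf and receives its label (`AIS`/`non_AIS`) and trajectory id. The
#' per-node case flow is recorded for audit: how many episodes entered each
#' decision node and how many took each branch (with the fraction of true
#' AIS among them when labels are available).
#'
#' @param flags A tibble from [extract_identifiers()]: `episode_id`,
#'   `principal_dx`, and the 17 logical flag columns (optionally
#'   `true_ais`).
#' @param ruleset A `stroke_ruleset`; default [default_ruleset()].
#' @return A `stroke_calls` tibble: `episode_id`, `principal_dx`, `label`
#'   (factor `AIS`/`non_AIS`), `trajectory_id`. The audit flow is available
#'   via [flow_counts()].
#' @export
#' @examples
#' cohort <- generate_validation_cohort(sim_config(n_episodes = 100, seed = 7))
#' calls <- cohort$claims |>
#'   build_episodes() |>
#'   extract_identifiers() |>
#'   classify_episodes()
#' table(calls$label)
classify_episodes <- function(flags, ruleset = default_ruleset()) {
  validate_ruleset(ruleset)
  missing_flags <- setdiff(identifier_names(), names(flags))
  if (length(missing_flags) > 0) {
    abort(paste0("flags table missing identifier column(s): ",
                 paste(missing_flags, collapse = ", ")))
  }
  n <- nrow(flags)
  labels <- character(n)
  traj <- character(n)
  has_truth <- "true_ais" %in% names(flags)
  flow <- list()

  walk <- function(ref, idx) {
    if (!is.null(ref$leaf)) {
      labels[idx] <<- ref$leaf$label
      traj[idx] <<- ref$leaf$trajectory_id
      return(invisible())
    }
    nid <- ref$node
    node <- ruleset$nodes[[nid]]
    res <- eval_test(node$test, flags, flags$principal_dx)[idx]
    idx_t <- idx[res]
    idx_f <- idx[!res]
    flow[[length(flow) + 1L]] <<- tibble(
      node_id = nid,
      test = test_to_string(node$test),
      n_in = length(idx),
      n_true = length(idx_t),
      n_false = length(idx_f),
      pct_true_ais_in = if (has_truth && length(idx) > 0) {
        mean(flags$true_ais[idx])
      } else {
        NA_real_
      }
    )
    walk(node$if_true, idx_t)
    walk(node$if_false, idx_f)
  }
  walk(node_ref(ruleset$root), seq_len(n))

  out <- tibble(
    episode_id = flags$episode_id,
    principal_dx = flags$principal_dx,
    label = factor(labels, levels = c("AIS", "non_AIS")),
    trajectory_id = traj
  )
  if (has_truth) out$true_ais <- flags$true_ais
  structure(
    out,
    flow = bind_rows(flow),
    ruleset_version = ruleset$version,
    class = c("stroke_calls", class(tibble()))
  )
}

#' Classify a single episode's flag vector
#'
#' @param flags A named logical vector (or one-row data frame) with the 17
#'   identifier flags.
#' @param principal_dx The episode's principal diagnosis code.
#' @param ruleset A `stroke_ruleset`.
#' @return A one-row tibble with `label` and `trajectory_id`.
#' @export
classify_episode <- function(flags, principal_dx,
                             ruleset = default_ruleset()) {
  if (is.logical(flags)) flags <- as_tibble(as.list(flags))
  flags <- as_tibble(flags)
  if (!"episode_id" %in% names(flags)) flags$episode_id <- "episode"
  flags$principal_dx <- principal_dx
  res <- classify_episodes(flags, ruleset)
  tibble(label = res$label, trajectory_id = res$trajectory_id)
}

#' Per-node audit flow of a classification
#'
#' @param calls A `stroke_calls` object from [classify_episodes()].
#' @return A tibble with one row per decision node: the test, the number of
#'   episodes entering (`n_in`) and leaving along each branch (`n_true`,
#'   `n_false`), and -- when gold-standard labels were attached -- the
#'   fraction of true AIS among entrants.
#' @export
flow_counts <- function(calls) {
  stopifnot(inherits(calls, "stroke_calls"))
  attr(calls, "flow")
}

#' Enumerate all root-to-leaf trajectories
#'
#' Walks the tree and lists every root-to-leaf path with its leaf label,
#' depth, and a readable signature of the decisions along the way. Used for
#' documentation and for the conformance snapshot guarding the shipped tree
#' against silent drift.
#'
#' @param ruleset A `stroke_ruleset`.
#' @return A tibble with `trajectory_id`, `label`, `depth` and `signature`.
#' @export
enumerate_trajectories <- function(ruleset) {
  stopifnot(inherits(ruleset, "stroke_ruleset"))
  acc <- list()
  walk <- function(ref, path) {
    if (!is.null(ref$leaf)) {
      acc[[length(acc) + 1L]] <<- tibble(
        trajectory_id = ref$leaf$trajectory_id,
        label = ref$leaf$label,
        depth = length(path),
        signature = paste(path, collapse = " > ")
      )
      return(invisible())
    }
    node <- ruleset$nodes[[ref$node]]
    s <- test_to_string(node$test)
    walk(node$if_true, c(path, paste0("[", s, "]+")))
    walk(node$if_false, c(path, paste0("[", s, "]-")))
  }
  walk(node_ref(ruleset$root), character(0))
  bind_rows(acc)
}

#' Write a ruleset to JSON
#'
#' @param ruleset A `stroke_ruleset`.
#' @param path File path to write.
#' @return `path`, invisibly.
#' @export
write_ruleset <- function(ruleset, path) {
  jsonlite::write_json(
    list(version = ruleset$version, root = ruleset$root,
         nodes = ruleset$nodes),
    path,
    auto_unbox = TRUE, pretty = TRUE
  )
  invisible(path)
}

#' Load and validate a ruleset from JSON
#'
#' @param path Path to a ruleset JSON file (see [write_ruleset()]).
#' @return A validated `stroke_ruleset`.
#' @export
load_ruleset <- function(path) {
  obj <- jsonlite::read_json(path)
  fix_ref <- function(ref) {
    if (!is.null(ref$leaf)) {
      list(leaf = list(label = ref$leaf$label,
                       trajectory_id = ref$leaf$trajectory_id))
    } else {
      list(node = ref$node)
    }
  }
  nodes <- lapply(obj$nodes, function(nd) {
    t <- nd$test
    test <- switch(
      t$type %||% "missing",
      flag = test_flag(t$flag),
      dx_prefix = test_dx_prefix(t$prefix),
      combo = test_combo(
        all_of = as.character(unlist(t$all_of)),
        any_of = as.character(unlist(t$any_of))
      ),
      list(type = t$type %||% "missing")
    )
    list(test = test, if_true = fix_ref(nd$if_true),
         if_false = fix_ref(nd$if_false))
  })
  rs <- new_stroke_ruleset(nodes, root = obj$root, version = obj$version)
  validate_ruleset(rs)
  rs
}
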