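# In-code fixtures: hand-built claim lines and small cohorts.

index0 <- as.Date("2012-06-01")

claim_row <- function(code,
                      offset = 0L,
                      kind = "procedure",
                      setting = "in_hospital",
                      dept = "other",
                      dx = if (kind == "diagnosis") "additional" else "none",
                      patient = "P1",
                      claim = NULL,
                      index = index0) {
  service <- index + offset
  if (is.null(claim)) {
    claim <- if (setting == "in_hospital") {
      paste0(patient, "-H")
    } else {
      paste0(patient, "-O", offset, "-", code)
    }
  }
  tibble::tibble(
    patient_id = patient, claim_id = claim, setting = setting,
    department = dept, code = code, code_kind = kind, dx_position = dx,
    service_date = service,
    claim_start_date = if (setting == "in_hospital") index else service
  )
}

# an index in-hospital claim (principal diagnosis at day 0) plus extra lines
make_claims <- function(..., principal = "I639", patient = "P1",
                        index = index0) {
  dplyr::bind_rows(
    claim_row(principal, 0L, "diagnosis", dx = "principal",
              dept = "neurology", patient = patient, index = index),
    ...
  )
}

one_episode <- function(..., principal = "I639") {
  build_episodes(make_claims(..., principal = principal))
}

# flags row with every identifier FALSE unless named
flags_row <- function(..., episode_id = "E1", principal_dx = "I639") {
  on <- c(...)
  vals <- stats::setNames(
    as.list(identifier_names() %in% on), identifier_names()
  )
  dplyr::bind_cols(
    tibble::tibble(episode_id = episode_id, principal_dx = principal_dx),
    tibble::as_tibble(vals)
  )
}
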