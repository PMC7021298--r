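# Code catalog: the claims-code sets, temporal windows and drug-ingredient
# map behind the 17 key identifiers ("CRCS-K-2020" version).
#
# Diagnosis code sets use prefix matching on the listed stems (claims carry
# 4-6 character KCD/ICD-10 codes); procedure and drug codes match exactly.

catalog_version <- "CRCS-K-2020"

# -- drug product codes by ingredient ----------------------------------------
# The aspirin+clopidogrel fixed-dose combination products (517900*) are
# listed once, under clopidogrel.
.antithrombotic_products <- list(
  aspirin = c(
    "110701ATB", "110701ATE", "110702ATB", "110801ATB", "110802ATB",
    "111001ACE", "111001ACH", "111001ATB", "111001ATE", "111002ATE",
    "111003ACE", "111003ATE", "256800ATB"
  ),
  clopidogrel = c(
    "136901ATB", "492501ATB", "495201ATB", "498801ATB", "501501ATB",
    "517900ACE", "517900ATE", "517900ACH"
  ),
  cilostazol = c(
    "133201ACR", "133201ATB", "133201ATR", "133201ATD", "133202ATB",
    "133203ATR", "506100ATB"
  ),
  triflusal = c("244101ACE", "244101ACH", "244102ACH"),
  ticlopidine = c("239201ATB", "239202ATB", "498900ATB", "565300ATB"),
  warfarin = c(
    "249103ATB", "249105ATB", "249101ATB", "249102ATB", "249104ATB",
    "249106ATB", "249107ATB", "249108ATB", "249109ATB"
  ),
  rivaroxaban = c("511401ATB", "511402ATB", "511403ATB", "511404ATB"),
  dabigatran = c("613701ACH", "613702ACH", "613703ACH"),
  apixaban = c("617001ATB", "617002ATB"),
  edoxaban = c("643601ATB", "643602ATB", "643603ATB"),
  enoxaparin = c(
    "152130BIJ", "152131BIJ", "152132BIJ", "152133BIJ", "152134BIJ",
    "152135BIJ", "152101BIJ", "152102BIJ", "152103BIJ", "152104BIJ",
    "152105BIJ", "152106BIJ"
  ),
  dalteparin = c(
    "140230BIJ", "140231BIJ", "140232BIJ", "140233BIJ", "140234BIJ",
    "140201BIJ", "140202BIJ", "140203BIJ"
  ),
  nadroparin = c(
    "198401BIJ", "198402BIJ", "198403BIJ", "198404BIJ", "198405BIJ",
    "198406BIJ", "198430BIJ", "198431BIJ", "198432BIJ"
  ),
  heparin = c("168630BIJ", "168632BIJ", "168631BIJ", "168601BIJ", "168602BIJ"),
  alteplase = c("223501BIJ", "223502BIJ")
)

.anticoagulant_ingredients <- c(
  "warfarin", "rivaroxaban", "dabigatran", "apixaban", "edoxaban",
  "enoxaparin", "dalteparin", "nadroparin", "heparin"
)

# antithrombotics for new-user logic: everything except the thrombolytic
.antithrombotic_ingredients <- setdiff(names(.antithrombotic_products), "alteplase")

.brain_ct_codes <- c("HA451", "HA441", "HA461", "HA851", "HA471")
.cta_codes <- "HA471"
.brain_mri_codes <- c(
  "HE101", "HE201", "HE301", "HE401", "HE501",
  "HE135", "HE136", "HE235", "HE236", "HE535", "HE536",
  "HF101", "HF202"
)

new_identifier_definition <- function(name, codes, match_mode, code_kind,
                                      window, scope,
                                      departments = NULL,
                                      special = "none") {
  stopifnot(
    length(window) == 2L, window[1] <= window[2],
    match_mode %in% c("exact", "prefix"),
    scope %in% c("in_hospital_only", "in_hospital_and_outpatient"),
    special %in% c("none", "image_followup", "new_antithrombotics",
                   "anticoagulants", "transfer_to_rehab")
  )
  structure(
    list(
      name = name, codes = codes, match_mode = match_mode,
      code_kind = code_kind, window = as.integer(window), scope = scope,
      departments = departments, special = special
    ),
    class = "identifier_definition"
  )
}

#' Canonical names of the 17 key identifiers
#'
#' Returns the identifier names in their fixed catalog order: atrial
#' fibrillation, four imaging categories, Holter monitoring, reperfusion
#' therapy (IVT/EVT), three interventions, the three new-antithrombotics
#' windows, anticoagulants, and the two rehabilitation identifiers.
#'
#' @return A character vector of length 17.
#' @export
#' @examples
#' identifier_names()
identifier_names <- function() {
  c(
    "af", "brain_ct", "brain_mri", "cta", "image_fu", "holter",
    "ivt", "evt", "cea", "carotid_angioplasty", "intracranial_angioplasty",
    "new_antithrombotics_3d", "new_antithrombotics_7d",
    "new_antithrombotics_90d_nrns_opd", "anticoagulants_7d",
    "rehab", "transfer_to_rehab"
  )
}

#' Default claims-code catalog ("CRCS-K-2020")
#'
#' Builds the shipped catalog of the 17 key-identifier definitions: the KCD
#' diagnosis, procedure and drug-product code sets, their temporal windows in
#' days relative to the index admission date (both endpoints inclusive), the
#' data scope (in-hospital only, or in-hospital plus outpatient), optional
#' department filters, and the drug-product-to-ingredient map used by the
#' antithrombotic new-user logic.
#'
#' Diagnosis code sets match by prefix (claims carry 4-6 character codes);
#' procedure and drug codes match exactly. The CT-angiography code set is a
#' subset of the brain-CT set, so `cta` implies `brain_ct`.
#'
#' @return An object of class `stroke_catalog`: a list with elements
#'   `identifiers` (named list of identifier definitions), `ingredient_map`
#'   (named character vector, product code to ingredient),
#'   `antithrombotic_ingredients`, `anticoagulant_ingredients` and `version`.
#' @export
#' @examples
#' cat17 <- default_catalog()
#' names(cat17$identifiers)
#' cat17$identifiers$brain_ct$window
default_catalog <- function() {
  at_codes <- unname(unlist(
    .antithrombotic_products[.antithrombotic_ingredients]
  ))
  ac_codes <- unname(unlist(
    .antithrombotic_products[.anticoagulant_ingredients]
  ))
  imaging <- unique(c(.brain_ct_codes, .brain_mri_codes, .cta_codes))

  defs <- list(
    new_identifier_definition(
      "af", c("I48", "I480", "I481", "I482", "I489"), "prefix", "diagnosis",
      c(0L, 30L), "in_hospital_and_outpatient"
    ),
    new_identifier_definition(
      "brain_ct", .brain_ct_codes, "exact", "procedure",
      c(-7L, 2L), "in_hospital_and_outpatient"
    ),
    new_identifier_definition(
      "brain_mri", .brain_mri_codes, "exact", "procedure",
      c(-7L, 2L), "in_hospital_and_outpatient"
    ),
    new_identifier_definition(
      "cta", .cta_codes, "exact", "procedure",
      c(-7L, 2L), "in_hospital_and_outpatient"
    ),
    new_identifier_definition(
      "image_fu", imaging, "exact", "procedure",
      c(-7L, 7L), "in_hospital_and_outpatient",
      special = "image_followup"
    ),
    new_identifier_definition(
      "holter", "E6545", "exact", "procedure",
      c(0L, 30L), "in_hospital_only"
    ),
    new_identifier_definition(
      "ivt", .antithrombotic_products$alteplase, "exact", "drug",
      c(0L, 2L), "in_hospital_only"
    ),
    new_identifier_definition(
      "evt",
      c("M6630", "M6631", "M6632", "M6633", "M6635", "M6636", "M6637", "M6639"),
      "exact", "procedure", c(0L, 2L), "in_hospital_only"
    ),
    new_identifier_definition(
      "cea", c("O0226", "O0227", "O2066"), "exact", "procedure",
      c(0L, 30L), "in_hospital_only"
    ),
    new_identifier_definition(
      "carotid_angioplasty", c("M6594", "M6602"), "exact", "procedure",
      c(0L, 30L), "in_hospital_only"
    ),
    new_identifier_definition(
      "intracranial_angioplasty",
      c("M6593", "M6597", "M6599", "M6601", "M6605"),
      "exact", "procedure", c(0L, 30L), "in_hospital_only"
    ),
    new_identifier_definition(
      "new_antithrombotics_3d", at_codes, "exact", "drug",
      c(0L, 3L), "in_hospital_and_outpatient",
      special = "new_antithrombotics"
    ),
    new_identifier_definition(
      "new_antithrombotics_7d", at_codes, "exact", "drug",
      c(0L, 7L), "in_hospital_and_outpatient",
      special = "new_antithrombotics"
    ),
    new_identifier_definition(
      "new_antithrombotics_90d_nrns_opd", at_codes, "exact", "drug",
      c(0L, 90L), "in_hospital_and_outpatient",
      departments = c("neurology", "neurosurgery"),
      special = "new_antithrombotics"
    ),
    new_identifier_definition(
      "anticoagulants_7d", ac_codes, "exact", "drug",
      c(0L, 7L), "in_hospital_and_outpatient",
      special = "anticoagulants"
    ),
    new_identifier_definition(
      "rehab",
      c("MX141", "MM301", "MM302", "MM101", "MM102", "MM103", "MM105",
        "MM111", "MM112", "MM113", "MM114"),
      "exact", "procedure", c(0L, 30L), "in_hospital_and_outpatient"
    ),
    new_identifier_definition(
      "transfer_to_rehab", character(0), "exact", "any",
      c(0L, 30L), "in_hospital_only",
      special = "transfer_to_rehab"
    )
  )
  names(defs) <- vapply(defs, `[[`, character(1), "name")
  stopifnot(identical(names(defs), identifier_names()))

  ingredient_map <- unlist(lapply(
    names(.antithrombotic_products),
    function(ing) setNames(
      rep(ing, length(.antithrombotic_products[[ing]])),
      .antithrombotic_products[[ing]]
    )
  ))
  stopifnot(!anyDuplicated(names(ingredient_map)))

  structure(
    list(
      identifiers = defs,
      ingredient_map = ingredient_map,
      antithrombotic_ingredients = .antithrombotic_ingredients,
      anticoagulant_ingredients = .anticoagulant_ingredients,
      version = catalog_version
    ),
    class = "stroke_catalog"
  )
}

#' @export
print.stroke_catalog <- function(x, ...) {
  cat("<stroke_catalog> version", x$version, "\n")
  cat(" ", length(x$identifiers), "key identifiers;",
      length(x$ingredient_map), "drug product codes across",
      length(unique(x$ingredient_map)), "ingredients\n")
  invisible(x)
}

#' Look up an identifier definition by name
#'
#' @param name One of [identifier_names()].
#' @param catalog A `stroke_catalog`, by default [default_catalog()].
#' @return The `identifier_definition`.
#' @export
identifier_definition <- function(name, catalog = default_catalog()) {
  if (!name %in% names(catalog$identifiers)) {
    abort(paste0("unknown identifier '", name, "'"))
  }
  catalog$identifiers[[name]]
}

#' Map drug product codes to ingredients
#'
#' Vectorised lookup of the catalog's drug-product-to-ingredient map
#' (antithrombotic agents plus alteplase). Uncatalogued codes return `NA`.
#'
#' @param code Character vector of drug product codes.
#' @param catalog A `stroke_catalog`.
#' @return Character vector of ingredient names, `NA` where unknown.
#' @export
#' @examples
#' ingredient_of(c("223501BIJ", "249103ATB", "ZZZ"))
ingredient_of <- function(code, catalog = default_catalog()) {
  unname(catalog$ingredient_map[code])
}

# TRUE where `code` belongs to the code set
code_in_set <- function(code, codes, match_mode) {
  if (length(codes) == 0) {
    return(rep(FALSE, length(code)))
  }
  if (match_mode == "exact") {
    code %in% codes
  } else {
    stringr::str_detect(
      code,
      paste0("^(?:", paste(sort(codes, decreasing = TRUE), collapse = "|"), ")")
    )
  }
}

#' Write a catalog to JSON
#'
#' The on-disk form is an editable structured config so that code-list drift
#' (e.g. newly marketed drug products) is a data change, not a code change.
#' [read_catalog()] restores an identical object (bit-exact round trip).
#'
#' @param catalog A `stroke_catalog`.
#' @param path File path to write.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(catalog, path) {
  ids <- lapply(catalog$identifiers, function(d) {
    out <- list(
      codes = d$codes, match_mode = d$match_mode, code_kind = d$code_kind,
      window_days = d$window, scope = d$scope, special = d$special
    )
    if (!is.null(d$departments)) out$departments <- d$departments
    out
  })
  obj <- list(
    version = catalog$version,
    identifiers = ids,
    ingredient_map = as.list(catalog$ingredient_map),
    antithrombotic_ingredients = catalog$antithrombotic_ingredients,
    anticoagulant_ingredients = catalog$anticoagulant_ingredients
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a catalog from JSON
#'
#' @param path Path to a catalog JSON file written by [write_catalog()].
#' @return A `stroke_catalog`.
#' @export
read_catalog <- function(path) {
  obj <- jsonlite::read_json(path)
  defs <- lapply(names(obj$identifiers), function(nm) {
    d <- obj$identifiers[[nm]]
    new_identifier_definition(
      nm,
      codes = as.character(unlist(d$codes)),
      match_mode = d$match_mode, code_kind = d$code_kind,
      window = as.integer(unlist(d$window_days)), scope = d$scope,
      departments = if (!is.null(d$departments)) {
        as.character(unlist(d$departments))
      },
      special = d$special
    )
  })
  names(defs) <- names(obj$identifiers)
  structure(
    list(
      identifiers = defs,
      ingredient_map = unlist(obj$ingredient_map),
      antithrombotic_ingredients = as.character(unlist(obj$antithrombotic_ingredients)),
      anticoagulant_ingredients = as.character(unlist(obj$anticoagulant_ingredients)),
      version = obj$version
    ),
    class = "stroke_catalog"
  )
}
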