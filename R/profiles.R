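# Chemical profiles: one row per chemical, holding pre-assigned 1-3 scores
# and/or raw property values, absorption observations, and per-endpoint
# certainty/potency evidence. "NI" / empty cells are missing; potency is NA
# (not applicable) wherever certainty is 0.

profile_score_cols <- c(
  "abs_oral_score", "abs_dermal_score", "abs_inhalation_score",
  "solubility_score", "kp_score", "vp_score"
)
profile_endpoint_cols <- c(
  "rd_certainty", "rd_potency", "carc_certainty", "carc_potency",
  "nt_certainty", "nt_potency", "ed_certainty", "ed_potency"
)
profile_raw_cols <- c(
  "water_solubility_mol_l", "vapor_pressure_mmhg", "kp_cm_h",
  "log_kow", "molecular_weight",
  "rd_noael", "rd_loael", "rd_rfd", "rd_uf",
  "ed_noael", "ed_loael", "ed_rfd", "ed_uf",
  "carc_td50_mouse", "carc_td50_rat",
  "abs_oral_percent", "abs_dermal_percent", "abs_inhalation_percent"
)
profile_flag_cols <- c(
  "abs_oral_unknown", "abs_dermal_unknown", "abs_inhalation_unknown"
)

#' Read a chemical-profile table
#'
#' Reads profiles from CSV or JSON. Required columns: `chemical_id`;
#' recognized optional columns are the pre-assigned score columns
#' (`abs_*_score`, `solubility_score`, `kp_score`, `vp_score`, per-endpoint
#' `*_certainty` / `*_potency`), raw property columns
#' (`water_solubility_mol_l`, `vapor_pressure_mmhg`, `kp_cm_h`, `log_kow`,
#' `molecular_weight`), absorption observations (`abs_*_percent`,
#' `abs_*_unknown`), and potency inputs (`*_noael`, `*_loael`, `*_rfd` +
#' `*_uf`, `carc_td50_mouse` / `carc_td50_rat`). `"NI"` and empty cells are
#' read as missing. Lines starting with `#` are comments.
#'
#' @param path Path to a `.csv` or `.json` file.
#' @return Validated tibble of profiles.
#' @export
read_profiles <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    df <- jsonlite::fromJSON(path)
  } else {
    df <- utils::read.csv(path, comment.char = "#", na.strings = c("NA", "NI", ""),
                          stringsAsFactors = FALSE, check.names = FALSE)
  }
  validate_profiles(tibble::as_tibble(df))
}

#' Validate a profile table
#'
#' Checks the profile invariants: unique non-empty `chemical_id`s; all
#' stored scores in 0-3 (absorption/property scores in 1-3); for solubility
#' and vapor pressure at least one of score or raw value present; dermal
#' permeability may be absent only when an observed dermal absorption is
#' available to fall back on; potency treated as not-applicable wherever
#' certainty is 0.
#'
#' @param profiles Data frame of profiles.
#' @return The validated profiles as a tibble (missing recognized columns
#'   are added as `NA`, `group` defaults to `"none"`).
#' @export
validate_profiles <- function(profiles) {
  profiles <- tibble::as_tibble(profiles)
  if (!"chemical_id" %in% names(profiles)) stop("profiles need a chemical_id column")
  if (anyNA(profiles$chemical_id) || any(!nzchar(profiles$chemical_id))) {
    stop("every profile needs a non-empty chemical_id")
  }
  if (anyDuplicated(profiles$chemical_id)) stop("duplicate chemical_id in profiles")
  if (!"name" %in% names(profiles)) profiles$name <- profiles$chemical_id
  if (!"group" %in% names(profiles)) profiles$group <- "none"
  profiles$group[is.na(profiles$group)] <- "none"
  known_groups <- c("phthalates", "parabens", "ethylene_glycols", "metals", "none")
  bad <- setdiff(unique(profiles$group), known_groups)
  if (length(bad) > 0) stop("unknown group(s): ", paste(bad, collapse = ", "))

  for (col in c(profile_score_cols, profile_endpoint_cols, profile_raw_cols)) {
    if (!col %in% names(profiles)) {
      profiles[[col]] <- NA_real_
    } else {
      profiles[[col]] <- suppressWarnings(as.numeric(profiles[[col]]))
    }
  }
  for (col in profile_flag_cols) {
    if (!col %in% names(profiles)) profiles[[col]] <- FALSE
    profiles[[col]][is.na(profiles[[col]])] <- FALSE
    profiles[[col]] <- as.logical(profiles[[col]])
  }

  chk_in <- function(col, allowed) {
    v <- profiles[[col]]
    if (any(!is.na(v) & !(v %in% allowed))) {
      stop("profile column '", col, "' has values outside {",
           paste(allowed, collapse = ","), "}")
    }
  }
  for (col in profile_score_cols) chk_in(col, 1:3)
  for (col in grep("_certainty$", profile_endpoint_cols, value = TRUE)) {
    chk_in(col, 0:3)
  }
  for (col in grep("_potency$", profile_endpoint_cols, value = TRUE)) {
    chk_in(col, 1:3)
  }

  need_one <- function(score_col, raw_col, what) {
    miss <- is.na(profiles[[score_col]]) & is.na(profiles[[raw_col]])
    if (any(miss)) {
      stop("profile(s) ", paste(profiles$chemical_id[miss], collapse = ", "),
           " lack both a score and a raw value for ", what)
    }
  }
  need_one("solubility_score", "water_solubility_mol_l", "water solubility")
  need_one("vp_score", "vapor_pressure_mmhg", "vapor pressure")
  # Kp may be derived from log Kow + MW, or absent entirely when an observed
  # dermal absorption provides the dermal toxicokinetic score on its own
  kp_miss <- is.na(profiles$kp_score) & is.na(profiles$kp_cm_h) &
    (is.na(profiles$log_kow) | is.na(profiles$molecular_weight))
  no_fallback <- kp_miss & is.na(profiles$abs_dermal_score) &
    is.na(profiles$abs_dermal_percent) & !profiles$abs_dermal_unknown
  if (any(no_fallback)) {
    stop("profile(s) ", paste(profiles$chemical_id[no_fallback], collapse = ", "),
         " lack dermal permeability and any dermal absorption fallback")
  }
  profiles
}

#' Bundled CSPA chemical profiles
#'
#' The package's bundled score table for the 21 most frequently reported
#' CSPA chemicals and chemical groups: observed absorption scores per route,
#' property scores (water solubility, dermal permeability, vapor pressure),
#' and certainty/potency scores for the four toxicity endpoints
#' (reproductive/developmental, carcinogenicity, neurotoxicity, endocrine
#' disruption). Missing cells are `NA`; metals are carried as total-element
#' groups because CSPA reports only total metal mass.
#'
#' @return Tibble of 21 validated profiles.
#' @examples
#' profs <- bundled_profiles()
#' nrow(profs)
#' chemical_profile(profs, "dibutyl phthalate")$rd_certainty
#' @export
bundled_profiles <- function() {
  path <- system.file("extdata", "cspa_chemical_profiles.csv",
                      package = "cspascore", mustWork = TRUE)
  read_profiles(path)
}

#' Look up one chemical profile
#'
#' Matches `chemical` against `chemical_id` and `name` after normalization
#' (case, punctuation and whitespace insensitive).
#'
#' @param profiles Profile tibble.
#' @param chemical Chemical id or display name.
#' @return One-row tibble.
#' @export
chemical_profile <- function(profiles, chemical) {
  key <- normalize_chemical_name(chemical)
  idx <- which(normalize_chemical_name(profiles$chemical_id) == key |
                 normalize_chemical_name(profiles$name) == key)
  if (length(idx) == 0) stop("no profile for chemical '", chemical, "'")
  profiles[idx[1], , drop = FALSE]
}

#' Write a profile table to CSV
#'
#' Inverse of [read_profiles()]: missing values serialize as `"NI"` so the
#' table round-trips losslessly through the package's own reader.
#'
#' @param profiles Profile tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profiles, path) {
  out <- as.data.frame(profiles)
  utils::write.csv(out, path, row.names = FALSE, na = "NI")
  invisible(path)
}
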