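# Exposure scoring: additive product block (lifestage + duration + skin
# application + concentration) plus route-weighted toxicokinetic components.
#
#   exposure = (LS + EX + A + Con)
#            + O_MF * (S  + Abs_oral)/2
#            + I_MF * (VP + Abs_inhalation)/2
#            + D_MF * (Kp + Abs_dermal)/2
#
# When an observed absorption score is missing the chemical property score
# stands alone for that route (and symmetrically for the one chemical with
# no dermal permeability value).

#' Lifestage score
#'
#' Products designed for children under age three score 3; products for
#' ages 3-12 score 1.
#'
#' @param target_age `"under_three"` or `"three_to_twelve"` (vectorized).
#' @param rules Rule set from [default_rules()].
#' @return Numeric score(s).
#' @export
score_lifestage <- function(target_age, rules = default_rules()) {
  out <- unname(rules$lifestage_map[target_age])
  if (anyNA(out)) stop("invalid target_age; expected under_three / three_to_twelve")
  out
}

#' Concentration score
#'
#' The six CSPA concentration ranges score on 0.5 increments from 0.5
#' (<100 ppm) to 3 (>10,000 ppm).
#'
#' @param concentration_bin Canonical bin token(s) or recognized variant.
#' @inheritParams score_lifestage
#' @return Numeric score(s).
#' @export
score_concentration <- function(concentration_bin, rules = default_rules()) {
  bin <- normalize_concentration_bin(concentration_bin)
  out <- unname(rules$concentration_map[bin])
  if (anyNA(out)) stop("invalid concentration_bin")
  out
}

#' Exposure-duration score
#'
#' Product segments assumed to involve long-term exposure (clothing,
#' footwear, beauty/personal care/hygiene, camping) score 3; all other
#' segments are treated as short-term and score 1. Unknown segments fall
#' back to short-term with a warning.
#'
#' @param segment Product segment string(s).
#' @inheritParams score_lifestage
#' @return Numeric score(s).
#' @export
score_duration <- function(segment, rules = default_rules()) {
  seg <- match_segment(segment)
  unknown <- is.na(seg)
  if (any(unknown)) {
    warning("unknown segment(s) ", paste(unique(segment[unknown]), collapse = ", "),
            "; duration defaulted to short-term")
  }
  long <- !is.na(seg) & seg %in% rules$long_term_segments
  ifelse(long, rules$duration_scores[["long_term"]],
         rules$duration_scores[["short_term"]])
}

#' Applied-directly-to-skin score
#'
#' Products in the beauty/personal care/hygiene segment are intended for
#' direct application to skin or body and score 3; everything else scores 1.
#'
#' @inheritParams score_duration
#' @return Numeric score(s).
#' @export
score_applied_to_skin <- function(segment, rules = default_rules()) {
  seg <- match_segment(segment)
  yes <- !is.na(seg) & seg %in% rules$applied_to_skin_segments
  ifelse(yes, rules$applied_scores[["yes"]], rules$applied_scores[["no"]])
}

#' Water-solubility score
#'
#' Oral-exposure potential: generally insoluble (<0.001 mol/L) scores 1,
#' 0.001-0.01 mol/L scores 2, soluble (>0.01 mol/L) scores 3.
#'
#' @param solubility Water solubility in mol/L (positive).
#' @inheritParams score_lifestage
#' @return Score(s) in 1-3.
#' @export
score_solubility <- function(solubility, rules = default_rules()) {
  if (any(!is.na(solubility) & solubility <= 0)) stop("solubility must be positive")
  cut <- rules$solubility_cutoffs
  ifelse(solubility < cut[1], 1, ifelse(solubility < cut[2], 2, 3))
}

#' Vapor-pressure score
#'
#' Inhalation-exposure potential at 25 C: nonvolatile (<0.075 mmHg) scores
#' 1, semi-volatile (0.075-32 mmHg) scores 2, volatile (>32 mmHg) scores 3.
#'
#' @param vp Vapor pressure in mmHg at 25 C (non-negative).
#' @inheritParams score_lifestage
#' @return Score(s) in 1-3.
#' @export
score_vapor_pressure <- function(vp, rules = default_rules()) {
  if (any(!is.na(vp) & vp < 0)) stop("vapor pressure must be non-negative")
  cut <- rules$vp_cutoffs
  ifelse(vp < cut[1], 1, ifelse(vp <= cut[2], 2, 3))
}

#' Dermal permeability coefficient (Potts-Guy QSPR)
#'
#' Predicts the skin permeability coefficient from the octanol-water
#' partition coefficient and molecular weight:
#' `log10(Kp) = -2.72 + 0.71 * log_kow - 0.0061 * MW`, with Kp in cm/h.
#'
#' @param log_kow Log octanol-water partition coefficient (unitless).
#' @param molecular_weight Molecular weight in g/mol (positive; 0 allowed
#'   only as the degenerate constant-term evaluation).
#' @return Kp in cm/h.
#' @examples
#' compute_kp(2, 100) # ~1.23e-2 cm/h
#' @export
compute_kp <- function(log_kow, molecular_weight) {
  if (any(!is.na(molecular_weight) & molecular_weight < 0)) {
    stop("molecular weight must be non-negative")
  }
  10^(-2.72 + 0.71 * log_kow - 0.0061 * molecular_weight)
}

#' Dermal permeability score
#'
#' Scores Kp by the tertiles of the bundled chemical set: <=3.395e-3 cm/h
#' scores 1, up to 6.7e-3 scores 2, above that scores 3 (cutoffs
#' configurable).
#'
#' @param kp Permeability coefficient in cm/h (positive).
#' @inheritParams score_lifestage
#' @return Score(s) in 1-3.
#' @export
score_kp <- function(kp, rules = default_rules()) {
  if (any(!is.na(kp) & kp <= 0)) stop("kp must be positive")
  cut <- rules$kp_cutoffs
  ifelse(kp <= cut[1], 1, ifelse(kp <= cut[2], 2, 3))
}

#' Observed absorption score
#'
#' Scores the observed percent absorbed via a route: up to 5% scores 1,
#' 5-10% (or absorbed at an unknown rate) scores 2, above 10% scores 3.
#' With `rules$absorption_high_above_5 = TRUE` the alternative binning is
#' used in which anything above 5% scores 3.
#'
#' @param observation Numeric percent in 0-100, the string
#'   `"unknown_rate"`, or `NA` (missing).
#' @inheritParams score_lifestage
#' @return Score in 1-3, or `NA` when the observation is missing.
#' @export
score_absorption <- function(observation, rules = default_rules()) {
  if (is.character(observation)) {
    if (!all(is.na(observation) | observation == "unknown_rate")) {
      stop("character observation must be 'unknown_rate'")
    }
    return(ifelse(is.na(observation), NA_real_, rules$unknown_rate_score))
  }
  if (any(!is.na(observation) & (observation < 0 | observation > 100))) {
    stop("absorption percent must be within [0, 100]")
  }
  cut <- rules$absorption_cutoffs
  if (isTRUE(rules$absorption_high_above_5)) {
    ifelse(is.na(observation), NA_real_,
           ifelse(observation <= cut[1], 1, 3))
  } else {
    ifelse(is.na(observation), NA_real_,
           ifelse(observation <= cut[1], 1,
                  ifelse(observation <= cut[2], 2, 3)))
  }
}

# --- exposure route assignment -------------------------------------------

brick_matches <- function(brick, pattern) {
  !is.na(brick) & grepl(pattern, normalize_label(brick))
}

#' Assign exposure routes from product metadata
#'
#' Determines primary/secondary/tertiary status for the oral, dermal and
#' inhalation routes from the product segment, optional brick and target
#' age, applying the rule cascade in order (first match wins at each step):
#'
#' 1. Special bricks: paints get primary inhalation / secondary dermal /
#'    tertiary oral; party blowers get dual primary oral + inhalation;
#'    fragrances get dual primary dermal + inhalation; pacifier, kitchen-toy,
#'    feeding-support and food-preparation bricks get primary oral.
#' 2. Otherwise by segment: kitchen merchandise gets primary oral; clothing,
#'    beauty/personal care/hygiene, footwear, arts/crafts, household,
#'    camping, personal accessories and toys/games get primary dermal; any
#'    remaining (or unknown) segment defaults to primary dermal with a
#'    warning.
#' 3. Primary-oral products get secondary dermal (children hold what they
#'    mouth).
#' 4. For under-three products whose primary route is not oral, oral
#'    becomes secondary.
#' 5. If neither oral nor inhalation ended up primary or secondary, both
#'    become tertiary (house-dust ingestion/inhalation as products
#'    disintegrate); every still-unassigned route floors at tertiary.
#'
#' Modifying factors: primary 3, secondary 2, tertiary 1.
#'
#' @param segment Product segment string.
#' @param brick Optional brick (sub-category) string.
#' @param target_age `"under_three"` or `"three_to_twelve"`.
#' @inheritParams score_lifestage
#' @return List with `oral_mf`, `dermal_mf`, `inhalation_mf` (each 1/2/3),
#'   and `rationale`, a named character vector tagging each route with its
#'   tier and the rule that fired.
#' @examples
#' assign_exposure_routes("Clothing", target_age = "under_three")
#' @export
assign_exposure_routes <- function(segment, brick = NA,
                                   target_age = "three_to_twelve",
                                   rules = default_rules()) {
  tier <- c(oral = NA_character_, dermal = NA_character_,
            inhalation = NA_character_)
  why <- c(oral = "", dermal = "", inhalation = "")
  set_tier <- function(route, level, reason) {
    if (is.na(tier[[route]])) {
      tier[[route]] <<- level
      why[[route]] <<- reason
    }
  }

  seg <- match_segment(segment)
  if (brick_matches(brick, "paint")) {
    set_tier("inhalation", "primary", "paint brick")
    set_tier("dermal", "secondary", "paint brick")
    set_tier("oral", "tertiary", "paint brick")
  } else if (brick_matches(brick, "party blower|party horn")) {
    set_tier("oral", "primary", "party-blower brick")
    set_tier("inhalation", "primary", "party-blower brick")
  } else if (brick_matches(brick, "fragrance|perfume")) {
    set_tier("dermal", "primary", "fragrance brick")
    set_tier("inhalation", "primary", "fragrance brick")
  } else if (brick_matches(brick, "pacifier|kitchen toy|feeding|food prep")) {
    set_tier("oral", "primary", "mouthing/feeding brick")
  } else if (!is.na(seg) && seg %in% rules$oral_primary_segments) {
    set_tier("oral", "primary", "oral-primary segment")
  } else if (!is.na(seg) && seg %in% rules$dermal_primary_segments) {
    set_tier("dermal", "primary", "dermal-primary segment")
  } else {
    if (is.na(seg)) {
      warning("unknown segment '", segment,
              "'; defaulting to primary dermal route")
    }
    set_tier("dermal", "primary", "default dermal primary")
  }

  if (identical(tier[["oral"]], "primary")) {
    set_tier("dermal", "secondary", "secondary dermal for primary-oral")
  }
  if (identical(target_age, "under_three") &&
      !identical(tier[["oral"]], "primary")) {
    set_tier("oral", "secondary", "secondary oral for under-3")
  }
  oral_ps <- isTRUE(tier[["oral"]] %in% c("primary", "secondary"))
  inh_ps <- isTRUE(tier[["inhalation"]] %in% c("primary", "secondary"))
  if (!oral_ps && !inh_ps) {
    set_tier("oral", "tertiary", "house-dust tertiary pair")
    set_tier("inhalation", "tertiary", "house-dust tertiary pair")
  }
  for (r in names(tier)) set_tier(r, "tertiary", "tertiary floor")

  mf <- stats::setNames(unname(rules$route_mf[tier]), names(tier))
  list(
    oral_mf = unname(mf[["oral"]]),
    dermal_mf = unname(mf[["dermal"]]),
    inhalation_mf = unname(mf[["inhalation"]]),
    rationale = stats::setNames(
      paste0(tier, " (", why, ")"), names(tier)
    )
  )
}

#' Route toxicokinetic component
#'
#' One term of the exposure equation: the modifying factor times the
#' route's toxicokinetic score. With both a chemical-property score and an
#' observed absorption score the toxicokinetic score is their average; when
#' either is missing the other stands alone.
#'
#' @param mf Route modifying factor (1, 2 or 3).
#' @param property_score Chemical-property score for the route (solubility,
#'   Kp or vapor pressure; 1-3, or `NA` with an absorption fallback).
#' @param absorption_score Observed absorption score (1-3) or `NA`.
#' @return Component value `mf * toxicokinetic_average`.
#' @export
route_component <- function(mf, property_score, absorption_score = NA) {
  stopifnot(mf %in% 1:3)
  if (is.na(property_score) && is.na(absorption_score)) {
    stop("route has neither a property score nor an absorption score")
  }
  tk <- mean(c(property_score, absorption_score), na.rm = TRUE)
  mf * tk
}

# resolve the per-route property and absorption scores for one profile row,
# honoring pre-assigned scores over raw values
resolve_route_scores <- function(profile, rules) {
  p <- as.list(profile)
  pick <- function(score, raw, scorer) {
    if (!is_missing_value(p[[score]])) return(p[[score]])
    if (!is_missing_value(p[[raw]])) return(scorer(p[[raw]], rules))
    NA_real_
  }
  s <- pick("solubility_score", "water_solubility_mol_l", score_solubility)
  vp <- pick("vp_score", "vapor_pressure_mmhg", score_vapor_pressure)
  kp <- pick("kp_score", "kp_cm_h", score_kp)
  if (is.na(kp) && !is_missing_value(p$log_kow) &&
      !is_missing_value(p$molecular_weight)) {
    kp <- score_kp(compute_kp(p$log_kow, p$molecular_weight), rules)
  }
  absf <- function(score, pct, unk) {
    if (!is_missing_value(p[[score]])) return(p[[score]])
    if (isTRUE(p[[unk]])) return(rules$unknown_rate_score)
    if (!is_missing_value(p[[pct]])) return(score_absorption(p[[pct]], rules))
    NA_real_
  }
  list(
    s = s, vp = vp, kp = kp,
    abs_oral = absf("abs_oral_score", "abs_oral_percent", "abs_oral_unknown"),
    abs_dermal = absf("abs_dermal_score", "abs_dermal_percent",
                      "abs_dermal_unknown"),
    abs_inhalation = absf("abs_inhalation_score", "abs_inhalation_percent",
                          "abs_inhalation_unknown")
  )
}

#' Exposure score for one report
#'
#' Evaluates the exposure equation for a validated product report and a
#' chemical profile: the additive block (lifestage + duration + applied to
#' skin + concentration) plus the three route-weighted toxicokinetic
#' components. The full breakdown is returned for audit.
#'
#' @param report One-row tibble from [validate_report()] (or a named list
#'   with the same fields).
#' @param profile One-row profile tibble (see [bundled_profiles()]).
#' @inheritParams score_lifestage
#' @return A list of class `exposure_breakdown` with elements `ls`, `ex`,
#'   `a`, `con`, per-route `mf`, `property`, `absorption`, `tk_average` and
#'   `component`, and `total`.
#' @examples
#' rep <- validate_report(list(chemical_id = "formaldehyde",
#'   segment = "Clothing", target_age = "under_three",
#'   concentration_bin = "100-500"))$report
#' exposure_score(rep, chemical_profile(bundled_profiles(), "formaldehyde"))$total
#' @export
exposure_score <- function(report, profile, rules = default_rules()) {
  report <- as.list(report)
  ls <- score_lifestage(report$target_age, rules)
  ex <- score_duration(report$segment, rules)
  a <- score_applied_to_skin(report$segment, rules)
  con <- score_concentration(report$concentration_bin, rules)
  routes <- assign_exposure_routes(report$segment, report$brick %||% NA,
                                   report$target_age, rules)
  rs <- resolve_route_scores(profile, rules)
  err_if_empty <- function(prop, abs, what) {
    if (is.na(prop) && is.na(abs)) {
      stop("profile '", profile$chemical_id,
           "' has no usable score for ", what)
    }
  }
  err_if_empty(rs$s, rs$abs_oral, "water solubility (oral route)")
  err_if_empty(rs$vp, rs$abs_inhalation, "vapor pressure (inhalation route)")
  err_if_empty(rs$kp, rs$abs_dermal, "dermal permeability (dermal route)")

  comp <- function(mf, prop, abs) route_component(mf, prop, abs)
  oral <- comp(routes$oral_mf, rs$s, rs$abs_oral)
  dermal <- comp(routes$dermal_mf, rs$kp, rs$abs_dermal)
  inhalation <- comp(routes$inhalation_mf, rs$vp, rs$abs_inhalation)

  tk <- function(prop, abs) mean(c(prop, abs), na.rm = TRUE)
  structure(list(
    ls = ls, ex = ex, a = a, con = con,
    oral = list(mf = routes$oral_mf, property = rs$s,
                absorption = rs$abs_oral,
                tk_average = tk(rs$s, rs$abs_oral), component = oral),
    dermal = list(mf = routes$dermal_mf, property = rs$kp,
                  absorption = rs$abs_dermal,
                  tk_average = tk(rs$kp, rs$abs_dermal), component = dermal),
    inhalation = list(mf = routes$inhalation_mf, property = rs$vp,
                      absorption = rs$abs_inhalation,
                      tk_average = tk(rs$vp, rs$abs_inhalation),
                      component = inhalation),
    route_rationale = routes$rationale,
    total = ls + ex + a + con + oral + dermal + inhalation
  ), class = "exposure_breakdown")
}

#' @export
print.exposure_breakdown <- function(x, ...) {
  cat(sprintf(
    "<exposure_breakdown> total %.1f = (LS %g + EX %g + A %g + Con %g) + oral %.2f + dermal %.2f + inhalation %.2f\n",
    x$total, x$ls, x$ex, x$a, x$con,
    x$oral$component, x$dermal$component, x$inhalation$component
  ))
  invisible(x)
}
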