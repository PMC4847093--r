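# Toxicity scoring: sum over four endpoints (endocrine disruption,
# reproductive/developmental toxicity, carcinogenicity, neurotoxicity) of
# certainty x potency. Certainty harmonizes curated-database verdicts as
# their maximum; potency derives from NOAEL/LOAEL/RfD tertiles (RD, ED),
# TD50 tertiles (carcinogenicity) or a constant (neurotoxicity).

endpoint_keys <- c("ed", "rd", "carc", "nt")

#' Harmonize certainty verdicts across sources
#'
#' Combines per-source classifications into one certainty score by taking
#' the highest classification in any source: `none` 0, `potential` 1,
#' `suspected` 2, `known` 3. An empty verdict set scores 0. For endocrine
#' disruption, ECHA categories map to these labels as candidate-unclassified
#' -> potential, category 2/3 -> suspected, category 1 -> known.
#'
#' @param verdicts Character vector (possibly named by source) of
#'   classifications in `none` / `potential` / `suspected` / `known`.
#' @return Certainty score 0-3.
#' @examples
#' harmonize_certainty(c(prop65 = "known", ghs = "none")) # 3
#' @export
harmonize_certainty <- function(verdicts) {
  if (length(verdicts) == 0) return(0)
  lut <- c(none = 0, potential = 1, suspected = 2, known = 3)
  key <- tolower(trimws(as.character(verdicts)))
  bad <- !key %in% names(lut)
  if (any(bad)) {
    stop("unknown verdict label(s): ", paste(unique(key[bad]), collapse = ", "))
  }
  max(unname(lut[key]))
}

#' Convert a LOAEL to a NOAEL-equivalent
#'
#' Divides the lowest observed adverse effect level by an uncertainty
#' factor (default 10) so critical doses are comparable across chemicals.
#'
#' @param loael LOAEL in mg/kg (positive).
#' @param uf Uncertainty factor (default from the rule set).
#' @return NOAEL-equivalent in mg/kg.
#' @export
loael_to_noael <- function(loael, uf = default_rules()$loael_uf) {
  if (any(!is.na(loael) & loael <= 0)) stop("LOAEL must be positive")
  loael / uf
}

#' Convert a reference dose back to a NOAEL-equivalent
#'
#' Multiplies an RfD by the product of the uncertainty factors reported
#' with it.
#'
#' @param rfd Reference dose in mg/kg/day (positive).
#' @param uf_product Product of the reported uncertainty factors (positive).
#' @return NOAEL-equivalent in mg/kg.
#' @export
rfd_to_noael <- function(rfd, uf_product) {
  if (any(!is.na(rfd) & rfd <= 0)) stop("RfD must be positive")
  if (any(!is.na(uf_product) & uf_product <= 0)) {
    stop("uncertainty-factor product must be positive")
  }
  rfd * uf_product
}

#' Potency score from a NOAEL-equivalent
#'
#' Bins a NOAEL-equivalent into the endpoint's potency tertiles: a dose
#' above the upper edge scores 1 (least potent), within the middle band 2,
#' below the lower edge 3. Defaults: RD 200/397 mg/kg, ED 336/667 mg/kg.
#'
#' @param noael_equiv NOAEL-equivalent in mg/kg (positive).
#' @param endpoint `"rd"` or `"ed"`.
#' @inheritParams score_lifestage
#' @return Potency score 1-3.
#' @export
potency_from_noael <- function(noael_equiv, endpoint = c("rd", "ed"),
                               rules = default_rules()) {
  endpoint <- match.arg(endpoint)
  if (any(!is.na(noael_equiv) & noael_equiv <= 0)) {
    stop("NOAEL-equivalent must be positive")
  }
  cut <- rules[[paste0(endpoint, "_noael_cutoffs")]]
  ifelse(noael_equiv > cut[2], 1, ifelse(noael_equiv >= cut[1], 2, 3))
}

#' Carcinogenic potency score from TD50
#'
#' Uses the lower TD50 of the two rodent species, binned by the tertile
#' cutoffs (default 233 / 465 mg/kg/day): above the upper edge scores 1,
#' the middle band 2, below the lower edge 3.
#'
#' @param td50_mouse,td50_rat TD50 in mg/kg/day for each species; at least
#'   one must be non-missing.
#' @inheritParams score_lifestage
#' @return Potency score 1-3.
#' @export
potency_from_td50 <- function(td50_mouse = NA, td50_rat = NA,
                              rules = default_rules()) {
  vals <- c(td50_mouse, td50_rat)
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0) stop("need a TD50 for at least one species")
  if (any(vals <= 0)) stop("TD50 must be positive")
  td <- min(vals)
  cut <- rules$td50_cutoffs
  if (td > cut[2]) 1 else if (td >= cut[1]) 2 else 3
}

#' Endpoint potency score
#'
#' Resolves the potency score for one endpoint given its certainty and the
#' available potency inputs. Certainty 0 yields `NA` (not applicable);
#' potential or suspected toxicants (certainty 1-2) get potency 1, so the
#' certainty signal is preserved when no dose data exist; known toxicants
#' (certainty 3) get their dose-derived score: constant `nt_potency` for
#' neurotoxicity, NOAEL-equivalent tertiles for RD/ED (NOAEL preferred,
#' then LOAEL / uncertainty factor, then RfD x uncertainty factors), TD50
#' tertiles for carcinogenicity. A known toxicant with no potency input
#' scores 1 with a warning.
#'
#' @param certainty Certainty score 0-3.
#' @param inputs Named list of available inputs: `noael`, `loael`, `rfd`,
#'   `uf`, `td50_mouse`, `td50_rat` (all optional).
#' @param endpoint One of `"ed"`, `"rd"`, `"carc"`, `"nt"`.
#' @inheritParams score_lifestage
#' @return Potency score 1-3, or `NA` when certainty is 0.
#' @export
endpoint_potency <- function(certainty, inputs = list(),
                             endpoint = c("ed", "rd", "carc", "nt"),
                             rules = default_rules()) {
  endpoint <- match.arg(endpoint)
  stopifnot(certainty %in% 0:3)
  if (certainty == 0) return(NA_real_)
  if (certainty < 3) return(rules$low_certainty_potency)
  if (endpoint == "nt") return(rules$nt_potency)
  if (endpoint == "carc") {
    has_td50 <- !is_missing_value(inputs$td50_mouse) ||
      !is_missing_value(inputs$td50_rat)
    if (!has_td50) {
      warning("known carcinogen with no TD50; potency defaulted to 1")
      return(1)
    }
    return(potency_from_td50(inputs$td50_mouse %||% NA,
                             inputs$td50_rat %||% NA, rules))
  }
  noael <- if (!is_missing_value(inputs$noael)) {
    inputs$noael
  } else if (!is_missing_value(inputs$loael)) {
    loael_to_noael(inputs$loael, rules$loael_uf)
  } else if (!is_missing_value(inputs$rfd) && !is_missing_value(inputs$uf)) {
    rfd_to_noael(inputs$rfd, inputs$uf)
  } else {
    NA_real_
  }
  if (is.na(noael)) {
    warning("known ", endpoint, " toxicant with no dose input; potency defaulted to 1")
    return(1)
  }
  potency_from_noael(noael, endpoint, rules)
}

#' Toxicity score for one chemical
#'
#' Evaluates the toxicity equation: the sum over the four endpoints of
#' certainty times potency. Pre-assigned potency scores in the profile win;
#' otherwise the potency is derived from the profile's dose inputs via
#' [endpoint_potency()]. Certainty 0 contributes 0 regardless of potency.
#'
#' @param profile One-row profile tibble.
#' @inheritParams score_lifestage
#' @return A list of class `toxicity_breakdown` with per-endpoint
#'   `certainty`, `potency`, `product`, and `total`.
#' @examples
#' toxicity_score(chemical_profile(bundled_profiles(), "dibutyl phthalate"))$total
#' @export
toxicity_score <- function(profile, rules = default_rules()) {
  p <- as.list(profile)
  out <- list()
  total <- 0
  for (e in endpoint_keys) {
    certainty <- p[[paste0(e, "_certainty")]]
    if (is_missing_value(certainty)) certainty <- 0
    stopifnot(certainty %in% 0:3)
    potency <- p[[paste0(e, "_potency")]]
    if (is_missing_value(potency)) {
      inputs <- list(
        noael = p[[paste0(e, "_noael")]],
        loael = p[[paste0(e, "_loael")]],
        rfd = p[[paste0(e, "_rfd")]],
        uf = p[[paste0(e, "_uf")]],
        td50_mouse = p$carc_td50_mouse,
        td50_rat = p$carc_td50_rat
      )
      potency <- endpoint_potency(certainty, inputs, e, rules)
    }
    product <- if (certainty == 0) 0 else certainty * potency
    out[[e]] <- list(certainty = certainty,
                     potency = if (certainty == 0) NA_real_ else potency,
                     product = product)
    total <- total + product
  }
  out$total <- total
  structure(out, class = "toxicity_breakdown")
}

#' @export
print.toxicity_breakdown <- function(x, ...) {
  parts <- vapply(endpoint_keys, function(e) {
    sprintf("%s %g", toupper(e), x[[e]]$product)
  }, character(1))
  cat("<toxicity_breakdown> total ", x$total, " = ",
      paste(parts, collapse = " + "), "\n", sep = "")
  invisible(x)
}
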