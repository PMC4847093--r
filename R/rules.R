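#' Canonical CSPA product segments
#'
#' The eleven product-segment categories used in CSPA reporting. Segment
#' strings are matched case-insensitively after whitespace/punctuation
#' normalization; anything else is treated as an unknown segment and scored
#' with documented fallbacks (never silently).
#'
#' @return Character vector of the 11 canonical segment names.
#' @export
cspa_segments <- function() {
  c(
    "Clothing",
    "Footwear",
    "Toys/Games",
    "Kitchen Merchandise",
    "Baby Care",
    "Beauty/Personal Care/Hygiene",
    "Arts/Crafts/Needlework",
    "Household/Office Furniture/Furnishings",
    "Personal Accessories",
    "Camping",
    "Stationery/Office Machinery/Occasion Supplies"
  )
}

#' Canonical concentration bin tokens
#'
#' CSPA concentration ranges are reported as one of six bins. The canonical
#' serialized tokens are `lt100`, `100-500`, `500-1000`, `1000-5000`,
#' `5000-10000`, `gt10000` (ppm); typographic variants such as `"<100"`,
#' `"100–500"` or `">10,000"` are normalized on read.
#'
#' @return Character vector of the six bin tokens, in increasing order.
#' @export
concentration_bins <- function() {
  c("lt100", "100-500", "500-1000", "1000-5000", "5000-10000", "gt10000")
}

#' Default scoring rule set
#'
#' Returns the framework's default rule set: every cutoff, bin edge and
#' constant used by the exposure and toxicity scoring equations. All values
#' can be overridden via [read_rules()] / the `overrides` argument.
#'
#' Key entries:
#' \describe{
#'   \item{lifestage_map}{under_three -> 3, three_to_twelve -> 1.}
#'   \item{concentration_map}{six bins -> 0.5, 1, 1.5, 2, 2.5, 3.}
#'   \item{long_term_segments / duration_scores}{segments assumed long-term
#'     score 3, all others 1.}
#'   \item{applied_to_skin_segments / applied_scores}{direct skin application
#'     scores 3, all others 1.}
#'   \item{route_mf}{modifying factors: primary 3, secondary 2, tertiary 1.}
#'   \item{solubility_cutoffs}{mol/L edges 0.001, 0.01 mapping to scores
#'     1/2/3.}
#'   \item{vp_cutoffs}{mmHg at 25 C edges 0.075, 32.}
#'   \item{kp_cutoffs}{cm/h tertile edges 3.395e-3, 6.7e-3.}
#'   \item{absorption_cutoffs}{percent edges 5, 10 (scores 1/2/3); with
#'     `absorption_high_above_5 = TRUE` anything above 5% scores 3 instead.}
#'   \item{unknown_rate_score}{absorbed-at-unknown-rate marker scores 2.}
#'   \item{rd_noael_cutoffs / ed_noael_cutoffs}{NOAEL-equivalent (mg/kg)
#'     potency tertile edges: RD 200/397, ED 336/667 (above top edge scores
#'     1, below bottom edge scores 3).}
#'   \item{td50_cutoffs}{carcinogenic TD50 (mg/kg/day) edges 233/465.}
#'   \item{low_certainty_potency}{potency 1 for potential/suspected
#'     toxicants.}
#'   \item{nt_potency}{constant neurotoxicant potency, default 2.}
#'   \item{loael_uf}{uncertainty factor 10 converting LOAEL to a
#'     NOAEL-equivalent.}
#' }
#'
#' @param overrides Optional named list; entries replace the corresponding
#'   defaults (unknown keys are an error).
#' @return A `cspa_rules` object (named list).
#' @examples
#' rules <- default_rules()
#' rules$lifestage_map[["under_three"]]
#' rules2 <- default_rules(overrides = list(nt_potency = 3))
#' @export
default_rules <- function(overrides = NULL) {
  bins <- concentration_bins()
  conc <- c(0.5, 1, 1.5, 2, 2.5, 3)
  names(conc) <- bins
  rules <- list(
    lifestage_map = c(under_three = 3, three_to_twelve = 1),
    concentration_map = conc,
    long_term_segments = c(
      "Clothing", "Footwear", "Beauty/Personal Care/Hygiene", "Camping"
    ),
    duration_scores = c(short_term = 1, long_term = 3),
    applied_to_skin_segments = "Beauty/Personal Care/Hygiene",
    applied_scores = c(no = 1, yes = 3),
    route_mf = c(tertiary = 1, secondary = 2, primary = 3),
    dermal_primary_segments = c(
      "Clothing", "Beauty/Personal Care/Hygiene", "Footwear",
      "Arts/Crafts/Needlework", "Household/Office Furniture/Furnishings",
      "Camping", "Personal Accessories", "Toys/Games"
    ),
    oral_primary_segments = "Kitchen Merchandise",
    solubility_cutoffs = c(0.001, 0.01),
    vp_cutoffs = c(0.075, 32),
    kp_cutoffs = c(3.395e-3, 6.7e-3),
    absorption_cutoffs = c(5, 10),
    absorption_high_above_5 = FALSE,
    unknown_rate_score = 2,
    rd_noael_cutoffs = c(200, 397),
    ed_noael_cutoffs = c(336, 667),
    td50_cutoffs = c(233, 465),
    low_certainty_potency = 1,
    nt_potency = 2,
    loael_uf = 10
  )
  if (!is.null(overrides)) {
    stopifnot(is.list(overrides))
    unknown <- setdiff(names(overrides), names(rules))
    if (length(unknown) > 0) {
      stop("unknown rule key(s): ", paste(unknown, collapse = ", "))
    }
    for (k in names(overrides)) {
      v <- overrides[[k]]
      if (is.list(v)) v <- unlist(v)
      if (!is.null(names(rules[[k]])) && is.null(names(v)) &&
          length(v) == length(rules[[k]])) {
        names(v) <- names(rules[[k]])
      }
      rules[[k]] <- v
    }
  }
  structure(rules, class = "cspa_rules")
}

#' @export
print.cspa_rules <- function(x, ...) {
  cat("<cspa_rules> ", length(x), " rule entries, hash ", rules_hash(x),
      "\n", sep = "")
  invisible(x)
}

validate_rules <- function(rules) {
  stopifnot(inherits(rules, "cspa_rules"))
  mono <- function(v) all(diff(v) > 0)
  for (k in c("solubility_cutoffs", "vp_cutoffs", "kp_cutoffs",
              "absorption_cutoffs", "rd_noael_cutoffs", "ed_noael_cutoffs",
              "td50_cutoffs", "concentration_map")) {
    if (!mono(unname(rules[[k]]))) {
      stop("rule '", k, "' must be strictly increasing")
    }
  }
  stopifnot(
    all(rules$route_mf %in% 1:3),
    all(rules$lifestage_map %in% c(1, 3)),
    rules$loael_uf > 0
  )
  invisible(rules)
}

#' Read / write a rule-set config file
#'
#' The rule set round-trips losslessly through a YAML config file. A partial
#' file is allowed: keys present override the defaults, everything else
#' inherits from [default_rules()].
#'
#' @param path Path to a YAML file.
#' @param rules A `cspa_rules` object.
#' @return `read_rules()` returns a `cspa_rules` object; `write_rules()`
#'   returns `path` invisibly.
#' @export
read_rules <- function(path) {
  raw <- yaml::read_yaml(path)
  rules <- default_rules(overrides = raw)
  validate_rules(rules)
}

#' @rdname read_rules
#' @export
write_rules <- function(rules, path) {
  validate_rules(rules)
  yaml::write_yaml(lapply(unclass(rules), function(v) {
    if (!is.null(names(v))) as.list(v) else v
  }), path)
  invisible(path)
}

#' Tertile cutoffs from observed potency values
#'
#' Helper for re-deriving potency bin edges from a novel chemical set: the
#' default NOAEL / TD50 cutoffs are the tertiles of the doses observed in the
#' bundled CSPA set, and the same construction can be applied to any vector
#' of NOAEL-equivalents (or TD50s) and passed back in through the rules
#' (e.g. `default_rules(overrides = list(rd_noael_cutoffs = tertile_cutoffs(x)))`).
#'
#' @param values Numeric vector of positive doses.
#' @return Length-2 numeric vector: the 1/3 and 2/3 quantiles.
#' @export
tertile_cutoffs <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 3) stop("need at least 3 values to form tertiles")
  if (any(values <= 0)) stop("doses must be positive")
  unname(stats::quantile(values, probs = c(1 / 3, 2 / 3), type = 7))
}
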