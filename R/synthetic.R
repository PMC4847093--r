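# Seeded generator of CSPA-like report databases. Records are independent
# draws from configurable categorical marginals (segment, chemical, age,
# concentration bin); the true joint distribution of the state database is
# unpublished, so only the marginals are emulated.

# segment weights proportional to the reported per-segment record counts
default_segment_weights <- function() {
  counts <- c(
    "Kitchen Merchandise" = 72,
    "Stationery/Office Machinery/Occasion Supplies" = 365,
    "Toys/Games" = 4910,
    "Arts/Crafts/Needlework" = 631,
    "Household/Office Furniture/Furnishings" = 1446,
    "Baby Care" = 991,
    "Footwear" = 4940,
    "Personal Accessories" = 1229,
    "Clothing" = 14551,
    "Camping" = 87,
    "Beauty/Personal Care/Hygiene" = 559
  )
  counts / sum(counts)
}

# chemical weights proportional to the per-chemical report counts of the
# bundled chemical set
default_chemical_weights <- function() {
  counts <- c(
    dibutyl_phthalate = 778, di_2_ethylhexyl_phthalate = 909,
    formaldehyde = 533, butyl_benzyl_phthalate = 610, styrene = 2251,
    diisodecyl_phthalate = 235, methyl_ethyl_ketone = 2378,
    di_n_hexyl_phthalate = 178, butyl_paraben = 83, ethylene_glycol = 6042,
    ethyl_paraben = 97, cobalt = 6927, diethyl_phthalate = 380,
    antimony = 3378, diisononyl_phthalate = 357, di_n_octyl_phthalate = 279,
    octamethylcyclotetrasiloxane = 2123, methyl_paraben = 251,
    molybdenum = 1617, phthalic_anhydride = 137, propyl_paraben = 207
  )
  counts / sum(counts)
}

#' Generator configuration
#'
#' Configuration for the synthetic CSPA-like report generator. Defaults:
#' segment weights proportional to the per-segment report counts of the
#' state database, chemical weights proportional to the bundled set's
#' report counts, under-three fraction 0.3, concentration weights mildly
#' decreasing with the bin (low concentrations are reported most often),
#' and no special-brick injection (turned on in the `edge_cases` scenario).
#'
#' @param n_reports Number of records to draw (>= 0).
#' @param seed Integer seed; generation is deterministic given the seed.
#' @param segment_weights Named probability vector over segments.
#' @param under_three_fraction Probability a record targets under-3.
#' @param concentration_weights Named probability vector over the six bins.
#' @param chemical_weights Named probability vector over chemical ids.
#' @param brick_injection_rates Named probability vector; each draw may
#'   inject one special brick (`pacifier`, `kitchen toy`, `paint`,
#'   `party blower`, `fragrance`) with the given probability.
#' @return A `generator_config` object (validated list).
#' @export
generator_config <- function(n_reports = 1000,
                             seed = 1L,
                             segment_weights = default_segment_weights(),
                             under_three_fraction = 0.3,
                             concentration_weights = c(
                               "lt100" = 0.30, "100-500" = 0.25,
                               "500-1000" = 0.18, "1000-5000" = 0.12,
                               "5000-10000" = 0.09, "gt10000" = 0.06
                             ),
                             chemical_weights = default_chemical_weights(),
                             brick_injection_rates = c(
                               pacifier = 0, `kitchen toy` = 0, paint = 0,
                               `party blower` = 0, fragrance = 0
                             )) {
  cfg <- list(
    n_reports = n_reports, seed = as.integer(seed),
    segment_weights = segment_weights,
    under_three_fraction = under_three_fraction,
    concentration_weights = concentration_weights,
    chemical_weights = chemical_weights,
    brick_injection_rates = brick_injection_rates
  )
  chk <- function(w, what, must_sum = TRUE) {
    if (any(is.na(w)) || any(w < 0)) stop(what, " must be non-negative")
    if (must_sum && abs(sum(w) - 1) > 1e-8) stop(what, " must sum to 1")
  }
  if (cfg$n_reports < 0) stop("n_reports must be >= 0")
  chk(cfg$segment_weights, "segment_weights")
  chk(cfg$concentration_weights, "concentration_weights")
  chk(cfg$chemical_weights, "chemical_weights")
  if (cfg$under_three_fraction < 0 || cfg$under_three_fraction > 1) {
    stop("under_three_fraction must be a probability")
  }
  chk(cfg$brick_injection_rates, "brick_injection_rates", must_sum = FALSE)
  if (sum(cfg$brick_injection_rates) > 1) {
    stop("brick_injection_rates must sum to at most 1")
  }
  structure(cfg, class = "generator_config")
}

#' Generate synthetic CSPA-like reports
#'
#' Draws `n_reports` independent records from the configured categorical
#' distributions using R's Mersenne-Twister generator seeded from
#' `config$seed` (the global random state is left untouched). Every
#' generated record passes [validate_report()] by construction.
#'
#' @param config A [generator_config()].
#' @return Tibble of valid product reports.
#' @examples
#' reports <- generate_reports(generator_config(n_reports = 5, seed = 42))
#' @export
generate_reports <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  n <- config$n_reports
  withr::with_seed(config$seed, {
    segments <- sample(names(config$segment_weights), n, replace = TRUE,
                       prob = config$segment_weights)
    chems <- sample(names(config$chemical_weights), n, replace = TRUE,
                    prob = config$chemical_weights)
    ages <- ifelse(stats::runif(n) < config$under_three_fraction,
                   "under_three", "three_to_twelve")
    bins <- sample(names(config$concentration_weights), n, replace = TRUE,
                   prob = config$concentration_weights)
    bricks <- rep(NA_character_, n)
    rates <- config$brick_injection_rates
    if (sum(rates) > 0) {
      u <- stats::runif(n)
      edges <- cumsum(rates)
      for (k in seq_along(rates)) {
        lo <- if (k == 1) 0 else edges[k - 1]
        bricks[u >= lo & u < edges[k]] <- names(rates)[k]
      }
    }
    tibble::tibble(
      report_id = sprintf("syn%06d", seq_len(n)),
      chemical_id = chems,
      segment = segments,
      segment_known = TRUE,
      brick = bricks,
      target_age = ages,
      concentration_bin = bins,
      chemical_function = NA_character_
    )
  })
}

#' Built-in test scenarios
#'
#' `"cspa_like"` pairs the bundled 21-chemical profile set with a
#' segment-weighted synthetic report database. `"edge_cases"` pairs the
#' profiles with a small hand-built report set that exercises every
#' routing rule (paint, party blower, fragrance, pacifier, kitchen toy,
#' under-3 with non-oral primary, unknown segment) and every concentration
#' bin.
#'
#' @param name `"cspa_like"` or `"edge_cases"`.
#' @param n_reports Number of synthetic reports for `"cspa_like"`.
#' @param seed Seed for `"cspa_like"`.
#' @return List with `reports` and `profiles`.
#' @export
scenario_fixture <- function(name = c("cspa_like", "edge_cases"),
                             n_reports = 1000, seed = 1L) {
  name <- match.arg(name)
  profiles <- bundled_profiles()
  if (name == "cspa_like") {
    reports <- generate_reports(generator_config(n_reports = n_reports,
                                                 seed = seed))
    return(list(reports = reports, profiles = profiles))
  }
  bins <- concentration_bins()
  raw <- tibble::tibble(
    report_id = sprintf("edge%02d", 1:10),
    chemical_id = c(
      "formaldehyde", "styrene", "dibutyl_phthalate", "methyl_ethyl_ketone",
      "butyl_paraben", "ethylene_glycol", "antimony", "cobalt",
      "octamethylcyclotetrasiloxane", "molybdenum"
    ),
    segment = c(
      "Arts/Crafts/Needlework",          # paint brick
      "Stationery/Office Machinery/Occasion Supplies", # party blower
      "Beauty/Personal Care/Hygiene",    # fragrance brick
      "Baby Care",                       # pacifier brick
      "Toys/Games",                      # kitchen toy brick
      "Clothing",                        # under-3 non-oral primary
      "Kitchen Merchandise",             # oral-primary segment
      "Craft Supplies",                  # unknown segment
      "Footwear",
      "Camping"
    ),
    brick = c("paint", "party blower", "fragrance", "pacifier",
              "kitchen toy", NA, NA, NA, NA, NA),
    target_age = c("three_to_twelve", "three_to_twelve", "three_to_twelve",
                   "under_three", "under_three", "under_three",
                   "three_to_twelve", "three_to_twelve", "three_to_twelve",
                   "under_three"),
    concentration_bin = c(bins, bins[1:4])
  )
  reports <- suppressWarnings(validate_reports(raw))$reports
  list(reports = reports, profiles = profiles)
}
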