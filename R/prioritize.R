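# Priority indices: total priority index = exposure x toxicity (a rank,
# not a risk estimate) and endpoint-specific scores = exposure x certainty
# x potency. Aggregation by chemical / group / segment, quadrant
# classification around the medians, PCA of score drivers and rank
# concordance against external schemes.

#' Score a report dataset
#'
#' Scores every report against its chemical profile: exposure breakdown,
#' toxicity breakdown, total priority index and the four endpoint-specific
#' priority scores. Reports whose `chemical_id` has no profile are
#' collected in a rejection table, never dropped silently.
#'
#' @param reports Tibble of validated reports (see [validate_reports()]).
#' @param profiles Profile tibble (default the bundled CSPA set).
#' @inheritParams score_lifestage
#' @return List with `scored` (one row per scored report: identifiers,
#'   additive exposure block, per-route components, exposure score,
#'   per-endpoint toxicity products, toxicity score, `total_priority_index`
#'   and `ed_score`/`rd_score`/`carc_score`/`nt_score`) and `rejections`
#'   (report rows with unknown chemicals).
#' @export
score_dataset <- function(reports, profiles = bundled_profiles(),
                          rules = default_rules()) {
  reports <- tibble::as_tibble(reports)
  empty <- tibble::tibble(
    report_id = character(), chemical_id = character(), name = character(),
    group = character(), segment = character(), brick = character(),
    target_age = character(), concentration_bin = character(),
    ls = numeric(), ex = numeric(), a = numeric(), con = numeric(),
    oral_mf = numeric(), dermal_mf = numeric(), inhalation_mf = numeric(),
    oral_component = numeric(), dermal_component = numeric(),
    inhalation_component = numeric(), exposure_score = numeric(),
    ed_product = numeric(), rd_product = numeric(), carc_product = numeric(),
    nt_product = numeric(), toxicity_score = numeric(),
    total_priority_index = numeric(), ed_score = numeric(),
    rd_score = numeric(), carc_score = numeric(), nt_score = numeric()
  )
  if (nrow(reports) == 0) {
    return(list(scored = empty, rejections = reports))
  }

  key <- normalize_chemical_name(profiles$chemical_id)
  idx <- match(normalize_chemical_name(reports$chemical_id), key)
  rejections <- reports[is.na(idx), , drop = FALSE]
  keep <- which(!is.na(idx))

  # toxicity is per-chemical: compute once per profile row used
  tox_cache <- list()
  rows <- vector("list", length(keep))
  for (j in seq_along(keep)) {
    i <- keep[j]
    prof <- profiles[idx[i], , drop = FALSE]
    cid <- prof$chemical_id
    if (is.null(tox_cache[[cid]])) tox_cache[[cid]] <- toxicity_score(prof, rules)
    tox <- tox_cache[[cid]]
    expb <- exposure_score(reports[i, , drop = FALSE], prof, rules)
    tpi <- expb$total * tox$total
    rows[[j]] <- tibble::tibble(
      report_id = reports$report_id[i],
      chemical_id = cid,
      name = prof$name,
      group = prof$group,
      segment = reports$segment[i],
      brick = reports$brick[i] %||% NA_character_,
      target_age = reports$target_age[i],
      concentration_bin = reports$concentration_bin[i],
      ls = expb$ls, ex = expb$ex, a = expb$a, con = expb$con,
      oral_mf = expb$oral$mf, dermal_mf = expb$dermal$mf,
      inhalation_mf = expb$inhalation$mf,
      oral_component = expb$oral$component,
      dermal_component = expb$dermal$component,
      inhalation_component = expb$inhalation$component,
      exposure_score = expb$total,
      ed_product = tox$ed$product, rd_product = tox$rd$product,
      carc_product = tox$carc$product, nt_product = tox$nt$product,
      toxicity_score = tox$total,
      total_priority_index = tpi,
      ed_score = expb$total * tox$ed$product,
      rd_score = expb$total * tox$rd$product,
      carc_score = expb$total * tox$carc$product,
      nt_score = expb$total * tox$nt$product
    )
  }
  scored <- if (length(rows) > 0) dplyr::bind_rows(rows) else empty
  list(scored = scored, rejections = rejections)
}

pop_sd <- function(x) {
  if (length(x) <= 1) return(0)
  sqrt(mean((x - mean(x))^2))
}

#' Aggregate scored reports
#'
#' Per-key report counts, means and population standard deviations of the
#' exposure score and total priority index, sorted by descending mean index
#' (ties broken by key name, ascending).
#'
#' @param scored Scored-report tibble from [score_dataset()].
#' @param key Aggregation key: `"chemical"`, `"group"` or `"segment"`.
#' @return Tibble with `key`, `n_reports`, `mean_exposure`, `sd_exposure`,
#'   `mean_index`, `sd_index`.
#' @export
aggregate_scores <- function(scored, key = c("chemical", "group", "segment")) {
  key <- match.arg(key)
  if (nrow(scored) == 0) stop("no scored records to aggregate")
  col <- switch(key, chemical = "name", group = "group", segment = "segment")
  out <- scored |>
    dplyr::group_by(key = .data[[col]]) |>
    dplyr::summarise(
      n_reports = dplyr::n(),
      mean_exposure = mean(.data$exposure_score),
      sd_exposure = pop_sd(.data$exposure_score),
      mean_index = mean(.data$total_priority_index),
      sd_index = pop_sd(.data$total_priority_index),
      .groups = "drop"
    )
  out[order(-out$mean_index, out$key), , drop = FALSE]
}

#' Quadrant classification of chemicals
#'
#' Places each chemical relative to the median mean-exposure score
#' (horizontal axis) and median toxicity score (vertical axis) across
#' chemicals: `high-high` (most concern), `high-exposure/low-toxicity`,
#' `low-exposure/high-toxicity`, `low-low`. Values exactly at a median
#' count as "high" (documented tie rule). Chemicals with toxicity 0 are
#' additionally flagged `no_toxicity_data` — absence of evidence in the
#' consulted databases, not evidence of safety.
#'
#' @param scored Scored-report tibble from [score_dataset()].
#' @return Tibble with one row per chemical: `name`, `mean_exposure`,
#'   `toxicity_score`, `quadrant`, `no_toxicity_data`.
#' @export
quadrant_classify <- function(scored) {
  per_chem <- scored |>
    dplyr::group_by(.data$name) |>
    dplyr::summarise(
      mean_exposure = mean(.data$exposure_score),
      toxicity_score = .data$toxicity_score[1],
      .groups = "drop"
    )
  if (nrow(per_chem) < 2) stop("need at least 2 chemicals to classify")
  med_exp <- stats::median(per_chem$mean_exposure)
  med_tox <- stats::median(per_chem$toxicity_score)
  hi_e <- per_chem$mean_exposure >= med_exp
  hi_t <- per_chem$toxicity_score >= med_tox
  per_chem$quadrant <- dplyr::case_when(
    hi_e & hi_t ~ "high-high",
    hi_e & !hi_t ~ "high-exposure/low-toxicity",
    !hi_e & hi_t ~ "low-exposure/high-toxicity",
    TRUE ~ "low-low"
  )
  per_chem$no_toxicity_data <- per_chem$toxicity_score == 0
  per_chem
}

#' Principal component analysis of score drivers
#'
#' Builds the per-chemical variable table — the four endpoint toxicity
#' products (ED, RD, Carc, NT) plus the mean additive exposure variables
#' (LS, EX, A, Con) and the mean oral/dermal/inhalation route components —
#' then runs a correlation PCA (columns centered and scaled to unit
#' variance; zero-variance columns dropped with a warning).
#'
#' @param scored Scored-report tibble from [score_dataset()].
#' @return A list of class `cspa_pca`: `variables` (the columns used),
#'   `scores` (chemicals x components), `loadings`, `variance_fraction`,
#'   and `table` (the per-chemical input matrix).
#' @export
pca_analysis <- function(scored) {
  tab <- scored |>
    dplyr::group_by(.data$name) |>
    dplyr::summarise(
      ed = .data$ed_product[1], rd = .data$rd_product[1],
      carc = .data$carc_product[1], nt = .data$nt_product[1],
      ls = mean(.data$ls), ex = mean(.data$ex), a = mean(.data$a),
      con = mean(.data$con),
      oral = mean(.data$oral_component),
      dermal = mean(.data$dermal_component),
      inhalation = mean(.data$inhalation_component),
      .groups = "drop"
    )
  if (nrow(tab) < 3) stop("need at least 3 chemicals for a PCA")
  m <- as.matrix(tab[, -1])
  rownames(m) <- tab$name
  keep <- apply(m, 2, stats::sd) > 0
  if (any(!keep)) {
    warning("dropping zero-variance variable(s): ",
            paste(colnames(m)[!keep], collapse = ", "))
  }
  m <- m[, keep, drop = FALSE]
  fit <- stats::prcomp(m, center = TRUE, scale. = TRUE)
  structure(list(
    variables = colnames(m),
    scores = fit$x,
    loadings = fit$rotation,
    variance_fraction = fit$sdev^2 / sum(fit$sdev^2),
    table = tab
  ), class = "cspa_pca")
}

#' @export
print.cspa_pca <- function(x, ...) {
  cat("<cspa_pca> ", nrow(x$scores), " chemicals x ", length(x$variables),
      " variables\n", sep = "")
  vf <- round(100 * x$variance_fraction[1:min(2, length(x$variance_fraction))], 1)
  cat("  PC1 ", vf[1], "% of variance",
      if (length(vf) > 1) paste0(", PC2 ", vf[2], "%"), "\n", sep = "")
  cat("  variables: ", paste(x$variables, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Rank concordance against an external score table
#'
#' Joins the framework's per-chemical scores against an external
#' prioritization scheme on normalized chemical name and reports the
#' overlap, Spearman rank correlation, a discordance list (chemicals in the
#' top tertile of one scheme and the bottom tertile of the other), and the
#' chemicals not shared. External scores are compared by rank only; no
#' attempt is made to place the two schemes on a common scale.
#'
#' @param chem_scores Tibble with columns `name` and `score` (the
#'   framework's per-chemical values, e.g. mean index or ED score).
#' @param external Tibble/data frame with columns `name` and `score`.
#' @return A list of class `concordance_report`: `n_overlap`, `spearman`,
#'   `merged` (per-chemical paired scores and ranks), `discordant`,
#'   `not_shared`.
#' @export
compare_external <- function(chem_scores, external) {
  a <- tibble::tibble(
    key = normalize_chemical_name(chem_scores$name),
    name = chem_scores$name, score_internal = chem_scores$score
  )
  b <- tibble::tibble(
    key = normalize_chemical_name(external$name),
    name_external = external$name, score_external = external$score
  )
  merged <- dplyr::inner_join(a, b, by = "key")
  if (nrow(merged) < 3) {
    stop("need at least 3 overlapping chemicals; overlap: ",
         if (nrow(merged) == 0) "(none)" else paste(merged$name, collapse = ", "))
  }
  merged$rank_internal <- rank(-merged$score_internal, ties.method = "average")
  merged$rank_external <- rank(-merged$score_external, ties.method = "average")
  rho <- stats::cor(merged$score_internal, merged$score_external,
                    method = "spearman")
  n <- nrow(merged)
  top <- function(r) r <= n / 3
  bottom <- function(r) r > 2 * n / 3
  disc <- merged[(top(merged$rank_internal) & bottom(merged$rank_external)) |
                   (top(merged$rank_external) & bottom(merged$rank_internal)), ]
  structure(list(
    n_overlap = n,
    spearman = rho,
    merged = merged,
    discordant = disc,
    not_shared = list(
      internal_only = setdiff(a$name[!a$key %in% b$key], character()),
      external_only = setdiff(b$name_external[!b$key %in% a$key], character())
    )
  ), class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat("<concordance_report> ", x$n_overlap, " shared chemicals, Spearman rho ",
      round(x$spearman, 3), "\n", sep = "")
  if (nrow(x$discordant) > 0) {
    cat("  discordant: ", paste(x$discordant$name, collapse = ", "), "\n",
        sep = "")
  }
  if (length(x$not_shared$external_only) + length(x$not_shared$internal_only) > 0) {
    cat("  not shared: ",
        length(x$not_shared$internal_only), " internal-only, ",
        length(x$not_shared$external_only), " external-only\n", sep = "")
  }
  invisible(x)
}
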