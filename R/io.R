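# File I/O: report CSVs, scored-output CSVs with provenance headers, run
# manifests. Dialect: comma-delimited UTF-8 with a header row; "NI" and
# empty cells are missing on read; provenance lines start with '#'.

#' Read a report table from CSV
#'
#' Reads raw report records and validates every row; lines starting with
#' `#` are treated as comments. Returns accepted reports plus a rejection
#' table (validation is total — nothing is silently coerced or dropped).
#'
#' @param path CSV path with columns `chemical_id`, `segment`,
#'   `target_age`, `concentration_bin` and optionally `report_id`, `brick`,
#'   `function`.
#' @return List as returned by [validate_reports()].
#' @export
read_reports <- function(path) {
  if (!file.exists(path)) stop("cannot read report file: ", path)
  df <- utils::read.csv(path, comment.char = "#",
                        na.strings = c("NA", "NI", ""),
                        stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("chemical_id", "segment", "target_age", "concentration_bin")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("malformed report header; missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (nrow(df) == 0) stop("empty report table: ", path)
  validate_reports(df)
}

#' Write a table with a provenance header
#'
#' Writes a CSV preceded by `#`-prefixed provenance lines (rule-set hash,
#' input names, seed, timestamp) so every output is traceable to the run
#' that produced it. The package's own readers skip these lines.
#'
#' @param x Data frame to write.
#' @param path Output path.
#' @param provenance Named list of provenance fields (e.g. `rules_hash`,
#'   `inputs`, `seed`); a `timestamp` line is added automatically.
#' @return `path`, invisibly.
#' @export
write_output_csv <- function(x, path, provenance = list()) {
  provenance$timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  for (k in names(provenance)) {
    writeLines(sprintf("# %s: %s", k,
                       paste(provenance[[k]], collapse = ", ")), con)
  }
  utils::write.csv(as.data.frame(x), con, row.names = FALSE, na = "NI")
  invisible(path)
}

#' Read a table written by [write_output_csv()]
#'
#' @param path CSV path.
#' @return Tibble (provenance comment lines skipped).
#' @export
read_output_csv <- function(path) {
  tibble::as_tibble(
    utils::read.csv(path, comment.char = "#",
                    na.strings = c("NA", "NI", ""),
                    stringsAsFactors = FALSE, check.names = FALSE)
  )
}

#' Write a run manifest
#'
#' Every pipeline run writes a JSON manifest recording inputs, rule
#' overrides, seed, record counts (read = accepted + rejected) and output
#' paths — including failed runs, so a run is always auditable.
#'
#' @param manifest Named list; recognized fields include `inputs`,
#'   `rules_hash`, `overrides`, `seed`, `n_read`, `n_accepted`,
#'   `n_rejected`, `outputs`, `status`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  if (!is.null(manifest$n_read)) {
    stopifnot(manifest$n_read == (manifest$n_accepted %||% 0) +
                (manifest$n_rejected %||% 0))
  }
  manifest$timestamp <- manifest$timestamp %||%
    format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Score a report file end to end
#'
#' Convenience pipeline behind the command-line `score` subcommand: reads
#' and validates reports, scores them against the profiles, and writes the
#' scored CSV, the rejection CSV and a run manifest into `out_dir`.
#'
#' @param reports_path Report CSV path.
#' @param profiles_path Optional profile CSV/JSON path (default: bundled
#'   profiles).
#' @param rules_path Optional YAML rule-override file.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the list from [score_dataset()] plus `manifest`.
#' @export
run_scoring <- function(reports_path, profiles_path = NULL,
                        rules_path = NULL, out_dir = ".") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rules <- if (is.null(rules_path)) default_rules() else read_rules(rules_path)
  profiles <- if (is.null(profiles_path)) bundled_profiles() else
    read_profiles(profiles_path)
  val <- read_reports(reports_path)
  res <- score_dataset(val$reports, profiles, rules)
  prov <- list(
    rules_hash = rules_hash(rules),
    inputs = c(reports_path, profiles_path %||% "bundled profiles")
  )
  scored_path <- file.path(out_dir, "scored_records.csv")
  rej_path <- file.path(out_dir, "rejections.csv")
  write_output_csv(res$scored, scored_path, prov)
  rejections <- dplyr::bind_rows(
    val$rejections,
    if (nrow(res$rejections) > 0) {
      tibble::tibble(row = NA_integer_,
                     reasons = paste0("unknown chemical: ",
                                      res$rejections$chemical_id))
    }
  )
  write_output_csv(rejections, rej_path, prov)
  manifest <- list(
    inputs = prov$inputs,
    rules_hash = prov$rules_hash,
    n_read = val$n_read,
    n_accepted = val$n_accepted - nrow(res$rejections),
    n_rejected = val$n_rejected + nrow(res$rejections),
    outputs = c(scored_path, rej_path),
    status = "ok"
  )
  write_manifest(manifest, file.path(out_dir, "manifest.json"))
  invisible(c(res, list(manifest = manifest)))
}
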