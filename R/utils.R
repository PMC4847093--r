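`%||%` <- function(x, y) if (is.null(x)) y else x

is_missing_value <- function(x) {
  is.null(x) || length(x) == 0L || all(is.na(x))
}

#' Normalize a label for matching
#'
#' Lower-cases, trims, and collapses all runs of whitespace, punctuation and
#' dashes to single spaces, so that e.g. `"Toys/Games"`, `"toys  games"` and
#' `"Toys-Games"` compare equal.
#'
#' @param x Character vector.
#' @return Normalized character vector.
#' @keywords internal
normalize_label <- function(x) {
  x <- tolower(trimws(as.character(x)))
  x <- gsub("[^a-z0-9]+", " ", x)
  trimws(x)
}

#' Normalize a chemical name for joining
#'
#' Used when joining the package's per-chemical outputs against external
#' score tables: case, punctuation and whitespace are ignored.
#'
#' @param x Character vector of chemical names or ids.
#' @return Normalized character vector.
#' @export
normalize_chemical_name <- function(x) {
  gsub(" ", "", normalize_label(x), fixed = TRUE)
}

# stable per-rule-set fingerprint used in output provenance headers
rules_hash <- function(rules) {
  canon <- jsonlite::toJSON(unclass(rules), auto_unbox = TRUE, digits = NA)
  # small polynomial rolling hash over the canonical JSON; avoids a digest dep
  bytes <- utf8ToInt(as.character(canon))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
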