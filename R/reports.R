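#' Normalize a concentration-bin label to its canonical token
#'
#' Accepts the canonical tokens plus typographic variants of the six CSPA
#' ranges (`"<100"`, `"100–500"`, `"> 10,000"`, `"10,000+"`, ...).
#' Unrecognized labels return `NA_character_`; they are never coerced to a
#' bin.
#'
#' @param x Character vector of bin labels.
#' @return Character vector of canonical tokens (see [concentration_bins()])
#'   with `NA` where the label is not a recognized bin.
#' @export
normalize_concentration_bin <- function(x) {
  squash <- function(v) gsub("[^a-z0-9+<>]", "", tolower(as.character(v)))
  # en/em dashes become "-" pre-squash so ranges collapse consistently
  x0 <- gsub("[–—]", "-", as.character(x))
  x0 <- gsub("-", "to", x0)
  key <- squash(x0)
  lut <- c(
    "lt100" = "lt100", "<100" = "lt100", "under100" = "lt100",
    "100to500" = "100-500",
    "500to1000" = "500-1000",
    "1000to5000" = "1000-5000",
    "5000to10000" = "5000-10000",
    "gt10000" = "gt10000", ">10000" = "gt10000", "10000+" = "gt10000"
  )
  out <- unname(lut[key])
  out[is.na(match(key, names(lut)))] <- NA_character_
  out
}

normalize_target_age <- function(x) {
  key <- gsub("[^a-z0-9]", "", tolower(as.character(x)))
  lut <- c(
    "underthree" = "under_three", "under3" = "under_three",
    "threetotwelve" = "three_to_twelve", "3to12" = "three_to_twelve",
    "3plus" = "three_to_twelve", "threeplus" = "three_to_twelve"
  )
  out <- unname(lut[key])
  out[is.na(match(key, names(lut)))] <- NA_character_
  out
}

# canonicalize a segment string; NA when not one of the 11 known segments
match_segment <- function(segment) {
  canon <- cspa_segments()
  idx <- match(normalize_label(segment), normalize_label(canon))
  canon[idx]
}

#' Validate a raw product-report record
#'
#' Validates one raw record (a named list or one-row data frame) against the
#' report invariants: a `chemical_id` must be present, `target_age` must be
#' one of the two CSPA age classes and `concentration_bin` one of the six
#' CSPA ranges. Validation is total: the result is either a valid report row
#' or a structured rejection naming every violated field — no silent
#' coercion.
#'
#' @param record Named list (or one-row data frame) with fields
#'   `chemical_id`, `segment`, `target_age`, `concentration_bin`, and
#'   optionally `report_id`, `brick`, `function`.
#' @return A list with `valid` (logical), `report` (one-row tibble when
#'   valid), and `errors` (character vector of violated-field messages when
#'   invalid).
#' @examples
#' validate_report(list(chemical_id = "styrene", segment = "Clothing",
#'                      target_age = "under_three",
#'                      concentration_bin = "100-500"))
#' @export
validate_report <- function(record) {
  record <- as.list(record)
  errors <- character()

  chem <- record$chemical_id
  if (is_missing_value(chem) || !nzchar(trimws(as.character(chem)))) {
    errors <- c(errors, "chemical_id: missing")
    chem <- NA_character_
  }

  age <- normalize_target_age(record$target_age %||% NA)
  if (is.na(age)) {
    errors <- c(errors, sprintf(
      "target_age: '%s' is not one of under_three / three_to_twelve",
      as.character(record$target_age %||% NA)
    ))
  }

  bin <- normalize_concentration_bin(record$concentration_bin %||% NA)
  if (is.na(bin)) {
    errors <- c(errors, sprintf(
      "concentration_bin: '%s' is not one of the six CSPA ranges",
      as.character(record$concentration_bin %||% NA)
    ))
  }

  seg_raw <- as.character(record$segment %||% NA)
  seg <- match_segment(seg_raw)
  segment_known <- !is.na(seg)
  if (is_missing_value(seg_raw) || !nzchar(trimws(seg_raw))) {
    errors <- c(errors, "segment: missing")
  }

  if (length(errors) > 0) {
    return(list(valid = FALSE, report = NULL, errors = errors))
  }

  report <- tibble::tibble(
    report_id = as.character(record$report_id %||% NA_character_),
    chemical_id = as.character(chem),
    segment = if (segment_known) seg else trimws(seg_raw),
    segment_known = segment_known,
    brick = as.character(record$brick %||% NA_character_),
    target_age = age,
    concentration_bin = bin,
    chemical_function = as.character(record[["function"]] %||%
                                       record$chemical_function %||%
                                       NA_character_)
  )
  list(valid = TRUE, report = report, errors = character())
}

#' Validate a table of raw report records
#'
#' Applies [validate_report()] to every row and splits the result into
#' accepted reports and a rejection table (one row per rejected record with
#' the reasons collapsed); nothing is dropped silently.
#'
#' @param records Data frame of raw records.
#' @return List with `reports` (tibble of valid reports), `rejections`
#'   (tibble with `row`, `reasons`), and counts `n_read`, `n_accepted`,
#'   `n_rejected`.
#' @export
validate_reports <- function(records) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  n <- nrow(records)
  oks <- vector("list", n)
  rej <- list()
  for (i in seq_len(n)) {
    res <- validate_report(records[i, , drop = FALSE])
    if (res$valid) {
      row <- res$report
      if (is.na(row$report_id)) row$report_id <- sprintf("r%05d", i)
      oks[[i]] <- row
    } else {
      rej[[length(rej) + 1]] <- tibble::tibble(
        row = i, reasons = paste(res$errors, collapse = "; ")
      )
    }
  }
  reports <- dplyr::bind_rows(oks)
  rejections <- if (length(rej) > 0) dplyr::bind_rows(rej) else
    tibble::tibble(row = integer(), reasons = character())
  list(
    reports = reports, rejections = rejections,
    n_read = n, n_accepted = nrow(reports), n_rejected = nrow(rejections)
  )
}
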