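# Scan-sampling data model: read, validate, write, and per-scan counts.

scan_columns <- c(
  "scan_id", "group", "species", "individual_id",
  "behaviour", "enclosure", "timestamp"
)

#' Read a scan-sampling table
#'
#' Reads a delimited text table of instantaneous scan-sampling records — one
#' row per individual per scan — and validates it. The canonical dialect is
#' comma-separated UTF-8 with a header row and columns `scan_id`, `group`,
#' `species`, `individual_id`, `behaviour`, `enclosure`, `timestamp`; the last
#' two may be empty. Accepted tokens: `group` in `r toString(group_levels())`;
#' `species` in `r toString(species_levels())`; `behaviour` in the seven-code
#' vocabulary of [behaviour_codes()]; `enclosure` in indoor/outdoor or empty.
#'
#' Rows with behaviour codes outside the vocabulary are rejected with their
#' row numbers, never silently coerced.
#'
#' @param path Path to the delimited text file.
#' @param delim Field delimiter (default comma, the canonical dialect).
#' @return A validated tibble of scan records (one row per individual per
#'   scan), with `enclosure`/`timestamp` as character and `NA` where empty.
#' @seealso [validate_scan_data()], [write_scan_table()], [scan_compositions()]
#' @export
#' @examples
#' path <- tempfile(fileext = ".csv")
#' write_scan_table(example_scans(), path)
#' scans <- read_scan_table(path)
read_scan_table <- function(path, delim = ",") {
  if (!file.exists(path)) {
    abort_schema(paste0("Scan table not found: ", path))
  }
  data <- readr::read_delim(
    path,
    delim = delim,
    col_types = readr::cols(.default = readr::col_character()),
    na = character(),
    progress = FALSE,
    show_col_types = FALSE
  )
  data[data == ""] <- NA_character_
  validate_scan_data(data)
}

#' Write a scan-sampling table
#'
#' Emits the same canonical dialect that [read_scan_table()] reads (comma
#' delimited, header row, `NA` written as the empty string), so a written
#' dataset round-trips to an identical record set.
#'
#' @param data A validated scan-record tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_scan_table <- function(data, path) {
  data <- validate_scan_data(data)
  readr::write_csv(data[scan_columns], path, na = "")
  invisible(path)
}

#' Validate a scan-record table
#'
#' Checks the schema and the scan-sampling invariants: required columns are
#' present, all tokens are in vocabulary, `(scan_id, individual_id)` pairs are
#' unique, and all records sharing a `scan_id` belong to one group (scans are
#' taken per group). Missing optional columns (`enclosure`, `timestamp`) are
#' added as `NA`.
#'
#' @param data A data frame of scan records.
#' @return The validated data as a tibble with the canonical column order.
#' @export
validate_scan_data <- function(data) {
  data <- tibble::as_tibble(data)
  required <- setdiff(scan_columns, c("enclosure", "timestamp"))
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    abort_schema(
      paste0("Missing required column(s): ", toString(missing_cols)),
      columns = missing_cols
    )
  }
  for (opt in c("enclosure", "timestamp")) {
    if (!opt %in% names(data)) data[[opt]] <- NA_character_
  }
  data <- dplyr::mutate(data, dplyr::across(
    dplyr::all_of(scan_columns),
    as.character
  ))

  check_tokens <- function(column, allowed, allow_na = FALSE) {
    values <- data[[column]]
    bad <- !values %in% allowed & !(allow_na & is.na(values))
    if (any(bad)) {
      rows <- which(bad)
      shown <- head(rows, 5)
      abort_validation(
        paste0(
          "Unknown ", column, " token(s): ",
          toString(unique(values[shown])),
          " (row", if (length(rows) > 1) "s" else "", " ",
          toString(shown), if (length(rows) > 5) ", ..." else "", ")"
        ),
        column = column, rows = rows
      )
    }
  }
  check_tokens("group", group_levels())
  check_tokens("species", species_levels())
  check_tokens("behaviour", behaviour_codes())
  check_tokens("enclosure", enclosure_levels(), allow_na = TRUE)
  if (any(is.na(data$scan_id) | is.na(data$individual_id))) {
    abort_validation("scan_id and individual_id must be non-missing")
  }

  dup <- duplicated(data[c("scan_id", "individual_id")])
  if (any(dup)) {
    pairs <- unique(paste0(
      "(", data$scan_id[dup], ", ", data$individual_id[dup], ")"
    ))
    abort_validation(
      paste0(
        "Duplicate (scan_id, individual_id) pair(s): ",
        toString(head(pairs, 5)),
        if (length(pairs) > 5) ", ..." else ""
      ),
      pairs = pairs
    )
  }

  groups_per_scan <- tapply(data$group, data$scan_id, function(g) length(unique(g)))
  mixed <- names(groups_per_scan)[groups_per_scan > 1]
  if (length(mixed) > 0) {
    abort_validation(
      paste0(
        "Scan(s) spanning more than one group: ",
        toString(head(mixed, 5))
      ),
      scans = mixed
    )
  }

  data[scan_columns]
}

#' Count distinct scans in a dataset
#'
#' @param data A validated scan-record tibble.
#' @return Integer number of distinct `scan_id` values.
#' @export
n_scans <- function(data) {
  dplyr::n_distinct(data$scan_id)
}

#' Per-scan, per-species behaviour compositions
#'
#' Tallies, for every `(scan_id, species)` pair, how many visible individuals
#' were engaged in each of the five analysed behaviours. Out-of-sight (`OOS`)
#' and `OTHER` records are excluded before counting, so `n_visible` is the
#' number of individuals contributing to the synchrony statistics. A species
#' that was scanned in a group but has no analysed-behaviour record in a
#' particular scan is retained as an `n_visible = 0` row (downstream
#' statistics apply their own minimum-N rules).
#'
#' @param data A validated scan-record tibble.
#' @return A tibble with one row per `(scan_id, species)` and columns
#'   `scan_id`, `group`, `species`, `V`, `F`, `L`, `R`, `P`, `n_visible`.
#' @export
#' @examples
#' scan_compositions(example_scans())
scan_compositions <- function(data) {
  data <- validate_scan_data(data)
  scans <- dplyr::distinct(data, .data$scan_id, .data$group)
  species_by_group <- dplyr::distinct(data, .data$group, .data$species)
  frame <- dplyr::inner_join(scans, species_by_group, by = "group",
                             relationship = "many-to-many")

  counts <- data |>
    dplyr::filter(.data$behaviour %in% analysed_behaviours()) |>
    dplyr::count(.data$scan_id, .data$species, .data$behaviour) |>
    tidyr::pivot_wider(
      names_from = "behaviour",
      values_from = "n",
      values_fill = 0L
    )
  for (b in analysed_behaviours()) {
    if (!b %in% names(counts)) counts[[b]] <- 0L
  }

  frame |>
    dplyr::left_join(counts, by = c("scan_id", "species")) |>
    dplyr::mutate(dplyr::across(
      dplyr::all_of(analysed_behaviours()),
      ~ tidyr::replace_na(as.integer(.x), 0L)
    )) |>
    dplyr::mutate(
      n_visible = rowSums(dplyr::pick(dplyr::all_of(analysed_behaviours())))
    ) |>
    dplyr::arrange(.data$scan_id, .data$species) |>
    dplyr::select(dplyr::all_of(c(
      "scan_id", "group", "species", analysed_behaviours(), "n_visible"
    )))
}

#' Fraction of scans with both species co-present in an enclosure
#'
#' For one group, the fraction of its scans in which at least one individual
#' of each species was recorded in the same enclosure category (indoor or
#' outdoor). Out-of-sight records carry no location and are ignored.
#'
#' @param data A validated scan-record tibble with the `enclosure` field
#'   populated for observed records.
#' @param group Group label, one of `r toString(group_levels())`.
#' @return A proportion in `[0, 1]`.
#' @export
co_presence_fraction <- function(data, group) {
  data <- validate_scan_data(data)
  group <- rlang::arg_match(group, group_levels())
  observed <- dplyr::filter(
    data,
    .data$group == !!group, .data$behaviour != "OOS"
  )
  if (nrow(observed) == 0) {
    abort_not_computable(paste0("No observed records for group '", group, "'"))
  }
  if (anyNA(observed$enclosure)) {
    abort_not_computable(
      "co_presence_fraction requires the enclosure field on observed records"
    )
  }
  observed |>
    dplyr::distinct(.data$scan_id, .data$species, .data$enclosure) |>
    dplyr::group_by(.data$scan_id, .data$enclosure) |>
    dplyr::summarise(
      both = dplyr::n_distinct(.data$species) == length(species_levels()),
      .groups = "drop"
    ) |>
    dplyr::group_by(.data$scan_id) |>
    dplyr::summarise(both = any(.data$both), .groups = "drop") |>
    dplyr::pull("both") |>
    mean()
}

#' A small worked example dataset
#'
#' Three scans of a two-species group, used throughout the documentation
#' examples. Purely illustrative.
#'
#' @return A validated scan-record tibble.
#' @export
example_scans <- function() {
  records <- tibble::tribble(
    ~scan_id, ~group, ~species, ~individual_id, ~behaviour, ~enclosure,
    "s1", "west", "capuchin", "c1", "V", "outdoor",
    "s1", "west", "capuchin", "c2", "V", "outdoor",
    "s1", "west", "capuchin", "c3", "F", "outdoor",
    "s1", "west", "squirrel", "q1", "V", "outdoor",
    "s1", "west", "squirrel", "q2", "OOS", NA,
    "s2", "west", "capuchin", "c1", "R", "indoor",
    "s2", "west", "capuchin", "c2", "R", "indoor",
    "s2", "west", "capuchin", "c3", "L", "outdoor",
    "s2", "west", "squirrel", "q1", "R", "indoor",
    "s2", "west", "squirrel", "q2", "F", "indoor",
    "s3", "west", "capuchin", "c1", "F", "outdoor",
    "s3", "west", "capuchin", "c2", "F", "outdoor",
    "s3", "west", "capuchin", "c3", "F", "outdoor",
    "s3", "west", "squirrel", "q1", "F", "outdoor",
    "s3", "west", "squirrel", "q2", "P", "outdoor"
  )
  records$timestamp <- NA_character_
  validate_scan_data(records)
}
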