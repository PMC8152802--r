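#' Egg record CSV column order
#'
#' Canonical column order for egg-record files written and read by the
#' package. Morphometry columns may be empty when an egg was not measured.
#'
#' @return character vector of column names.
#' @export
egg_csv_columns <- function() {
  c(
    "egg_id", "site_id", "trap_id", "collection_date", "status",
    "length_rep1_um", "length_rep2_um", "length_rep3_um",
    "width_rep1_um", "width_rep2_um", "width_rep3_um"
  )
}

.morph_cols <- function() {
  c(
    "length_rep1_um", "length_rep2_um", "length_rep3_um",
    "width_rep1_um", "width_rep2_um", "width_rep3_um"
  )
}

#' Validate a tibble of egg records
#'
#' Checks the structural invariants of per-egg records: known status codes,
#' parseable dates, ISO week consistency, and triplicate morphometry that is
#' either absent (all six values missing) or complete with positive lengths
#' and widths and mean width strictly below mean length. Problems are
#' collected per row and reported together, never silently dropped.
#'
#' @param eggs a data frame with the columns of [egg_csv_columns()]
#'   (plus optional `iso_year`/`iso_week`, which are recomputed).
#' @param source label used in error messages (e.g. a file path).
#' @return the validated tibble, with `collection_date` as `Date`, `status`
#'   as character, derived `iso_year`/`iso_week` columns, and the canonical
#'   column order. Errors with row-numbered diagnostics when any row is
#'   invalid.
#' @export
validate_eggs <- function(eggs, source = "egg records") {
  eggs <- tibble::as_tibble(eggs)
  needed <- c("egg_id", "site_id", "trap_id", "collection_date", "status")
  missing_cols <- setdiff(needed, names(eggs))
  if (length(missing_cols) > 0) {
    abort(sprintf(
      "%s: missing mandatory column(s): %s",
      source, paste(missing_cols, collapse = ", ")
    ))
  }
  for (mc in .morph_cols()) {
    if (!mc %in% names(eggs)) eggs[[mc]] <- NA_real_
  }

  n <- nrow(eggs)
  problems <- character(0)
  note <- function(rows, msg, ids) {
    if (length(rows) == 0) return(invisible(NULL))
    problems <<- c(problems, sprintf(
      "row %d (egg_id %s): %s", rows, ids, msg
    ))
    invisible(NULL)
  }

  dates <- suppressWarnings(as.Date(as.character(eggs$collection_date),
                                    format = "%Y-%m-%d"))
  bad_date <- which(is.na(dates))
  note(bad_date, "unparseable collection_date (expect ISO 8601 YYYY-MM-DD)",
       eggs$egg_id[bad_date])

  status <- toupper(trimws(as.character(eggs$status)))
  bad_status <- which(!status %in% EGG_STATUSES)
  note(bad_status,
       sprintf("unknown status %s", dQuote(eggs$status[bad_status], FALSE)),
       eggs$egg_id[bad_status])

  morph <- as.matrix(eggs[, .morph_cols()])
  storage.mode(morph) <- "double"
  n_present <- rowSums(!is.na(morph))
  partial <- which(n_present > 0 & n_present < 6)
  note(partial, "morphometry must have all 6 replicate values or none",
       eggs$egg_id[partial])
  complete <- which(n_present == 6)
  if (length(complete) > 0) {
    nonpos <- complete[apply(morph[complete, , drop = FALSE] <= 0, 1, any)]
    note(nonpos, "morphometric replicates must be > 0", eggs$egg_id[nonpos])
    lmean <- rowMeans(morph[complete, 1:3, drop = FALSE])
    wmean <- rowMeans(morph[complete, 4:6, drop = FALSE])
    swapped <- complete[!(wmean < lmean) &
                          !complete %in% nonpos]
    note(swapped, "mean width must be smaller than mean length",
         eggs$egg_id[swapped])
  }

  if (length(problems) > 0) {
    abort(paste0(
      source, ": ", length(problems), " invalid row(s):\n",
      paste("  -", problems, collapse = "\n")
    ))
  }

  eggs$collection_date <- dates
  eggs$status <- status
  wk <- iso_week_of(dates)
  eggs$iso_year <- wk$iso_year
  eggs$iso_week <- wk$iso_week
  eggs[, c(egg_csv_columns()[1:5], "iso_year", "iso_week",
           .morph_cols())]
}

#' Read per-egg records from CSV
#'
#' Reads a UTF-8, comma-separated, headered egg-record file (columns of
#' [egg_csv_columns()]), validates every row, and derives the ISO week date
#' of each collection. A non-default `schema` maps the file's column names
#' onto the canonical ones.
#'
#' @param path file path.
#' @param schema optional named character vector `c(canonical = file_column)`
#'   renaming file columns to the canonical schema.
#' @return a validated egg tibble (see [validate_eggs()]).
#' @export
read_eggs <- function(path, schema = NULL) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  if (!is.null(schema)) {
    for (canon in names(schema)) {
      from <- schema[[canon]]
      if (!from %in% names(raw)) {
        abort(sprintf("%s: schema column %s not found in file", path, from))
      }
      names(raw)[names(raw) == from] <- canon
    }
  }
  for (mc in .morph_cols()) {
    if (mc %in% names(raw)) raw[[mc]] <- as.numeric(raw[[mc]])
  }
  validate_eggs(raw, source = path)
}

#' Write per-egg records to CSV
#'
#' Deterministic writer: canonical column order, ISO dates, plain decimal
#' numbers. `write_eggs()` then [read_eggs()] restores an identical tibble,
#' and writing twice yields byte-identical files.
#'
#' @param eggs a validated egg tibble.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_eggs <- function(eggs, path) {
  eggs <- validate_eggs(eggs, source = "write_eggs input")
  out <- eggs[, egg_csv_columns()[1:5]]
  out$collection_date <- format(eggs$collection_date, "%Y-%m-%d")
  for (mc in .morph_cols()) out[[mc]] <- eggs[[mc]]
  readr::write_csv(out, path, na = "", progress = FALSE)
  invisible(path)
}

#' Serialize an analysis result as JSON
#'
#' Writes any result object (list, tibble, model summary) as pretty-printed
#' JSON with full numeric precision. Units should be carried in explicit
#' fields by the caller.
#'
#' @param x object to serialize.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_summary <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", na = "null",
                       force = TRUE)
  invisible(path)
}

#' Tally egg-status cohorts per week or two-week bin
#'
#' Counts HATCHED (H), EMBRYONATED_UNHATCHED (E), PARTIAL_EMBRYO (P) and
#' UNFERTILISED (U) eggs per ISO week, or per two-week bin. EXCLUDED eggs
#' (hatched before collection, dried or damaged) never enter the counts;
#' they are tracked in the `n_excluded` attribute. Two-week bins start at
#' the first observed collection week of each season and pair consecutive
#' ISO weeks.
#'
#' @param eggs a validated egg tibble.
#' @param group_by `"week"` or `"two_week"`.
#' @return a tibble with `iso_year`, `iso_week` (bin start week for
#'   two-week bins), counts `H`, `E`, `P`, `U` and `n_tested`; attribute
#'   `n_excluded` carries the number of EXCLUDED records set aside.
#' @export
tally_cohorts <- function(eggs, group_by = c("week", "two_week")) {
  group_by <- match.arg(group_by)
  eggs <- validate_eggs(eggs, source = "tally_cohorts input")
  n_excluded <- sum(eggs$status == "EXCLUDED")
  kept <- dplyr::filter(eggs, .data$status != "EXCLUDED")

  if (nrow(kept) == 0) {
    out <- tibble::tibble(
      iso_year = integer(), iso_week = integer(),
      H = integer(), E = integer(), P = integer(), U = integer(),
      n_tested = integer()
    )
    attr(out, "n_excluded") <- n_excluded
    return(out)
  }

  if (group_by == "two_week") {
    kept <- kept |>
      dplyr::group_by(.data$iso_year) |>
      dplyr::mutate(
        iso_week = min(.data$iso_week) +
          2L * ((.data$iso_week - min(.data$iso_week)) %/% 2L)
      ) |>
      dplyr::ungroup()
  }

  out <- kept |>
    dplyr::count(.data$iso_year, .data$iso_week, .data$status) |>
    tidyr::pivot_wider(
      names_from = "status", values_from = "n", values_fill = 0L
    )
  for (col in c("HATCHED", "EMBRYONATED_UNHATCHED", "PARTIAL_EMBRYO",
                "UNFERTILISED")) {
    if (!col %in% names(out)) out[[col]] <- 0L
  }
  out <- out |>
    dplyr::transmute(
      iso_year = .data$iso_year,
      iso_week = .data$iso_week,
      H = .data$HATCHED,
      E = .data$EMBRYONATED_UNHATCHED,
      P = .data$PARTIAL_EMBRYO,
      U = .data$UNFERTILISED,
      n_tested = .data$H + .data$E + .data$P + .data$U
    ) |>
    dplyr::arrange(.data$iso_year, .data$iso_week)
  attr(out, "n_excluded") <- n_excluded
  out
}
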