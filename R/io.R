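#' Growth stage codes, in phenological order
#'
#' The five sampling stages used throughout: tillering (TS), jointing (JS),
#' booting (BS), heading (HS) and full heading (FHS).
#'
#' @return Character vector of the five stage codes, ordered.
#' @export
stage_levels <- function() c("TS", "JS", "BS", "HS", "FHS")

#' Cropping seasons
#' @return Character vector `c("early", "late")`.
#' @export
season_levels <- function() c("early", "late")

# canonical column order of the observation CSV format
obs_columns <- function() {
  c("variety", "season", "year", "stage", "n_rate", "replicate",
    "ldm", "pnc", "yield", "ldm_se", "pnc_se", "sig_letter")
}

mandatory_columns <- function() {
  c("variety", "season", "year", "stage", "n_rate", "ldm", "pnc")
}

#' Validate a table of plot observations
#'
#' Checks the invariants of the observation data model: positive `ldm` and
#' `pnc`, non-negative `n_rate`, `stage` among [stage_levels()], `season`
#' among [season_levels()], and uniqueness of the
#' (variety, season, year, stage, n_rate, replicate) key. `year` and
#' `replicate` may be missing (mean-level records carry no replicate;
#' the packaged fixture does not state its year).
#'
#' @param x A data frame of observations.
#' @return `x` as a tibble, invisibly usable downstream. Errors carry the
#'   offending row indices.
#' @export
validate_observations <- function(x) {
  stopifnot(is.data.frame(x))
  missing_cols <- setdiff(mandatory_columns(), names(x))
  if (length(missing_cols) > 0) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  x <- tibble::as_tibble(x)
  for (col in c("replicate", "yield", "ldm_se", "pnc_se", "sig_letter")) {
    if (!col %in% names(x)) {
      x[[col]] <- if (col == "sig_letter") NA_character_ else NA_real_
    }
  }
  for (col in c("n_rate", "ldm", "pnc", "yield", "ldm_se", "pnc_se")) {
    x[[col]] <- as.numeric(x[[col]])
  }

  bad <- function(cond) which(!is.na(cond) & cond)
  fail <- list(
    "non-positive ldm"    = bad(x$ldm <= 0) ,
    "non-positive pnc"    = bad(x$pnc <= 0),
    "negative n_rate"     = bad(x$n_rate < 0),
    "unknown stage"       = which(!x$stage %in% stage_levels()),
    "unknown season"      = which(!x$season %in% season_levels()),
    "missing ldm"         = which(is.na(x$ldm)),
    "missing pnc"         = which(is.na(x$pnc)),
    "missing n_rate"      = which(is.na(x$n_rate)),
    "non-positive yield"  = bad(x$yield <= 0)
  )
  fail <- fail[vapply(fail, length, 1L) > 0]
  if (length(fail) > 0) {
    msg <- vapply(names(fail), function(nm) {
      paste0(nm, " at row(s) ", paste(fail[[nm]], collapse = ", "))
    }, character(1))
    stop("invalid observation(s): ", paste(msg, collapse = "; "), call. = FALSE)
  }

  key <- paste(x$variety, x$season, x$year, x$stage, x$n_rate, x$replicate,
               sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicated (variety, season, year, stage, n_rate, replicate) key ",
         "at row(s) ", paste(which(duplicated(key)), collapse = ", "),
         call. = FALSE)
  }

  # every date of one (variety, season, year) series should see the same
  # N-rate grid; a mismatch is suspicious but not fatal
  grid <- x |>
    dplyr::group_by(.data$variety, .data$season, .data$year, .data$stage) |>
    dplyr::summarise(
      rates = paste(sort(unique(.data$n_rate)), collapse = ","),
      .groups = "drop_last"
    ) |>
    dplyr::summarise(n_grids = dplyr::n_distinct(.data$rates), .groups = "drop")
  if (any(grid$n_grids > 1)) {
    warning("some (variety, season, year) series use different N-rate sets ",
            "across stages", call. = FALSE)
  }
  x
}

#' Read plot observations from a CSV file
#'
#' Reads the delimited observation format (comma separated, header row,
#' `.` decimal mark, empty field = missing) and validates it with
#' [validate_observations()]. Extra columns are preserved.
#'
#' @param path Path to a CSV file with at least the columns
#'   `variety, season, year, stage, n_rate, ldm, pnc`; optionally
#'   `replicate, yield, ldm_se, pnc_se, sig_letter`.
#' @return A validated tibble of observations.
#' @examples
#' tab <- load_table2_fixture()
#' tmp <- tempfile(fileext = ".csv")
#' write_observations(tab, tmp)
#' identical(nrow(read_observations(tmp)), nrow(tab))
#' @export
read_observations <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"),
                  check.names = FALSE)
  validate_observations(raw)
}

#' Write plot observations to a CSV file
#'
#' Inverse of [read_observations()]: the canonical columns are written first
#' (missing optional columns are emitted empty), extra columns follow, and
#' missing values are written as empty fields so that a read/write cycle is
#' the identity up to floating-point text round-trip.
#'
#' @param table A data frame accepted by [validate_observations()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_observations <- function(table, path) {
  table <- validate_observations(table)
  extra <- setdiff(names(table), obs_columns())
  table <- table[, c(obs_columns(), extra), drop = FALSE]
  write.csv(table, path, row.names = FALSE, na = "")
  invisible(path)
}
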