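#' Read and validate an eye-tracking session table
#'
#' Loads a delimited session log and checks it against the schema the
#' correction engine expects: a numeric, non-decreasing `Timestamp` column
#' (milliseconds), a `Data` column carrying user-input event strings, and at
#' least one of the coordinate pairs `Gaze.X`/`Gaze.Y` or
#' `Fixation.X`/`Fixation.Y` in screen pixels. Vendor exports with different
#' column names can be adapted on the fly with `column_map`.
#'
#' @param path Path to a CSV file (comma-delimited, header row, UTF-8;
#'   missing values as empty fields or `NA`).
#' @param column_map Optional named character vector renaming columns before
#'   validation, in `c(NewName = "old_name")` form (the [dplyr::rename()]
#'   convention).
#' @return A tibble ordered as on disk, validated as a session table.
#' @examples
#' path <- tempfile(fileext = ".csv")
#' readr::write_csv(tibble::tibble(
#'   Timestamp = c(0, 10), Data = NA_character_,
#'   Gaze.X = c(100, 105), Gaze.Y = c(200, 198)
#' ), path)
#' read_session(path)
#' @export
read_session <- function(path, column_map = NULL) {
  if (!file.exists(path)) {
    sg_abort(paste0("Session file does not exist: ", path), "io")
  }
  session <- readr::read_csv(
    path,
    col_types = readr::cols(.default = readr::col_guess()),
    na = c("", "NA"),
    show_col_types = FALSE,
    progress = FALSE
  )
  if (!is.null(column_map)) {
    session <- dplyr::rename(session, dplyr::all_of(column_map))
  }
  validate_session(session)
}

#' Validate a session table in place
#'
#' Checks the invariants of the session schema (see [read_session()]) and
#' returns the table unchanged on success. `Data` is coerced to character and
#' added as all-missing if absent.
#'
#' @param session A data frame with session rows.
#' @return The validated session as a tibble.
#' @export
validate_session <- function(session) {
  session <- as_tibble(session)
  if (!"Timestamp" %in% names(session)) {
    sg_abort("Session is missing the mandatory 'Timestamp' column.", "schema")
  }
  if (!is.numeric(session$Timestamp)) {
    sg_abort("'Timestamp' must be numeric (milliseconds).", "schema")
  }
  has_gaze <- all(c("Gaze.X", "Gaze.Y") %in% names(session))
  has_fix <- all(c("Fixation.X", "Fixation.Y") %in% names(session))
  if (!has_gaze && !has_fix) {
    sg_abort(
      paste0(
        "Session must contain at least one coordinate pair: ",
        "'Gaze.X'/'Gaze.Y' or 'Fixation.X'/'Fixation.Y'. ",
        "Absent: ",
        paste(setdiff(c("Gaze.X", "Gaze.Y", "Fixation.X", "Fixation.Y"),
                      names(session)), collapse = ", ")
      ),
      "schema"
    )
  }
  if (!"Data" %in% names(session)) {
    session$Data <- NA_character_
  }
  session$Data <- as.character(session$Data)
  ts <- session$Timestamp
  if (nrow(session) > 1L) {
    bad <- which(diff(ts) < 0)
    if (length(bad) > 0L) {
      sg_abort(
        paste0("Timestamps are not chronologically ordered: row ", bad[1] + 1L,
               " (Timestamp ", ts[bad[1] + 1L], ") precedes row ", bad[1],
               " (Timestamp ", ts[bad[1]], ")."),
        "order"
      )
    }
  }
  for (pair in list(c("Gaze.X", "Gaze.Y"), c("Fixation.X", "Fixation.Y"))) {
    if (all(pair %in% names(session))) {
      mismatch <- which(is.na(session[[pair[1]]]) != is.na(session[[pair[2]]]))
      if (length(mismatch) > 0L) {
        sg_abort(
          paste0("Row ", mismatch[1], ": ", pair[1], " and ", pair[2],
                 " must be both present or both missing."),
          "schema"
        )
      }
    }
  }
  session
}

#' Parse a mouse-wheel event string
#'
#' Session logs record user input in the `Data` column as semicolon-separated
#' `key:value` pairs, e.g.
#' `"X:1478;Y:399; MouseEvent:WM_MOUSEWHEEL; ScrollDelta:-120;"`. Only wheel
#' events (`MouseEvent:WM_MOUSEWHEEL`) are consumed by the scroll engine;
#' clicks, key presses and other events parse to `NULL`. Whitespace around
#' pairs and a trailing semicolon are tolerated; keys are case-sensitive;
#' extra keys are ignored.
#'
#' @param data A single event string, or `NA`/`NULL`.
#' @return A list with integer fields `x`, `y` (mouse screen position) and
#'   `delta` (raw wheel delta: positive = scroll up, negative = scroll down),
#'   or `NULL` when the string is not a wheel event.
#' @examples
#' parse_wheel_event("X:1478;Y:399; MouseEvent:WM_MOUSEWHEEL; ScrollDelta:-120;")
#' parse_wheel_event("MouseEvent:WM_LBUTTONDOWN;X:10;Y:20;")
#' @export
parse_wheel_event <- function(data) {
  if (is.null(data) || length(data) == 0L || is.na(data) || !nzchar(trimws(data))) {
    return(NULL)
  }
  parts <- strsplit(data, ";", fixed = TRUE)[[1]]
  parts <- trimws(parts)
  parts <- parts[nzchar(parts)]
  kv <- regmatches(parts, regexpr(":", parts), invert = TRUE)
  keys <- vapply(kv, function(p) trimws(p[1]), character(1))
  vals <- vapply(kv, function(p) if (length(p) > 1L) trimws(p[2]) else NA_character_,
                 character(1))
  me <- match("MouseEvent", keys)
  if (is.na(me) || !identical(vals[me], "WM_MOUSEWHEEL")) {
    return(NULL)
  }
  get_int <- function(key) {
    i <- match(key, keys)
    if (is.na(i) || is.na(vals[i]) || !grepl("^[+-]?[0-9]+$", vals[i])) {
      sg_abort(
        paste0("Malformed wheel event: '", key,
               "' absent or not an integer in \"", data, "\"."),
        "parse"
      )
    }
    as.integer(vals[i])
  }
  delta <- get_int("ScrollDelta")
  if (delta == 0L) {
    sg_abort(paste0("Malformed wheel event: ScrollDelta is zero in \"", data, "\"."),
             "parse")
  }
  xy <- tryCatch(list(x = get_int("X"), y = get_int("Y")),
                 scrollgaze_parse_error = function(e) NULL)
  if (is.null(xy)) {
    # without a mouse position we cannot tell whether the wheel input reached
    # the scrollable content; treat it as outside the viewing area
    sg_warn(paste0("Wheel event without usable mouse coordinates ignored: \"",
                   data, "\"."), "event")
    return(NULL)
  }
  list(x = xy$x, y = xy$y, delta = delta)
}

#' Format a mouse-wheel event string
#'
#' Inverse of [parse_wheel_event()]: renders a wheel event in the logged
#' `key:value` grammar.
#'
#' @param x,y Integer mouse screen coordinates.
#' @param delta Signed integer wheel delta (negative = scroll down).
#' @return A single event string.
#' @export
format_wheel_event <- function(x, y, delta) {
  sprintf("X:%d;Y:%d; MouseEvent:WM_MOUSEWHEEL; ScrollDelta:%d;",
          as.integer(x), as.integer(y), as.integer(delta))
}

# Parse every Data entry of a session, keeping the originating row index so
# engine errors can point at the offending line.
parse_all_wheel_events <- function(data, rows = seq_along(data)) {
  out <- vector("list", length(data))
  for (i in seq_along(data)) {
    ev <- tryCatch(
      parse_wheel_event(data[i]),
      scrollgaze_parse_error = function(e) {
        sg_abort(paste0("Row ", rows[i], ": ", conditionMessage(e)), "parse")
      }
    )
    if (!is.null(ev)) out[[i]] <- tibble(row = rows[i], x = ev$x, y = ev$y,
                                         delta = ev$delta)
  }
  if (all(vapply(out, is.null, logical(1)))) {
    return(tibble(row = integer(), x = integer(), y = integer(), delta = integer()))
  }
  dplyr::bind_rows(out)
}

#' Write a corrected session table to CSV
#'
#' Writes all columns in original row order; missing values are written as
#' `NA` so a read-back with [read_session()] (or `readr::read_csv()`)
#' reproduces the table exactly.
#'
#' @param table A corrected session table (see [eye_scroll_correct()]).
#' @param path Output CSV path.
#' @return `table`, invisibly.
#' @export
write_corrected <- function(table, path) {
  ok <- tryCatch({
    readr::write_csv(table, path, na = "NA", progress = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    sg_abort(paste0("Cannot write to '", path, "': ", conditionMessage(ok)), "io")
  }
  invisible(table)
}
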