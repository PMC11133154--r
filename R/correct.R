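#' Map a session to full-page-image coordinates
#'
#' The core engine. Iterates a chronologically ordered session, maintains the
#' number of pixels the page has been scrolled from the top (a clamped,
#' optionally lag-delayed step function driven by mouse-wheel events in the
#' `Data` column), and maps every gaze/fixation sample from screen coordinates
#' to the coordinate system of the full-page image.
#'
#' Processing order per session:
#' 1. `Timestamp.Shifted = Timestamp + time_shift`; rows with a shifted
#'    timestamp before `timestamp_start` or after `timestamp_stop` are removed
#'    (the bounds themselves are retained).
#' 2. The scroll state starts at `starting_scroll` pixels (clamped into
#'    `[0, image_height - viewport_height]` with a warning if necessary).
#' 3. Rows are visited in order. Pending wheel events whose effective time
#'    (event timestamp + `scroll_lag`) has been reached are applied
#'    oldest-first, each moving the offset by its notch count times the
#'    calibration's `scroll_pixels` and clamping after every application — a
#'    page cannot scroll past its top or bottom. Then, if the row's `Data`
#'    parses to a wheel event whose mouse position lies inside the viewing
#'    area (inclusive), the event is enqueued; wheel input with the cursor
#'    outside the viewing area does not scroll the page. A raw delta of
#'    magnitude `d` counts as `max(1, round(d / 120))` notches (the
#'    conventional wheel message reports 120 per notch); positive deltas
#'    scroll up, negative down.
#' 4. Coordinates are translated to the viewing-area origin
#'    (`x - tl.x`, `y - tl.y`).
#' 5. A sample whose raw screen position is captured by an active fixed area
#'    (see [active_areas()], [capture_area()]) is redirected to that area's
#'    image rectangle; any other sample gets the current scroll offset added
#'    to its translated y.
#' 6. With `outside_image_is_na = TRUE`, samples whose raw screen position
#'    falls outside the viewing area are set to `NA`, as is any corrected
#'    point landing outside the full-page image.
#'
#' Rules are evaluated against the same effective (lag-adjusted, clamped)
#' scroll state used for the coordinate correction, so bundle switching and
#' y-offsetting stay mutually consistent. The reported `Scroll` column is that
#' effective value: an event that has been received but whose display change
#' has not yet happened (within `scroll_lag`) is not yet reflected.
#'
#' @param session A session table (see [read_session()]); validated on entry.
#' @param calibration A `scroll_calibration`.
#' @param image_width,image_height Full-page image size in pixels;
#'   `image_width` must equal the calibration's viewport width.
#' @param time_shift Milliseconds added to every timestamp (default 0).
#' @param starting_scroll Pixels already scrolled before the first row
#'   (default 0).
#' @param timestamp_start,timestamp_stop Closed retention window on shifted
#'   timestamps (defaults keep everything).
#' @param scroll_lag Milliseconds by which display changes trail wheel input
#'   (default 0); see [get_scroll_lag()].
#' @param outside_image_is_na Replace out-of-viewport samples and
#'   out-of-image corrected points with `NA` (default `TRUE`).
#' @param bundles,rules Positionally paired fixed-area bundles and activation
#'   rules (default none); see [bundle()] and [rule_always_active()].
#' @param output_file If non-empty, the corrected table is also written there
#'   as CSV via [write_corrected()].
#' @return A tibble of class `scroll_corrected`: all original columns plus
#'   `Scroll`, `Timestamp.Shifted`, and `Corrected.Gaze.X/Y` and/or
#'   `Corrected.Fixation.X/Y` in full-page-image pixels.
#' @examples
#' cal <- scroll_calibration_manual(1280, 720, c(0, 0), c(1279, 719), 100)
#' s <- tibble::tibble(
#'   Timestamp = c(0, 10, 20, 30),
#'   Data = c(NA, NA, format_wheel_event(600, 300, -120), NA),
#'   Gaze.X = c(400, 400, NA, 400),
#'   Gaze.Y = c(300, 300, NA, 300)
#' )
#' eye_scroll_correct(s, cal, image_width = 1280, image_height = 5000)
#' @export
eye_scroll_correct <- function(session, calibration,
                               image_width, image_height,
                               time_shift = 0,
                               starting_scroll = 0,
                               timestamp_start = -Inf,
                               timestamp_stop = Inf,
                               scroll_lag = 0,
                               outside_image_is_na = TRUE,
                               bundles = list(),
                               rules = list(),
                               output_file = "") {
  session <- validate_session(session)
  ctx <- check_correction_config(calibration, image_width, image_height,
                                 timestamp_start, timestamp_stop, scroll_lag,
                                 starting_scroll, bundles, rules)
  starting_scroll <- ctx$starting_scroll

  out <- dplyr::mutate(session, Timestamp.Shifted = .data$Timestamp + time_shift)
  keep <- out$Timestamp.Shifted >= timestamp_start &
    out$Timestamp.Shifted <= timestamp_stop
  orig_rows <- which(keep)
  out <- out[keep, , drop = FALSE]
  n <- nrow(out)

  tl <- calibration$viewport_top_left
  br <- calibration$viewport_bottom_right
  sp <- calibration$scroll_pixels
  max_scroll <- ctx$max_scroll

  events <- parse_all_wheel_events(out$Data, rows = orig_rows)
  ev_at <- match(seq_len(n), match(events$row, orig_rows))

  has_gaze <- all(c("Gaze.X", "Gaze.Y") %in% names(out))
  has_fix <- all(c("Fixation.X", "Fixation.Y") %in% names(out))

  scroll_col <- numeric(n)
  cg_x <- cg_y <- cf_x <- cf_y <- rep(NA_real_, n)

  scrolled <- starting_scroll
  pend_eff <- numeric(0)   # effective times, sorted (appended in enqueue order)
  pend_dn <- numeric(0)    # down-notches (positive scrolls down)

  for (i in seq_len(n)) {
    t <- out$Timestamp.Shifted[i]

    # apply due pending scrolls, oldest first, clamping after each
    while (length(pend_eff) > 0L && pend_eff[1] <= t) {
      scrolled <- min(max_scroll, max(0, scrolled + pend_dn[1] * sp))
      pend_eff <- pend_eff[-1]
      pend_dn <- pend_dn[-1]
    }

    # enqueue this row's wheel event if the mouse was inside the viewport
    if (!is.na(ev_at[i])) {
      ev <- events[ev_at[i], ]
      if (point_in_rect(ev$x, ev$y, tl, br)) {
        pend_eff <- c(pend_eff, t + scroll_lag)
        pend_dn <- c(pend_dn, -sign(ev$delta) * max(1, round(abs(ev$delta) / 120)))
      }
    }

    scroll_col[i] <- scrolled

    state <- list(scrolled = scrolled, timestamp = t)
    areas <- if (length(bundles) > 0L) active_areas(bundles, rules, state) else list()

    correct_pair <- function(x, y) {
      if (is.na(x) || is.na(y)) return(c(NA_real_, NA_real_))
      cap <- capture_area(areas, c(x, y))
      p <- if (!is.null(cap)) {
        redirect_point(cap, c(x, y))
      } else {
        c(x - tl[1], y - tl[2] + scrolled)
      }
      if (outside_image_is_na) {
        if (!point_in_rect(x, y, tl, br)) return(c(NA_real_, NA_real_))
        if (p[1] < 0 || p[1] > image_width - 1 ||
            p[2] < 0 || p[2] > image_height - 1) {
          return(c(NA_real_, NA_real_))
        }
      }
      p
    }

    if (has_gaze) {
      p <- correct_pair(out$Gaze.X[i], out$Gaze.Y[i])
      cg_x[i] <- p[1]; cg_y[i] <- p[2]
    }
    if (has_fix) {
      p <- correct_pair(out$Fixation.X[i], out$Fixation.Y[i])
      cf_x[i] <- p[1]; cf_y[i] <- p[2]
    }
  }

  out$Scroll <- scroll_col
  if (has_gaze) {
    out$Corrected.Gaze.X <- cg_x
    out$Corrected.Gaze.Y <- cg_y
  }
  if (has_fix) {
    out$Corrected.Fixation.X <- cf_x
    out$Corrected.Fixation.Y <- cf_y
  }

  out <- structure(out, class = c("scroll_corrected", class(out)))
  attr(out, "calibration") <- calibration
  attr(out, "config") <- list(
    image_width = image_width, image_height = image_height,
    time_shift = time_shift, starting_scroll = starting_scroll,
    timestamp_start = timestamp_start, timestamp_stop = timestamp_stop,
    scroll_lag = scroll_lag, outside_image_is_na = outside_image_is_na
  )

  if (nzchar(output_file)) {
    write_corrected(out, output_file)
  }
  out
}

# Shared validation for the engine and the reference implementation.
check_correction_config <- function(calibration, image_width, image_height,
                                    timestamp_start, timestamp_stop, scroll_lag,
                                    starting_scroll, bundles, rules) {
  if (!inherits(calibration, "scroll_calibration")) {
    sg_abort("'calibration' must be a scroll_calibration object.", "validation")
  }
  vw <- viewport_width(calibration)
  vh <- viewport_height(calibration)
  if (!is_scalar_number(image_width) || !is_scalar_number(image_height) ||
      image_width <= 0 || image_height <= 0) {
    sg_abort("'image_width' and 'image_height' must be positive numbers.",
             "validation")
  }
  if (image_width != vw) {
    sg_abort(paste0("Full-page image width (", image_width, " px) must equal ",
                    "the calibration's viewport width (", vw, " px); the ",
                    "full-page capture and the viewing area must share a ",
                    "pixel scale."),
             "validation")
  }
  if (timestamp_start > timestamp_stop) {
    sg_abort("'timestamp_start' must not exceed 'timestamp_stop'.", "validation")
  }
  if (!is_scalar_number(scroll_lag) && !identical(scroll_lag, 0)) {
    sg_abort("'scroll_lag' must be a single number of milliseconds.", "validation")
  }
  if (scroll_lag < 0) {
    sg_abort("'scroll_lag' must be non-negative.", "validation")
  }
  if (length(bundles) != length(rules)) {
    sg_abort(paste0("'bundles' (", length(bundles), ") and 'rules' (",
                    length(rules), ") must have the same length."),
             "config")
  }
  max_scroll <- max(0, image_height - vh)
  if (starting_scroll < 0 || starting_scroll > max_scroll) {
    sg_warn(paste0("'starting_scroll' (", starting_scroll, ") outside [0, ",
                   max_scroll, "]; clamping."), "clamp")
    starting_scroll <- min(max_scroll, max(0, starting_scroll))
  }
  list(max_scroll = max_scroll, starting_scroll = starting_scroll)
}

#' @method glance scroll_corrected
#' @export
glance.scroll_corrected <- function(x, ...) {
  cfg <- attr(x, "config")
  coord_cols <- intersect(c("Corrected.Gaze.X", "Corrected.Fixation.X"), names(x))
  n_mapped <- if (length(coord_cols) > 0) {
    sum(rowSums(!is.na(as.matrix(x[coord_cols]))) > 0)
  } else 0L
  tibble(
    n_rows = nrow(x),
    n_mapped = n_mapped,
    prop_mapped = if (nrow(x) > 0) n_mapped / nrow(x) else NA_real_,
    max_scroll_reached = if (nrow(x) > 0) max(x$Scroll) else NA_real_,
    scroll_lag = cfg$scroll_lag,
    image_width = cfg$image_width,
    image_height = cfg$image_height
  )
}

#' Plot a corrected session
#'
#' Two-panel overview of a correction result: the scroll-offset step function
#' over time, and the corrected sample positions on the full-page image
#' canvas (y grows downward, as in image coordinates).
#'
#' @param object A `scroll_corrected` table.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot scroll_corrected
#' @export
autoplot.scroll_corrected <- function(object, ...) {
  cfg <- attr(object, "config")
  xcol <- intersect(c("Corrected.Fixation.X", "Corrected.Gaze.X"), names(object))[1]
  ycol <- sub("X$", "Y", xcol)
  pts <- tibble(
    x = object[[xcol]], y = object[[ycol]],
    t = object$Timestamp.Shifted
  )
  pts <- pts[!is.na(pts$x), , drop = FALSE]
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$x, y = .data$y, colour = .data$t)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::scale_y_reverse(limits = c(cfg$image_height - 1, 0)) +
    ggplot2::scale_x_continuous(limits = c(0, cfg$image_width - 1)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "page x (px)", y = "page y (px)", colour = "time (ms)",
                  title = "Corrected samples on the full-page canvas") +
    ggplot2::theme_minimal()
}
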