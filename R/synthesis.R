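#' Describe a synthetic browsing setup
#'
#' A `page_spec` fixes everything the synthetic generators need: the
#' full-page image size, the screen and viewing-area geometry, the per-notch
#' scroll amount, the true display latency between a wheel input and the
#' visible change, and optional fixed-area bundles. The full-page image width
#' must equal the viewport width, and the page must be at least as tall as
#' the viewport.
#'
#' @param image_width,image_height Full-page image size (px).
#' @param screen_width,screen_height Screen resolution (px).
#' @param viewport_top_left,viewport_bottom_right Viewing-area corners
#'   (0-based, inclusive).
#' @param scroll_pixels Pixels per wheel notch.
#' @param display_latency True latency (ms) between a wheel event and the
#'   visible display change (default 0).
#' @param bundles,rules Optional fixed-area configuration.
#' @return A `page_spec` object.
#' @export
page_spec <- function(image_width, image_height,
                      screen_width, screen_height,
                      viewport_top_left, viewport_bottom_right,
                      scroll_pixels, display_latency = 0,
                      bundles = list(), rules = list()) {
  cal <- scroll_calibration_manual(screen_width, screen_height,
                                   viewport_top_left, viewport_bottom_right,
                                   scroll_pixels)
  if (image_width != viewport_width(cal)) {
    sg_abort(paste0("'image_width' (", image_width, ") must equal the ",
                    "viewport width (", viewport_width(cal), ")."),
             "validation")
  }
  if (image_height < viewport_height(cal)) {
    sg_abort(paste0("'image_height' (", image_height, ") must be at least the ",
                    "viewport height (", viewport_height(cal), ")."),
             "validation")
  }
  if (!is_scalar_number(display_latency) || display_latency < 0) {
    sg_abort("'display_latency' must be a non-negative number of ms.",
             "validation")
  }
  structure(
    list(image_width = image_width, image_height = image_height,
         calibration = cal, scroll_pixels = scroll_pixels,
         display_latency = display_latency,
         bundles = bundles, rules = rules),
    class = "page_spec"
  )
}

#' Calibration implied by a page spec
#'
#' @param page A `page_spec`.
#' @return The `scroll_calibration` describing the page's screen geometry.
#' @export
page_calibration <- function(page) {
  page$calibration
}

#' Generate a synthetic calibration screenshot
#'
#' Renders a screen-sized raster on a neutral grey background with one solid
#' marker square of each color whose extremal pixels coincide exactly with
#' the viewport corners, emulating a screenshot of a marker calibration page.
#' Marker squares shrink to fit small viewports; 1-pixel markers still
#' calibrate exactly because detection uses extremal pixels.
#'
#' @param page A `page_spec`.
#' @param marker_colors List with `top_left`/`bottom_right` RGB triples in
#'   `0..255` (defaults match [scroll_calibration_auto()]).
#' @param marker_size Marker square side in pixels (default 20).
#' @return An `height x width x 3` raster array in `[0, 1]`.
#' @export
generate_calibration_image <- function(page,
                                       marker_colors = list(
                                         top_left = c(255, 0, 0),
                                         bottom_right = c(0, 0, 255)
                                       ),
                                       marker_size = 20) {
  cal <- page$calibration
  w <- cal$screen_width
  h <- cal$screen_height
  tl <- cal$viewport_top_left
  br <- cal$viewport_bottom_right
  vw <- viewport_width(cal)
  vh <- viewport_height(cal)
  ms <- min(marker_size, vw, vh)
  if (2 * ms > vw && 2 * ms > vh) {
    # squares would overlap corner-to-corner inside the viewport
    ms <- max(1L, floor(min(vw, vh) / 2))
  }
  if (ms < 1) {
    sg_abort("Viewport too small to place non-overlapping marker squares.",
             "geometry")
  }
  img <- array(0.5, dim = c(h, w, 3))
  paint <- function(img, x0, y0, x1, y1, rgb255) {
    rows <- (y0 + 1):(y1 + 1)
    cols <- (x0 + 1):(x1 + 1)
    for (ch in 1:3) img[rows, cols, ch] <- rgb255[ch] / 255
    img
  }
  img <- paint(img, tl[1], tl[2], tl[1] + ms - 1, tl[2] + ms - 1,
               marker_colors$top_left)
  img <- paint(img, br[1] - ms + 1, br[2] - ms + 1, br[1], br[2],
               marker_colors$bottom_right)
  img
}

#' Generate a synthetic full-page image
#'
#' A deterministic tall test pattern (vertical luminance gradient with
#' horizontal guide bands every 100 px) for heatmap demonstrations and tests.
#'
#' @param page A `page_spec`.
#' @return An `height x width x 3` raster array in `[0, 1]`.
#' @export
generate_page_image <- function(page) {
  h <- page$image_height
  w <- page$image_width
  grad <- 0.25 + 0.5 * (seq_len(h) - 1) / max(1, h - 1)
  img <- array(rep(grad, times = 3 * w), dim = c(h, w, 3))
  bands <- which((seq_len(h) - 1) %% 100 == 0)
  img[bands, , 1] <- 0.9
  img[bands, , 2] <- 0.9
  img[bands, , 3] <- 0.2
  img
}

#' Generate a synthetic browsing session with known ground truth
#'
#' Simulates a participant looking at known full-page coordinates while
#' scrolling a tall page. Wheel events (one per scroll-script entry, delta
#' `-120` per down-notch, `+120` per up-notch, mouse at the viewport center)
#' are written into the `Data` column in the logged `key:value` grammar. The
#' true viewport offset follows a clamped step function in which each event
#' becomes visible `display_latency` ms after its timestamp. Gaze targets are
#' drawn uniformly over the currently visible part of the page (integer
#' pixels), then expressed in screen coordinates via the true offset; the
#' generating page coordinates are returned as ground truth.
#'
#' Samples falling strictly between an event's timestamp and its visibility
#' time are flagged `ambiguous` in the truth table: during that window no
#' observer can know which offset the display showed, so exact-recovery
#' checks should exclude them.
#'
#' @param page A `page_spec`.
#' @param n_samples Number of gaze samples (>= 0).
#' @param sampling_rate Sampling rate in Hz (> 0).
#' @param scroll_script Data frame with columns `time` (ms) and `notches`
#'   (positive = scroll down, negative = up), or `NULL` to draw a random
#'   script (about one event per 25 samples, notch counts in -3..3).
#' @param seed Integer seed; output is deterministic given the seed.
#' @param start_time First sample timestamp (ms, default 0).
#' @param starting_scroll True offset before the first event (default 0).
#' @param gaze_noise_sd Optional zero-mean Gaussian screen-pixel noise added
#'   to samples (default 0, so exactness tests stay exact).
#' @param fixations Also emit `Fixation.X/Y` columns equal to the gaze
#'   columns (default `FALSE`).
#' @return A `synthetic_session` list: `session` (session tibble), `truth`
#'   (tibble with `row`, `page_x`, `page_y`, `offset`, `ambiguous`, aligned
#'   to coordinate-bearing session rows), and `events` (tibble with `time`,
#'   `notches`, `delta`).
#' @export
generate_session <- function(page, n_samples, sampling_rate,
                             scroll_script = NULL, seed = 1L,
                             start_time = 0, starting_scroll = 0,
                             gaze_noise_sd = 0, fixations = FALSE) {
  if (!is_scalar_number(sampling_rate) || sampling_rate <= 0) {
    sg_abort("'sampling_rate' must be a positive frequency in Hz.", "validation")
  }
  if (!is_scalar_number(n_samples) || n_samples < 0) {
    sg_abort("'n_samples' must be a non-negative count.", "validation")
  }
  cal <- page$calibration
  tl <- cal$viewport_top_left
  vw <- viewport_width(cal)
  vh <- viewport_height(cal)
  max_scroll <- max(0, page$image_height - vh)
  span <- if (n_samples > 1) (n_samples - 1) * 1000 / sampling_rate else 0
  t_end <- start_time + span

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(seed)

  if (is.null(scroll_script)) {
    n_ev <- max(1L, n_samples %/% 25L)
    times <- sort(round(stats::runif(n_ev, start_time, t_end), 1))
    notches <- sample(c(-3:-1, 1:3), n_ev, replace = TRUE)
    scroll_script <- tibble(time = times, notches = notches)
  } else {
    scroll_script <- as_tibble(scroll_script)
    if (!all(c("time", "notches") %in% names(scroll_script))) {
      sg_abort("'scroll_script' needs columns 'time' and 'notches'.", "config")
    }
    if (nrow(scroll_script) > 0 &&
        (min(scroll_script$time) < start_time || max(scroll_script$time) > t_end)) {
      sg_abort(paste0("Scroll-script times must lie within the session span [",
                      start_time, ", ", t_end, "] ms."),
               "config")
    }
    scroll_script <- dplyr::arrange(scroll_script, .data$time)
  }
  scroll_script <- scroll_script[scroll_script$notches != 0, , drop = FALSE]

  # true offset step function: event i becomes visible at time_i + latency
  visible <- scroll_script$time + page$display_latency
  offsets <- numeric(nrow(scroll_script) + 1L)
  offsets[1] <- min(max_scroll, max(0, starting_scroll))
  for (k in seq_len(nrow(scroll_script))) {
    offsets[k + 1] <- min(max_scroll,
                          max(0, offsets[k] + scroll_script$notches[k] *
                                page$scroll_pixels))
  }
  true_offset <- function(t) offsets[sum(visible <= t) + 1L]

  sample_t <- if (n_samples > 0) {
    start_time + (seq_len(n_samples) - 1) * 1000 / sampling_rate
  } else numeric(0)
  off <- vapply(sample_t, true_offset, numeric(1))
  page_x <- if (n_samples > 0) sample(0:(vw - 1), n_samples, replace = TRUE)
            else integer(0)
  page_y <- if (n_samples > 0) {
    vapply(off, function(o) sample(o:(o + vh - 1), 1L), numeric(1))
  } else numeric(0)
  screen_x <- page_x + tl[1]
  screen_y <- page_y - off + tl[2]
  if (gaze_noise_sd > 0 && n_samples > 0) {
    screen_x <- screen_x + stats::rnorm(n_samples, 0, gaze_noise_sd)
    screen_y <- screen_y + stats::rnorm(n_samples, 0, gaze_noise_sd)
  }
  ambiguous <- vapply(sample_t, function(t) {
    any(t > scroll_script$time & t < visible)
  }, logical(1))

  mouse <- floor((tl + c(cal$viewport_bottom_right)) / 2)
  sample_rows <- tibble(
    Timestamp = sample_t,
    Data = NA_character_,
    Gaze.X = screen_x,
    Gaze.Y = screen_y,
    .is_event = FALSE
  )
  event_rows <- tibble(
    Timestamp = scroll_script$time,
    Data = vapply(scroll_script$notches, function(nn) {
      format_wheel_event(mouse[1], mouse[2], -120L * as.integer(nn))
    }, character(1)),
    Gaze.X = NA_real_,
    Gaze.Y = NA_real_,
    .is_event = TRUE
  )
  session <- dplyr::bind_rows(sample_rows, event_rows)
  # stable chronological order; at equal timestamps the event precedes the
  # sample, matching a display change already visible at that instant
  session <- session[order(session$Timestamp, !session$.is_event), , drop = FALSE]
  truth_row <- which(!session$.is_event)
  session$.is_event <- NULL
  if (fixations) {
    session$Fixation.X <- session$Gaze.X
    session$Fixation.Y <- session$Gaze.Y
  }

  structure(
    list(
      session = as_tibble(session),
      truth = tibble(row = truth_row, page_x = page_x[order(sample_t)],
                     page_y = page_y[order(sample_t)],
                     offset = off[order(sample_t)],
                     ambiguous = ambiguous[order(sample_t)]),
      events = tibble(time = scroll_script$time,
                      notches = scroll_script$notches,
                      delta = -120L * as.integer(scroll_script$notches))
    ),
    class = "synthetic_session"
  )
}

#' @export
print.synthetic_session <- function(x, ...) {
  cat("<synthetic_session>\n")
  cat("  samples:", sum(!is.na(x$session$Gaze.X)), " events:", nrow(x$events), "\n")
  cat("  offset range:", paste(range(x$truth$offset), collapse = " - "), "px\n")
  invisible(x)
}
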