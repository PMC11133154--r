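# Shared fixtures, built in code at test time.

# The canonical four-row session extract: two gaze+fixation rows, one wheel
# event row, one post-scroll row.
extract_session <- function() {
  tibble::tibble(
    Timestamp = c(55080, 55089, 55095, 55097),
    Data = c(NA, NA, "X:1478;Y:399; MouseEvent:WM_MOUSEWHEEL; ScrollDelta:-120;", NA),
    Gaze.X = c(803, 794, NA, 805),
    Gaze.Y = c(384, 375, NA, 387),
    Fixation.X = c(783, 783, NA, 783),
    Fixation.Y = c(380, 380, NA, 380)
  )
}

# Full-screen-viewport calibration on a 1920x1080 screen, 125 px per notch.
extract_calibration <- function() {
  scroll_calibration_manual(1920, 1080, c(0, 0), c(1919, 1079), 125)
}

simple_calibration <- function(scroll_pixels = 100) {
  scroll_calibration_manual(1280, 720, c(0, 0), c(1279, 719), scroll_pixels)
}

# A gaze-only session of samples at fixed screen position with scripted
# wheel-event rows (delta units; negative = down).
scripted_session <- function(sample_times, events, x = 400, y = 300,
                             mouse = c(400, 300)) {
  s <- tibble::tibble(
    Timestamp = sample_times, Data = NA_character_,
    Gaze.X = x, Gaze.Y = y, .ev = FALSE
  )
  if (nrow(events) > 0) {
    e <- tibble::tibble(
      Timestamp = events$time,
      Data = vapply(
        events$delta,
        function(d) format_wheel_event(mouse[1], mouse[2], d),
        character(1)
      ),
      Gaze.X = NA_real_, Gaze.Y = NA_real_, .ev = TRUE
    )
    s <- dplyr::bind_rows(s, e)
  }
  s <- s[order(s$Timestamp, !s$.ev), , drop = FALSE]
  s$.ev <- NULL
  s
}

# Randomized correction scenario for implementation-vs-reference equivalence:
# random geometry, lag, events (some with the mouse outside the viewport,
# some multi-notch), gaze positions in and out of the viewport, missing
# values, and optional fixed areas.
random_correction_case <- function(seed) {
  set.seed(seed)
  vw <- sample(200:400, 1)
  vh <- sample(150:300, 1)
  tlx <- sample(0:50, 1)
  tly <- sample(0:80, 1)
  cal <- scroll_calibration_manual(tlx + vw + 10, tly + vh + 10,
                                   c(tlx, tly), c(tlx + vw - 1, tly + vh - 1),
                                   sample(40:140, 1))
  image_height <- vh + sample(0:1200, 1)
  lag <- sample(c(0, 8.333, 25, 50), 1)
  n <- sample(10:60, 1)
  ts <- sort(round(cumsum(runif(n, 0, 12)), 1))
  is_ev <- runif(n) < 0.3
  data <- rep(NA_character_, n)
  for (i in which(is_ev)) {
    mx <- sample(0:(tlx + vw + 9), 1)   # sometimes outside the viewport
    my <- sample(0:(tly + vh + 9), 1)
    delta <- sample(c(-360, -240, -120, -60, 60, 120, 240), 1)
    data[i] <- format_wheel_event(mx, my, delta)
  }
  gx <- ifelse(is_ev, NA_real_, sample(0:(tlx + vw + 9), n, replace = TRUE))
  gy <- ifelse(is_ev, NA_real_, sample(0:(tly + vh + 9), n, replace = TRUE))
  drop_coord <- !is_ev & runif(n) < 0.1
  gx[drop_coord] <- NA_real_
  gy[drop_coord] <- NA_real_
  session <- tibble::tibble(Timestamp = ts, Data = data, Gaze.X = gx, Gaze.Y = gy)

  bundles <- list()
  rules <- list()
  if (runif(1) < 0.5) {
    a1 <- fixed_area(c(tlx, tly), c(tlx + 40, tly + 20),
                     c(0, 0), c(40, 20))
    a2 <- fixed_area(c(tlx + 20, tly + 10), c(tlx + 80, tly + 40),
                     c(100, 50), c(130, 65))   # half-size target rect
    bundles <- list(bundle(a1), bundle(a2))
    thr <- sample(50:400, 1)
    rules <- list(rule_scrolled_less_than(thr), rule_scrolled_at_least(thr))
  }
  list(
    session = session, calibration = cal,
    image_width = vw, image_height = image_height,
    scroll_lag = lag,
    starting_scroll = sample(c(0, 100), 1),
    outside_image_is_na = runif(1) < 0.7,
    bundles = bundles, rules = rules
  )
}

run_both <- function(case) {
  args <- c(list(session = case$session, calibration = case$calibration,
                 image_width = case$image_width, image_height = case$image_height,
                 scroll_lag = case$scroll_lag,
                 starting_scroll = case$starting_scroll,
                 outside_image_is_na = case$outside_image_is_na,
                 bundles = case$bundles, rules = case$rules))
  engine <- suppressWarnings(do.call(eye_scroll_correct, args))
  reference <- suppressWarnings(do.call(scroll_correct_reference, args))
  strip <- function(d) {
    d <- as.data.frame(d)
    attr(d, "calibration") <- NULL
    attr(d, "config") <- NULL
    rownames(d) <- NULL
    d
  }
  list(engine = strip(engine), reference = strip(reference))
}

# A small synthetic study page: 1280x720 viewport at (0,80) on a 1280x800
# screen, 4000 px tall page.
demo_page <- function(display_latency = 0, scroll_pixels = 125) {
  page_spec(
    image_width = 1280, image_height = 4000,
    screen_width = 1280, screen_height = 800,
    viewport_top_left = c(0, 80), viewport_bottom_right = c(1279, 799),
    scroll_pixels = scroll_pixels, display_latency = display_latency
  )
}
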