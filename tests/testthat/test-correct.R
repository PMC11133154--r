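test_that("a logged wheel event shifts subsequent samples by one notch of pixels", {
  cal <- extract_calibration()   # full-screen viewport, 125 px / notch
  out <- eye_scroll_correct(extract_session(), cal,
                            image_width = 1920, image_height = 4377)
  expect_equal(out$Scroll, c(0, 0, 0, 125))
  expect_equal(out$Corrected.Gaze.Y, c(384, 375, NA, 387 + 125))
  expect_equal(out$Corrected.Gaze.X, c(803, 794, NA, 805))
  expect_equal(out$Corrected.Fixation.Y, c(380, 380, NA, 380 + 125))
  expect_equal(out$Timestamp.Shifted, out$Timestamp)
})

test_that("with no events and an origin viewport the correction is the identity", {
  cal <- simple_calibration()
  s <- scripted_session(seq(0, 200, by = 20), tibble::tibble(time = numeric(), delta = numeric()),
                        x = 321.5, y = 456.25)
  out <- eye_scroll_correct(s, cal, image_width = 1280, image_height = 3000)
  expect_equal(out$Corrected.Gaze.X, s$Gaze.X)   # continuous values preserved
  expect_equal(out$Corrected.Gaze.Y, s$Gaze.Y)
  expect_true(all(out$Scroll == 0))
})

test_that("the viewport translation is applied to both coordinates", {
  cal <- scroll_calibration_manual(1400, 900, c(100, 150), c(1299, 849), 100)
  s <- tibble::tibble(Timestamp = 0, Data = NA_character_,
                      Gaze.X = 350, Gaze.Y = 400)
  out <- eye_scroll_correct(s, cal, image_width = 1200, image_height = 2000)
  expect_equal(out$Corrected.Gaze.X, 250)
  expect_equal(out$Corrected.Gaze.Y, 250)
})

test_that("scrolling clamps at the page bottom and returns to the top", {
  cal <- scroll_calibration_manual(1280, 1000, c(0, 0), c(1279, 999), 100)
  down20 <- tibble::tibble(time = seq_len(20) * 10, delta = -120)
  up20 <- tibble::tibble(time = 300 + seq_len(20) * 10, delta = 120)
  s <- scripted_session(c(250, 550), dplyr::bind_rows(down20, up20),
                        x = 400, y = 10)
  out <- eye_scroll_correct(s, cal, image_width = 1280, image_height = 2000)
  samples <- out[!is.na(out$Gaze.Y), ]
  # 20 down-notches on a 1000 px scroll range: clamped at 1000, not 2000
  expect_equal(samples$Scroll[1], 1000)
  expect_equal(samples$Corrected.Gaze.Y[1], 1010)
  expect_equal(samples$Scroll[2], 0)
  expect_equal(samples$Corrected.Gaze.Y[2], 10)
})

test_that("delta magnitudes are converted to notches robustly", {
  cal <- simple_calibration(100)
  events <- tibble::tibble(time = c(10, 30, 50), delta = c(-240, -60, 120))
  s <- scripted_session(c(20, 40, 60), events, y = 5)
  out <- eye_scroll_correct(s, cal, image_width = 1280, image_height = 5000)
  samples <- out[!is.na(out$Gaze.Y), ]
  # -240 = 2 notches down, -60 = 1 notch down (minimum one), +120 = 1 up
  expect_equal(samples$Scroll, c(200, 300, 200))
})

test_that("wheel events with the mouse outside the viewing area do not scroll", {
  cal <- scroll_calibration_manual(1280, 800, c(0, 80), c(1279, 799), 100)
  s <- scripted_session(c(20, 40), tibble::tibble(time = c(10, 30), delta = -120),
                        x = 400, y = 300, mouse = c(400, 40))  # above the viewport
  out <- eye_scroll_correct(s, cal, image_width = 1280, image_height = 3000)
  expect_true(all(out$Scroll == 0))
})

test_that("the timestamp window is closed and applied after shifting", {
  cal <- simple_calibration()
  s <- scripted_session(c(0, 10, 20, 30, 40),
                        tibble::tibble(time = numeric(), delta = numeric()))
  out <- eye_scroll_correct(s, cal, image_width = 1280, image_height = 2000,
                            time_shift = 100, timestamp_start = 110,
                            timestamp_stop = 130)
  expect_equal(out$Timestamp.Shifted, c(110, 120, 130))
  expect_equal(out$Timestamp, c(10, 20, 30))
})

test_that("events outside the retention window are discarded with their rows", {
  cal <- simple_calibration(100)
  s <- scripted_session(c(100, 200), tibble::tibble(time = 50, delta = -120))
  out <- eye_scroll_correct(s, cal, image_width = 1280, image_height = 2000,
                            timestamp_start = 100)
  expect_true(all(out$Scroll == 0))
})

test_that("scroll_lag delays the offset and the Scroll column reports the effective value", {
  cal <- simple_calibration(100)
  s <- scripted_session(c(0, 255, 262, 280),
                        tibble::tibble(time = 250, delta = -120))
  out <- eye_scroll_correct(s, cal, image_width = 1280, image_height = 3000,
                            scroll_lag = 25)
  samples <- out[!is.na(out$Gaze.Y), ]
  # effective at 275: samples at 255 and 262 still see the pre-scroll display
  expect_equal(samples$Scroll, c(0, 0, 0, 100))
  expect_equal(samples$Corrected.Gaze.Y, c(300, 300, 300, 400))
})

test_that("lagging events equals shifting event timestamps by the lag", {
  cal <- simple_calibration(100)
  lag <- 8.333
  sample_times <- seq(0, 400, by = 7)
  events <- tibble::tibble(time = c(30, 95, 95, 210), delta = c(-120, -120, 240, -360))
  lagged <- eye_scroll_correct(
    scripted_session(sample_times, events), cal,
    image_width = 1280, image_height = 2200, scroll_lag = lag
  )
  pre_shifted <- eye_scroll_correct(
    scripted_session(sample_times, dplyr::mutate(events, time = time + lag)),
    cal, image_width = 1280, image_height = 2200, scroll_lag = 0
  )
  l <- lagged[!is.na(lagged$Gaze.Y), ]
  p <- pre_shifted[!is.na(pre_shifted$Gaze.Y), ]
  expect_equal(l$Scroll, p$Scroll)
  expect_equal(l$Corrected.Gaze.Y, p$Corrected.Gaze.Y)
})

test_that("correction composes across a session split with chained starting_scroll", {
  cal <- simple_calibration(80)
  sample_times <- seq(0, 300, by = 10)
  events <- tibble::tibble(time = c(40, 120, 160, 240), delta = c(-120, -240, 120, -120))
  s <- scripted_session(sample_times, events)
  whole <- eye_scroll_correct(s, cal, image_width = 1280, image_height = 2500)
  first <- s[s$Timestamp <= 150, ]
  second <- s[s$Timestamp > 150, ]
  out1 <- eye_scroll_correct(first, cal, image_width = 1280, image_height = 2500)
  out2 <- eye_scroll_correct(second, cal, image_width = 1280, image_height = 2500,
                             starting_scroll = out1$Scroll[nrow(out1)])
  chained <- c(out1$Corrected.Gaze.Y, out2$Corrected.Gaze.Y)
  expect_equal(chained, whole$Corrected.Gaze.Y)
})

test_that("x-coordinates of non-captured points only receive the viewport translation", {
  case <- random_correction_case(101)
  case$bundles <- list()
  case$rules <- list()
  case$outside_image_is_na <- FALSE
  out <- suppressWarnings(do.call(eye_scroll_correct, c(
    list(session = case$session, calibration = case$calibration,
         image_width = case$image_width, image_height = case$image_height,
         scroll_lag = case$scroll_lag, starting_scroll = case$starting_scroll,
         outside_image_is_na = FALSE)
  )))
  tlx <- case$calibration$viewport_top_left[1]
  ok <- !is.na(out$Gaze.X)
  expect_equal(out$Corrected.Gaze.X[ok], out$Gaze.X[ok] - tlx)
})

test_that("samples in fixed areas are redirected independently of the scroll state", {
  cal <- extract_calibration()
  area <- fixed_area(c(0, 0), c(1919, 149), c(0, 3377), c(1919, 3526))
  s <- scripted_session(c(0, 100, 300),
                        tibble::tibble(time = 150, delta = -120),
                        x = 100, y = 30)
  out <- eye_scroll_correct(s, cal, image_width = 1920, image_height = 4377,
                            bundles = list(bundle(area)),
                            rules = list(rule_always_active()))
  samples <- out[!is.na(out$Gaze.Y), ]
  expect_equal(unique(samples$Corrected.Gaze.X), 100)
  expect_equal(unique(samples$Corrected.Gaze.Y), 30 + 3377)
  expect_equal(samples$Scroll, c(0, 0, 125))   # state moved, redirect did not
})

test_that("bundle switching follows the effective scroll state", {
  cal <- scroll_calibration_manual(1280, 1000, c(0, 0), c(1279, 999), 500)
  big <- fixed_area(c(0, 0), c(1279, 149), c(0, 0), c(1279, 149))
  small <- fixed_area(c(0, 0), c(1279, 74), c(0, 0), c(1279, 74))
  bundles <- list(bundle(big), bundle(small))
  rules <- list(rule_scrolled_less_than(1000), rule_scrolled_at_least(1000))
  s <- scripted_session(c(0, 300, 600),
                        tibble::tibble(time = c(100, 400), delta = c(-120, -120)),
                        x = 400, y = 100)
  out <- eye_scroll_correct(s, cal, image_width = 1280, image_height = 4000,
                            bundles = bundles, rules = rules)
  samples <- out[!is.na(out$Gaze.Y), ]
  # at scroll 0 and 500 the tall menu captures y=100; at 1000 it has shrunk,
  # so the sample is ordinary content and receives the offset
  expect_equal(samples$Corrected.Gaze.Y, c(100, 100, 1100))
})

test_that("outside_image_is_na masks out-of-viewport samples but keeps Scroll", {
  cal <- scroll_calibration_manual(1280, 800, c(0, 80), c(1279, 799), 100)
  s <- tibble::tibble(
    Timestamp = c(0, 10, 20),
    Data = NA_character_,
    Gaze.X = c(400, 400, 400),
    Gaze.Y = c(40, 300, 795)    # first is above the viewing area
  )
  out <- eye_scroll_correct(s, cal, image_width = 1280, image_height = 3000)
  expect_equal(is.na(out$Corrected.Gaze.Y), c(TRUE, FALSE, FALSE))
  expect_equal(out$Scroll, c(0, 0, 0))
  kept <- eye_scroll_correct(s, cal, image_width = 1280, image_height = 3000,
                             outside_image_is_na = FALSE)
  expect_equal(kept$Corrected.Gaze.Y[1], -40)   # translated, unmasked
})

test_that("ordinary corrected points cannot overshoot the page, redirected ones are masked", {
  # for a non-captured in-viewport sample, y + scroll <= image_height - 1 by
  # construction of the clamp, so only redirection can leave the page
  cal <- scroll_calibration_manual(1280, 1000, c(0, 0), c(1279, 999), 100)
  s <- scripted_session(c(20, 25), tibble::tibble(time = 10, delta = -120),
                        x = 400, y = 999)
  out <- eye_scroll_correct(s, cal, image_width = 1280, image_height = 1100)
  samples <- out[!is.na(out$Gaze.Y), ]
  expect_equal(samples$Corrected.Gaze.Y, c(1099, 1099))   # exactly the last pixel

  over <- fixed_area(c(0, 0), c(99, 99), c(0, 1950), c(99, 2049))
  s2 <- tibble::tibble(Timestamp = 0, Data = NA_character_,
                       Gaze.X = 50, Gaze.Y = 80)
  masked <- eye_scroll_correct(s2, cal, image_width = 1280, image_height = 2000,
                               bundles = list(bundle(over)),
                               rules = list(rule_always_active()))
  expect_true(is.na(masked$Corrected.Gaze.Y))
  kept <- eye_scroll_correct(s2, cal, image_width = 1280, image_height = 2000,
                             outside_image_is_na = FALSE,
                             bundles = list(bundle(over)),
                             rules = list(rule_always_active()))
  expect_equal(kept$Corrected.Gaze.Y, 2030)
})

test_that("a mismatched full-page image width is a hard error naming both widths", {
  cal <- simple_calibration()
  s <- scripted_session(0, tibble::tibble(time = numeric(), delta = numeric()))
  err <- expect_error(
    eye_scroll_correct(s, cal, image_width = 1920, image_height = 2000),
    class = "scrollgaze_validation_error"
  )
  expect_match(conditionMessage(err), "1920")
  expect_match(conditionMessage(err), "1280")
})

test_that("starting_scroll outside the feasible range is clamped with a warning", {
  cal <- simple_calibration()
  s <- scripted_session(0, tibble::tibble(time = numeric(), delta = numeric()), y = 5)
  expect_warning(
    out <- eye_scroll_correct(s, cal, image_width = 1280, image_height = 2000,
                              starting_scroll = 99999),
    class = "scrollgaze_clamp_warning"
  )
  expect_equal(out$Scroll, 1280)   # image_height - viewport_height
})

test_that("malformed wheel strings surface as parse errors with a row index", {
  cal <- simple_calibration()
  s <- tibble::tibble(
    Timestamp = c(0, 10),
    Data = c(NA, "MouseEvent:WM_MOUSEWHEEL;X:1;Y:2"),
    Gaze.X = c(10, NA), Gaze.Y = c(10, NA)
  )
  err <- expect_error(
    eye_scroll_correct(s, cal, image_width = 1280, image_height = 2000),
    class = "scrollgaze_parse_error"
  )
  expect_match(conditionMessage(err), "Row 2")
})

test_that("an empty session yields an empty corrected table with the new columns", {
  cal <- simple_calibration()
  s <- extract_session()[0, ]
  out <- eye_scroll_correct(s, cal, image_width = 1280, image_height = 2000)
  expect_equal(nrow(out), 0)
  expect_true(all(c("Scroll", "Timestamp.Shifted", "Corrected.Gaze.X",
                    "Corrected.Fixation.Y") %in% names(out)))
  ref <- scroll_correct_reference(s, cal, image_width = 1280, image_height = 2000)
  expect_equal(nrow(ref), 0)
})

test_that("engine and reference agree on a hand-computable single-event session", {
  cal <- simple_calibration(100)
  s <- scripted_session(c(0, 100), tibble::tibble(time = 50, delta = -120), y = 10)
  both <- run_both(list(session = s, calibration = cal, image_width = 1280,
                        image_height = 2000, scroll_lag = 0, starting_scroll = 0,
                        outside_image_is_na = TRUE, bundles = list(), rules = list()))
  expect_equal(both$engine, both$reference)
  expect_equal(both$engine$Corrected.Gaze.Y[!is.na(both$engine$Gaze.Y)], c(10, 110))
})

test_that("engine and reference agree exactly on randomized sessions", {
  for (seed in 1:60) {
    both <- run_both(random_correction_case(seed))
    expect_equal(both$engine, both$reference, info = paste("seed", seed))
  }
})

test_that("glance summarizes a corrected session", {
  cal <- simple_calibration(100)
  s <- scripted_session(c(0, 100), tibble::tibble(time = 50, delta = -120))
  out <- eye_scroll_correct(s, cal, image_width = 1280, image_height = 2000)
  g <- glance(out)
  expect_equal(g$n_rows, 3)
  expect_equal(g$n_mapped, 2)
  expect_equal(g$max_scroll_reached, 100)
})
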