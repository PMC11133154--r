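#' Reference correction by step-function lookup
#'
#' An independent re-implementation of [eye_scroll_correct()] used for
#' cross-validation. Instead of iterating row by row with a pending-event
#' queue, it first constructs the complete viewport-offset step function over
#' time — replaying every in-viewport wheel event at its effective time with
#' stepwise clamping — and then maps each row independently by looking up the
#' offset at the row's shifted timestamp. The two implementations must agree
#' exactly on every input; disagreement indicates a defect in one of them.
#'
#' Tie-breaking matches the engine: an event becomes effective for all rows at
#' or after its effective time, except that with `scroll_lag = 0` an event
#' never affects its own row (the state is read before the event is applied).
#'
#' @inheritParams eye_scroll_correct
#' @return A tibble with the same columns as [eye_scroll_correct()].
#' @export
scroll_correct_reference <- function(session, calibration,
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
  max_scroll <- ctx$max_scroll
  tl <- calibration$viewport_top_left
  br <- calibration$viewport_bottom_right
  sp <- calibration$scroll_pixels

  out <- as_tibble(session)
  out$Timestamp.Shifted <- out$Timestamp + time_shift
  out <- out[out$Timestamp.Shifted >= timestamp_start &
               out$Timestamp.Shifted <= timestamp_stop, , drop = FALSE]
  n <- nrow(out)

  # --- build the full offset step function -------------------------------
  evs <- parse_all_wheel_events(out$Data, rows = seq_len(n))
  if (nrow(evs) > 0L) {
    inside <- mapply(function(x, y) point_in_rect(x, y, tl, br), evs$x, evs$y)
    evs <- evs[inside, , drop = FALSE]
  }
  eff <- out$Timestamp.Shifted[evs$row] + scroll_lag
  dn <- -sign(evs$delta) * pmax(1, round(abs(evs$delta) / 120))
  ord <- order(eff, evs$row)          # stable: row order breaks eff ties
  eff <- eff[ord]; dn <- dn[ord]; ev_row <- evs$row[ord]

  # offsets[k+1] = offset after the first k events
  offsets <- numeric(length(eff) + 1L)
  offsets[1] <- starting_scroll
  for (k in seq_along(eff)) {
    offsets[k + 1] <- min(max_scroll, max(0, offsets[k] + dn[k] * sp))
  }

  offset_at <- function(t, row) {
    k <- sum(eff < t | (eff == t & ev_row < row))
    offsets[k + 1L]
  }

  # --- map each row independently ----------------------------------------
  has_gaze <- all(c("Gaze.X", "Gaze.Y") %in% names(out))
  has_fix <- all(c("Fixation.X", "Fixation.Y") %in% names(out))
  scroll_col <- numeric(n)
  cg_x <- cg_y <- cf_x <- cf_y <- rep(NA_real_, n)

  map_pair <- function(x, y, scrolled, t) {
    if (is.na(x) || is.na(y)) return(c(NA_real_, NA_real_))
    state <- list(scrolled = scrolled, timestamp = t)
    p <- NULL
    for (bi in seq_along(bundles)) {
      if (!isTRUE(rules[[bi]](state))) next
      for (a in bundles[[bi]]) {
        if (x >= a$screen_tl[1] && x <= a$screen_br[1] &&
            y >= a$screen_tl[2] && y <= a$screen_br[2]) {
          sw <- a$screen_br - a$screen_tl + 1
          iw <- a$image_br - a$image_tl + 1
          sc <- ifelse(sw == 1, 1, (iw - 1) / (sw - 1))
          p <- a$image_tl + (c(x, y) - a$screen_tl) * sc
          break
        }
      }
      if (!is.null(p)) break
    }
    if (is.null(p)) {
      p <- c(x - tl[1], y - tl[2] + scrolled)
    }
    if (outside_image_is_na) {
      if (x < tl[1] || x > br[1] || y < tl[2] || y > br[2]) {
        return(c(NA_real_, NA_real_))
      }
      if (p[1] < 0 || p[1] > image_width - 1 ||
          p[2] < 0 || p[2] > image_height - 1) {
        return(c(NA_real_, NA_real_))
      }
    }
    p
  }

  for (i in seq_len(n)) {
    t <- out$Timestamp.Shifted[i]
    scrolled <- offset_at(t, i)
    scroll_col[i] <- scrolled
    if (has_gaze) {
      p <- map_pair(out$Gaze.X[i], out$Gaze.Y[i], scrolled, t)
      cg_x[i] <- p[1]; cg_y[i] <- p[2]
    }
    if (has_fix) {
      p <- map_pair(out$Fixation.X[i], out$Fixation.Y[i], scrolled, t)
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
  if (nzchar(output_file)) {
    write_corrected(out, output_file)
  }
  out
}
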