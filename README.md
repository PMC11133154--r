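# scrollgaze

Eye trackers report gaze in **screen** coordinates. When a participant
browses a scrollable page, the stimulus moves underneath those coordinates:
the same screen pixel shows different content before and after every turn of
the mouse wheel. Any analysis tied to page content — areas of interest,
reading order, attention heatmaps — first has to remap each sample from the
screen onto a single tall **full-page image** of the stimulus.

`scrollgaze` does that remapping deterministically from the input log itself,
with no video coding. It is aimed at researchers running web-browsing or
other scrollable-stimulus studies who export a timestamped table of gaze (or
fixation) samples interleaved with user-input events.

## The model

The session log carries wheel events as `key:value` strings,
e.g. `X:1478;Y:399; MouseEvent:WM_MOUSEWHEEL; ScrollDelta:-120;`. The engine
maintains the *scrolled offset* `s(t)` — pixels the page content has moved up
from its top — as a clamped step function:

- each wheel event with the mouse inside the viewing area changes the offset
  by `n · scroll_pixels`, where `n = max(1, round(|delta| / 120))` notches
  (sign: negative delta scrolls down) and `scroll_pixels` comes from a
  one-off calibration;
- after every event the offset is clamped to `[0, H_page − H_viewport]` — a
  page cannot scroll past its top or bottom;
- a non-captured sample at screen position `(x, y)` maps to page position
  `(x − v_x, y − v_y + s(t))`, where `(v_x, v_y)` is the viewing area's
  top-left pixel.

Because a monitor refreshes at a finite rate, the display changes only some
milliseconds after the wheel message. The engine therefore applies each
event with a configurable delay, the *scroll lag*

```
scroll_lag = (n_frame − 1) · 1000/refresh_rate + ½ · 1000/refresh_rate   [ms]
```

(`get_scroll_lag(60, 1)` = 8.333 ms, the minimum sensible value on a 60-Hz
monitor; `n_frame = 2` is the recommended default).

Screen regions that do **not** scroll (menus, sidebars, sticky ads) are
declared as *fixed areas*, grouped into *bundles* with activation *rules* on
the scroll state (`always_active`, `scrolled_less_than(v)`,
`scrolled_at_least(v)`); samples captured by an active fixed area are
redirected to its designated rectangle on the full-page image instead of
receiving the offset.

Everything is testable without recorded data: a synthetic-session generator
produces browsing sessions, marker screenshots, and page images with known
ground truth, and an independent reference implementation
(`scroll_correct_reference()`) cross-checks the engine on randomized
sessions.

## Worked example

```r
library(scrollgaze)

cal <- scroll_calibration_manual(1920, 1080, c(0, 0), c(1919, 1079), 125)

session <- tibble::tibble(
  Timestamp = c(55080, 55089, 55095, 55097),
  Data = c(NA, NA, "X:1478;Y:399; MouseEvent:WM_MOUSEWHEEL; ScrollDelta:-120;", NA),
  Gaze.X = c(803, 794, NA, 805),
  Gaze.Y = c(384, 375, NA, 387)
)

corrected <- eye_scroll_correct(session, cal,
                                image_width = 1920, image_height = 4377)
corrected[, c("Timestamp", "Scroll", "Corrected.Gaze.X", "Corrected.Gaze.Y")]
#> # A tibble: 4 × 4
#>   Timestamp Scroll Corrected.Gaze.X Corrected.Gaze.Y
#>       <dbl>  <dbl>            <dbl>            <dbl>
#> 1     55080      0              803              384
#> 2     55089      0              794              375
#> 3     55095      0               NA               NA
#> 4     55097    125              805              512
```

The wheel event at `t = 55095` (delta −120, one notch down, 125 px per
notch) raises the offset to 125, so the next sample's screen-y of 387 maps to
page-y `387 + 125 = 512`. The event row itself carries no coordinates but
keeps its `Scroll` value. `glance(corrected)` summarizes the run
(here: 4 rows, 3 mapped, maximum offset 125), `autoplot(corrected)` plots the
mapped samples on the page canvas, and `generate_heatmap()` overlays a
Gaussian-smoothed density on the full-page image.

A command-line front end wrapping the same functions (subcommands
`calibrate`, `correct`, `heatmap`, `simulate`) ships at
`system.file("cli", "scrollgaze", package = "scrollgaze")`.

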