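---
title: "Mapping gaze on scrolling pages: model, assumptions, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping gaze on scrolling pages}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scrollgaze)
```

## The problem

An eye tracker measures where on the *screen* a participant looks. On a
scrollable stimulus — typically a web page taller than the browser window —
the mapping from screen pixels to page content changes every time the user
turns the mouse wheel. `scrollgaze` reconstructs that mapping offline from
the session log alone: it replays the logged wheel events to recover the
scroll position at every instant and translates each gaze or fixation sample
into the coordinate system of a full-page image of the stimulus.

The approach is deterministic and input-driven. It deliberately avoids video
recordings: a screen recording at 24–30 fps is a *subsampled* view of a
60 Hz+ display, so frame-based coding of when a scroll became visible is
systematically late. `next_frame_time(24)` = `r round(next_frame_time(24), 2)` ms
is the earliest a 24-fps video can show a change that the monitor displayed
at, say, t = 1 ms — a frame-based coder is then wrong for
`frame_coding_error(24, 1)` = `r round(frame_coding_error(24, 1), 2)` ms,
and longer whenever frames are skipped or delayed.

## The scroll state machine

Let `s(t)` be the number of pixels the page content has been scrolled up
from its top. The engine (`eye_scroll_correct()`) maintains `s` as a clamped
step function while iterating the session chronologically:

1. Timestamps are shifted by `time_shift` (for synchronizing with external
   clocks), then rows outside the closed window
   `[timestamp_start, timestamp_stop]` are dropped. Windowing happens on
   shifted timestamps, and events in dropped rows are never applied.
2. `s` starts at `starting_scroll` (clamped into the feasible range with a
   warning — user-supplied starting offsets are often approximate).
3. A wheel event with raw delta `d` and the mouse *inside* the viewing area
   contributes `sign` × `max(1, round(|d| / 120))` notches (wheel messages
   conventionally report ±120 per notch; drivers that report multiples are
   handled by the rounding, and sub-120 magnitudes count as one notch).
   Positive deltas scroll up, negative down. Wheel input with the cursor
   outside the viewing area — over browser tabs, the desktop — does not
   scroll the page and is ignored.
4. Each applied event moves `s` by `notches × scroll_pixels` and `s` is
   clamped to `[0, image_height − viewport_height]` after *every individual
   event*: over-scrolling at the page ends is discarded, not banked, which
   is how browsers behave.
5. A sample at screen `(x, y)` outside any fixed area maps to
   `(x − v_x, y − v_y + s)`, the viewport translation plus the current
   offset. X-coordinates never receive more than the constant translation.

### Input lag

The display change trails the wheel message because monitors refresh at a
finite rate. If the interval between an input and the next refresh is
uniformly distributed over one frame, the change becomes visible on the
`n_frame`-th following frame after an expected

\[
\mathrm{scroll\_lag} = (n_\mathrm{frame}-1)\cdot\frac{1000}{\mathrm{refresh\_rate}}
 + \frac{1}{2}\cdot\frac{1000}{\mathrm{refresh\_rate}} \ \mathrm{ms}.
\]

`get_scroll_lag()` evaluates this; on a 60-Hz monitor the minimum
(`n_frame = 1`) is `r round(get_scroll_lag(60, 1), 3)` ms and the
general-purpose recommendation (`n_frame = 2`) is
`r get_scroll_lag(60, 2)` ms. The engine implements the lag with a pending
queue: an event received at time `t` becomes *effective* at `t + scroll_lag`,
and pending events are applied (oldest first, clamping after each) whenever
a row's timestamp reaches their effective time.

Two consequences are worth documenting because the log format cannot decide
them:

* **The `Scroll` column is post-lag.** Between an event's arrival and its
  effective time the column reports the offset still shown on the display,
  which is what the participant saw. Samples strictly inside that window are
  irreducibly ambiguous — no offline method can know which refresh actually
  carried the change — and the synthetic generator flags them.
* **Rules see the same post-lag state.** Fixed-area bundle switching and
  y-offsetting are evaluated against one state, so a menu that retracts
  after 1000 scrolled pixels switches at the same instant the offsets do.

### Tie-breaking

Within a row, pending-event application precedes enqueueing of that row's
own event, so with `scroll_lag = 0` an event never affects the row it
arrives on — its change is first visible to later rows (a sample logged at
the same millisecond as a wheel message cannot yet reflect the repaint).
Events with equal effective times apply in row order. These conventions are
fixed by the implementation and exercised by the equivalence tests.

## Calibration

Three numbers anchor the geometry: the screen resolution, the inclusive
pixel rectangle of the viewing area, and `scroll_pixels`, the pixels moved
per wheel notch (browser- and page-dependent; smooth scrolling must be
disabled during recording so each notch is a discrete jump).

`scroll_calibration_auto()` recovers the rectangle from a lossless
screenshot of a marker page: one solid square of a known color at each
viewing-area corner. Detection finds connected regions (4-connectivity) of
the *exact* marker color and takes the extremal pixel of each region, so
marker size is irrelevant and 1-pixel markers work. Defaults are pure red
`(255,0,0)` top-left and pure blue `(0,0,255)` bottom-right — concrete
choices, overridable, with exact matching chosen over tolerance matching to
fail loudly on lossy screenshots rather than mis-calibrate silently.
`scroll_pixels` is read by the user from the calibration page rather than
OCR'd from the screenshot.

All pixel coordinates in the package are 0-based, origin at the screen's
top-left, y growing downward, and all rectangles are inclusive on every
edge; these conventions are applied uniformly rather than stated per
function.

## Fixed areas, bundles, rules

Regions that stay put while content scrolls (menus, sidebars) are described
as `fixed_area(screen_rect, image_rect)` pairs. Capture uses the *raw*
screen position (the areas exist on the screen, pre-translation);
redirection maps the point into the area's image rectangle by an affine map
that scales each coordinate by `(image extent − 1)/(screen extent − 1)`
about the rectangle's top-left. Equal-size rectangles reduce to pure
translation; unequal sizes support pages whose fixed regions shrink after
scrolling. Among overlapping active areas the first in
bundle-then-area declaration order wins — the format does not define an
overlap semantics, so a deterministic, user-controllable order was chosen.

The rule vocabulary in the declarative JSON config is limited to
`always_active`, `scrolled_less_than(v)`, `scrolled_at_least(v)`; the two
threshold rules partition the state space exactly at `v` (`< v` vs `>= v`).
Arbitrary predicate functions remain available programmatically.

## Heatmaps

`generate_heatmap()` places a unit mass at each corrected sample (an
optional weight column overrides the unit; by default one row per sample
already encodes dwell time), smooths with an isotropic Gaussian, normalizes
the field to peak 1, and alpha-composites a colormapped overlay at per-pixel
opacity `max_alpha ×` density. Defaults — `kernel_sigma = 50` px, a
perceptually uniform palette, `max_alpha = 0.6` — are presentation choices,
all overridable. The blur uses a separable kernel truncated at 4σ with zero
padding, and FFT residue below 10⁻¹² of the field maximum is snapped to
zero, so pixels the participant never looked near are returned bit-identical
to the input image.

## The synthetic generator

`generate_session()` emulates exactly the machinery the corrector models: a
participant fixating uniformly random integer page positions within the
currently visible region of a tall page, wheel events from a script or a
random walk formatted in the logged `key:value` grammar, and a true offset
timeline in which each event becomes visible `display_latency` ms after its
timestamp, clamped stepwise. Ground truth (page coordinates and offset per
sample) is returned alongside, and generation is deterministic given the
seed without disturbing the caller's RNG stream.

What it does *not* emulate — and therefore what passing tests cannot show —
includes eye-tracker measurement error beyond optional Gaussian jitter,
saccade/fixation dynamics (fixation detection is assumed upstream, e.g. an
I-VT filter), smooth-scrolling animation, scrollbar dragging and keyboard
navigation, frame-quantized display latency variation, and real page
rendering. Exact-recovery results are statements about the scroll model's
internal consistency, not about tracker accuracy on real sessions.

The default study conditions used across the test suite are a 1280×720
viewing area below an 80-px browser chrome on a 1280×800 screen, a
1280×4000 page, 125 px per notch, 120-Hz sampling, and display latencies
spanning 0–41.67 ms; randomized-equivalence cases draw geometry, lag,
per-event deltas (±60…±360), out-of-viewport mouse positions, and fixed-area
configurations from wide ranges. Suite-scale choices — 1000 equivalence
sessions, five 2100-sample recovery sessions, a 5⁴ calibration grid on a
120×90 screen — keep full coverage of every code path at a few minutes of
runtime.

## Numerical and degenerate-input choices

* Corrected coordinates keep the input's numeric precision (trackers emit
  continuous coordinates); nothing is rounded to integer pixels except the
  heatmap binning.
* A wheel string with a malformed `ScrollDelta` is a hard parse error
  pointing at the row; a wheel string without usable mouse coordinates is
  ignored with a warning (without a cursor position one cannot tell whether
  the input reached the scrollable content, and ignoring it matches the
  outside-viewport rule).
* `ScrollDelta:0` is rejected — a zero-delta wheel message is a logging
  fault, not a scroll.
* Empty sessions produce empty corrected tables with the full output schema;
  rows whose coordinates are missing still carry `Scroll` and
  `Timestamp.Shifted`.
* With `outside_image_is_na = TRUE` (default), samples outside the viewing
  area and corrected points outside the page are set to `NA`. For ordinary
  (non-redirected) in-viewport samples the clamp already guarantees
  `y + s ≤ image_height − 1`, so only redirection targets can leave the page.
* `starting_scroll` outside the feasible range clamps with a warning rather
  than erroring (tolerant of approximate user input).

## Verification strategy

Two independent implementations of the mapping must agree exactly:
the single-pass engine with its pending queue, and
`scroll_correct_reference()`, which first builds the complete offset step
function and then maps each row by timestamp lookup. The suite asserts
bit-exact agreement on 1000 randomized sessions covering clamping episodes,
lags, multi-notch deltas, ignored events, and fixed-area switching, plus
exact ground-truth recovery through the generator when `scroll_lag` equals
the generator's `display_latency`. Algebraic properties (lagging events ≡
pre-shifting their timestamps; correction composes across a session split
with chained `starting_scroll`; redirection between equal-size rectangles is
an isometry) are tested directly.

## Known limitations

Only discrete wheel scrolling is modeled: page-up/page-down keys, scrollbar
drags, analog touchpad or free-spinning wheels, and nested scrollable
subcomponents are out of scope, as is fixation detection itself. Scroll
amounts must be constant per notch (disable smooth scrolling, hide overlay
scrollbars). The irreducible temporal ambiguity around each display change —
half a frame on average, bounded by the monitor period — applies to any
offline method; the lag model centers it but cannot remove it.
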