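#' Manual scroll calibration
#'
#' Builds the calibration record that anchors screen coordinates to the
#' scrollable viewing area: the screen resolution, the inclusive pixel
#' rectangle of the viewing area (its top-leftmost and bottom-rightmost
#' pixels), and how many pixels one wheel notch scrolls. All pixel coordinates
#' are 0-based with the origin at the screen's top-left corner and y growing
#' downward.
#'
#' @param screen_width,screen_height Screen resolution in pixels.
#' @param viewport_top_left,viewport_bottom_right Length-2 numeric `(x, y)`
#'   pixel coordinates of the viewing-area corners (inclusive).
#' @param scroll_pixels Pixels scrolled per wheel notch (> 0).
#' @return A `scroll_calibration` object.
#' @examples
#' scroll_calibration_manual(1920, 1080, c(0, 87), c(1919, 1079), 125)
#' @export
scroll_calibration_manual <- function(screen_width, screen_height,
                                      viewport_top_left, viewport_bottom_right,
                                      scroll_pixels) {
  tl <- as.numeric(viewport_top_left)
  br <- as.numeric(viewport_bottom_right)
  if (!is_scalar_number(screen_width) || screen_width <= 0) {
    sg_abort("'screen_width' must be a positive number.", "validation")
  }
  if (!is_scalar_number(screen_height) || screen_height <= 0) {
    sg_abort("'screen_height' must be a positive number.", "validation")
  }
  if (length(tl) != 2L || length(br) != 2L || anyNA(tl) || anyNA(br)) {
    sg_abort("Viewport corners must be length-2 numeric (x, y) vectors.",
             "validation")
  }
  if (!(tl[1] >= 0 && tl[1] < br[1] && br[1] < screen_width)) {
    sg_abort(paste0("Viewport x-range invalid: need 0 <= tl.x < br.x < ",
                    "screen_width (got tl.x = ", tl[1], ", br.x = ", br[1],
                    ", screen_width = ", screen_width, ")."),
             "geometry")
  }
  if (!(tl[2] >= 0 && tl[2] < br[2] && br[2] < screen_height)) {
    sg_abort(paste0("Viewport y-range invalid: need 0 <= tl.y < br.y < ",
                    "screen_height (got tl.y = ", tl[2], ", br.y = ", br[2],
                    ", screen_height = ", screen_height, ")."),
             "geometry")
  }
  if (!is_scalar_number(scroll_pixels) || scroll_pixels <= 0) {
    sg_abort("'scroll_pixels' must be a positive number of pixels per notch.",
             "validation")
  }
  structure(
    list(
      screen_width = as.numeric(screen_width),
      screen_height = as.numeric(screen_height),
      viewport_top_left = tl,
      viewport_bottom_right = br,
      scroll_pixels = as.numeric(scroll_pixels)
    ),
    class = "scroll_calibration"
  )
}

#' @export
print.scroll_calibration <- function(x, ...) {
  cat("<scroll_calibration>\n")
  cat("  screen:        ", x$screen_width, "x", x$screen_height, "px\n")
  cat("  viewport:      (", x$viewport_top_left[1], ",", x$viewport_top_left[2],
      ") - (", x$viewport_bottom_right[1], ",", x$viewport_bottom_right[2],
      ")  [", viewport_width(x), "x", viewport_height(x), "px ]\n")
  cat("  scroll_pixels: ", x$scroll_pixels, "px / notch\n")
  invisible(x)
}

#' Viewport extent helpers
#'
#' Width and height of the viewing area described by a calibration, as
#' inclusive pixel counts (`bottom_right - top_left + 1`).
#'
#' @param calibration A `scroll_calibration`.
#' @return Number of pixels.
#' @export
viewport_width <- function(calibration) {
  calibration$viewport_bottom_right[1] - calibration$viewport_top_left[1] + 1
}

#' @rdname viewport_width
#' @export
viewport_height <- function(calibration) {
  calibration$viewport_bottom_right[2] - calibration$viewport_top_left[2] + 1
}

#' Automatic scroll calibration from a marker screenshot
#'
#' Recovers the calibration from a lossless full-screen screenshot of a
#' calibration page that displays one solid-colored marker square in the top
#' left and one in the bottom right corner of the viewing area. The screen
#' resolution is the image size; the viewport corners are the extremal pixels
#' of the two marker regions (so marker size is irrelevant); `scroll_pixels`
#' is read by the user from the page and passed through.
#'
#' Markers are detected as connected regions (4-connectivity) of the exact
#' marker colors, by default pure red `(255, 0, 0)` for the top-left marker
#' and pure blue `(0, 0, 255)` for the bottom-right one. Exact matching
#' requires a lossless (PNG) screenshot.
#'
#' @param image A PNG file path or an `height x width x channels` array with
#'   values in `[0, 1]` (as returned by [png::readPNG()]).
#' @param scroll_pixels Pixels scrolled per wheel notch, read from the page.
#' @param marker_colors List with `top_left` and `bottom_right` RGB triples in
#'   `0..255`.
#' @return A `scroll_calibration` object.
#' @export
scroll_calibration_auto <- function(image, scroll_pixels,
                                    marker_colors = list(
                                      top_left = c(255, 0, 0),
                                      bottom_right = c(0, 0, 255)
                                    )) {
  img <- load_raster(image)
  h <- dim(img)[1]
  w <- dim(img)[2]
  tl <- marker_extremum(img, marker_colors$top_left, "top_left")
  br <- marker_extremum(img, marker_colors$bottom_right, "bottom_right")
  if (!(br[1] > tl[1] && br[2] > tl[2])) {
    sg_abort(
      paste0("Markers are in inverted order: bottom-right marker pixel (",
             br[1], ",", br[2], ") is not below-right of top-left marker pixel (",
             tl[1], ",", tl[2], ")."),
      "geometry"
    )
  }
  scroll_calibration_manual(w, h, tl, br, scroll_pixels)
}

# Locate the single connected region of an exact RGB color and return its
# extremal pixel: (min x, min y) for the top_left marker, (max x, max y) for
# the bottom_right one. 0-based coordinates.
marker_extremum <- function(img, rgb255, which_marker) {
  mask <- (round(img[, , 1] * 255) == rgb255[1]) &
    (round(img[, , 2] * 255) == rgb255[2]) &
    (round(img[, , 3] * 255) == rgb255[3])
  if (!any(mask)) {
    sg_abort(paste0("Marker '", which_marker, "' (RGB ",
                    paste(rgb255, collapse = ","),
                    ") not found in the screenshot."),
             "detection")
  }
  labels <- EBImage::bwlabel(mask * 1)
  n <- max(labels)
  if (n != 1L) {
    sg_abort(paste0("Marker '", which_marker, "' is ambiguous: found ", n,
                    " connected regions of RGB ",
                    paste(rgb255, collapse = ","), "; expected exactly one."),
             "detection")
  }
  idx <- which(mask, arr.ind = TRUE)   # (row, col), 1-based
  x <- idx[, 2] - 1
  y <- idx[, 1] - 1
  if (which_marker == "top_left") c(min(x), min(y)) else c(max(x), max(y))
}

# Accept a path or an in-memory raster; always return h x w x 3+ array.
load_raster <- function(image) {
  if (is.character(image)) {
    if (!file.exists(image)) {
      sg_abort(paste0("Image file does not exist: ", image), "io")
    }
    image <- png::readPNG(image)
  }
  if (is.matrix(image)) {   # greyscale -> replicate channels
    image <- array(rep(image, 3), dim = c(dim(image), 3))
  }
  if (length(dim(image)) != 3L || dim(image)[3] < 3L) {
    sg_abort("Image must be an RGB(A) raster array or a PNG path.", "validation")
  }
  image
}

#' Recommended scroll lag from monitor timing
#'
#' Wheel input never changes the display instantly: the change appears on a
#' later monitor refresh. Assuming the delay between an input and the next
#' frame is uniform over one frame duration, the expected latency until the
#' change is visible on the `n_frame`-th subsequent frame is
#' \deqn{(n_{frame}-1) \cdot 1000/refresh\_rate + \tfrac{1}{2} \cdot 1000/refresh\_rate}
#' milliseconds. Use the result as the `scroll_lag` argument of
#' [eye_scroll_correct()]; `n_frame = 2` is a reasonable general-purpose
#' choice, `n_frame = 1` the minimum (half a frame).
#'
#' @param refresh_rate Monitor refresh rate in Hz (> 0).
#' @param n_frame Rank of the frame on which the change is assumed visible
#'   (positive integer).
#' @return Recommended lag in milliseconds.
#' @examples
#' get_scroll_lag(60, 1)   # 8.333 ms
#' get_scroll_lag(60, 2)   # 25 ms
#' @export
get_scroll_lag <- function(refresh_rate, n_frame = 2) {
  if (!is_scalar_number(refresh_rate) || refresh_rate <= 0) {
    sg_abort("'refresh_rate' must be a positive frequency in Hz.", "domain")
  }
  if (!is_scalar_number(n_frame) || n_frame < 1 || n_frame != round(n_frame)) {
    sg_abort("'n_frame' must be a positive integer.", "domain")
  }
  (n_frame - 1) * 1000 / refresh_rate + 0.5 * 1000 / refresh_rate
}

#' Video-frame timing of a display change
#'
#' Screen recordings run at far fewer frames per second than the monitor
#' refreshes, so frame-based coding of when a scroll became visible is
#' systematically late. `next_frame_time()` gives the timestamp of the first
#' video frame strictly after `after_ms` (frames at `k * 1000 / fps`,
#' `k = 1, 2, ...`). `frame_coding_error()` gives how long a coder working
#' frame-by-frame remains wrong about a change that became visible on the
#' monitor at `visible_ms`: the time from `visible_ms` until the next video
#' frame boundary.
#'
#' @param fps Video frame rate in frames per second (> 0).
#' @param after_ms Reference time in ms (default 0).
#' @param visible_ms Time (ms) at which the change was actually visible on
#'   the monitor; must fall strictly inside a frame interval.
#' @return Milliseconds.
#' @examples
#' next_frame_time(24)            # 41.67 ms
#' frame_coding_error(24, 1)      # 40.67 ms
#' @export
next_frame_time <- function(fps, after_ms = 0) {
  if (!is_scalar_number(fps) || fps <= 0) {
    sg_abort("'fps' must be a positive frame rate.", "domain")
  }
  fd <- 1000 / fps
  k <- floor(after_ms / fd) + 1
  k * fd
}

#' @rdname next_frame_time
#' @export
frame_coding_error <- function(fps, visible_ms) {
  next_frame_time(fps, after_ms = visible_ms) - visible_ms
}

#' Read and write calibration files
#'
#' Calibrations are serialized as a small JSON document so they can be reused
#' across sessions and passed to the command-line interface.
#'
#' @param calibration A `scroll_calibration`.
#' @param path File path.
#' @return `read_calibration()` returns a `scroll_calibration`;
#'   `write_calibration()` returns its input invisibly.
#' @export
write_calibration <- function(calibration, path) {
  stopifnot(inherits(calibration, "scroll_calibration"))
  jsonlite::write_json(unclass(calibration), path, auto_unbox = TRUE, digits = NA)
  invisible(calibration)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  scroll_calibration_manual(x$screen_width, x$screen_height,
                            x$viewport_top_left, x$viewport_bottom_right,
                            x$scroll_pixels)
}

#' @method tidy scroll_calibration
#' @export
tidy.scroll_calibration <- function(x, ...) {
  tibble(
    screen_width = x$screen_width,
    screen_height = x$screen_height,
    viewport_left = x$viewport_top_left[1],
    viewport_top = x$viewport_top_left[2],
    viewport_right = x$viewport_bottom_right[1],
    viewport_bottom = x$viewport_bottom_right[2],
    viewport_width = viewport_width(x),
    viewport_height = viewport_height(x),
    scroll_pixels = x$scroll_pixels
  )
}
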