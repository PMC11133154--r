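#' Fixed screen areas, bundles and rules
#'
#' Web pages commonly contain regions that stay put while the rest of the
#' content scrolls — top menus, sidebars, sticky ads. Gaze samples landing in
#' such a region must not receive the scroll offset; instead they are
#' *redirected* to the region's designated location on the full-page image.
#'
#' A `fixed_area` pairs an inclusive pixel rectangle on the screen with an
#' inclusive pixel rectangle on the full-page image. A `bundle` is an ordered,
#' non-empty set of fixed areas describing one page configuration; a *rule*
#' (a predicate on the current scroll state) decides when the bundle applies,
#' which captures pages whose fixed regions shrink or disappear once the user
#' has scrolled past a threshold.
#'
#' @param screen_tl,screen_br Length-2 `(x, y)` corners of the screen
#'   rectangle (0-based, inclusive).
#' @param image_tl,image_br Length-2 `(x, y)` corners of the target rectangle
#'   on the full-page image (0-based, inclusive).
#' @return `fixed_area()` returns a `fixed_area` object; `bundle()` an
#'   `area_bundle` (list of fixed areas).
#' @examples
#' top_menu <- fixed_area(c(0, 0), c(1919, 149), c(0, 0), c(1919, 149))
#' b <- bundle(top_menu)
#' @export
fixed_area <- function(screen_tl, screen_br, image_tl, image_br) {
  check_rect <- function(tl, br, what) {
    tl <- as.numeric(tl); br <- as.numeric(br)
    if (length(tl) != 2L || length(br) != 2L || anyNA(c(tl, br))) {
      sg_abort(paste0("Fixed-area ", what, " corners must be length-2 numeric."),
               "validation")
    }
    if (br[1] < tl[1] || br[2] < tl[2]) {
      sg_abort(paste0("Fixed-area ", what, " rectangle is degenerate: ",
                      "bottom-right (", br[1], ",", br[2],
                      ") is above-left of top-left (", tl[1], ",", tl[2], ")."),
               "geometry")
    }
    list(tl = tl, br = br)
  }
  s <- check_rect(screen_tl, screen_br, "screen")
  i <- check_rect(image_tl, image_br, "image")
  structure(
    list(screen_tl = s$tl, screen_br = s$br, image_tl = i$tl, image_br = i$br),
    class = "fixed_area"
  )
}

#' @param ... For `bundle()`: one or more `fixed_area` objects.
#' @rdname fixed_area
#' @export
bundle <- function(...) {
  areas <- list(...)
  if (length(areas) == 1L && is.list(areas[[1]]) && !inherits(areas[[1]], "fixed_area")) {
    areas <- areas[[1]]
  }
  if (length(areas) == 0L) {
    sg_abort("A bundle must contain at least one fixed area.", "config")
  }
  if (!all(vapply(areas, inherits, logical(1), "fixed_area"))) {
    sg_abort("All bundle members must be 'fixed_area' objects.", "config")
  }
  structure(areas, class = "area_bundle")
}

#' Bundle activation rules
#'
#' Rules are deterministic predicates on the current scroll state, evaluated
#' row by row by the correction engine against the *effective* (lag-adjusted,
#' clamped) number of pixels scrolled from the top. Three common rules are
#' provided; any function taking a state list (fields `scrolled`, `timestamp`)
#' and returning a logical scalar can be used in their place.
#'
#' @param value Threshold in scrolled pixels.
#' @return A predicate function of the scroll state, classed `scroll_rule`.
#' @examples
#' r <- rule_scrolled_less_than(1000)
#' r(list(scrolled = 999))   # TRUE
#' r(list(scrolled = 1000))  # FALSE
#' @export
rule_always_active <- function() {
  new_rule(function(state) TRUE, "always_active", NA_real_)
}

#' @rdname rule_always_active
#' @export
rule_scrolled_less_than <- function(value) {
  force(value)
  new_rule(function(state) state$scrolled < value, "scrolled_less_than", value)
}

#' @rdname rule_always_active
#' @export
rule_scrolled_at_least <- function(value) {
  force(value)
  new_rule(function(state) state$scrolled >= value, "scrolled_at_least", value)
}

new_rule <- function(fn, kind, value) {
  structure(fn, class = c("scroll_rule", "function"), kind = kind, value = value)
}

#' Fixed areas active under a scroll state
#'
#' Evaluates each bundle's rule against `state` and concatenates, in bundle
#' order then area order, the areas of every bundle whose rule holds.
#'
#' @param bundles List of `area_bundle` objects.
#' @param rules List of rules, positionally paired with `bundles`.
#' @param state Scroll state list with at least `scrolled` (pixels).
#' @return Ordered list of `fixed_area` objects (possibly empty).
#' @export
active_areas <- function(bundles, rules, state) {
  if (length(bundles) != length(rules)) {
    sg_abort(paste0("'bundles' (", length(bundles), ") and 'rules' (",
                    length(rules), ") must have the same length and pairing."),
             "config")
  }
  out <- list()
  for (i in seq_along(bundles)) {
    if (isTRUE(rules[[i]](state))) {
      out <- c(out, unclass(bundles[[i]]))
    }
  }
  out
}

#' First fixed area capturing a screen point
#'
#' Containment is inclusive on all rectangle edges; among overlapping areas
#' the first in declaration order wins.
#'
#' @param areas Ordered list of `fixed_area` objects.
#' @param point Length-2 `(x, y)` screen coordinates.
#' @return The capturing `fixed_area`, or `NULL`.
#' @export
capture_area <- function(areas, point) {
  for (a in areas) {
    if (point_in_rect(point[1], point[2], a$screen_tl, a$screen_br)) {
      return(a)
    }
  }
  NULL
}

#' Redirect a captured screen point to the full-page image
#'
#' Maps a point inside the area's screen rectangle to the corresponding
#' location in its image rectangle by an affine map: each coordinate is scaled
#' by `(image extent - 1) / (screen extent - 1)` about the rectangle's
#' top-left corner, then offset by the image rectangle's top-left. Equal-size
#' rectangles reduce to a pure translation.
#'
#' @param area A `fixed_area`.
#' @param point Length-2 `(x, y)` screen coordinates inside
#'   `area$screen_tl..screen_br`.
#' @return Length-2 `(x, y)` full-page-image coordinates.
#' @export
redirect_point <- function(area, point) {
  if (!point_in_rect(point[1], point[2], area$screen_tl, area$screen_br)) {
    sg_abort(paste0("Point (", point[1], ",", point[2],
                    ") is outside the fixed area's screen rectangle."),
             "contract")
  }
  map1 <- function(p, stl, sbr, itl, ibr) {
    sext <- sbr - stl + 1
    iext <- ibr - itl + 1
    scale <- if (sext == 1) 1 else (iext - 1) / (sext - 1)
    itl + (p - stl) * scale
  }
  c(
    map1(point[1], area$screen_tl[1], area$screen_br[1],
         area$image_tl[1], area$image_br[1]),
    map1(point[2], area$screen_tl[2], area$screen_br[2],
         area$image_tl[2], area$image_br[2])
  )
}

#' Load a declarative fixed-area configuration
#'
#' Reads bundles and their rules from a JSON document of the form
#' ```json
#' {"bundles": [
#'   {"rule": {"kind": "scrolled_less_than", "value": 1000},
#'    "areas": [{"screen": {"tl": [0,0],   "br": [1919,149]},
#'               "image":  {"tl": [0,0],   "br": [1919,149]}}]}
#' ]}
#' ```
#' Supported rule kinds: `always_active`, `scrolled_less_than`,
#' `scrolled_at_least` (the latter two take `value`, a pixel threshold).
#'
#' @param path Path to the JSON configuration.
#' @return A list with elements `bundles` and `rules`, ready for
#'   [eye_scroll_correct()].
#' @export
read_area_config <- function(path) {
  if (!file.exists(path)) {
    sg_abort(paste0("Area configuration file does not exist: ", path), "io")
  }
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  entries <- doc$bundles %||% list()
  bundles <- list()
  rules <- list()
  for (e in entries) {
    rule <- e$rule
    if (is.null(rule$kind)) {
      sg_abort("Every bundle needs a rule with a 'kind' field.", "config")
    }
    r <- switch(
      rule$kind,
      always_active = rule_always_active(),
      scrolled_less_than = rule_scrolled_less_than(as.numeric(rule$value)),
      scrolled_at_least = rule_scrolled_at_least(as.numeric(rule$value)),
      sg_abort(paste0("Unknown rule kind '", rule$kind, "'; supported: ",
                      "always_active, scrolled_less_than, scrolled_at_least."),
               "config")
    )
    areas <- lapply(e$areas, function(a) {
      fixed_area(unlist(a$screen$tl), unlist(a$screen$br),
                 unlist(a$image$tl), unlist(a$image$br))
    })
    bundles <- c(bundles, list(bundle(areas)))
    rules <- c(rules, list(r))
  }
  list(bundles = bundles, rules = rules)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
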