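#' @importFrom rlang abort warn .data :=
#' @importFrom tibble tibble as_tibble
NULL

# Condition helper: all package errors carry "scrollgaze_error" plus a
# machine-readable subclass so callers (and the CLI) can branch on them.
sg_abort <- function(message, class, ...) {
  abort(message, class = c(paste0("scrollgaze_", class, "_error"), "scrollgaze_error"), ...)
}

sg_warn <- function(message, class = "generic") {
  warn(message, class = c(paste0("scrollgaze_", class, "_warning"), "scrollgaze_warning"))
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

# inclusive rectangle containment, 0-based pixel coordinates
point_in_rect <- function(x, y, tl, br) {
  x >= tl[1] && x <= br[1] && y >= tl[2] && y <= br[2]
}
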