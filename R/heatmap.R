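#' Read and write full-page images
#'
#' Thin wrappers around [png::readPNG()]/[png::writePNG()] that keep images
#' as `height x width x channel` arrays with values in `[0, 1]`.
#'
#' @param path PNG file path.
#' @param image Raster array.
#' @return `read_page_image()` returns the raster array;
#'   `write_page_image()` its input, invisibly.
#' @export
read_page_image <- function(path) {
  load_raster(path)
}

#' @rdname read_page_image
#' @export
write_page_image <- function(image, path) {
  png::writePNG(image, path)
  invisible(image)
}

#' Overlay a gaze-density heatmap on the full-page image
#'
#' Builds a density surface from the corrected sample positions — unit point
#' masses (optionally weighted) smoothed by an isotropic Gaussian kernel and
#' normalized to peak 1 — and alpha-composites a colormapped version of it
#' over the full-page image. Pixels with zero density are returned untouched,
#' so the overlay is strictly local to where the participant looked.
#'
#' @param corrected A corrected session table (see [eye_scroll_correct()]),
#'   or any data frame with `Corrected.Fixation.X/Y` or `Corrected.Gaze.X/Y`
#'   columns. Missing corrected coordinates are skipped silently (they are a
#'   documented output state of the correction).
#' @param image Full-page image: PNG path or raster array; output has the
#'   same dimensions.
#' @param kernel_sigma Gaussian kernel standard deviation in pixels
#'   (default 50).
#' @param colormap Palette name understood by [grDevices::hcl.colors()]
#'   (default `"viridis"`, perceptually uniform).
#' @param max_alpha Overlay opacity at the density peak, in `(0, 1]`
#'   (default 0.6).
#' @param source Which coordinate pair to use: `"auto"` prefers fixations and
#'   falls back to gaze; `"fixation"` or `"gaze"` force one.
#' @param weight_col Optional name of a per-row weight column (e.g. fixation
#'   duration); default unweighted, since one row per sample already encodes
#'   dwell time.
#' @return The composited raster array (same dimensions as `image`).
#' @export
generate_heatmap <- function(corrected, image,
                             kernel_sigma = 50,
                             colormap = "viridis",
                             max_alpha = 0.6,
                             source = c("auto", "fixation", "gaze"),
                             weight_col = NULL) {
  source <- match.arg(source)
  img <- load_raster(image)
  h <- dim(img)[1]
  w <- dim(img)[2]
  if (!is_scalar_number(kernel_sigma) || kernel_sigma <= 0) {
    sg_abort("'kernel_sigma' must be a positive number of pixels.", "validation")
  }
  if (!is_scalar_number(max_alpha) || max_alpha <= 0 || max_alpha > 1) {
    sg_abort("'max_alpha' must lie in (0, 1].", "validation")
  }

  cols <- heatmap_source_cols(corrected, source)
  x <- corrected[[cols[1]]]
  y <- corrected[[cols[2]]]
  wt <- if (!is.null(weight_col)) corrected[[weight_col]] else rep(1, length(x))
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]; wt <- wt[keep]
  # points are in 0-based image coordinates; bin to the nearest pixel
  px <- round(x) + 1L
  py <- round(y) + 1L
  inb <- px >= 1L & px <= w & py >= 1L & py <= h
  px <- px[inb]; py <- py[inb]; wt <- wt[inb]

  if (length(px) == 0L) {
    sg_warn("No non-missing corrected points; returning the image unchanged.",
            "empty")
    return(img)
  }

  density <- matrix(0, nrow = h, ncol = w)
  for (k in seq_along(px)) {
    density[py[k], px[k]] <- density[py[k], px[k]] + wt[k]
  }
  density <- gaussian_blur(density, kernel_sigma)
  density <- density / max(density)

  ramp <- grDevices::colorRamp(grDevices::hcl.colors(256, colormap))
  col <- ramp(as.vector(density)) / 255
  alpha <- max_alpha * as.vector(density)

  out <- img
  for (ch in 1:3) {
    base <- as.vector(img[, , ch])
    out[, , ch] <- matrix((1 - alpha) * base + alpha * col[, ch], nrow = h)
  }
  out
}

heatmap_source_cols <- function(corrected, source) {
  fix <- c("Corrected.Fixation.X", "Corrected.Fixation.Y")
  gaze <- c("Corrected.Gaze.X", "Corrected.Gaze.Y")
  has <- function(p) all(p %in% names(corrected))
  cols <- switch(source,
    fixation = if (has(fix)) fix else NULL,
    gaze = if (has(gaze)) gaze else NULL,
    auto = if (has(fix)) fix else if (has(gaze)) gaze else NULL
  )
  if (is.null(cols)) {
    sg_abort(paste0("Corrected table lacks the '", source,
                    "' corrected coordinate columns."),
             "schema")
  }
  cols
}

# Separable Gaussian blur with a truncated (4 sigma) kernel and zero padding,
# so the smoothed field is exactly zero outside the kernel support — the
# overlay must not leak across the whole image the way periodic (FFT
# wrap-around) boundary conditions would.
gaussian_blur <- function(mat, sigma) {
  r <- max(1L, as.integer(ceiling(4 * sigma)))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  conv1 <- function(v) {
    out <- stats::convolve(v, rev(k), type = "open")
    out[(r + 1):(r + length(v))]
  }
  mat <- apply(mat, 2, conv1)     # along columns (y)
  mat <- t(apply(mat, 1, conv1))  # along rows (x)
  # the FFT leaves ~1e-17 residue (and sign wobble) where the true
  # convolution is zero; snap it back so the field is exactly local
  mat[abs(mat) < max(abs(mat)) * 1e-12] <- 0
  pmax(mat, 0)
}

#' Plot a page image or heatmap with ggplot2
#'
#' @param image Raster array or PNG path.
#' @return A ggplot object drawing the raster at pixel scale.
#' @export
plot_page_image <- function(image) {
  img <- load_raster(image)
  h <- dim(img)[1]
  w <- dim(img)[2]
  ggplot2::ggplot() +
    ggplot2::annotation_raster(img, xmin = 0, xmax = w, ymin = -h, ymax = 0) +
    ggplot2::scale_x_continuous(limits = c(0, w), expand = c(0, 0)) +
    ggplot2::scale_y_continuous(limits = c(-h, 0), expand = c(0, 0),
                                labels = function(b) -b) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (px)", y = "y (px)") +
    ggplot2::theme_void()
}
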