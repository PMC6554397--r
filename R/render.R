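#' Rendering parameters for synthetic two-channel fluorescence images
#'
#' Cells are painted as filled ellipses (long axis along the flow) into the
#' channel matching their lineage color, then blurred, overlaid on a
#' background with a linear gradient, and corrupted with additive Gaussian
#' noise. The ground-truth masks are the pre-blur, pre-noise labelings.
#'
#' The default pixel size, 0.1791 um/pixel, is back-derived from the printed
#' equivalence of the mean single-cell footprint (1.29 um^2) with 40.2
#' pixels; it makes the pipeline's 15-pixel and 200-pixel area thresholds
#' physically meaningful on synthetic data. The exact
#' magnification-to-pixel mapping of the original acquisitions is not
#' recoverable, so this value is an inference, not a measurement.
#'
#' @param pixel_um pixel size (um/pixel), positive.
#' @param footprint_um2 projected cell area (um^2); default 1.29.
#' @param aspect cell aspect ratio (length/width); default 2.5, giving a
#'   roughly 2 x 0.8 um crescentoid footprint.
#' @param blur_um Gaussian blur scale (um); default 0.25.
#' @param background baseline background intensity; default 0.08.
#' @param gradient amplitude of a linear background gradient along x;
#'   default 0.04.
#' @param noise_sd additive Gaussian noise scale; default 0.01.
#' @param cell_intensity intensity added per cell; default 0.6.
#' @param seed integer RNG seed for the noise draw.
#' @return an object of class `render_params`.
#' @export
render_params <- function(pixel_um = 0.1791, footprint_um2 = 1.29,
                          aspect = 2.5, blur_um = 0.25, background = 0.08,
                          gradient = 0.04, noise_sd = 0.01,
                          cell_intensity = 0.6, seed = NULL) {
  if (pixel_um <= 0) stop("pixel_um must be positive", call. = FALSE)
  if (footprint_um2 <= 0) stop("footprint_um2 must be positive", call. = FALSE)
  if (aspect < 1) stop("aspect must be >= 1", call. = FALSE)
  if (blur_um < 0 || noise_sd < 0 || background < 0) {
    stop("blur, noise and background must be nonnegative", call. = FALSE)
  }
  structure(
    list(pixel_um = pixel_um, footprint_um2 = footprint_um2, aspect = aspect,
         blur_um = blur_um, background = background, gradient = gradient,
         noise_sd = noise_sd, cell_intensity = cell_intensity, seed = seed),
    class = "render_params"
  )
}

# paint filled ellipses (semi-axes a, b in px) at continuous pixel coords
# (cx, cy) into a logical/numeric accumulator of dim (nx, ny); a pixel
# belongs to a cell when at least half of it is covered (5 x 5 subpixel
# sampling, which keeps rasterized areas within ~1-2 px of the continuum
# footprint at any subpixel phase)
paint_ellipses <- function(nx, ny, cx, cy, a, b, intensity = NULL) {
  truth <- matrix(FALSE, nx, ny)
  img <- if (is.null(intensity)) NULL else matrix(0, nx, ny)
  sub <- (seq_len(5) - 3) / 5           # subpixel offsets -2/5 ... 2/5
  for (k in seq_along(cx)) {
    ix <- seq(max(1L, ceiling(cx[k] - a + 0.5 - 1e-9)),
              min(nx, floor(cx[k] + a + 0.5 + 1e-9)))
    iy <- seq(max(1L, ceiling(cy[k] - b + 0.5 - 1e-9)),
              min(ny, floor(cy[k] + b + 0.5 + 1e-9)))
    if (!length(ix) || !length(iy) || ix[1] > ix[length(ix)] ||
        iy[1] > iy[length(iy)]) next
    cover <- matrix(0L, length(ix), length(iy))
    for (ox in sub) for (oy in sub) {
      dx <- (ix - 0.5 + ox - cx[k]) / a
      dy <- (iy - 0.5 + oy - cy[k]) / b
      cover <- cover + (outer(dx^2, dy^2, `+`) <= 1)
    }
    inside <- cover >= 13L              # >= half of the 25 subsamples
    if (any(inside)) {
      truth[ix, iy] <- truth[ix, iy] | inside
      if (!is.null(img)) img[ix, iy] <- img[ix, iy] + intensity * inside
    }
  }
  list(truth = truth, img = img)
}

#' Render a surface population into a two-channel synthetic image
#'
#' @param cells data.frame with columns `x_um`, `y_um`, `color`
#'   (`"green"`/`"magenta"`), e.g. from [cells_at()]. May be empty.
#' @param window viewing window on the floor, a list/vector with `x_um`,
#'   `y_um` (lower corner), `width_um`, `height_um`.
#' @param params a [render_params()].
#' @param geometry optional [channel_geometry()]; if given, the window must
#'   lie within the channel floor.
#' @return an object of class `synthetic_image`: intensity rasters `ch1`
#'   (green) and `ch2` (magenta) as matrices indexed \[x, y\], logical
#'   ground-truth masks `truth1`, `truth2`, 8-connected ground-truth label
#'   matrices `labels1`, `labels2`, `pixel_um`, and provenance (`params`,
#'   `window`).
#' @export
render_population <- function(cells, window, params = render_params(),
                              geometry = NULL) {
  stopifnot(inherits(params, "render_params"))
  window <- as.list(window)
  req <- c("x_um", "y_um", "width_um", "height_um")
  if (!all(req %in% names(window))) {
    stop("window needs fields ", paste(req, collapse = ", "), call. = FALSE)
  }
  if (!is.null(geometry)) {
    stopifnot(is_channel_geometry(geometry))
    if (window$x_um < 0 || window$y_um < 0 ||
        um_to_m(window$x_um + window$width_um) > geometry$length ||
        um_to_m(window$y_um + window$height_um) > geometry$width) {
      stop("window extends outside the channel floor", call. = FALSE)
    }
  }
  px <- params$pixel_um
  nx <- round(window$width_um / px)
  ny <- round(window$height_um / px)
  if (nx * ny * px^2 < params$footprint_um2) {
    stop("window smaller than one cell footprint", call. = FALSE)
  }
  b_um <- sqrt(params$footprint_um2 / (pi * params$aspect))
  a_px <- params$aspect * b_um / px
  b_px <- b_um / px

  channels <- list(green = NULL, magenta = NULL)
  for (col in names(channels)) {
    sel <- nrow(cells) > 0 && any(cells$color == col)
    if (isTRUE(sel)) {
      cc <- cells[cells$color == col, , drop = FALSE]
      # keep cells whose ellipse can intersect the window
      inwin <- cc$x_um > window$x_um - 2 * params$aspect * b_um &
               cc$x_um < window$x_um + window$width_um + 2 * params$aspect * b_um &
               cc$y_um > window$y_um - 2 * b_um &
               cc$y_um < window$y_um + window$height_um + 2 * b_um
      cc <- cc[inwin, , drop = FALSE]
      channels[[col]] <- paint_ellipses(
        nx, ny,
        (cc$x_um - window$x_um) / px, (cc$y_um - window$y_um) / px,
        a_px, b_px, intensity = params$cell_intensity)
    } else {
      channels[[col]] <- list(truth = matrix(FALSE, nx, ny),
                              img = matrix(0, nx, ny))
    }
  }

  if (!is.null(params$seed)) set.seed(params$seed)
  bg <- params$background +
    params$gradient * matrix(rep(seq_len(nx) / nx, ny), nx, ny)
  finish <- function(img) {
    if (params$blur_um > 0) {
      sigma <- params$blur_um / px
      img <- EBImage::imageData(EBImage::gblur(EBImage::Image(img), sigma))
    }
    img <- img + bg
    if (params$noise_sd > 0) {
      img <- img + matrix(stats::rnorm(nx * ny, 0, params$noise_sd), nx, ny)
    }
    pmax(img, 0)
  }
  ch1 <- finish(channels$green$img)
  ch2 <- finish(channels$magenta$img)

  structure(
    list(ch1 = ch1, ch2 = ch2,
         truth1 = channels$green$truth, truth2 = channels$magenta$truth,
         labels1 = label8(channels$green$truth),
         labels2 = label8(channels$magenta$truth),
         pixel_um = px, params = params, window = window),
    class = "synthetic_image"
  )
}

#' @export
print.synthetic_image <- function(x, ...) {
  cat(sprintf(
    "synthetic image: %d x %d px at %.4f um/px; %d green / %d magenta ground-truth objects\n",
    nrow(x$ch1), ncol(x$ch1), x$pixel_um, max(x$labels1), max(x$labels2)))
  invisible(x)
}

# assemble a synthetic_image from explicit truth masks (for fixtures)
image_from_truth <- function(truth1, truth2, pixel_um = 0.1791, seed = 1,
                             background = 0.05, noise_sd = 0.005,
                             cell_intensity = 0.6) {
  set.seed(seed)
  nx <- nrow(truth1); ny <- ncol(truth1)
  mk <- function(truth) {
    pmax(cell_intensity * truth + background +
           matrix(stats::rnorm(nx * ny, 0, noise_sd), nx, ny), 0)
  }
  structure(
    list(ch1 = mk(truth1), ch2 = mk(truth2),
         truth1 = truth1, truth2 = truth2,
         labels1 = label8(truth1), labels2 = label8(truth2),
         pixel_um = pixel_um,
         params = list(pixel_um = pixel_um, background = background,
                       noise_sd = noise_sd, cell_intensity = cell_intensity,
                       seed = seed),
         window = NULL),
    class = "synthetic_image"
  )
}

#' Deterministic toy fixtures with documented ground truth
#'
#' Small seed-pinned synthetic images used to exercise the quantification
#' pipeline:
#' \describe{
#'   \item{blank}{128 x 128, no objects in either channel.}
#'   \item{single_cell}{one rendered cell of the default 1.29 um^2
#'     footprint at the default 0.1791 um pixel (about 40 px).}
#'   \item{two_squares_gap6}{two 20 x 20 px squares in the green channel
#'     separated by a 6 px gap: radius-5 closing bridges the gap.}
#'   \item{two_squares_gap20}{same squares with a 20 px gap: closing does
#'     not bridge.}
#'   \item{checkerboard_mixed}{an 8 x 8 chessboard of 5 x 5 px squares with
#'     16 px centroid spacing, colors alternating, so every object's
#'     nearest other-color centroid is exactly 16 px away.}
#'   \item{segregated_halves}{one green and one magenta block with centroids
#'     70 px apart (facing edges 30 px apart).}
#'   \item{near_saturated}{green coverage above 0.8, to exercise the
#'     coverage gate.}
#' }
#'
#' @param name one of the fixture names above.
#' @return a `synthetic_image`.
#' @export
make_fixture <- function(name) {
  fixtures <- c("blank", "single_cell", "two_squares_gap6",
                "two_squares_gap20", "checkerboard_mixed",
                "segregated_halves", "near_saturated")
  if (!is.character(name) || length(name) != 1L || !(name %in% fixtures)) {
    stop("unknown fixture; valid fixtures: ",
         paste(fixtures, collapse = ", "), call. = FALSE)
  }
  empty <- function(nx, ny) matrix(FALSE, nx, ny)
  switch(
    name,
    blank = image_from_truth(empty(128, 128), empty(128, 128), seed = 101),
    single_cell = {
      cells <- data.frame(x_um = 11.64, y_um = 11.5, color = "green",
                          stringsAsFactors = FALSE)
      render_population(
        cells,
        window = list(x_um = 0, y_um = 0, width_um = 23, height_um = 23),
        params = render_params(blur_um = 0.15, noise_sd = 0.005, seed = 102))
    },
    two_squares_gap6 = {
      t1 <- empty(120, 80)
      t1[20:39, 30:49] <- TRUE
      t1[46:65, 30:49] <- TRUE
      image_from_truth(t1, empty(120, 80), seed = 103)
    },
    two_squares_gap20 = {
      t1 <- empty(120, 80)
      t1[20:39, 30:49] <- TRUE
      t1[60:79, 30:49] <- TRUE
      image_from_truth(t1, empty(120, 80), seed = 104)
    },
    checkerboard_mixed = {
      t1 <- empty(144, 144); t2 <- empty(144, 144)
      for (i in 0:7) for (j in 0:7) {
        ix <- (9 + 16 * i):(13 + 16 * i)
        iy <- (9 + 16 * j):(13 + 16 * j)
        if ((i + j) %% 2 == 0) t1[ix, iy] <- TRUE else t2[ix, iy] <- TRUE
      }
      image_from_truth(t1, t2, seed = 105)
    },
    segregated_halves = {
      t1 <- empty(140, 90); t2 <- empty(140, 90)
      t1[21:50, 21:70] <- TRUE    # centroid x = 35
      t2[91:120, 21:70] <- TRUE   # centroid x = 105
      image_from_truth(t1, t2, seed = 106)
    },
    near_saturated = {
      t1 <- empty(100, 100)
      t1[5:96, 5:96] <- TRUE      # coverage 0.8464
      image_from_truth(t1, empty(100, 100), seed = 107)
    }
  )
}
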