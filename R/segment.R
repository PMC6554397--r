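#' 8-connected component labelling
#'
#' Labels connected components of a logical mask using 8-connectivity
#' (edge- and corner-adjacent pixels belong to the same object). Built on
#' EBImage's 4-connected labelling with a union-find merge of diagonally
#' touching labels; labels are contiguous positive integers.
#'
#' @param mask logical matrix.
#' @return integer matrix of the same dimension; 0 is background.
#' @export
label8 <- function(mask) {
  stopifnot(is.matrix(mask))
  storage.mode(mask) <- "logical"
  if (!any(mask)) return(matrix(0L, nrow(mask), ncol(mask)))
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask)))
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  nlab <- max(lab)
  if (nlab > 1L) {
    nx <- nrow(lab); ny <- ncol(lab)
    # diagonal label adjacencies (down-right and up-right neighbours)
    a1 <- lab[-nx, -ny]; b1 <- lab[-1, -1]
    a2 <- lab[-1, -ny]; b2 <- lab[-nx, -1]
    s1 <- a1 > 0L & b1 > 0L & a1 != b1
    s2 <- a2 > 0L & b2 > 0L & a2 != b2
    pairs <- rbind(cbind(a1[s1], b1[s1]), cbind(a2[s2], b2[s2]))
    if (nrow(pairs)) {
      parent <- seq_len(nlab)
      find <- function(i) {
        while (parent[i] != i) {
          parent[i] <<- parent[parent[i]]
          i <- parent[i]
        }
        i
      }
      for (r in seq_len(nrow(pairs))) {
        ri <- find(pairs[r, 1]); rj <- find(pairs[r, 2])
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
      root <- vapply(seq_len(nlab), find, integer(1))
      remap <- match(root, sort(unique(root)))
      lab[lab > 0L] <- remap[lab[lab > 0L]]
    }
  }
  lab
}

# areas (px) and centroids (px, pixel-center convention) of labelled objects
label_stats <- function(labels) {
  idx <- which(labels > 0L)
  if (!length(idx)) {
    return(list(areas = integer(0),
                centroids = matrix(numeric(0), 0, 2,
                                   dimnames = list(NULL, c("cx", "cy")))))
  }
  lab <- labels[idx]
  nx <- nrow(labels)
  ix <- ((idx - 1L) %% nx) + 1L
  iy <- ((idx - 1L) %/% nx) + 1L
  areas <- tabulate(lab)
  cx <- rowsum(ix - 0.5, lab)[, 1] / areas
  cy <- rowsum(iy - 0.5, lab)[, 1] / areas
  list(areas = areas, centroids = cbind(cx = cx, cy = cy))
}

# drop labelled objects below min_area px and relabel contiguously
filter_small <- function(labels, min_area) {
  if (max(labels) == 0L || min_area <= 1) return(labels)
  areas <- tabulate(labels[labels > 0L])
  keep <- which(areas >= min_area)
  remap <- integer(length(areas))
  remap[keep] <- seq_along(keep)
  out <- labels
  out[out > 0L] <- remap[out[out > 0L]]
  out
}

#' Morphological closing with a disc structuring element
#'
#' Dilation followed by erosion with a disc brush of the given radius
#' (nominal radius 5 px by default, matching the pipeline's
#' colony-bridging step).
#'
#' @param mask logical matrix.
#' @param radius disc radius in pixels.
#' @return logical matrix.
#' @export
close_mask <- function(mask, radius = 5) {
  stopifnot(is.matrix(mask))
  if (radius <= 0 || !any(mask)) return(mask)
  kern <- EBImage::makeBrush(2 * radius + 1, shape = "disc")
  m <- EBImage::imageData(
    EBImage::closing(EBImage::Image(mask * 1), kern))
  matrix(m > 0.5, nrow(mask), ncol(mask))
}

#' Segmentation parameters
#'
#' The segmentation discriminates cells from background with a local-mean
#' adaptive threshold whose sensitivity, and the percentage of dimmest
#' pixels removed as background, both depend on the image's median
#' intensity through configurable piecewise-linear mappings. Objects below
#' `min_area` pixels (default 15, the minimal footprint of a single cell
#' standing vertically) are discarded. The original calibrations of the
#' sensitivity and background mappings are not recoverable, so the defaults
#' here are declared approximations: sensitivity 0.5 at zero median rising
#' to 0.65 at high median, background removal 0 to 10%.
#'
#' @param sens_breaks,sens_values piecewise-linear mapping from median
#'   intensity to threshold sensitivity in (0, 1\]; higher sensitivity
#'   lowers the threshold (more foreground).
#' @param bg_breaks,bg_values mapping from median intensity to the fraction
#'   of dimmest pixels forced to background.
#' @param window_px odd box size (pixels) of the local-mean neighbourhood;
#'   `NULL` derives `2 * floor(min(dim)/16) + 1` from the image.
#' @param min_area minimum object area in pixels (>= 1).
#' @return an object of class `seg_params`.
#' @export
seg_params <- function(sens_breaks = c(0, 0.15),
                       sens_values = c(0.5, 0.65),
                       bg_breaks = c(0, 0.15),
                       bg_values = c(0, 0.10),
                       window_px = NULL, min_area = 15) {
  if (any(sens_values <= 0) || any(sens_values > 1)) {
    stop("sensitivity values must lie in (0, 1]", call. = FALSE)
  }
  if (min_area < 1) stop("min_area must be >= 1", call. = FALSE)
  if (!is.null(window_px) && (window_px < 3 || window_px %% 2 == 0)) {
    stop("window_px must be an odd integer >= 3", call. = FALSE)
  }
  structure(
    list(sens_breaks = sens_breaks, sens_values = sens_values,
         bg_breaks = bg_breaks, bg_values = bg_values,
         window_px = window_px, min_area = min_area),
    class = "seg_params"
  )
}

piecewise <- function(x, breaks, values) {
  stats::approx(breaks, values, xout = x, rule = 2)$y
}

#' Segment one fluorescence channel
#'
#' Local-mean adaptive threshold: a pixel is foreground when its intensity
#' exceeds the local mean (box neighbourhood, replicated borders) by
#' `(1 - sensitivity) * A / 2`, where `A` is the image's signal amplitude
#' (99.9th percentile minus median); the sensitivity is chosen from the
#' median-intensity mapping in [seg_params()]. The quarter-amplitude
#' offset at the default sensitivity 0.5 keeps dimly lit single-layer
#' cells while rejecting background, also in fields whose amplitude is
#' inflated by multi-cell stacking; a noise floor of three robust standard
#' deviations of the local residual prevents spurious objects on
#' signal-free images. The mapped fraction of
#' dimmest pixels is then removed, components are labelled with
#' 8-connectivity, and objects below `min_area` pixels are discarded.
#' A constant-intensity raster yields an empty result with a warning
#' (aberrant segmentation).
#'
#' @param raster numeric matrix of nonnegative intensities, indexed \[x, y\].
#' @param params a [seg_params()].
#' @param channel optional channel tag carried through to the result.
#' @return an object of class `segmentation_result`: logical `mask`,
#'   integer `labels`, per-object `areas` (px) and `centroids` (px), the
#'   resolved `sensitivity` and `bg_fraction`, and `channel`.
#' @export
segment_channel <- function(raster, params = seg_params(), channel = NA) {
  stopifnot(is.matrix(raster), inherits(params, "seg_params"))
  if (any(raster < 0)) stop("raster intensities must be nonnegative",
                            call. = FALSE)
  empty_result <- function(sens = NA_real_, bgf = NA_real_) {
    structure(
      list(mask = matrix(FALSE, nrow(raster), ncol(raster)),
           labels = matrix(0L, nrow(raster), ncol(raster)),
           areas = integer(0),
           centroids = matrix(numeric(0), 0, 2,
                              dimnames = list(NULL, c("cx", "cy"))),
           sensitivity = sens, bg_fraction = bgf, channel = channel,
           params = params),
      class = "segmentation_result")
  }
  rng <- range(raster)
  if (diff(rng) == 0) {
    warning("constant-intensity raster: aberrant segmentation, ",
            "returning empty result")
    return(empty_result())
  }
  med <- stats::median(raster)
  sens <- piecewise(med, params$sens_breaks, params$sens_values)
  bgf <- piecewise(med, params$bg_breaks, params$bg_values)
  w <- params$window_px
  if (is.null(w)) w <- 2L * (min(dim(raster)) %/% 16L) + 1L
  w <- min(w, 2L * ((min(dim(raster)) - 1L) %/% 2L) + 1L)
  box <- EBImage::makeBrush(w, shape = "box") / w^2
  local_mean <- EBImage::imageData(
    EBImage::filter2(EBImage::Image(raster), box, boundary = "replicate"))
  amp <- stats::quantile(raster, 0.999, names = FALSE) - med
  if (amp <= 0) {
    warning("no signal above the median: returning empty result")
    return(empty_result(sens, bgf))
  }
  # noise floor: never threshold below 3x the robust residual scale, so
  # pure-noise images do not segment into spurious objects
  resid_scale <- stats::mad(raster - local_mean)
  mask <- raster > local_mean + pmax((1 - sens) * amp / 2, 3 * resid_scale)
  if (bgf > 0) {
    mask[raster <= stats::quantile(raster, bgf, names = FALSE)] <- FALSE
  }
  labels <- filter_small(label8(mask), params$min_area)
  mask <- labels > 0L
  st <- label_stats(labels)
  structure(
    list(mask = mask, labels = labels, areas = st$areas,
         centroids = st$centroids, sensitivity = sens, bg_fraction = bgf,
         channel = channel, params = params),
    class = "segmentation_result"
  )
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf(
    "segmentation: %d objects (sensitivity %.3f, background removal %.1f%%)\n",
    length(x$areas), x$sensitivity, 100 * x$bg_fraction))
  invisible(x)
}
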