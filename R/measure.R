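#' Surface coverage of two merged segmentation masks
#'
#' The two channel masks are merged with a logical OR and coverage is the
#' occupied fraction of the image.
#'
#' @param mask_a,mask_b logical matrices of identical dimension (one may be
#'   `NULL` to measure a single channel).
#' @return fraction in \[0, 1\].
#' @export
surface_coverage <- function(mask_a, mask_b = NULL) {
  if (is.null(mask_b)) mask_b <- mask_a
  stopifnot(is.matrix(mask_a), is.matrix(mask_b))
  if (!all(dim(mask_a) == dim(mask_b))) {
    stop("mask shape mismatch", call. = FALSE)
  }
  mean(mask_a | mask_b)
}

#' Microcolony areas from merged channel masks
#'
#' Implements the colony-area pipeline: coverage is computed first and
#' images with coverage above the gate (default 0.8, where individual
#' clusters can no longer be discriminated) are excluded from area
#' measurement. Otherwise the OR-merged mask is filtered of objects smaller
#' than `min_colony_px` (default 200 px, about five cells), closed with a
#' disc of radius `close_radius` (default 5 px), and connected-component
#' areas are reported in um^2 together with their median. The
#' filter-then-close order is the default; `filter_then_close = FALSE`
#' swaps it for sensitivity analysis.
#'
#' @param mask_a,mask_b logical channel masks of identical dimension.
#' @param pixel_um pixel size (um/pixel).
#' @param gate coverage gate; default 0.8.
#' @param min_colony_px minimum colony area in pixels; default 200.
#' @param close_radius disc radius for closing; default 5 px.
#' @param filter_then_close apply the size filter before closing (default).
#' @return an object of class `colony_stats`: `coverage`, `gated`,
#'   `areas_um2`, `median_um2`, `n_colonies`, `pixel_um`.
#' @export
colony_areas <- function(mask_a, mask_b, pixel_um, gate = 0.8,
                         min_colony_px = 200, close_radius = 5,
                         filter_then_close = TRUE) {
  if (pixel_um <= 0) stop("pixel_um must be positive", call. = FALSE)
  coverage <- surface_coverage(mask_a, mask_b)
  if (coverage > gate) {
    return(structure(
      list(coverage = coverage, gated = TRUE, areas_um2 = NULL,
           median_um2 = NA_real_, n_colonies = NA_integer_,
           pixel_um = pixel_um),
      class = "colony_stats"))
  }
  merged <- mask_a | mask_b
  if (filter_then_close) {
    merged <- filter_small(label8(merged), min_colony_px) > 0L
    merged <- close_mask(merged, close_radius)
    labels <- label8(merged)
  } else {
    merged <- close_mask(merged, close_radius)
    labels <- filter_small(label8(merged), min_colony_px)
  }
  areas_px <- label_stats(labels)$areas
  areas_um2 <- areas_px * pixel_um^2
  structure(
    list(coverage = coverage, gated = FALSE, areas_um2 = areas_um2,
         median_um2 = if (length(areas_um2)) stats::median(areas_um2)
                      else NA_real_,
         n_colonies = length(areas_um2), pixel_um = pixel_um),
    class = "colony_stats"
  )
}

#' @export
print.colony_stats <- function(x, ...) {
  if (x$gated) {
    cat(sprintf(
      "colony stats: coverage %.1f%% > gate, excluded from area analysis\n",
      100 * x$coverage))
  } else {
    cat(sprintf(
      "colony stats: coverage %.1f%%, %d colonies, median area %.2f um^2\n",
      100 * x$coverage, x$n_colonies, x$median_um2))
  }
  invisible(x)
}

# nearest-neighbour distances from each row of A to the rows of B (px)
nn_dist <- function(a, b) {
  d2 <- outer(a[, 1], b[, 1], `-`)^2 + outer(a[, 2], b[, 2], `-`)^2
  sqrt(apply(d2, 1, min))
}

#' Cross-lineage mixing from two segmented channels
#'
#' Each channel mask is closed (disc radius `close_radius`), its objects'
#' centroids extracted, and for every object of one color the Euclidean
#' distance to the nearest centroid of the other color is recorded;
#' distances from both directions are pooled. By default no colony-size
#' filter is applied before the mixing analysis (`min_colony_px = NULL`);
#' pass 200 to reproduce the alternative reading where only colony-sized
#' objects enter. If either channel has no objects, mixing is undefined
#' (distinct from zero) and reported as missing.
#'
#' @param result_a,result_b [segment_channel()] results (or logical masks)
#'   from same-shaped rasters; the coverage gate is assumed to have been
#'   applied upstream.
#' @param pixel_um pixel size (um/pixel).
#' @param close_radius disc radius for the pre-centroid closing; default 5.
#' @param min_colony_px optional minimum object size (px) applied before
#'   closing; default `NULL` (no filter).
#' @return an object of class `mixing_stats`: `defined`, pooled
#'   `distances_um`, `mean_um`, `sd_um`, `n` (= objects in A + objects in
#'   B), and per-channel object counts.
#' @export
cross_lineage_mixing <- function(result_a, result_b, pixel_um,
                                 close_radius = 5, min_colony_px = NULL) {
  if (pixel_um <= 0) stop("pixel_um must be positive", call. = FALSE)
  get_mask <- function(r) {
    if (inherits(r, "segmentation_result")) r$mask
    else if (is.matrix(r)) r
    else stop("expected a segmentation_result or logical mask", call. = FALSE)
  }
  ma <- get_mask(result_a); mb <- get_mask(result_b)
  if (!all(dim(ma) == dim(mb))) stop("mask shape mismatch", call. = FALSE)
  prep <- function(m) {
    if (!is.null(min_colony_px)) {
      m <- filter_small(label8(m), min_colony_px) > 0L
    }
    label_stats(label8(close_mask(m, close_radius)))$centroids
  }
  ca <- prep(ma); cb <- prep(mb)
  if (nrow(ca) == 0L || nrow(cb) == 0L) {
    return(structure(
      list(defined = FALSE, distances_um = numeric(0), mean_um = NA_real_,
           sd_um = NA_real_, n = 0L, n_a = nrow(ca), n_b = nrow(cb)),
      class = "mixing_stats"))
  }
  d <- c(nn_dist(ca, cb), nn_dist(cb, ca)) * pixel_um
  structure(
    list(defined = TRUE, distances_um = d, mean_um = mean(d),
         sd_um = if (length(d) > 1) stats::sd(d) else NA_real_,
         n = length(d), n_a = nrow(ca), n_b = nrow(cb)),
    class = "mixing_stats"
  )
}

#' @export
print.mixing_stats <- function(x, ...) {
  if (!x$defined) {
    cat("cross-lineage mixing: undefined (a channel has no objects)\n")
  } else {
    cat(sprintf(
      "cross-lineage mixing: mean %.2f um, sd %.2f um (n = %d distances)\n",
      x$mean_um, x$sd_um, x$n))
  }
  invisible(x)
}

#' Cross-lineage mixing from a simulated cell table (ground truth)
#'
#' Bypasses rendering and segmentation: cells are grouped by founder
#' lineage (the ground-truth notion of a colony), each group's centroid is
#' computed, and cross-color nearest-neighbour centroid distances are
#' pooled from both directions, exactly as in [cross_lineage_mixing()].
#'
#' @param cells data.frame with `x_um`, `y_um`, `color`, `founder` (e.g.
#'   from [cells_at()]).
#' @param min_cells minimum number of cells for a lineage group to count as
#'   a colony; default 1.
#' @return a `mixing_stats` object.
#' @export
mixing_from_table <- function(cells, min_cells = 1) {
  stopifnot(all(c("x_um", "y_um", "color", "founder") %in% names(cells)))
  undefined <- structure(
    list(defined = FALSE, distances_um = numeric(0), mean_um = NA_real_,
         sd_um = NA_real_, n = 0L, n_a = 0L, n_b = 0L),
    class = "mixing_stats")
  if (nrow(cells) == 0L) return(undefined)
  grp <- interaction(cells$founder, cells$color, drop = TRUE)
  size <- as.vector(table(grp)[as.character(levels(grp))])
  cx <- tapply(cells$x_um, grp, mean)
  cy <- tapply(cells$y_um, grp, mean)
  col <- tapply(cells$color, grp, function(z) z[1])
  keep <- size >= min_cells
  ca <- cbind(cx, cy)[keep & col == "green", , drop = FALSE]
  cb <- cbind(cx, cy)[keep & col == "magenta", , drop = FALSE]
  if (nrow(ca) == 0L || nrow(cb) == 0L) return(undefined)
  d <- c(nn_dist(ca, cb), nn_dist(cb, ca))
  structure(
    list(defined = TRUE, distances_um = d, mean_um = mean(d),
         sd_um = if (length(d) > 1) stats::sd(d) else NA_real_,
         n = length(d), n_a = nrow(ca), n_b = nrow(cb)),
    class = "mixing_stats"
  )
}

#' Detect attachment events from a time-ordered frame sequence
#'
#' An attachment event is a new object that remains at the same location
#' (centroid within `eps_px`) for at least `min_consecutive` consecutive
#' frames; the event is recorded at the first frame of each maximal
#' persistent run. Objects are linked frame-to-frame by greedy
#' nearest-centroid matching within `eps_px`.
#'
#' @param frames list of per-frame object tables (data.frames with `x`,
#'   `y` centroid columns, in pixels), time-ordered; or a list of
#'   [segment_channel()] results.
#' @param times frame times (s), uniformly spaced, same length as `frames`.
#' @param eps_px same-location tolerance in pixels; default 3.
#' @param min_consecutive minimum run length; default 3 frames.
#' @return numeric vector of event times (s), sorted.
#' @export
detect_attachment_events <- function(frames, times, eps_px = 3,
                                     min_consecutive = 3) {
  if (length(frames) != length(times)) {
    stop("frames and times must have equal length", call. = FALSE)
  }
  if (length(frames) < min_consecutive) {
    stop("need at least ", min_consecutive, " frames", call. = FALSE)
  }
  dt <- diff(times)
  if (any(abs(dt - dt[1]) > 1e-6 * max(abs(dt[1]), 1e-300))) {
    stop("non-uniform frame timestamps", call. = FALSE)
  }
  as_tab <- function(f) {
    if (inherits(f, "segmentation_result")) {
      data.frame(x = f$centroids[, "cx"], y = f$centroids[, "cy"])
    } else f
  }
  # active tracks: x, y, start frame index, run length
  tr_x <- numeric(0); tr_y <- numeric(0)
  tr_start <- integer(0); tr_len <- integer(0)
  events <- numeric(0)
  close_tracks <- function(idx) {
    done <- tr_len[idx] >= min_consecutive
    events <<- c(events, times[tr_start[idx[done]]])
  }
  for (fi in seq_along(frames)) {
    tab <- as_tab(frames[[fi]])
    nobj <- if (is.null(tab)) 0L else nrow(tab)
    matched_tr <- rep(FALSE, length(tr_x))
    matched_ob <- rep(FALSE, nobj)
    if (nobj > 0L && length(tr_x) > 0L) {
      d <- sqrt(outer(tab$x, tr_x, `-`)^2 + outer(tab$y, tr_y, `-`)^2)
      repeat {
        m <- which.min(d)
        if (!length(m) || d[m] > eps_px) break
        oi <- ((m - 1L) %% nobj) + 1L
        ti <- ((m - 1L) %/% nobj) + 1L
        matched_ob[oi] <- TRUE; matched_tr[ti] <- TRUE
        tr_x[ti] <- tab$x[oi]; tr_y[ti] <- tab$y[oi]
        tr_len[ti] <- tr_len[ti] + 1L
        d[oi, ] <- Inf; d[, ti] <- Inf
      }
    }
    if (any(!matched_tr)) {
      close_tracks(which(!matched_tr))
      keep <- matched_tr
      tr_x <- tr_x[keep]; tr_y <- tr_y[keep]
      tr_start <- tr_start[keep]; tr_len <- tr_len[keep]
    }
    if (any(!matched_ob)) {
      new <- which(!matched_ob)
      tr_x <- c(tr_x, tab$x[new]); tr_y <- c(tr_y, tab$y[new])
      tr_start <- c(tr_start, rep(fi, length(new)))
      tr_len <- c(tr_len, rep(1L, length(new)))
    }
  }
  if (length(tr_x)) close_tracks(seq_along(tr_x))
  sort(events)
}

#' Attachment rate from event times
#'
#' Ordinary least squares of the cumulative attached-cell count against
#' frame time; the slope is the attachment rate r (cells per second).
#'
#' @param event_times attachment event times (s).
#' @param frame_times the observation frame times (s); the cumulative count
#'   is evaluated at each.
#' @return an object of class `attachment_rate`: `rate` (cells s^-1), its
#'   standard error `se`, the number of events `n_events`, and
#'   `no_events` flag (zero events give rate 0 with infinite relative
#'   error).
#' @export
attachment_rate <- function(event_times, frame_times) {
  if (length(frame_times) < 2) stop("need at least 2 frames", call. = FALSE)
  if (diff(range(frame_times)) <= 0) stop("observation span must be positive",
                                          call. = FALSE)
  if (length(event_times) == 0L) {
    return(structure(
      list(rate = 0, se = NA_real_, n_events = 0L, no_events = TRUE),
      class = "attachment_rate"))
  }
  count <- vapply(frame_times, function(t) sum(event_times <= t), numeric(1))
  fit <- stats::lm(count ~ frame_times)
  sm <- suppressWarnings(summary(fit))   # exact-count data fits perfectly
  structure(
    list(rate = unname(stats::coef(fit)[2]),
         se = unname(sm$coefficients[2, 2]),
         n_events = length(event_times), no_events = FALSE),
    class = "attachment_rate"
  )
}

#' @export
print.attachment_rate <- function(x, ...) {
  cat(sprintf("attachment rate: %.4g cells/s (se %.3g, %d events)\n",
              x$rate, x$se, x$n_events))
  invisible(x)
}

#' Attachment probability from rate, flow and concentration
#'
#' The probability that a cell transiting the channel attaches is the
#' attachment rate normalized by the incoming cell flux:
#' `p_att = r / (J A) = r / (Q C)`, with flux `J = Q C / A`. Normalization
#' by flux is required because the number of cells passing through per unit
#' time depends on the flow rate.
#'
#' @param r attachment rate (cells s^-1), nonnegative.
#' @param Q volumetric flow rate (m^3 s^-1), positive.
#' @param C cell concentration (cells m^-3), positive.
#' @param geometry optional [channel_geometry()]; if given, the flux `J`
#'   (cells m^-2 s^-1) is also reported.
#' @return an object of class `attachment_probability` with `p_att`, `flux`
#'   (or `NA`), and the inputs.
#' @examples
#' # r = 9 cells/s at Q = 1 ul/s and C = 4.5e4 cells/ul -> 2e-4
#' attachment_probability(9, Q = 1e-9, C = 4.5e13)$p_att
#' @export
attachment_probability <- function(r, Q, C, geometry = NULL) {
  if (r < 0) stop("r must be nonnegative", call. = FALSE)
  if (Q <= 0 || C <= 0) stop("Q and C must be positive", call. = FALSE)
  p <- r / (Q * C)
  if (p > 1) {
    stop("r/(Q*C) = ", signif(p, 3),
         " > 1: more attachments than through-flux; inconsistent inputs",
         call. = FALSE)
  }
  flux <- if (!is.null(geometry)) {
    stopifnot(is_channel_geometry(geometry))
    Q * C / geometry$area
  } else NA_real_
  structure(list(p_att = p, flux = flux, r = r, Q = Q, C = C),
            class = "attachment_probability")
}

#' @export
print.attachment_probability <- function(x, ...) {
  cat(sprintf("attachment probability: p_att = %.4g\n", x$p_att))
  invisible(x)
}
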