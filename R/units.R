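#' Unit conversions to and from SI
#'
#' All internal computations in this package use SI units (metres, seconds,
#' cubic metres). Experimental microfluidics work is usually reported in
#' micrometres, millimetres per second, microlitres per minute and
#' cm^2 s^-1; these helpers convert at the boundary so that no function ever
#' mixes unit systems internally.
#'
#' @param x numeric vector of values to convert.
#' @return numeric vector in the target unit.
#' @name unit-conversions
NULL

#' @rdname unit-conversions
#' @export
um_to_m <- function(x) x * 1e-6

#' @rdname unit-conversions
#' @export
m_to_um <- function(x) x * 1e6

#' @rdname unit-conversions
#' @export
mm_to_m <- function(x) x * 1e-3

#' @rdname unit-conversions
#' @export
cm_to_m <- function(x) x * 1e-2

#' @rdname unit-conversions
#' @export
mm_s_to_m_s <- function(x) x * 1e-3

#' @rdname unit-conversions
#' @export
m_s_to_mm_s <- function(x) x * 1e3

#' @rdname unit-conversions
#' @export
ul_min_to_m3_s <- function(x) x * 1e-9 / 60

#' @rdname unit-conversions
#' @export
m3_s_to_ul_min <- function(x) x * 60 * 1e9

#' @rdname unit-conversions
#' @export
cm2_s_to_m2_s <- function(x) x * 1e-4

#' @rdname unit-conversions
#' @export
m2_s_to_cm2_s <- function(x) x * 1e4

#' Effective diffusivity defaults
#'
#' `D_SWIM` is the effective diffusion coefficient attributed to unbiased
#' swimming of a motile bacterium (4e-6 cm^2 s^-1, the classic E. coli value
#' also adopted for C. crescentus swarmers). `D_PASSIVE` is a Stokes-Einstein
#' order-of-magnitude diffusivity for a nonmotile ~1 um particle
#' (2e-9 cm^2 s^-1), used for flagellum-less cells. Both in m^2 s^-1.
#'
#' @export
D_SWIM <- 4e-10

#' @rdname D_SWIM
#' @export
D_PASSIVE <- 2e-13

#' Rectangular microchannel geometry
#'
#' Constructs a channel geometry with length `length` (flow direction),
#' width `width` and height `height`, all in metres. The cross-sectional
#' area `A = width * height` is derived. Channels are assumed wider than
#' tall (`height <= width`), matching typical soft-lithography devices where
#' only the coverslip floor is imaged.
#'
#' @param length channel length in m (flow direction).
#' @param width channel width in m.
#' @param height channel height (depth) in m.
#' @return an object of class `channel_geometry` with fields `length`,
#'   `width`, `height`, `area`.
#' @examples
#' geom <- channel_geometry(cm_to_m(1), um_to_m(500), um_to_m(90))
#' geom$area  # 4.5e-8 m^2
#' @export
channel_geometry <- function(length, width, height) {
  for (nm in c("length", "width", "height")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("invalid geometry: '", nm, "' must be a single positive number",
           call. = FALSE)
    }
  }
  if (height > width) {
    stop("invalid geometry: height (", height, " m) exceeds width (", width,
         " m); channels are wider than tall", call. = FALSE)
  }
  structure(
    list(length = length, width = width, height = height,
         area = width * height),
    class = "channel_geometry"
  )
}

#' @export
print.channel_geometry <- function(x, ...) {
  cat(sprintf(
    "channel geometry: L = %.3g mm, w = %.3g um, h = %.3g um, A = %.4g m^2\n",
    x$length * 1e3, m_to_um(x$width), m_to_um(x$height), x$area))
  invisible(x)
}

is_channel_geometry <- function(x) inherits(x, "channel_geometry")

#' Mean flow velocity from volumetric flow rate
#'
#' The mean flow velocity in a channel of cross-section `A` carrying a
#' volumetric rate `Q` is `v = Q / A`.
#'
#' @param Q volumetric flow rate in m^3 s^-1 (use [ul_min_to_m3_s()] for
#'   syringe-pump settings in ul/min).
#' @param geometry a [channel_geometry()].
#' @return mean velocity in m s^-1.
#' @examples
#' geom <- channel_geometry(cm_to_m(1), um_to_m(500), um_to_m(90))
#' m_s_to_mm_s(mean_velocity(ul_min_to_m3_s(0.81), geom))  # 0.3 mm/s
#' @export
mean_velocity <- function(Q, geometry) {
  stopifnot(is_channel_geometry(geometry))
  if (!is.numeric(Q) || any(!is.finite(Q)) || any(Q < 0)) {
    stop("Q must be finite and nonnegative", call. = FALSE)
  }
  Q / geometry$area
}

#' Flow condition in a channel
#'
#' Couples a volumetric rate and mean velocity to a geometry; either `Q` or
#' `v` may be supplied and the other is derived through `v = Q/A`. If both
#' are supplied they must agree to within floating tolerance.
#'
#' @param geometry a [channel_geometry()].
#' @param Q volumetric flow rate (m^3 s^-1), or `NULL`.
#' @param v mean flow velocity (m s^-1), or `NULL`.
#' @return an object of class `flow_condition` with fields `Q`, `v`,
#'   `geometry`.
#' @export
flow_condition <- function(geometry, Q = NULL, v = NULL) {
  stopifnot(is_channel_geometry(geometry))
  if (is.null(Q) && is.null(v)) stop("supply Q or v", call. = FALSE)
  if (is.null(Q)) {
    if (v < 0) stop("v must be nonnegative", call. = FALSE)
    Q <- v * geometry$area
  } else if (is.null(v)) {
    v <- mean_velocity(Q, geometry)
  } else {
    if (abs(v - Q / geometry$area) >
        1e-9 * max(abs(v), abs(Q / geometry$area), 1e-300)) {
      stop("inconsistent flow condition: v != Q/A", call. = FALSE)
    }
  }
  structure(list(Q = Q, v = v, geometry = geometry), class = "flow_condition")
}

#' @export
print.flow_condition <- function(x, ...) {
  cat(sprintf("flow condition: Q = %.4g ul/min, v = %.4g mm/s\n",
              m3_s_to_ul_min(x$Q), m_s_to_mm_s(x$v)))
  invisible(x)
}

#' Peclet number for cross-channel exploration under axial advection
#'
#' `Pe = h^2 v / (D L)`: the ratio of the time to diffuse across the channel
#' depth (`tau_D = h^2/D`) to the residence time in the channel
#' (`tau_a = L/v`). Small Pe means a swimming cell explores the full depth
#' (and so can find the floor) well before being washed out; large Pe means
#' washout wins.
#'
#' @param v mean flow velocity (m s^-1), nonnegative.
#' @param geometry a [channel_geometry()].
#' @param D effective diffusion coefficient (m^2 s^-1), positive.
#' @return dimensionless Peclet number.
#' @examples
#' geom <- channel_geometry(cm_to_m(1), um_to_m(500), um_to_m(90))
#' peclet(mm_s_to_m_s(1), geom, D_SWIM)  # 2.025
#' @export
peclet <- function(v, geometry, D = D_SWIM) {
  stopifnot(is_channel_geometry(geometry))
  if (!is.numeric(D) || length(D) != 1L || !is.finite(D) || D <= 0) {
    stop("invalid parameter: D must be a single positive number",
         call. = FALSE)
  }
  if (any(v < 0)) stop("v must be nonnegative", call. = FALSE)
  geometry$height^2 * v / (D * geometry$length)
}

#' Transport timescales and their ratio
#'
#' Returns the advective residence timescale `tau_a = L/v`, the cross-depth
#' diffusion timescale `tau_D = h^2/D`, and their ratio `Pe = tau_D/tau_a`.
#' By convention `v = 0` gives `tau_a = Inf` and `Pe = 0` (pure diffusion)
#' rather than an error, so limit cases remain testable.
#'
#' @inheritParams peclet
#' @return an object of class `transport_scales` with fields `tau_a`,
#'   `tau_D`, `Pe`, `v`, `D`, `geometry`.
#' @export
transport_scales <- function(v, geometry, D = D_SWIM) {
  stopifnot(is_channel_geometry(geometry))
  if (!is.numeric(D) || D <= 0) {
    stop("invalid parameter: D must be positive", call. = FALSE)
  }
  if (v < 0) stop("v must be nonnegative", call. = FALSE)
  tau_a <- if (v == 0) Inf else geometry$length / v
  tau_D <- geometry$height^2 / D
  pe <- if (v == 0) 0 else tau_D / tau_a
  structure(list(tau_a = tau_a, tau_D = tau_D, Pe = pe,
                 v = v, D = D, geometry = geometry),
            class = "transport_scales")
}

#' @export
print.transport_scales <- function(x, ...) {
  cat(sprintf("tau_a = %.4g s, tau_D = %.4g s, Pe = %.4g\n",
              x$tau_a, x$tau_D, x$Pe))
  invisible(x)
}
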