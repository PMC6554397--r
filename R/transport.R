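#' Parameters for Brownian-dynamics transport simulation
#'
#' Planktonic cells are advected along the channel (x) and diffuse across its
#' depth (z, with z = 0 the coverslip floor). The floor is partially
#' absorbing with surface reactivity `kappa` (m s^-1); the ceiling reflects.
#' The dimensionless reactivity `kappa * h / D` controls the capture regime:
#' values below 0.1 are reaction-limited (capture limited by sticking
#' kinetics, not transport), which is the regime in which the attachment
#' probability scales as 1/Pe.
#'
#' The timestep defaults to the stricter of two resolution rules: the
#' diffusive step `sqrt(2 D dt)` must not exceed `h/50`, and the advective
#' step `v dt` must not exceed `L/100`. The maximum simulated time defaults
#' to ten residence times (`10 L / v`) when `v > 0`.
#'
#' @param geometry a [channel_geometry()].
#' @param flow a [flow_condition()], or a velocity in m s^-1.
#' @param D effective diffusivity (m^2 s^-1).
#' @param kappa floor reactivity (m s^-1). Defaults to
#'   `kappa_h_D * D / h`.
#' @param kappa_h_D dimensionless reactivity used to derive `kappa` when
#'   `kappa` is not given; default 0.01 (reaction-limited).
#' @param dt timestep (s); default derived from the resolution rules above.
#' @param profile axial flow profile: `"plug"` (uniform `v`) or
#'   `"parabolic"` (`6 v (z/h)(1 - z/h)`, the plane-Poiseuille profile with
#'   mean `v`).
#' @param max_time maximum simulated time (s); required when `v = 0`.
#' @return an object of class `transport_params`.
#' @export
transport_params <- function(geometry, flow, D = D_SWIM, kappa = NULL,
                             kappa_h_D = 0.01, dt = NULL,
                             profile = c("plug", "parabolic"),
                             max_time = NULL) {
  stopifnot(is_channel_geometry(geometry))
  profile <- match.arg(profile)
  if (is.numeric(flow)) flow <- flow_condition(geometry, v = flow)
  stopifnot(inherits(flow, "flow_condition"))
  if (!is.numeric(D) || D <= 0) stop("D must be positive", call. = FALSE)
  h <- geometry$height
  if (is.null(kappa)) {
    if (kappa_h_D < 0) stop("kappa_h_D must be nonnegative", call. = FALSE)
    kappa <- kappa_h_D * D / h
  }
  if (kappa < 0) stop("kappa must be nonnegative", call. = FALSE)
  v <- flow$v
  if (is.null(dt)) {
    dt <- (h / 50)^2 / (2 * D)
    if (v > 0) dt <- min(dt, geometry$length / (100 * v))
  }
  if (dt <= 0) stop("dt must be positive", call. = FALSE)
  if (v * dt > geometry$length / 100 * (1 + 1e-9)) {
    warning("advective step v*dt exceeds L/100; results may be coarse")
  }
  if (is.null(max_time)) {
    if (v == 0) {
      stop("max_time must be supplied when v = 0", call. = FALSE)
    }
    max_time <- 10 * geometry$length / v
  }
  structure(
    list(geometry = geometry, flow = flow, D = D, kappa = kappa,
         kappa_h_D = kappa * h / D, dt = dt, profile = profile,
         max_time = max_time,
         reaction_limited = (kappa * h / D) < 0.1),
    class = "transport_params"
  )
}

#' @export
print.transport_params <- function(x, ...) {
  cat(sprintf(
    "transport: v = %.4g mm/s, D = %.3g m^2/s, kappa*h/D = %.3g (%s), dt = %.3g s, %s flow\n",
    m_s_to_mm_s(x$flow$v), x$D, x$kappa_h_D,
    if (x$reaction_limited) "reaction-limited" else "not reaction-limited",
    x$dt, x$profile))
  invisible(x)
}

#' Per-contact sticking probability for a reactive floor
#'
#' Discretizing a partially absorbing (Robin) boundary in a random-walk
#' simulation requires a per-contact sticking probability that depends on the
#' timestep, `P = kappa * sqrt(pi * dt / D)`, so that the continuum
#' absorption rate is recovered independently of `dt` as `dt -> 0`. The
#' value is clipped to \[0, 1\]; values above 0.5 indicate the timestep is
#' too coarse for the requested reactivity and trigger a warning.
#'
#' @param kappa floor reactivity (m s^-1), nonnegative.
#' @param D diffusivity (m^2 s^-1), positive.
#' @param dt timestep (s), positive.
#' @return sticking probability in \[0, 1\].
#' @export
sticking_probability <- function(kappa, D, dt) {
  if (kappa < 0) stop("kappa must be nonnegative", call. = FALSE)
  if (D <= 0) stop("D must be positive", call. = FALSE)
  if (dt <= 0) stop("dt must be positive", call. = FALSE)
  p <- kappa * sqrt(pi * dt / D)
  if (p > 0.5) {
    warning("sticking probability ", signif(p, 3),
            " > 0.5: dt too coarse for this kappa")
  }
  min(max(p, 0), 1)
}

#' Simulate planktonic cell transport through the channel
#'
#' Each particle advances by `x <- x + u(z) dt` (plug: `u = v`; parabolic:
#' `u = 6 v (z/h)(1 - z/h)`) and diffuses vertically by
#' `z <- z + sqrt(2 D dt) * N(0,1)`. The ceiling reflects; a floor crossing
#' either absorbs the particle (with the per-contact probability from
#' [sticking_probability()]) or reflects it. A particle exits when
#' `x > L`. Statuses are terminal. The simulation is deterministic given
#' `seed`.
#'
#' @param params a [transport_params()].
#' @param n number of particles (>= 1).
#' @param release `"uniform_inlet"` (x = 0, z uniform in (0, h)) or
#'   `"floor_point"` (released on the floor at `release_x`, as a freshly
#'   divided daughter would be).
#' @param release_x release position for `"floor_point"` (m).
#' @param seed integer RNG seed (recorded in the output).
#' @return an object of class `attachment_outcome`: counts
#'   (`n_attached`, `n_exited`, `n_swimming`, `n_total`), the estimated
#'   attachment probability `p_att` with an exact binomial 95% CI,
#'   attachment positions `x_att` and times `t_att`, and provenance.
#' @export
simulate_transport <- function(params, n,
                               release = c("uniform_inlet", "floor_point"),
                               release_x = 0, seed = NULL) {
  stopifnot(inherits(params, "transport_params"))
  release <- match.arg(release)
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  n <- as.integer(n)
  if (!is.null(seed)) set.seed(seed)

  g <- params$geometry
  L <- g$length; h <- g$height
  v <- params$flow$v; D <- params$D; dt <- params$dt
  p_stick <- if (params$kappa > 0) sticking_probability(params$kappa, D, dt)
             else 0
  sigma <- sqrt(2 * D * dt)

  if (release == "uniform_inlet") {
    x <- rep(0, n)
    z <- stats::runif(n, 0, h)
  } else {
    if (release_x < 0 || release_x > L) {
      stop("release_x outside channel", call. = FALSE)
    }
    x <- rep(release_x, n)
    z <- rep(0, n)
  }

  status <- integer(n)              # 0 swimming, 1 attached, 2 exited
  x_att <- rep(NA_real_, n)
  t_att <- rep(NA_real_, n)
  active <- seq_len(n)
  t <- 0
  n_steps <- ceiling(params$max_time / dt)

  for (step in seq_len(n_steps)) {
    if (length(active) == 0L) break
    t <- t + dt
    zi <- z[active]
    u <- if (params$profile == "plug") v else 6 * v * (zi / h) * (1 - zi / h)
    xi <- x[active] + u * dt
    if (sigma > 0) zi <- zi + sigma * stats::rnorm(length(active))

    below <- zi < 0
    if (any(below)) {
      idx_b <- which(below)
      stick <- if (p_stick >= 1) rep(TRUE, length(idx_b))
               else stats::runif(length(idx_b)) < p_stick
      if (any(stick)) {
        ids <- active[idx_b[stick]]
        status[ids] <- 1L
        x_att[ids] <- pmin(pmax(xi[idx_b[stick]], 0), L)
        t_att[ids] <- t
      }
      zi[idx_b] <- -zi[idx_b]       # reflect the survivors
    }
    above <- zi > h
    if (any(above)) zi[above] <- 2 * h - zi[above]
    zi <- pmin(pmax(zi, 0), h)

    x[active] <- xi
    z[active] <- zi
    newly_attached <- status[active] == 1L
    exited <- !newly_attached & xi > L
    if (any(exited)) status[active[exited]] <- 2L
    active <- active[!(newly_attached | exited)]
  }

  n_att <- sum(status == 1L)
  n_exit <- sum(status == 2L)
  ci <- as.numeric(stats::binom.test(n_att, n)$conf.int)
  structure(
    list(n_attached = n_att, n_exited = n_exit,
         n_swimming = n - n_att - n_exit, n_total = n,
         p_att = n_att / n, ci = ci,
         x_att = x_att[status == 1L], t_att = t_att[status == 1L],
         release = release, release_x = release_x,
         seed = seed, params = params),
    class = "attachment_outcome"
  )
}

#' @export
print.attachment_outcome <- function(x, ...) {
  cat(sprintf(
    "attachment outcome: %d/%d attached (p = %.4g, 95%% CI %.3g-%.3g), %d exited, %d still swimming\n",
    x$n_attached, x$n_total, x$p_att, x$ci[1], x$ci[2],
    x$n_exited, x$n_swimming))
  invisible(x)
}

#' Closed-form attachment probability in the reaction-limited regime
#'
#' When sticking kinetics (not transport to the wall) limit capture
#' (`kappa h / D < 0.1`), a cell is well mixed across the depth and attaches
#' at rate `kappa / h` during its residence time `L / v`, giving
#' `p = 1 - exp(-kappa L / (v h))`. Since
#' `kappa L / (v h) = (kappa h / D) / Pe`, this yields `p ~ 1/Pe` whenever
#' `p` is small. Outside the reaction-limited regime the formula is invalid
#' and the function refuses to evaluate.
#'
#' @param params a [transport_params()] with `v > 0`.
#' @return attachment probability in \[0, 1\].
#' @export
analytic_attachment_probability <- function(params) {
  stopifnot(inherits(params, "transport_params"))
  if (!params$reaction_limited) {
    stop("analytic form requires the reaction-limited regime ",
         "(kappa*h/D < 0.1); here kappa*h/D = ",
         signif(params$kappa_h_D, 3),
         ". In the transport-limited regime capture depends on the full ",
         "boundary-layer structure and no well-mixed closed form applies.",
         call. = FALSE)
  }
  v <- params$flow$v
  if (v <= 0) stop("analytic form requires v > 0", call. = FALSE)
  g <- params$geometry
  1 - exp(-params$kappa * g$length / (v * g$height))
}

#' Empirical dispersal kernel from a floor-point release
#'
#' The downstream displacement between a daughter cell's release point and
#' its reattachment site. Requires a `"floor_point"` release; with plug flow
#' all displacements are nonnegative. Returns an empty kernel (not an
#' error) when no particle attached.
#'
#' @param outcome an [simulate_transport()] result.
#' @param release_x release position (m); defaults to the one recorded in
#'   `outcome`.
#' @return an object of class `dispersal_kernel` with fields
#'   `displacements` (m), `mean`, `sd`, `n`.
#' @export
dispersal_kernel <- function(outcome, release_x = outcome$release_x) {
  stopifnot(inherits(outcome, "attachment_outcome"))
  if (outcome$release != "floor_point") {
    stop("dispersal kernel requires a floor_point release", call. = FALSE)
  }
  d <- outcome$x_att - release_x
  structure(
    list(displacements = d,
         mean = if (length(d)) mean(d) else NA_real_,
         sd = if (length(d) > 1) stats::sd(d) else NA_real_,
         n = length(d), release_x = release_x),
    class = "dispersal_kernel"
  )
}

#' Fit the power-law exponent of attachment probability versus Peclet number
#'
#' Ordinary least squares of `log10(p)` on `log10(Pe)`; the slope is the
#' scaling exponent (a 1/Pe law has slope -1, by `alpha log x = log x^alpha`).
#'
#' @param pe_values Peclet numbers, strictly positive, length >= 3.
#' @param p_values attachment probabilities, strictly positive, same length.
#' @return an object of class `scaling_fit` with fields `slope`,
#'   `intercept`, `slope_se`, `r_squared`, `n`.
#' @examples
#' fit_scaling_exponent(c(1, 10, 100), 0.05 / c(1, 10, 100))$slope  # -1
#' @export
fit_scaling_exponent <- function(pe_values, p_values) {
  if (length(pe_values) != length(p_values)) {
    stop("pe_values and p_values must have equal length", call. = FALSE)
  }
  if (length(pe_values) < 3) {
    stop("need at least 3 (Pe, p) pairs", call. = FALSE)
  }
  bad <- which(!is.finite(pe_values) | !is.finite(p_values) |
               pe_values <= 0 | p_values <= 0)
  if (length(bad)) {
    stop("invalid input: nonpositive or nonfinite value at index ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  fit <- stats::lm(log10(p_values) ~ log10(pe_values))
  sm <- suppressWarnings(summary(fit))   # constructed laws fit perfectly
  structure(
    list(slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         slope_se = unname(sm$coefficients[2, 2]),
         r_squared = sm$r.squared,
         n = length(pe_values)),
    class = "scaling_fit"
  )
}

#' @export
print.scaling_fit <- function(x, ...) {
  cat(sprintf("log-log scaling fit: slope = %.3f +/- %.3f (n = %d, R^2 = %.3f)\n",
              x$slope, x$slope_se, x$n, x$r_squared))
  invisible(x)
}
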