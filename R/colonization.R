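#' Parameters for the agent-based surface colonization simulator
#'
#' Surface-attached mother cells divide asymmetrically at stochastic
#' intervals. At each division the daughter either attaches immediately
#' downstream of its mother (probability `p_near`), or is released into the
#' bulk where fluid transport and swimming decide between reattachment
#' somewhere downstream and washout (see [bulk_fate()]). Attachment is
#' irreversible (holdfast).
#'
#' The bulk attachment waiting time is exponential with rate
#' `1 / (h/kappa + h^2/(2 D))`: the reactive-capture resistance `h/kappa`
#' and the cross-depth diffusion resistance `h^2/(2 D)` in series. In the
#' reaction-limited regime (`kappa h / D << 1`) this reduces to the
#' well-mixed rate `kappa / h` (within `kappa h / (2 D)` relative), so the
#' implied attachment probability matches the transport module's analytic
#' form; for nonmotile cells (`D = D_PASSIVE`, `kappa` unchanged) diffusion
#' across the depth becomes limiting and attachment is correspondingly
#' rarer, as observed for flagellum-less mutants.
#'
#' @param geometry a [channel_geometry()].
#' @param flow a [flow_condition()] or a velocity (m s^-1).
#' @param D effective diffusivity of planktonic daughters (m^2 s^-1);
#'   use `D_PASSIVE` with an explicitly supplied motile `kappa` for the
#'   nonmotile mode.
#' @param kappa floor reactivity (m s^-1); default `kappa_h_D * D / h`.
#' @param kappa_h_D dimensionless reactivity used when `kappa` is `NULL`;
#'   default 0.01.
#' @param T_div mean division interval (s); default 5400 (a 90-min doubling,
#'   typical for C. crescentus in rich medium at 30 C).
#' @param cv_div coefficient of variation of the division interval
#'   (gamma-distributed); default 0.15.
#' @param p_near probability that a daughter attaches locally, immediately
#'   downstream of its mother; default 0.4, identical for motile and
#'   nonmotile cells (attachment immediately after division is
#'   motility-independent).
#' @param offset local daughter placement: downstream distance from the
#'   mother (m); default 2e-6 (about one cell length).
#' @param jitter isotropic standard deviation of local placement (m);
#'   default 3e-7.
#' @param footprint projected cell area (m^2); default 1.29e-12 (the mean
#'   single-cell footprint, 1.29 um^2).
#' @param horizon simulation horizon (s); default 86400 (24 h).
#' @param cap hard cap on the number of surface cells (default 5e5); when
#'   exceeded the simulation truncates with a warning.
#' @return an object of class `colonization_params`.
#' @export
colonization_params <- function(geometry, flow, D = D_SWIM, kappa = NULL,
                                kappa_h_D = 0.01, T_div = 5400,
                                cv_div = 0.15, p_near = 0.4,
                                offset = 2e-6, jitter = 3e-7,
                                footprint = 1.29e-12, horizon = 86400,
                                cap = 5e5) {
  stopifnot(is_channel_geometry(geometry))
  if (is.numeric(flow)) flow <- flow_condition(geometry, v = flow)
  stopifnot(inherits(flow, "flow_condition"))
  h <- geometry$height
  if (is.null(kappa)) kappa <- kappa_h_D * D / h
  if (kappa < 0) stop("kappa must be nonnegative", call. = FALSE)
  if (D <= 0) stop("D must be positive", call. = FALSE)
  if (T_div <= 0) stop("T_div must be positive", call. = FALSE)
  if (cv_div < 0) stop("cv_div must be nonnegative", call. = FALSE)
  if (p_near < 0 || p_near > 1) stop("p_near must be in [0, 1]", call. = FALSE)
  if (footprint <= 0) stop("footprint must be positive", call. = FALSE)
  bulk_rate <- if (kappa == 0) 0 else 1 / (h / kappa + h^2 / (2 * D))
  structure(
    list(geometry = geometry, flow = flow, D = D, kappa = kappa,
         kappa_h_D = kappa * h / D, bulk_rate = bulk_rate,
         T_div = T_div, cv_div = cv_div, p_near = p_near,
         offset = offset, jitter = jitter, footprint = footprint,
         horizon = horizon, cap = cap),
    class = "colonization_params"
  )
}

#' @export
print.colonization_params <- function(x, ...) {
  cat(sprintf(
    "colonization: v = %.3g mm/s, kappa*h/D = %.3g, T_div = %.0f s (CV %.2f), p_near = %.2f\n",
    m_s_to_mm_s(x$flow$v), x$kappa_h_D, x$T_div, x$cv_div, x$p_near))
  invisible(x)
}

# division-interval draw (gamma with mean T_div, coefficient of variation cv)
rdivision <- function(n, params) {
  if (params$cv_div == 0) return(rep(params$T_div, n))
  shape <- 1 / params$cv_div^2
  stats::rgamma(n, shape = shape, scale = params$T_div / shape)
}

# fold a coordinate into [0, w] by reflection at both sidewalls
reflect_into <- function(y, w) {
  r <- y %% (2 * w)
  ifelse(r > w, 2 * w - r, r)
}

#' Initial surface population of founder cells
#'
#' Founders are placed uniformly at random on the channel floor with lineage
#' colors drawn multinomially from `color_fractions` (default the 1:1
#' two-label loading). Division clocks are drawn from the division-interval
#' distribution. Deterministic given `seed`.
#'
#' @param n_founders number of founders (>= 1).
#' @param color_fractions named proportions over `c("green", "magenta")`,
#'   summing to 1.
#' @param params a [colonization_params()].
#' @param seed integer RNG seed, or `NULL` to use the current RNG state.
#' @return an object of class `colonization_snapshot`: `time`, `cells`
#'   (data.frame `x`, `y` in m, `color`, `founder`, `birth`, `next_div`),
#'   and cumulative event `counts` (divisions, local, reattached, washed).
#' @export
init_population <- function(n_founders,
                            color_fractions = c(green = 0.5, magenta = 0.5),
                            params, seed = NULL) {
  stopifnot(inherits(params, "colonization_params"))
  if (n_founders < 1) stop("n_founders must be >= 1", call. = FALSE)
  if (abs(sum(color_fractions) - 1) > 1e-9) {
    stop("color_fractions must sum to 1", call. = FALSE)
  }
  g <- params$geometry
  floor_area <- g$length * g$width
  if (n_founders * params$footprint > floor_area) {
    stop("n_founders exceeds the packing bound for the floor area",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n_founders)
  cells <- data.frame(
    x = stats::runif(n, 0, g$length),
    y = stats::runif(n, 0, g$width),
    color = sample(names(color_fractions), n, replace = TRUE,
                   prob = color_fractions),
    founder = seq_len(n),
    birth = 0,
    next_div = rdivision(n, params),
    stringsAsFactors = FALSE
  )
  structure(
    list(time = 0, cells = cells,
         counts = c(divisions = 0, local = 0, reattached = 0, washed = 0),
         truncated = FALSE),
    class = "colonization_snapshot"
  )
}

#' @export
print.colonization_snapshot <- function(x, ...) {
  cat(sprintf(
    "colonization snapshot at t = %.0f s: %d cells; %d divisions (%d local, %d reattached, %d washed)%s\n",
    x$time, nrow(x$cells), x$counts[["divisions"]], x$counts[["local"]],
    x$counts[["reattached"]], x$counts[["washed"]],
    if (isTRUE(x$truncated)) " [truncated at cap]" else ""))
  invisible(x)
}

#' Fate of a daughter cell released into the bulk
#'
#' Samples an attachment waiting time `t ~ Exponential(bulk_rate)` (see
#' [colonization_params()] for the rate). If the cell would be carried past
#' the outlet (`x + v t > L`) it is washed out; otherwise it reattaches at
#' `x' = x + v t`, laterally displaced by `Normal(0, sqrt(2 D t))` with
#' reflection at the sidewalls.
#'
#' @param x,y release position on the floor (m).
#' @param params a [colonization_params()].
#' @return a list with `fate` (`"attached"` or `"washed_out"`) and, when
#'   attached, `x`, `y` and the waiting time `t`.
#' @export
bulk_fate <- function(x, y, params) {
  stopifnot(inherits(params, "colonization_params"))
  g <- params$geometry
  if (x < 0 || x > g$length || y < 0 || y > g$width) {
    stop("release position outside the channel floor", call. = FALSE)
  }
  res <- bulk_fate_vec(x, y, params)
  if (res$washed[1]) list(fate = "washed_out")
  else list(fate = "attached", x = res$x[1], y = res$y[1], t = res$t[1])
}

# vectorized bulk fate used by advance(); positions in m
bulk_fate_vec <- function(x, y, params) {
  n <- length(x)
  g <- params$geometry
  v <- params$flow$v
  if (params$bulk_rate == 0) {
    return(list(washed = rep(TRUE, n), x = numeric(0), y = numeric(0),
                t = numeric(0)))
  }
  t_wait <- stats::rexp(n, rate = params$bulk_rate)
  x2 <- x + v * t_wait
  washed <- x2 > g$length
  keep <- !washed
  y2 <- reflect_into(
    y[keep] + stats::rnorm(sum(keep), 0, sqrt(2 * params$D * t_wait[keep])),
    g$width)
  list(washed = washed, x = x2[keep], y = y2, t = t_wait[keep])
}

#' Advance a colonization snapshot to a later time
#'
#' Processes all division events up to `until`. At each division the mother
#' persists and re-arms her clock; the daughter either attaches at the
#' mother's position plus the downstream offset (probability `p_near`,
#' inheriting color and founder id) or is resolved by [bulk_fate()].
#' Attached cells never detach; overlapping cells are permitted (density is
#' handled at rendering). Event counts accumulate; at every return,
#' `divisions = local + reattached + washed`.
#'
#' Reattached daughters whose waiting time ends after `until` are kept in
#' the state with their actual `birth` time; use [cells_at()] to extract
#' the cells present on the floor at a given time.
#'
#' @param state a `colonization_snapshot`.
#' @param until target time (s), `>= state$time`.
#' @param params a [colonization_params()].
#' @return the advanced `colonization_snapshot`.
#' @export
advance <- function(state, until, params) {
  stopifnot(inherits(state, "colonization_snapshot"),
            inherits(params, "colonization_params"))
  if (until < state$time) stop("until must be >= state$time", call. = FALSE)
  g <- params$geometry
  v <- params$flow$v
  cells <- state$cells
  counts <- state$counts
  truncated <- isTRUE(state$truncated)

  while (!truncated) {
    due <- which(cells$next_div <= until)
    if (length(due) == 0L) break
    t_d <- cells$next_div[due]
    nd <- length(due)
    counts[["divisions"]] <- counts[["divisions"]] + nd

    is_local <- stats::runif(nd) < params$p_near
    new_list <- vector("list", 2L)

    if (any(is_local)) {
      li <- due[is_local]
      nl <- length(li)
      xd <- pmin(pmax(cells$x[li] + params$offset +
                        stats::rnorm(nl, 0, params$jitter), 0), g$length)
      yd <- reflect_into(cells$y[li] + stats::rnorm(nl, 0, params$jitter),
                         g$width)
      bd <- t_d[is_local]
      new_list[[1L]] <- data.frame(
        x = xd, y = yd, color = cells$color[li],
        founder = cells$founder[li], birth = bd,
        next_div = bd + rdivision(nl, params),
        stringsAsFactors = FALSE)
      counts[["local"]] <- counts[["local"]] + nl
    }

    if (any(!is_local)) {
      bi <- due[!is_local]
      fate <- bulk_fate_vec(cells$x[bi], cells$y[bi], params)
      counts[["washed"]] <- counts[["washed"]] + sum(fate$washed)
      if (any(!fate$washed)) {
        ki <- bi[!fate$washed]
        bd <- t_d[!is_local][!fate$washed] + fate$t
        new_list[[2L]] <- data.frame(
          x = fate$x, y = fate$y, color = cells$color[ki],
          founder = cells$founder[ki], birth = bd,
          next_div = bd + rdivision(length(ki), params),
          stringsAsFactors = FALSE)
        counts[["reattached"]] <- counts[["reattached"]] + length(ki)
      }
    }

    cells$next_div[due] <- t_d + rdivision(nd, params)
    new_cells <- do.call(rbind, new_list[!vapply(new_list, is.null, TRUE)])
    if (!is.null(new_cells)) cells <- rbind(cells, new_cells)

    if (nrow(cells) > params$cap) {
      warning("population exceeded cap (", params$cap,
              ") at t = ", round(min(t_d)), " s; truncating further growth")
      truncated <- TRUE
    }
  }

  structure(list(time = until, cells = cells, counts = counts,
                 truncated = truncated),
            class = "colonization_snapshot")
}

#' Cells present on the floor at a given time
#'
#' Filters a snapshot's cell table to cells whose (re)attachment time is at
#' or before `time`, returning positions in micrometres for rendering and
#' measurement.
#'
#' @param state a `colonization_snapshot`.
#' @param time time (s); defaults to the snapshot time.
#' @return data.frame with `x_um`, `y_um`, `color`, `founder`, `birth`.
#' @export
cells_at <- function(state, time = state$time) {
  stopifnot(inherits(state, "colonization_snapshot"))
  keep <- state$cells$birth <= time
  data.frame(
    x_um = m_to_um(state$cells$x[keep]),
    y_um = m_to_um(state$cells$y[keep]),
    color = state$cells$color[keep],
    founder = state$cells$founder[keep],
    birth = state$cells$birth[keep],
    stringsAsFactors = FALSE
  )
}

#' Run a colonization simulation with snapshots
#'
#' Initializes a founder population and advances it through the sorted
#' `snapshot_times`, returning one snapshot per time. Deterministic given
#' `seed`.
#'
#' @inheritParams init_population
#' @param snapshot_times sorted times (s), all within the horizon.
#' @return a list of `colonization_snapshot` objects.
#' @export
run_colonization <- function(params, n_founders,
                             color_fractions = c(green = 0.5, magenta = 0.5),
                             snapshot_times, seed = NULL) {
  stopifnot(inherits(params, "colonization_params"))
  if (is.unsorted(snapshot_times)) {
    stop("snapshot_times must be sorted", call. = FALSE)
  }
  if (any(snapshot_times > params$horizon)) {
    stop("snapshot_times must lie within the horizon", call. = FALSE)
  }
  state <- init_population(n_founders, color_fractions, params, seed = seed)
  out <- vector("list", length(snapshot_times))
  for (i in seq_along(snapshot_times)) {
    state <- advance(state, snapshot_times[i], params)
    out[[i]] <- state
  }
  out
}
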