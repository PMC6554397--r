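#' Configuration for the end-to-end replica pipeline
#'
#' Bundles every stage's settings: channel geometry, the flow conditions to
#' compare, growth and transport parameters for the colonization simulator,
#' the imaging window, render and segmentation settings, and the
#' Peclet grid for the transport-scaling stage.
#'
#' @param geometry a [channel_geometry()]; default the 1 cm x 250 um x
#'   90 um channel.
#' @param velocities_mm_s mean flow velocities to simulate (mm s^-1).
#' @param n_seeds replicate simulations per velocity.
#' @param D,kappa_h_D,T_div,cv_div,p_near,n_founders,horizon,cap passed to
#'   [colonization_params()] / [init_population()].
#' @param snapshot_time measurement time (s); default = `horizon`.
#' @param window imaging window (um), a list with `x_um`, `y_um`,
#'   `width_um`, `height_um`; default a 250 x 250 um field centred 9 mm
#'   downstream of the inlet.
#' @param render a [render_params()].
#' @param seg a [seg_params()].
#' @param pe_grid Peclet numbers for the transport-scaling stage.
#' @param n_particles particles per transport condition.
#' @param transport_kappa_h_D dimensionless reactivity for the transport
#'   stage; default 0.01.
#' @return a list of class `replica_config`.
#' @export
replica_config <- function(geometry = channel_geometry(cm_to_m(1),
                                                       um_to_m(250),
                                                       um_to_m(90)),
                           velocities_mm_s = c(2, 27),
                           n_seeds = 3,
                           D = D_SWIM, kappa_h_D = 0.01,
                           T_div = 5400, cv_div = 0.15, p_near = 0.4,
                           n_founders = 400, horizon = 86400,
                           cap = 5e5, snapshot_time = NULL,
                           window = NULL,
                           render = render_params(seed = NULL),
                           seg = seg_params(),
                           pe_grid = c(3, 10, 30, 100, 300),
                           n_particles = 2e4,
                           transport_kappa_h_D = 0.01) {
  if (is.null(snapshot_time)) snapshot_time <- horizon
  if (is.null(window)) {
    w_um <- m_to_um(geometry$width)
    side <- min(250, w_um)
    window <- list(x_um = 9000 - side / 2,
                   y_um = (w_um - side) / 2,
                   width_um = side, height_um = side)
  }
  structure(
    list(geometry = geometry, velocities_mm_s = velocities_mm_s,
         n_seeds = n_seeds, D = D, kappa_h_D = kappa_h_D, T_div = T_div,
         cv_div = cv_div, p_near = p_near, n_founders = n_founders,
         horizon = horizon, cap = cap, snapshot_time = snapshot_time,
         window = window, render = render, seg = seg, pe_grid = pe_grid,
         n_particles = n_particles,
         transport_kappa_h_D = transport_kappa_h_D),
    class = "replica_config"
  )
}

# deterministic per-stage seed derivation (kept below .Machine$integer.max)
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) %% 2147483563 * 48271 + 7919 * k) %%
               2147483563) + 1L
}

# one colonization -> render -> quantify pass; returns a one-row data.frame
measure_condition <- function(config, v_mm_s, seed, D = config$D,
                              kappa = NULL) {
  params <- colonization_params(
    config$geometry, mm_s_to_m_s(v_mm_s), D = D, kappa = kappa,
    kappa_h_D = config$kappa_h_D, T_div = config$T_div,
    cv_div = config$cv_div, p_near = config$p_near,
    horizon = config$horizon, cap = config$cap)
  snap <- run_colonization(params, config$n_founders,
                           snapshot_times = config$snapshot_time,
                           seed = seed)[[1]]
  cells <- cells_at(snap)
  rp <- config$render
  rp$seed <- derive_seed(seed, 1)
  img <- render_population(cells, config$window, rp,
                           geometry = config$geometry)
  seg1 <- segment_channel(img$ch1, config$seg, channel = "green")
  seg2 <- segment_channel(img$ch2, config$seg, channel = "magenta")
  cov <- surface_coverage(seg1$mask, seg2$mask)
  cst <- colony_areas(seg1$mask, seg2$mask, img$pixel_um)
  mix <- cross_lineage_mixing(seg1, seg2, img$pixel_um)
  win <- config$window
  inwin <- cells$x_um >= win$x_um & cells$x_um <= win$x_um + win$width_um &
           cells$y_um >= win$y_um & cells$y_um <= win$y_um + win$height_um
  mix_truth <- mixing_from_table(cells[inwin, , drop = FALSE])
  data.frame(
    v_mm_s = v_mm_s, seed = seed,
    n_cells = nrow(cells), n_reattached = snap$counts[["reattached"]],
    n_washed = snap$counts[["washed"]],
    coverage = cov, truth_coverage = surface_coverage(img$truth1, img$truth2),
    median_area_um2 = cst$median_um2, n_colonies = cst$n_colonies,
    gated = cst$gated,
    mixing_mean_um = mix$mean_um, mixing_sd_um = mix$sd_um,
    mixing_truth_mean_um = mix_truth$mean_um
  )
}

#' Run the full replica pipeline
#'
#' For each flow condition: agent-based colonization, rendering of the
#' imaging window, segmentation, coverage, colony-area and mixing
#' measurements (plus table-based ground-truth mixing). Separately, the
#' Brownian-dynamics transport stage sweeps the Peclet grid and fits the
#' log-log attachment-probability scaling. Deterministic given `seed`; all
#' per-stage seeds are derived from it.
#'
#' @param config a [replica_config()].
#' @param seed integer master seed.
#' @param transport include the transport-scaling stage; default TRUE.
#' @return an object of class `replica_report`: `patterns` (one row per
#'   velocity x seed), `pattern_summary` (one row per velocity),
#'   `transport` (one row per Pe), `scaling` (a `scaling_fit` or `NULL`),
#'   `config`, `seed`.
#' @export
run_replica <- function(config = replica_config(), seed = 1,
                        transport = TRUE) {
  stopifnot(inherits(config, "replica_config"))
  rows <- list()
  k <- 0L
  for (v in config$velocities_mm_s) {
    for (i in seq_len(config$n_seeds)) {
      k <- k + 1L
      rows[[k]] <- measure_condition(config, v, derive_seed(seed, 100 + k))
    }
  }
  patterns <- if (length(rows)) do.call(rbind, rows) else
    data.frame(v_mm_s = numeric(0))

  pattern_summary <- NULL
  if (nrow(patterns)) {
    agg <- function(f, col) {
      tapply(patterns[[col]], patterns$v_mm_s, f)
    }
    med_no_na <- function(z) stats::median(z, na.rm = TRUE)
    pattern_summary <- data.frame(
      v_mm_s = as.numeric(names(agg(mean, "coverage"))),
      coverage = as.numeric(agg(mean, "coverage")),
      median_area_um2 = as.numeric(agg(med_no_na, "median_area_um2")),
      mixing_mean_um = as.numeric(agg(med_no_na, "mixing_mean_um")),
      n_reattached = as.numeric(agg(mean, "n_reattached"))
    )
  }

  transport_tab <- NULL
  scaling <- NULL
  if (transport && length(config$pe_grid)) {
    g <- config$geometry
    trows <- lapply(seq_along(config$pe_grid), function(i) {
      pe <- config$pe_grid[i]
      v <- pe * config$D * g$length / g$height^2
      tp <- transport_params(g, v, D = config$D,
                             kappa_h_D = config$transport_kappa_h_D)
      out <- simulate_transport(tp, config$n_particles,
                                seed = derive_seed(seed, 500 + i))
      data.frame(pe = pe, v_mm_s = m_s_to_mm_s(v), p_att = out$p_att,
                 p_analytic = analytic_attachment_probability(tp),
                 n = out$n_total)
    })
    transport_tab <- do.call(rbind, trows)
    ok <- transport_tab$p_att > 0
    if (sum(ok) >= 3) {
      scaling <- fit_scaling_exponent(transport_tab$pe[ok],
                                      transport_tab$p_att[ok])
    }
  }

  structure(
    list(patterns = patterns, pattern_summary = pattern_summary,
         transport = transport_tab, scaling = scaling,
         config = config, seed = seed),
    class = "replica_report"
  )
}

#' @export
print.replica_report <- function(x, ...) {
  cat("replica report (seed ", x$seed, ")\n", sep = "")
  if (!is.null(x$pattern_summary)) {
    cat("colonization patterns:\n")
    print(x$pattern_summary, row.names = FALSE)
  }
  if (!is.null(x$scaling)) {
    cat(sprintf("attachment scaling: slope %.3f +/- %.3f\n",
                x$scaling$slope, x$scaling$slope_se))
  }
  invisible(x)
}
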