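test_that("per-contact sticking probability follows the sqrt(dt) rule", {
  expect_identical(sticking_probability(0, 4e-10, 1e-3), 0)
  expect_equal(sticking_probability(1e-6, 4e-10, 1e-3), 2.8025e-3,
               tolerance = 1e-4)
  p1 <- sticking_probability(2e-7, 4e-10, 1e-3)
  p2 <- sticking_probability(4e-7, 4e-10, 1e-3)
  expect_equal(p2, 2 * p1)
  expect_warning(p_big <- sticking_probability(3e-4, 4e-10, 1e-3),
                 "too coarse")
  expect_lte(p_big, 1)
  expect_error(sticking_probability(1e-6, 0, 1e-3), "positive")
})

test_that("pure advection never reaches the floor and particles conserve", {
  geom <- default_geometry()
  tp <- transport_params(geom, mm_s_to_m_s(5), D = 1e-16, kappa = 0,
                         dt = 0.02)
  out <- simulate_transport(tp, 500, seed = 31)
  expect_identical(out$n_attached, 0L)
  expect_identical(out$p_att, 0)
  expect_identical(out$n_attached + out$n_exited + out$n_swimming,
                   out$n_total)
  expect_identical(out$n_exited, 500L)
})

test_that("zero flow with a reactive floor: no washout, capture accumulates", {
  geom <- channel_geometry(cm_to_m(1), um_to_m(500), um_to_m(25))
  kappa <- 0.05 * D_SWIM / geom$height
  rate <- kappa / geom$height                  # well-mixed attachment rate
  tp <- transport_params(geom, 0, kappa = kappa,
                         dt = (geom$height / 20)^2 / (2 * D_SWIM),
                         max_time = 2 / rate)
  out <- simulate_transport(tp, 300, seed = 32)
  expect_identical(out$n_exited, 0L)
  expect_gt(out$p_att, 0.7)                    # 1 - exp(-2) = 0.86 expected
})

test_that("simulated attachment matches the reaction-limited closed form", {
  geom <- default_geometry()
  tp <- transport_params(geom, velocity_for_pe(10, geom), kappa_h_D = 0.01)
  out <- simulate_transport(tp, 5000, seed = 42)
  pa <- analytic_attachment_probability(tp)
  se <- sqrt(pa * (1 - pa) / 5000)
  expect_lt(abs(out$p_att - pa), 3 * se)
  expect_identical(out$n_attached + out$n_exited + out$n_swimming,
                   out$n_total)
  # determinism given seed
  out2 <- simulate_transport(tp, 5000, seed = 42)
  expect_identical(out$x_att, out2$x_att)
  expect_identical(out$p_att, out2$p_att)
})

test_that("analytic probability: examples and regime guard", {
  geom <- default_geometry()
  tp0 <- transport_params(geom, mm_s_to_m_s(1), kappa = 0)
  expect_identical(analytic_attachment_probability(tp0), 0)
  # kappa L / (v h) = 0.1  ->  1 - exp(-0.1); choose a slow flow so that
  # the implied kappa stays reaction-limited (kappa h / D = 0.1 Pe < 0.1)
  v <- velocity_for_pe(0.4, geom)
  kappa <- 0.1 * v * geom$height / geom$length
  tp <- transport_params(geom, v, kappa = kappa)
  expect_true(tp$reaction_limited)
  expect_equal(analytic_attachment_probability(tp), 1 - exp(-0.1),
               tolerance = 1e-12)
  # washout limit: very fast flow drives p toward zero
  tp_fast <- transport_params(geom, mm_s_to_m_s(1000), kappa = kappa)
  expect_lt(analytic_attachment_probability(tp_fast), 1e-4)
  # outside the reaction-limited regime the formula refuses
  tp_bad <- transport_params(geom, v, kappa_h_D = 0.5)
  expect_false(tp_bad$reaction_limited)
  expect_error(analytic_attachment_probability(tp_bad), "reaction-limited")
})

test_that("dispersal kernel is advective for plug flow", {
  geom <- default_geometry()
  tp <- transport_params(geom, mm_s_to_m_s(2), kappa_h_D = 0.01)
  out <- simulate_transport(tp, 4000, release = "floor_point",
                            release_x = 0, seed = 24)
  expect_gt(out$n_attached, 0)
  kern <- dispersal_kernel(out)
  expect_true(all(kern$displacements >= 0))
  # for plug flow the displacement is exactly v * attachment time
  expect_equal(kern$mean, tp$flow$v * mean(out$t_att), tolerance = 1e-12)
  # zero attachments give an empty kernel, not an exception
  tp0 <- transport_params(geom, mm_s_to_m_s(2), kappa = 0)
  out0 <- simulate_transport(tp0, 50, release = "floor_point", seed = 25)
  kern0 <- dispersal_kernel(out0)
  expect_identical(kern0$n, 0L)
  expect_true(is.na(kern0$mean))
})

test_that("attachment decreases with flow and increases with reactivity", {
  geom <- default_geometry()
  sim_p <- function(pe, khd, seed) {
    tp <- transport_params(geom, velocity_for_pe(pe, geom), kappa_h_D = khd)
    simulate_transport(tp, 4000, seed = seed)$p_att
  }
  expect_gt(sim_p(3, 0.02, 51), sim_p(30, 0.02, 52))    # washout with v
  expect_gt(sim_p(10, 0.05, 53), sim_p(10, 0.005, 54))  # capture with kappa
})

test_that("halving the timestep leaves the attachment estimate unchanged", {
  geom <- default_geometry()
  v <- velocity_for_pe(3, geom)
  tp1 <- transport_params(geom, v, kappa_h_D = 0.01)
  tp2 <- transport_params(geom, v, kappa_h_D = 0.01, dt = tp1$dt / 2)
  o1 <- simulate_transport(tp1, 1e4, seed = 22)
  o2 <- simulate_transport(tp2, 1e4, seed = 23)
  pooled_se <- sqrt(o1$p_att * (1 - o1$p_att) / 1e4 +
                    o2$p_att * (1 - o2$p_att) / 1e4)
  expect_lt(abs(o1$p_att - o2$p_att), 3 * pooled_se)
})

test_that("power-law exponent fitting is exact on constructed laws", {
  pe <- c(1, 10, 100)
  fit <- fit_scaling_exponent(pe, 0.05 / pe)
  expect_equal(fit$slope, -1, tolerance = 1e-10)
  flat <- fit_scaling_exponent(pe, rep(0.02, 3))
  expect_equal(flat$slope, 0, tolerance = 1e-10)
  expect_error(fit_scaling_exponent(c(1, 10), c(0.1, 0.01)), "at least 3")
  expect_error(fit_scaling_exponent(c(1, 10, 100), c(0.1, 0, 0.01)),
               "index 2")
  expect_error(fit_scaling_exponent(c(1, -10, 100, 0), c(0.1, 0.1, 0.1, 0.1)),
               "index 2, 4")
})
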