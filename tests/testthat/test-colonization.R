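col_params <- function(v_mm_s = 2, width_um = 250, ...) {
  g <- default_geometry(width_um)
  colonization_params(g, mm_s_to_m_s(v_mm_s), ...)
}

test_that("founder initialization: determinism, colors, packing bound", {
  p <- col_params()
  s1 <- init_population(200, params = p, seed = 61)
  s2 <- init_population(200, params = p, seed = 61)
  expect_identical(s1$cells, s2$cells)
  expect_identical(s1$counts[["divisions"]], 0)
  all_green <- init_population(50, c(green = 1, magenta = 0), p, seed = 62)
  expect_true(all(all_green$cells$color == "green"))
  expect_error(init_population(10, c(green = 0.7, magenta = 0.7), p, 63),
               "sum to 1")
  tiny <- colonization_params(
    channel_geometry(1e-5, 5e-6, 5e-6), 1e-3)
  expect_error(init_population(1000, params = tiny, seed = 64), "packing")
})

test_that("bulk fate matches the closed-form attachment probability", {
  p <- col_params(v_mm_s = 1, kappa_h_D = 0.05)
  g <- p$geometry
  set.seed(65)
  res <- flowcolonize:::bulk_fate_vec(rep(0, 1e4), rep(g$width / 2, 1e4), p)
  p_emp <- 1 - mean(res$washed)
  p_form <- 1 - exp(-p$kappa * g$length / (p$flow$v * g$height))
  se <- sqrt(p_form * (1 - p_form) / 1e4)
  expect_lt(abs(p_emp - p_form), 3 * se)
  # attached positions stay on the floor
  expect_true(all(res$x >= 0 & res$x <= g$length))
  expect_true(all(res$y >= 0 & res$y <= g$width))
  # single-release interface and its guards
  set.seed(66)
  f <- bulk_fate(0, g$width / 2, p)
  expect_true(f$fate %in% c("attached", "washed_out"))
  expect_error(bulk_fate(-1e-3, g$width / 2, p), "outside")
})

test_that("stronger capture shortens dispersal; faster flow washes out", {
  g <- default_geometry(250)
  # slow flow, so residence is long enough for capture kinetics to matter
  set.seed(67)
  disp <- sapply(c(0.01, 0.3), function(khd) {
    p <- colonization_params(g, mm_s_to_m_s(0.02), kappa_h_D = khd)
    r <- flowcolonize:::bulk_fate_vec(rep(0, 4000), rep(g$width / 2, 4000), p)
    mean(r$x)
  })
  expect_lt(disp[2], disp[1])
  p_fast <- colonization_params(g, mm_s_to_m_s(500), kappa_h_D = 0.01)
  set.seed(68)
  r <- flowcolonize:::bulk_fate_vec(rep(0, 2000), rep(g$width / 2, 2000),
                                    p_fast)
  expect_gt(mean(r$washed), 0.995)
})

test_that("division ledger balances after every advance", {
  p <- col_params(v_mm_s = 2)
  state <- init_population(100, params = p, seed = 71)
  prev <- state$counts
  for (t in c(10000, 30000, 60000, 86400)) {
    state <- advance(state, t, p)
    cts <- state$counts
    expect_identical(cts[["divisions"]],
                     cts[["local"]] + cts[["reattached"]] + cts[["washed"]])
    expect_true(all(cts >= prev))                 # nondecreasing
    prev <- cts
  }
  # all positions remain within the floor rectangle
  g <- p$geometry
  expect_true(all(state$cells$x >= 0 & state$cells$x <= g$length))
  expect_true(all(state$cells$y >= 0 & state$cells$y <= g$width))
})

test_that("local-only and washout-only limits behave exactly", {
  p1 <- col_params(p_near = 1)
  s <- advance(init_population(50, params = p1, seed = 72), 40000, p1)
  expect_identical(s$counts[["washed"]], 0)
  expect_identical(s$counts[["reattached"]], 0)
  expect_identical(nrow(s$cells), 50L + as.integer(s$counts[["local"]]))

  p0 <- col_params(p_near = 0, kappa = 0)
  s0 <- advance(init_population(50, params = p0, seed = 73), 86400, p0)
  expect_identical(nrow(s0$cells), 50L)
  expect_identical(s0$counts[["washed"]], s0$counts[["divisions"]])
})

test_that("population respects the doubling bound and the cap", {
  p <- col_params(cv_div = 0, T_div = 5400)
  s <- advance(init_population(40, params = p, seed = 74), 4.5 * 5400, p)
  expect_lte(nrow(s$cells), 40 * 2^4.5)
  pc <- col_params(cap = 300)
  expect_warning(
    advance(init_population(200, params = pc, seed = 75), 86400, pc),
    "cap")
})

test_that("runs are deterministic and reattachment falls with flow", {
  p <- col_params(v_mm_s = 2)
  r1 <- run_colonization(p, 150, snapshot_times = c(43200, 86400), seed = 76)
  r2 <- run_colonization(p, 150, snapshot_times = c(43200, 86400), seed = 76)
  expect_identical(r1[[2]]$cells, r2[[2]]$cells)
  expect_identical(r1[[1]]$counts, r2[[1]]$counts)

  reatt <- sapply(1:12, function(s) {
    sapply(c(1, 27), function(v) {
      pp <- col_params(v_mm_s = v)
      run_colonization(pp, 150, snapshot_times = 86400,
                       seed = 700 + s)[[1]]$counts[["reattached"]]
    })
  })
  # more reattachment-seeded colonies in weak flow, statistically over seeds
  expect_gt(mean(reatt[1, ]), 2 * mean(reatt[2, ]))
})

test_that("slower division lowers the final population", {
  n_final <- sapply(1:8, function(s) {
    sapply(c(5400, 10800), function(td) {
      p <- col_params(T_div = td)
      nrow(run_colonization(p, 60, snapshot_times = 64800,
                            seed = 800 + s)[[1]]$cells)
    })
  })
  expect_true(all(n_final[2, ] < n_final[1, ]))
})

test_that("cells_at excludes reattachments that land after the query time", {
  p <- col_params(v_mm_s = 1)
  s <- advance(init_population(300, params = p, seed = 77), 60000, p)
  tab_now <- cells_at(s)
  expect_true(all(tab_now$birth <= s$time))
  expect_lte(nrow(tab_now), nrow(s$cells))
  expect_named(tab_now, c("x_um", "y_um", "color", "founder", "birth"))
})
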