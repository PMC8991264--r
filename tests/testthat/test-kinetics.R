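p_monod <- function() kinetic_params(0.05, 15, 0.45, 19.6, 34.34, X0 = 0.8)

test_that("specific growth rates match their defining forms", {
  p <- kinetic_params(0.06, 10, 0.4, 20, 30, X0 = 0.5, ki = 90, kp = 60)
  # half saturation
  expect_equal(growth_rate("monod", p, Cs = 10), 0.03)
  # Aibe with no product is Monod at every substrate level
  cs <- seq(0.1, 30, length.out = 50)
  expect_equal(growth_rate("aibe", p, cs, Cp = 0),
               growth_rate("monod", p, cs))
  # Andrews is maximized at sqrt(ks * ki): dense grid oracle
  grid <- seq(0.01, 100, by = 0.01)
  mu <- growth_rate("andrews", p, grid)
  expect_equal(grid[which.max(mu)], sqrt(10 * 90), tolerance = 1e-3)
  # Contois at constant unit biomass equals Monod with the same ks
  expect_equal(growth_rate("contois", p, cs, X = 1),
               growth_rate("monod", p, cs))
  # domain guards
  expect_error(growth_rate("monod", p, Cs = -1),
               class = "epferm_domain_error")
  expect_error(growth_rate("contois", p, Cs = 5, X = 0),
               class = "epferm_singularity_error")
  # rates never exceed mumax
  for (kind in c("monod", "contois", "andrews", "aibe")) {
    mu <- growth_rate(kind, p, cs, X = 2, Cp = 30)
    expect_true(all(mu >= 0 & mu <= p$mumax + 1e-12))
  }
})

test_that("batch simulation honours the yield couplings", {
  times <- seq(0, 80, by = 2)
  for (kind in c("monod", "contois", "andrews", "aibe")) {
    p <- kinetic_params(0.06, 12, 0.45, 19.6, 34.34, X0 = 0.8,
                        ki = 120, kp = 80)
    sim <- simulate_batch(kind, p, times)
    # biomass-substrate conservation
    lhs <- sim$biomass_g_per_L - p$X0
    rhs <- p$Yb * (p$C0 - sim$substrate_g_per_L)
    expect_lt(max(abs(lhs - rhs) / pmax(abs(rhs), 1e-6)), 1e-6)
    # substrate never increases
    expect_true(all(diff(sim$substrate_g_per_L) <= 1e-10))
    # product coupling
    expect_equal(sim$product, p$Yp * (p$C0 - sim$substrate_g_per_L),
                 tolerance = 1e-8)
  }
})

test_that("ODE trajectories satisfy the integrated closed forms", {
  # dual-route check: numerically integrated (t, Cs) pairs plugged into the
  # algebraic integrated forms must return the elapsed time
  set.seed(11)
  times <- seq(0, 80, by = 4)
  for (kind in c("monod", "contois", "andrews", "aibe")) {
    for (rep in 1:20) {
      p <- random_params(kind)
      sim <- simulate_batch(kind, p, times)
      keep <- sim$substrate_g_per_L > 1e-6 &
        sim$substrate_g_per_L < attr(sim, "C0_eff")
      t_pred <- integrated_time(kind, p, sim$substrate_g_per_L[keep],
                                C0_eff = attr(sim, "C0_eff"))
      expect_lt(max(abs(t_pred - sim$time_h[keep])), 1e-3)
    }
  }
})

test_that("inhibition models reduce to Monod in the appropriate limits", {
  times <- seq(0, 80, by = 4)
  p0 <- p_monod()
  ref <- simulate_batch("monod", p0, times)
  p_and <- kinetic_params(0.05, 15, 0.45, 19.6, 34.34, X0 = 0.8, ki = 1e9)
  p_aib <- kinetic_params(0.05, 15, 0.45, 19.6, 34.34, X0 = 0.8, kp = 1e9)
  expect_equal(simulate_batch("andrews", p_and, times)$substrate_g_per_L,
               ref$substrate_g_per_L, tolerance = 1e-6)
  expect_equal(simulate_batch("aibe", p_aib, times)$substrate_g_per_L,
               ref$substrate_g_per_L, tolerance = 1e-6)
})

test_that("regressor transforms follow the integrated linearized forms", {
  # symmetric midpoint: the log-ratio vanishes
  series <- data.frame(time_h = seq(0, 70, by = 10),
                       substrate_g_per_L = c(30, 27, 25, 20, 15, 10, 5, 3))
  tab <- transform_regressors("monod", series, C0_eff = 30)
  expect_equal(nrow(tab), 7)  # t = 0 point excluded at the singularity
  expect_equal(tab$ln_ratio[tab$t == 40], 0)
  expect_equal(tab$ln_C0_minus_Cs[tab$t == 40], log(15))

  expect_equal(ncol(transform_regressors("aibe", series, 30)), 5)

  # closed-form substitution: true coefficients reproduce t exactly
  p <- p_monod()
  sim <- simulate_batch("monod", p, seq(0, 80, length.out = 21))
  C0e <- attr(sim, "C0_eff")
  tab <- suppressMessages(transform_regressors("monod", sim, C0e))
  t_pred <- -p$ks / (C0e * p$mumax) * tab$ln_ratio +
    tab$ln_C0_minus_Cs / p$mumax
  const <- tab$t[1] - t_pred[1]
  expect_equal(tab$t, t_pred + const, tolerance = 1e-6)

  # domain handling
  expect_error(transform_regressors("monod", series, C0_eff = 20),
               class = "epferm_domain_error")
  short <- series[1:3, ]
  expect_error(transform_regressors("monod", short, 30),
               class = "epferm_insufficient_data_error")
})

test_that("noiseless round trips recover the kinetic parameters within 1%", {
  times <- seq(0, 80, length.out = 21)
  cases <- list(
    monod = kinetic_params(0.05, 15, 0.45, 19.6, 34.34, X0 = 0.8),
    contois = kinetic_params(0.0488, 8, 0.45, 19.63, 34.34, X0 = 0.8),
    andrews = kinetic_params(0.07, 6, 0.45, 19.6, 34.34, X0 = 0.8, ki = 80),
    aibe = kinetic_params(0.09, 12, 0.45, 19.6, 34.34, X0 = 0.8, kp = 90)
  )
  for (kind in names(cases)) {
    p <- cases[[kind]]
    sim <- simulate_batch(kind, p, times)
    fit <- fit_integrated(kind, sim, C0_eff = attr(sim, "C0_eff"),
                          Yb = p$Yb, Yp = p$Yp,
                          X0_over_Yb = p$X0 / p$Yb)
    expect_lt(abs(fit$parameters[["mumax"]] - p$mumax) / p$mumax, 0.01)
    expect_lt(abs(fit$parameters[["ks"]] - p$ks) / p$ks, 0.01)
    if (kind == "andrews") {
      expect_lt(abs(fit$parameters[["ki"]] - p$ki) / p$ki, 0.01)
    }
    if (kind == "aibe") {
      expect_lt(abs(fit$parameters[["Yp_over_kp"]] - p$Yp / p$kp) /
                  (p$Yp / p$kp), 0.01)
      expect_lt(abs(fit$parameters[["kp"]] - p$kp) / p$kp, 0.01)
      expect_equal(fit$parameters[["ks_consistency"]],
                   fit$parameters[["ks"]], tolerance = 1e-6)
    }
    expect_gt(fit$r2, 0.999)
  }
})

test_that("parameter recovery degrades gracefully under 2% noise", {
  # an effective initial substrate of 34.34 g/L composed of 30 g/L charge
  # plus the substrate equivalent of the inoculum
  p <- kinetic_params(0.05, 15, 0.45, 19.6, C0 = 30, X0 = 1.953)
  times <- seq(0, 80, length.out = 20)
  errs <- t(vapply(1:100, function(seed) {
    spec <- trajectory_spec("monod", p, times,
                            cv = c(substrate = 0.02, biomass = 0.02,
                                   product = 0.02), seed = seed)
    noisy <- generate_batch_series(spec)
    fit <- suppressMessages(
      fit_integrated("monod", noisy, C0_eff = attr(noisy, "C0_eff")))
    c(mumax = abs(fit$parameters[["mumax"]] - p$mumax) / p$mumax,
      ks = abs(fit$parameters[["ks"]] - p$ks) / p$ks)
  }, c(mumax = 1, ks = 1)))
  expect_lt(median(errs[, "mumax"]), 0.15)
  expect_lt(median(errs[, "ks"]), 0.15)
})

test_that("model comparison is complete, deterministic and self-consistent", {
  p <- p_monod()
  sim <- simulate_batch("monod", p, seq(0, 80, length.out = 21))
  cmp <- compare_models(sim, attr(sim, "C0_eff"), Yb = p$Yb, Yp = p$Yp)
  expect_equal(nrow(cmp$ranking), 4)
  # the generating model is first or tied-first
  expect_equal(cmp$ranking$rank[cmp$ranking$kind == "monod"], 1L)
  cmp2 <- compare_models(sim, attr(sim, "C0_eff"), Yb = p$Yb, Yp = p$Yp)
  expect_identical(cmp$ranking, cmp2$ranking)

  # degenerate series: every model flagged failed, entries kept
  flat <- data.frame(time_h = seq(0, 40, by = 4),
                     substrate_g_per_L = rep(20, 11))
  cmp3 <- suppressMessages(compare_models(flat, C0_eff = 34))
  expect_equal(nrow(cmp3$ranking), 4)
  expect_true(all(cmp3$ranking$failed))
})

test_that("faster growth reaches half-substrate sooner", {
  times <- seq(0, 200, by = 0.5)
  half_time <- function(mumax) {
    p <- kinetic_params(mumax, 15, 0.45, 19.6, 34.34, X0 = 0.8)
    sim <- simulate_batch("monod", p, times)
    min(sim$time_h[sim$substrate_g_per_L <= 34.34 / 2])
  }
  ht <- vapply(c(0.03, 0.05, 0.08), half_time, 1)
  expect_true(all(diff(ht) < 0))
})
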