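fixture_model <- function() {
  # published coefficient column of the response fit, used as a known truth
  response_model(
    intercept = -270.021,
    quadratic = list(time_h = c(alpha = 8.617, beta = -0.059),
                     glycerol = c(alpha = 50.605, beta = -6.234)),
    linear = c(yeast_powder = 15.755, peptone = -43.796, znso4 = -466.113,
               mgso4 = 135.518, kh2po4 = 177.269)
  )
}

test_that("long table expansion has the replication structure of the design", {
  d <- load_design_fixture()
  long <- assemble_long_table(d)
  expect_equal(nrow(long), 40)
  expect_equal(long$ep_ug_per_L[long$run == 1 & long$time_h == 56], 244.67)
  # each factor level occurs once per run, hence four times in the long table
  for (f in c("glycerol", "peptone", "kh2po4")) {
    expect_true(all(table(long[[f]]) == 4))
  }
  d$responses[2, 3] <- NA
  expect_error(assemble_long_table(d),
               class = "epferm_incomplete_design_error")
})

test_that("noiseless synthetic responses are interpolated exactly", {
  d <- load_design_fixture()
  truth <- fixture_model()
  d0 <- generate_design_responses(d, design_noise_spec(truth, sd = 0))
  fit <- fit_response_surface(assemble_long_table(d0))
  expect_equal(fit$intercept, truth$intercept, tolerance = 1e-8)
  expect_equal(fit$quadratic, truth$quadratic, tolerance = 1e-8)
  expect_equal(fit$linear, truth$linear, tolerance = 1e-8)
  expect_equal(fit$stats$r2, 1, tolerance = 1e-10)
})

test_that("coefficient estimates are unbiased under Gaussian noise", {
  d <- load_design_fixture()
  truth <- fixture_model()
  n_rep <- 200
  est <- vapply(seq_len(n_rep), function(i) {
    di <- generate_design_responses(d, design_noise_spec(truth, sd = 10,
                                                         seed = i))
    fit <- fit_response_surface(assemble_long_table(di))
    fit$quadratic$time_h[["alpha"]]
  }, 1)
  mc_se <- sd(est) / sqrt(n_rep)
  expect_lt(abs(mean(est) - 8.617), 2 * mc_se)
})

test_that("classical 95% confidence intervals have nominal coverage", {
  d <- load_design_fixture()
  truth <- fixture_model()
  long0 <- assemble_long_table(
    generate_design_responses(d, design_noise_spec(truth, sd = 0)))
  n_rep <- 500
  alpha_true <- 8.617
  covered <- vapply(seq_len(n_rep), function(i) {
    di <- generate_design_responses(d, design_noise_spec(truth, sd = 10,
                                                         seed = 1000 + i))
    fit <- fit_response_surface(assemble_long_table(di))
    row <- fit$stats$coefficients[fit$stats$coefficients$term == "time_h", ]
    half <- qt(0.975, fit$stats$df[2]) * row$se
    abs(row$estimate - alpha_true) <= half
  }, TRUE)
  expect_gte(mean(covered), 0.92)
  expect_lte(mean(covered), 0.98)
})

test_that("OLS identities hold on the fitted model", {
  fit <- fit_response_surface(assemble_long_table(load_design_fixture()))
  x <- stats::model.matrix(fit$fit)
  r <- stats::residuals(fit$fit)
  expect_lt(max(abs(crossprod(x, r))), 1e-7)
  expect_equal(fit$stats$r2,
               cor(stats::fitted(fit$fit), stats::fitted(fit$fit) + r)^2,
               tolerance = 1e-12)
})

test_that("stationary points follow -alpha/(2 beta) with curvature flags", {
  m <- fixture_model()
  st <- stationary_point(m, "time_h")
  expect_equal(st$value, 8.617 / 0.118, tolerance = 1e-12)
  expect_equal(st$curvature, "maximum")
  sg <- stationary_point(m, "glycerol")
  expect_equal(sg$value, 50.605 / 12.468, tolerance = 1e-12)

  sym <- response_model(0, list(time_h = c(alpha = 0, beta = -1)),
                        c(x = 1))
  expect_equal(stationary_point(sym, "time_h")$value, 0)

  flat <- response_model(0, list(time_h = c(alpha = 1, beta = 0)),
                         c(x = 1))
  expect_error(stationary_point(flat, "time_h"),
               class = "epferm_no_stationary_point_error")
})

test_that("optimum recommendation reproduces the optimized medium recipe", {
  m <- fixture_model()
  opt <- recommend_optimum(m, load_design_fixture())
  expect_equal(
    opt$recipe_g_per_L,
    c(glycerol = 40, yeast_powder = 6.5, peptone = 2, znso4 = 0.05,
      mgso4 = 2.4, kh2po4 = 2.4)
  )
  expect_equal(unname(opt$optimum_time), 8.617 / 0.118, tolerance = 1e-12)
  setv <- setNames(opt$settings$value, opt$settings$factor)
  expect_equal(unname(setv["glycerol"]), 50.605 / 12.468, tolerance = 1e-12)
  prov <- setNames(opt$settings$provenance, opt$settings$factor)
  expect_equal(unname(prov["glycerol"]), "interior-stationary")
  expect_equal(unname(prov["peptone"]), "clamped-lower")
})

test_that("all-negative linear coefficients clamp every linear factor low", {
  m <- response_model(
    0, list(time_h = c(alpha = 8, beta = -0.06)),
    c(a = -1, b = -0.5, c = -20)
  )
  ranges <- list(time_h = c(28, 112), a = c(1, 2), b = c(0.1, 0.9),
                 c = c(0.01, 0.05))
  opt <- recommend_optimum(m, ranges)
  prov <- setNames(opt$settings$provenance, opt$settings$factor)
  expect_true(all(prov[c("a", "b", "c")] == "clamped-lower"))
})

test_that("recommendation is invariant to factor order and unit rescaling", {
  d <- load_design_fixture()
  long <- assemble_long_table(d)
  fit <- fit_response_surface(long)
  opt <- recommend_optimum(fit, d)

  # shuffled linear-factor order
  shuffled <- fit_response_surface(
    long, linear = c("kh2po4", "znso4", "peptone", "mgso4", "yeast_powder"))
  opt_sh <- recommend_optimum(shuffled, d)
  v1 <- setNames(opt$settings$value, opt$settings$factor)
  v2 <- setNames(opt_sh$settings$value, opt_sh$settings$factor)
  expect_equal(v1[names(v2)], v2, tolerance = 1e-10)

  # znso4 rescaled to mg/100 mL: its optimum maps through the same factor
  long_mg <- long
  long_mg$znso4 <- long_mg$znso4 * 1000
  fit_mg <- fit_response_surface(long_mg)
  d_mg <- d
  d_mg$factors[[4]]$levels <- d_mg$factors[[4]]$levels * 1000
  d_mg$layout$znso4 <- d_mg$layout$znso4 * 1000
  opt_mg <- recommend_optimum(fit_mg, d_mg)
  v3 <- setNames(opt_mg$settings$value, opt_mg$settings$factor)
  expect_equal(unname(v3["znso4"]), unname(v1["znso4"]) * 1000,
               tolerance = 1e-8)
  expect_equal(v3[setdiff(names(v3), "znso4")],
               v1[setdiff(names(v1), "znso4")], tolerance = 1e-8)
})

test_that("yield prediction is a plain polynomial evaluation", {
  m <- fixture_model()
  zero <- setNames(rep(0, 6), c("glycerol", "yeast_powder", "peptone",
                                "znso4", "mgso4", "kh2po4"))
  expect_warning(
    y0 <- predict_yield(m, zero, 0),
    "negative"
  )
  expect_equal(y0, m$intercept)

  settings <- c(glycerol = 4.059, yeast_powder = 0.65, peptone = 0.2,
                znso4 = 0.005, mgso4 = 0.24, kh2po4 = 0.24)
  # concave in time: the stationary time beats any other time
  y <- predict_yield(m, settings, c(28, 56, 8.617 / 0.118, 84, 112))
  expect_equal(which.max(y), 3L)

  # independent term-by-term evaluation at fixture run 1, t = 56
  run1 <- c(glycerol = 4.5, yeast_powder = 0.5, peptone = 0.2,
            znso4 = 0.035, mgso4 = 0.06, kh2po4 = 0.18)
  by_hand <- -270.021 +
    8.617 * 56 - 0.059 * 56^2 +
    50.605 * 4.5 - 6.234 * 4.5^2 +
    15.755 * 0.5 - 43.796 * 0.2 - 466.113 * 0.035 +
    135.518 * 0.06 + 177.269 * 0.18
  expect_equal(predict_yield(m, run1, 56), by_hand, tolerance = 1e-12)

  expect_error(predict_yield(m, run1[-1], 56),
               class = "epferm_configuration_error")
})

test_that("rank-deficient and underdetermined observation tables error", {
  long <- assemble_long_table(load_design_fixture())
  long$dup <- long$glycerol
  expect_error(
    fit_response_surface(long, linear = c("yeast_powder", "peptone", "znso4",
                                          "mgso4", "kh2po4", "dup")),
    class = "epferm_collinearity_error"
  )
  expect_error(fit_response_surface(long[1:8, ]),
               class = "epferm_underdetermined_error")
})
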