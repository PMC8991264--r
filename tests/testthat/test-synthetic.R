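truth_model <- function() {
  response_model(
    intercept = -270.021,
    quadratic = list(time_h = c(alpha = 8.617, beta = -0.059),
                     glycerol = c(alpha = 50.605, beta = -6.234)),
    linear = c(yeast_powder = 15.755, peptone = -43.796, znso4 = -466.113,
               mgso4 = 135.518, kh2po4 = 177.269)
  )
}

test_that("generators are bitwise reproducible for a fixed seed", {
  d <- load_design_fixture()
  spec <- design_noise_spec(truth_model(), sd = 10, seed = 123)
  expect_identical(generate_design_responses(d, spec)$responses,
                   generate_design_responses(d, spec)$responses)

  tspec <- default_trajectory_spec(seed = 9)
  expect_identical(as.data.frame(generate_batch_series(tspec)),
                   as.data.frame(generate_batch_series(tspec)))
  # and the caller's RNG stream is left untouched
  set.seed(1)
  before <- .Random.seed
  invisible(generate_batch_series(tspec))
  expect_identical(.Random.seed, before)
})

test_that("empirical residual noise converges to the specified SD", {
  d <- load_design_fixture()
  truth <- truth_model()
  many_times <- seq(1, 1000)
  spec <- design_noise_spec(truth, sd = 12, seed = 5)
  noisy <- generate_design_responses(d, spec, sampling_times = many_times)
  clean <- generate_design_responses(d, design_noise_spec(truth, sd = 0),
                                     sampling_times = many_times)
  resid <- noisy$responses - clean$responses  # 10,000 cells
  expect_equal(sd(as.numeric(resid)), 12, tolerance = 0.05)
})

test_that("the fitted response coefficient distribution centres on truth", {
  d <- load_design_fixture()
  truth <- truth_model()
  est <- vapply(1:500, function(seed) {
    di <- generate_design_responses(d, design_noise_spec(truth, sd = 10,
                                                         seed = seed))
    fit_response_surface(assemble_long_table(di))$quadratic$time_h[["alpha"]]
  }, 1)
  expect_lt(abs(mean(est) - 8.617), 2 * sd(est) / sqrt(length(est)))
})

test_that("default calibrated trajectory matches the fermentor run scale", {
  spec <- default_trajectory_spec()
  spec$cv[] <- 0
  series <- generate_batch_series(spec)
  expect_equal(series$substrate_g_per_L[series$time_h == 0], 34.34)
  cs80 <- series$substrate_g_per_L[series$time_h == 80]
  expect_gte(cs80, 19)
  expect_lte(cs80, 23)
  # product on the observed concentration scale at the end of production
  expect_equal(series$product[series$time_h == 80], 261, tolerance = 0.01)
})

test_that("product decay produces an interior late-run peak", {
  cfg_kd <- yaml::read_yaml(system.file("extdata", "default_kinetics.yaml",
                                        package = "epferm"))$batch$kd_shape
  spec <- default_trajectory_spec(kd = cfg_kd)
  spec$cv[] <- 0
  series <- generate_batch_series(spec)
  peak <- series$time_h[which.max(series$product)]
  expect_gt(peak, 60)
  expect_lt(peak, 90)
  expect_lt(series$product[nrow(series)], max(series$product))
})

test_that("zero noise and zero decay reduce to the plain batch simulation", {
  spec <- default_trajectory_spec()
  spec$cv[] <- 0
  series <- generate_batch_series(spec)
  direct <- simulate_batch(spec$kind, spec$params, spec$times)
  expect_equal(as.data.frame(series), as.data.frame(direct),
               tolerance = 1e-12, ignore_attr = TRUE)
  # exact product-substrate coupling before noise
  p <- spec$params
  expect_equal(series$product,
               p$Yp * (p$C0 - series$substrate_g_per_L), tolerance = 1e-10)
})

test_that("group fixtures encode the three supplementation schedules", {
  fx <- make_group_fixtures()
  expect_equal(nrow(fx$schedules$group1$events), 0)
  expect_equal(fx$schedules$group2$events$time, c(40, 60))
  expect_equal(fx$schedules$group2$events$volume_L, c(1, 1))
  expect_equal(fx$schedules$group2$events$glycerol_g, c(0, 0))
  expect_equal(sum(fx$schedules$group3$events$glycerol_g), 600)
  expect_equal(fx$schedules$group3$events$volume_L, c(1, 1))
  expect_equal(fx$schedules$group1$initial_volume_L, 15)
  expect_equal(fx$spec$params$C0, 20)
})
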