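test_that("fractionation builder reproduces the experimental schedules", {
  # 10 Gy at 0.1 Gy/min average, 1-Gy fractions at 1 Gy/min beam rate:
  # 10 fractions over 100 min with 10-min gaps
  p <- make_fractionation_protocol(10, 1, 1.0, 0.1)
  expect_equal(nrow(p), 10L)
  expect_equal(sum(p$dose), 10)
  elapsed <- p$start[10] + p$duration[10] - p$start[1]
  expect_equal(elapsed, 100 / 60, tolerance = 1e-9)
  gaps <- p$start[-1] - (p$start[-10] + p$duration[-10])
  expect_equal(gaps, rep(10 / 60, 9), tolerance = 1e-12)

  # 6 Gy at 0.25 Gy/min average: 24 min elapsed, 3.6-min gaps
  p6 <- make_fractionation_protocol(6, 1, 1.0, 0.25)
  expect_equal(nrow(p6), 6L)
  elapsed6 <- p6$start[6] + p6$duration[6] - p6$start[1]
  expect_equal(elapsed6, 24 / 60, tolerance = 1e-9)
  gaps6 <- p6$start[-1] - (p6$start[-6] + p6$duration[-6])
  expect_equal(gaps6, rep(3.6 / 60, 5), tolerance = 1e-12)
})

test_that("builder conserves dose and elapsed time over random designs", {
  set.seed(17)
  for (i in 1:20) {
    n <- sample(2:12, 1)
    fs <- runif(1, 0.5, 2)
    beam <- runif(1, 0.5, 2)
    avg <- runif(1, 0.05, beam)
    p <- make_fractionation_protocol(n * fs, fs, beam, avg)
    expect_equal(sum(p$dose), n * fs, tolerance = 1e-12)
    elapsed <- p$start[nrow(p)] + p$duration[nrow(p)] - p$start[1]
    expect_equal(elapsed, n * fs / avg / 60, tolerance = 1e-9)
  }
})

test_that("degenerate and infeasible schedules are handled", {
  # average rate equal to beam rate: one continuous block
  p <- make_fractionation_protocol(6, 1, 1.0, 1.0)
  expect_equal(nrow(p), 1L)
  expect_equal(p$duration, 6 / 60)
  expect_error(make_fractionation_protocol(6, 1, 0.5, 1.0), "infeasible")
  expect_error(make_fractionation_protocol(5, 1.5, 1, 0.5), "multiple")
})

test_that("noiseless datasets equal the model predictions exactly", {
  ctx <- test_ctx()
  m <- sas_model()
  d <- simulate_survival_dataset(m, ctx, sigma = 0, replicates = 2, seed = 1)
  mu <- survival_curve(m, ctx, unique(d$dose), dose_rate = 1.0)$neg_log_S
  expect_equal(d$neg_log_S, rep(mu, each = 2), tolerance = 1e-12)
})

test_that("noise on -ln S has the configured scale", {
  ctx <- test_ctx()
  m <- sas_model()
  d <- simulate_survival_dataset(m, ctx, doses = seq(0, 10, by = 2),
                                 replicates = 3, sigma = 0.1, seed = 7)
  mu <- survival_curve(m, ctx, unique(d$dose), dose_rate = 1.0)$neg_log_S
  resid <- d$neg_log_S - rep(mu, each = 3)
  # chi-square bounds on a sample SD at n = 18, sigma = 0.1
  expect_gt(sd(resid), 0.07)
  expect_lt(sd(resid), 0.13)
})

test_that("generators are deterministic at a fixed seed", {
  ctx <- test_ctx()
  m <- sas_model()
  d1 <- simulate_survival_dataset(m, ctx, sigma = 0.1, seed = 11)
  d2 <- simulate_survival_dataset(m, ctx, sigma = 0.1, seed = 11)
  expect_identical(d1$neg_log_S, d2$neg_log_S)
  b1 <- simulate_experiment_bundle(seed = 12)
  b2 <- simulate_experiment_bundle(seed = 12)
  expect_identical(b1$parent$neg_log_S, b2$parent$neg_log_S)
  expect_identical(b1$recovery$S, b2$recovery$S)
  expect_identical(b1$flow_parent$draws, b2$flow_parent$draws)
})

test_that("recovery-curve generator matches its closed form", {
  sas <- sas_progeny()
  rc <- simulate_recovery_curve(sas, GAMMA_TAB, 2, 2, intervals = c(0, 24))
  # S(24)/S(0) = exp(2 b0 D1 D2 (1 - e^{-24k})) ~ exp(2 b0 D1 D2)
  ratio <- rc$S[rc$tau == 24] / rc$S[rc$tau == 0]
  expect_equal(ratio, exp(2 * 0.044 * 4 * (1 - exp(-24 * 1.279))),
               tolerance = 1e-12)
  expect_equal(ratio, exp(2 * 0.044 * 4), tolerance = 1e-4)
  # deterministic when sigma = 0
  rc2 <- simulate_recovery_curve(sas, GAMMA_TAB, 2, 2, intervals = c(0, 24))
  expect_identical(rc$S, rc2$S)
})

test_that("optional colony-count layer adds Poisson sampling noise", {
  ctx <- test_ctx()
  m <- sas_model()
  d <- simulate_survival_dataset(m, ctx, doses = c(0, 2, 4), replicates = 50,
                                 sigma = 0, colony_counts = TRUE,
                                 cells_seeded = 5000, seed = 13)
  mu <- survival_curve(m, ctx, c(0, 2, 4), dose_rate = 1.0)$neg_log_S
  # with many cells the count ratio concentrates on the model value
  means <- tapply(d$neg_log_S, d$dose, mean)
  expect_lt(max(abs(unname(means) - mu)), 0.02)
  # but individual replicates scatter
  expect_gt(sd(d$neg_log_S[d$dose == 4]), 0)
  d2 <- simulate_survival_dataset(m, ctx, doses = c(0, 2, 4), replicates = 50,
                                  sigma = 0, colony_counts = TRUE,
                                  cells_seeded = 5000, seed = 13)
  expect_identical(d$neg_log_S, d2$neg_log_S)
})

test_that("flow-cytometry generator respects truncation and converges", {
  f0 <- simulate_flow_cytometry(0.1, sd = 0, n_experiments = 5)
  expect_equal(f0$mean, 0.1)
  expect_equal(f0$sd, 0)
  f1 <- simulate_flow_cytometry(0.1, sd = 0.04, n_experiments = 1000,
                                seed = 19)
  expect_lt(abs(f1$mean - 0.1), 0.005)
  f2 <- simulate_flow_cytometry(0.005, sd = 0.02, n_experiments = 5000,
                                seed = 20)
  expect_gte(min(f2$draws), 0)
  expect_lte(max(f2$draws), 1)
})
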