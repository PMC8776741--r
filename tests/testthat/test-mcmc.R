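theta_truth <- function() {
  truth <- sas_family_parameters()
  unlist(truth[c("alpha0p", "beta0p", "repair_p", "alpha0s", "beta0s",
                 "w_SLDR", "f_s_parent", "f_s_resistant")])
}

test_that("log-likelihood matches the Gaussian closed form", {
  ctx <- test_ctx()
  th <- theta_truth()
  # one record with zero residual: log density = log(1/(0.1 sqrt(2 pi)))
  model <- sas_model()
  mu <- survival_curve(model, ctx, 2)$neg_log_S
  d1 <- survival_dataset("SAS", 2, neg_log_S = mu)
  expect_equal(log_likelihood(d1, th, sigma = 0.1, ctx = ctx),
               log(3.98942), tolerance = 1e-5)
  # doubling sigma at zero residual costs N log 2
  d3 <- survival_dataset("SAS", c(2, 2, 2), neg_log_S = rep(mu, 3))
  expect_equal(log_likelihood(d3, th, 0.1, ctx) -
                 log_likelihood(d3, th, 0.2, ctx),
               3 * log(2), tolerance = 1e-10)
})

test_that("constraint violations yield -Inf density, not an error", {
  ctx <- test_ctx()
  d <- survival_dataset("SAS", c(0, 2), neg_log_S = c(0, 0.7))
  th <- theta_truth()
  th["alpha0s"] <- th["alpha0p"] + 0.01  # stem must stay below progeny
  expect_identical(log_likelihood(d, th, 0.1, ctx), -Inf)
  th <- theta_truth(); th["beta0s"] <- th["beta0p"]
  expect_identical(log_likelihood(d, th, 0.1, ctx), -Inf)
  th <- theta_truth(); th["f_s_parent"] <- 1.2
  expect_identical(log_likelihood(d, th, 0.1, ctx), -Inf)
})

test_that("Metropolis acceptance probability follows the posterior ratio", {
  expect_identical(mh_acceptance_prob(-5, -5), 1)
  expect_equal(mh_acceptance_prob(-5 - log(2), -5), 0.5)
  expect_identical(mh_acceptance_prob(-Inf, -5), 0)
  expect_identical(mh_acceptance_prob(-Inf, -Inf), 0)
  expect_identical(mh_acceptance_prob(-2, -10), 1)
})

test_that("coefficient of determination on the -ln S scale", {
  expect_identical(r_squared(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_identical(r_squared(c(1, 2, 3), rep(2, 3)), 0)
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 4)), 0.5)
  expect_error(r_squared(c(1, 1), c(1, 2)), "zero variance")
  expect_error(r_squared(1, c(1, 2)), "equal length")
})

test_that("sampler reproduces a known 1-parameter Gaussian posterior", {
  # All parameters but (a+c)_p pinned; acute (T = 0) data carry no
  # information about the repair rate, so its posterior is exactly its
  # normal prior: N(1.5, 0.3^2).
  ctx <- test_ctx()
  th <- theta_truth()
  model <- sas_model()
  mu <- survival_curve(model, ctx, c(0, 2, 4, 6))$neg_log_S
  d <- survival_dataset("SAS", c(0, 2, 4, 6), neg_log_S = mu)
  pr <- prior_spec(repair_mean = 1.5, repair_sd = 0.3,
                   f_s_parent = c(th[["f_s_parent"]], 0),
                   f_s_resistant = c(th[["f_s_resistant"]], 0))
  fit <- imk_fit(d, NULL, priors = pr, ctx = ctx, sigma = 0.1,
                 control = imk_control(n_iter = 30000),
                 fixed_params = th[c("alpha0p", "beta0p", "alpha0s",
                                     "beta0s", "w_SLDR")],
                 seed = 99)
  s <- fit$summary[fit$summary$parameter == "repair_p", ]
  mcse <- s$sd / sqrt(s$ess)
  expect_lt(abs(s$mean - 1.5), 3 * mcse + 0.01)
  expect_equal(s$sd, 0.3, tolerance = 0.05)
})

test_that("point-mass priors pin the posterior at the truth", {
  ctx <- test_ctx()
  th <- theta_truth()
  sim <- simulate_family_datasets(seed = 3)
  fit <- imk_fit(sim$parent, sim$resistant,
                 priors = sas_priors(), ctx = ctx, sigma = 0.1,
                 control = imk_control(n_iter = 500),
                 fixed_params = th, seed = 7)
  means <- colMeans(fit$chain)[names(th)]
  sds <- apply(fit$chain[, names(th)], 2, sd)
  expect_equal(unname(means), unname(th), tolerance = 1e-12)
  expect_true(all(sds == 0))
})

test_that("the stem repair rate satisfies its structural tie in every sample", {
  sim <- simulate_family_datasets(seed = 4)
  fit <- imk_fit(sim$parent, sim$resistant, priors = sas_priors(),
                 ctx = test_ctx(), sigma = 0.1,
                 control = imk_control(n_iter = 1500), seed = 8)
  expect_equal(fit$chain[, "repair_H"],
               fit$chain[, "w_SLDR"] * fit$chain[, "repair_p"],
               tolerance = 1e-15)
  expect_equal(fit$chain[, "alpha0p_star"],
               fit$chain[, "alpha0p"] / fit$chain[, "w_SLDR"],
               tolerance = 1e-15)
})

test_that("without resistant-line data the enhancement ratio stays at its prior", {
  ctx <- test_ctx()
  sim <- simulate_family_datasets(seed = 5)
  fit <- imk_fit(sim$parent, NULL, priors = sas_priors(), ctx = ctx,
                 sigma = 0.1, control = imk_control(n_iter = 20000),
                 seed = 9)
  s <- fit$summary[fit$summary$parameter == "w_SLDR", ]
  # prior is uniform on [1, 5]: mean 3, sd 4/sqrt(12)
  expect_equal(s$mean, 3, tolerance = 0.1)
  expect_equal(s$sd, 4 / sqrt(12), tolerance = 0.1)
})

test_that("independent chains agree within Monte-Carlo error", {
  ctx <- test_ctx()
  sim <- simulate_family_datasets(seed = 6)
  pr <- sas_priors()
  ctl <- imk_control(n_iter = 12000)
  protos <- list(acute = list(dose_rate_Gy_min = 1.0))
  f1 <- imk_fit(sim$parent, sim$resistant, priors = pr, ctx = ctx,
                sigma = 0.1, protocols = protos, control = ctl, seed = 21)
  f2 <- imk_fit(sim$parent, sim$resistant, priors = pr, ctx = ctx,
                sigma = 0.1, protocols = protos, control = ctl, seed = 22)
  for (p in c("alpha0p", "beta0p", "w_SLDR", "f_s_resistant")) {
    s1 <- f1$summary[f1$summary$parameter == p, ]
    s2 <- f2$summary[f2$summary$parameter == p, ]
    mcse <- sqrt(s1$sd^2 / s1$ess + s2$sd^2 / s2$ess)
    expect_lt(abs(s1$mean - s2$mean), 3 * mcse + 0.02 * s1$sd)
  }
})

test_that("fits are bit-for-bit reproducible at a fixed seed", {
  sim <- simulate_family_datasets(seed = 2)
  ctl <- imk_control(n_iter = 800)
  f1 <- imk_fit(sim$parent, sim$resistant, priors = sas_priors(),
                ctx = test_ctx(), sigma = 0.1, control = ctl, seed = 33)
  f2 <- imk_fit(sim$parent, sim$resistant, priors = sas_priors(),
                ctx = test_ctx(), sigma = 0.1, control = ctl, seed = 33)
  expect_identical(f1$chain, f2$chain)
})
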