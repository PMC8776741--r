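test_that("protraction factor: acute limit, direct values, asymptote", {
  expect_identical(lea_catcheside_factor(1.279, 0), 1)
  expect_identical(lea_catcheside_factor(2.0, 0), 1)
  # direct evaluation at x = (a+c)T = 1.279
  x <- 1.279
  expect_equal(lea_catcheside_factor(1.279, 1),
               2 / x^2 * (x + exp(-x) - 1), tolerance = 1e-12)
  expect_lt(abs(lea_catcheside_factor(1.279, 1) - 0.6813), 1e-4)
  # long-delivery asymptote ~ 2/((a+c)T)
  expect_equal(lea_catcheside_factor(2.0, 100), 0.00990, tolerance = 1e-2)
  expect_lt(abs(lea_catcheside_factor(2.0, 100) - 0.00990), 1e-4)
  expect_error(lea_catcheside_factor(2.0, -1), ">= 0")
  expect_error(lea_catcheside_factor(0, 1), "positive")
})

test_that("protraction factor is continuous at the series branch and decreasing", {
  k <- 1.5
  Ts <- c(0, 1e-9, 1e-7, 1e-5, 1e-3, 0.01, 0.1, 1, 10, 100)
  F <- lea_catcheside_factor(k, Ts)
  expect_true(all(F > 0 & F <= 1))
  expect_true(all(diff(F) < 0 | diff(Ts) == 0))
  # no jump at the series/exact branch point x = 1e-4 beyond the true
  # local variation of F (~x/3 per unit relative change in x)
  expect_equal(lea_catcheside_factor(1, 0.99e-4),
               lea_catcheside_factor(1, 1.01e-4), tolerance = 1e-6)
  # F*T -> 2/(a+c) as T grows
  expect_equal(lea_catcheside_factor(k, 1e5) * 1e5, 2 / k, tolerance = 1e-4)
})

test_that("single-dose burden reproduces the acute closed form", {
  sas <- sas_progeny()
  expect_equal(neg_log_survival_single(sas, GAMMA_TAB, 2, 0),
               0.675952, tolerance = 1e-6)
  expect_equal(exp(-neg_log_survival_single(sas, GAMMA_TAB, 2, 0)),
               0.5087, tolerance = 1e-4)
  expect_identical(neg_log_survival_single(sas, GAMMA_TAB, 0, 0), 0)
  # protraction strictly reduces the burden
  acute <- neg_log_survival_single(sas, GAMMA_TAB, 10, 0)
  slow <- neg_log_survival_single(sas, GAMMA_TAB, 10, 10 / 0.6)
  expect_lt(slow, acute)
  # non-decreasing in dose
  d <- seq(0, 15, by = 0.5)
  expect_true(all(diff(neg_log_survival_single(sas, GAMMA_TAB, d, 0)) >= 0))
  expect_error(neg_log_survival_single(sas, GAMMA_TAB, -1, 0), ">= 0")
})

test_that("split-dose burden: collapse, independence and cross-term values", {
  sas <- sas_progeny()
  # tau = 0 collapses to a single acute 4 Gy dose, to machine precision
  expect_equal(neg_log_survival_split(sas, GAMMA_TAB, 2, 2, 0),
               neg_log_survival_single(sas, GAMMA_TAB, 4, 0),
               tolerance = 1e-15)
  expect_equal(neg_log_survival_split(sas, GAMMA_TAB, 2, 2, 0),
               1.70390, tolerance = 1e-5)
  # infinite interval: two independent acute fractions
  expect_equal(neg_log_survival_split(sas, GAMMA_TAB, 2, 2, 1e6),
               2 * neg_log_survival_single(sas, GAMMA_TAB, 2, 0),
               tolerance = 1e-9)
  expect_equal(neg_log_survival_split(sas, GAMMA_TAB, 2, 2, 1e6),
               1.35190, tolerance = 1e-4)
  # 3 h interval with (a+c) = 1.279
  expect_equal(neg_log_survival_split(sas, GAMMA_TAB, 2, 2, 3),
               1.35949, tolerance = 1e-5)
  # monotone decreasing in tau
  tau <- seq(0, 24, by = 0.5)
  expect_true(all(diff(neg_log_survival_split(sas, GAMMA_TAB, 2, 2, tau)) < 0))
  expect_error(neg_log_survival_split(sas, GAMMA_TAB, 2, 2, -1), ">= 0")
})

test_that("protocol evaluator specialises to the split and single forms", {
  sas <- sas_progeny()
  p2 <- irradiation_protocol(c(2, 2), start = c(0, 3))
  expect_equal(neg_log_survival_protocol(sas, GAMMA_TAB, p2),
               neg_log_survival_split(sas, GAMMA_TAB, 2, 2, 3),
               tolerance = 1e-15)
  p1 <- irradiation_protocol(10, 0, 10 / 60)
  expect_equal(neg_log_survival_protocol(sas, GAMMA_TAB, p1),
               neg_log_survival_single(sas, GAMMA_TAB, 10, 1 / 6),
               tolerance = 1e-15)
})

test_that("many small fractions converge to the continuous-delivery form", {
  sas <- sas_progeny()
  cont <- neg_log_survival_single(sas, GAMMA_TAB, 10, 1)
  for (spec in list(c(100, 0.01), c(1000, 0.001))) {
    n <- spec[1]
    pn <- irradiation_protocol(rep(10 / n, n), start = seq(0, 1, length.out = n))
    rel <- abs(neg_log_survival_protocol(sas, GAMMA_TAB, pn) - cont) / cont
    expect_lt(rel, spec[2])
  }
})

test_that("overlapping fractions are rejected", {
  expect_error(irradiation_protocol(c(2, 2), start = c(0, 0.1),
                                    duration = c(0.5, 0)), "overlap")
  expect_error(irradiation_protocol(c(2, 2), start = c(1, 1)),
               "strictly increasing")
})

test_that("resistant-progeny derivation reproduces the family parameter table", {
  # HSC2 family: parent (0.166, 0.168, 1.499), w = 1.896
  r <- derive_resistant_progeny(hsc2_progeny(), 1.896)
  expect_equal(round(r$alpha0, 3), 0.088)
  expect_equal(round(r$beta0, 3), 0.089)
  expect_equal(round(r$repair_rate, 3), 2.842)
  # SAS family: alpha0p* from 3-decimal inputs rounds to 0.196-0.197
  r2 <- derive_resistant_progeny(sas_progeny(), 1.059)
  expect_equal(r2$alpha0, 0.19641, tolerance = 1e-4)
  expect_lt(abs(r2$alpha0 - 0.197), 1e-3)
  # w = 1 is the identity (non-resistant branch)
  expect_equal(derive_resistant_progeny(sas_progeny(), 1), sas_progeny())
  expect_error(derive_resistant_progeny(sas_progeny(), 0), "positive")
})

test_that("repair-enhancement scaling preserves the alpha/beta ratio", {
  for (w in c(1.059, 1.5, 1.896, 3)) {
    r <- derive_resistant_progeny(sas_progeny(), w)
    expect_equal(r$alpha0 / r$beta0, 0.208 / 0.044, tolerance = 1e-12)
  }
})

test_that("mixture survival is the affine combination of its components", {
  expect_equal(mixture_survival(0.1, 0.3, 0.5), 0.2)
  expect_equal(mixture_survival(0.01, 0.5, 0.012), 0.01588)
  expect_identical(mixture_survival(0.37, 0.9, 0), 0.37)
  expect_identical(mixture_survival(0.37, 0.9, 1), 0.9)
  # bounded by its components; affine in f_s
  set.seed(11)
  for (i in 1:25) {
    sp <- runif(1); ss <- runif(1); fs <- runif(1)
    m <- mixture_survival(sp, ss, fs)
    expect_gte(m, min(sp, ss)); expect_lte(m, max(sp, ss))
    m2 <- mixture_survival(sp, ss, fs / 2)
    expect_equal(m2, (mixture_survival(sp, ss, 0) + m) / 2, tolerance = 1e-12)
  }
  expect_error(mixture_survival(0.5, 0.5, 1.2), "\\[0, 1\\]")
  expect_error(mixture_survival(1.5, 0.5, 0.2), "\\[0, 1\\]")
})

test_that("two-population curve collapses and flattens as expected", {
  ctx <- test_ctx()
  truth <- sas_family_parameters()
  # f_s = 0 reduces exactly to the progeny-only curve
  m0 <- two_population_model(sas_progeny(), truth$alpha0s, truth$beta0s,
                             f_s = 0, w_SLDR = truth$w_SLDR)
  d <- c(0, 2, 4, 6, 8, 10)
  curve <- survival_curve(m0, ctx, d)
  expect_equal(curve$neg_log_S,
               neg_log_survival_single(sas_progeny(), ctx$gamma, d, 0),
               tolerance = 1e-12)
  # high-dose tail of the mixture approaches the stem-population slope
  m <- sas_model()
  stem <- population_params(truth$alpha0s, truth$beta0s,
                            truth$w_SLDR * truth$repair_p)
  slope_at <- function(D) {
    mix <- diff(survival_curve(m, ctx, c(D - 1, D))$neg_log_S)
    st <- diff(neg_log_survival_single(stem, ctx$gamma, c(D - 1, D), 0))
    abs(mix - st) / st
  }
  expect_lt(slope_at(20), slope_at(15))  # convergence with dose
  expect_lt(slope_at(20), 0.05)
  # survival at fixed dose is non-decreasing as dose rate falls
  rates <- c(1.0, 0.25, 0.1, 0.05, 0.01)
  S10 <- vapply(rates, function(r)
    survival_curve(m, ctx, 10, dose_rate = r)$surviving_fraction, numeric(1))
  expect_true(all(diff(S10) >= 0))
})
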