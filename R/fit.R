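# Joint Bayesian fit of a cell-line family (parent + radioresistant)
# by Gaussian random-walk Metropolis sampling.

#' Sampler settings for [imk_fit()]
#'
#' @param n_iter Total Metropolis sweeps (each sweep updates every free
#'   parameter once, component-wise).
#' @param burn_frac Fraction of sweeps discarded as burn-in.
#' @param thin Keep every `thin`-th post-burn-in sweep.
#' @param adapt_interval During burn-in, rescale each proposal SD every
#'   this many sweeps towards the target acceptance window.
#' @param target_accept Length-2 acceptance-rate window the per-parameter
#'   proposal scales are tuned into during burn-in; adaptation is frozen
#'   afterwards so the retained chain satisfies detailed balance.
#' @param init_scales Optional named numeric of initial proposal SDs.
#' @param estimate_sigma If `TRUE`, the residual SD sigma is sampled
#'   alongside theta under a weak half-normal prior (scale
#'   `sigma_prior_scale`) instead of being held fixed.
#' @param sigma_prior_scale Scale of the half-normal prior on sigma.
#' @return List of class `imk_control`.
#' @export
imk_control <- function(n_iter = 50000L, burn_frac = 0.2, thin = 1L,
                        adapt_interval = 100L, target_accept = c(0.2, 0.4),
                        init_scales = NULL, estimate_sigma = FALSE,
                        sigma_prior_scale = 0.5) {
  stopifnot(n_iter >= 100L, burn_frac > 0, burn_frac < 1, thin >= 1L)
  structure(list(n_iter = as.integer(n_iter), burn_frac = burn_frac,
                 thin = as.integer(thin),
                 adapt_interval = as.integer(adapt_interval),
                 target_accept = target_accept, init_scales = init_scales,
                 estimate_sigma = estimate_sigma,
                 sigma_prior_scale = sigma_prior_scale),
            class = "imk_control")
}

# Pooled replicate SD of -ln S within (line, protocol, dose) groups.
.pooled_sigma <- function(...) {
  datasets <- list(...)
  ss <- 0; df <- 0
  for (d in datasets) {
    g <- split(d$neg_log_S, paste(d$cell_line, d$protocol_id, d$dose))
    for (v in g) {
      if (length(v) > 1L) {
        ss <- ss + sum((v - mean(v))^2)
        df <- df + length(v) - 1L
      }
    }
  }
  if (df == 0) return(NA_real_)
  sqrt(ss / df)
}

# Deterministic feasible starting point inside the prior support.
.init_theta <- function(priors) {
  ab <- priors$alpha_bounds; bb <- priors$beta_bounds; wb <- priors$w_bounds
  mid <- function(b, f) b[1] + f * (b[2] - b[1])
  clamp01 <- function(x) min(max(x, 1e-4), 1 - 1e-4)
  c(alpha0p = mid(ab, 0.4), beta0p = mid(bb, 0.4),
    repair_p = max(priors$repair_mean, 0.05),
    alpha0s = mid(ab, 0.15), beta0s = mid(bb, 0.15),
    w_SLDR = mid(wb, 0.25),
    f_s_parent = clamp01(priors$f_s_parent[1]),
    f_s_resistant = clamp01(priors$f_s_resistant[1]))
}

#' Fit the two-population survival model to a cell-line family
#'
#' Jointly fits the parental (non-radioresistant) and radioresistant
#' survival curves of one cell-line family. The two lines share the
#' parental progeny parameters (\eqn{\alpha_{0p}, \beta_{0p}, (a+c)_p}),
#' the stem-like parameters (\eqn{\alpha_{0s}, \beta_{0s}}), and the
#' repair-enhancement ratio \eqn{w_{SLDR}}; they differ in their
#' stem-like fractions (`f_s_parent`, `f_s_resistant`) and in that the
#' resistant line's progeny parameters are modulated by \eqn{w_{SLDR}}
#' (see [derive_resistant_progeny()]). The stem compartment's repair rate
#' is \eqn{(a+c)_H = w_{SLDR}(a+c)_p} in both lines.
#'
#' Sampling is seeded Gaussian random-walk Metropolis, component-wise,
#' with proposal scales adapted during burn-in only. Parameters whose
#' prior is a point mass (SD 0, or coincident uniform bounds) are held
#' fixed. The residual SD `sigma` of the Gaussian likelihood on
#' \eqn{-\ln S} defaults to the pooled replicate SD of the observations.
#'
#' @param parent_data,resistant_data [survival_dataset()]s of the two
#'   lines. `resistant_data` may be `NULL` to fit a single line (then
#'   `w_SLDR` and `f_s_resistant` are prior-driven).
#' @param priors A [prior_spec()].
#' @param ctx A [microdosimetric_context()].
#' @param protocols Named list mapping the datasets' `protocol_id` values
#'   to either an [irradiation_protocol()], a list
#'   `list(dose_rate_Gy_min = r)` for continuous delivery, or the string
#'   `"acute"`. Ids not listed are treated as acute.
#' @param sigma Residual SD on \eqn{-\ln S}; default is the pooled
#'   replicate SD of the data (an error if no replicates and no value
#'   given and `estimate_sigma` is off).
#' @param control An [imk_control()].
#' @param fixed_params Optional named numeric vector pinning any subset
#'   of the parameters (e.g. `c(w_SLDR = 1)` for a family with no
#'   resistant line); pinned parameters are not updated by the sampler.
#' @param seed Integer seed; the fit is bit-for-bit reproducible at a
#'   fixed seed.
#' @return An object of class `imk_fit` with components `chain` (matrix
#'   of retained samples, including derived columns `repair_H`,
#'   `alpha0p_star`, `beta0p_star`), `summary` (posterior means/SDs/
#'   quantiles/ESS), `acceptance` (per-parameter rates after burn-in),
#'   `sigma`, `r_squared` (per line, at posterior means), `data`,
#'   `priors`, `ctx`, `protocols`, `control`, `seed`.
#' @examples
#' \donttest{
#' ctx <- microdosimetric_context()
#' truth <- sas_family_parameters()
#' sim <- simulate_family_datasets(truth, ctx, seed = 1)
#' pr <- prior_spec(repair_mean = 1.3, repair_sd = 0.7,
#'                  f_s_parent = c(0.012, 0.006),
#'                  f_s_resistant = c(0.083, 0.046))
#' fit <- imk_fit(sim$parent, sim$resistant, priors = pr, sigma = 0.1,
#'                control = imk_control(n_iter = 2000), seed = 1)
#' summary(fit)
#' }
#' @export
imk_fit <- function(parent_data, resistant_data = NULL,
                    priors = prior_spec(), ctx = microdosimetric_context(),
                    protocols = list(), sigma = NULL,
                    control = imk_control(), fixed_params = NULL,
                    seed = NULL) {
  stopifnot(inherits(parent_data, "survival_dataset"),
            inherits(priors, "prior_spec"), inherits(control, "imk_control"))
  if (nrow(parent_data) == 0L)
    stop("'parent_data' is empty", call. = FALSE)
  if (!is.null(resistant_data))
    stopifnot(inherits(resistant_data, "survival_dataset"))
  if (!is.null(seed)) set.seed(seed)

  gamma <- gamma_coefficient(ctx)
  pred_parent <- .compile_design(parent_data, protocols, gamma)
  pred_res <- if (!is.null(resistant_data))
    .compile_design(resistant_data, protocols, gamma) else NULL
  obs_parent <- parent_data$neg_log_S
  obs_res <- if (!is.null(resistant_data)) resistant_data$neg_log_S

  est_sigma <- isTRUE(control$estimate_sigma)
  if (is.null(sigma)) {
    sigma <- .pooled_sigma(parent_data, resistant_data)
    if (!est_sigma && (!is.finite(sigma) || sigma <= 0))
      stop("cannot determine 'sigma': no replicate structure in the data; ",
           "supply sigma or set estimate_sigma = TRUE", call. = FALSE)
    if (est_sigma && (!is.finite(sigma) || sigma <= 0)) sigma <- 0.1
  }

  log_post <- function(theta, sig) {
    lp <- .log_prior(theta, priors)
    if (!is.finite(lp)) return(-Inf)
    if (est_sigma) {
      if (sig <= 0) return(-Inf)
      lp <- lp - sig^2 / (2 * control$sigma_prior_scale^2)  # half-normal
    }
    cal_p <- .line_neg_log_S(theta, pred_parent, resistant = FALSE)
    ll <- sum(stats::dnorm(obs_parent, cal_p, sig, log = TRUE))
    if (!is.null(pred_res)) {
      cal_r <- .line_neg_log_S(theta, pred_res, resistant = TRUE)
      ll <- ll + sum(stats::dnorm(obs_res, cal_r, sig, log = TRUE))
    }
    lp + ll
  }

  # Fixed (point-mass) parameters are excluded from updating.
  fixed <- c(alpha0p = FALSE, beta0p = FALSE,
             repair_p = priors$repair_sd == 0,
             alpha0s = FALSE, beta0s = FALSE,
             w_SLDR = priors$w_bounds[1] == priors$w_bounds[2],
             f_s_parent = priors$f_s_parent[2] == 0,
             f_s_resistant = priors$f_s_resistant[2] == 0)

  if (!is.null(fixed_params)) {
    bad <- setdiff(names(fixed_params), .PAR_NAMES)
    if (length(bad))
      stop("unknown parameter(s) in 'fixed_params': ",
           paste(bad, collapse = ", "), call. = FALSE)
    fixed[names(fixed_params)] <- TRUE
  }

  theta <- .init_theta(priors)
  if (!is.null(fixed_params)) theta[names(fixed_params)] <- fixed_params
  scales <- c(alpha0p = 0.02, beta0p = 0.01, repair_p = 0.15,
              alpha0s = 0.02, beta0s = 0.005, w_SLDR = 0.05,
              f_s_parent = max(priors$f_s_parent[2] / 2, 1e-4),
              f_s_resistant = max(priors$f_s_resistant[2] / 2, 1e-4))
  if (!is.null(control$init_scales))
    scales[names(control$init_scales)] <- control$init_scales
  sig_scale <- 0.05

  lp_cur <- log_post(theta, sigma)
  if (!is.finite(lp_cur)) {
    for (try in seq_len(1000L)) {
      cand <- theta
      free <- names(theta)[!fixed]
      cand[free] <- theta[free] * exp(stats::rnorm(length(free), 0, 0.2))
      cand["f_s_parent"] <- min(cand[["f_s_parent"]], 0.999)
      cand["f_s_resistant"] <- min(cand[["f_s_resistant"]], 0.999)
      lp_try <- log_post(cand, sigma)
      if (is.finite(lp_try)) { theta <- cand; lp_cur <- lp_try; break }
    }
    if (!is.finite(lp_cur))
      stop("could not find a feasible starting point under the priors",
           call. = FALSE)
  }

  n_iter <- control$n_iter
  n_burn <- as.integer(floor(control$burn_frac * n_iter))
  keep_idx <- seq.int(n_burn + 1L, n_iter, by = control$thin)
  free <- names(theta)[!fixed]
  np <- length(free)
  chain <- matrix(NA_real_, length(keep_idx), length(theta) + est_sigma,
                  dimnames = list(NULL, c(names(theta),
                                          if (est_sigma) "sigma")))
  acc <- stats::setNames(numeric(np), free)
  acc_win <- stats::setNames(numeric(np), free)
  sig_acc <- 0; sig_acc_win <- 0
  k_keep <- 0L

  # Adaptive-Metropolis block proposal: learn the joint covariance of the
  # free parameters during burn-in, freeze it afterwards, and mix one
  # correlated joint update into every sweep. This decorrelates the
  # strongly coupled LQ coefficients that component-wise walks traverse
  # slowly.
  burn_store <- if (np >= 2L) matrix(NA_real_, n_burn, np,
                                     dimnames = list(NULL, free))
  joint_L <- NULL
  half_burn <- as.integer(floor(n_burn / 2))
  make_L <- function(rows) {
    S <- stats::cov(burn_store[rows, , drop = FALSE])
    S <- S + diag(1e-12 + 1e-6 * diag(S), np)
    tryCatch(t(chol((2.38^2 / np) * S)), error = function(e) NULL)
  }

  for (it in seq_len(n_iter)) {
    for (j in free) {
      cand <- theta
      cand[j] <- theta[[j]] + stats::rnorm(1, 0, scales[[j]])
      lp_cand <- log_post(cand, sigma)
      if (stats::runif(1) < mh_acceptance_prob(lp_cand, lp_cur)) {
        theta <- cand; lp_cur <- lp_cand
        if (it > n_burn) acc[j] <- acc[j] + 1
        acc_win[j] <- acc_win[j] + 1
      }
    }
    if (!is.null(joint_L)) {
      cand <- theta
      cand[free] <- theta[free] + as.vector(joint_L %*% stats::rnorm(np))
      lp_cand <- log_post(cand, sigma)
      if (stats::runif(1) < mh_acceptance_prob(lp_cand, lp_cur)) {
        theta <- cand; lp_cur <- lp_cand
      }
    }
    if (est_sigma) {
      sig_cand <- sigma + stats::rnorm(1, 0, sig_scale)
      lp_cand <- log_post(theta, sig_cand)
      if (stats::runif(1) < mh_acceptance_prob(lp_cand, lp_cur)) {
        sigma <- sig_cand; lp_cur <- lp_cand
        if (it > n_burn) sig_acc <- sig_acc + 1
        sig_acc_win <- sig_acc_win + 1
      }
    }
    # proposal-scale adaptation, burn-in only
    if (it <= n_burn && it %% control$adapt_interval == 0L) {
      rate <- acc_win / control$adapt_interval
      lo <- control$target_accept[1]; hi <- control$target_accept[2]
      scales[free][rate < lo] <- scales[free][rate < lo] * 0.7
      scales[free][rate > hi] <- scales[free][rate > hi] * 1.4
      acc_win[] <- 0
      if (est_sigma) {
        r <- sig_acc_win / control$adapt_interval
        if (r < lo) sig_scale <- sig_scale * 0.7
        if (r > hi) sig_scale <- sig_scale * 1.4
        sig_acc_win <- 0
      }
    }
    if (!is.null(burn_store) && it <= n_burn) {
      burn_store[it, ] <- theta[free]
      if (it == half_burn && half_burn >= 50L)
        joint_L <- make_L(seq.int(max(1L, half_burn %/% 2), half_burn))
      if (it == n_burn && n_burn >= 100L)
        joint_L <- make_L(seq.int(half_burn + 1L, n_burn))
    }
    if (it > n_burn && (it - n_burn - 1L) %% control$thin == 0L) {
      k_keep <- k_keep + 1L
      chain[k_keep, seq_along(theta)] <- theta
      if (est_sigma) chain[k_keep, "sigma"] <- sigma
    }
  }

  acc_rate <- acc / (n_iter - n_burn)
  if (np > 0L && mean(acc_rate) < 0.01)
    stop("sampler stuck: post-burn-in acceptance rate below 1%",
         call. = FALSE)

  # derived parameters, computed per retained sample
  derived <- cbind(
    repair_H = chain[, "w_SLDR"] * chain[, "repair_p"],
    alpha0p_star = chain[, "alpha0p"] / chain[, "w_SLDR"],
    beta0p_star = chain[, "beta0p"] / chain[, "w_SLDR"])
  chain <- cbind(chain, derived)

  summ <- .posterior_summary(chain)
  theta_hat <- colMeans(chain)[.PAR_NAMES]

  r2 <- c(parent = r_squared(obs_parent,
                             .line_neg_log_S(theta_hat, pred_parent, FALSE)))
  if (!is.null(pred_res))
    r2 <- c(r2, resistant = r_squared(obs_res,
                                      .line_neg_log_S(theta_hat, pred_res, TRUE)))

  structure(list(chain = chain, summary = summ, acceptance = acc_rate,
                 sigma = if (est_sigma) mean(chain[, "sigma"]) else sigma,
                 estimate_sigma = est_sigma,
                 r_squared = r2, theta_hat = theta_hat,
                 data = list(parent = parent_data, resistant = resistant_data),
                 priors = priors, ctx = ctx, protocols = protocols,
                 control = control, seed = seed, fixed = fixed,
                 call = match.call()),
            class = "imk_fit")
}

# Mean, SD, central quantiles and a crude initial-sequence ESS per column.
.posterior_summary <- function(chain) {
  ess <- function(x) {
    n <- length(x)
    if (stats::sd(x) == 0) return(n)
    rho <- stats::acf(x, lag.max = min(200L, n - 1L), plot = FALSE,
                      demean = TRUE)$acf[-1]
    neg <- which(rho < 0)
    if (length(neg)) rho <- rho[seq_len(neg[1] - 1L)]
    max(1, n / (1 + 2 * sum(rho)))
  }
  data.frame(
    parameter = colnames(chain),
    mean = colMeans(chain),
    sd = apply(chain, 2, stats::sd),
    q2.5 = apply(chain, 2, stats::quantile, 0.025),
    q50 = apply(chain, 2, stats::quantile, 0.5),
    q97.5 = apply(chain, 2, stats::quantile, 0.975),
    ess = apply(chain, 2, ess),
    row.names = NULL)
}

#' @export
print.imk_fit <- function(x, ...) {
  cat("Two-population IMK survival model fit (random-walk Metropolis)\n")
  cat(sprintf("  lines: %s%s\n",
              x$data$parent$cell_line[1],
              if (!is.null(x$data$resistant))
                paste0(" + ", x$data$resistant$cell_line[1]) else ""))
  cat(sprintf("  retained samples: %d, sigma = %.4g%s\n", nrow(x$chain),
              x$sigma, if (x$estimate_sigma) " (sampled)" else " (fixed)"))
  cat(sprintf("  mean acceptance rate: %.2f\n", mean(x$acceptance)))
  cat("  posterior means:\n")
  est <- x$summary[x$summary$parameter %in% .PAR_NAMES, ]
  for (i in seq_len(nrow(est)))
    cat(sprintf("    %-14s %.4g (sd %.3g)\n", est$parameter[i],
                est$mean[i], est$sd[i]))
  cat(sprintf("  R^2: %s\n",
              paste(sprintf("%s %.3f", names(x$r_squared), x$r_squared),
                    collapse = ", ")))
  invisible(x)
}

#' @export
summary.imk_fit <- function(object, ...) {
  out <- object$summary
  attr(out, "r_squared") <- object$r_squared
  attr(out, "acceptance") <- object$acceptance
  class(out) <- c("summary.imk_fit", "data.frame")
  out
}

#' @export
print.summary.imk_fit <- function(x, ...) {
  cat("Posterior summary\n")
  df <- x; class(df) <- "data.frame"
  print(df, digits = 4, row.names = FALSE)
  cat("\nR^2:",
      paste(sprintf("%s %.3f", names(attr(x, "r_squared")),
                    attr(x, "r_squared")), collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.imk_fit <- function(object, ...) colMeans(object$chain)

#' Posterior-mean model of a fitted line
#'
#' @param object An `imk_fit`.
#' @param line `"parent"` or `"resistant"`.
#' @return A [two_population_model()] built from posterior means.
#' @export
as_two_population_model <- function(object, line = c("parent", "resistant")) {
  stopifnot(inherits(object, "imk_fit"))
  line <- match.arg(line)
  th <- object$theta_hat
  two_population_model(
    progeny = population_params(th[["alpha0p"]], th[["beta0p"]],
                                th[["repair_p"]]),
    stem_alpha0 = th[["alpha0s"]], stem_beta0 = th[["beta0s"]],
    f_s = if (line == "parent") th[["f_s_parent"]] else th[["f_s_resistant"]],
    w_SLDR = max(th[["w_SLDR"]], 1), resistant = line == "resistant")
}

#' Predict surviving fractions from a fitted model
#'
#' @param object An `imk_fit`.
#' @param doses Dose grid in Gy.
#' @param line `"parent"` or `"resistant"`.
#' @param dose_rate Dose rate in Gy/min (`Inf` = acute).
#' @param ... Unused.
#' @return Data frame `dose_Gy`, `surviving_fraction`, `neg_log_S`.
#' @export
predict.imk_fit <- function(object, doses = seq(0, 10, by = 0.5),
                            line = c("parent", "resistant"),
                            dose_rate = Inf, ...) {
  line <- match.arg(line)
  model <- as_two_population_model(object, line)
  survival_curve(model, object$ctx, doses, dose_rate = dose_rate)
}

#' @export
residuals.imk_fit <- function(object, ...) {
  gamma <- gamma_coefficient(object$ctx)
  th <- object$theta_hat
  res <- list()
  pd <- object$data$parent
  pred <- .compile_design(pd, object$protocols, gamma)
  res$parent <- pd$neg_log_S - .line_neg_log_S(th, pred, FALSE)
  rd <- object$data$resistant
  if (!is.null(rd)) {
    predr <- .compile_design(rd, object$protocols, gamma)
    res$resistant <- rd$neg_log_S - .line_neg_log_S(th, predr, TRUE)
  }
  res
}

#' Posterior-predictive simulation from a fitted model
#'
#' Draws parameter vectors from the retained chain and simulates new
#' \eqn{-\ln S} observations at the fitted design points with Gaussian
#' noise of scale `sigma`.
#'
#' @param object An `imk_fit`.
#' @param nsim Number of simulated datasets.
#' @param seed Optional seed.
#' @param ... Unused.
#' @return List of `nsim` lists with elements `parent` and (if fitted)
#'   `resistant`, each a [survival_dataset()].
#' @export
simulate.imk_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  gamma <- gamma_coefficient(object$ctx)
  pd <- object$data$parent
  rd <- object$data$resistant
  pred_p <- .compile_design(pd, object$protocols, gamma)
  pred_r <- if (!is.null(rd)) .compile_design(rd, object$protocols, gamma)
  draws <- sample.int(nrow(object$chain), nsim, replace = TRUE)
  lapply(draws, function(i) {
    th <- object$chain[i, .PAR_NAMES]
    out <- list()
    mu <- .line_neg_log_S(th, pred_p, FALSE)
    out$parent <- survival_dataset(pd$cell_line, pd$dose,
      neg_log_S = pmax(mu + stats::rnorm(length(mu), 0, object$sigma), 0),
      protocol_id = pd$protocol_id, replicate = pd$replicate)
    if (!is.null(rd)) {
      mur <- .line_neg_log_S(th, pred_r, TRUE)
      out$resistant <- survival_dataset(rd$cell_line, rd$dose,
        neg_log_S = pmax(mur + stats::rnorm(length(mur), 0, object$sigma), 0),
        protocol_id = rd$protocol_id, replicate = rd$replicate)
    }
    out
  })
}

#' Plot a fitted survival curve against the data
#'
#' @param x An `imk_fit`.
#' @param doses Dose grid for the fitted curves.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.imk_fit <- function(x, doses = NULL, ...) {
  pd <- x$data$parent
  rd <- x$data$resistant
  if (is.null(doses))
    doses <- seq(0, max(pd$dose, if (!is.null(rd)) rd$dose else 0),
                 length.out = 60)
  cp <- predict(x, doses, "parent")
  graphics::plot(pd$dose, exp(-pd$neg_log_S), log = "y", col = "blue",
                 xlab = "Dose (Gy)", ylab = "Surviving fraction",
                 ylim = range(c(exp(-pd$neg_log_S),
                                if (!is.null(rd)) exp(-rd$neg_log_S),
                                cp$surviving_fraction)), ...)
  graphics::lines(cp$dose_Gy, cp$surviving_fraction, col = "blue")
  if (!is.null(rd)) {
    cr <- predict(x, doses, "resistant")
    graphics::points(rd$dose, exp(-rd$neg_log_S), col = "red", pch = 2)
    graphics::lines(cr$dose_Gy, cr$surviving_fraction, col = "red")
    graphics::legend("bottomleft",
                     legend = c(pd$cell_line[1], rd$cell_line[1]),
                     col = c("blue", "red"), pch = c(1, 2), lty = 1,
                     bty = "n")
  }
  invisible(x)
}
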