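# Survival datasets, priors, and the Gaussian likelihood on -ln S.

#' Clonogenic survival dataset
#'
#' Observed surviving fractions from a colony-formation assay, stored on
#' the \eqn{-\ln S} scale the likelihood works on.
#'
#' @param cell_line Character vector of cell-line identifiers.
#' @param dose Absorbed doses in Gy (>= 0).
#' @param surviving_fraction Observed surviving fractions in (0, 1]
#'   (after plating-efficiency normalisation). Mutually exclusive with
#'   `neg_log_S`.
#' @param neg_log_S Observed \eqn{-\ln S} values (>= 0); alternative
#'   input scale.
#' @param protocol_id Protocol identifiers (default `"acute"`).
#' @param replicate Replicate identifiers.
#' @return Object of class `survival_dataset` (a data frame with columns
#'   `cell_line`, `protocol_id`, `dose`, `neg_log_S`, `replicate`).
#' @export
survival_dataset <- function(cell_line, dose, surviving_fraction = NULL,
                             neg_log_S = NULL, protocol_id = "acute",
                             replicate = 1L) {
  if (is.null(neg_log_S) == is.null(surviving_fraction))
    stop("supply exactly one of 'surviving_fraction' or 'neg_log_S'",
         call. = FALSE)
  if (!is.null(surviving_fraction)) {
    if (any(!is.finite(surviving_fraction)) || any(surviving_fraction <= 0) ||
        any(surviving_fraction > 1))
      stop("surviving fractions must lie in (0, 1]", call. = FALSE)
    neg_log_S <- -log(surviving_fraction)
  }
  if (any(!is.finite(neg_log_S)) || any(neg_log_S < 0))
    stop("'neg_log_S' must be finite and >= 0", call. = FALSE)
  if (any(!is.finite(dose)) || any(dose < 0))
    stop("doses must be finite and >= 0", call. = FALSE)
  n <- length(dose)
  out <- data.frame(cell_line = rep_len(as.character(cell_line), n),
                    protocol_id = rep_len(as.character(protocol_id), n),
                    dose = dose,
                    neg_log_S = neg_log_S,
                    replicate = rep_len(replicate, n))
  class(out) <- c("survival_dataset", "data.frame")
  out
}

#' Prior specification for the joint two-population fit
#'
#' Uniform priors on the LQ coefficients and on the repair-enhancement
#' ratio; a normal prior on the parental SLDR rate (typically carried
#' over from the split-dose analysis), truncated at 0; truncated-normal
#' priors on the two stem-like fractions (typically the flow-cytometry
#' mean +/- SD), truncated to [0, 1]. A parameter whose prior SD is 0 (or
#' whose bounds coincide) is held fixed at that value during sampling.
#'
#' @param alpha_bounds,beta_bounds Uniform bounds for \eqn{\alpha_{0p}},
#'   \eqn{\alpha_{0s}} (Gy^-1) and \eqn{\beta_{0p}}, \eqn{\beta_{0s}}
#'   (Gy^-2). The stem coefficients are additionally constrained below
#'   the progeny ones.
#' @param w_bounds Uniform bounds for \eqn{w_{SLDR}} (dimensionless,
#'   lower bound >= 1 by default; set the lower bound below 1 to relax).
#' @param repair_mean,repair_sd Normal prior on \eqn{(a+c)_p} in h^-1.
#' @param f_s_parent,f_s_resistant Length-2 vectors `c(mean, sd)` of the
#'   truncated-normal priors on the stem-like fractions.
#' @return Object of class `prior_spec`.
#' @examples
#' prior_spec(repair_mean = 1.31, repair_sd = 0.69,
#'            f_s_parent = c(0.0097, 0.0068),
#'            f_s_resistant = c(0.0965, 0.0365))
#' @export
prior_spec <- function(alpha_bounds = c(0, 1), beta_bounds = c(0, 0.5),
                       w_bounds = c(1, 5),
                       repair_mean = 1.5, repair_sd = 0.7,
                       f_s_parent = c(0.01, 0.01),
                       f_s_resistant = c(0.1, 0.05)) {
  chk2 <- function(x, nm, allow_equal = FALSE) {
    if (length(x) != 2L || any(!is.finite(x)) || (!allow_equal && x[2] < x[1]))
      stop("'", nm, "' must be a finite length-2 vector", call. = FALSE)
  }
  chk2(alpha_bounds, "alpha_bounds"); chk2(beta_bounds, "beta_bounds")
  chk2(w_bounds, "w_bounds")
  chk2(f_s_parent, "f_s_parent", TRUE); chk2(f_s_resistant, "f_s_resistant", TRUE)
  if (repair_sd < 0 || f_s_parent[2] < 0 || f_s_resistant[2] < 0)
    stop("prior SDs must be >= 0", call. = FALSE)
  structure(list(alpha_bounds = alpha_bounds, beta_bounds = beta_bounds,
                 w_bounds = w_bounds,
                 repair_mean = repair_mean, repair_sd = repair_sd,
                 f_s_parent = f_s_parent, f_s_resistant = f_s_resistant),
            class = "prior_spec")
}

# Parameter order used throughout the sampler.
.PAR_NAMES <- c("alpha0p", "beta0p", "repair_p", "alpha0s", "beta0s",
                "w_SLDR", "f_s_parent", "f_s_resistant")

# Hard support + ordering constraints of the parameter vector.
.theta_ok <- function(theta, priors) {
  all(is.finite(theta)) &&
    theta[["alpha0p"]] > priors$alpha_bounds[1] &&
    theta[["alpha0p"]] < priors$alpha_bounds[2] &&
    theta[["beta0p"]] > priors$beta_bounds[1] &&
    theta[["beta0p"]] < priors$beta_bounds[2] &&
    theta[["alpha0s"]] > priors$alpha_bounds[1] &&
    theta[["beta0s"]] > priors$beta_bounds[1] &&
    theta[["alpha0s"]] < theta[["alpha0p"]] &&
    theta[["beta0s"]] < theta[["beta0p"]] &&
    theta[["repair_p"]] > 0 &&
    theta[["w_SLDR"]] >= priors$w_bounds[1] &&
    theta[["w_SLDR"]] <= priors$w_bounds[2] &&
    theta[["f_s_parent"]] >= 0 && theta[["f_s_parent"]] <= 1 &&
    theta[["f_s_resistant"]] >= 0 && theta[["f_s_resistant"]] <= 1
}

# Log prior density (up to additive constants not depending on theta).
.log_prior <- function(theta, priors) {
  if (!.theta_ok(theta, priors)) return(-Inf)
  lp <- 0
  if (priors$repair_sd > 0)
    lp <- lp + stats::dnorm(theta[["repair_p"]], priors$repair_mean,
                            priors$repair_sd, log = TRUE)
  if (priors$f_s_parent[2] > 0)
    lp <- lp + stats::dnorm(theta[["f_s_parent"]], priors$f_s_parent[1],
                            priors$f_s_parent[2], log = TRUE)
  if (priors$f_s_resistant[2] > 0)
    lp <- lp + stats::dnorm(theta[["f_s_resistant"]], priors$f_s_resistant[1],
                            priors$f_s_resistant[2], log = TRUE)
  lp
}

# Compile a dataset + protocol table into a fast -ln S predictor.
# protocols: named list; each element is an irradiation_protocol, a list
# with dose_rate_Gy_min, or "acute". Unlisted ids are acute (T = 0).
.compile_design <- function(data, protocols, gamma) {
  n <- nrow(data)
  T <- numeric(n)
  proto <- vector("list", n)
  for (i in seq_len(n)) {
    p <- protocols[[data$protocol_id[i]]]
    if (is.null(p) || identical(p, "acute")) {
      T[i] <- 0
    } else if (inherits(p, "irradiation_protocol")) {
      d <- p$dose
      np <- nrow(p)
      cmp <- list(d = d, dur = p$duration, total = sum(d))
      if (np > 1L) {
        ends <- p$start + p$duration
        tau <- outer(p$start, ends, "-")
        keep <- lower.tri(tau)
        cmp$tauv <- tau[keep]
        cmp$ddv <- outer(d, d)[keep]
      } else {
        cmp$tauv <- numeric(0); cmp$ddv <- numeric(0)
      }
      proto[[i]] <- cmp
    } else if (is.list(p) && !is.null(p$dose_rate_Gy_min)) {
      T[i] <- data$dose[i] / p$dose_rate_Gy_min / 60
    } else {
      stop("unresolvable protocol id '", data$protocol_id[i], "'",
           call. = FALSE)
    }
  }
  simple <- vapply(proto, is.null, logical(1))
  D <- data$dose
  function(alpha, beta, k) {
    out <- numeric(n)
    if (any(simple)) {
      Ds <- D[simple]
      out[simple] <- (alpha + gamma * beta) * Ds +
        lea_catcheside_factor(k, T[simple]) * beta * Ds^2
    }
    for (i in which(!simple)) {
      cmp <- proto[[i]]
      out[i] <- (alpha + gamma * beta) * cmp$total +
        beta * sum(lea_catcheside_factor(k, cmp$dur) * cmp$d^2) +
        2 * beta * sum(exp(-k * cmp$tauv) * cmp$ddv)
    }
    out
  }
}

# Mixture -ln S for one line given theta; pred is a compiled predictor.
.line_neg_log_S <- function(theta, pred, resistant) {
  w <- theta[["w_SLDR"]]
  if (resistant) {
    lp <- pred(theta[["alpha0p"]] / w, theta[["beta0p"]] / w,
               w * theta[["repair_p"]])
    fs <- theta[["f_s_resistant"]]
  } else {
    lp <- pred(theta[["alpha0p"]], theta[["beta0p"]], theta[["repair_p"]])
    fs <- theta[["f_s_parent"]]
  }
  ls <- pred(theta[["alpha0s"]], theta[["beta0s"]], w * theta[["repair_p"]])
  -log((1 - fs) * exp(-lp) + fs * exp(-ls))
}

#' Gaussian log-likelihood of survival data
#'
#' The likelihood compares observed and model \eqn{-\ln S} record by
#' record with independent Gaussian errors of scale `sigma`:
#' \deqn{\log P(d \mid \theta) = \sum_{i=1}^N \log
#'   \mathcal{N}(-\ln S_{\mathrm{exp},i};\ -\ln S_{\mathrm{cal},i},
#'   \sigma^2),}
#' with the standard normalisation \eqn{1/(\sigma\sqrt{2\pi})}. A
#' parameter vector violating the support or ordering constraints
#' (stem-like coefficients must be smaller than progeny ones) yields
#' `-Inf` rather than an error, so the sampler simply rejects it.
#'
#' @param data A [survival_dataset()].
#' @param theta Named numeric vector with elements `alpha0p`, `beta0p`,
#'   `repair_p`, `alpha0s`, `beta0s`, `w_SLDR`, `f_s_parent`,
#'   `f_s_resistant`.
#' @param sigma Residual SD on the \eqn{-\ln S} scale (> 0).
#' @param ctx A [microdosimetric_context()].
#' @param protocols Named list resolving the dataset's `protocol_id`
#'   values (see Details of [imk_fit()]); unlisted ids mean acute delivery.
#' @param resistant Logical: is this the radioresistant line of the
#'   family?
#' @param priors A [prior_spec()] supplying the support bounds used for
#'   the constraint check.
#' @return The summed log-density (scalar; `-Inf` on constraint
#'   violation).
#' @export
log_likelihood <- function(data, theta, sigma, ctx = microdosimetric_context(),
                           protocols = list(), resistant = FALSE,
                           priors = prior_spec()) {
  stopifnot(inherits(data, "survival_dataset"), sigma > 0)
  theta <- theta[.PAR_NAMES]
  if (!.theta_ok(theta, priors)) return(-Inf)
  pred <- .compile_design(data, protocols, gamma_coefficient(ctx))
  cal <- .line_neg_log_S(theta, pred, resistant)
  sum(stats::dnorm(data$neg_log_S, cal, sigma, log = TRUE))
}

#' Metropolis acceptance probability
#'
#' For a symmetric proposal the acceptance probability is the posterior
#' ratio \eqn{P(\theta^{cand}\mid d) / P(\theta^{(t)}\mid d)}, capped at
#' 1, computed in log space for stability. If both densities are
#' degenerate (`-Inf`) the move is rejected.
#'
#' @param log_post_candidate,log_post_current Log posterior densities.
#' @return Acceptance probability in [0, 1].
#' @export
mh_acceptance_prob <- function(log_post_candidate, log_post_current) {
  if (!is.finite(log_post_candidate)) return(0)
  if (!is.finite(log_post_current)) return(1)
  exp(min(0, log_post_candidate - log_post_current))
}

#' Coefficient of determination on the -ln S scale
#'
#' \eqn{R^2 = 1 - SS_{res}/SS_{tot}} between observed and model
#' \eqn{-\ln S} values.
#'
#' @param observed,predicted Numeric vectors of equal length (>= 2).
#' @return A scalar <= 1.
#' @export
r_squared <- function(observed, predicted) {
  if (length(observed) != length(predicted) || length(observed) < 2L)
    stop("'observed' and 'predicted' must have equal length >= 2",
         call. = FALSE)
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0)
    stop("R^2 undefined: observed values have zero variance", call. = FALSE)
  1 - sum((observed - predicted)^2) / ss_tot
}
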