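# Synthetic clonogenic-assay data with the statistical structure the
# likelihood assumes: Gaussian noise on -ln S, seeded and reproducible.
#
# Seed policy: every generator takes one integer seed. Composite
# generators (a family of two lines, a full experiment bundle) derive
# per-component sub-seeds as seed + fixed small offsets, so regenerating
# one component in isolation reproduces it exactly.

#' Reference parameter sets for the SAS and HSC2 cell-line families
#'
#' Convenience constructors returning the fitted two-population parameter
#' sets of the SAS family (`sas_family_parameters()`) and the HSC2 family
#' (`hsc2_family_parameters()`) of human oral squamous carcinoma lines:
#' parental progeny LQ coefficients and SLDR rate, stem-like LQ
#' coefficients, the repair-enhancement ratio of the radioresistant line,
#' and the two stem-like fractions. These are the default "truth" of the
#' synthetic-data generators.
#'
#' @return Named list with elements `alpha0p`, `beta0p`, `repair_p`,
#'   `alpha0s`, `beta0s`, `w_SLDR`, `f_s_parent`, `f_s_resistant`, and
#'   the line labels `parent_name`, `resistant_name`.
#' @export
sas_family_parameters <- function() {
  list(alpha0p = 0.208, beta0p = 0.044, repair_p = 1.279,
       alpha0s = 0.074, beta0s = 0.027, w_SLDR = 1.059,
       f_s_parent = 0.012, f_s_resistant = 0.083,
       parent_name = "SAS", resistant_name = "SAS-R")
}

#' @rdname sas_family_parameters
#' @export
hsc2_family_parameters <- function() {
  list(alpha0p = 0.166, beta0p = 0.168, repair_p = 1.499,
       alpha0s = 0.194, beta0s = 0.019, w_SLDR = 1.896,
       f_s_parent = 0.014, f_s_resistant = 0.127,
       parent_name = "HSC2", resistant_name = "HSC2-R")
}

# family parameter list -> the two line models
.family_models <- function(truth) {
  progeny <- population_params(truth$alpha0p, truth$beta0p, truth$repair_p)
  list(
    parent = two_population_model(progeny, truth$alpha0s, truth$beta0s,
                                  f_s = truth$f_s_parent,
                                  w_SLDR = max(truth$w_SLDR, 1),
                                  resistant = FALSE),
    resistant = two_population_model(progeny, truth$alpha0s, truth$beta0s,
                                     f_s = truth$f_s_resistant,
                                     w_SLDR = max(truth$w_SLDR, 1),
                                     resistant = TRUE))
}

#' Simulate a clonogenic survival dataset
#'
#' For every dose x replicate the observed lethal-lesion burden is the
#' model value plus Gaussian noise, \eqn{-\ln S_{obs} = -\ln S_{model} +
#' \epsilon}, \eqn{\epsilon \sim N(0, \sigma^2)} — the error model the
#' Gaussian likelihood assumes. Negative draws are truncated at 0 (a
#' surviving fraction cannot exceed 1).
#'
#' @param model A [two_population_model()].
#' @param ctx A [microdosimetric_context()].
#' @param doses Dose grid in Gy (default the acute experimental grid
#'   0-10 Gy in 2-Gy steps).
#' @param dose_rate Delivery dose rate in Gy/min (default 1.0, the acute
#'   beam rate; use `Inf` for instantaneous delivery).
#' @param replicates Replicates per dose point (default 3).
#' @param sigma Noise SD on \eqn{-\ln S} (default 0.1).
#' @param cell_line Line label recorded in the dataset.
#' @param protocol_id Protocol label recorded in the dataset.
#' @param colony_counts If `TRUE`, layer Poisson colony-count noise on
#'   top instead of (or, with `sigma > 0`, in addition to) the Gaussian
#'   noise: colonies ~ Poisson(cells_seeded x plating_efficiency x S),
#'   and the observed surviving fraction is the count ratio. Zero counts
#'   are replaced by 0.5 (continuity correction) to stay in the log
#'   domain. Off by default, which matches the likelihood's error model.
#' @param cells_seeded,plating_efficiency Colony-assay design used when
#'   `colony_counts = TRUE`; `cells_seeded` is recycled over doses (in
#'   practice more cells are seeded at higher doses).
#' @param seed Optional integer seed.
#' @return A [survival_dataset()] with attribute `truth` recording the
#'   generating model and settings.
#' @export
simulate_survival_dataset <- function(model, ctx = microdosimetric_context(),
                                      doses = seq(0, 10, by = 2),
                                      dose_rate = 1.0, replicates = 3L,
                                      sigma = 0.1, cell_line = "synthetic",
                                      protocol_id = "acute",
                                      colony_counts = FALSE,
                                      cells_seeded = 200,
                                      plating_efficiency = 0.7,
                                      seed = NULL) {
  stopifnot(replicates >= 1L, sigma >= 0)
  if (!is.null(seed)) set.seed(seed)
  curve <- survival_curve(model, ctx, doses, dose_rate = dose_rate)
  D <- rep(doses, each = replicates)
  mu <- rep(curve$neg_log_S, each = replicates)
  obs <- pmax(mu + stats::rnorm(length(mu), 0, sigma), 0)
  if (colony_counts) {
    cells <- rep(rep_len(cells_seeded, length(doses)), each = replicates)
    expected <- cells * plating_efficiency * exp(-obs)
    counts <- stats::rpois(length(expected), expected)
    counts[counts == 0L] <- 0.5
    obs <- pmax(-log(counts / (cells * plating_efficiency)), 0)
  }
  out <- survival_dataset(cell_line = cell_line, dose = D, neg_log_S = obs,
                          protocol_id = protocol_id,
                          replicate = rep(seq_len(replicates),
                                          times = length(doses)))
  attr(out, "truth") <- list(model = model, sigma = sigma,
                             dose_rate = dose_rate, seed = seed)
  out
}

#' Simulate both lines of a cell-line family
#'
#' Generates parental and radioresistant acute dose-response datasets
#' from one family parameter set (default: the SAS family), with
#' sub-seeds `seed + 1` and `seed + 2` for the two lines.
#'
#' @param truth Family parameter list (see [sas_family_parameters()]).
#' @param ctx A [microdosimetric_context()].
#' @param doses,dose_rate,replicates,sigma As in
#'   [simulate_survival_dataset()].
#' @param seed Integer seed for the pair.
#' @return List with `parent` and `resistant` [survival_dataset()]s and
#'   `truth`.
#' @export
simulate_family_datasets <- function(truth = sas_family_parameters(),
                                     ctx = microdosimetric_context(),
                                     doses = seq(0, 10, by = 2),
                                     dose_rate = 1.0, replicates = 3L,
                                     sigma = 0.1, seed = NULL) {
  models <- .family_models(truth)
  list(
    parent = simulate_survival_dataset(models$parent, ctx, doses, dose_rate,
                                       replicates, sigma,
                                       cell_line = truth$parent_name,
                                       seed = if (!is.null(seed)) seed + 1L),
    resistant = simulate_survival_dataset(models$resistant, ctx, doses,
                                          dose_rate, replicates, sigma,
                                          cell_line = truth$resistant_name,
                                          seed = if (!is.null(seed)) seed + 2L),
    truth = truth)
}

#' Simulate a split-dose recovery curve
#'
#' Split-dose survival (two acute fractions) over a grid of
#' inter-fraction intervals, with Gaussian noise on \eqn{-\ln S}.
#' The default interval grid spans the experimental design: 0-24 h with
#' dense early sampling where recovery is fastest.
#'
#' @param pop [population_params()] of the recovering population.
#' @param gamma Per-domain dose coefficient, Gy.
#' @param D1,D2 Fraction doses in Gy (default 2 + 2 Gy).
#' @param intervals Inter-fraction intervals in h.
#' @param sigma Noise SD on \eqn{-\ln S}.
#' @param replicates Replicates per interval.
#' @param seed Optional integer seed.
#' @return A [recovery_curve()] with attribute `truth`.
#' @export
simulate_recovery_curve <- function(pop, gamma = 0.954, D1 = 2, D2 = 2,
                                    intervals = c(0, 0.5, 1, 2, 3, 6, 12, 24),
                                    sigma = 0, replicates = 1L, seed = NULL) {
  stopifnot(replicates >= 1L, sigma >= 0)
  if (!is.null(seed)) set.seed(seed)
  tau <- rep(intervals, each = replicates)
  mu <- neg_log_survival_split(pop, gamma, D1, D2, tau)
  obs <- pmax(mu + stats::rnorm(length(mu), 0, sigma), 0)
  out <- recovery_curve(tau, exp(-obs),
                        replicate = rep(seq_len(replicates),
                                        times = length(intervals)),
                        D1 = D1, D2 = D2)
  attr(out, "truth") <- list(pop = pop, gamma = gamma, sigma = sigma,
                             seed = seed)
  out
}

#' Simulate flow-cytometry estimates of the stem-like fraction
#'
#' Emulates repeated ALDH-positivity measurements: `n_experiments`
#' truncated-normal draws in [0, 1] around the true fraction, summarised
#' as mean and SD for use as a [prior_spec()] input.
#'
#' @param f_s_true True stem-like fraction in [0, 1].
#' @param sd Measurement SD on the fraction scale.
#' @param n_experiments Number of repeat experiments (>= 2, unless
#'   `sd = 0`).
#' @param seed Optional integer seed.
#' @return List with `mean`, `sd`, `n`, and the raw `draws`.
#' @export
simulate_flow_cytometry <- function(f_s_true, sd = 0.005,
                                    n_experiments = 3L, seed = NULL) {
  stopifnot(f_s_true >= 0, f_s_true <= 1, sd >= 0, n_experiments >= 1L)
  if (!is.null(seed)) set.seed(seed)
  if (sd == 0) {
    draws <- rep(f_s_true, n_experiments)
  } else {
    draws <- numeric(n_experiments)
    for (i in seq_len(n_experiments)) {
      repeat {
        x <- stats::rnorm(1, f_s_true, sd)
        if (x >= 0 && x <= 1) break
      }
      draws[i] <- x
    }
  }
  list(mean = mean(draws), sd = stats::sd(draws), n = n_experiments,
       draws = draws)
}

#' Simulate a complete experiment bundle for one family
#'
#' Everything the full analysis pipeline consumes, generated from one
#' seed: acute dose-response datasets for both lines, a split-dose
#' recovery curve of the parental line (2 Gy + 2 Gy), and flow-cytometry
#' summaries of both stem-like fractions. Sub-seeds are `seed + 1..5`
#' per component.
#'
#' @param truth Family parameter list (see [sas_family_parameters()]).
#' @param ctx A [microdosimetric_context()].
#' @param sigma Noise SD on \eqn{-\ln S}.
#' @param replicates Replicates per design point.
#' @param flow_sd Flow-cytometry measurement SD; defaults to half the
#'   true fraction, matching the relative spread of the reported
#'   ALDH-positive measurements.
#' @param seed Integer seed.
#' @return List with `parent`, `resistant`, `recovery`, `flow_parent`,
#'   `flow_resistant`, `truth`, `seed`.
#' @export
simulate_experiment_bundle <- function(truth = sas_family_parameters(),
                                       ctx = microdosimetric_context(),
                                       sigma = 0.1, replicates = 3L,
                                       flow_sd = NULL, seed = 1L) {
  fam <- simulate_family_datasets(truth, ctx, sigma = sigma,
                                  replicates = replicates, seed = seed)
  gamma <- gamma_coefficient(ctx)
  progeny <- population_params(truth$alpha0p, truth$beta0p, truth$repair_p)
  recovery <- simulate_recovery_curve(progeny, gamma, sigma = sigma,
                                      replicates = replicates,
                                      seed = seed + 3L)
  if (is.null(flow_sd)) flow_sd <- pmax(c(truth$f_s_parent,
                                          truth$f_s_resistant) / 2, 1e-3)
  flow_sd <- rep_len(flow_sd, 2L)
  list(parent = fam$parent, resistant = fam$resistant, recovery = recovery,
       flow_parent = simulate_flow_cytometry(truth$f_s_parent, flow_sd[1],
                                             seed = seed + 4L),
       flow_resistant = simulate_flow_cytometry(truth$f_s_resistant,
                                                flow_sd[2], seed = seed + 5L),
       truth = truth, seed = seed)
}
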