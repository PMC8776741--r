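# Readers, writers and the end-to-end analysis driver.
#
# CSV dialect throughout: comma-separated, UTF-8, dot decimal, header
# mandatory.

#' Read a clonogenic survival CSV
#'
#' Expected header: `cell_line, protocol_id, dose_Gy, surviving_fraction,
#' replicate` (`protocol_id` and `replicate` optional). Surviving
#' fractions are converted to \eqn{-\ln S}; rows with `S <= 0` or
#' `S > 1` are rejected with their row numbers.
#'
#' @param path Path to the CSV file.
#' @return A [survival_dataset()].
#' @export
read_survival_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("cell_line", "dose_Gy", "surviving_fraction")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("survival CSV format error, missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  bad <- which(!is.finite(df$surviving_fraction) |
                 df$surviving_fraction <= 0 | df$surviving_fraction > 1)
  if (length(bad))
    stop("survival CSV: surviving_fraction outside (0, 1] in row(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  survival_dataset(
    cell_line = df$cell_line,
    dose = df$dose_Gy,
    surviving_fraction = df$surviving_fraction,
    protocol_id = if ("protocol_id" %in% names(df)) df$protocol_id else "acute",
    replicate = if ("replicate" %in% names(df)) df$replicate else 1L)
}

#' Write a survival dataset to CSV
#' @param data A [survival_dataset()].
#' @param path Output path.
#' @export
write_survival_csv <- function(data, path) {
  stopifnot(inherits(data, "survival_dataset"))
  out <- data.frame(cell_line = data$cell_line,
                    protocol_id = data$protocol_id,
                    dose_Gy = data$dose,
                    surviving_fraction = exp(-data$neg_log_S),
                    replicate = data$replicate)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a split-dose recovery CSV
#'
#' Expected header: `interval_h, surviving_fraction, replicate`
#' (`replicate` optional). The split doses default to 2 + 2 Gy unless
#' given.
#'
#' @param path Path to the CSV file.
#' @param D1,D2 Split doses in Gy.
#' @return A [recovery_curve()].
#' @export
read_recovery_csv <- function(path, D1 = 2, D2 = 2) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("interval_h", "surviving_fraction")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("recovery CSV format error, missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  recovery_curve(df$interval_h, df$surviving_fraction,
                 replicate = if ("replicate" %in% names(df)) df$replicate
                             else 1L,
                 D1 = D1, D2 = D2)
}

#' Write a recovery curve to CSV
#' @param curve A [recovery_curve()].
#' @param path Output path.
#' @export
write_recovery_csv <- function(curve, path) {
  stopifnot(inherits(curve, "recovery_curve"))
  out <- data.frame(interval_h = curve$tau,
                    surviving_fraction = curve$S,
                    replicate = curve$replicate)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a predicted survival curve to CSV
#'
#' Header: `dose_Gy, surviving_fraction, neg_log_S`.
#'
#' @param curve Data frame from [survival_curve()] or
#'   [predict.imk_fit()].
#' @param path Output path.
#' @export
write_curve_csv <- function(curve, path) {
  stopifnot(all(c("dose_Gy", "surviving_fraction", "neg_log_S") %in%
                  names(curve)))
  utils::write.csv(curve, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialise a two-population model (with context) to JSON
#'
#' Schema: `microdosimetry {y_D_keV_um, rho_g_cm3, r_d_um}`,
#' `populations {progeny {alpha0, beta0, repair_rate_h}, stem {...}}`,
#' `f_s`, `w_SLDR`, `resistant`.
#'
#' @param model A [two_population_model()].
#' @param ctx A [microdosimetric_context()].
#' @param path Output path.
#' @export
write_model_json <- function(model, ctx, path) {
  stopifnot(inherits(model, "two_population_model"))
  obj <- list(
    microdosimetry = list(y_D_keV_um = ctx$y_D, rho_g_cm3 = ctx$rho,
                          r_d_um = ctx$r_d),
    populations = list(
      progeny = list(alpha0 = model$parent_progeny$alpha0,
                     beta0 = model$parent_progeny$beta0,
                     repair_rate_h = model$parent_progeny$repair_rate),
      stem = list(alpha0 = model$stem$alpha0, beta0 = model$stem$beta0,
                  repair_rate_h = model$stem$repair_rate)),
    f_s = model$f_s, w_SLDR = model$w_SLDR, resistant = model$resistant)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a two-population model (with context) from JSON
#' @param path Path written by [write_model_json()].
#' @return List with elements `model` and `ctx`.
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  ctx <- microdosimetric_context(obj$microdosimetry$y_D_keV_um,
                                 obj$microdosimetry$rho_g_cm3,
                                 obj$microdosimetry$r_d_um)
  prog <- obj$populations$progeny
  model <- two_population_model(
    population_params(prog$alpha0, prog$beta0, prog$repair_rate_h),
    stem_alpha0 = obj$populations$stem$alpha0,
    stem_beta0 = obj$populations$stem$beta0,
    f_s = obj$f_s, w_SLDR = obj$w_SLDR,
    resistant = isTRUE(obj$resistant))
  list(model = model, ctx = ctx)
}

#' Run the full two-stage analysis
#'
#' Reproduces the analysis workflow end to end: (i) estimate the
#' parental SLDR rate from the split-dose recovery curve and use it as
#' the normal prior on \eqn{(a+c)_p}; (ii) jointly fit the parental and
#' radioresistant dose-response data by MCMC with flow-cytometry-derived
#' priors on the stem-like fractions; then write the posterior summary,
#' the retained chain, and fitted acute/split/dose-rate prediction
#' curves.
#'
#' @param config Named list (or path to a JSON file) with entries:
#'   \describe{
#'     \item{parent_csv, resistant_csv}{survival CSV paths (resistant
#'       optional).}
#'     \item{recovery_csv}{split-dose recovery CSV path; optional if
#'       `repair_prior` is given, in which case stage (i) is skipped.}
#'     \item{repair_prior}{`c(mean, sd)` normal prior on \eqn{(a+c)_p},
#'       used when `recovery_csv` is absent.}
#'     \item{flow_parent, flow_resistant}{`c(mean, sd)` stem-fraction
#'       priors.}
#'     \item{sigma}{residual SD on \eqn{-\ln S} (optional; default
#'       pooled replicate SD).}
#'     \item{y_D, rho, r_d}{microdosimetric constants (optional).}
#'     \item{n_iter, burn_frac, thin}{sampler settings (optional).}
#'     \item{seed}{integer seed (required).}
#'     \item{out_dir}{output directory.}
#'   }
#' @return Invisibly, a list with `sldr` (stage-i result or `NULL`),
#'   `fit` (the [imk_fit()]), and the written file paths.
#' @export
run_full_analysis <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  stopifnot(is.list(config), !is.null(config$parent_csv),
            !is.null(config$out_dir), !is.null(config$seed))
  seed <- as.integer(config$seed)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  ctx <- microdosimetric_context(
    y_D = config$y_D %||% 4.68,
    rho = config$rho %||% 1.0,
    r_d = config$r_d %||% 0.5)

  # stage (i): SLDR rate from the split-dose recovery curve
  sldr <- NULL
  if (!is.null(config$recovery_csv)) {
    curve <- read_recovery_csv(config$recovery_csv)
    sldr <- estimate_sldr_rate(curve, n_boot = config$n_boot %||% 1000L,
                               seed = seed + 10L)
    repair_prior <- c(sldr$rate_h,
                      if (is.finite(sldr$rate_sd)) sldr$rate_sd
                      else 0.5 * sldr$rate_h)
  } else if (!is.null(config$repair_prior)) {
    repair_prior <- as.numeric(config$repair_prior)
  } else {
    stop("config needs either 'recovery_csv' or 'repair_prior'",
         call. = FALSE)
  }

  parent <- read_survival_csv(config$parent_csv)
  resistant <- if (!is.null(config$resistant_csv))
    read_survival_csv(config$resistant_csv)

  priors <- prior_spec(
    repair_mean = repair_prior[1], repair_sd = repair_prior[2],
    f_s_parent = as.numeric(config$flow_parent %||% c(0.01, 0.01)),
    f_s_resistant = as.numeric(config$flow_resistant %||% c(0.1, 0.05)))

  control <- imk_control(
    n_iter = config$n_iter %||% 50000L,
    burn_frac = config$burn_frac %||% 0.2,
    thin = config$thin %||% 1L)

  # stage (ii): joint MCMC fit of the family
  fit <- imk_fit(parent, resistant, priors = priors, ctx = ctx,
                 sigma = config$sigma, control = control, seed = seed)

  paths <- list(
    summary = file.path(config$out_dir, "posterior_summary.json"),
    chain = file.path(config$out_dir, "chain.csv"),
    curve_parent = file.path(config$out_dir, "fitted_curve_parent.csv"))

  summ <- list(seed = seed,
               sigma = fit$sigma,
               sldr_stage = if (!is.null(sldr))
                 list(rate_h = sldr$rate_h, rate_sd = sldr$rate_sd,
                      S0 = sldr$S0, S_inf = sldr$S_inf,
                      initial_slope = sldr$initial_slope),
               posterior = stats::setNames(
                 lapply(seq_len(nrow(fit$summary)), function(i)
                   list(mean = fit$summary$mean[i], sd = fit$summary$sd[i])),
                 fit$summary$parameter),
               r_squared = as.list(fit$r_squared))
  jsonlite::write_json(summ, paths$summary, auto_unbox = TRUE, digits = 10)

  utils::write.csv(as.data.frame(fit$chain), paths$chain, row.names = FALSE)

  doses <- seq(0, max(parent$dose), length.out = 31)
  write_curve_csv(predict(fit, doses, "parent"), paths$curve_parent)
  if (!is.null(resistant)) {
    paths$curve_resistant <- file.path(config$out_dir,
                                       "fitted_curve_resistant.csv")
    write_curve_csv(predict(fit, doses, "resistant"), paths$curve_resistant)
  }

  invisible(list(sldr = sldr, fit = fit, paths = paths))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
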