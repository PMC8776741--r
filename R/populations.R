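# Cell-population parameter containers and the repair-enhancement map.

#' Linear-quadratic parameters of one cell sub-population
#'
#' Holds the radiosensitivity parameters of a single cell population in the
#' microdosimetric-kinetic survival model: the first-order lethality
#' coefficient \eqn{\alpha_0} (Gy^-1), the second-order coefficient
#' \eqn{\beta_0} (Gy^-2), and the sub-lethal damage repair (SLDR) rate
#' \eqn{(a+c)} (h^-1) that governs recovery between and during dose
#' fractions.
#'
#' @param alpha0 First-order lethality coefficient, Gy^-1 (>= 0).
#' @param beta0 Second-order lethality coefficient, Gy^-2 (>= 0).
#' @param repair_rate SLDR rate \eqn{(a+c)}, h^-1 (> 0).
#' @return An object of class `population_params`.
#' @examples
#' sas_progeny <- population_params(0.208, 0.044, 1.279)
#' @export
population_params <- function(alpha0, beta0, repair_rate) {
  if (!is.numeric(alpha0) || length(alpha0) != 1L || !is.finite(alpha0) || alpha0 < 0)
    stop("'alpha0' must be a single non-negative number", call. = FALSE)
  if (!is.numeric(beta0) || length(beta0) != 1L || !is.finite(beta0) || beta0 < 0)
    stop("'beta0' must be a single non-negative number", call. = FALSE)
  if (!is.numeric(repair_rate) || length(repair_rate) != 1L ||
      !is.finite(repair_rate) || repair_rate <= 0)
    stop("'repair_rate' must be a single strictly positive number", call. = FALSE)
  structure(list(alpha0 = alpha0, beta0 = beta0, repair_rate = repair_rate),
            class = "population_params")
}

#' @export
print.population_params <- function(x, ...) {
  cat(sprintf(
    "Population parameters: alpha0 = %g Gy^-1, beta0 = %g Gy^-2, (a+c) = %g h^-1\n",
    x$alpha0, x$beta0, x$repair_rate))
  invisible(x)
}

#' Progeny parameters of a radioresistant line
#'
#' Radioresistant lines retain the stem-like compartment of their parental
#' line but their progeny cells acquire an enhanced SLDR rate. Scaling the
#' parental repair rate by the enhancement ratio \eqn{w_{SLDR}} modulates
#' the whole progeny parameter set, because \eqn{\alpha_0} and
#' \eqn{\beta_0} are inversely proportional to \eqn{(a+c)}:
#' \deqn{\alpha_0^* = \alpha_0 / w, \quad \beta_0^* = \beta_0 / w, \quad
#'       (a+c)^* = w \, (a+c).}
#' With \eqn{w = 1} the parental parameters are returned unchanged
#' (the non-radioresistant case).
#'
#' @param parent [population_params()] of the parental (non-resistant)
#'   progeny population.
#' @param w_SLDR Dimensionless repair-enhancement ratio (> 0; fitted values
#'   are >= 1).
#' @return A [population_params()] for the resistant progeny population.
#' @examples
#' hsc2 <- population_params(0.166, 0.168, 1.499)
#' derive_resistant_progeny(hsc2, 1.896)  # HSC2-R progeny
#' @export
derive_resistant_progeny <- function(parent, w_SLDR) {
  stopifnot(inherits(parent, "population_params"))
  if (!is.numeric(w_SLDR) || length(w_SLDR) != 1L || !is.finite(w_SLDR) ||
      w_SLDR <= 0)
    stop("'w_SLDR' must be a single strictly positive number", call. = FALSE)
  population_params(parent$alpha0 / w_SLDR,
                    parent$beta0 / w_SLDR,
                    w_SLDR * parent$repair_rate)
}

#' Two-population cell-line model
#'
#' A cell line is modelled as a mixture of progeny cells (fraction
#' \eqn{1 - f_s}) and cancer stem-like cells (fraction \eqn{f_s}). The
#' stem compartment's SLDR rate is structurally tied to the parental
#' progeny rate through the enhancement ratio:
#' \eqn{(a+c)_H = w_{SLDR} (a+c)_p}. It is always derived, never stored,
#' so the parameter state cannot become inconsistent.
#'
#' @param progeny [population_params()] of the parental progeny population
#'   (\eqn{\alpha_{0p}, \beta_{0p}, (a+c)_p}).
#' @param stem_alpha0,stem_beta0 LQ coefficients of the stem-like
#'   population (typically smaller than the progeny values).
#' @param f_s Stem-like fraction in [0, 1].
#' @param w_SLDR Repair-enhancement ratio (>= 1); 1 for a non-resistant
#'   line.
#' @param resistant Logical; if `TRUE` the line's progeny cells carry the
#'   enhanced repair rate (their parameters are derived via
#'   [derive_resistant_progeny()]); if `FALSE` they are the parental
#'   progeny parameters as given.
#' @return An object of class `two_population_model` with elements
#'   `progeny` (effective progeny parameters for this line), `stem`
#'   (stem-like parameters with repair rate \eqn{w (a+c)_p}), `f_s`,
#'   `w_SLDR`, `resistant`, and `parent_progeny` (the unscaled parental
#'   set).
#' @examples
#' sas <- two_population_model(
#'   progeny = population_params(0.208, 0.044, 1.279),
#'   stem_alpha0 = 0.074, stem_beta0 = 0.027,
#'   f_s = 0.012, w_SLDR = 1.059, resistant = FALSE)
#' @export
two_population_model <- function(progeny, stem_alpha0, stem_beta0,
                                 f_s, w_SLDR = 1, resistant = FALSE) {
  stopifnot(inherits(progeny, "population_params"))
  if (!is.numeric(f_s) || length(f_s) != 1L || !is.finite(f_s) ||
      f_s < 0 || f_s > 1)
    stop("'f_s' must be a single number in [0, 1]", call. = FALSE)
  if (!is.numeric(w_SLDR) || length(w_SLDR) != 1L || !is.finite(w_SLDR) ||
      w_SLDR < 1)
    stop("'w_SLDR' must be >= 1", call. = FALSE)
  stem <- population_params(stem_alpha0, stem_beta0,
                            w_SLDR * progeny$repair_rate)
  eff_progeny <- if (resistant) derive_resistant_progeny(progeny, w_SLDR)
                 else progeny
  structure(list(progeny = eff_progeny, stem = stem, f_s = f_s,
                 w_SLDR = w_SLDR, resistant = resistant,
                 parent_progeny = progeny),
            class = "two_population_model")
}

#' @export
print.two_population_model <- function(x, ...) {
  cat(sprintf("Two-population model (%s line)\n",
              if (x$resistant) "radioresistant" else "non-resistant"))
  cat(sprintf("  progeny: alpha0 = %.4g, beta0 = %.4g, (a+c) = %.4g h^-1\n",
              x$progeny$alpha0, x$progeny$beta0, x$progeny$repair_rate))
  cat(sprintf("  stem:    alpha0 = %.4g, beta0 = %.4g, (a+c)_H = %.4g h^-1\n",
              x$stem$alpha0, x$stem$beta0, x$stem$repair_rate))
  cat(sprintf("  f_s = %.4g, w_SLDR = %.4g\n", x$f_s, x$w_SLDR))
  invisible(x)
}
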