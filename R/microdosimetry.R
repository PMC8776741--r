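# Track-structure constants and the per-domain dose coefficient.

# 1 keV in joule (CODATA exact elementary charge)
.KEV_TO_J <- 1.602176634e-16

#' Microdosimetric context
#'
#' Bundles the track-structure constants of the microdosimetric-kinetic
#' model: the dose-mean lineal energy \eqn{y_D} of the radiation field, the
#' density of the medium, and the radius of the sub-nuclear interaction
#' domain.
#'
#' @param y_D Dose-mean lineal energy in keV/um. For the 150 kVp X-rays the
#'   model was developed against this is 4.68 keV/um.
#' @param rho Density of the medium in g/cm^3 (liquid water: 1.0).
#' @param r_d Domain radius in um (default 0.5).
#'
#' @return An object of class `microdosimetric_context` with fields `y_D`,
#'   `rho`, `r_d` and the derived per-domain dose coefficient `gamma` (Gy).
#'
#' @examples
#' ctx <- microdosimetric_context(y_D = 4.68)
#' ctx$gamma  # ~0.954 Gy
#' @export
microdosimetric_context <- function(y_D = 4.68, rho = 1.0, r_d = 0.5) {
  for (nm in c("y_D", "rho", "r_d")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("invalid microdosimetric context: '", nm,
           "' must be a single strictly positive number", call. = FALSE)
  }
  ctx <- structure(list(y_D = y_D, rho = rho, r_d = r_d),
                   class = "microdosimetric_context")
  ctx$gamma <- gamma_coefficient(ctx)
  ctx
}

#' Per-domain dose coefficient
#'
#' Converts the dose-mean lineal energy into the mean specific energy per
#' event deposited in one domain,
#' \deqn{\gamma = y_D / (\rho \pi r_d^2),}
#' expressed in Gy. This coefficient multiplies \eqn{\beta_0} in the linear
#' term of the survival model and carries the whole microdosimetric content
#' of the dose response.
#'
#' @param ctx A [microdosimetric_context()].
#' @return The coefficient in Gy (single numeric).
#'
#' @examples
#' gamma_coefficient(microdosimetric_context(4.68, 1.0, 0.5))
#' @export
gamma_coefficient <- function(ctx) {
  if (!inherits(ctx, "microdosimetric_context")) {
    if (is.list(ctx) && all(c("y_D", "rho", "r_d") %in% names(ctx)))
      ctx <- microdosimetric_context(ctx$y_D, ctx$rho, ctx$r_d)
    else
      stop("'ctx' must be a microdosimetric_context", call. = FALSE)
  }
  # y_D [keV/um] -> J/um; rho [g/cm^3] -> kg/um^3 (1e-15); Gy = J/kg
  (ctx$y_D * .KEV_TO_J) / (ctx$rho * 1e-15 * pi * ctx$r_d^2)
}

#' @export
print.microdosimetric_context <- function(x, ...) {
  cat("Microdosimetric context\n")
  cat(sprintf("  y_D   = %g keV/um\n", x$y_D))
  cat(sprintf("  rho   = %g g/cm^3\n", x$rho))
  cat(sprintf("  r_d   = %g um\n", x$r_d))
  cat(sprintf("  gamma = %.4f Gy (per-domain dose coefficient)\n", x$gamma))
  invisible(x)
}
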