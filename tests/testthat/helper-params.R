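# Shared fixtures: the fitted family parameter sets and context used
# throughout the tests.

sas_progeny <- function() population_params(0.208, 0.044, 1.279)
hsc2_progeny <- function() population_params(0.166, 0.168, 1.499)

test_ctx <- function() microdosimetric_context(y_D = 4.68, rho = 1.0, r_d = 0.5)

GAMMA_TAB <- 0.954  # per-domain dose coefficient printed for this beam

sas_model <- function(resistant = FALSE) {
  truth <- sas_family_parameters()
  two_population_model(sas_progeny(), truth$alpha0s, truth$beta0s,
                       f_s = if (resistant) truth$f_s_resistant
                             else truth$f_s_parent,
                       w_SLDR = truth$w_SLDR, resistant = resistant)
}

sas_priors <- function() {
  prior_spec(repair_mean = 1.31, repair_sd = 0.69,
             f_s_parent = c(0.0097, 0.0068),
             f_s_resistant = c(0.0965, 0.0365))
}
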