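# Shared fixtures: the default TCB/LVM-like models, grid, and a noiseless
# calibration set (built once; every curve is exact under Beer-Lambert).
test_models <- default_models()
test_grid <- default_grid()
test_calib <- build_calibrations(test_models, test_grid)

all_methods <- c("RS_SS", "CM_SS", "FC_SS", "DS_SS", "D1CM_SS", "D1FC_SS",
                 "DD1", "CV", "CNV")

# independent closed-form oracle for the generator: per-unit Gaussian-band
# response at a wavelength, evaluated directly from the band table
unit_response <- function(model, lambda) {
  sum(model$bands$height *
        exp(-(lambda - model$bands$center)^2 / (2 * model$bands$sigma^2)))
}

noiseless_mixture <- function(tcb, lvm, grid = test_grid) {
  mixture_spectrum(test_models, c(TCB = unname(tcb), LVM = unname(lvm)),
                   grid)
}

# relative error, guarding the zero-truth case
rel_err <- function(found, truth) {
  ifelse(truth == 0, abs(found), abs(found - truth) / abs(truth))
}
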