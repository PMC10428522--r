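#' Configure a resolution method
#'
#' Bundles the settings a quantification route needs: analyte names,
#' divisor concentration, plateau window, factorization wavelength, the
#' response reads per analyte, and the derivative settings. The defaults
#' for the nine TCB/LVM routes ship with [default_method_config()] and as
#' the bundled `tcb_lvm.yaml`.
#'
#' @param method one of `"RS_SS"`, `"CM_SS"`, `"FC_SS"`, `"DS_SS"`,
#'   `"D1CM_SS"`, `"D1FC_SS"`, `"DD1"`, `"CV"`, `"CNV"`.
#' @param extended,other names of the spectrally extended analyte (the one
#'   still absorbing in the plateau window) and the other analyte.
#' @param divisor_conc divisor concentration in ug/mL (ratio-based
#'   routes). For `DD1`, a named vector giving the divisor concentration
#'   per *divisor* analyte, e.g. `c(LVM = 4, TCB = 3)`.
#' @param plateau_region plateau window `c(lo, hi)` in nm; required for
#'   RS/CM/DS/D1CM/CV/CNV routes.
#' @param factorization_ref reference wavelength (nm) for the factorized
#'   routes.
#' @param responses named list: analyte -> character vector of response
#'   keys such as `"D0@304"`, `"D1@P228-216"`, `"DD1@P219"`.
#' @param delta_lambda,scale derivative window (nm) and presentation
#'   factor.
#' @return An object of class `method_config`.
#' @export
method_config <- function(method, extended = "TCB", other = "LVM",
                          divisor_conc = NULL, plateau_region = NULL,
                          factorization_ref = NULL, responses = list(),
                          delta_lambda = 4, scale = 10) {
  methods <- c("RS_SS", "CM_SS", "FC_SS", "DS_SS", "D1CM_SS", "D1FC_SS",
               "DD1", "CV", "CNV")
  method <- match.arg(method, methods)
  if (method %in% c("RS_SS", "CM_SS", "DS_SS", "D1CM_SS", "CV", "CNV") &&
      is.null(plateau_region)) {
    stop(sprintf("%s requires a plateau_region", method), call. = FALSE)
  }
  if (method %in% c("FC_SS", "D1FC_SS") && is.null(factorization_ref)) {
    stop(sprintf("%s requires a factorization_ref", method), call. = FALSE)
  }
  structure(
    list(method = method, extended = extended, other = other,
         divisor_conc = divisor_conc, plateau_region = plateau_region,
         factorization_ref = factorization_ref, responses = responses,
         delta_lambda = delta_lambda, scale = scale),
    class = "method_config"
  )
}

#' Paper-shaped default configuration for one route
#'
#' The wavelengths, divisors and plateau windows of the TCB/LVM study:
#' a 5.0 ug/mL TCB divisor and the 290--306 nm plateau for the zero-order
#' ratio routes, the wider 280--315 nm plateau for their first-derivative
#' counterparts, factorization at 304 nm (D0) / 310 nm (D1), and
#' derivative-ratio divisors of 4.0 ug/mL LVM (for TCB, read P 230-220 nm)
#' and 3.0 ug/mL TCB (for LVM, read at 219 nm).
#'
#' @param method route name (see [method_config()]).
#' @return A `method_config`.
#' @export
default_method_config <- function(method) {
  switch(method,
    RS_SS = method_config("RS_SS", divisor_conc = 5,
      plateau_region = c(290, 306),
      responses = list(TCB = c("D0@304", "D0@220"), LVM = "D0@214")),
    CM_SS = method_config("CM_SS", divisor_conc = 5,
      plateau_region = c(290, 306),
      responses = list(TCB = c("D0@220", "D0@304"), LVM = "D0@214")),
    FC_SS = method_config("FC_SS", factorization_ref = 304,
      responses = list(TCB = c("D0@220", "D0@304"), LVM = "D0@214")),
    DS_SS = method_config("DS_SS", divisor_conc = 5,
      plateau_region = c(280, 315),
      responses = list(TCB = c("D1@310", "D1@P228-216"),
                       LVM = "D1@P221")),
    D1CM_SS = method_config("D1CM_SS", divisor_conc = 5,
      plateau_region = c(280, 315),
      responses = list(TCB = c("D1@P228-216", "D1@310"),
                       LVM = "D1@P221")),
    D1FC_SS = method_config("D1FC_SS", factorization_ref = 310,
      responses = list(TCB = c("D1@P228-216", "D1@310"),
                       LVM = "D1@P221")),
    DD1 = method_config("DD1", divisor_conc = c(LVM = 4, TCB = 3),
      responses = list(TCB = "DD1@P230-220", LVM = "DD1@P219")),
    CV = method_config("CV", plateau_region = c(290, 306),
      responses = list(TCB = "CV")),
    CNV = method_config("CNV", plateau_region = c(290, 306),
      responses = list(TCB = "CNV")),
    stop("unknown method: ", method, call. = FALSE)
  )
}

# parse a response key like "D0@304", "D1@P228-216", "DD1@P219" into a
# response_descriptor; DD1 keys read on derivative-of-ratio spectra
parse_response_key <- function(key) {
  parts <- strsplit(key, "@", fixed = TRUE)[[1]]
  if (length(parts) != 2L || !parts[1] %in% c("D0", "D1", "DD1")) {
    stop("unrecognised response key: ", key, call. = FALSE)
  }
  order <- if (parts[1] == "D0") 0L else 1L
  body <- sub("^P", "", parts[2])
  lams <- as.numeric(strsplit(body, "-", fixed = TRUE)[[1]])
  if (length(lams) == 2L) {
    response_descriptor("peak_to_peak", order, lams[1], lams[2])
  } else {
    response_descriptor("amplitude_at", order, lams[1])
  }
}

resolution_result <- function(method, resolved, constants, concentrations,
                              diagnostics = list()) {
  structure(list(method = method, resolved = resolved,
                 constants = constants, concentrations = concentrations,
                 diagnostics = diagnostics),
            class = "resolution_result")
}

#' @export
print.resolution_result <- function(x, ...) {
  cat(sprintf("<resolution result> %s\n", x$method))
  for (an in names(x$concentrations)) {
    v <- x$concentrations[[an]]
    cat(sprintf("  %s: %s ug/mL\n", an,
                paste(sprintf("%s = %.4f", names(v), v), collapse = ", ")))
  }
  for (nm in names(x$constants)) {
    cat(sprintf("  constant %s = %.6g\n", nm, x$constants[[nm]]$value))
  }
  invisible(x)
}

# read every configured response of one analyte off its resolved spectrum
# and map through the matching calibration curve
concentrations_from <- function(spec, analyte, keys, calib) {
  out <- vapply(keys, function(key) {
    curve <- calib[[analyte]][[key]]
    if (is.null(curve)) {
      stop(sprintf("no calibration curve for %s %s", analyte, key),
           call. = FALSE)
    }
    as.numeric(predict_concentration(curve,
                                     read_response(spec, parse_response_key(key))))
  }, numeric(1))
  names(out) <- keys
  out
}

ss_concentrations <- function(resolved, cfg, calib) {
  out <- list()
  for (an in names(cfg$responses)) {
    out[[an]] <- concentrations_from(resolved[[an]], an,
                                     cfg$responses[[an]], calib)
  }
  out
}

#' Ratio subtraction coupled with spectrum subtraction (RS-SS)
#'
#' Divides the mixture spectrum by a pure divisor spectrum of the extended
#' component, takes the plateau constant in the extended region, subtracts
#' it from the ratio spectrum, and multiplies back by the divisor: what
#' remains is the other component's spectrum. Spectrum subtraction then
#' recovers the extended component as mixture minus resolved spectrum, so
#' the two resolved spectra add back to the mixture by construction.
#'
#' @param mixture mixture spectrum (order matching the route: 0 here).
#' @param divisor pure extended-component spectrum at the configured
#'   divisor concentration (same order and grid).
#' @param calib nested calibration list, `calib[[analyte]][[response
#'   key]]`, as built by [build_calibrations()].
#' @param cfg a [method_config()]; defaults to the paper-shaped RS-SS
#'   configuration.
#' @return A `resolution_result` with both resolved spectra, the plateau
#'   constant, and the concentrations read through each configured
#'   response.
#' @export
resolve_rs_ss <- function(mixture, divisor, calib,
                          cfg = default_method_config("RS_SS")) {
  ratio <- sp_divide(mixture, divisor, label = "mixture / divisor")
  k <- plateau_constant(ratio, cfg$plateau_region)
  # (ratio - k) * divisor == mixture - k * divisor pointwise wherever the
  # division is defined; the subtraction form extends it over masked points
  res_other <- sp_combine(mixture, divisor, 1, -k$value,
                          label = paste("resolved", cfg$other))
  res_ext <- sp_combine(mixture, res_other, 1, -1,
                        label = paste("resolved", cfg$extended))
  resolved <- stats::setNames(list(res_ext, res_other),
                              c(cfg$extended, cfg$other))
  resolution_result(cfg$method, resolved,
                    list(plateau = k),
                    ss_concentrations(resolved, cfg, calib))
}

#' Constant multiplication coupled with spectrum subtraction (CM-SS)
#'
#' Same plateau constant as RS-SS, but used the other way around: the
#' constant times the divisor reconstructs the extended component
#' directly, and subtraction from the mixture leaves the other component.
#'
#' @inheritParams resolve_rs_ss
#' @return A `resolution_result`.
#' @export
resolve_cm_ss <- function(mixture, divisor, calib,
                          cfg = default_method_config("CM_SS")) {
  ratio <- sp_divide(mixture, divisor, label = "mixture / divisor")
  k <- plateau_constant(ratio, cfg$plateau_region)
  res_ext <- sp_scale(divisor, k$value,
                      label = paste("resolved", cfg$extended))
  res_other <- sp_combine(mixture, res_ext, 1, -1,
                          label = paste("resolved", cfg$other))
  resolved <- stats::setNames(list(res_ext, res_other),
                              c(cfg$extended, cfg$other))
  resolution_result(cfg$method, resolved,
                    list(plateau = k),
                    ss_concentrations(resolved, cfg, calib))
}

#' Factorized response spectrum coupled with spectrum subtraction (FC-SS)
#'
#' Reads the mixture amplitude at a wavelength where only the extended
#' component responds, multiplies it with the factorized pure spectrum
#' (unit response at that wavelength) to reconstruct the extended
#' component, and subtracts to recover the other. No divisor spectrum is
#' involved.
#'
#' @inheritParams resolve_rs_ss
#' @param factorized factorized pure spectrum of the extended component
#'   (see [sp_factorize()]); its value at the configured reference
#'   wavelength must be 1.
#' @param interferent optional pure spectrum of the other component at a
#'   known concentration; if it responds at the reference wavelength above
#'   `leak_tol`, a warning reports the violated zero-contribution
#'   assumption.
#' @param leak_tol leakage warning threshold in AU (default 1e-4).
#' @return A `resolution_result`.
#' @export
resolve_fc_ss <- function(mixture, factorized, calib,
                          cfg = default_method_config("FC_SS"),
                          interferent = NULL, leak_tol = 1e-4) {
  ref <- cfg$factorization_ref
  fval <- value_at(factorized, ref)
  if (abs(fval - 1) > 1e-6) {
    stop(sprintf("factorized spectrum reads %.6g (not 1) at %g nm", fval,
                 ref), call. = FALSE)
  }
  diagnostics <- list()
  if (!is.null(interferent)) {
    leak <- value_at(interferent, ref)
    if (abs(leak) > leak_tol) {
      diagnostics$leakage <- leak
      warning(sprintf(
        "interferent responds %.3g AU at %g nm; zero-contribution assumption violated",
        leak, ref), call. = FALSE)
    }
  }
  amp <- value_at(mixture, ref)
  res_ext <- sp_scale(factorized, amp,
                      label = paste("resolved", cfg$extended))
  res_other <- sp_combine(mixture, res_ext, 1, -1,
                          label = paste("resolved", cfg$other))
  resolved <- stats::setNames(list(res_ext, res_other),
                              c(cfg$extended, cfg$other))
  resolution_result(cfg$method, resolved, list(),
                    ss_concentrations(resolved, cfg, calib),
                    diagnostics)
}

#' First-derivative counterparts of the ratio routes (DS-SS, D1CM-SS,
#' D1FC-SS)
#'
#' Derivatizes the zero-order mixture and divisor (or pure spectrum) and
#' applies the corresponding zero-order algorithm verbatim on the order-1
#' spectra, with the wider 280--315 nm plateau (DS/D1CM) or factorization
#' at 310 nm (D1FC).
#'
#' @inheritParams resolve_rs_ss
#' @param divisor_or_pure for `DS_SS`/`D1CM_SS`: the pure extended-component
#'   divisor spectrum (order 0); for `D1FC_SS`: a pure extended-component
#'   spectrum at any concentration, derivatized and factorized internally
#'   at the configured reference.
#' @param route which derivative route to run.
#' @return A `resolution_result`; its resolved spectra are order 1.
#' @export
resolve_derivative_route <- function(mixture, divisor_or_pure, calib,
                                     route = c("DS_SS", "D1CM_SS", "D1FC_SS"),
                                     cfg = default_method_config(match.arg(route))) {
  route <- match.arg(route)
  d_mix <- sp_derivative(mixture, cfg$delta_lambda, cfg$scale)
  d_div <- sp_derivative(divisor_or_pure, cfg$delta_lambda, cfg$scale)
  out <- switch(route,
    DS_SS = {
      c2 <- cfg; c2$method <- "DS_SS"
      resolve_rs_ss(d_mix, d_div, calib, c2)
    },
    D1CM_SS = {
      c2 <- cfg; c2$method <- "D1CM_SS"
      resolve_cm_ss(d_mix, d_div, calib, c2)
    },
    D1FC_SS = {
      fact <- sp_factorize(d_div, cfg$factorization_ref)
      c2 <- cfg; c2$method <- "D1FC_SS"
      resolve_fc_ss(d_mix, fact, calib, c2)
    })
  out$method <- route
  out
}

#' First derivative of ratio spectra (DD1)
#'
#' Divides the mixture by a pure spectrum of one component and
#' derivatizes: the divisor component's contribution, now a constant,
#' vanishes, so the read amplitude is proportional to the *other*
#' component alone. Run once per analyte with the complementary divisor
#' (here 4.0 ug/mL LVM to read TCB at P 230-220 nm, 3.0 ug/mL TCB to read
#' LVM at 219 nm).
#'
#' @inheritParams resolve_rs_ss
#' @param divisors named list of pure order-0 divisor spectra keyed by the
#'   *divisor* analyte name, e.g. `list(LVM = lvm4, TCB = tcb3)`.
#' @return A `resolution_result`; `resolved` holds the derivative ratio
#'   spectra keyed by the analyte they quantify.
#' @export
resolve_dd1 <- function(mixture, divisors, calib,
                        cfg = default_method_config("DD1")) {
  concs <- list(); resolved <- list()
  for (an in names(cfg$responses)) {
    div_name <- setdiff(c(cfg$extended, cfg$other), an)
    div <- divisors[[div_name]]
    if (is.null(div)) {
      stop(sprintf("no %s divisor supplied for %s", div_name, an),
           call. = FALSE)
    }
    ratio <- sp_divide(mixture, div,
                       label = sprintf("mixture / %s divisor", div_name))
    d <- sp_derivative(ratio, cfg$delta_lambda, cfg$scale)
    resolved[[an]] <- d
    concs[[an]] <- concentrations_from(d, an, cfg$responses[[an]], calib)
  }
  resolution_result("DD1", resolved, list(), concs)
}

# internal: sp_derivative operates on order-0 input; ratio spectra keep
# order 0 after division of two order-0 spectra, so DD1 derivatizes the
# ratio directly

#' Constant value method (CV)
#'
#' The plateau constant of the mixture over a *normalized* (per 1 ug/mL)
#' pure spectrum of the extended component is substituted into the CV
#' regression (plateau amplitude versus concentration built from pure
#' standards divided by the same normalized divisor). On ideal
#' Beer-Lambert data that regression is the identity.
#'
#' @inheritParams resolve_rs_ss
#' @param normalized_divisor pure extended-component spectrum per 1 ug/mL
#'   (see [sp_normalize()]).
#' @param cv_curve the CV [fit_calibration()] curve
#'   (`calib[[extended]][["CV"]]` when `calib` is given instead).
#' @return A `resolution_result` with the extended component's
#'   concentration.
#' @export
resolve_cv <- function(mixture, normalized_divisor, cv_curve,
                       cfg = default_method_config("CV")) {
  ratio <- sp_divide(mixture, normalized_divisor,
                     label = "mixture / normalized divisor")
  k <- plateau_constant(ratio, cfg$plateau_region)
  conc <- as.numeric(predict_concentration(cv_curve, k$value))
  resolution_result("CV", list(), list(plateau = k),
                    stats::setNames(list(c(CV = conc)), cfg$extended))
}

#' Concentration value method (CNV)
#'
#' Like CV, but the plateau constant over the normalized divisor *is* the
#' concentration: no regression substitution is needed, because dividing
#' by the per-unit spectrum makes the plateau equal c x 1 ug/mL.
#'
#' @inheritParams resolve_cv
#' @return A `resolution_result` with the extended component's
#'   concentration.
#' @export
resolve_cnv <- function(mixture, normalized_divisor,
                        cfg = default_method_config("CNV")) {
  ratio <- sp_divide(mixture, normalized_divisor,
                     label = "mixture / normalized divisor")
  k <- plateau_constant(ratio, cfg$plateau_region)
  resolution_result("CNV", list(), list(plateau = k),
                    stats::setNames(list(c(CNV = k$value)), cfg$extended))
}

#' Run any of the nine routes from shared ingredients
#'
#' Convenience dispatcher used by the study pipeline and the command-line
#' interface: given the mixture, the pure component models and a
#' calibration set, prepares whatever divisor/factorized/normalized
#' spectrum the route needs and runs it.
#'
#' @param mixture order-0 mixture spectrum.
#' @param method route name.
#' @param models named list of [component_model()] objects (names matching
#'   the configured analytes).
#' @param calib calibration list from [build_calibrations()].
#' @param cfg optional [method_config()]; defaults per method.
#' @return A `resolution_result`.
#' @export
resolve_mixture <- function(mixture, method, models, calib, cfg = NULL) {
  if (is.null(cfg)) cfg <- default_method_config(method)
  grid <- mixture$wavelength
  ext_model <- models[[cfg$extended]]
  switch(method,
    RS_SS = resolve_rs_ss(mixture,
      component_spectrum(ext_model, cfg$divisor_conc, grid), calib, cfg),
    CM_SS = resolve_cm_ss(mixture,
      component_spectrum(ext_model, cfg$divisor_conc, grid), calib, cfg),
    FC_SS = resolve_fc_ss(mixture,
      sp_factorize(component_spectrum(ext_model, 10, grid),
                   cfg$factorization_ref), calib, cfg),
    DS_SS = ,
    D1CM_SS = resolve_derivative_route(mixture,
      component_spectrum(ext_model, cfg$divisor_conc, grid), calib,
      method, cfg),
    D1FC_SS = resolve_derivative_route(mixture,
      component_spectrum(ext_model, 10, grid), calib, method, cfg),
    DD1 = {
      dl <- lapply(names(cfg$divisor_conc), function(nm) {
        component_spectrum(models[[nm]], cfg$divisor_conc[[nm]], grid)
      })
      names(dl) <- names(cfg$divisor_conc)
      resolve_dd1(mixture, dl, calib, cfg)
    },
    CV = resolve_cv(mixture,
      sp_normalize(component_spectrum(ext_model, 10, grid), 10),
      calib[[cfg$extended]][["CV"]], cfg),
    CNV = resolve_cnv(mixture,
      sp_normalize(component_spectrum(ext_model, 10, grid), 10), cfg),
    stop("unknown method: ", method, call. = FALSE)
  )
}

#' Build the full calibration set from pure standards
#'
#' Simulates (or, with `noise_sd = 0`, computes exactly) pure-component
#' standard series and fits one calibration curve per response key:
#' zero-order and first-derivative amplitude reads, the derivative-ratio
#' reads (each standard divided by the complementary divisor before
#' derivatization), and the CV plateau regression against the normalized
#' divisor.
#'
#' @param models named list of [component_model()] objects (must contain
#'   the analytes named in the configs).
#' @param grid wavelength grid.
#' @param concs named list of concentration series per analyte / response
#'   key group; defaults follow the study's linearity ranges (TCB
#'   2--20 ug/mL at 304 nm-class reads, 1--10 ug/mL at 220 nm-class reads,
#'   LVM 2--14 ug/mL).
#' @param noise_sd additive noise on each standard spectrum (AU).
#' @param seed optional seed for the noise.
#' @return Nested list `calib[[analyte]][[response key]]` of
#'   [fit_calibration()] curves.
#' @export
build_calibrations <- function(models, grid = default_grid(), concs = NULL,
                               noise_sd = 0, seed = NULL) {
  if (is.null(concs)) {
    concs <- list(
      TCB = list("D0@304" = seq(2, 20, 2), "D0@220" = 1:10,
                 "D1@310" = seq(2, 20, 2), "D1@P228-216" = 1:10,
                 "DD1@P230-220" = seq(2, 20, 2), "CV" = seq(2, 20, 2)),
      LVM = list("D0@214" = seq(2, 14, 2), "D1@P221" = seq(2, 14, 2),
                 "DD1@P219" = seq(2, 14, 2))
    )
  }
  if (!is.null(seed)) set.seed(seed)
  dd1_cfg <- default_method_config("DD1")
  cv_cfg <- default_method_config("CV")
  ext <- cv_cfg$extended
  norm_div <- sp_normalize(component_spectrum(models[[ext]], 10, grid), 10)
  calib <- list()
  for (an in names(concs)) {
    calib[[an]] <- list()
    for (key in names(concs[[an]])) {
      cc <- concs[[an]][[key]]
      responses <- vapply(cc, function(ci) {
        s <- component_spectrum(models[[an]], ci, grid)
        if (noise_sd > 0) {
          s$value <- s$value + stats::rnorm(length(grid), sd = noise_sd)
        }
        if (key == "CV") {
          return(plateau_constant(sp_divide(s, norm_div),
                                  cv_cfg$plateau_region)$value)
        }
        if (startsWith(key, "DD1")) {
          div_name <- setdiff(names(concs), an)
          div <- component_spectrum(models[[div_name]],
                                    dd1_cfg$divisor_conc[[div_name]], grid)
          s <- sp_derivative(sp_divide(s, div), dd1_cfg$delta_lambda,
                             dd1_cfg$scale)
        } else if (startsWith(key, "D1")) {
          s <- sp_derivative(s)
        }
        read_response(s, parse_response_key(key))
      }, numeric(1))
      desc <- if (key == "CV") NULL else parse_response_key(key)
      calib[[an]][[key]] <- fit_calibration(cc, responses, desc,
                                            analyte = an)
    }
  }
  calib
}
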