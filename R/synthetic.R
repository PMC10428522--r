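#' Define a Gaussian-band Beer-Lambert component model
#'
#' A component model is a sum of Gaussian absorption bands whose heights
#' are expressed per unit concentration (AU per ug/mL), so the spectrum it
#' generates is strictly linear in concentration: the Beer-Lambert
#' additivity every resolution route in this package relies on holds by
#' construction.
#'
#' @param name analyte name.
#' @param bands data frame with columns `center` (nm), `sigma` (nm, > 0)
#'   and `height` (AU per ug/mL, >= 0), one row per band.
#' @param baseline constant baseline in AU (default 0).
#' @return An object of class `component_model`.
#' @export
component_model <- function(name, bands, baseline = 0) {
  bands <- as.data.frame(bands)
  stopifnot(all(c("center", "sigma", "height") %in% names(bands)),
            all(bands$sigma > 0), all(bands$height >= 0))
  structure(list(name = name, bands = bands, baseline = baseline),
            class = "component_model")
}

#' @export
print.component_model <- function(x, ...) {
  cat(sprintf("<component model> %s: %d band(s)\n", x$name, nrow(x$bands)))
  for (i in seq_len(nrow(x$bands))) {
    cat(sprintf("  center %g nm, sigma %g nm, height %g AU per ug/mL\n",
                x$bands$center[i], x$bands$sigma[i], x$bands$height[i]))
  }
  invisible(x)
}

#' Generate a pure-component spectrum
#'
#' Evaluates the model's Gaussian bands at `conc` ug/mL on `grid`.
#'
#' @param model a [component_model()].
#' @param conc concentration in ug/mL, >= 0.
#' @param grid wavelength grid (default [default_grid()]).
#' @return An order-0 `spectrum`, labelled with the analyte and
#'   concentration.
#' @export
component_spectrum <- function(model, conc, grid = default_grid()) {
  stopifnot(inherits(model, "component_model"), conc >= 0)
  v <- rep(model$baseline, length(grid))
  for (i in seq_len(nrow(model$bands))) {
    b <- model$bands[i, ]
    v <- v + conc * b$height * exp(-(grid - b$center)^2 / (2 * b$sigma^2))
  }
  new_spectrum(grid, v, order = 0L,
               label = sprintf("%s %g ug/mL", model$name, conc))
}

#' Default triclabendazole-like and levamisole-like models
#'
#' Emulates the TCB/LVM overlap: the TCB-like component has a strong band
#' at 220 nm and a weaker one at 304 nm whose long-wavelength flank is the
#' "extended" region 290--306 nm; the LVM-like component has a single band
#' at 214 nm and, with sigma = 8 nm, contributes < 1e-6 AU per ug/mL
#' anywhere above 285 nm. Band heights equal the per-unit zero-order
#' responses of the real pair at their maxima (0.1322 and 0.0533 AU per
#' ug/mL for TCB at 220/304 nm, 0.0834 for LVM at 214 nm).
#'
#' @return Named list with elements `TCB` and `LVM`, each a
#'   [component_model()].
#' @examples
#' m <- default_models()
#' read_response(component_spectrum(m$TCB, 10),
#'               response_descriptor("amplitude_at", 0, 304)) # 0.533
#' @export
default_models <- function() {
  list(
    TCB = component_model("TCB", data.frame(
      center = c(220, 304), sigma = c(9, 10), height = c(0.1322, 0.0533))),
    LVM = component_model("LVM", data.frame(
      center = 214, sigma = 8, height = 0.0834))
  )
}

#' Simulate a binary mixture spectrum
#'
#' Sums the component spectra at the stated concentrations and adds
#' i.i.d. Gaussian photometric noise. With `noise_sd = 0` the result is
#' exactly the Beer-Lambert sum of the components.
#'
#' @param models named list of [component_model()] objects.
#' @param concs named numeric vector of concentrations (ug/mL), names
#'   matching `models`.
#' @param grid wavelength grid.
#' @param noise_sd standard deviation of additive noise in AU (default 0;
#'   0.002 AU is a typical photometric noise level).
#' @param seed optional integer; when supplied the RNG is seeded locally so
#'   the same call reproduces the same spectrum without disturbing the
#'   caller's RNG stream.
#' @return An order-0 `spectrum`; the label records the true
#'   concentrations.
#' @export
mixture_spectrum <- function(models, concs, grid = default_grid(),
                             noise_sd = 0, seed = NULL) {
  stopifnot(length(models) >= 1L, all(names(models) %in% names(concs)),
            noise_sd >= 0)
  v <- rep(0, length(grid))
  for (nm in names(models)) {
    v <- v + component_spectrum(models[[nm]], concs[[nm]], grid)$value
  }
  if (noise_sd > 0) {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
      on.exit(if (!is.null(old))
        assign(".Random.seed", old, envir = globalenv()), add = TRUE)
      set.seed(seed)
    }
    v <- v + stats::rnorm(length(grid), sd = noise_sd)
  }
  lab <- paste(sprintf("%s=%g", names(models),
                       unlist(concs[names(models)])), collapse = ", ")
  new_spectrum(grid, v, order = 0L,
               label = sprintf("mixture (%s ug/mL)", lab))
}

#' Laboratory-mixture ratio grid for the specificity study
#'
#' The five TCB:LVM ratios of the specificity study (2:3, 3:4, 1:1,
#' 4.5:2.5 and the dosage-form ratio 4:2.5), scaled by 2 into the linear
#' calibration ranges.
#'
#' @return Data frame with columns `tcb`, `lvm` (ug/mL) and `ratio`
#'   (label); the dosage-form row is flagged in `dosage_form`.
#' @export
table_ratio_grid <- function() {
  data.frame(
    tcb = c(4, 6, 10, 9, 8),
    lvm = c(6, 8, 10, 5, 5),
    ratio = c("2:3", "3:4", "1:1", "4.5:2.5", "4:2.5"),
    dosage_form = c(FALSE, FALSE, FALSE, FALSE, TRUE)
  )
}
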