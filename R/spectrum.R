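#' Construct a spectrum object
#'
#' A `spectrum` is a sampled curve on a strictly increasing, uniform
#' wavelength grid. Zero-order (`order = 0`) spectra hold absorbance in AU;
#' first-derivative spectra (`order = 1`) hold scaled amplitude per nm.
#' Points excluded by a division guard are tracked in a logical mask and
#' never feed downstream amplitude or plateau reads.
#'
#' @param wavelength numeric vector of wavelengths (nm), strictly increasing
#'   with constant spacing (to within 1e-9 nm), length >= 2.
#' @param value numeric vector of responses, same length as `wavelength`.
#' @param order derivative order, 0 or 1.
#' @param label free-text label (analyte, concentration, provenance).
#' @param masked optional logical vector marking excluded grid points.
#' @return An object of class `spectrum`.
#' @examples
#' s <- new_spectrum(seq(200, 400, 0.5), rep(0.1, 401), label = "flat")
#' s
#' @export
new_spectrum <- function(wavelength, value, order = 0L, label = "",
                         masked = NULL) {
  wavelength <- as.numeric(wavelength)
  value <- as.numeric(value)
  if (length(wavelength) < 2L || length(wavelength) != length(value)) {
    stop("wavelength and value must have equal length >= 2", call. = FALSE)
  }
  steps <- diff(wavelength)
  if (any(steps <= 0)) {
    stop("wavelength grid must be strictly increasing", call. = FALSE)
  }
  if (max(steps) - min(steps) > 1e-9) {
    stop("wavelength grid spacing must be constant to within 1e-9 nm",
         call. = FALSE)
  }
  if (!order %in% c(0L, 1L)) {
    stop("order must be 0 or 1", call. = FALSE)
  }
  if (is.null(masked)) masked <- rep(FALSE, length(value))
  stopifnot(is.logical(masked), length(masked) == length(value))
  structure(
    list(wavelength = wavelength, value = value, order = as.integer(order),
         label = as.character(label), masked = masked),
    class = "spectrum"
  )
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf(
    "<spectrum> order D%d, %d points, %.1f-%.1f nm (step %.4g nm)%s\n",
    x$order, length(x$wavelength), min(x$wavelength), max(x$wavelength),
    sp_step(x),
    if (any(x$masked)) sprintf(", %d masked", sum(x$masked)) else ""
  ))
  if (nzchar(x$label)) cat("  label:", x$label, "\n")
  invisible(x)
}

#' @export
as.data.frame.spectrum <- function(x, ...) {
  data.frame(wavelength_nm = x$wavelength,
             value = x$value,
             masked = x$masked)
}

is_spectrum <- function(x) inherits(x, "spectrum")

sp_step <- function(s) (s$wavelength[length(s$wavelength)] - s$wavelength[1]) /
  (length(s$wavelength) - 1L)

same_grid <- function(a, b, tol = 1e-9) {
  length(a$wavelength) == length(b$wavelength) &&
    max(abs(a$wavelength - b$wavelength)) <= tol
}

#' Default wavelength grid
#'
#' The instrument scan range 200--400 nm sampled every 0.5 nm; all bundled
#' method configurations assume spectra on (or resampled to) this grid.
#'
#' @param from,to,by grid limits and spacing in nm.
#' @return numeric wavelength vector.
#' @export
default_grid <- function(from = 200, to = 400, by = 0.5) seq(from, to, by = by)

#' Resample a spectrum onto a new wavelength grid
#'
#' Linear interpolation of the stored values onto `grid`. The target grid
#' must lie within the span of the source; extrapolation is refused. A
#' resampled point is masked if either bracketing source point is masked.
#'
#' @param s a [new_spectrum()] object.
#' @param grid target wavelength grid (uniform, increasing).
#' @return A `spectrum` on `grid`, order and label preserved.
#' @export
sp_resample <- function(s, grid) {
  stopifnot(is_spectrum(s))
  grid <- as.numeric(grid)
  lo <- s$wavelength[1]; hi <- s$wavelength[length(s$wavelength)]
  if (min(grid) < lo - 1e-9 || max(grid) > hi + 1e-9) {
    stop(sprintf(
      "resampling would extrapolate: target [%g, %g] nm outside source [%g, %g] nm",
      min(grid), max(grid), lo, hi), call. = FALSE)
  }
  v <- stats::approx(s$wavelength, s$value, xout = grid, rule = 1)$y
  # carry the mask: a target point inherits masking from its bracketing points
  m <- stats::approx(s$wavelength, as.numeric(s$masked), xout = grid,
                     rule = 1)$y > 0
  new_spectrum(grid, v, order = s$order, label = s$label, masked = m)
}

#' Linear combination of two spectra
#'
#' Pointwise `wa * a + wb * b`. Subtraction of a resolved component from a
#' mixture is `sp_combine(mixture, resolved, 1, -1)`. Both spectra must share
#' the grid and derivative order; masks are ORed.
#'
#' @param a,b spectra on identical grids with identical order.
#' @param wa,wb scalar weights.
#' @param label label for the result.
#' @return A `spectrum`.
#' @export
sp_combine <- function(a, b, wa = 1, wb = 1, label = "") {
  stopifnot(is_spectrum(a), is_spectrum(b))
  if (!same_grid(a, b)) stop("grids differ; resample first", call. = FALSE)
  if (a$order != b$order) stop("derivative orders differ", call. = FALSE)
  new_spectrum(a$wavelength, wa * a$value + wb * b$value, order = a$order,
               label = label, masked = a$masked | b$masked)
}

#' Scale a spectrum by a scalar
#'
#' @param s a spectrum; @param k scalar factor.
#' @return A `spectrum`.
#' @export
sp_scale <- function(s, k, label = s$label) {
  stopifnot(is_spectrum(s))
  new_spectrum(s$wavelength, k * s$value, order = s$order, label = label,
               masked = s$masked)
}

#' Divide two spectra to form a ratio spectrum
#'
#' Pointwise quotient `numerator / divisor`. Grid points where the divisor
#' magnitude falls below `epsilon` are masked (value set to 0, excluded from
#' all downstream plateau and amplitude reads); the mask travels with the
#' result.
#'
#' @param num,div spectra on identical grids with identical order.
#' @param epsilon division guard in AU (default 1e-4); divisor points with
#'   `|value| < epsilon` are masked.
#' @param label label for the ratio spectrum.
#' @return A `spectrum` carrying the quotient and the mask.
#' @export
sp_divide <- function(num, div, epsilon = 1e-4, label = "") {
  stopifnot(is_spectrum(num), is_spectrum(div), epsilon > 0)
  if (!same_grid(num, div)) stop("grids differ; resample first", call. = FALSE)
  if (num$order != div$order) stop("derivative orders differ", call. = FALSE)
  bad <- abs(div$value) < epsilon | div$masked | num$masked
  if (all(bad)) {
    stop(sprintf("divisor entirely below epsilon = %g AU", epsilon),
         call. = FALSE)
  }
  v <- numeric(length(num$value))
  v[!bad] <- num$value[!bad] / div$value[!bad]
  new_spectrum(num$wavelength, v, order = num$order, label = label,
               masked = bad)
}

#' First derivative of a spectrum
#'
#' Savitzky--Golay first derivative (quadratic fit) over a symmetric window
#' of width `delta_lambda`, multiplied by `scale`. The kernel is exact on
#' straight lines and antisymmetric, so the derivative of a symmetric band
#' crosses zero at the band centre. The output grid is trimmed by half a
#' window at each end; any output point whose window touches a masked input
#' point is masked.
#'
#' @param s an order-0 spectrum.
#' @param delta_lambda window width in nm; must be a positive even multiple
#'   of the grid step (default 4 nm).
#' @param scale multiplicative presentation factor (default 10).
#' @return An order-1 `spectrum`.
#' @export
sp_derivative <- function(s, delta_lambda = 4, scale = 10) {
  stopifnot(is_spectrum(s))
  if (s$order != 0L) {
    stop("only first derivatives of zero-order spectra are supported",
         call. = FALSE)
  }
  h <- sp_step(s)
  half <- delta_lambda / 2 / h
  if (delta_lambda <= 0 || abs(half - round(half)) > 1e-9) {
    stop(sprintf(
      "delta_lambda = %g nm is not an even multiple of the grid step %g nm",
      delta_lambda, h), call. = FALSE)
  }
  half <- as.integer(round(half))
  n <- 2L * half + 1L
  v <- s$value
  v[s$masked] <- 0 # placeholder; affected windows are masked below
  d <- signal::sgolayfilt(v, p = 2, n = n, m = 1, ts = h) * scale
  keep <- (half + 1L):(length(v) - half)
  touched <- as.logical(stats::filter(as.numeric(s$masked),
                                      rep(1, n), sides = 2) > 0)
  touched[is.na(touched)] <- TRUE
  new_spectrum(s$wavelength[keep], d[keep], order = s$order + 1L,
               label = s$label, masked = touched[keep])
}

#' Describe an amplitude read on a spectrum
#'
#' A response descriptor names how a scalar response is read from a
#' spectrum: a single amplitude at `lambda1`, or a peak-to-peak difference
#' `value(lambda1) - value(lambda2)` on a derivative spectrum.
#'
#' @param mode `"amplitude_at"` or `"peak_to_peak"`.
#' @param order derivative order the read applies to (0 or 1).
#' @param lambda1,lambda2 read wavelengths in nm inside 200--400;
#'   `lambda2` only for peak-to-peak and must differ from `lambda1`.
#' @return An object of class `response_descriptor`.
#' @examples
#' response_descriptor("peak_to_peak", 1, 228, 216) # P 228-216 nm
#' @export
response_descriptor <- function(mode = c("amplitude_at", "peak_to_peak"),
                                order = 0L, lambda1, lambda2 = NULL) {
  mode <- match.arg(mode)
  stopifnot(order %in% c(0L, 1L))
  lam <- c(lambda1, lambda2)
  if (any(lam < 200 | lam > 400)) {
    stop("read wavelengths must lie inside 200-400 nm", call. = FALSE)
  }
  if (mode == "peak_to_peak") {
    if (is.null(lambda2) || lambda1 == lambda2) {
      stop("peak_to_peak needs two distinct wavelengths", call. = FALSE)
    }
  } else if (!is.null(lambda2)) {
    stop("lambda2 only applies to peak_to_peak", call. = FALSE)
  }
  structure(list(mode = mode, order = as.integer(order),
                 lambda1 = lambda1, lambda2 = lambda2),
            class = "response_descriptor")
}

#' @export
print.response_descriptor <- function(x, ...) {
  cat(if (x$mode == "amplitude_at") {
    sprintf("<response> D%d amplitude at %g nm\n", x$order, x$lambda1)
  } else {
    sprintf("<response> D%d P %g-%g nm (peak-to-peak)\n", x$order,
            x$lambda1, x$lambda2)
  })
  invisible(x)
}

# value at a single wavelength: snap to the grid point when lambda sits on
# the grid (within 1e-6 nm), else linear interpolation between the two
# bracketing points; masked points refuse the read
value_at <- function(s, lambda) {
  n <- length(s$wavelength)
  if (lambda < s$wavelength[1] - 1e-9 || lambda > s$wavelength[n] + 1e-9) {
    stop(sprintf("wavelength %g nm outside spectrum span [%g, %g] nm",
                 lambda, s$wavelength[1], s$wavelength[n]), call. = FALSE)
  }
  i <- which.min(abs(s$wavelength - lambda))
  if (abs(s$wavelength[i] - lambda) < 1e-6) {
    if (s$masked[i]) {
      stop(sprintf("requested wavelength %g nm is masked", lambda),
           call. = FALSE)
    }
    return(s$value[i])
  }
  lo <- max(which(s$wavelength <= lambda))
  hi <- min(lo + 1L, n)
  if (s$masked[lo] || s$masked[hi]) {
    stop(sprintf("requested wavelength %g nm falls in a masked region",
                 lambda), call. = FALSE)
  }
  stats::approx(s$wavelength[c(lo, hi)], s$value[c(lo, hi)], xout = lambda)$y
}

#' Read a scalar response from a spectrum
#'
#' Applies a [response_descriptor()]: either the amplitude at one
#' wavelength or the peak-to-peak difference between two. Reads at masked
#' grid points are an error. Peak-to-peak is antisymmetric in its two
#' wavelengths.
#'
#' @param s a spectrum whose order matches the descriptor.
#' @param d a [response_descriptor()].
#' @return scalar response (AU for order 0, scaled AU/nm for order 1).
#' @export
read_response <- function(s, d) {
  stopifnot(is_spectrum(s), inherits(d, "response_descriptor"))
  if (s$order != d$order) {
    stop(sprintf("descriptor order D%d does not match spectrum order D%d",
                 d$order, s$order), call. = FALSE)
  }
  if (d$mode == "amplitude_at") {
    value_at(s, d$lambda1)
  } else {
    value_at(s, d$lambda1) - value_at(s, d$lambda2)
  }
}

#' Extract the plateau constant of a ratio spectrum
#'
#' In the wavelength window where only the divisor's component absorbs, a
#' mixture-over-divisor ratio spectrum is flat and equals the concentration
#' ratio (Beer--Lambert). The constant is the mean of the ratio over the
#' region; flatness is diagnosed as the percent relative standard deviation
#' across the region, and a warning (not an error) is raised when it
#' exceeds `flatness_tol`, since real plateaus drift.
#'
#' @param ratio a ratio spectrum from [sp_divide()].
#' @param region numeric length-2, plateau window in nm (e.g. `c(290, 306)`
#'   on zero-order spectra, `c(280, 315)` on first derivatives).
#' @param flatness_tol warning threshold on the plateau RSD, in percent.
#' @return An object of class `plateau_constant` with fields `value`,
#'   `region`, `flatness_rsd`, `n_points`.
#' @export
plateau_constant <- function(ratio, region, flatness_tol = 2) {
  stopifnot(is_spectrum(ratio), length(region) == 2L)
  region <- sort(as.numeric(region))
  if (diff(region) <= 0) stop("region width must be > 0", call. = FALSE)
  inside <- ratio$wavelength >= region[1] - 1e-9 &
    ratio$wavelength <= region[2] + 1e-9
  ok <- inside & !ratio$masked
  if (sum(ok) < 3L) {
    stop(sprintf("fewer than 3 unmasked grid points in [%g, %g] nm",
                 region[1], region[2]), call. = FALSE)
  }
  v <- ratio$value[ok]
  m <- mean(v)
  rsd <- if (abs(m) > 0) 100 * stats::sd(v) / abs(m) else NA_real_
  out <- structure(
    list(value = m, region = region, flatness_rsd = rsd,
         n_points = sum(ok)),
    class = "plateau_constant"
  )
  if (is.finite(rsd) && rsd > flatness_tol) {
    warning(sprintf(
      "plateau over [%g, %g] nm is not flat: RSD %.2f%% exceeds %g%%",
      region[1], region[2], rsd, flatness_tol), call. = FALSE)
  }
  out
}

#' @export
print.plateau_constant <- function(x, ...) {
  cat(sprintf("<plateau constant> %.6g over [%g, %g] nm (%d points, RSD %.3g%%)\n",
              x$value, x$region[1], x$region[2], x$n_points,
              x$flatness_rsd))
  invisible(x)
}

#' Normalize a spectrum to unit concentration
#'
#' Divides the stored values by the concentration at which the pure
#' standard was recorded, yielding the per-1-ug/mL spectrum used as the
#' normalized divisor of the concentration-value route.
#'
#' @param s a pure-component spectrum.
#' @param concentration recording concentration in ug/mL, > 0.
#' @return A `spectrum` labelled as normalized.
#' @export
sp_normalize <- function(s, concentration) {
  stopifnot(is_spectrum(s), concentration > 0)
  sp_scale(s, 1 / concentration,
           label = trimws(paste(s$label, "(normalized)")))
}

#' Factorize a spectrum at a reference wavelength
#'
#' Divides a pure-component spectrum by its own response at `lambda_ref`,
#' so the result reads exactly 1 there. Multiplying the factorized spectrum
#' by a measured mixture amplitude at `lambda_ref` reconstructs that
#' component's contribution. Factorization is concentration-invariant under
#' Beer--Lambert linearity.
#'
#' @param s a pure-component spectrum (order 0 or 1).
#' @param lambda_ref reference wavelength in nm.
#' @param epsilon refuse factorization when the reference response
#'   magnitude is below this (AU).
#' @return A `spectrum` with value 1 at `lambda_ref`.
#' @export
sp_factorize <- function(s, lambda_ref, epsilon = 1e-4) {
  stopifnot(is_spectrum(s))
  ref <- value_at(s, lambda_ref)
  if (abs(ref) < epsilon) {
    stop(sprintf("response at %g nm (%.3g) is below epsilon = %g",
                 lambda_ref, ref, epsilon), call. = FALSE)
  }
  sp_scale(s, 1 / ref,
           label = trimws(sprintf("%s (factorized at %g nm)", s$label,
                                  lambda_ref)))
}
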