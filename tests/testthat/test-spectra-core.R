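test_that("resample is the identity on its own grid and exact on lines", {
  s <- new_spectrum(seq(200, 210, 1), seq(200, 210, 1))
  expect_identical(sp_resample(s, s$wavelength)$value, s$value)

  fine <- seq(200.5, 209.5, 0.5)
  r <- sp_resample(s, fine)
  expect_equal(r$value, fine) # y = lambda stays exact under linear interp
  expect_equal(r$order, s$order)
})

test_that("resample refuses extrapolation, naming the offending bounds", {
  s <- new_spectrum(seq(210, 300, 1), rnorm(91))
  expect_error(sp_resample(s, seq(200, 250, 1)), "extrapolate")
  expect_error(sp_resample(s, seq(250, 310, 1)), "\\[210, 300\\]")
})

test_that("resampling a coarse Gaussian band stays within 1e-3 AU of the
           analytic curve for sigma >= 5 nm", {
  # per-unit band heights as in the generator (<= 0.14 AU per ug/mL)
  for (sigma in c(5, 8, 10)) {
    coarse <- seq(200, 400, 1)
    fine <- seq(200, 400, 0.5)
    band <- function(l) 0.1322 * exp(-(l - 304)^2 / (2 * sigma^2))
    s <- new_spectrum(coarse, band(coarse))
    r <- sp_resample(s, fine)
    expect_lt(max(abs(r$value - band(fine))), 1e-3)
  }
})

test_that("combine is the stated pointwise linear combination", {
  s <- component_spectrum(test_models$TCB, 7, test_grid)
  z <- sp_combine(s, s, 1, -1)
  expect_equal(z$value, rep(0, length(test_grid)))

  zero <- new_spectrum(test_grid, rep(0, length(test_grid)))
  expect_equal(sp_combine(s, zero, 2, 1)$value, 2 * s$value)

  # Beer-Lambert additivity: pure + pure equals the generated mixture
  tcb <- component_spectrum(test_models$TCB, 10, test_grid)
  lvm <- component_spectrum(test_models$LVM, 10, test_grid)
  expect_equal(sp_combine(tcb, lvm)$value, noiseless_mixture(10, 10)$value)
})

test_that("combine and divide refuse mismatched grids or orders", {
  a <- new_spectrum(seq(200, 300, 1), rep(1, 101))
  b <- new_spectrum(seq(200, 300, 0.5), rep(1, 201))
  expect_error(sp_combine(a, b), "grids")
  expect_error(sp_divide(a, b), "grids")
  d <- sp_derivative(component_spectrum(test_models$TCB, 5, test_grid))
  expect_error(sp_combine(d, component_spectrum(test_models$TCB, 5,
                                                d$wavelength)), "order")
})

test_that("divide returns 1 for self-division and masks vanishing divisors", {
  s <- component_spectrum(test_models$TCB, 10, test_grid)
  r <- sp_divide(s, s)
  expect_true(all(abs(r$value[!r$masked] - 1) < 1e-12))

  # mixture / half-concentration divisor = 2 wherever only TCB absorbs
  mix <- noiseless_mixture(10, 10)
  div <- component_spectrum(test_models$TCB, 5, test_grid)
  r2 <- sp_divide(mix, div)
  ext <- r2$wavelength >= 290 & r2$wavelength <= 306 & !r2$masked
  expect_true(all(abs(r2$value[ext] - 2) < 1e-10))

  # LVM has no response in the extended region: pure LVM over the TCB
  # divisor is tiny there
  lvm <- component_spectrum(test_models$LVM, 10, test_grid)
  r3 <- sp_divide(lvm, div)
  expect_true(all(abs(r3$value[ext & !r3$masked]) < 1e-6))

  tiny <- new_spectrum(test_grid, rep(1e-6, length(test_grid)))
  expect_error(sp_divide(s, tiny), "entirely below")
})

test_that("derivative is zero on constants and scale*m on lines", {
  const <- new_spectrum(test_grid, rep(0.4, length(test_grid)))
  expect_equal(sp_derivative(const)$value,
               rep(0, length(sp_derivative(const)$value)))

  line <- new_spectrum(test_grid, 0.003 * test_grid - 0.1)
  d <- sp_derivative(line, delta_lambda = 4, scale = 10)
  expect_equal(d$value, rep(10 * 0.003, length(d$value)))
  expect_equal(d$order, 1L)
  # half-window trimmed at each end
  expect_equal(d$wavelength[1], test_grid[1] + 2)
})

test_that("derivative of the synthetic bands changes sign at each centre", {
  tcb <- component_spectrum(test_models$TCB, 10, test_grid)
  d <- sp_derivative(tcb)
  sign_flip <- function(lo, hi) {
    i <- d$wavelength >= lo & d$wavelength <= hi
    v <- d$value[i]
    sum(diff(sign(v[v != 0])) != 0)
  }
  expect_equal(sign_flip(215, 225), 1) # around the 220 nm band
  expect_equal(sign_flip(299, 309), 1) # around the 304 nm band

  # a pure single band crosses zero exactly once inside its support
  lvm <- component_spectrum(test_models$LVM, 10, test_grid)
  dl <- sp_derivative(lvm)
  i <- dl$wavelength >= 214 - 24 & dl$wavelength <= 214 + 24
  v <- dl$value[i]
  expect_equal(sum(diff(sign(v[v != 0])) != 0), 1)
})

test_that("derivative rejects a window not representable on the grid", {
  s <- new_spectrum(seq(200, 300, 1), rnorm(101))
  expect_error(sp_derivative(s, delta_lambda = 3), "multiple")
})

test_that("response reads are linear, antisymmetric, and refuse masked points", {
  zero <- new_spectrum(test_grid, rep(0, length(test_grid)))
  expect_equal(read_response(zero, response_descriptor("amplitude_at", 0, 250)),
               0)

  tcb <- component_spectrum(test_models$TCB, 10, test_grid)
  expect_equal(read_response(tcb, response_descriptor("amplitude_at", 0, 304)),
               10 * unit_response(test_models$TCB, 304))

  d <- sp_derivative(tcb)
  p1 <- read_response(d, response_descriptor("peak_to_peak", 1, 228, 216))
  p2 <- read_response(d, response_descriptor("peak_to_peak", 1, 216, 228))
  expect_equal(p1, -p2)

  expect_error(response_descriptor("peak_to_peak", 1, 228, 228), "distinct")
  expect_error(response_descriptor("amplitude_at", 0, 450), "200-400")

  lvm <- component_spectrum(test_models$LVM, 4, test_grid)
  ratio <- sp_divide(tcb, lvm) # masked where LVM vanishes (long wavelengths)
  expect_error(read_response(ratio, response_descriptor("amplitude_at", 0, 304)),
               "masked")
})

test_that("plateau constants equal the concentration ratio and flag drift", {
  const <- new_spectrum(test_grid, rep(3.25, length(test_grid)))
  k <- plateau_constant(const, c(250, 300))
  expect_equal(k$value, 3.25)
  expect_equal(k$flatness_rsd, 0)

  div <- component_spectrum(test_models$TCB, 5, test_grid)
  for (lvm_conc in c(0, 4, 12)) {
    mix <- noiseless_mixture(10, lvm_conc)
    kk <- plateau_constant(sp_divide(mix, div), c(290, 306))
    expect_lt(abs(kk$value - 2) / 2, 1e-10)
  }

  # a ratio straddling the other component's band is not flat
  lvm <- component_spectrum(test_models$LVM, 10, test_grid)
  mix <- noiseless_mixture(10, 10)
  expect_warning(plateau_constant(sp_divide(mix, div), c(210, 240)),
                 "not flat")

  few <- sp_divide(mix, div)
  expect_error(plateau_constant(few, c(290, 290.4)), "fewer than 3")
})

test_that("normalize divides by concentration and matches the unit spectrum", {
  s <- component_spectrum(test_models$TCB, 10, test_grid)
  expect_equal(sp_normalize(s, 1)$value, s$value)
  expect_equal(sp_normalize(s, 10)$value,
               component_spectrum(test_models$TCB, 1, test_grid)$value)
  d <- response_descriptor("amplitude_at", 0, 304)
  expect_equal(read_response(sp_normalize(s, 4), d),
               read_response(s, d) / 4)
})

test_that("factorization reads 1 at the reference and cancels concentration", {
  at304 <- response_descriptor("amplitude_at", 0, 304)
  for (conc in c(4, 12)) {
    f <- sp_factorize(component_spectrum(test_models$TCB, conc, test_grid),
                      304)
    expect_equal(read_response(f, at304), 1)
  }
  f4 <- sp_factorize(component_spectrum(test_models$TCB, 4, test_grid), 304)
  f12 <- sp_factorize(component_spectrum(test_models$TCB, 12, test_grid), 304)
  expect_equal(f4$value, f12$value)

  d <- sp_derivative(component_spectrum(test_models$TCB, 10, test_grid))
  fd <- sp_factorize(d, 310)
  expect_equal(read_response(fd, response_descriptor("amplitude_at", 1, 310)),
               1)

  lvm <- component_spectrum(test_models$LVM, 10, test_grid)
  expect_error(sp_factorize(lvm, 304), "below epsilon")
})
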