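# Exactness on noiseless Beer-Lambert mixtures is the primary oracle: all
# the algebra is linear, so every route must hand back the true
# concentrations to numerical precision.

test_that("all nine routes are exact on noiseless mixtures across the grid", {
  grid_df <- table_ratio_grid()
  for (i in seq_len(nrow(grid_df))) {
    truth <- c(TCB = grid_df$tcb[i], LVM = grid_df$lvm[i])
    mix <- noiseless_mixture(truth["TCB"], truth["LVM"])
    for (meth in all_methods) {
      res <- resolve_mixture(mix, meth, test_models, test_calib)
      for (an in names(res$concentrations)) {
        for (found in res$concentrations[[an]]) {
          expect_lt(rel_err(found, truth[[an]]), 1e-6,
                    label = sprintf("%s %s @ ratio %s relative error",
                                    meth, an, grid_df$ratio[i]))
        }
      }
    }
  }
})

test_that("spectrum-subtraction routes conserve the mixture pointwise", {
  mix <- noiseless_mixture(9, 5)
  for (meth in c("RS_SS", "CM_SS", "FC_SS")) {
    res <- resolve_mixture(mix, meth, test_models, test_calib)
    total <- res$resolved$TCB$value + res$resolved$LVM$value
    expect_lt(max(abs(total - mix$value)), 1e-10, label = meth)
  }
  d_mix <- sp_derivative(mix)
  for (meth in c("DS_SS", "D1CM_SS", "D1FC_SS")) {
    res <- resolve_mixture(mix, meth, test_models, test_calib)
    total <- res$resolved$TCB$value + res$resolved$LVM$value
    expect_lt(max(abs(total - d_mix$value)), 1e-10, label = meth)
  }
})

test_that("degenerate one-component mixtures resolve to zero for the other", {
  pure_tcb <- noiseless_mixture(10, 0)
  res <- resolve_mixture(pure_tcb, "RS_SS", test_models, test_calib)
  expect_lt(max(abs(res$resolved$LVM$value)), 1e-12)
  expect_equal(res$resolved$TCB$value, pure_tcb$value, tolerance = 1e-12)

  pure_lvm <- noiseless_mixture(0, 10)
  # a near-zero plateau mean makes the flatness RSD meaningless; the
  # warning is expected here
  res_cm <- suppressWarnings(
    resolve_cm_ss(pure_lvm,
                  component_spectrum(test_models$TCB, 5, test_grid),
                  test_calib))
  expect_lt(abs(res_cm$constants$plateau$value), 1e-10)
  expect_lt(max(abs(res_cm$resolved$TCB$value)), 1e-10)

  # DD1 with the divisor's own component only: the ratio is constant, the
  # derivative vanishes, the other analyte reads zero
  res_dd1 <- resolve_mixture(pure_lvm, "DD1", test_models, test_calib)
  expect_lt(abs(res_dd1$concentrations$TCB[["DD1@P230-220"]]), 1e-8)
  expect_lt(rel_err(res_dd1$concentrations$LVM[["DD1@P219"]], 10), 1e-6)
})

test_that("DD1 response is linear in the measured component", {
  div_lvm <- component_spectrum(test_models$LVM, 4, test_grid)
  p <- response_descriptor("peak_to_peak", 1, 230, 220)
  read_tcb <- function(tcb_conc) {
    mix <- noiseless_mixture(tcb_conc, 7)
    read_response(sp_derivative(sp_divide(mix, div_lvm)), p)
  }
  expect_equal(read_tcb(12), 2 * read_tcb(6), tolerance = 1e-9)
})

test_that("plateau constants scale as 1/divisor and recoveries are
           divisor-invariant", {
  mix <- noiseless_mixture(10, 10)
  for (meth in c("RS_SS", "CM_SS")) {
    cfg <- default_method_config(meth)
    k <- list()
    for (dc in c(2.5, 5)) {
      div <- component_spectrum(test_models$TCB, dc, test_grid)
      fn <- if (meth == "RS_SS") resolve_rs_ss else resolve_cm_ss
      res <- fn(mix, div, test_calib, cfg)
      k[[as.character(dc)]] <- res$constants$plateau$value
      for (an in names(res$concentrations)) {
        for (found in res$concentrations[[an]]) {
          expect_lt(rel_err(found, 10), 1e-6,
                    label = sprintf("%s divisor %g", meth, dc))
        }
      }
    }
    expect_equal(k[["2.5"]], 2 * k[["5"]], tolerance = 1e-10)
  }
})

test_that("the D1 plateau equals the D0 plateau (derivative preserves ratios)", {
  mix <- noiseless_mixture(10, 4)
  div <- component_spectrum(test_models$TCB, 5, test_grid)
  k0 <- plateau_constant(sp_divide(mix, div), c(290, 306))
  k1 <- plateau_constant(sp_divide(sp_derivative(mix), sp_derivative(div)),
                         c(280, 315))
  expect_equal(k1$value, k0$value, tolerance = 1e-9)
  expect_equal(k0$value, 2, tolerance = 1e-10)
})

test_that("factorized-route bias under reference-wavelength leakage has the
           closed form leak/response", {
  # give the LVM-like component a deliberate small band at 304 nm
  leaky_lvm <- component_model("LVM", rbind(
    test_models$LVM$bands,
    data.frame(center = 304, sigma = 6, height = 0.001)))
  models2 <- list(TCB = test_models$TCB, LVM = leaky_lvm)
  c_tcb <- 10; c_lvm <- 8
  mix <- mixture_spectrum(models2, c(TCB = c_tcb, LVM = c_lvm), test_grid)
  fact <- sp_factorize(component_spectrum(test_models$TCB, 10, test_grid),
                       304)
  res <- suppressWarnings(
    resolve_fc_ss(mix, fact, test_calib,
                  interferent = component_spectrum(leaky_lvm, c_lvm,
                                                   test_grid)))
  leak <- c_lvm * 0.001 # AU contributed by LVM at 304 nm
  bias_expected <- leak / unit_response(test_models$TCB, 304)
  found <- res$concentrations$TCB[["D0@304"]]
  expect_equal(found - c_tcb, bias_expected, tolerance = 1e-6)
  expect_warning(
    resolve_fc_ss(mix, fact, test_calib,
                  interferent = component_spectrum(leaky_lvm, c_lvm,
                                                   test_grid)),
    "zero-contribution")
})

test_that("CNV reads the concentration directly and CV agrees through its
           identity regression", {
  norm_div <- sp_normalize(component_spectrum(test_models$TCB, 10, test_grid),
                           10)
  cv_curve <- test_calib$TCB$CV
  for (tcb in c(4, 10, 18)) {
    mix <- noiseless_mixture(tcb, 6)
    cnv <- resolve_cnv(mix, norm_div)
    cv <- resolve_cv(mix, norm_div, cv_curve)
    expect_lt(rel_err(cnv$concentrations$TCB[["CNV"]], tcb), 1e-10)
    expect_lt(abs(cv$concentrations$TCB[["CV"]] -
                    cnv$concentrations$TCB[["CNV"]]) / tcb, 0.005)
  }
  # no extended component: the plateau, and hence the read, is ~0 (its
  # flatness warning is expected at zero mean)
  mix0 <- noiseless_mixture(0, 10)
  cnv0 <- suppressWarnings(resolve_cnv(mix0, norm_div))
  expect_lt(abs(cnv0$concentrations$TCB[["CNV"]]), 1e-10)
})

test_that("configurations loaded from the bundled YAML reproduce the
           defaults", {
  path <- system.file("extdata", "tcb_lvm.yaml", package = "specres")
  cfgs <- load_method_config(path)
  expect_setequal(names(cfgs), all_methods)
  for (meth in all_methods) {
    ref <- default_method_config(meth)
    got <- cfgs[[meth]]
    expect_equal(got$plateau_region, ref$plateau_region, label = meth)
    expect_equal(got$factorization_ref, ref$factorization_ref, label = meth)
    expect_equal(sort(unlist(got$responses)), sort(unlist(ref$responses)),
                 label = meth)
  }
  expect_equal(cfgs$DD1$divisor_conc[["LVM"]], 4)
  expect_equal(cfgs$DD1$divisor_conc[["TCB"]], 3)

  mix <- noiseless_mixture(6, 8)
  res <- resolve_mixture(mix, "RS_SS", test_models, test_calib,
                         cfg = cfgs$RS_SS)
  expect_lt(rel_err(res$concentrations$TCB[["D0@304"]], 6), 1e-6)
})
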