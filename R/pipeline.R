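#' Sequential dilution arithmetic for a dosage form
#'
#' Starting from a labelled concentration in mg/mL, applies each
#' `(aliquot, final volume)` step as a factor `aliquot / final`, returning
#' the working concentration in ug/mL. The suspension assay's two steps
#' (1 mL into 100 mL, then 1 mL into 50 mL) take a 120 mg/mL label to a
#' 1200.0 ug/mL stock and a 24.0 ug/mL working solution.
#'
#' @param label_mg_per_ml labelled concentration, mg/mL.
#' @param steps list of `c(aliquot_ml, final_ml)` pairs; every aliquot
#'   must not exceed its final volume.
#' @return numeric vector of the concentration (ug/mL) after each step.
#' @examples
#' dilution_chain(120, list(c(1, 100), c(1, 50))) # 1200, 24
#' @export
dilution_chain <- function(label_mg_per_ml, steps) {
  stopifnot(label_mg_per_ml > 0, length(steps) >= 1L)
  conc <- label_mg_per_ml * 1000 # ug/mL
  out <- numeric(length(steps))
  for (i in seq_along(steps)) {
    st <- steps[[i]]
    if (length(st) != 2L || any(st <= 0) || st[1] > st[2]) {
      stop("each step must be c(aliquot, final) with 0 < aliquot <= final",
           call. = FALSE)
    }
    conc <- conc * st[1] / st[2]
    out[i] <- conc
  }
  out
}

#' Run the full comparative study
#'
#' Orchestrates the workflow end to end on synthetic spectra: fit the
#' calibration set from pure standards, simulate replicate mixtures at
#' every ratio of the specificity grid (plus, optionally, the dosage-form
#' working mixture), resolve each with every requested route, and compile
#' recovery, calibration, method-comparison and greenness blocks.
#'
#' @param models component models (default [default_models()]).
#' @param grid wavelength grid.
#' @param ratios data frame with `tcb`/`lvm` concentrations per mixture
#'   (default [table_ratio_grid()]).
#' @param methods routes to run (default all nine).
#' @param replicates replicate mixtures per cell (default 3).
#' @param noise_sd photometric noise on each mixture spectrum, AU.
#' @param seed RNG seed for reproducibility.
#' @param dosage optional list `list(tcb = , lvm = )` of working
#'   concentrations (ug/mL) for a dosage-form scenario cell.
#' @return list of class `study_report` with elements `recoveries` (long
#'   data frame: method, ratio, analyte, response, replicate, taken,
#'   found, recovery_pct), `summary` (mean/SD per cell), `calibration`
#'   (per-curve slope/intercept/r/LOD/LOQ), `comparison` (t/F of every
#'   method vs the first, plus single-factor ANOVA across methods) and
#'   `greenness`.
#' @export
run_study <- function(models = default_models(), grid = default_grid(),
                      ratios = table_ratio_grid(),
                      methods = c("RS_SS", "CM_SS", "FC_SS", "DS_SS",
                                  "D1CM_SS", "D1FC_SS", "DD1", "CV", "CNV"),
                      replicates = 3, noise_sd = 0, seed = NULL,
                      dosage = NULL) {
  if (!is.null(seed)) set.seed(seed)
  calib <- build_calibrations(models, grid)
  if (!is.null(dosage)) {
    ratios <- rbind(ratios[, c("tcb", "lvm")],
                    data.frame(tcb = dosage$tcb, lvm = dosage$lvm))
    ratios$ratio <- paste0(ratios$tcb, ":", ratios$lvm)
    ratios$dosage_form <- c(rep(FALSE, nrow(ratios) - 1L), TRUE)
  }
  rows <- list()
  for (m in methods) {
    for (i in seq_len(nrow(ratios))) {
      taken <- c(TCB = ratios$tcb[i], LVM = ratios$lvm[i])
      for (rep_i in seq_len(replicates)) {
        mix <- mixture_spectrum(models, taken, grid, noise_sd = noise_sd)
        notes <- character()
        res <- withCallingHandlers(
          tryCatch(resolve_mixture(mix, m, models, calib),
                   error = function(e) e),
          warning = function(w) { # collect plateau-drift diagnostics
            notes <<- c(notes, conditionMessage(w))
            invokeRestart("muffleWarning")
          }
        )
        if (inherits(res, "error")) {
          rows[[length(rows) + 1L]] <- data.frame(
            method = m, ratio = ratios$ratio[i], analyte = NA,
            response = NA, replicate = rep_i, taken = NA, found = NA,
            recovery_pct = NA, note = conditionMessage(res))
          next
        }
        for (an in names(res$concentrations)) {
          found <- res$concentrations[[an]]
          rows[[length(rows) + 1L]] <- data.frame(
            method = m, ratio = ratios$ratio[i], analyte = an,
            response = names(found), replicate = rep_i,
            taken = taken[[an]], found = as.numeric(found),
            recovery_pct = recovery(as.numeric(found), taken[[an]]),
            note = paste(unique(notes), collapse = "; "))
        }
      }
    }
  }
  recoveries <- do.call(rbind, rows)
  ok <- !is.na(recoveries$recovery_pct)
  summary_df <- stats::aggregate(
    recovery_pct ~ method + ratio + analyte + response,
    data = recoveries[ok, ],
    FUN = function(v) c(mean = mean(v), sd = stats::sd(v)))
  summary_df <- cbind(summary_df[, 1:4],
                      mean = summary_df$recovery_pct[, "mean"],
                      sd = summary_df$recovery_pct[, "sd"])
  calib_rows <- list()
  for (an in names(calib)) {
    for (key in names(calib[[an]])) {
      cc <- calib[[an]][[key]]
      calib_rows[[length(calib_rows) + 1L]] <- data.frame(
        analyte = an, response = key, slope = cc$slope,
        intercept = cc$intercept, r = cc$r, range_lo = cc$range[1],
        range_hi = cc$range[2], lod = cc$lod, loq = cc$loq)
    }
  }
  # primary-response recoveries per method feed the t/F/ANOVA block
  primary <- recoveries[ok & recoveries$analyte == "TCB", ]
  groups <- split(primary$recovery_pct, primary$method)
  groups <- groups[lengths(groups) >= 2L]
  comparison <- NULL
  if (length(groups) >= 2L && stats::sd(unlist(groups)) > 0) {
    refname <- names(groups)[1]
    cmp <- lapply(names(groups)[-1], function(nm) {
      ct <- tryCatch(compare_methods(groups[[refname]], groups[[nm]]),
                     error = function(e) NULL) # e.g. noiseless constants
      if (is.null(ct)) return(NULL)
      data.frame(reference = refname, method = nm, t = ct$t,
                 t_crit = ct$t_crit, f = ct$f, f_crit = ct$f_crit,
                 significant = ct$significant_t | ct$significant_f)
    })
    cmp <- cmp[!vapply(cmp, is.null, logical(1))]
    if (length(cmp)) {
      comparison <- list(pairwise = do.call(rbind, cmp),
                         anova = anova_single_factor(groups))
    }
  }
  structure(
    list(recoveries = recoveries, summary = summary_df,
         calibration = do.call(rbind, calib_rows),
         comparison = comparison,
         greenness = list(eco_scale = eco_scale(reference_eco_profile()),
                          nemi = nemi(FALSE, TRUE, 5, 10))),
    class = "study_report"
  )
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study report>\n")
  cat(sprintf("  %d recovery measurements over %d method(s)\n",
              sum(!is.na(x$recoveries$recovery_pct)),
              length(unique(x$recoveries$method))))
  cat(sprintf("  eco-scale score %d (%s)\n", x$greenness$eco_scale$score,
              x$greenness$eco_scale$grade))
  invisible(x)
}

#' Write a study report to disk
#'
#' Recoveries, per-cell summary and calibration tables as CSV; the
#' comparison and greenness blocks as JSON.
#'
#' @param report a [run_study()] result.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_study_report <- function(report, dir) {
  stopifnot(inherits(report, "study_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$recoveries, file.path(dir, "recoveries.csv"),
                   row.names = FALSE)
  utils::write.csv(report$summary, file.path(dir, "summary.csv"),
                   row.names = FALSE)
  utils::write.csv(report$calibration, file.path(dir, "calibration.csv"),
                   row.names = FALSE)
  blob <- list(
    comparison = if (!is.null(report$comparison)) list(
      pairwise = report$comparison$pairwise,
      anova = report$comparison$anova$table,
      anova_p = report$comparison$anova$p_value) else NULL,
    greenness = list(
      eco_scale = report$greenness$eco_scale[c("score", "grade")],
      eco_penalties = report$greenness$eco_scale$penalties,
      nemi = as.list(report$greenness$nemi))
  )
  jsonlite::write_json(blob, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Load a method configuration from YAML
#'
#' Reads a key-value file mirroring [method_config()]; the bundled
#' `tcb_lvm.yaml` (see `system.file("extdata", "tcb_lvm.yaml", package =
#' "specres")`) reproduces the study's wavelengths and divisors.
#'
#' @param path YAML file path.
#' @param method optional route name; when the file holds several method
#'   blocks under `methods:`, selects one.
#' @return A `method_config` (or named list of them when `method` is
#'   `NULL` and the file holds several).
#' @export
load_method_config <- function(path, method = NULL) {
  raw <- yaml::read_yaml(path)
  blocks <- if (!is.null(raw$methods)) raw$methods else
    stats::setNames(list(raw), raw$method)
  build <- function(b) {
    dc <- b$divisor_conc
    if (is.list(dc)) dc <- unlist(dc)
    method_config(
      b$method,
      extended = if (!is.null(b$extended)) b$extended else "TCB",
      other = if (!is.null(b$other)) b$other else "LVM",
      divisor_conc = dc,
      plateau_region = if (!is.null(b$plateau_region))
        as.numeric(b$plateau_region),
      factorization_ref = b$factorization_ref,
      responses = lapply(b$responses, unlist),
      delta_lambda = if (!is.null(b$delta_lambda)) b$delta_lambda else 4,
      scale = if (!is.null(b$scale)) b$scale else 10
    )
  }
  if (!is.null(method)) {
    hit <- blocks[[method]]
    if (is.null(hit)) stop("no config block for method ", method,
                           call. = FALSE)
    return(build(hit))
  }
  if (length(blocks) == 1L) build(blocks[[1]]) else lapply(blocks, build)
}

#' Load an Eco-Scale profile from YAML
#'
#' @param path YAML file with `reagents` (list of name/pictograms/
#'   signal_word/amount_class), `energy_class`, `occupational_hazard`,
#'   `waste_amount_class`, `waste_treatment`.
#' @return An [eco_scale_profile()].
#' @export
load_eco_profile <- function(path) {
  raw <- yaml::read_yaml(path)
  reagents <- do.call(rbind, lapply(raw$reagents, as.data.frame))
  eco_scale_profile(
    reagents = reagents,
    energy_class = raw$energy_class,
    occupational_hazard = isTRUE(raw$occupational_hazard),
    waste_amount_class = raw$waste_amount_class,
    waste_treatment = raw$waste_treatment
  )
}
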