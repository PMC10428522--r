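#' Describe a procedure for Analytical Eco-Scale scoring
#'
#' Collects the reagent, instrument and waste descriptors that feed the
#' penalty-point scheme: each reagent carries its GHS pictogram count,
#' signal word and per-analysis amount class; the instrument its energy
#' class and whether it emits vapours; the waste its amount class and
#' treatment.
#'
#' @param reagents data frame with columns `name`, `pictograms` (>= 0),
#'   `signal_word` (`"none"`, `"warning"`, `"danger"`) and `amount_class`
#'   (`"<10"`, `"10-100"`, `">100"` mL or g per analysis).
#' @param energy_class instrument energy per sample: `"<=0.1"`, `"<=1.5"`
#'   or `">1.5"` kWh.
#' @param occupational_hazard `TRUE` when the process emits vapours into
#'   the working space.
#' @param waste_amount_class `"none"`, `"<1"`, `"1-10"` or `">10"` mL (g).
#' @param waste_treatment `"none"`, `"recycling"` or
#'   `"degradation_passivation"`.
#' @return An object of class `eco_scale_profile`.
#' @export
eco_scale_profile <- function(reagents,
                              energy_class = c("<=0.1", "<=1.5", ">1.5"),
                              occupational_hazard = FALSE,
                              waste_amount_class = c("none", "<1", "1-10", ">10"),
                              waste_treatment = c("none", "recycling",
                                                  "degradation_passivation")) {
  reagents <- as.data.frame(reagents)
  stopifnot(all(c("name", "pictograms", "signal_word", "amount_class")
                %in% names(reagents)),
            all(reagents$pictograms >= 0))
  if (!all(reagents$signal_word %in% c("none", "warning", "danger"))) {
    stop("signal_word must be one of none/warning/danger", call. = FALSE)
  }
  if (!all(reagents$amount_class %in% c("<10", "10-100", ">100"))) {
    stop("reagent amount_class must be one of <10, 10-100, >100",
         call. = FALSE)
  }
  structure(
    list(reagents = reagents, energy_class = match.arg(energy_class),
         occupational_hazard = isTRUE(occupational_hazard),
         waste_amount_class = match.arg(waste_amount_class),
         waste_treatment = match.arg(waste_treatment)),
    class = "eco_scale_profile"
  )
}

#' Analytical Eco-Scale score
#'
#' Penalty points (PPs) are summed over the profile and subtracted from
#' 100. A reagent's PP is its amount sub-PP (1, 2 or 3 for <10, 10-100,
#' >100 mL/g) times its hazard sub-PP (pictogram count times 1 for signal
#' word "warning" or 2 for "danger"; hazard-free reagents score 0).
#' Instrument energy adds 0/1/2 PPs by class, vapour emission 3, and
#' waste its amount PP (0/1/3/5) plus a treatment PP (recycling 0,
#' degradation or passivation 1, none 3 when waste exists). Scores above
#' 75 grade "excellent", above 50 "acceptable", otherwise "inadequate".
#'
#' @param profile an [eco_scale_profile()].
#' @return list with `score`, `grade`, and `penalties` (data frame of
#'   per-item penalty points).
#' @examples
#' p <- eco_scale_profile(
#'   reagents = data.frame(
#'     name = c("methanol", "HCl"),
#'     pictograms = c(3, 1),
#'     signal_word = c("danger", "danger"),
#'     amount_class = c("<10", "<10")),
#'   energy_class = "<=0.1",
#'   waste_amount_class = "1-10", waste_treatment = "recycling")
#' eco_scale(p)$score # 89
#' @export
eco_scale <- function(profile) {
  stopifnot(inherits(profile, "eco_scale_profile"))
  amount_pp <- c("<10" = 1, "10-100" = 2, ">100" = 3)
  word_mult <- c(none = 0, warning = 1, danger = 2)
  rg <- profile$reagents
  reagent_pps <- amount_pp[rg$amount_class] *
    (rg$pictograms * word_mult[rg$signal_word])
  energy_pp <- c("<=0.1" = 0, "<=1.5" = 1, ">1.5" = 2)[profile$energy_class]
  hazard_pp <- if (profile$occupational_hazard) 3 else 0
  waste_amount_pp <- c(none = 0, "<1" = 1, "1-10" = 3,
                       ">10" = 5)[profile$waste_amount_class]
  waste_treat_pp <- if (profile$waste_amount_class == "none") 0 else
    c(none = 3, recycling = 0,
      degradation_passivation = 1)[profile$waste_treatment]
  penalties <- data.frame(
    item = c(rg$name, "instrument energy", "occupational hazard", "waste"),
    pp = unname(c(reagent_pps, energy_pp, hazard_pp,
                  waste_amount_pp + waste_treat_pp))
  )
  score <- 100 - sum(penalties$pp)
  grade <- if (score > 75) "excellent" else if (score > 50) "acceptable"
    else "inadequate"
  list(score = score, grade = grade, penalties = penalties)
}

#' AGREE 12-principle greenness score
#'
#' Weighted mean of the twelve per-principle scores (each in [0, 1],
#' deep red to deep green); the reported value is conventionally rounded
#' to two decimals.
#'
#' @param scores numeric vector of exactly 12 principle scores in [0, 1].
#' @param weights optional positive weights (default equal).
#' @return list with `score` (unrounded) and `reported` (2 decimals).
#' @export
agree_score <- function(scores, weights = NULL) {
  if (length(scores) != 12L) {
    stop("AGREE needs exactly 12 principle scores", call. = FALSE)
  }
  if (any(scores < 0 | scores > 1)) {
    stop("principle scores must lie in [0, 1]", call. = FALSE)
  }
  if (is.null(weights)) weights <- rep(1, 12)
  if (length(weights) != 12L || any(weights <= 0)) {
    stop("weights must be 12 positive numbers", call. = FALSE)
  }
  sc <- sum(scores * weights) / sum(weights)
  list(score = sc, reported = round(sc, 2))
}

#' NEMI quadrant assessment
#'
#' The four National Environmental Methods Index quadrants are green when:
#' no reagent is PBT-listed (persistent/bioaccumulative/toxic); no reagent
#' is on the RCRA hazardous-waste lists; the sample pH stays in [2, 12]
#' (non-corrosive); and waste is below 50 g per sample (strict).
#'
#' @param pbt_listed any reagent on the PBT list?
#' @param hazardous_listed any reagent on the RCRA lists?
#' @param ph sample pH, in [0, 14].
#' @param waste_g_per_sample waste mass per sample in g, >= 0.
#' @return named logical vector of the four quadrants
#'   (`TRUE` = green, `FALSE` = blank).
#' @export
nemi <- function(pbt_listed, hazardous_listed, ph, waste_g_per_sample) {
  stopifnot(ph >= 0, ph <= 14, waste_g_per_sample >= 0)
  c(pbt = !isTRUE(pbt_listed),
    hazardous = !isTRUE(hazardous_listed),
    corrosive = ph >= 2 && ph <= 12,
    waste = waste_g_per_sample < 50)
}

#' The study's own Eco-Scale profile
#'
#' Methanol (3 pictograms, signal word Danger, under 10 mL per analysis),
#' dilute HCl (1 pictogram, Danger, under 10 mL), a spectrophotometer in
#' the lowest energy class, no vapour emission, and 1-10 mL of waste
#' recycled by distillation.
#'
#' @return An [eco_scale_profile()].
#' @export
reference_eco_profile <- function() {
  eco_scale_profile(
    reagents = data.frame(
      name = c("methanol", "HCl"),
      pictograms = c(3, 1),
      signal_word = c("danger", "danger"),
      amount_class = c("<10", "<10")
    ),
    energy_class = "<=0.1",
    occupational_hazard = FALSE,
    waste_amount_class = "1-10",
    waste_treatment = "recycling"
  )
}
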