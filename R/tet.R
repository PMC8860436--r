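# Tetracycline dosimetry: effective exposure with maternal carryover and the
# dose-response of female survival through the X-linked female-lethal circuit.
#
# Tetracycline in the food represses the tTA positive-feedback circuit that
# kills females; Tet deposited maternally in oocytes carries part of the
# mother's exposure into the next generation, which delays female lethality
# by one generation at high rearing concentrations.

#' Tetracycline dose-response parameters
#'
#' @param kappa maternal carryover fraction: the share of the mother's
#'   effective exposure deposited in her oocytes (dimensionless, in (0,1)).
#' @param ec50 half-maximal effective exposure of the female-survival Hill
#'   curve (ug/ml-equivalent).
#' @param hill_h Hill coefficient (> 0).
#' @param s_max maximum relative female survival at saturating Tet; values
#'   below 1 encode the residual leak of the female-lethal transgene (the
#'   male-biased sex ratio seen even on Tet food).
#' @param e_floor exposure below which the circuit fires fully and female
#'   survival is exactly 0 (ug/ml-equivalent); also the repression threshold
#'   for the RIDL cassette.
#' @return An object of class \code{tet_params}.
#' @examples
#' tet_params()
#' @export
tet_params <- function(kappa = 0.07, ec50 = 6.0, hill_h = 2.0,
                       s_max = 0.85, e_floor = 2.0) {
  stopifnot(is.numeric(kappa), kappa > 0, kappa < 1,
            is.numeric(e_floor), e_floor > 0,
            is.numeric(ec50), ec50 > e_floor,
            is.numeric(hill_h), hill_h > 0,
            is.numeric(s_max), s_max > 0, s_max <= 1)
  structure(list(kappa = kappa, ec50 = ec50, hill_h = hill_h,
                 s_max = s_max, e_floor = e_floor),
            class = "tet_params")
}

#' @export
print.tet_params <- function(x, ...) {
  cat("Tet dose-response parameters:\n",
      sprintf("  kappa (maternal carryover) = %g\n", x$kappa),
      sprintf("  ec50 = %g, Hill h = %g, s_max = %g\n", x$ec50, x$hill_h,
              x$s_max),
      sprintf("  e_floor (hard lethality threshold) = %g ug/ml-equiv\n",
              x$e_floor), sep = "")
  invisible(x)
}

#' Effective tetracycline exposure of an offspring
#'
#' The exposure an individual experiences is its own food concentration plus
#' the maternally deposited fraction \code{kappa} of its mother's exposure:
#' \code{E = food_tet + kappa * maternal_E}.
#'
#' @param food_tet food tetracycline concentration (ug/ml), >= 0.
#' @param maternal_E the mother's effective exposure (ug/ml-equivalent),
#'   >= 0.
#' @param p a [tet_params()] object.
#' @return Effective exposure in ug/ml-equivalents (vectorised).
#' @export
effective_exposure <- function(food_tet, maternal_E, p = tet_params()) {
  if (!is.numeric(food_tet) || !is.numeric(maternal_E) ||
      any(is.na(food_tet)) || any(is.na(maternal_E)) ||
      any(food_tet < 0) || any(maternal_E < 0))
    stop("food_tet and maternal_E must be non-negative numbers",
         call. = FALSE)
  food_tet + p$kappa * maternal_E
}

#' Steady-state exposure of a stock maintained at constant food Tet
#'
#' Iterating \code{E_child = food_tet + kappa * E_mother} over generations
#' converges geometrically to the fixed point \code{food_tet / (1 - kappa)},
#' the exposure carried by a long-maintained laboratory stock.
#'
#' @inheritParams effective_exposure
#' @return The fixed-point exposure (ug/ml-equivalent, vectorised).
#' @examples
#' rearing_steady_state(100) # 107.527
#' @export
rearing_steady_state <- function(food_tet, p = tet_params()) {
  if (!is.numeric(food_tet) || any(is.na(food_tet)) || any(food_tet < 0))
    stop("food_tet must be non-negative", call. = FALSE)
  food_tet / (1 - p$kappa)
}

#' Female survival through the female-lethal circuit
#'
#' Relative survival of an FL-bearing female at effective exposure \code{E}:
#' exactly 0 below the hard threshold \code{e_floor} (the circuit fires
#' fully), otherwise the Hill curve
#' \code{s_max * E^h / (ec50^h + E^h)}.  Males, and females without an FL
#' allele, are unaffected (survival multiplier 1, handled by callers).
#'
#' @param E effective exposure (ug/ml-equivalent), >= 0; vectorised.
#' @param p a [tet_params()] object.
#' @return Survival probability in [0, s_max].
#' @export
female_survival <- function(E, p = tet_params()) {
  if (!is.numeric(E) || any(is.na(E)) || any(E < 0))
    stop("E must be non-negative", call. = FALSE)
  s <- p$s_max * E^p$hill_h / (p$ec50^p$hill_h + E^p$hill_h)
  s[E < p$e_floor] <- 0
  s
}

#' Expected adult female fraction given relative female survival
#'
#' With a 50:50 zygotic sex ratio and male survival 1, a relative female
#' survival of \code{S} yields an adult female fraction of
#' \code{S / (1 + S)}.
#'
#' @param S relative female survival in [0, 1]; vectorised.
#' @return Expected fraction of females among surviving adults.
#' @export
adult_female_fraction <- function(S) {
  if (!is.numeric(S) || any(is.na(S)) || any(S < 0) || any(S > 1))
    stop("S must be in [0, 1]", call. = FALSE)
  S / (1 + S)
}

#' Check the dose-response calibration against its empirical anchors
#'
#' Evaluates the model-predicted adult female fraction at the four anchor
#' conditions: (1) a stock maintained on 10 ug/ml Tet (target 0.40-0.45);
#' (2) mothers at the 100 ug/ml steady state with offspring on Tet-free food
#' (target 0.35); (3) mothers at the 10 ug/ml steady state with offspring on
#' Tet-free food (target 0: no surviving females); (4) the second Tet-free
#' generation after 100 ug/ml rearing (target 0: complete female lethality).
#'
#' @param p a [tet_params()] object.
#' @return A data frame with one row per anchor: \code{condition},
#'   \code{predicted}, \code{target}, \code{residual} (predicted - target;
#'   for the interval anchor, distance outside the interval).
#' @export
check_anchors <- function(p = tet_params()) {
  ss10 <- rearing_steady_state(10, p)
  ss100 <- rearing_steady_state(100, p)
  # F1 off Tet after 100-rearing; then F2 off Tet
  e_f1_100 <- effective_exposure(0, ss100, p)
  e_f2_100 <- effective_exposure(0, e_f1_100, p)
  e_f1_10 <- effective_exposure(0, ss10, p)
  pred <- c(
    adult_female_fraction(female_survival(ss10, p)),
    adult_female_fraction(female_survival(e_f1_100, p)),
    adult_female_fraction(female_survival(e_f1_10, p)),
    adult_female_fraction(female_survival(e_f2_100, p))
  )
  target_lo <- c(0.40, 0.35, 0.00, 0.00)
  target_hi <- c(0.45, 0.35, 0.00, 0.00)
  residual <- ifelse(pred < target_lo, pred - target_lo,
                     ifelse(pred > target_hi, pred - target_hi, 0))
  data.frame(
    condition = c("stock on 10 ug/ml",
                  "mothers @100 steady state, offspring Tet-free",
                  "mothers @10 steady state, offspring Tet-free",
                  "second Tet-free generation after 100 ug/ml"),
    predicted = pred,
    target = c("0.40-0.45", "0.35", "0", "0"),
    residual = residual,
    stringsAsFactors = FALSE
  )
}

#' Simulate adult sex ratio and female lethality in a zygote cohort
#'
#' Draws a cohort of zygotes at a 50:50 sex ratio from an FL-homozygous
#' (SSIMS-type) stock, applies the female-survival dose-response given the
#' maternal exposure and the rearing food, and tallies survivors.  Males are
#' unaffected by the female-lethal circuit.
#'
#' @param n number of zygotes (>= 1).
#' @param maternal_E the mothers' effective exposure (ug/ml-equivalent).
#' @param food_tet food Tet concentration experienced by the cohort (ug/ml).
#' @param p a [tet_params()] object.
#' @return A list with \code{n_female_zygotes}, \code{n_male_zygotes},
#'   \code{n_female_adults}, \code{n_male_adults},
#'   \code{female_lethality_pct} (among female zygotes) and
#'   \code{adult_female_pct} (among surviving adults), plus the cohort
#'   exposure \code{E}.
#' @examples
#' set.seed(1)
#' simulate_sex_ratio(2000, maternal_E = rearing_steady_state(100),
#'                    food_tet = 0)
#' @export
simulate_sex_ratio <- function(n, maternal_E, food_tet, p = tet_params()) {
  stopifnot(is.numeric(n), length(n) == 1L, n >= 1)
  n <- as.integer(n)
  E <- effective_exposure(food_tet, maternal_E, p)
  n_f <- stats::rbinom(1L, n, 0.5)
  n_m <- n - n_f
  s <- female_survival(E, p)
  n_f_adult <- if (s == 0) 0L else stats::rbinom(1L, n_f, s)
  list(
    E = E,
    n_female_zygotes = n_f,
    n_male_zygotes = n_m,
    n_female_adults = n_f_adult,
    n_male_adults = n_m,
    female_lethality_pct = 100 * (1 - n_f_adult / n_f),
    adult_female_pct = 100 * n_f_adult / (n_f_adult + n_m)
  )
}
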