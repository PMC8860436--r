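# Daily-time-step agent-based model of a Spotted Wing Drosophila population
# under scheduled releases of engineered biocontrol agents.
#
# The population is held in a column-oriented store (parallel atomic
# vectors) rather than one object per fly; all daily dynamics are
# vectorised.  Allele coding (integers): X slot 0 = Y/absent, 1 = "+",
# 2 = "FL"; pyr 1 = "wt", 2 = "res"; pta 1 = "+", 2 = "PTA";
# ridl 1 = "+", 2 = "RIDL".  Stages: 1 egg, 2 larva, 3 pupa, 4 adult.
# Sex: 1 female, 2 male.  Origin: 1 wild, 2 released, 3 field-born.

.CLASS_LEVELS  <- c("WT", "SSIMS", "EGI", "FL", "RIDL", "OTHER")
.SEX_LEVELS    <- c("female", "male")
.STAGE_LEVELS  <- c("egg", "larva", "pupa", "adult")
.ORIGIN_LEVELS <- c("wild", "released", "field")

.POP_COLS <- c("sex", "stage", "x1", "x2", "pyr1", "pyr2", "pta1", "pta2",
               "ridl1", "ridl2", "gen", "origin")

.pop_empty <- function() {
  p <- stats::setNames(rep(list(integer(0)), length(.POP_COLS)), .POP_COLS)
  p$dd <- numeric(0); p$E <- numeric(0); p$adage <- integer(0)
  p
}

.pop_n <- function(pop) length(pop$sex)

.pop_bind <- function(a, b) {
  for (nm in names(a)) a[[nm]] <- c(a[[nm]], b[[nm]])
  a
}

.pop_subset <- function(pop, keep) {
  for (nm in names(pop)) pop[[nm]] <- pop[[nm]][keep]
  pop
}

# vectorised strain classification -> integer codes into .CLASS_LEVELS
.classify_codes <- function(pop) {
  n <- .pop_n(pop)
  if (n == 0L) return(integer(0))
  has_fl  <- pop$x1 == 2L | pop$x2 == 2L
  all_fl  <- pop$x1 == 2L & (pop$sex == 2L | pop$x2 == 2L)
  any_res <- pop$pyr1 == 2L | pop$pyr2 == 2L
  res_hom <- pop$pyr1 == 2L & pop$pyr2 == 2L
  any_pta <- pop$pta1 == 2L | pop$pta2 == 2L
  pta_hom <- pop$pta1 == 2L & pop$pta2 == 2L
  has_rdl <- pop$ridl1 == 2L | pop$ridl2 == 2L
  cl <- rep(6L, n)                                   # OTHER
  cl[has_rdl] <- 5L                                  # RIDL
  cl[has_fl & !any_pta] <- 4L                        # FL
  cl[!has_fl & res_hom & pta_hom] <- 3L              # EGI
  cl[all_fl & res_hom & pta_hom] <- 2L               # SSIMS
  cl[!has_fl & !any_pta & !any_res & !has_rdl] <- 1L # WT
  cl
}

# choose a or b elementwise with probability 1/2 (meiotic segregation)
.pick <- function(a, b) {
  sel <- stats::runif(length(a)) < 0.5
  a[sel] <- b[sel]
  a
}

.sire_row <- function(pop, j) {
  c(pop$x1[j], pop$pyr1[j], pop$pyr2[j], pop$pta1[j], pop$pta2[j],
    pop$ridl1[j], pop$ridl2[j])
}

.store_add <- function(store, sire_row, p2) {
  if (is.null(store)) {
    list(w = 1, g = matrix(sire_row, nrow = 1L))
  } else {
    list(w = c(store$w * (1 - p2), p2),
         g = rbind(store$g, sire_row, deparse.level = 0))
  }
}

#' Update a female's sperm store after a mating (last-male precedence)
#'
#' The newest sire takes weight \code{p2}; all prior sires' weights are
#' scaled by \code{1 - p2}, so the weights always sum to 1.  Sire identity
#' may be any label (e.g. a genotype code).
#'
#' @param store a data frame with columns \code{sire} and \code{weight}, or
#'   \code{NULL} / zero rows for an unmated female.
#' @param new_sire label of the newest mate.
#' @param p2 last-male sperm precedence in [0, 1].
#' @return The updated store data frame (weights sum to 1).
#' @examples
#' s <- update_sperm_store(NULL, "A")
#' s <- update_sperm_store(s, "B", p2 = 0.8)   # A 0.2, B 0.8
#' update_sperm_store(s, "C", p2 = 0.8)        # A 0.04, B 0.16, C 0.8
#' @export
update_sperm_store <- function(store, new_sire, p2 = 0.8) {
  if (!is.numeric(p2) || length(p2) != 1L || p2 < 0 || p2 > 1)
    stop("p2 must be in [0, 1]", call. = FALSE)
  if (is.null(store) || nrow(store) == 0L)
    return(data.frame(sire = new_sire, weight = 1,
                      stringsAsFactors = FALSE))
  out <- data.frame(sire = c(store$sire, new_sire),
                    weight = c(store$weight * (1 - p2), p2),
                    stringsAsFactors = FALSE)
  out
}

#' Lifecycle (vital-rate) parameters for the field model
#'
#' Degree-day phenology with per-stage thermal requirements above a common
#' base temperature, temperature-dependent adult mortality and fecundity
#' (piecewise-linear in the daily mean), a constant juvenile background
#' mortality, and a larval carrying capacity acting on daily egg survival
#' via \code{1 / (1 + L / K)}.
#'
#' Adult mortality is \code{m_opt} on the thermal plateau
#' \code{[t_opt_lo, t_opt_hi]} and ramps linearly to \code{m_cold} at or
#' below \code{t_cold} and to \code{m_hot} at or above \code{t_hot}.  The
#' cold-side default reflects overwintered (winter-morph) adults, which
#' tolerate near-freezing spring temperatures well.  Fecundity is 0 at or
#' below \code{f_tmin}, peaks at \code{f_peak} eggs/female/day on
#' \code{[f_opt_lo, f_opt_hi]}, and falls to 0 at \code{f_tmax}.  All
#' heat-side knots are on the daily-mean scale: a daily mean near 24 C in
#' continental summer implies afternoon maxima near 30 C, the range where
#' oviposition stops and mortality of adults and of developing stages in
#' sun-exposed fruit rises sharply.  The default curves are calibrated so
#' an unmanaged population expands to tens of thousands by early July and
#' declines through the hot mid-summer.
#'
#' @param dd_base degree-day base temperature (C).
#' @param dd_egg,dd_larva,dd_pupa per-stage degree-day requirements.
#' @param juvenile_mortality daily background mortality of eggs/larvae/pupae
#'   at benign temperatures.
#' @param j_t_lo,j_t_hot,j_m_hot juvenile heat-mortality ramp: daily
#'   juvenile mortality holds the background value up to \code{j_t_lo} and
#'   rises linearly to \code{j_m_hot} at or beyond \code{j_t_hot}
#'   (developing stages in sun-exposed fruit are highly heat-sensitive).
#' @param m_opt,t_opt_lo,t_opt_hi adult daily mortality on the plateau and
#'   the plateau bounds (C).
#' @param m_cold,t_cold cold-end adult mortality and its temperature.
#' @param m_hot,t_hot hot-end adult mortality and its temperature.
#' @param f_peak peak fecundity (eggs/female/day).
#' @param f_tmin,f_opt_lo,f_opt_hi,f_tmax fecundity curve knots (C).
#' @param K larval carrying capacity.
#' @param max_adult_days maximum adult lifespan in active days (days whose
#'   mean temperature exceeds \code{dd_base}; cool days do not age an
#'   overwintering adult).
#' @param init_adults wild adults seeded on day 1 (50:50, females mated).
#' @return An object of class \code{lifecycle_params}.
#' @export
lifecycle_params <- function(dd_base = 7.2,
                             dd_egg = 20, dd_larva = 120, dd_pupa = 130,
                             juvenile_mortality = 0.01,
                             j_t_lo = 20, j_t_hot = 27, j_m_hot = 0.35,
                             m_opt = 0.03, t_opt_lo = 12, t_opt_hi = 20,
                             m_cold = 0.03, t_cold = 0,
                             m_hot = 0.28, t_hot = 26,
                             f_peak = 12, f_tmin = 8, f_opt_lo = 14,
                             f_opt_hi = 20, f_tmax = 23,
                             K = 8000, max_adult_days = 50,
                             init_adults = 350) {
  stopifnot(dd_egg > 0, dd_larva > 0, dd_pupa > 0,
            juvenile_mortality >= 0, juvenile_mortality <= 1,
            j_m_hot >= 0, j_m_hot <= 1, j_t_hot > j_t_lo,
            m_opt >= 0, m_opt <= 1, m_cold >= 0, m_cold <= 1,
            m_hot >= 0, m_hot <= 1,
            t_cold < t_opt_lo, t_opt_lo <= t_opt_hi, t_opt_hi < t_hot,
            f_peak >= 0, f_tmin < f_opt_lo, f_opt_lo <= f_opt_hi,
            f_opt_hi < f_tmax, K > 0, max_adult_days >= 1,
            init_adults >= 0)
  structure(as.list(environment()), class = "lifecycle_params")
}

#' Adult daily mortality as a function of temperature
#' @param temp daily mean temperature (C); vectorised.
#' @param lp a [lifecycle_params()] object.
#' @return Daily mortality probability.
#' @export
adult_mortality_rate <- function(temp, lp = lifecycle_params()) {
  stats::approx(x = c(lp$t_cold, lp$t_opt_lo, lp$t_opt_hi, lp$t_hot),
                y = c(lp$m_cold, lp$m_opt, lp$m_opt, lp$m_hot),
                xout = temp, rule = 2)$y
}

#' Juvenile daily mortality as a function of temperature
#' @inheritParams adult_mortality_rate
#' @return Daily mortality probability of eggs, larvae and pupae.
#' @export
juvenile_mortality_rate <- function(temp, lp = lifecycle_params()) {
  stats::approx(x = c(lp$j_t_lo, lp$j_t_hot),
                y = c(lp$juvenile_mortality, lp$j_m_hot),
                xout = temp, rule = 2)$y
}

#' Per-female daily fecundity as a function of temperature
#' @inheritParams adult_mortality_rate
#' @return Expected eggs per mated female per day.
#' @export
fecundity_rate <- function(temp, lp = lifecycle_params()) {
  stats::approx(x = c(lp$f_tmin, lp$f_opt_lo, lp$f_opt_hi, lp$f_tmax),
                y = c(0, lp$f_peak, lp$f_peak, 0),
                xout = temp, rule = 2)$y
}

#' Mating-system parameters
#'
#' @param p_mate_virgin daily mating probability of a virgin female when at
#'   least one adult male is present.
#' @param p_remate daily remating probability of a mated female.
#' @param p2 last-male sperm precedence (share of subsequent fertilisations
#'   won by the most recent mate).
#' @return An object of class \code{mating_params}.
#' @export
mating_params <- function(p_mate_virgin = 0.8, p_remate = 0.03, p2 = 0.8) {
  stopifnot(p_mate_virgin >= 0, p_mate_virgin <= 1,
            p_remate >= 0, p_remate <= 1, p2 >= 0, p2 <= 1)
  structure(list(p_mate_virgin = p_mate_virgin, p_remate = p_remate,
                 p2 = p2), class = "mating_params")
}

#' Release strategy
#'
#' Defines which engineered strain is released, how it was reared and
#' hatched (which fixes the released sex composition and the females'
#' carried Tet exposure), the per-event size \code{n}, the interval
#' \code{interval} in days, and an optional release window.
#'
#' Kinds: \code{"none"}; \code{"RIDL"} (bi-sex homozygous dominant-lethal);
#' \code{"FL"} (bi-sex female-lethal line, reared at 100 ug/ml);
#' \code{"SSIMS_male_only"} (reared at 10, hatched Tet-free, so only males
#' emerge); \code{"SSIMS_single_amp"} (reared and hatched at 10: bi-sex, one
#' male-only field generation possible); \code{"SSIMS_double_amp"} (reared
#' and hatched at 100: bi-sex, two field generations possible).
#'
#' @param kind strategy kind (see above).
#' @param n agents per release event (>= 0).
#' @param interval days between release events (>= 1).
#' @param rearing_tet,hatching_tet ug/ml; defaults chosen by kind.
#' @param female_frac fraction of females in the released cohort; defaults
#'   by kind (0 for male-only, 0.5 for bi-sex).
#' @param window optional length-2 Date (or ISO string) vector limiting
#'   releases; \code{NULL} means the whole simulated season.
#' @return An object of class \code{release_strategy}.
#' @export
release_strategy <- function(kind = c("none", "RIDL", "FL",
                                      "SSIMS_male_only", "SSIMS_single_amp",
                                      "SSIMS_double_amp"),
                             n = 0, interval = 7,
                             rearing_tet = NULL, hatching_tet = NULL,
                             female_frac = NULL, window = NULL) {
  kind <- match.arg(kind)
  if (!is.numeric(n) || n < 0) stop("n must be >= 0", call. = FALSE)
  if (!is.numeric(interval) || interval < 1)
    stop("interval must be >= 1 day", call. = FALSE)
  defaults <- switch(kind,
    none             = list(rear = 0,   hatch = 0,   ff = 0),
    RIDL             = list(rear = 100, hatch = 100, ff = 0.5),
    FL               = list(rear = 100, hatch = 100, ff = 0.5),
    SSIMS_male_only  = list(rear = 10,  hatch = 0,   ff = 0),
    SSIMS_single_amp = list(rear = 10,  hatch = 10,  ff = 0.5),
    SSIMS_double_amp = list(rear = 100, hatch = 100, ff = 0.5))
  if (is.null(rearing_tet)) rearing_tet <- defaults$rear
  if (is.null(hatching_tet)) hatching_tet <- defaults$hatch
  if (is.null(female_frac)) female_frac <- defaults$ff
  if (!is.null(window)) window <- as.Date(window)
  structure(list(kind = kind, n = as.integer(n),
                 interval = as.integer(interval),
                 rearing_tet = rearing_tet, hatching_tet = hatching_tet,
                 female_frac = female_frac, window = window),
            class = "release_strategy")
}

# genotype template of a strategy as an allele row generator
.strategy_strain <- function(kind) {
  switch(kind,
         RIDL = "RIDL", FL = "FL",
         SSIMS_male_only = , SSIMS_single_amp = , SSIMS_double_amp = "SSIMS",
         stop("strategy kind has no genotype template: ", kind,
              call. = FALSE))
}

# build a pop block of n adults of a named strain; exact sex split
.cohort_block <- function(strain, n, female_frac, E, origin, tp) {
  n <- as.integer(n)
  n_f <- as.integer(floor(n * female_frac))
  n_m <- n - n_f
  sex <- rep(c(1L, 2L), c(n_f, n_m))
  x_al <- if (strain %in% c("SSIMS", "FL")) 2L else 1L
  egi  <- strain %in% c("SSIMS", "EGI")
  rdl  <- strain == "RIDL"
  list(sex = sex, stage = rep(4L, n),
       x1 = rep(x_al, n),
       x2 = ifelse(sex == 1L, x_al, 0L),
       pyr1 = rep(if (egi) 2L else 1L, n), pyr2 = rep(if (egi) 2L else 1L, n),
       pta1 = rep(if (egi) 2L else 1L, n), pta2 = rep(if (egi) 2L else 1L, n),
       ridl1 = rep(if (rdl) 2L else 1L, n), ridl2 = rep(if (rdl) 2L else 1L, n),
       gen = rep(0L, n), origin = rep(origin, n),
       dd = rep(0, n), E = rep(E, n), adage = rep(0L, n))
}

#' Build a released cohort of adult biocontrol agents
#'
#' Released agents are adults of the strategy's strain; females carry the
#' steady-state Tet exposure of the rearing concentration.  Male-only SSIMS
#' emits 100\% males; bi-sex strategies use an exact
#' \code{floor(n * female_frac)} female split.
#'
#' @param strategy a [release_strategy()].
#' @param n cohort size (defaults to \code{strategy$n}).
#' @param tp a [tet_params()] object.
#' @return A population block (internal column store) of \code{n} adults.
#' @export
released_cohort <- function(strategy, n = strategy$n, tp = tet_params()) {
  if (!inherits(strategy, "release_strategy"))
    stop("strategy must be a release_strategy", call. = FALSE)
  if (strategy$kind == "none" || n == 0L) {
    blk <- .pop_empty()
    return(blk)
  }
  strain <- .strategy_strain(strategy$kind)
  E <- rearing_steady_state(strategy$rearing_tet, tp)
  .cohort_block(strain, n, strategy$female_frac, E, origin = 2L, tp = tp)
}

#' Season configuration for the field model
#'
#' @param lifecycle a [lifecycle_params()] object.
#' @param mating a [mating_params()] object.
#' @param tet a [tet_params()] object.
#' @param strategy a [release_strategy()] object.
#' @param field_tet food tetracycline concentration in the field (ug/ml);
#'   0 unless a foliar-spray scenario is being explored.
#' @return An object of class \code{season_config}.
#' @export
season_config <- function(lifecycle = lifecycle_params(),
                          mating = mating_params(),
                          tet = tet_params(),
                          strategy = release_strategy("none"),
                          field_tet = 0) {
  stopifnot(inherits(lifecycle, "lifecycle_params"),
            inherits(mating, "mating_params"),
            inherits(tet, "tet_params"),
            inherits(strategy, "release_strategy"),
            is.numeric(field_tet), field_tet >= 0)
  structure(list(lifecycle = lifecycle, mating = mating, tet = tet,
                 strategy = strategy, field_tet = field_tet),
            class = "season_config")
}

#' Create an empty or seeded simulation state
#'
#' @param config a [season_config()].
#' @param init_adults wild adults to seed (50:50, females mated to wild
#'   males); defaults to \code{config$lifecycle$init_adults}.
#' @return A state list with the population store, sperm stores and
#'   bookkeeping counters, suitable for [step_day()].
#' @export
new_season_state <- function(config = season_config(),
                             init_adults = config$lifecycle$init_adults) {
  pop <- .pop_empty()
  sperm <- list()
  n <- as.integer(init_adults)
  if (n > 0L) {
    pop <- .pop_bind(pop, .cohort_block("WT", n, 0.5, E = 0, origin = 1L,
                                        tp = config$tet))
    sperm <- vector("list", n)
    wt_sire <- c(1L, 1L, 1L, 1L, 1L, 1L, 1L)  # X+, wt/wt, +/+, +/+
    for (i in which(pop$sex == 1L))
      sperm[[i]] <- list(w = 1, g = matrix(wt_sire, nrow = 1L))
  }
  list(pop = pop, sperm = sperm, day = 0L,
       n_created = n, n_deaths = 0L,
       cum_wt_hatched = 0L)
}

# append a pop block (e.g. a release) to a state
.state_add <- function(state, blk) {
  n_new <- length(blk$sex)
  if (n_new == 0L) return(state)
  state$pop <- .pop_bind(state$pop, blk)
  state$sperm <- c(state$sperm, vector("list", n_new))
  state$n_created <- state$n_created + n_new
  state
}

#' Advance the field population by one day
#'
#' Applies, in order: degree-day accrual and stage promotion with viability
#' enforcement at the stage boundaries (EGI lethality at egg hatch;
#' female-lethal and RIDL lethality at the larva-to-pupa transition);
#' stage- and temperature-dependent mortality; mating and remating with
#' last-male sperm precedence; oviposition (per-mated-female Poisson egg
#' counts, sires drawn per egg from sperm-store weights, maternal Tet
#' carryover); and density-dependent daily egg survival
#' \code{1 / (1 + L / K)} using the larval census.
#'
#' @param state a state from [new_season_state()] (or a previous step).
#' @param temp the day's mean temperature (C).
#' @param config a [season_config()].
#' @return The updated state.  Draws from the current RNG stream.
#' @export
step_day <- function(state, temp, config = season_config()) {
  lp <- config$lifecycle; mp <- config$mating; tp <- config$tet
  pop <- state$pop; sperm <- state$sperm
  state$day <- state$day + 1L
  n <- .pop_n(pop)
  deaths <- 0L

  if (n > 0L) {
    ## (1) degree-day accrual and promotion, (2) boundary viability
    juv <- pop$stage < 4L
    gain <- max(0, temp - lp$dd_base)
    pop$dd[juv] <- pop$dd[juv] + gain
    dead <- rep(FALSE, n)

    hatch <- pop$stage == 1L & pop$dd >= lp$dd_egg
    if (any(hatch)) {
      inviable <- hatch & (pop$pta1 == 2L | pop$pta2 == 2L) &
        (pop$pyr1 == 1L | pop$pyr2 == 1L)
      dead[inviable] <- TRUE
      ok <- hatch & !inviable
      pop$stage[ok] <- 2L
      pop$dd[ok] <- pop$dd[ok] - lp$dd_egg
    }
    pup <- pop$stage == 2L & pop$dd >= lp$dd_larva & !dead
    if (any(pup)) {
      # RIDL dominant lethality off Tet (field food), both sexes
      ridl_kill <- pup & (pop$ridl1 == 2L | pop$ridl2 == 2L) &
        config$field_tet < tp$e_floor
      # FL females: survive the larva/pupa transition with Hill probability
      flf <- pup & pop$sex == 1L & (pop$x1 == 2L | pop$x2 == 2L) & !ridl_kill
      if (any(flf)) {
        s <- female_survival(pop$E[flf], tp)
        die <- stats::runif(sum(flf)) >= s
        idx <- which(flf)[die]
        dead[idx] <- TRUE
      }
      dead[ridl_kill] <- TRUE
      ok <- pup & !dead
      pop$stage[ok] <- 3L
      pop$dd[ok] <- pop$dd[ok] - lp$dd_larva
    }
    ecl <- pop$stage == 3L & pop$dd >= lp$dd_pupa & !dead
    if (any(ecl)) {
      pop$stage[ecl] <- 4L
      pop$dd[ecl] <- 0
      cl <- .classify_codes(.pop_subset(pop, ecl))
      state$cum_wt_hatched <- state$cum_wt_hatched + sum(cl == 1L)
    }

    ## (3) mortality
    m_ad <- adult_mortality_rate(temp, lp)
    m_juv <- juvenile_mortality_rate(temp, lp)
    p_die <- ifelse(pop$stage == 4L, m_ad, m_juv)
    dead <- dead | (stats::runif(n) < p_die) |
      (pop$stage == 4L & pop$adage >= lp$max_adult_days)
    if (any(dead)) {
      deaths <- deaths + sum(dead)
      keep <- !dead
      pop <- .pop_subset(pop, keep)
      sperm <- sperm[keep]
      n <- .pop_n(pop)
    }
    # adults age only on physiologically active days
    if (temp > lp$dd_base)
      pop$adage[pop$stage == 4L] <- pop$adage[pop$stage == 4L] + 1L
  }

  if (n > 0L) {
    ## (4) mating / remating
    males <- which(pop$stage == 4L & pop$sex == 2L)
    if (length(males) > 0L) {
      fems <- which(pop$stage == 4L & pop$sex == 1L)
      if (length(fems) > 0L) {
        virgin <- vapply(sperm[fems], is.null, logical(1))
        p <- ifelse(virgin, mp$p_mate_virgin, mp$p_remate)
        mate_now <- fems[stats::runif(length(fems)) < p]
        if (length(mate_now) > 0L) {
          sires <- males[sample.int(length(males), length(mate_now),
                                    replace = TRUE)]
          for (k in seq_along(mate_now)) {
            i <- mate_now[k]
            sperm[[i]] <- .store_add(sperm[[i]], .sire_row(pop, sires[k]),
                                     mp$p2)
          }
        }
      }
    }

    ## (5) oviposition
    lam <- fecundity_rate(temp, lp)
    if (lam > 0) {
      mothers <- which(pop$stage == 4L & pop$sex == 1L)
      mothers <- mothers[!vapply(sperm[mothers], is.null, logical(1))]
      if (length(mothers) > 0L) {
        n_eggs <- stats::rpois(length(mothers), lam)
        tot <- sum(n_eggs)
        if (tot > 0L) {
          mom <- rep.int(mothers, n_eggs)
          sire_g <- matrix(0L, nrow = tot, ncol = 7L)
          pos <- 1L
          for (k in seq_along(mothers)) {
            nk <- n_eggs[k]
            if (nk == 0L) next
            S <- sperm[[mothers[k]]]
            if (nrow(S$g) == 1L) {
              sire_g[pos:(pos + nk - 1L), ] <-
                matrix(S$g[1L, ], nrow = nk, ncol = 7L, byrow = TRUE)
            } else {
              idx <- sample.int(nrow(S$g), nk, replace = TRUE, prob = S$w)
              sire_g[pos:(pos + nk - 1L), ] <- S$g[idx, , drop = FALSE]
            }
            pos <- pos + nk
          }
          # maternal gametes
          ex   <- .pick(pop$x1[mom], pop$x2[mom])
          epyr <- .pick(pop$pyr1[mom], pop$pyr2[mom])
          epta <- .pick(pop$pta1[mom], pop$pta2[mom])
          erdl <- .pick(pop$ridl1[mom], pop$ridl2[mom])
          # paternal gametes: Y with probability 1/2, else the sire's X
          y <- stats::runif(tot) < 0.5
          spyr <- .pick(sire_g[, 2L], sire_g[, 3L])
          spta <- .pick(sire_g[, 4L], sire_g[, 5L])
          srdl <- .pick(sire_g[, 6L], sire_g[, 7L])
          blk <- list(
            sex = ifelse(y, 2L, 1L), stage = rep(1L, tot),
            x1 = ex, x2 = ifelse(y, 0L, sire_g[, 1L]),
            pyr1 = epyr, pyr2 = spyr, pta1 = epta, pta2 = spta,
            ridl1 = erdl, ridl2 = srdl,
            gen = pop$gen[mom] + 1L, origin = rep(3L, tot),
            dd = rep(0, tot),
            E = effective_exposure(config$field_tet, pop$E[mom], tp),
            adage = rep(0L, tot))
          pop <- .pop_bind(pop, blk)
          sperm <- c(sperm, vector("list", tot))
          state$n_created <- state$n_created + tot
          n <- .pop_n(pop)
        }
      }
    }

    ## (6) density-dependent daily egg survival
    eggs <- pop$stage == 1L
    if (any(eggs)) {
      L <- sum(pop$stage == 2L)
      p_surv <- 1 / (1 + L / lp$K)
      die <- eggs & (stats::runif(n) >= p_surv)
      if (any(die)) {
        deaths <- deaths + sum(die)
        keep <- !die
        pop <- .pop_subset(pop, keep)
        sperm <- sperm[keep]
      }
    }
  }

  state$pop <- pop
  state$sperm <- sperm
  state$n_deaths <- state$n_deaths + deaths
  state
}

# daily census: 6 classes x 2 sexes x 4 stages x 3 origins -> length-144
.census <- function(pop) {
  n <- .pop_n(pop)
  if (n == 0L) return(integer(144L))
  cl <- .classify_codes(pop)
  idx <- cl + 6L * (pop$sex - 1L) + 12L * (pop$stage - 1L) +
    48L * (pop$origin - 1L)
  tabulate(idx, nbins = 144L)
}

#' Run a full field season
#'
#' Seeds the initial wild population on day 1, executes releases on the
#' strategy's schedule (every \code{interval} days within the release
#' window, starting at its first day), advances the population daily with
#' [step_day()], and returns a season summary with daily stage-, sex-,
#' strain- and origin-resolved censuses.
#'
#' @param config a [season_config()].
#' @param temps a \code{temperature_series} covering the season (default: a
#'   synthetic Upper-Midwest March 1 - September 1 season generated from
#'   \code{seed}).
#' @param seed integer RNG seed; the run is fully reproducible.
#' @return An object of class \code{season_summary}.
#' @examples
#' \donttest{
#' s <- run_season(season_config(), seed = 1)
#' print(s)
#' }
#' @export
run_season <- function(config = season_config(), temps = NULL, seed = 1L) {
  if (!inherits(config, "season_config"))
    stop("config must be a season_config", call. = FALSE)
  if (is.null(temps))
    temps <- synthesize_season(seed = as.integer(seed))
  if (!inherits(temps, "temperature_series"))
    stop("temps must be a temperature_series", call. = FALSE)
  n_days <- nrow(temps)
  if (n_days < 2L) stop("temperature series shorter than the season window",
                        call. = FALSE)
  set.seed(as.integer(seed))
  strat <- config$strategy
  release_days <- integer(0)
  if (strat$kind != "none" && strat$n > 0L) {
    if (is.null(strat$window)) {
      w0 <- 1L; w1 <- n_days
    } else {
      w0 <- as.integer(strat$window[1] - temps$date[1]) + 1L
      w1 <- as.integer(strat$window[2] - temps$date[1]) + 1L
      if (w0 < 1L || w1 > n_days || w0 > w1)
        stop("release window outside the temperature series", call. = FALSE)
    }
    release_days <- seq.int(w0, w1, by = strat$interval)
  }

  state <- new_season_state(config)
  counts <- matrix(0L, nrow = n_days, ncol = 144L)
  cum_wt <- integer(n_days)
  gm_f_pupa_gen1 <- integer(n_days)
  gm_f_pupa_gen2 <- integer(n_days)
  n_released <- 0L

  for (d in seq_len(n_days)) {
    if (d %in% release_days) {
      blk <- released_cohort(strat, tp = config$tet)
      n_released <- n_released + length(blk$sex)
      state <- .state_add(state, blk)
    }
    state <- step_day(state, temps$tmean[d], config)
    counts[d, ] <- .census(state$pop)
    cum_wt[d] <- state$cum_wt_hatched
    pop <- state$pop
    gm_f <- .pop_n(pop) > 0L
    if (gm_f) {
      cl <- .classify_codes(pop)
      sel <- cl != 1L & pop$origin == 3L & pop$sex == 1L & pop$stage >= 3L
      gm_f_pupa_gen1[d] <- sum(sel & pop$gen == 1L)
      gm_f_pupa_gen2[d] <- sum(sel & pop$gen >= 2L)
    }
  }

  dim(counts) <- c(n_days, 6L, 2L, 4L, 3L)
  dimnames(counts) <- list(NULL, .CLASS_LEVELS, .SEX_LEVELS, .STAGE_LEVELS,
                           .ORIGIN_LEVELS)
  wt_total <- apply(counts[, 1L, , , , drop = FALSE], 1L, sum)
  # engineered, field-born, hatched (beyond the egg stage)
  gm_hatched <- apply(counts[, -1L, , -1L, 3L, drop = FALSE], 1L, sum)
  total <- apply(counts, 1L, sum)

  structure(list(
    dates = temps$date,
    counts = counts,
    total = total,
    wt_total = wt_total,
    gm_field_hatched = gm_hatched,
    gm_female_pupa_gen1 = gm_f_pupa_gen1,
    gm_female_pupa_gen2plus = gm_f_pupa_gen2,
    cum_wt_hatched = cum_wt,
    eradication_day = .first_persistent_zero(wt_total),
    seed = as.integer(seed),
    n_released = n_released,
    conservation = list(created = state$n_created,
                        deaths = state$n_deaths,
                        alive = .pop_n(state$pop)),
    config = config
  ), class = "season_summary")
}

.first_persistent_zero <- function(trace) {
  if (all(trace == 0)) return(1L)
  nz <- max(which(trace != 0))
  if (nz == length(trace)) return(NA_integer_)
  nz + 1L
}

#' First day from which the wild-type population stays at zero
#'
#' @param x a \code{season_summary}, or a numeric daily trace of wild-type
#'   counts.
#' @return The 1-based day index of eradication, or \code{NA} if not
#'   reached by the end of the trace.
#' @examples
#' days_to_eradication(c(5, 2, 0, 0))     # 3
#' days_to_eradication(c(1, 0, 3, 0, 0))  # 4 (zero must persist)
#' @export
days_to_eradication <- function(x) {
  if (inherits(x, "season_summary")) return(x$eradication_day)
  if (!is.numeric(x)) stop("x must be a season_summary or numeric trace",
                           call. = FALSE)
  .first_persistent_zero(x)
}

#' @export
print.season_summary <- function(x, ...) {
  n <- length(x$dates)
  cat(sprintf("Field season: %s to %s (%d days), strategy %s, seed %d\n",
              x$dates[1], x$dates[n], n, x$config$strategy$kind, x$seed))
  cat(sprintf("  peak population: %d on %s\n", max(x$total),
              x$dates[which.max(x$total)]))
  cat(sprintf("  cumulative wild-type adults hatched: %d\n",
              x$cum_wt_hatched[n]))
  if (is.na(x$eradication_day)) {
    cat("  wild-type eradication: not reached\n")
  } else {
    cat(sprintf("  wild-type eradication: day %d (%s)\n",
                x$eradication_day, x$dates[x$eradication_day]))
  }
  invisible(x)
}

#' @export
summary.season_summary <- function(object, ...) {
  n <- length(object$dates)
  data.frame(
    strategy = object$config$strategy$kind,
    n_days = n,
    peak_total = max(object$total),
    peak_date = object$dates[which.max(object$total)],
    cumulative_wt_hatched = object$cum_wt_hatched[n],
    eradication_day = object$eradication_day,
    n_released = object$n_released,
    seed = object$seed,
    stringsAsFactors = FALSE
  )
}

#' Tidy long-format daily census of a season run
#'
#' @param x a \code{season_summary}.
#' @param row.names,optional,... standard [as.data.frame()] arguments
#'   (unused).
#' @param drop_zero drop zero-count rows (default TRUE).
#' @return A data frame with columns \code{day}, \code{date}, \code{class},
#'   \code{sex}, \code{stage}, \code{origin}, \code{count}.
#' @export
as.data.frame.season_summary <- function(x, row.names = NULL,
                                         optional = FALSE, drop_zero = TRUE,
                                         ...) {
  n <- length(x$dates)
  g <- expand.grid(day = seq_len(n), class = .CLASS_LEVELS,
                   sex = .SEX_LEVELS, stage = .STAGE_LEVELS,
                   origin = .ORIGIN_LEVELS, stringsAsFactors = FALSE)
  g$count <- as.vector(x$counts)
  g$date <- x$dates[g$day]
  g <- g[, c("day", "date", "class", "sex", "stage", "origin", "count")]
  if (drop_zero) g <- g[g$count > 0L, , drop = FALSE]
  rownames(g) <- NULL
  g
}

#' @export
plot.season_summary <- function(x, ...) {
  graphics::plot(x$dates, x$wt_total, type = "l", col = "steelblue",
                 lwd = 2, xlab = "date", ylab = "individuals",
                 ylim = c(0, max(x$total, 1)), ...)
  graphics::lines(x$dates, x$gm_field_hatched +
                    apply(x$counts[, -1L, , , 2L, drop = FALSE], 1L, sum),
                  col = "darkorange", lwd = 2)
  graphics::lines(x$dates, x$total, col = "grey40", lty = 2)
  graphics::legend("topleft", c("wild-type", "engineered", "total"),
                   col = c("steelblue", "darkorange", "grey40"),
                   lty = c(1, 1, 2), lwd = c(2, 2, 1), bty = "n")
  invisible(x)
}
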