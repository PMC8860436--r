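# Discrete-event simulator of the laboratory cage-trial protocol: adults
# live in a cage at constant 25 C; reproduction happens in a weekly bottle
# (24 h egg-lay, eclosion 10 days later over a 3-day window); population and
# genotype composition are assessed by a weekly removal trap; fecundity of
# up to 10 trapped wild-type females is assayed in vials before returning
# them to the cage.

#' Cage-trial configuration
#'
#' @param init_wt wild-type adults seeded on day 1 of week 1 (50:50,
#'   females virgin).
#' @param release_size engineered (SSIMS) adults added per release week.
#' @param release_female_frac fraction of females among released SSIMS
#'   (default 0.45, an approximately 45:55 female:male ratio).
#' @param release_weeks weeks in which SSIMS additions occur (default 1-8).
#' @param rearing_tet Tet concentration the released stock was maintained
#'   on (ug/ml); released females carry its steady-state exposure.
#' @param trap_p weekly capture probability per adult present.  The
#'   default 1/3 reads the observation that the standing cage population
#'   was about three times the weekly trap catch; it is exposed here
#'   because that fraction was never validated against density.
#' @param bottle_fecundity expected eggs per mated female during the 24-h
#'   bottle egg-lay.
#' @param bottle_cap maximum emergers per reproduction bottle (prevents
#'   larval overcrowding).
#' @param bottle_juvenile_mortality daily background mortality applied to
#'   the bottle cohort during development.
#' @param eclosion_lag days from egg-lay to the bottle being uncapped.
#' @param emerge_window days over which the bottle cohort ecloses into the
#'   cage.
#' @param assay_n wild-type females sampled weekly for the fecundity assay.
#' @param assay_mean calibrated expected offspring per assay vial for a
#'   fully wild-type-sired female.
#' @param assay_days days an assay female is away from the cage.
#' @param weeks weeks simulated.
#' @param adult_mortality daily adult mortality at the constant cage
#'   temperature (25 C).
#' @param max_adult_days maximum adult lifespan (days); at 25 C every day
#'   is physiologically active.
#' @param mating a [mating_params()] object.  The cage default raises the
#'   daily remating probability to 0.15: in a male-saturated cage, resident
#'   females remate within days, consistent with sperm-displacement assays
#'   in which offspring of previously mated females drop by ~98\% within
#'   one egg-lay window of adding engineered males.
#' @param tet a [tet_params()] object.
#' @return An object of class \code{cage_config}.
#' @export
cage_config <- function(init_wt = 600, release_size = 600,
                        release_female_frac = 0.45, release_weeks = 1:8,
                        rearing_tet = 100, trap_p = 1/3,
                        bottle_fecundity = 25, bottle_cap = 800,
                        bottle_juvenile_mortality = 0.01,
                        eclosion_lag = 10, emerge_window = 3,
                        assay_n = 10, assay_mean = 75, assay_days = 3,
                        weeks = 16, adult_mortality = 0.03,
                        max_adult_days = 50,
                        mating = mating_params(p_remate = 0.15),
                        tet = tet_params()) {
  stopifnot(init_wt >= 0, release_size >= 0,
            release_female_frac >= 0, release_female_frac <= 1,
            trap_p >= 0, trap_p <= 1, bottle_fecundity >= 0,
            bottle_cap >= 1, eclosion_lag >= 1, emerge_window >= 1,
            assay_n >= 0, assay_mean >= 0, weeks >= 1,
            adult_mortality >= 0, adult_mortality <= 1,
            max_adult_days >= 1,
            inherits(mating, "mating_params"), inherits(tet, "tet_params"))
  structure(as.list(environment()), class = "cage_config")
}

# bottle reproduction: mated females present lay for 24 h; returns the
# pop block of adults that will eclose (viability and the bottle cap
# already applied), with an attribute giving eggs laid.
.bottle_offspring <- function(pop, sperm, present, cfg) {
  tp <- cfg$tet
  mothers <- which(present & pop$stage == 4L & pop$sex == 1L)
  mothers <- mothers[!vapply(sperm[mothers], is.null, logical(1))]
  empty <- {
    b <- .pop_empty(); attr(b, "eggs_laid") <- 0L; b
  }
  if (length(mothers) == 0L) return(empty)
  n_eggs <- stats::rpois(length(mothers), cfg$bottle_fecundity)
  tot <- sum(n_eggs)
  if (tot == 0L) return(empty)
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
  ex   <- .pick(pop$x1[mom], pop$x2[mom])
  epyr <- .pick(pop$pyr1[mom], pop$pyr2[mom])
  epta <- .pick(pop$pta1[mom], pop$pta2[mom])
  erdl <- .pick(pop$ridl1[mom], pop$ridl2[mom])
  y <- stats::runif(tot) < 0.5
  spyr <- .pick(sire_g[, 2L], sire_g[, 3L])
  spta <- .pick(sire_g[, 4L], sire_g[, 5L])
  srdl <- .pick(sire_g[, 6L], sire_g[, 7L])
  sex <- ifelse(y, 2L, 1L)
  x2 <- ifelse(y, 0L, sire_g[, 1L])
  E_child <- effective_exposure(0, pop$E[mom], tp)  # bottle food is Tet-free
  gen <- pop$gen[mom] + 1L

  # EGI-incompatible zygotes die at hatch and never compete for bottle
  # capacity; female-lethal and RIDL carriers die as larvae/pupae, i.e.
  # after competing for one of the bottle's rearing slots
  egi_ok <- !((epta == 2L | spta == 2L) & (epyr == 1L | spyr == 1L))
  larvae <- which(egi_ok &
                    (stats::runif(tot) <
                       (1 - cfg$bottle_juvenile_mortality)^cfg$eclosion_lag))
  if (length(larvae) > cfg$bottle_cap)
    larvae <- sort(sample(larvae, cfg$bottle_cap))
  ridl_ok <- !(erdl[larvae] == 2L | srdl[larvae] == 2L)
  fl_female <- sex[larvae] == 1L & (ex[larvae] == 2L | x2[larvae] == 2L)
  surv <- rep(TRUE, length(larvae))
  if (any(fl_female)) {
    sv <- female_survival(E_child[larvae][fl_female], tp)
    surv[fl_female] <- stats::runif(sum(fl_female)) < sv
  }
  idx <- larvae[ridl_ok & surv]
  blk <- list(sex = sex[idx], stage = rep(4L, length(idx)),
              x1 = ex[idx], x2 = x2[idx],
              pyr1 = epyr[idx], pyr2 = spyr[idx],
              pta1 = epta[idx], pta2 = spta[idx],
              ridl1 = erdl[idx], ridl2 = srdl[idx],
              gen = gen[idx], origin = rep(3L, length(idx)),
              dd = rep(0, length(idx)), E = E_child[idx],
              adage = rep(0L, length(idx)))
  attr(blk, "eggs_laid") <- tot
  blk
}

#' Simulated single-female fecundity assay
#'
#' Draws an egg clutch for one female (Poisson around the calibrated
#' per-vial mean), assigns each egg's sire from the sperm-store weights,
#' and applies the viability rules on Tet-free vial food: EGI
#' incompatibility, RIDL dominant lethality, and the female-lethal circuit
#' given the egg's maternally carried exposure.  A female whose store is
#' 100\% SSIMS yields 0; an unmated female yields 0.
#'
#' @param store the female's sperm store: a data frame with columns
#'   \code{sire} (genotype string codes) and \code{weight}, or \code{NULL}
#'   if unmated.
#' @param mother the female's genotype (an \code{ssims_genotype}; must be
#'   XX).
#' @param mother_E the female's effective Tet exposure (ug/ml-equivalent).
#' @param mean_eggs expected eggs laid over the assay.
#' @param tp a [tet_params()] object.
#' @return Integer count of surviving adult offspring.
#' @examples
#' set.seed(1)
#' wt <- format(strain_genotype("WT", "male"))
#' fecundity_assay(data.frame(sire = wt, weight = 1))
#' @export
fecundity_assay <- function(store,
                            mother = strain_genotype("WT", "female"),
                            mother_E = 0, mean_eggs = 75,
                            tp = tet_params()) {
  if (!inherits(mother, "ssims_genotype"))
    stop("mother must be an ssims_genotype", call. = FALSE)
  if (mother$karyotype != "XX")
    stop("fecundity assay requires a female", call. = FALSE)
  if (is.null(store) || nrow(store) == 0L) return(0L)
  if (!all(c("sire", "weight") %in% names(store)))
    stop("store needs columns sire, weight", call. = FALSE)
  n <- stats::rpois(1L, mean_eggs)
  if (n == 0L) return(0L)
  # per-sire expected offspring survival on Tet-free food
  E_child <- effective_exposure(0, mother_E, tp)
  v <- vapply(store$sire, function(code) {
    sire <- parse_genotype(code)
    cd <- cross_distribution(mother, sire)
    p <- 0
    for (i in seq_len(nrow(cd))) {
      if (!cd$egi_viable[i]) next
      z <- parse_genotype(cd$genotype[i])
      if (any(z$ridl == "RIDL")) next  # Tet-free vial
      s <- if (sex_of(z) == "female" && any(z$x == "FL"))
        female_survival(E_child, tp) else 1
      p <- p + cd$probability[i] * s
    }
    p
  }, numeric(1))
  n_per_sire <- stats::rmultinom(1L, n, store$weight / sum(store$weight))[, 1L]
  sum(stats::rbinom(length(v), n_per_sire, v))
}

#' Run a laboratory cage trial
#'
#' Simulates \code{weeks} weeks at constant 25 C.  Each week, in order:
#' SSIMS addition (in release weeks), a 24-h reproduction-bottle egg lay by
#' mated females, removal trapping, the fecundity assay on up to
#' \code{assay_n} trapped wild-type females (returned to the cage after
#' \code{assay_days} days), scheduled eclosion of bottle cohorts laid
#' 10-12 days earlier, with daily mating and adult mortality throughout.
#'
#' @param config a [cage_config()].
#' @param seed integer RNG seed.
#' @return An object of class \code{cage_trial}: weekly trap counts by
#'   strain class and sex, weekly fecundity-assay counts, and weekly cage
#'   censuses.
#' @examples
#' \donttest{
#' ct <- run_cage(cage_config(weeks = 4), seed = 1)
#' print(ct)
#' }
#' @export
run_cage <- function(config = cage_config(), seed = 1L) {
  if (!inherits(config, "cage_config"))
    stop("config must be a cage_config", call. = FALSE)
  set.seed(as.integer(seed))
  cfg <- config
  mp <- cfg$mating
  tp <- cfg$tet
  weeks <- as.integer(cfg$weeks)
  n_days <- weeks * 7L

  pop <- .pop_empty()
  sperm <- list()
  away_until <- integer(0)   # day a trapped assay female returns; 0 = present

  add_block <- function(blk) {
    k <- length(blk$sex)
    if (k == 0L) return(invisible(NULL))
    pop <<- .pop_bind(pop, blk)
    sperm <<- c(sperm, vector("list", k))
    away_until <<- c(away_until, integer(k))
    invisible(NULL)
  }

  pending <- vector("list", n_days + cfg$eclosion_lag + cfg$emerge_window + 1L)

  trap_counts <- array(0L, dim = c(weeks, 6L, 2L),
                       dimnames = list(NULL, .CLASS_LEVELS, .SEX_LEVELS))
  census <- array(0L, dim = c(weeks, 6L, 2L),
                  dimnames = list(NULL, .CLASS_LEVELS, .SEX_LEVELS))
  fecundity <- vector("list", weeks)
  eggs_laid <- integer(weeks)

  ssims_E <- rearing_steady_state(cfg$rearing_tet, tp)

  for (day in seq_len(n_days)) {
    week <- ((day - 1L) %/% 7L) + 1L
    wday <- ((day - 1L) %% 7L) + 1L
    present <- away_until < day
    away_until[away_until <= day] <- 0L
    present <- away_until == 0L

    if (wday == 1L) {
      if (week == 1L)
        add_block(.cohort_block("WT", cfg$init_wt, 0.5, E = 0, origin = 1L,
                                tp = tp))
      if (week %in% cfg$release_weeks)
        add_block(.cohort_block("SSIMS", cfg$release_size,
                                cfg$release_female_frac, E = ssims_E,
                                origin = 2L, tp = tp))
      present <- away_until == 0L
    }

    ## daily mating among present adults
    n <- .pop_n(pop)
    if (n > 0L) {
      males <- which(present & pop$sex == 2L)
      fems <- which(present & pop$sex == 1L)
      if (length(males) > 0L && length(fems) > 0L) {
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

    ## weekly reproduction bottle (24 h egg lay on day 1)
    if (wday == 1L && .pop_n(pop) > 0L) {
      blk <- .bottle_offspring(pop, sperm, present, cfg)
      eggs_laid[week] <- attr(blk, "eggs_laid")
      k <- length(blk$sex)
      if (k > 0L) {
        arrive <- day + cfg$eclosion_lag +
          sample.int(cfg$emerge_window, k, replace = TRUE) - 1L
        for (a in unique(arrive)) {
          sel <- arrive == a
          sub <- lapply(blk[names(blk)], function(v) v[sel])
          pending[[a]] <- if (is.null(pending[[a]])) sub else
            .pop_bind(pending[[a]], sub)
        }
      }
    }

    ## weekly removal trap (day 2): the yeast/sugar/detergent trap kills
    ## every fly it catches
    if (wday == 2L && .pop_n(pop) > 0L) {
      idx <- which(present)
      trapped <- idx[stats::runif(length(idx)) < cfg$trap_p]
      if (length(trapped) > 0L) {
        cl <- .classify_codes(.pop_subset(pop, trapped))
        sx <- pop$sex[trapped]
        for (c6 in 1:6) for (s2 in 1:2)
          trap_counts[week, c6, s2] <- sum(cl == c6 & sx == s2)
        keep <- !(seq_len(.pop_n(pop)) %in% trapped)
        pop <- .pop_subset(pop, keep)
        sperm <- sperm[keep]
        away_until <- away_until[keep]
      }
    }

    ## weekly fecundity assay (day 3): a separate, non-lethal food-bottle
    ## trapping; up to assay_n wild-type females are isolated into vials
    ## for 3 days and then returned to the cage
    if (wday == 3L && .pop_n(pop) > 0L && cfg$assay_n > 0L) {
      present <- away_until == 0L
      cl <- .classify_codes(pop)
      wt_f <- which(present & cl == 1L & pop$sex == 1L)
      assay <- if (length(wt_f) > cfg$assay_n)
        sample(wt_f, cfg$assay_n) else wt_f
      if (length(assay) > 0L) {
        counts <- integer(length(assay))
        for (k in seq_along(assay)) {
          i <- assay[k]
          S <- sperm[[i]]
          counts[k] <- if (is.null(S)) 0L else {
            codes <- apply(S$g, 1L, .code_from_sire_row)
            fecundity_assay(data.frame(sire = codes, weight = S$w,
                                       stringsAsFactors = FALSE),
                            mother_E = pop$E[i],
                            mean_eggs = cfg$assay_mean, tp = tp)
          }
        }
        fecundity[[week]] <- counts
        away_until[assay] <- day + cfg$assay_days
      } else {
        fecundity[[week]] <- integer(0)
      }
    }

    ## eclosion of scheduled bottle cohorts
    if (!is.null(pending[[day]])) {
      add_block(pending[[day]])
      pending[day] <- list(NULL)
    }

    ## daily adult mortality and maximum lifespan
    n <- .pop_n(pop)
    if (n > 0L) {
      dead <- stats::runif(n) < cfg$adult_mortality |
        pop$adage >= cfg$max_adult_days
      if (any(dead)) {
        keep <- !dead
        pop <- .pop_subset(pop, keep)
        sperm <- sperm[keep]
        away_until <- away_until[keep]
      }
      pop$adage <- pop$adage + 1L
    }

    ## end-of-week census
    if (wday == 7L && .pop_n(pop) > 0L) {
      cl <- .classify_codes(pop)
      for (c6 in 1:6) for (s2 in 1:2)
        census[week, c6, s2] <- sum(cl == c6 & pop$sex == s2)
    }
  }

  structure(list(
    weeks = weeks,
    trap = trap_counts,
    census = census,
    fecundity = fecundity,
    eggs_laid = eggs_laid,
    seed = as.integer(seed),
    config = config
  ), class = "cage_trial")
}

# genotype string code from an internal 7-integer sire row
.code_from_sire_row <- function(r) {
  x <- c("+", "FL")[r[1L]]
  pyr <- c("wt", "res")[r[2:3]]
  pta <- c("+", "PTA")[r[4:5]]
  ridl <- c("+", "RIDL")[r[6:7]]
  format(genotype("XY", x, pyr, pta, ridl))
}

#' @export
print.cage_trial <- function(x, ...) {
  cat(sprintf("Cage trial: %d weeks, seed %d\n", x$weeks, x$seed))
  wt_f <- x$trap[, "WT", "female"]
  wt_m <- x$trap[, "WT", "male"]
  gm <- rowSums(x$trap[, -1L, , drop = FALSE])
  cat("  weekly wild-type trap counts (F/M):\n")
  cat("   ", paste(sprintf("%d/%d", wt_f, wt_m), collapse = " "), "\n")
  cat("  weekly engineered trap counts:", paste(gm, collapse = " "), "\n")
  lz <- which(wt_f == 0L)
  if (length(lz) > 0L && all(wt_f[min(lz):x$weeks] == 0L))
    cat(sprintf("  wild-type females absent from traps from week %d\n",
                min(lz)))
  invisible(x)
}

#' Tidy long-format weekly trap counts of a cage trial
#'
#' @inheritParams as.data.frame.season_summary
#' @param x a \code{cage_trial}.
#' @return A data frame with columns \code{week}, \code{class}, \code{sex},
#'   \code{trap_count}.
#' @export
as.data.frame.cage_trial <- function(x, row.names = NULL, optional = FALSE,
                                     ...) {
  g <- expand.grid(week = seq_len(x$weeks), class = .CLASS_LEVELS,
                   sex = .SEX_LEVELS, stringsAsFactors = FALSE)
  g$trap_count <- as.vector(x$trap)
  g
}

#' @export
plot.cage_trial <- function(x, ...) {
  wk <- seq_len(x$weeks)
  wt <- rowSums(x$trap[, "WT", , drop = FALSE])
  gm <- rowSums(x$trap[, -1L, , drop = FALSE])
  graphics::plot(wk, wt, type = "b", col = "steelblue", lwd = 2,
                 xlab = "week", ylab = "weekly trap count",
                 ylim = c(0, max(wt, gm, 1)), ...)
  graphics::lines(wk, gm, type = "b", col = "seagreen", lwd = 2)
  graphics::legend("topright", c("wild-type", "engineered"),
                   col = c("steelblue", "seagreen"), lwd = 2, bty = "n")
  invisible(x)
}
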