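# Experiment drivers: release-grid sweeps over strategy x size x interval,
# the April-limited release scenario, and a Hill dose-response fitting
# utility.

#' Sweep specification
#'
#' @param strategies character vector of [release_strategy()] kinds.
#' @param sizes release sizes N per event.
#' @param intervals release intervals F in days.
#' @param replicates stochastic replicates per grid cell.
#' @param seed_base base seed; replicate r of cell i runs with seed
#'   \code{seed_base + 1000 * (i - 1) + r}.
#' @return An object of class \code{sweep_spec}.
#' @export
sweep_spec <- function(strategies = c("RIDL", "FL", "SSIMS_male_only",
                                      "SSIMS_single_amp",
                                      "SSIMS_double_amp"),
                       sizes = c(10, 20, 40, 80),
                       intervals = c(7, 14, 25, 50),
                       replicates = 10, seed_base = 1L) {
  stopifnot(length(strategies) > 0, length(sizes) > 0, length(intervals) > 0,
            replicates >= 1)
  structure(list(strategies = strategies, sizes = as.integer(sizes),
                 intervals = as.integer(intervals),
                 replicates = as.integer(replicates),
                 seed_base = as.integer(seed_base)),
            class = "sweep_spec")
}

#' Run a release-grid sweep
#'
#' Runs [run_season()] for every (strategy, release size, interval,
#' replicate) combination and collects the season-level outcomes used to
#' rank strategies: cumulative wild-type adults hatched and the day of
#' wild-type eradication.
#'
#' @param spec a [sweep_spec()].
#' @param config a [season_config()]; its strategy slot is overridden per
#'   grid cell.
#' @param temps a \code{temperature_series} shared by all runs (default: a
#'   synthetic season generated from \code{spec$seed_base}).
#' @return A long-format data frame (class \code{sweep_result}) with one
#'   row per run: \code{strategy}, \code{N}, \code{F}, \code{replicate},
#'   \code{seed}, \code{cumulative_wt}, \code{eradication_day}.
#' @export
run_sweep <- function(spec = sweep_spec(), config = season_config(),
                      temps = NULL) {
  if (is.null(temps)) temps <- synthesize_season(seed = spec$seed_base)
  grid <- expand.grid(strategy = spec$strategies, N = spec$sizes,
                      F = spec$intervals, stringsAsFactors = FALSE)
  rows <- vector("list", nrow(grid) * spec$replicates)
  k <- 0L
  for (i in seq_len(nrow(grid))) {
    strat <- release_strategy(grid$strategy[i], n = grid$N[i],
                              interval = grid$F[i])
    cfg <- config
    cfg$strategy <- strat
    for (r in seq_len(spec$replicates)) {
      seed <- spec$seed_base + 1000L * (i - 1L) + r
      s <- run_season(cfg, temps = temps, seed = seed)
      k <- k + 1L
      rows[[k]] <- data.frame(
        strategy = grid$strategy[i], N = grid$N[i], F = grid$F[i],
        replicate = r, seed = seed,
        cumulative_wt = s$cum_wt_hatched[length(s$cum_wt_hatched)],
        eradication_day = s$eradication_day,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("sweep_result", "data.frame")
  out
}

#' Summarise a sweep by grid cell
#'
#' @param object a \code{sweep_result} from [run_sweep()].
#' @param ... unused.
#' @return A data frame with per-cell mean and s.d. of cumulative wild-type
#'   hatched and mean eradication day (NA-aware: cells where some
#'   replicates never eradicate report the mean over eradicating
#'   replicates and the fraction eradicated).
#' @export
summary.sweep_result <- function(object, ...) {
  sp <- split(object, list(object$strategy, object$N, object$F),
              drop = TRUE)
  out <- do.call(rbind, lapply(sp, function(d) {
    data.frame(strategy = d$strategy[1], N = d$N[1], F = d$F[1],
               mean_cumulative_wt = mean(d$cumulative_wt),
               sd_cumulative_wt = stats::sd(d$cumulative_wt),
               mean_eradication_day = mean(d$eradication_day, na.rm = TRUE),
               frac_eradicated = mean(!is.na(d$eradication_day)),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$strategy, out$N, out$F), , drop = FALSE]
}

#' April-limited release scenario
#'
#' Weekly releases of \code{n} agents on four successive weekly dates in
#' April only; the rest of the season runs unmanaged.  Reports full-season
#' wild-type and engineered traces per replicate plus the wild-type and
#' engineered (field-hatched plus surviving released) counts at the June 1
#' and July 1 checkpoints.
#'
#' @param kind a [release_strategy()] kind.
#' @param n agents per weekly release (default 80).
#' @param config a [season_config()]; strategy is overridden.
#' @param temps a \code{temperature_series}; must span April through July.
#' @param seeds integer vector of replicate seeds.
#' @return A list (class \code{april_run}) with \code{traces} (list per
#'   replicate of data frames date/wt/gm) and \code{checkpoints} (data
#'   frame: replicate, date, wt, gm).
#' @export
april_limited_run <- function(kind, n = 80, config = season_config(),
                              temps = NULL, seeds = 1:10) {
  if (is.null(temps)) temps <- synthesize_season(seed = seeds[1])
  yr <- format(temps$date[1], "%Y")
  window <- as.Date(c(paste0(yr, "-04-01"), paste0(yr, "-04-30")))
  cfg <- config
  cfg$strategy <- release_strategy(kind, n = n, interval = 7,
                                   window = window)
  cps <- as.Date(c(paste0(yr, "-06-01"), paste0(yr, "-07-01")))
  traces <- vector("list", length(seeds))
  rows <- list()
  for (r in seq_along(seeds)) {
    s <- run_season(cfg, temps = temps, seed = seeds[r])
    gm_rel <- apply(s$counts[, -1L, , , 2L, drop = FALSE], 1L, sum)
    gm <- s$gm_field_hatched + gm_rel
    traces[[r]] <- data.frame(date = s$dates, wt = s$wt_total, gm = gm)
    for (cp in seq_along(cps)) {
      d <- which(s$dates == cps[cp])
      if (length(d) == 1L)
        rows[[length(rows) + 1L]] <- data.frame(
          replicate = r, date = cps[cp], wt = s$wt_total[d], gm = gm[d])
    }
  }
  # release schedule keeps only 4 successive weekly April dates
  structure(list(kind = kind, n = n,
                 traces = traces,
                 checkpoints = do.call(rbind, rows)),
            class = "april_run")
}

#' Fit a Hill dose-response curve
#'
#' Least-squares fit of \code{response = top * d^h / (ec50^h + d^h)} by
#' Levenberg-Marquardt ([minpack.lm::nlsLM()]), as used for the
#' dose-dependent female-survival curve.
#'
#' @param doses non-negative dose vector (>= 4 distinct values).
#' @param responses observed responses, same length.
#' @return An object of class \code{hill_fit}: list with \code{top},
#'   \code{ec50}, \code{h}, \code{r_squared}, \code{t_value} (the
#'   Hill-slope t statistic), \code{residuals} and the underlying
#'   \code{fit}.
#' @examples
#' d <- c(0, 1, 2, 5, 10, 20, 50, 100)
#' y <- 1 * d^2 / (5^2 + d^2)
#' fit_hill(d, y)
#' @export
fit_hill <- function(doses, responses) {
  if (!is.numeric(doses) || !is.numeric(responses) ||
      length(doses) != length(responses))
    stop("doses and responses must be numeric vectors of equal length",
         call. = FALSE)
  if (length(unique(doses)) < 4L)
    stop("need at least 4 distinct dose points", call. = FALSE)
  if (any(doses < 0)) stop("doses must be >= 0", call. = FALSE)
  if (stats::sd(responses) == 0 || all(responses == 0))
    stop("degenerate (constant) responses: Hill fit is undefined",
         call. = FALSE)
  d <- doses; y <- responses
  start <- list(top = max(y),
                ec50 = max(stats::median(d[d > 0]), 1e-3),
                h = 2)
  fit <- minpack.lm::nlsLM(
    y ~ top * d^h / (ec50^h + d^h),
    start = start,
    lower = c(top = 0, ec50 = 1e-9, h = 1e-3),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- stats::coef(fit)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  tv <- tryCatch(summary(fit)$coefficients["h", "t value"],
                 error = function(e) NA_real_)
  structure(list(top = unname(cf["top"]), ec50 = unname(cf["ec50"]),
                 h = unname(cf["h"]),
                 r_squared = 1 - ss_res / ss_tot,
                 t_value = tv,
                 residuals = stats::residuals(fit),
                 fit = fit),
            class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf(
    "Hill fit: top = %.4g, ec50 = %.4g, h = %.4g (R^2 = %.3f, slope t = %.3g)\n",
    x$top, x$ec50, x$h, x$r_squared, x$t_value))
  invisible(x)
}

#' @export
coef.hill_fit <- function(object, ...) {
  c(top = object$top, ec50 = object$ec50, h = object$h)
}

#' @export
predict.hill_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(stats::fitted(object$fit))
  d <- if (is.list(newdata)) newdata$d else newdata
  object$top * d^object$h / (object$ec50^object$h + d^object$h)
}
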