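# Plate-level phenotype statistics: 4-day hatching rates, population
# metrics (days to 50 viable worms, days to 50 L4-or-older worms,
# population death) with 30-day termination, and product-limit survival
# curves in the cumulative-incidence orientation used for screen
# figures.

#' Hatching rate of one plate
#'
#' Total hatched embryos over total eggs laid across the (up to 4)
#' assay days, as a percentage to two decimals.  Progeny from mothers
#' that died or were lost stay included.  A plate with zero eggs laid
#' yields `NA` (undefined rate), not an error, so batch summaries keep
#' going.
#'
#' @param plate data.frame with columns `eggs_laid` and `hatched`, one
#'   row per day.
#' @return percentage (0-100) or `NA`.
#' @examples
#' hatching_rate(data.frame(eggs_laid = c(60, 40), hatched = c(30, 20)))
#' @export
hatching_rate <- function(plate) {
  laid <- sum(plate$eggs_laid)
  hatched <- sum(plate$hatched)
  if (hatched > laid)
    stop_domain("more embryos hatched (", hatched, ") than eggs laid (",
                laid, ")")
  if (laid == 0) return(NA_real_)
  round_half_up(100 * hatched / laid, 2)
}

#' Event records of one population plate
#'
#' For each of the three population metrics, the first day the metric is
#' met (observed) or the day observation ends (censored).  "Reaching 50"
#' is implemented as the first day the daily count is `>= threshold`
#' (counts are daily snapshots).  A plate that dies before reaching a
#' count metric is censored for that metric at its death day (competing
#' event treated as censoring); plates alive without reaching a metric
#' are censored at the `horizon` (default 30 days, when the assay is
#' terminated).
#'
#' @param plate data.frame for one plate, columns `day`, `viable`,
#'   `l4plus`, and optionally `dead_flag`; rows must be sorted by day.
#' @param threshold population size defining the count metrics.
#' @param horizon termination day.
#' @return data.frame with columns `metric` (`reach_viable`,
#'   `reach_l4`, `death`), `day`, `observed`.
#' @export
population_events <- function(plate, threshold = 50L, horizon = 30L) {
  if (is.unsorted(plate$day, strictly = TRUE))
    stop_domain("plate days must be strictly increasing")
  if (any(plate$l4plus > plate$viable))
    stop_domain("l4plus exceeds viable count")
  dead <- if ("dead_flag" %in% names(plate)) plate$dead_flag == 1
  else plate$viable == 0
  death_day <- if (any(dead)) plate$day[which(dead)[1]] else NA_integer_
  end_day <- if (!is.na(death_day)) death_day else horizon

  first_cross <- function(counts) {
    hit <- which(counts >= threshold)
    if (length(hit)) c(day = plate$day[hit[1]], observed = 1L)
    else c(day = end_day, observed = 0L)
  }
  v <- first_cross(plate$viable)
  l <- first_cross(plate$l4plus)
  d <- if (!is.na(death_day)) c(day = death_day, observed = 1L)
  else c(day = horizon, observed = 0L)
  data.frame(metric = c("reach_viable", "reach_l4", "death"),
             day = as.integer(c(v["day"], l["day"], d["day"])),
             observed = as.logical(c(v["observed"], l["observed"],
                                     d["observed"])),
             stringsAsFactors = FALSE)
}

#' Product-limit survival curve over plates
#'
#' Standard Kaplan-Meier estimate `S(t) = prod_{u <= t} (1 - d_u/n_u)`
#' over the plate-level event records of one metric, with events
#' preceding censorings at tied days.  The complement `1 - S(t)` is the
#' "percentage of plates to reach the metric by day t" orientation used
#' in screen figures.
#'
#' @param event_records data.frame with columns `day` and `observed`
#'   (logical), one row per plate.
#' @return object of class `SurvivalCurve`: list with `event_times`,
#'   `estimates` (S at those times), `cumulative_incidence` (1 - S),
#'   `n_risk`, `n_events`, `n_censored`.
#' @export
km_curve <- function(event_records) {
  if (nrow(event_records) == 0)
    stop_domain("km_curve needs at least one record")
  fit <- survival::survfit(
    survival::Surv(event_records$day, event_records$observed) ~ 1,
    conf.type = "none")
  structure(list(event_times = as.integer(fit$time),
                 estimates = fit$surv,
                 cumulative_incidence = 1 - fit$surv,
                 n_risk = fit$n.risk, n_events = fit$n.event,
                 n_censored = fit$n.censor),
            class = "SurvivalCurve")
}

#' Evaluate a survival curve at given days
#'
#' Right-continuous step-function evaluation; `S(t) = 1` before the
#' first event time.
#'
#' @param curve a [km_curve()] result.
#' @param days numeric vector of days.
#' @return survival estimates at `days`.
#' @export
survival_at <- function(curve, days) {
  vapply(days, function(d) {
    i <- which(curve$event_times <= d)
    if (length(i) == 0) 1 else curve$estimates[max(i)]
  }, numeric(1))
}

#' @export
print.SurvivalCurve <- function(x, ...) {
  cat("<SurvivalCurve> ", length(x$event_times), " time point(s), ",
      sum(x$n_events), " event(s), ", sum(x$n_censored),
      " censored\n", sep = "")
  invisible(x)
}

#' @export
plot.SurvivalCurve <- function(x, incidence = TRUE,
                               xlab = "day",
                               ylab = if (incidence)
                                 "fraction of plates reaching metric"
                               else "S(t)", ...) {
  y <- if (incidence) x$cumulative_incidence else x$estimates
  y0 <- if (incidence) 0 else 1
  graphics::plot(stats::stepfun(x$event_times, c(y0, y)),
                 do.points = FALSE, xlab = xlab, ylab = ylab,
                 ylim = c(0, 1), ...)
  invisible(x)
}

#' Per-strain phenotype summary table
#'
#' Aggregates hatch and population plates per strain: mean eggs laid
#' per plate, pooled hatching rate (total hatched / total laid across
#' plates), percentage of plates reaching each count metric, percentage
#' dying, and plate count.
#'
#' @param hatch hatch data.frame (`strain_id, plate_id, day, eggs_laid,
#'   hatched`); may be `NULL`.
#' @param population population data.frame (`strain_id, plate_id, day,
#'   viable, l4plus, dead_flag`); may be `NULL`.
#' @param threshold,horizon see [population_events()].
#' @return data.frame, one row per strain: `strain_id`,
#'   `mean_eggs_laid`, `hatching_rate`, `pct_reach_viable`,
#'   `pct_reach_l4`, `pct_died`, `n_plates`.
#' @export
strain_summary <- function(hatch = NULL, population = NULL,
                           threshold = 50L, horizon = 30L) {
  strains <- unique(c(if (!is.null(hatch)) hatch$strain_id,
                      if (!is.null(population)) population$strain_id))
  rows <- lapply(strains, function(s) {
    mean_eggs <- NA_real_; rate <- NA_real_
    n_h <- 0L
    if (!is.null(hatch)) {
      h <- hatch[hatch$strain_id == s, , drop = FALSE]
      if (nrow(h)) {
        per_plate <- tapply(h$eggs_laid, h$plate_id, sum)
        n_h <- length(per_plate)
        mean_eggs <- mean(per_plate)
        laid <- sum(h$eggs_laid)
        rate <- if (laid > 0)
          round_half_up(100 * sum(h$hatched) / laid, 2) else NA_real_
      }
    }
    pv <- NA_real_; pl <- NA_real_; pd <- NA_real_
    n_p <- 0L
    if (!is.null(population)) {
      p <- population[population$strain_id == s, , drop = FALSE]
      if (nrow(p)) {
        ev <- do.call(rbind, lapply(split(p, p$plate_id),
                                    population_events,
                                    threshold = threshold,
                                    horizon = horizon))
        n_p <- length(unique(p$plate_id))
        pct <- function(metric) round_half_up(
          100 * sum(ev$observed[ev$metric == metric]) / n_p, 2)
        pv <- pct("reach_viable"); pl <- pct("reach_l4")
        pd <- pct("death")
      }
    }
    data.frame(strain_id = s, mean_eggs_laid = mean_eggs,
               hatching_rate = rate, pct_reach_viable = pv,
               pct_reach_l4 = pl, pct_died = pd,
               n_plates = max(n_h, n_p), stringsAsFactors = FALSE)
  })
  if (length(rows)) do.call(rbind, rows)
  else data.frame(strain_id = character(), mean_eggs_laid = numeric(),
                  hatching_rate = numeric(), pct_reach_viable = numeric(),
                  pct_reach_l4 = numeric(), pct_died = numeric(),
                  n_plates = integer(), stringsAsFactors = FALSE)
}
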