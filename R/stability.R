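#' Per-tick detected-cow counts on a complete grid
#'
#' Collapses long-form detection snapshots to the number of IDs detected at
#' every tick of every day, filling ticks at which nothing was detected with
#' zero so the grid is complete (288 ticks per day at the default 5-minute
#' interval).
#'
#' @param snapshots long-form data.frame (day, tick_minute, id) as produced
#'   by [emulate_system()] or read from file.
#' @param n_days number of days in the study period (default: max day seen).
#' @param tick sampling interval in minutes (default 5).
#' @return data.frame (day, tick_minute, count), `n_days * 1440/tick` rows.
#' @export
snapshot_counts <- function(snapshots, n_days = max(snapshots$day),
                            tick = 5L) {
  stopifnot(1440 %% tick == 0)
  ticks <- seq.int(0L, 1439L, by = tick)
  tab <- table(factor(snapshots$day, levels = seq_len(n_days)),
               factor(snapshots$tick_minute, levels = ticks))
  data.frame(day = rep(seq_len(n_days), each = length(ticks)),
             tick_minute = rep(ticks, times = n_days),
             count = as.vector(t(tab)))
}

#' Hourly mean detection proportions
#'
#' Averages the per-tick detected counts within each hour (12 ticks per hour
#' at a 5-minute interval) and divides by the day's AMS-visiting cow count —
#' the day's ground-truth herd presence. Proportions above 1 are legal and
#' retained: they indicate overdetection (more simultaneous detections than
#' cows, e.g. ghost tracks under difficult lighting).
#'
#' @param counts data.frame (day, tick_minute, count) from
#'   [snapshot_counts()].
#' @param ams_daily_counts named vector or mapping day -> number of cows in
#'   the day's AMS list.
#' @param tick sampling interval in minutes (default 5).
#' @return data.frame (day, hour, mean_count, proportion, complete), one row
#'   per (day, hour); `complete` flags hours with all ticks present. Rows for
#'   days with a zero AMS count are dropped with a warning.
#' @export
hourly_proportions <- function(counts, ams_daily_counts, tick = 5L) {
  need <- c("day", "tick_minute", "count")
  stopifnot(all(need %in% names(counts)))
  per_hour <- 60 / tick
  hour <- counts$tick_minute %/% 60L
  agg <- stats::aggregate(counts$count,
                          by = list(day = counts$day, hour = hour),
                          FUN = function(v) c(mean = mean(v), n = length(v)))
  out <- data.frame(day = agg$day, hour = agg$hour,
                    mean_count = agg$x[, "mean"],
                    n_ticks = agg$x[, "n"])
  out <- out[order(out$day, out$hour), ]
  out$complete <- out$n_ticks == per_hour
  if (any(!out$complete)) {
    warning(sprintf("%d (day, hour) cell(s) have missing ticks; flagged",
                    sum(!out$complete)), call. = FALSE)
  }

  days <- as.character(out$day)
  denom <- ams_daily_counts[days]
  if (anyNA(denom)) {
    stop("missing AMS daily count for day(s): ",
         paste(unique(days[is.na(denom)]), collapse = ", "), call. = FALSE)
  }
  zero <- denom == 0
  if (any(zero)) {
    warning(sprintf("excluding %d row(s) with zero AMS count",
                    sum(zero)), call. = FALSE)
  }
  out$proportion <- ifelse(zero, NA_real_, out$mean_count / denom)
  out <- out[!zero, c("day", "hour", "mean_count", "proportion", "complete")]
  rownames(out) <- NULL
  out
}

#' AMS daily cow counts from a visit log
#'
#' @param visits AMS visit data.frame (day, visit_minute, cow_id).
#' @param n_days number of days (default: max day seen).
#' @return named integer vector, day -> number of distinct visiting cows.
#' @export
ams_daily_counts <- function(visits, n_days = max(visits$day)) {
  cnt <- vapply(split(visits$cow_id, factor(visits$day,
                                            levels = seq_len(n_days))),
                function(v) length(unique(v)), integer(1))
  names(cnt) <- as.character(seq_len(n_days))
  cnt
}

#' Fit the hour-fixed / day-random detection-stability model
#'
#' Fits, to a balanced table of hourly detection proportions (every day
#' contributes every hour), the variance-components model
#' `y[day, hour] = mu + hour_effect + day_effect + error`, with hour a fixed
#' effect and day a random effect capturing day-to-day repeated measurement.
#' Balance permits exact moment-based (ANOVA) estimation, which coincides
#' with REML in this layout: hour means are the per-hour averages across
#' days, the residual variance is the hour-by-day interaction mean square,
#' and the day variance is `max(0, (MS_day - MS_resid) / n_hours)`.
#' Unbalanced input is an explicit error, never silently approximated.
#'
#' @param rows data.frame with columns `day`, `hour`, `proportion` (e.g.
#'   from [hourly_proportions()]).
#' @return an object of class `stability_fit`: hour estimated marginal means,
#'   their common standard error `sqrt((var_day + var_resid) / n_days)`,
#'   variance components, the pairwise-contrast standard error
#'   `sqrt(2 * var_resid / n_days)` (day effects cancel within a day), and
#'   the residual degrees of freedom `(n_hours - 1) * (n_days - 1)`.
#' @export
fit_hour_day_model <- function(rows) {
  stopifnot(all(c("day", "hour", "proportion") %in% names(rows)))
  if (anyNA(rows$proportion)) {
    stop("proportions contain NA; clean or exclude first", call. = FALSE)
  }
  days <- sort(unique(rows$day))
  hours <- sort(unique(rows$hour))
  D <- length(days)
  H <- length(hours)
  if (D < 2) stop("need >= 2 days to separate day and residual variance",
                  call. = FALSE)
  if (H < 2) stop("need >= 2 hours", call. = FALSE)
  if (nrow(rows) != D * H ||
      anyDuplicated(rows[c("day", "hour")]) > 0) {
    stop("unbalanced layout: every day must contribute every hour exactly once",
         call. = FALSE)
  }

  y <- matrix(NA_real_, D, H, dimnames = list(days, hours))
  y[cbind(match(rows$day, days), match(rows$hour, hours))] <- rows$proportion

  grand <- mean(y)
  hour_means <- colMeans(y)
  day_means <- rowMeans(y)
  ss_day <- H * sum((day_means - grand)^2)
  resid <- y - outer(day_means, hour_means, "+") + grand
  ss_resid <- sum(resid^2)
  ms_day <- ss_day / (D - 1)
  df_resid <- as.integer((H - 1) * (D - 1))
  ms_resid <- ss_resid / df_resid
  var_resid <- ms_resid
  var_day <- max(0, (ms_day - ms_resid) / H)

  structure(list(
    hour_means = hour_means,
    hours = hours,
    se_mean = sqrt((var_day + var_resid) / D),
    se_contrast = sqrt(2 * var_resid / D),
    var_day = var_day,
    var_resid = var_resid,
    df_resid = df_resid,
    n_days = D,
    n_hours = H,
    grand_mean = grand
  ), class = "stability_fit")
}

#' @export
print.stability_fit <- function(x, ...) {
  cat(sprintf("<stability_fit> %d hours x %d days\n", x$n_hours, x$n_days))
  cat(sprintf("  day variance %.5g, residual variance %.5g, df = %d\n",
              x$var_day, x$var_resid, x$df_resid))
  cat(sprintf("  hourly-mean SE %.4g; grand mean %.4g\n",
              x$se_mean, x$grand_mean))
  invisible(x)
}

#' Tukey-adjusted pairwise hour comparisons
#'
#' All `choose(n_hours, 2)` pairwise differences of hourly estimated marginal
#' means (276 pairs for a full 24-hour day), each with a familywise-adjusted
#' p-value from the studentized range distribution with `n_hours` groups and
#' the model's residual degrees of freedom. Day effects cancel in within-day
#' contrasts, so the contrast standard error involves only the residual
#' variance. A degenerate fit (zero residual variance with unequal means)
#' yields p = 0 and is flagged as a boundary case.
#'
#' @param fit a [fit_hour_day_model()] result.
#' @param alpha significance threshold (default 0.01).
#' @return data.frame (hour_a, hour_b, difference, adjusted_p, significant).
#' @export
tukey_pairwise <- function(fit, alpha = 0.01) {
  stopifnot(inherits(fit, "stability_fit"), alpha > 0, alpha < 1)
  H <- fit$n_hours
  if (H < 2) stop("need >= 2 hours for pairwise comparisons", call. = FALSE)
  idx <- utils::combn(H, 2)
  a <- idx[1, ]
  b <- idx[2, ]
  diff <- fit$hour_means[b] - fit$hour_means[a]
  se_q <- sqrt(fit$var_resid / fit$n_days)  # SE on the studentized-range scale
  if (se_q == 0) {
    if (any(diff != 0)) {
      warning("zero residual variance with unequal means: boundary case, p = 0",
              call. = FALSE)
    }
    p <- ifelse(diff == 0, 1, 0)
  } else {
    p <- stats::ptukey(abs(diff) / se_q, nmeans = H, df = fit$df_resid,
                       lower.tail = FALSE)
  }
  data.frame(hour_a = fit$hours[a], hour_b = fit$hours[b],
             difference = unname(diff), adjusted_p = unname(p),
             significant = unname(p < alpha))
}
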