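#' Activity and zone vocabularies
#'
#' The monitoring system classifies each cow at each sampling tick into one of
#' six activities and one of six barn zones. Both vocabularies are closed: no
#' other label is admitted anywhere in the package.
#'
#' @return a character vector of labels.
#' @export
activity_labels <- function() {
  c("eating", "drinking", "lying", "standing", "walking", "waiting")
}

#' @rdname activity_labels
#' @export
zone_labels <- function() {
  c("alley", "drinking_trough", "feeding_trough", "cubicle", "ams",
    "ams_waiting_area")
}

# activity -> admissible zones. "waiting" is by definition standing in the
# AMS waiting area before milking, so it is only ever generated there.
.compat_map <- list(
  eating   = "feeding_trough",
  drinking = "drinking_trough",
  lying    = "cubicle",
  waiting  = "ams_waiting_area",
  standing = c("alley", "cubicle", "ams", "ams_waiting_area",
               "feeding_trough"),
  walking  = "alley"
)

# canonical zone used when a single zone must represent an activity
.canonical_zone <- c(
  eating = "feeding_trough", drinking = "drinking_trough", lying = "cubicle",
  standing = "alley", walking = "alley", waiting = "ams_waiting_area"
)

#' Activity/zone compatibility
#'
#' Deterministic truth value from a fixed compatibility map: eating only at
#' the feeding trough, drinking only at the drinking trough, lying only in a
#' cubicle, waiting only in the AMS waiting area, walking only in the alley,
#' and standing anywhere a cow can stand (alley, cubicle, AMS, AMS waiting
#' area, feeding trough).
#'
#' @param activity,zone label vectors (recycled to common length).
#' @return logical vector.
#' @examples
#' activity_zone_compatible("waiting", "ams_waiting_area") # TRUE
#' activity_zone_compatible("drinking", "cubicle")         # FALSE
#' @export
activity_zone_compatible <- function(activity, zone) {
  if (!all(activity %in% activity_labels())) {
    stop("unknown activity label", call. = FALSE)
  }
  if (!all(zone %in% zone_labels())) {
    stop("unknown zone label", call. = FALSE)
  }
  mapply(function(a, z) z %in% .compat_map[[a]], activity, zone,
         USE.NAMES = FALSE)
}

#' Herd behavior profile
#'
#' Parameters governing the synthetic herd's time budgets. Defaults emulate a
#' freestall Holstein herd: roughly half the day lying (more at night), a
#' morning TMR feeding peak between 0700 and 0900, and at least one voluntary
#' AMS visit per cow per day.
#'
#' @param weights named non-negative base time-budget weights over the six
#'   activities; not all zero. They need not sum to one.
#' @param night_lying_mult multiplicative boost (> 0) of the lying weight
#'   during night hours; values > 1 produce the night-increased lying typical
#'   of dairy cows.
#' @param night_window `c(start, end)` night window in minutes since midnight,
#'   wrapping midnight; default 2200-0600.
#' @param feeding_window `c(start, end)` minutes since midnight of the daily
#'   fresh-feed delivery; eating weight is boosted inside it.
#' @param feeding_boost multiplicative boost of the eating weight inside the
#'   feeding window.
#' @param mean_bout_ticks named mean activity-bout lengths in ticks (geometric
#'   bout model, minimum one tick).
#' @param mean_ams_visits mean AMS visits per cow per day (Poisson, truncated
#'   at >= 1 for cow-days that visit at all).
#' @param visit_prob per-cow-day probability of at least one AMS visit
#'   (default 1: every cow is milked every day, so the daily AMS list covers
#'   the whole herd).
#' @return an object of class `behavior_profile`.
#' @export
behavior_profile <- function(weights = c(eating = 0.20, drinking = 0.02,
                                         lying = 0.50, standing = 0.15,
                                         walking = 0.08, waiting = 0.05),
                             night_lying_mult = 2.5,
                             night_window = c(22 * 60, 6 * 60),
                             feeding_window = c(7 * 60, 9 * 60),
                             feeding_boost = 3,
                             mean_bout_ticks = c(eating = 6, drinking = 1,
                                                 lying = 12, standing = 3,
                                                 walking = 1, waiting = 2),
                             mean_ams_visits = 2.5,
                             visit_prob = 1.0) {
  acts <- activity_labels()
  stopifnot(
    setequal(names(weights), acts), all(weights >= 0), any(weights > 0),
    night_lying_mult > 0, feeding_boost > 0,
    setequal(names(mean_bout_ticks), acts), all(mean_bout_ticks >= 1),
    mean_ams_visits > 0, visit_prob >= 0, visit_prob <= 1
  )
  structure(list(weights = weights[acts], night_lying_mult = night_lying_mult,
                 night_window = night_window,
                 feeding_window = feeding_window,
                 feeding_boost = feeding_boost,
                 mean_bout_ticks = mean_bout_ticks[acts],
                 mean_ams_visits = mean_ams_visits, visit_prob = visit_prob),
            class = "behavior_profile")
}

#' Simulation configuration
#'
#' @param seed integer seed; the whole simulation is reproducible from it.
#' @param n_days number of simulated days (default 31, a one-month
#'   observation period).
#' @param tick sampling interval in minutes (default 5); must divide 1440.
#' @param profile a [behavior_profile()].
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(seed, n_days = 31, tick = 5,
                       profile = behavior_profile()) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  if (!is.numeric(n_days) || n_days < 1 || n_days != trunc(n_days)) {
    stop_field("n_days", "must be an integer >= 1")
  }
  if (!is.numeric(tick) || tick < 1 || 1440 %% tick != 0) {
    stop_field("tick", "must divide 1440 minutes")
  }
  stopifnot(inherits(profile, "behavior_profile"))
  structure(list(seed = as.integer(seed), n_days = as.integer(n_days),
                 tick = as.integer(tick), profile = profile),
            class = "sim_config")
}

# minutes-since-midnight in the (possibly midnight-wrapping) window?
in_window <- function(minute, window) {
  if (window[1] <= window[2]) {
    minute >= window[1] & minute < window[2]
  } else {
    minute >= window[1] | minute < window[2]
  }
}

#' Simulate gold-standard herd behavior
#'
#' Generates one activity/zone record per cow per sampling tick over the study
#' period, plus an AMS visit log, with the marginal structure the evaluation
#' assumes: six-activity / six-zone closed vocabularies, every emitted
#' (activity, zone) pair compatible, a higher herd-level lying proportion at
#' night (in expectation) when the profile's night multiplier exceeds 1, and
#' at least one AMS visit per cow-day with the profile's visit probability.
#'
#' Behavior is a per-cow semi-Markov schedule: activity bouts are drawn with
#' time-of-day-modulated weights and geometric bout lengths (minimum one
#' tick). Zones follow the activity deterministically except for standing
#' bouts, which draw one admissible zone per bout.
#'
#' @param cfg a [farm_config()]; `n_cows` sets the herd.
#' @param sim a [sim_config()].
#' @return a list of class `herd_truth` with elements
#' \describe{
#'   \item{truth}{data.frame (day, tick_minute, cow_id, activity, zone), one
#'     row per cow per tick — `n_cows * n_days * 1440/tick` rows.}
#'   \item{visits}{data.frame (day, visit_minute, cow_id) of AMS visits.}
#'   \item{herd}{character vector of cow IDs.}
#'   \item{tick, n_days}{the sampling grid used.}
#' }
#' @export
simulate_herd <- function(cfg, sim) {
  stopifnot(inherits(cfg, "farm_config"), inherits(sim, "sim_config"))
  if (cfg$n_cows < 1) stop_field("n_cows", "empty herd")
  set.seed(sim$seed)

  pr <- sim$profile
  n_ticks <- 1440L %/% sim$tick
  ticks <- seq.int(0L, 1439L, by = sim$tick)
  herd <- sprintf("cow%03d", seq_len(cfg$n_cows))
  acts <- activity_labels()

  # tick-by-activity weight matrix for one day
  W <- matrix(pr$weights, nrow = n_ticks, ncol = 6L, byrow = TRUE)
  night <- in_window(ticks, pr$night_window)
  W[night, 3L] <- W[night, 3L] * pr$night_lying_mult  # lying
  feed <- in_window(ticks, pr$feeding_window)
  W[feed, 1L] <- W[feed, 1L] * pr$feeding_boost       # eating
  p_bout <- 1 / pr$mean_bout_ticks                    # geometric stop prob

  n_cowdays <- cfg$n_cows * sim$n_days
  act_codes <- vector("list", n_cowdays)
  cd <- 0L
  for (day in seq_len(sim$n_days)) {
    for (cow in seq_len(cfg$n_cows)) {
      a <- integer(n_ticks)
      pos <- 0L
      while (pos < n_ticks) {
        lab <- sample.int(6L, 1L, prob = W[pos + 1L, ])
        len <- 1L + stats::rgeom(1L, p_bout[lab])
        len <- min(len, n_ticks - pos)
        a[(pos + 1L):(pos + len)] <- lab
        pos <- pos + len
      }
      cd <- cd + 1L
      act_codes[[cd]] <- a
    }
  }
  act <- unlist(act_codes, use.names = FALSE)

  # zones: deterministic per activity except standing (one draw per bout)
  zone <- .canonical_zone[acts[act]]
  r <- rle(act)
  stand_runs <- which(r$values == 4L)
  if (length(stand_runs)) {
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    zchoice <- sample(.compat_map$standing, length(stand_runs),
                      replace = TRUE,
                      prob = c(0.50, 0.20, 0.05, 0.10, 0.15))
    for (k in seq_along(stand_runs)) {
      i <- stand_runs[k]
      zone[starts[i]:ends[i]] <- zchoice[k]
    }
  }

  truth <- data.frame(
    day = rep(seq_len(sim$n_days), each = cfg$n_cows * n_ticks),
    tick_minute = rep(ticks, times = n_cowdays),
    cow_id = rep(rep(herd, each = n_ticks), times = sim$n_days),
    activity = acts[act],
    zone = unname(zone),
    stringsAsFactors = FALSE
  )

  # AMS visits: Bernoulli(visit_prob) per cow-day; zero-truncated Poisson
  # count for visiting cow-days; visit times uniform over the day
  visiting <- stats::runif(n_cowdays) < pr$visit_prob
  lam <- pr$mean_ams_visits
  nvis <- sum(visiting)
  k <- integer(n_cowdays)
  if (nvis) {
    u <- stats::runif(nvis, stats::ppois(0, lam), 1)
    k[visiting] <- stats::qpois(u, lam)
  }
  vis_day <- rep(rep(seq_len(sim$n_days), each = cfg$n_cows), times = 1L)
  vis_cow <- rep(herd, times = sim$n_days)
  visits <- data.frame(
    day = rep(vis_day, k),
    visit_minute = sample.int(1440L, sum(k), replace = TRUE) - 1L,
    cow_id = rep(vis_cow, k),
    stringsAsFactors = FALSE
  )
  visits <- visits[order(visits$day, visits$visit_minute, visits$cow_id), ]
  rownames(visits) <- NULL

  structure(list(truth = truth, visits = visits, herd = herd,
                 tick = sim$tick, n_days = sim$n_days),
            class = "herd_truth")
}

#' @export
print.herd_truth <- function(x, ...) {
  cat(sprintf("<herd_truth> %d cows, %d days, %d-min tick: %s truth rows, %s AMS visits\n",
              length(x$herd), x$n_days, x$tick,
              format(nrow(x$truth), big.mark = ","),
              format(nrow(x$visits), big.mark = ",")))
  invisible(x)
}
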