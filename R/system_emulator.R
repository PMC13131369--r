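#' Discrete Frechet distance between two trajectories
#'
#' The discrete Frechet distance is the minimum over all order-preserving
#' couplings of two point sequences of the maximal pointwise Euclidean
#' distance. It is the trajectory-similarity measure used to associate an
#' observed track with the RFID-anchored reference trajectories recorded
#' during system calibration. Computed by the standard dynamic program
#' `c(i,j) = max(d(p_i, q_j), min(c(i-1,j), c(i-1,j-1), c(i,j-1)))`.
#'
#' @param p,q trajectories: numeric matrices with two columns (x, y) in
#'   meters and at least one row each.
#' @return non-negative distance in meters; 0 iff the sequences are
#'   identical. Symmetric in its arguments.
#' @examples
#' discrete_frechet(rbind(c(0, 0)), rbind(c(3, 4))) # 5
#' @export
discrete_frechet <- function(p, q) {
  p <- as_trajectory(p)
  q <- as_trajectory(q)
  n <- nrow(p)
  m <- nrow(q)
  d <- sqrt(outer(p[, 1], q[, 1], "-")^2 + outer(p[, 2], q[, 2], "-")^2)
  ca <- matrix(0, n, m)
  ca[1, 1] <- d[1, 1]
  for (i in seq_len(n)[-1]) ca[i, 1] <- max(ca[i - 1, 1], d[i, 1])
  for (j in seq_len(m)[-1]) ca[1, j] <- max(ca[1, j - 1], d[1, j])
  if (n > 1 && m > 1) {
    for (i in 2:n) {
      for (j in 2:m) {
        ca[i, j] <- max(d[i, j],
                        min(ca[i - 1, j], ca[i - 1, j - 1], ca[i, j - 1]))
      }
    }
  }
  ca[n, m]
}

as_trajectory <- function(p) {
  p <- as.matrix(p)
  if (is.null(dim(p)) || ncol(p) != 2L || nrow(p) < 1L) {
    stop("a trajectory is a matrix of >= 1 planar (x, y) positions",
         call. = FALSE)
  }
  if (!all(is.finite(p))) stop("trajectory coordinates must be finite",
                               call. = FALSE)
  storage.mode(p) <- "double"
  p
}

#' Associate observed trajectories with reference trajectories
#'
#' Matches each observed track to the calibration pool by discrete Frechet
#' distance. A single observation gets the pool ID with minimal distance if
#' that minimum is below `threshold`, else `NA` (unassigned). When several
#' observations compete in one batch the assignment is injective — no two
#' tracks may carry the same identity simultaneously: the batch solution
#' minimizes total matching cost, with an unassigned track priced at
#' `threshold` (so a track is matched exactly when a reference within the
#' threshold is available to it). Exact ties are broken by lexicographic
#' reference ID for determinism.
#'
#' @param obs a trajectory, or a list of trajectories for batch assignment.
#' @param pool named list mapping cow IDs to reference trajectories;
#'   non-empty.
#' @param threshold matching gate in meters (> 0): distances at or above it
#'   never match.
#' @return for a single trajectory, a cow ID or `NA_character_`; for a list,
#'   a character vector of the same length.
#' @export
assign_identity <- function(obs, pool, threshold) {
  if (!length(pool)) stop("empty reference pool", call. = FALSE)
  if (is.null(names(pool)) || anyNA(names(pool)) || any(names(pool) == "")) {
    stop("reference pool must be named by cow ID", call. = FALSE)
  }
  stopifnot(is.numeric(threshold), threshold > 0)
  single <- !is.list(obs)
  if (single) obs <- list(obs)

  ord <- order(names(pool))  # lexicographic tie-break
  pool <- pool[ord]
  D <- vapply(pool, function(ref) {
    vapply(obs, discrete_frechet, numeric(1), q = ref)
  }, numeric(length(obs)))
  D <- matrix(D, nrow = length(obs), ncol = length(pool),
              dimnames = list(NULL, names(pool)))

  idx <- .solve_assignment(D, threshold)
  out <- ifelse(is.na(idx), NA_character_, colnames(D)[idx])
  if (single) out[1L] else out
}

# exact min-total-cost injective assignment; option 0 = unassigned at cost
# `threshold`. Depth-first search over observations with branch-and-bound;
# references tried in increasing-cost order, index order on ties, so the
# first optimum found is the lexicographically preferred one.
.solve_assignment <- function(D, threshold) {
  n <- nrow(D)
  m <- ncol(D)
  best_cost <- Inf
  best <- rep(NA_integer_, n)
  assign <- rep(NA_integer_, n)
  used <- logical(m)

  recurse <- function(i, cost) {
    if (cost >= best_cost) return()
    if (i > n) {
      best_cost <<- cost
      best <<- assign
      return()
    }
    opts <- which(!used & D[i, ] < threshold)
    opts <- opts[order(D[i, opts], opts)]
    for (j in opts) {
      used[j] <<- TRUE
      assign[i] <<- j
      recurse(i + 1L, cost + D[i, j])
      used[j] <<- FALSE
      assign[i] <<- NA_integer_
    }
    recurse(i + 1L, cost + threshold)  # leave i unassigned
  }
  recurse(1L, 0)
  best
}

#' Monitoring-system error model
#'
#' Parameters of the stochastic degradation applied to gold-standard herd
#' data to emulate the outputs of a multi-camera tracking system. Defaults
#' are set to the operating point of a commercial freestall installation:
#' roughly 7% of cow-days missed, spurious "ghost" detections at 10% of herd
#' size per day, 75% correct identity assignment, activity labels 90%
#' accurate, location errors mostly co-occurring with activity errors, and a
#' night-time detection drop of 15 percentage points.
#'
#' @param daily_miss probability a truly present cow is absent from a given
#'   day's detected set (detection error acts at the cow-day level because
#'   detection is evaluated daily).
#' @param ghost_rate expected ghost detections per day, as a fraction of herd
#'   size; ghosts carry IDs from a disjoint namespace (`ghost*`), i.e. they
#'   are detections of "cows" absent from the herd registry.
#' @param id_correct probability a detected cow's record carries her true
#'   identity.
#' @param id_swap_share among identity errors, the fraction assigned some
#'   other herd ID; the remainder are emitted as `"unknown"`.
#' @param activity_confusion 6x6 row-stochastic matrix over
#'   [activity_labels()] (rows = true, columns = emitted).
#' @param location_cooccur probability a location error accompanies an
#'   activity error (errors are coupled: a misread activity usually comes
#'   with a misread zone).
#' @param zone_base_error independent zone-error rate when the activity is
#'   correct.
#' @param night_detect_drop additive reduction of the per-tick detection
#'   probability during night ticks.
#' @param night_window `c(start, end)` night window in minutes since
#'   midnight, wrapping midnight.
#' @return an object of class `error_model`.
#' @export
error_model <- function(daily_miss = 0.07, ghost_rate = 0.10,
                        id_correct = 0.75, id_swap_share = 0.5,
                        activity_confusion = default_activity_confusion(),
                        location_cooccur = 0.8, zone_base_error = 0.02,
                        night_detect_drop = 0.15,
                        night_window = c(22 * 60, 6 * 60)) {
  probs <- c(daily_miss = daily_miss, ghost_rate = ghost_rate,
             id_correct = id_correct, id_swap_share = id_swap_share,
             location_cooccur = location_cooccur,
             zone_base_error = zone_base_error,
             night_detect_drop = night_detect_drop)
  bad <- names(probs)[probs < 0 | probs > 1]
  if (length(bad)) stop_field(bad[1L], "probability must be in [0, 1]")
  cm <- as.matrix(activity_confusion)
  if (!identical(dim(cm), c(6L, 6L)) || any(cm < 0) ||
      any(abs(rowSums(cm) - 1) > 1e-9)) {
    stop_field("activity_confusion",
               "must be a 6x6 row-stochastic matrix (rows sum to 1)")
  }
  dimnames(cm) <- list(activity_labels(), activity_labels())
  structure(list(daily_miss = daily_miss, ghost_rate = ghost_rate,
                 id_correct = id_correct, id_swap_share = id_swap_share,
                 activity_confusion = cm,
                 location_cooccur = location_cooccur,
                 zone_base_error = zone_base_error,
                 night_detect_drop = night_detect_drop,
                 night_window = night_window),
            class = "error_model")
}

#' @rdname error_model
#' @param accuracy diagonal of the default confusion matrix; off-diagonal
#'   mass is spread uniformly.
#' @export
default_activity_confusion <- function(accuracy = 0.90) {
  stopifnot(accuracy >= 0, accuracy <= 1)
  cm <- matrix((1 - accuracy) / 5, 6, 6,
               dimnames = list(activity_labels(), activity_labels()))
  diag(cm) <- accuracy
  cm
}

#' Emulate monitoring-system outputs from gold-standard data
#'
#' Applies the [error_model()] to simulated truth: whole cow-days are
#' suppressed with probability `daily_miss`; ghost IDs appear at rate
#' `ghost_rate`; surviving records keep the true identity with probability
#' `id_correct` (otherwise another herd ID or `"unknown"`, split by
#' `id_swap_share`); activity labels pass through the confusion matrix; zone
#' errors co-occur with activity errors with probability `location_cooccur`
#' and otherwise arise at `zone_base_error`; and per-tick presence is thinned
#' by `night_detect_drop` at night. Fully reproducible for a fixed seed.
#'
#' Records carry a `true_id` column (the generator's ground-truth linkage,
#' `NA` for ghosts). A real deployment has no such column — it is what the
#' on-farm observer supplies — and it exists here so evaluation can align
#' system output with truth.
#'
#' @param ht a [simulate_herd()] result.
#' @param em an [error_model()].
#' @param seed integer seed for the emulation stage.
#' @return a list of class `mcmct_emulation` with elements
#' \describe{
#'   \item{records}{data.frame (day, tick_minute, assigned_id, activity,
#'     zone, true_id) of per-cow system records plus ghost records.}
#'   \item{snapshots}{data.frame (day, tick_minute, id) in long form: the set
#'     of detected IDs at each tick (true cow IDs of detected cows plus ghost
#'     IDs; never a duplicate ID within one tick).}
#'   \item{cow_days}{data.frame (cow_id, day, detected) — the emulator's own
#'     bookkeeping of cow-day suppression.}
#'   \item{herd, tick, n_days}{carried over from the input.}
#' }
#' @export
emulate_system <- function(ht, em = error_model(), seed = 1L) {
  stopifnot(inherits(ht, "herd_truth"), inherits(em, "error_model"))
  truth <- ht$truth
  herd <- ht$herd
  if (!all(truth$cow_id %in% herd)) {
    stop("truth contains a cow absent from the herd registry", call. = FALSE)
  }
  set.seed(seed)
  n_cows <- length(herd)
  n_days <- ht$n_days

  # (a) cow-day suppression
  cow_days <- expand.grid(cow_id = herd, day = seq_len(n_days),
                          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cow_days$detected <- stats::runif(nrow(cow_days)) >= em$daily_miss
  key <- paste(cow_days$cow_id, cow_days$day)
  keep_cd <- cow_days$detected[match(paste(truth$cow_id, truth$day), key)]

  # (f) per-tick night thinning
  night <- in_window(truth$tick_minute, em$night_window)
  keep_tick <- !night | stats::runif(nrow(truth)) >= em$night_detect_drop

  rec <- truth[keep_cd & keep_tick, , drop = FALSE]
  nr <- nrow(rec)

  # (c) identity assignment
  assigned <- rec$cow_id
  u <- stats::runif(nr)
  err <- u >= em$id_correct
  swap <- err & (u < em$id_correct + (1 - em$id_correct) * em$id_swap_share)
  if (any(swap)) {
    true_pos <- match(rec$cow_id[swap], herd)
    # uniform over the other n-1 herd IDs
    off <- 1L + floor(stats::runif(sum(swap)) * (n_cows - 1))
    assigned[swap] <- herd[1L + (true_pos - 1L + off) %% n_cows]
  }
  assigned[err & !swap] <- "unknown"

  # (d) activity confusion, grouped by true label
  acts <- activity_labels()
  sys_act <- rec$activity
  for (a in acts) {
    rows <- which(rec$activity == a)
    if (length(rows)) {
      sys_act[rows] <- sample(acts, length(rows), replace = TRUE,
                              prob = em$activity_confusion[a, ])
    }
  }

  # (e) zone errors, coupled to activity errors
  sys_zone <- rec$zone
  act_err <- sys_act != rec$activity
  u2 <- stats::runif(nr)
  coupled <- act_err & u2 < em$location_cooccur
  sys_zone[coupled] <- .canonical_zone[sys_act[coupled]]
  base_err <- !act_err & u2 < em$zone_base_error
  if (any(base_err)) {
    zl <- zone_labels()
    cur <- match(sys_zone[base_err], zl)
    off <- 1L + floor(stats::runif(sum(base_err)) * 5)
    sys_zone[base_err] <- zl[1L + (cur - 1L + off) %% 6L]
  }

  records <- data.frame(day = rec$day, tick_minute = rec$tick_minute,
                        assigned_id = assigned, activity = sys_act,
                        zone = sys_zone, true_id = rec$cow_id,
                        stringsAsFactors = FALSE)

  # (b) ghost detections: Poisson count per day, each a short presence bout
  n_ticks <- 1440L %/% ht$tick
  n_ghost <- stats::rpois(n_days, em$ghost_rate * n_cows)
  ghost_rows <- vector("list", n_days)
  for (d in seq_len(n_days)) {
    k <- n_ghost[d]
    if (!k) next
    gid <- sprintf("ghost%02d_%02d", d, seq_len(k))
    start <- sample.int(n_ticks, k, replace = TRUE) - 1L
    len <- 1L + stats::rgeom(k, 1 / 6)
    gact <- sample(acts, k, replace = TRUE)
    ghost_rows[[d]] <- data.frame(
      day = rep(d, sum(pmin(len, n_ticks - start))),
      tick_minute = unlist(lapply(seq_len(k), function(i) {
        seq.int(start[i], min(n_ticks - 1L, start[i] + len[i] - 1L)) * ht$tick
      })),
      assigned_id = rep(gid, pmin(len, n_ticks - start)),
      activity = rep(gact, pmin(len, n_ticks - start)),
      zone = rep(.canonical_zone[gact], pmin(len, n_ticks - start)),
      true_id = NA_character_,
      stringsAsFactors = FALSE
    )
  }
  ghosts <- do.call(rbind, ghost_rows)
  if (!is.null(ghosts)) {
    rownames(ghosts) <- NULL
    records <- rbind(records, ghosts)
  }

  # detection snapshots: true identities of detected cows + ghost IDs.
  snap_id <- c(rec$cow_id, if (!is.null(ghosts)) ghosts$assigned_id)
  snapshots <- data.frame(
    day = c(rec$day, if (!is.null(ghosts)) ghosts$day),
    tick_minute = c(rec$tick_minute, if (!is.null(ghosts)) ghosts$tick_minute),
    id = snap_id,
    stringsAsFactors = FALSE
  )
  # set semantics per tick (cow rows are unique by construction; guard anyway)
  snapshots <- snapshots[!duplicated(snapshots), , drop = FALSE]
  snapshots <- snapshots[order(snapshots$day, snapshots$tick_minute,
                               snapshots$id), , drop = FALSE]
  rownames(snapshots) <- NULL

  structure(list(records = records, snapshots = snapshots,
                 cow_days = cow_days, herd = herd, tick = ht$tick,
                 n_days = n_days),
            class = "mcmct_emulation")
}

#' @export
print.mcmct_emulation <- function(x, ...) {
  cat(sprintf("<mcmct_emulation> %d cows, %d days: %s records, %s snapshot entries, %.1f%% cow-days detected\n",
              length(x$herd), x$n_days,
              format(nrow(x$records), big.mark = ","),
              format(nrow(x$snapshots), big.mark = ","),
              100 * mean(x$cow_days$detected)))
  invisible(x)
}

#' Jittered reference-trajectory pool
#'
#' Builds a calibration pool from observed trajectories by adding isotropic
#' Gaussian position noise — a stand-in for the reference tracks a real
#' system records as cows pass the RFID reader during calibration.
#'
#' @param trajectories named list of trajectories (cow ID -> matrix).
#' @param sigma jitter standard deviation in meters per coordinate.
#' @param seed integer seed.
#' @return a named list of jittered trajectories.
#' @export
reference_pool <- function(trajectories, sigma = 0.25, seed = 1L) {
  stopifnot(is.list(trajectories), !is.null(names(trajectories)), sigma >= 0)
  set.seed(seed)
  lapply(trajectories, function(p) {
    p <- as_trajectory(p)
    p + matrix(stats::rnorm(length(p), 0, sigma), nrow(p), 2L)
  })
}
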