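#' Daily detection evaluation
#'
#' Compares the set of cows that visited the AMS at least once during a day
#' (the RFID-anchored ground truth of presence) with the set of IDs the
#' tracking system detected that day. Because every animal in the camera
#' field belongs to the herd and is traceable, true negatives do not exist at
#' the detection stage; the cells are
#' \describe{
#'   \item{tp_d}{present (in the AMS list) and detected,}
#'   \item{fn_d}{present but not detected,}
#'   \item{fp_d}{detected IDs absent from the day's herd registry (ghosts).}
#' }
#'
#' @param ams_cows set (character vector) of cow IDs that visited the AMS
#'   that day; must be a subset of `day_registry`.
#' @param detected set of IDs the system reported that day.
#' @param day_registry the day's herd registry (all cow IDs present).
#' @return an object of class `detection_counts` with fields `tp_d`, `fn_d`,
#'   `fp_d`.
#' @export
evaluate_detection_day <- function(ams_cows, detected, day_registry) {
  ams_cows <- unique(as.character(ams_cows))
  detected <- unique(as.character(detected))
  day_registry <- unique(as.character(day_registry))
  if (!all(ams_cows %in% day_registry)) {
    stop("AMS visitors must be a subset of the day's herd registry",
         call. = FALSE)
  }
  structure(list(tp_d = length(intersect(ams_cows, detected)),
                 fn_d = length(setdiff(ams_cows, detected)),
                 fp_d = length(setdiff(detected, day_registry))),
            class = "detection_counts")
}

#' Detection evaluation over a whole emulation
#'
#' Applies [evaluate_detection_day()] to every day of an emulation: the AMS
#' list is the set of cows with at least one visit that day, the detected set
#' is the union of IDs in the day's snapshots, and the registry is the herd.
#'
#' @param emu an [emulate_system()] result.
#' @param visits the AMS visit log from [simulate_herd()].
#' @return a data.frame with one row per day (day, tp_d, fn_d, fp_d) plus
#'   attribute `"pooled"`, the summed `detection_counts`.
#' @export
evaluate_detection <- function(emu, visits) {
  stopifnot(inherits(emu, "mcmct_emulation"))
  days <- seq_len(emu$n_days)
  det_by_day <- split(emu$snapshots$id, factor(emu$snapshots$day,
                                               levels = days))
  ams_by_day <- split(visits$cow_id, factor(visits$day, levels = days))
  rows <- lapply(days, function(d) {
    dc <- evaluate_detection_day(ams_by_day[[d]], det_by_day[[d]], emu$herd)
    data.frame(day = d, tp_d = dc$tp_d, fn_d = dc$fn_d, fp_d = dc$fp_d)
  })
  out <- do.call(rbind, rows)
  pooled <- structure(list(tp_d = sum(out$tp_d), fn_d = sum(out$fn_d),
                           fp_d = sum(out$fp_d)), class = "detection_counts")
  attr(out, "pooled") <- pooled
  out
}

#' Hybrid confusion-matrix counts
#'
#' The merged two-stage confusion matrix reflecting the sequential dependency
#' detection-then-identification: a cow must be detected before any identity,
#' activity or location can be assigned. Final TP = correctly detected and
#' task-correct; FN = detection miss or task error among present cows; FP =
#' detection-stage spurious outputs. True negatives never exist, and
#' identification-stage false positives are structurally impossible.
#' `tp + fn` always equals the number of truly present evaluated cows.
#'
#' Counts may be fractional so that percentage rows from a published
#' performance table can be fed directly to [compute_metrics()].
#'
#' @param tp,fn,fp non-negative counts (or percent units).
#' @return an object of class `hybrid_counts`.
#' @export
hybrid_counts <- function(tp, fn, fp) {
  stopifnot(is.numeric(tp), is.numeric(fn), is.numeric(fp),
            tp >= 0, fn >= 0, fp >= 0)
  structure(list(tp = tp, fn = fn, fp = fp), class = "hybrid_counts")
}

#' Build observation pairs from an emulation
#'
#' Reconstructs, for chosen days and ticks, the pairing an on-farm observer
#' would record: for every cow truly present, the gold identity/activity/zone
#' against the system's output (if the cow was detected at that tick), plus
#' one pair per ghost record (system output with no corresponding cow).
#'
#' @param ht a [simulate_herd()] result.
#' @param emu the matching [emulate_system()] result.
#' @param days days to include (default: all).
#' @param ticks ticks (minutes since midnight) to include (default: all).
#' @return a data.frame with columns present, gold_id, gold_activity,
#'   gold_zone, detected, sys_id, sys_activity, sys_zone.
#' @export
observation_pairs <- function(ht, emu, days = NULL, ticks = NULL) {
  stopifnot(inherits(ht, "herd_truth"), inherits(emu, "mcmct_emulation"))
  truth <- ht$truth
  rec <- emu$records
  if (!is.null(days)) {
    truth <- truth[truth$day %in% days, ]
    rec <- rec[rec$day %in% days, ]
  }
  if (!is.null(ticks)) {
    truth <- truth[truth$tick_minute %in% ticks, ]
    rec <- rec[rec$tick_minute %in% ticks, ]
  }
  ghost <- is.na(rec$true_id)
  cowrec <- rec[!ghost, ]
  m <- match(paste(truth$day, truth$tick_minute, truth$cow_id),
             paste(cowrec$day, cowrec$tick_minute, cowrec$true_id))
  detected <- !is.na(m)
  pairs <- data.frame(
    present = TRUE,
    gold_id = truth$cow_id,
    gold_activity = truth$activity,
    gold_zone = truth$zone,
    detected = detected,
    sys_id = ifelse(detected, cowrec$assigned_id[m], NA_character_),
    sys_activity = ifelse(detected, cowrec$activity[m], NA_character_),
    sys_zone = ifelse(detected, cowrec$zone[m], NA_character_),
    stringsAsFactors = FALSE
  )
  if (any(ghost)) {
    g <- rec[ghost, ]
    pairs <- rbind(pairs, data.frame(
      present = FALSE, gold_id = NA_character_,
      gold_activity = NA_character_, gold_zone = NA_character_,
      detected = TRUE, sys_id = g$assigned_id, sys_activity = g$activity,
      sys_zone = g$zone, stringsAsFactors = FALSE
    ))
  }
  rownames(pairs) <- NULL
  pairs
}

#' Classify observation pairs into hybrid confusion cells
#'
#' For `task = "identification"`, a pair is task-correct when the system's
#' assigned ID matches the gold ear-tag ID. For `"activity"` and
#' `"location"`, correctness is a label match on activity / zone among
#' detected cows — by default regardless of whether the identity was correct
#' (`restrict_to_identified = TRUE` restricts credit to correctly identified
#' cows). In every task, FN additionally counts detection misses, and FP is
#' the detection-stage false positives, shared across tasks.
#'
#' @param pairs a data.frame as returned by [observation_pairs()] (or read
#'   from an observer log with the same columns).
#' @param task one of `"identification"`, `"activity"`, `"location"`.
#' @param restrict_to_identified for activity/location, require a correct
#'   identity before a label can score as TP (default `FALSE`).
#' @return a [hybrid_counts()] object.
#' @export
classify_pairs <- function(pairs,
                           task = c("identification", "activity", "location"),
                           restrict_to_identified = FALSE) {
  task <- match.arg(task)
  need <- c("present", "gold_id", "gold_activity", "gold_zone", "detected",
            "sys_id", "sys_activity", "sys_zone")
  if (!all(need %in% names(pairs))) {
    stop("pairs must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  gold_ok <- pairs$gold_activity[pairs$present] %in% activity_labels() &
    pairs$gold_zone[pairs$present] %in% zone_labels()
  if (!all(gold_ok)) stop("gold labels outside the closed vocabularies",
                          call. = FALSE)

  fp <- sum(!pairs$present & pairs$detected)
  pres <- pairs[pairs$present, ]
  det <- pres$detected
  id_ok <- det & !is.na(pres$sys_id) & pres$sys_id == pres$gold_id
  correct <- switch(task,
    identification = id_ok,
    activity = det & pres$sys_activity == pres$gold_activity,
    location = det & pres$sys_zone == pres$gold_zone
  )
  if (task != "identification" && restrict_to_identified) {
    correct <- correct & id_ok
  }
  correct[is.na(correct)] <- FALSE
  tp <- sum(correct)
  fn <- nrow(pres) - tp
  hybrid_counts(tp, fn, fp)
}

#' Recall, precision and F1 from hybrid counts
#'
#' `recall = TP / (TP + FN)`, `precision = TP / (TP + FP)`, and the F1-score
#' is their harmonic mean `2 * precision * recall / (precision + recall)`.
#' A zero denominator yields `NA` with a warning — never a silent 0.
#'
#' @param h a [hybrid_counts()] (counts may be fractional / percent units).
#' @return an object of class `eval_metrics`: list with `recall`,
#'   `precision`, `f1` as proportions in `[0, 1]`.
#' @examples
#' compute_metrics(hybrid_counts(69.01, 30.94, 6.57)) # precision 91.31%
#' @export
compute_metrics <- function(h) {
  stopifnot(inherits(h, "hybrid_counts"))
  recall <- if (h$tp + h$fn > 0) h$tp / (h$tp + h$fn) else NA_real_
  precision <- if (h$tp + h$fp > 0) h$tp / (h$tp + h$fp) else NA_real_
  if (is.na(recall)) warning("recall undefined: tp + fn = 0", call. = FALSE)
  if (is.na(precision)) warning("precision undefined: tp + fp = 0",
                                call. = FALSE)
  f1 <- if (!is.na(recall) && !is.na(precision) && recall + precision > 0) {
    2 * precision * recall / (precision + recall)
  } else NA_real_
  structure(list(recall = recall, precision = precision, f1 = f1),
            class = "eval_metrics")
}

#' @export
print.eval_metrics <- function(x, ...) {
  cat(sprintf("recall %s  precision %s  F1 %s\n",
              percent(x$recall), percent(x$precision), percent(x$f1)))
  invisible(x)
}

#' Format a proportion as a percentage
#'
#' Half-up rounding to two decimals, the convention of published performance
#' tables (0.913072 -> "91.31").
#'
#' @param x proportion(s) in `[0, 1]` (values above 1 permitted:
#'   overdetection).
#' @param digits decimals (default 2).
#' @return character vector; `NA` stays `NA`.
#' @export
percent <- function(x, digits = 2) {
  ifelse(is.na(x), NA_character_,
         formatC(round_half_up(100 * x, digits), format = "f",
                 digits = digits))
}

#' Minimum sample size for estimating a proportion
#'
#' Classical population-proportion sample size: `n0 = z^2 p (1 - p) / e^2`,
#' adjusted for a finite population of size `N` by
#' `n = n0 / (1 + (n0 - 1) / N)`, rounded up. Used to size on-farm visual
#' validation campaigns; with the conservative `p = 0.5`, a 5% absolute
#' margin and 95% confidence, a 70-cow herd needs 60 observations.
#'
#' @param p expected proportion, strictly between 0 and 1.
#' @param e absolute margin of error, strictly between 0 and 1.
#' @param conf confidence level (default 0.95); the z-value is the exact
#'   two-sided normal quantile (1.959964 at 95%), not the rounded 1.96.
#' @param N optional finite population size (>= 1); the result never
#'   exceeds it.
#' @param z optional explicit z-value overriding `conf`.
#' @return integer minimum sample size.
#' @examples
#' sample_size(0.5, 0.05, 0.95, N = 70) # 60
#' sample_size(0.5, 0.05, 0.95)         # 385
#' @export
sample_size <- function(p, e, conf = 0.95, N = NULL, z = NULL) {
  if (!is.numeric(p) || p <= 0 || p >= 1) {
    stop_field("p", "must be strictly between 0 and 1")
  }
  if (!is.numeric(e) || e <= 0 || e >= 1) {
    stop_field("e", "must be strictly between 0 and 1")
  }
  if (is.null(z)) {
    if (!is.numeric(conf) || conf <= 0 || conf >= 1) {
      stop_field("conf", "must be strictly between 0 and 1")
    }
    z <- stats::qnorm(1 - (1 - conf) / 2)
  }
  n0 <- z^2 * p * (1 - p) / e^2
  if (!is.null(N)) {
    if (!is.numeric(N) || N < 1) stop_field("N", "must be >= 1")
    n <- ceiling(n0 / (1 + (n0 - 1) / N))
    as.integer(min(n, N))
  } else {
    as.integer(ceiling(n0))
  }
}
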