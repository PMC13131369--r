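#' Delimited-text readers and writers
#'
#' All pipeline artifacts are comma-separated UTF-8 text with a mandatory
#' header row and no locale-dependent number formatting, so every writer's
#' output round-trips through its reader with field-level equality.
#' Snapshots are written one row per (day, tick) with the detected IDs
#' joined by `";"`.
#'
#' @param x the table to write.
#' @param path file path.
#' @name pipeline_io
NULL

write_csv_plain <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
}
read_csv_plain <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}

#' @rdname pipeline_io
#' @export
write_truth_events <- function(x, path) {
  write_csv_plain(x[c("day", "tick_minute", "cow_id", "activity", "zone")],
                  path)
}
#' @rdname pipeline_io
#' @export
read_truth_events <- function(path) read_csv_plain(path)

#' @rdname pipeline_io
#' @export
write_ams_visits <- function(x, path) {
  write_csv_plain(x[c("day", "visit_minute", "cow_id")], path)
}
#' @rdname pipeline_io
#' @export
read_ams_visits <- function(path) read_csv_plain(path)

#' @rdname pipeline_io
#' @export
write_system_records <- function(x, path) {
  write_csv_plain(x[c("day", "tick_minute", "assigned_id", "activity",
                      "zone", "true_id")], path)
}
#' @rdname pipeline_io
#' @export
read_system_records <- function(path) read_csv_plain(path)

#' @rdname pipeline_io
#' @export
write_snapshots <- function(x, path) {
  key <- interaction(x$day, x$tick_minute, drop = FALSE)
  ids <- tapply(x$id, list(x$day, x$tick_minute),
                function(v) paste(sort(v), collapse = ";"))
  grid <- expand.grid(day = sort(unique(x$day)),
                      tick_minute = sort(unique(x$tick_minute)),
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[order(grid$day, grid$tick_minute), ]
  grid$id_list <- mapply(function(d, t) {
    v <- ids[as.character(d), as.character(t)]
    if (is.na(v)) "" else v
  }, grid$day, grid$tick_minute)
  write_csv_plain(grid, path)
}
#' @rdname pipeline_io
#' @export
read_snapshots <- function(path) {
  wide <- read_csv_plain(path)
  ids <- strsplit(ifelse(is.na(wide$id_list), "", wide$id_list), ";",
                  fixed = TRUE)
  n <- lengths(ids)
  out <- data.frame(day = rep(wide$day, n),
                    tick_minute = rep(wide$tick_minute, n),
                    id = unlist(ids), stringsAsFactors = FALSE)
  out[out$id != "", , drop = FALSE]
}

.pipeline_stages <- c("simulate", "emulate", "evaluate", "stability",
                      "samplesize", "report")

#' Run the evaluation pipeline end to end
#'
#' Orchestrates the stages simulate -> emulate -> evaluate -> stability ->
#' samplesize -> report, writing every artifact as delimited text under
#' `outdir` together with a JSON manifest recording the seed and a hash of
#' the configuration. Rerunning with identical configuration and seed
#' reproduces byte-identical data files. The requested stages must be a
#' prefix-closed subset of the pipeline order: a stage either finds its
#' upstream artifacts in this run or in `outdir` from a previous run, and
#' errors otherwise.
#'
#' All randomness flows from the single `seed` via [stage_seed()], so stages
#' are independently rerunnable yet exactly reproducible.
#'
#' @param farm a [farm_config()] (or path to a YAML farm config).
#' @param outdir output directory, created if needed.
#' @param seed master seed.
#' @param n_days,tick simulation grid (defaults 31 days, 5 minutes).
#' @param profile a [behavior_profile()].
#' @param errors an [error_model()].
#' @param stages stages to run, in pipeline order.
#' @param alpha significance threshold for the stability comparisons.
#' @return (invisibly) the manifest: a list of artifact paths plus the seed
#'   and config hash.
#' @export
run_pipeline <- function(farm, outdir, seed, n_days = 31, tick = 5,
                         profile = behavior_profile(),
                         errors = error_model(),
                         stages = .pipeline_stages, alpha = 0.01) {
  if (is.character(farm)) farm <- read_farm_config(farm)
  stopifnot(inherits(farm, "farm_config"))
  stages <- match.arg(stages, .pipeline_stages, several.ok = TRUE)
  stages <- .pipeline_stages[.pipeline_stages %in% stages]
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (file.access(outdir, 2) != 0) {
    stop("output directory not writable: ", outdir, call. = FALSE)
  }
  pth <- function(f) file.path(outdir, f)
  manifest <- list(farm_id = farm$farm_id, seed = seed,
                   stages = stages, files = list())
  log <- character(0)
  note <- function(fmt, ...) log <<- c(log, sprintf(fmt, ...))

  cfg_for_hash <- list(farm = unclass(farm), n_days = n_days, tick = tick,
                       profile = unclass(profile), errors = unclass(errors))
  tf <- tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg_for_hash, tf)
  manifest$config_hash <- unname(tools::md5sum(tf))
  unlink(tf)

  need <- function(file, stage) {
    p <- pth(file)
    if (!file.exists(p)) {
      stop(sprintf("stage '%s' needs missing upstream artifact %s", stage, p),
           call. = FALSE)
    }
    p
  }

  ht <- NULL
  emu <- NULL
  if ("simulate" %in% stages) {
    s <- stage_seed(seed, "simulate")
    note("simulate: seed %d", s)
    ht <- simulate_herd(farm, sim_config(seed = s, n_days = n_days,
                                         tick = tick, profile = profile))
    write_truth_events(ht$truth, pth("truth_events.csv"))
    write_ams_visits(ht$visits, pth("ams_visits.csv"))
    manifest$files$truth <- pth("truth_events.csv")
    manifest$files$visits <- pth("ams_visits.csv")
  }
  if ("emulate" %in% stages) {
    if (is.null(ht)) {
      truth <- read_truth_events(need("truth_events.csv", "emulate"))
      visits <- read_ams_visits(need("ams_visits.csv", "emulate"))
      ht <- structure(list(truth = truth, visits = visits,
                           herd = sort(unique(truth$cow_id)),
                           tick = tick, n_days = max(truth$day)),
                      class = "herd_truth")
    }
    s <- stage_seed(seed, "emulate")
    note("emulate: seed %d", s)
    emu <- emulate_system(ht, errors, seed = s)
    write_system_records(emu$records, pth("system_records.csv"))
    write_snapshots(emu$snapshots, pth("detection_snapshots.csv"))
    manifest$files$records <- pth("system_records.csv")
    manifest$files$snapshots <- pth("detection_snapshots.csv")
  }

  metrics_tab <- NULL
  if ("evaluate" %in% stages) {
    if (is.null(emu) || is.null(ht)) {
      stop("stage 'evaluate' needs 'emulate' outputs in the same run",
           call. = FALSE)
    }
    det <- evaluate_detection(emu, ht$visits)
    pooled <- attr(det, "pooled")
    det_m <- compute_metrics(hybrid_counts(pooled$tp_d, pooled$fn_d,
                                           pooled$fp_d))
    pairs <- observation_pairs(ht, emu)
    rows <- lapply(c("identification", "activity", "location"), function(tk) {
      h <- classify_pairs(pairs, tk)
      m <- compute_metrics(h)
      n_pres <- h$tp + h$fn
      data.frame(farm = farm$farm_id, task = tk,
                 tp_pct = 100 * h$tp / n_pres, fn_pct = 100 * h$fn / n_pres,
                 fp_pct = 100 * h$fp / n_pres,
                 recall = 100 * m$recall, precision = 100 * m$precision,
                 f1 = 100 * m$f1)
    })
    metrics_tab <- do.call(rbind, rows)
    detection_row <- data.frame(
      farm = farm$farm_id, task = "detection",
      tp_pct = 100 * pooled$tp_d / (pooled$tp_d + pooled$fn_d),
      fn_pct = 100 * pooled$fn_d / (pooled$tp_d + pooled$fn_d),
      fp_pct = 100 * pooled$fp_d / (pooled$tp_d + pooled$fn_d),
      recall = 100 * det_m$recall, precision = 100 * det_m$precision,
      f1 = 100 * det_m$f1)
    metrics_tab <- rbind(detection_row, metrics_tab)
    write_csv_plain(det, pth("detection_daily.csv"))
    write_csv_plain(metrics_tab, pth("metrics.csv"))
    manifest$files$detection_daily <- pth("detection_daily.csv")
    manifest$files$metrics <- pth("metrics.csv")
  }

  stab_summary <- NULL
  if ("stability" %in% stages) {
    if (is.null(emu) || is.null(ht)) {
      stop("stage 'stability' needs 'emulate' outputs in the same run",
           call. = FALSE)
    }
    counts <- snapshot_counts(emu$snapshots, n_days = emu$n_days,
                              tick = emu$tick)
    hp <- hourly_proportions(counts, ams_daily_counts(ht$visits, emu$n_days),
                             tick = emu$tick)
    fit <- fit_hour_day_model(hp)
    pw <- tukey_pairwise(fit, alpha = alpha)
    write_csv_plain(hp[c("day", "hour", "mean_count", "proportion")],
                    pth("hourly_proportions.csv"))
    write_csv_plain(pw, pth("stability_pairwise.csv"))
    manifest$files$hourly_proportions <- pth("hourly_proportions.csv")
    manifest$files$stability_pairwise <- pth("stability_pairwise.csv")
    stab_summary <- list(fit = fit, n_significant = sum(pw$significant),
                         alpha = alpha)
  }

  ss <- NULL
  if ("samplesize" %in% stages) {
    ss <- sample_size(0.5, 0.05, 0.95, N = farm$n_cows)
    manifest$sample_size <- ss
  }

  if ("report" %in% stages) {
    if (is.null(metrics_tab)) {
      stop("stage 'report' needs 'evaluate' outputs in the same run",
           call. = FALSE)
    }
    rpt <- render_report(metrics_tab, stab_summary, sample_size = ss)
    writeLines(rpt, pth("report.txt"))
    manifest$files$report <- pth("report.txt")
  }

  writeLines(log, pth("pipeline.log"))
  jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(manifest)
}

#' Render a performance report
#'
#' Emits, per farm and task, the TP/FN/FP percentages followed by recall,
#' precision and F1, all half-up rounded to two decimals in the column order
#' of a standard performance table, plus an optional stability summary.
#'
#' @param metrics data.frame with columns farm, task, tp_pct, fn_pct,
#'   fp_pct, recall, precision, f1 (percent units); may have zero rows.
#' @param stability optional list with elements `fit` (a `stability_fit`),
#'   `n_significant` and `alpha`.
#' @param sample_size optional minimum sample size to include.
#' @return character vector of report lines.
#' @export
render_report <- function(metrics, stability = NULL, sample_size = NULL) {
  fmt <- function(x) formatC(round_half_up(x, 2), format = "f", digits = 2)
  header <- sprintf("%-6s %-16s %8s %8s %8s %8s %10s %8s",
                    "Farm", "Task", "TP(%)", "FN(%)", "FP(%)", "Recall",
                    "Precision", "F1")
  lines <- c("Performance of detection, identification, activity classification, and location",
             header)
  if (!is.null(metrics) && nrow(metrics)) {
    for (i in seq_len(nrow(metrics))) {
      r <- metrics[i, ]
      lines <- c(lines, sprintf("%-6s %-16s %8s %8s %8s %8s %10s %8s",
                                r$farm, r$task, fmt(r$tp_pct), fmt(r$fn_pct),
                                fmt(r$fp_pct), fmt(r$recall),
                                fmt(r$precision), fmt(r$f1)))
    }
  }
  if (!is.null(stability)) {
    f <- stability$fit
    lines <- c(lines, "",
               sprintf("Detection stability: %d hours x %d days; hourly-mean SE %s%%; day var %.3g, residual var %.3g",
                       f$n_hours, f$n_days, fmt(100 * f$se_mean),
                       f$var_day, f$var_resid),
               sprintf("Tukey-adjusted pairwise hour comparisons: %d of %d significant at alpha = %g",
                       stability$n_significant, choose(f$n_hours, 2),
                       stability$alpha))
  }
  if (!is.null(sample_size)) {
    lines <- c(lines, "",
               sprintf("Minimum visual-observation sample size (p = 0.5, e = 0.05, 95%% confidence, finite herd): %d",
                       sample_size))
  }
  lines
}

#' Reference performance table of the three study farms
#'
#' The published identification / activity / location performance
#' percentages of three commercial farms (70, 140 and 250 cows), shipped as
#' plain text under `inst/extdata/`. TP and FN percentages sum to ~100
#' within rounding; FP sits outside that sum (detection-stage false
#' positives, constant per farm across tasks).
#'
#' @return data.frame with columns task, farm, tp_pct, fn_pct, fp_pct,
#'   recall, precision, f1.
#' @export
reference_performance_table <- function() {
  read_csv_plain(system.file("extdata", "reference_performance.csv",
                             package = "mcmcteval", mustWork = TRUE))
}

#' Bundled farm configuration files
#'
#' @param farm_id one of `"H1"`, `"H2"`, `"H3"`.
#' @return path to the YAML farm config shipped with the package.
#' @export
example_farm_path <- function(farm_id = c("H1", "H2", "H3")) {
  farm_id <- match.arg(farm_id)
  system.file("extdata", paste0("farm_", tolower(farm_id), ".yaml"),
              package = "mcmcteval", mustWork = TRUE)
}
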