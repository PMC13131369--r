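test_that("daily detection counts match the element-wise oracle", {
  dc <- evaluate_detection_day(paste0("c", 1:10), paste0("c", 1:10),
                               paste0("c", 1:10))
  expect_identical(unclass(dc), list(tp_d = 10L, fn_d = 0L, fp_d = 0L))
  dc <- evaluate_detection_day(c("c1", "c2"), c("c1", "g9"),
                               c("c1", "c2", "c3"))
  expect_identical(unclass(dc), list(tp_d = 1L, fn_d = 1L, fp_d = 1L))
  expect_error(evaluate_detection_day("x", "x", "y"), "subset")

  set.seed(808)
  ids <- paste0("c", 1:12)
  for (rep in 1:50) {
    registry <- sample(ids, sample(2:8, 1))
    ams <- sample(registry, sample(0:length(registry), 1))
    pool <- c(registry, "g1", "g2")
    detected <- sample(pool, sample(0:min(8, length(pool)), 1))
    got <- evaluate_detection_day(ams, detected, registry)
    want <- detection_elementwise_oracle(unique(ams), unique(detected),
                                         registry)
    expect_identical(unclass(got)[1:3], want)
  }
})

test_that("the hand-enumerated 20-pair mini-set classifies as (14, 5, 1)", {
  # 19 present cows: 2 detection misses, 3 identity errors among the 17
  # detected, everyone else fully correct; plus 1 ghost output
  mk <- function(n, detected, sys_id) {
    data.frame(present = TRUE, gold_id = paste0("c", n),
               gold_activity = "lying", gold_zone = "cubicle",
               detected = detected, sys_id = sys_id,
               sys_activity = ifelse(detected, "lying", NA),
               sys_zone = ifelse(detected, "cubicle", NA),
               stringsAsFactors = FALSE)
  }
  pairs <- rbind(
    do.call(rbind, lapply(1:14, function(i) mk(i, TRUE, paste0("c", i)))),
    mk(15, TRUE, "c99"), mk(16, TRUE, "unknown"), mk(17, TRUE, "c98"),
    mk(18, FALSE, NA), mk(19, FALSE, NA),
    data.frame(present = FALSE, gold_id = NA, gold_activity = NA,
               gold_zone = NA, detected = TRUE, sys_id = "ghost01",
               sys_activity = "standing", sys_zone = "alley",
               stringsAsFactors = FALSE)
  )
  h <- classify_pairs(pairs, "identification")
  expect_identical(unclass(h), list(tp = 14L, fn = 5L, fp = 1L))
  # activity ignores the 3 identity errors by default…
  ha <- classify_pairs(pairs, "activity")
  expect_identical(unclass(ha), list(tp = 17L, fn = 2L, fp = 1L))
  # …but not when restricted to correctly identified cows
  har <- classify_pairs(pairs, "activity", restrict_to_identified = TRUE)
  expect_identical(unclass(har), list(tp = 14L, fn = 5L, fp = 1L))
  expect_error(classify_pairs(pairs, "locomotion"), "arg")
})

test_that("published percentage rows feed through compute_metrics", {
  m <- compute_metrics(hybrid_counts(69.01, 30.94, 6.57))
  expect_identical(percent(m$precision), "91.31")
  m3 <- compute_metrics(hybrid_counts(99.01, 0.99, 15.22))
  expect_identical(percent(m3$precision), "86.68")
  perfect <- compute_metrics(hybrid_counts(12, 0, 0))
  expect_identical(c(perfect$recall, perfect$precision, perfect$f1),
                   c(1, 1, 1))
})

test_that("undefined metric denominators yield flagged NA, never silent 0", {
  expect_warning(m <- compute_metrics(hybrid_counts(0, 0, 3)), "recall")
  expect_true(is.na(m$recall))
  expect_warning(m2 <- compute_metrics(hybrid_counts(0, 4, 0)), "precision")
  expect_true(is.na(m2$precision))
  expect_true(is.na(m2$f1))
})

test_that("F1 is the harmonic mean and sits between precision and recall", {
  set.seed(42)
  for (rep in 1:100) {
    h <- hybrid_counts(runif(1, 1, 50), runif(1, 0, 50), runif(1, 0, 50))
    m <- compute_metrics(h)
    expect_gte(m$f1 + 1e-12, min(m$precision, m$recall))
    expect_lte(m$f1 - 1e-12, max(m$precision, m$recall))
    expect_equal(m$f1, 2 / (1 / m$precision + 1 / m$recall))
  }
})

test_that("sample size reproduces the worked values and the FPC limits", {
  expect_identical(sample_size(0.5, 0.05, 0.95, N = 70), 60L)
  expect_identical(sample_size(0.5, 0.05, 0.95), 385L)
  expect_identical(sample_size(0.5, 0.05, 0.95, N = 1), 1L)
  # non-decreasing in N, converging to the infinite-population value
  ns <- vapply(c(10, 70, 300, 1e3, 1e5, 1e7), function(N) {
    sample_size(0.5, 0.05, 0.95, N = N)
  }, integer(1))
  expect_true(all(diff(ns) >= 0))
  expect_identical(ns[length(ns)], 385L)
  expect_true(all(ns <= 385L))
  expect_error(sample_size(0, 0.05), "p")
  expect_error(sample_size(0.5, 0), "e")
  expect_error(sample_size(0.5, 0.05, N = 0.5), "N")
  # explicit z override (rounded 1.96 convention)
  expect_identical(sample_size(0.5, 0.05, z = 1.96), 385L)
})

test_that("estimated rates recover the emulator's parameters", {
  run <- recovery_run()  # daily_miss = 0.10, id_correct = 0.80
  det <- evaluate_detection(run$emu, run$ht$visits)
  pooled <- attr(det, "pooled")
  m <- compute_metrics(hybrid_counts(pooled$tp_d, pooled$fn_d, pooled$fp_d))
  n_cowdays <- pooled$tp_d + pooled$fn_d
  se_det <- sqrt(0.90 * 0.10 / n_cowdays)
  expect_lt(abs(m$recall - 0.90), 3 * se_det)

  # identification recall among detected cows converges on id_correct
  pairs <- observation_pairs(run$ht, run$emu,
                             ticks = seq(0, 1435, by = 60))
  pres <- pairs[pairs$present & pairs$detected, ]
  id_ok <- mean(pres$sys_id == pres$gold_id)
  se_id <- sqrt(0.80 * 0.20 / nrow(pres))
  expect_lt(abs(id_ok - 0.80), 3 * se_id)
})

test_that("sequential-dependency closure holds on evaluation runs", {
  run <- recovery_run()
  days <- c(1, 5, 9)
  pairs <- observation_pairs(run$ht, run$emu, days = days,
                             ticks = seq(0, 1435, by = 120))
  n_present <- sum(pairs$present)
  tp_d <- sum(pairs$present & pairs$detected)
  for (task in c("identification", "activity", "location")) {
    h <- classify_pairs(pairs, task)
    # conservation: tp + fn = number of truly present evaluated cows
    expect_identical(h$tp + h$fn, n_present)
    # FP is the detection stage's, shared across tasks
    expect_identical(h$fp, sum(!pairs$present & pairs$detected))
  }
  # tp_id + fn_id(excluding detection misses) = tp_d: identity errors are
  # only defined among detected cows — no identification-level FP exists
  h_id <- classify_pairs(pairs, "identification")
  fn_detection <- sum(pairs$present & !pairs$detected)
  expect_identical(h_id$tp + (h_id$fn - fn_detection), tp_d)
})
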