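test_that("events covering every bin give the maximum total of 12 per epoch", {
  ev <- tibble::tibble(behaviour = "chase", start_s = 0, end_s = 360)
  sheet <- score_intervals(ev, light_protocol())
  tot <- epoch_totals(sheet)
  expect_true(all(tot$total[tot$behaviour == "chase"] == 12))
  expect_true(all(tot$n_bins == 12))
})

test_that("no events give zero totals everywhere", {
  ev <- tibble::tibble(behaviour = character(), start_s = numeric(),
                       end_s = numeric())
  tot <- epoch_totals(score_intervals(ev, light_protocol()))
  expect_true(all(tot$total == 0))
})

test_that("bin marks match a brute-force overlap count", {
  # chases only in bins 1 and 5 of the high epoch (epoch 2: 120-240 s)
  ev <- tibble::tibble(behaviour = "chase",
                       start_s = c(122, 161.5), end_s = c(124, 161.6))
  sheet <- score_intervals(ev, light_protocol())
  tot <- epoch_totals(sheet)
  expect_identical(tot$total[tot$behaviour == "chase" & tot$epoch == 2], 2L)
  marks <- sheet[sheet$behaviour == "chase" & sheet$epoch == 2, ]$mark
  expect_identical(which(marks == 1L), c(1L, 5L))
})

test_that("totals are monotone in the event set and bounded by the bin count", {
  withr::with_seed(31, {
    base <- tibble::tibble(behaviour = "chase",
                           start_s = runif(5, 0, 350))
    base$end_s <- base$start_s + runif(5, 0.5, 5)
    more <- dplyr::bind_rows(base, tibble::tibble(
      behaviour = "chase", start_s = 200, end_s = 230))
    t1 <- epoch_totals(score_intervals(base, light_protocol()))
    t2 <- epoch_totals(score_intervals(more, light_protocol()))
    expect_true(all(t2$total >= t1$total))
    expect_true(all(t2$total >= 0 & t2$total <= 12))
  })
})

test_that("alternating 5-s windows consult only the ROI's half-bin", {
  # event in the second half of the first 10-s bin
  ev <- tibble::tibble(behaviour = "chase", start_s = 6, end_s = 8)
  t1 <- epoch_totals(score_intervals(ev, light_protocol(),
                                     mode = "alternating", roi_phase = 1))
  t2 <- epoch_totals(score_intervals(ev, light_protocol(),
                                     mode = "alternating", roi_phase = 2))
  expect_identical(t1$total[t1$behaviour == "chase" & t1$epoch == 1], 0L)
  expect_identical(t2$total[t2$behaviour == "chase" & t2$epoch == 1], 1L)
})

test_that("events outside the recording span raise a range error", {
  ev <- tibble::tibble(behaviour = "chase", start_s = 350, end_s = 400)
  expect_error(score_intervals(ev, light_protocol()),
               class = "flycourt_range")
})

test_that("paired comparison matches an independent textbook computation", {
  low <- c(1, 2, 1, 0, 2)
  high <- c(9, 10, 12, 8, 11)
  totals <- tibble::tibble(
    roi = rep(1:5, 2),
    behaviour = "chase",
    epoch = rep(1:2, each = 5),
    label = rep(c("low", "high"), each = 5),
    total = c(low, high))
  cmp <- compare_epochs(totals, design = "paired")
  got <- tidy(cmp)

  # independent hand computation of the paired t statistic
  d <- high - low
  t_hand <- mean(d) / (stats::sd(d) / sqrt(length(d)))
  p_hand <- 2 * stats::pt(-abs(t_hand), df = length(d) - 1)
  expect_equal(got$statistic, t_hand, tolerance = 1e-6)
  expect_equal(got$p.value, p_hand, tolerance = 1e-6)
  expect_identical(got$sig, "***")
  g <- glance(cmp)
  expect_identical(g$design, "paired")
})

test_that("identical scores across epochs give t = 0 and p = 1", {
  totals <- tibble::tibble(
    roi = rep(1:12, 2), behaviour = "chase",
    epoch = rep(1:2, each = 12),
    label = rep(c("low", "high"), each = 12),
    total = rep(5, 24))
  got <- tidy(compare_epochs(totals, design = "paired"))
  expect_equal(got$statistic, 0)
  expect_equal(got$p.value, 1)
})

test_that("one-way ANOVA type-I error is calibrated under the null", {
  withr::with_seed(97, {
    hits <- replicate(100, {
      totals <- tibble::tibble(
        roi = 1:24, behaviour = "chase", epoch = 1, label = "high",
        group = rep(c("a", "b", "c"), each = 8),
        total = rnorm(24, mean = 6, sd = 2))
      tst <- tidy(compare_epochs(totals, design = "multi_group"))
      tst$p.value[tst$comparison == "omnibus"] < 0.05
    })
    # 99% binomial band around 0.05 with 100 repetitions
    expect_gte(sum(hits), stats::qbinom(0.005, 100, 0.05))
    expect_lte(sum(hits), stats::qbinom(0.995, 100, 0.05))
  })
})

test_that("multi-group comparison reports Bonferroni-corrected pairwise tests", {
  withr::with_seed(13, {
    totals <- tibble::tibble(
      roi = 1:30, behaviour = "chase", epoch = 1, label = "high",
      group = rep(c("wt", "norpA", "orco"), each = 10),
      total = c(rnorm(10, 10, 1), rnorm(10, 1, 1), rnorm(10, 10, 1)))
    tst <- tidy(compare_epochs(totals, design = "multi_group"))
    expect_identical(sum(tst$comparison == "omnibus"), 1L)
    expect_identical(sum(tst$comparison != "omnibus"), 3L)
    expect_lt(tst$p.value[tst$comparison == "omnibus"], 0.001)
  })
})

test_that("dose-response locates the steepest proportional rise", {
  tab <- tibble::tibble(intensity_klx = c(0.4, 2, 6, 18),
                        total = c(1, 2, 10, 11))
  dr <- dose_response(tab)
  expect_equal(dr$steepest$from_klx, 2)
  expect_equal(dr$steepest$to_klx, 6)
  expect_true(dr$monotone)
  flat <- dose_response(tibble::tibble(intensity_klx = c(0.4, 2, 6),
                                       total = c(3, 3, 3)))
  expect_true(is.na(flat$steepest$from_klx))
  expect_error(dose_response(tibble::tibble(intensity_klx = 1, total = 1)),
               class = "flycourt_levels")
})

test_that("spectrum normalization divides by the peak and is idempotent", {
  sp <- tibble::tibble(wavelength_nm = c(400, 500, 600),
                       emission = c(2, 4, 8))
  ns <- normalize_spectrum(sp)
  expect_equal(ns$normalized_emission, c(0.25, 0.5, 1))
  again <- normalize_spectrum(
    dplyr::mutate(ns, emission = normalized_emission))
  expect_equal(again$normalized_emission, ns$normalized_emission)
  withr::with_seed(3, {
    v <- runif(50, 0.01, 7)
    nr <- normalize_spectrum(tibble::tibble(wavelength_nm = 189:238,
                                            emission = v))
    expect_equal(max(nr$normalized_emission), 1)
    expect_identical(which.max(nr$normalized_emission), which.max(v))
    # scale invariance
    n2 <- normalize_spectrum(tibble::tibble(wavelength_nm = 189:238,
                                            emission = 13 * v))
    expect_equal(n2$normalized_emission, nr$normalized_emission)
  })
  expect_error(normalize_spectrum(tibble::tibble(wavelength_nm = 1:3,
                                                 emission = c(0, 0, 0))),
               class = "flycourt_degenerate")
})
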