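day_epochs <- function(value = 100) rep(value, 1440)

test_that("non-wear detection applies the >=60 min of <=25 g-min rule", {
  e <- day_epochs()
  e[101:160] <- 25                       # exactly 60 min at the threshold
  expect_equal(detect_nonwear(e), cbind(start = 100L, end = 160L))

  e <- day_epochs()
  e[101:159] <- 0                        # 59 min: below the run threshold
  expect_equal(nrow(detect_nonwear(e)), 0)

  # a single 26 g-min epoch splits a 121-min low block into two 60-min runs
  e <- day_epochs()
  e[1:121] <- 0
  e[61] <- 26
  expect_equal(detect_nonwear(e),
               cbind(start = c(0L, 61L), end = c(60L, 121L)))

  expect_error(detect_nonwear(rep(0, 100)), "1440")
  expect_error(detect_nonwear(c(rep(0, 1439), -1)), ">= 0")
})

test_that("epoch classification respects cut points and precedence", {
  e <- day_epochs(0)
  e[1:6] <- c(94, 93, 49, 48, 47, 120)
  sleep <- cbind(start = 5L, end = 6L)   # covers the 120 g-min epoch
  lab <- classify_epochs(e, nonwear_intervals = NULL, sleep_intervals = sleep)
  expect_equal(as.character(lab[1:6]),
               c("mvpa", "lpa", "lpa", "sb", "sb", "sleep"))

  # non-wear overrides intensity, sleep overrides non-wear
  nw <- cbind(start = 0L, end = 100L)
  lab2 <- classify_epochs(e, nw, sleep)
  expect_equal(as.character(lab2[1]), "nonwear")
  expect_equal(as.character(lab2[6]), "sleep")

  expect_error(classify_epochs(e, sleep_intervals = cbind(1400L, 1500L)),
               "intervals")
  expect_error(classify_epochs(e, sleep_intervals = rbind(c(0L, 10L), c(5L, 20L))),
               "overlap")
})

test_that("valid-day rule is waking wear time >= 600 min", {
  lab <- rep("sb", 1440)
  lab[1:500] <- "sleep"
  lab[501:740] <- c(rep("lpa", 180), rep("mvpa", 60))
  d <- summarize_day(lab, "weekday")
  expect_true(d$valid)
  expect_equal(d[, c("sleep", "sb", "lpa", "mvpa", "nonwear")],
               data.frame(sleep = 500L, sb = 700L, lpa = 180L, mvpa = 60L,
                          nonwear = 0L))

  lab <- c(rep("sleep", 480), rep("nonwear", 900), rep("sb", 60))
  expect_false(summarize_day(lab, "weekday")$valid)

  # boundary: waking wear exactly 600 min is valid
  lab <- c(rep("sleep", 480), rep("nonwear", 360), rep("sb", 600))
  expect_true(summarize_day(lab, "weekend")$valid)
  # one fewer worn minute fails
  lab <- c(rep("sleep", 480), rep("nonwear", 361), rep("sb", 599))
  expect_false(summarize_day(lab, "weekend")$valid)
})

test_that("averaging keeps valid days only and closes to 1440", {
  day <- function(day_type, sleep = 480, sb = 576, lpa = 216, mvpa = 96,
                  nonwear = 72, valid = TRUE)
    data.frame(sleep = sleep, sb = sb, lpa = lpa, mvpa = mvpa,
               nonwear = nonwear, day_type = day_type, valid = valid)

  # 3 valid weekdays but no valid weekend day: rejected
  r <- average_valid_days(rbind(day("weekday"), day("weekday"), day("weekday")))
  expect_false(r$included)
  expect_equal(r$reason, "valid_week_rule")

  # 5 valid days with non-wear redistributed proportionally
  r <- average_valid_days(do.call(rbind, c(
    replicate(4, day("weekday"), simplify = FALSE), list(day("weekend")))))
  expect_true(r$included)
  expect_equal(unname(r$composition),
               c(480, 576, 216, 96) * 1440 / 1368, tolerance = 1e-9)
  expect_equal(round(unname(r$composition), 2),
               c(505.26, 606.32, 227.37, 101.05))

  # identical zero-nonwear days pass through unchanged; invalid days dropped
  d5 <- day("weekday", 480, 600, 240, 120, 0)
  bad <- day("weekday", 480, 100, 20, 10, 830, valid = FALSE)
  r <- average_valid_days(rbind(d5, d5, d5, bad, day("weekend", 480, 600, 240, 120, 0)))
  expect_equal(unname(r$composition), c(480, 600, 240, 120))
  expect_equal(r$n_valid_weekday, 3)
  expect_equal(r$n_valid_weekend, 1)
})

test_that("adding a non-wear run never increases any behaviour's minutes", {
  set.seed(7)
  e <- runif(1440, 26, 400)
  sleep <- cbind(start = 0L, end = 480L)
  base <- summarize_day(classify_epochs(e, detect_nonwear(e), sleep), "weekday")
  for (start in c(500L, 700L, 1000L)) {
    e2 <- e
    e2[(start + 1):(start + 90)] <- 0
    with_nw <- summarize_day(
      classify_epochs(e2, detect_nonwear(e2), sleep), "weekday")
    for (cl in c("sleep", "sb", "lpa", "mvpa"))
      expect_lte(with_nw[[cl]], base[[cl]])
  }
})

test_that("synthetic epoch weeks round-trip through the processing chain", {
  targets <- data.frame(
    day_type = c(rep("weekday", 5), rep("weekend", 2)),
    sleep = 480, sb = 600, lpa = 240, mvpa = 120, nonwear = 0)
  s <- generate_epoch_series(targets, "P0001", seed = 11)
  out <- process_epochs(epoch_series_to_df(s))
  expect_true(out$included)
  expect_equal(unname(unlist(out[, c("sleep_min", "sb_min", "lpa_min", "mvpa_min")])),
               c(480, 600, 240, 120))
  expect_equal(out$n_valid_weekday, 5)
  expect_equal(out$n_valid_weekend, 2)

  # a 120-min non-wear target is detected as exactly 120 min
  t2 <- targets
  t2$sb <- 480
  t2$nonwear <- 120
  s2 <- generate_epoch_series(t2, "P0002", seed = 12)
  nw <- detect_nonwear(s2$days[[1]]$epochs)
  expect_equal(sum(nw[, "end"] - nw[, "start"]), 120)
  out2 <- process_epochs(epoch_series_to_df(s2))
  expect_equal(unname(unlist(out2[, c("sleep_min", "sb_min", "lpa_min", "mvpa_min")])),
               unname(closure(c(480, 480, 240, 120))), tolerance = 1e-9)

  expect_error(generate_epoch_series(
    data.frame(day_type = "weekday", sleep = 480, sb = 570, lpa = 240,
               mvpa = 120, nonwear = 30)), "detectable run")
  expect_error(generate_epoch_series(
    data.frame(day_type = "weekday", sleep = 480, sb = 590, lpa = 240,
               mvpa = 120, nonwear = 10)), "detectable run")
  expect_error(generate_epoch_series(
    data.frame(day_type = "weekday", sleep = 400, sb = 600, lpa = 240,
               mvpa = 120, nonwear = 0)), "sum to 1440")
})
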