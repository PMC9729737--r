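## Accelerometry epoch processing: non-wear detection, cut-point
## classification, valid-day and valid-week rules, averaging to a daily
## time-use composition.
##
## Epochs are 1-min activity values in g-min. Cut points: non-wear runs of
## >= 60 min at <= 25 g-min; waking epochs classified SB (<= 48), LPA
## (48, 93], MVPA (> 93). Intervals are half-open [start, end) on 0-based
## epoch indices 0..1439, matching the epoch CSV schema.

EPOCHS_PER_DAY <- 1440L

#' Default accelerometry cut points and wear rules
#'
#' @return Named list: `nonwear_threshold` (g-min), `nonwear_min_run`
#'   (min), `sb_max` and `lpa_max` (g-min intensity band edges),
#'   `min_waking_wear` (min/day for a valid day), `min_valid_weekdays`,
#'   `min_valid_weekend`.
#' @export
accel_rules <- function() {
  list(nonwear_threshold = 25, nonwear_min_run = 60L,
       sb_max = 48, lpa_max = 93,
       min_waking_wear = 600L,
       min_valid_weekdays = 3L, min_valid_weekend = 1L)
}

check_epochs <- function(epochs) {
  if (length(epochs) != EPOCHS_PER_DAY)
    stop("a day must have exactly ", EPOCHS_PER_DAY, " one-minute epochs, got ",
         length(epochs))
  if (any(!is.finite(epochs)) || any(epochs < 0))
    stop("epoch values must be finite and >= 0")
  invisible(epochs)
}

#' Detect non-wear intervals in a day of 1-min epochs
#'
#' Non-wear is any maximal run of consecutive epochs at or below the
#' threshold whose length reaches the minimum run (default: >= 60 min of
#' <= 25 g-min).
#'
#' @param epochs Numeric vector of 1440 epoch values (g-min).
#' @param threshold Inclusive g-min threshold for a candidate epoch.
#' @param min_run Minimum run length in minutes.
#' @return Integer matrix with columns `start`, `end`: disjoint, sorted,
#'   half-open 0-based intervals. Zero rows when none detected.
#' @export
#' @examples
#' e <- rep(100, 1440); e[101:160] <- 0
#' detect_nonwear(e)
detect_nonwear <- function(epochs, threshold = 25, min_run = 60L) {
  check_epochs(epochs)
  r <- rle(epochs <= threshold)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values & r$lengths >= min_run
  cbind(start = as.integer(starts[keep]), end = as.integer(ends[keep]))
}

check_intervals <- function(iv, what, allow_overlap = FALSE) {
  if (is.null(iv)) return(cbind(start = integer(0), end = integer(0)))
  iv <- as.matrix(iv)
  if (ncol(iv) != 2) stop(what, " intervals must have two columns [start, end)")
  colnames(iv) <- c("start", "end")
  if (nrow(iv) == 0) return(iv)
  if (any(iv[, 1] < 0) || any(iv[, 2] > EPOCHS_PER_DAY) || any(iv[, 1] >= iv[, 2]))
    stop(what, " intervals must satisfy 0 <= start < end <= ", EPOCHS_PER_DAY)
  o <- order(iv[, 1])
  iv <- iv[o, , drop = FALSE]
  if (!allow_overlap && nrow(iv) > 1 &&
      any(iv[-1, 1] < iv[-nrow(iv), 2]))
    stop(what, " intervals must not overlap")
  iv
}

interval_mask <- function(iv) {
  mask <- logical(EPOCHS_PER_DAY)
  for (i in seq_len(nrow(iv))) mask[(iv[i, 1] + 1):iv[i, 2]] <- TRUE
  mask
}

#' Classify each epoch of a day
#'
#' Precedence: diary sleep > detected non-wear > intensity bands. Waking
#' worn epochs are MVPA above 93 g-min, LPA in (48, 93], SB at or below 48.
#'
#' @param epochs Numeric vector of 1440 epoch values.
#' @param nonwear_intervals Matrix of `[start, end)` non-wear intervals
#'   (e.g. from [detect_nonwear()]).
#' @param sleep_intervals Matrix of `[start, end)` diary sleep intervals;
#'   must not overlap each other.
#' @param rules Cut-point rules, see [accel_rules()].
#' @return Factor of length 1440 with levels sleep, nonwear, sb, lpa, mvpa.
#' @export
classify_epochs <- function(epochs, nonwear_intervals = NULL,
                            sleep_intervals = NULL, rules = accel_rules()) {
  check_epochs(epochs)
  nw <- check_intervals(nonwear_intervals, "non-wear", allow_overlap = TRUE)
  sl <- check_intervals(sleep_intervals, "sleep")
  lab <- rep("sb", EPOCHS_PER_DAY)
  lab[epochs > rules$sb_max] <- "lpa"
  lab[epochs > rules$lpa_max] <- "mvpa"
  lab[interval_mask(nw)] <- "nonwear"
  lab[interval_mask(sl)] <- "sleep"
  factor(lab, levels = c("sleep", "nonwear", "sb", "lpa", "mvpa"))
}

#' Summarise one classified day
#'
#' Counts minutes per class and applies the valid-day rule: a day is valid
#' when waking wear time (1440 minus sleep minus non-wear) is at least 10 h.
#'
#' @param labels Factor from [classify_epochs()].
#' @param day_type `"weekday"` or `"weekend"`.
#' @param rules See [accel_rules()].
#' @return One-row data.frame: `sleep`, `sb`, `lpa`, `mvpa`, `nonwear`
#'   minutes, `day_type`, `valid`.
#' @export
summarize_day <- function(labels, day_type = c("weekday", "weekend"),
                          rules = accel_rules()) {
  day_type <- match.arg(day_type)
  if (length(labels) != EPOCHS_PER_DAY)
    stop("need ", EPOCHS_PER_DAY, " labels")
  labels <- factor(labels, levels = c("sleep", "nonwear", "sb", "lpa", "mvpa"))
  if (anyNA(labels)) stop("unknown epoch label")
  n <- as.list(table(labels))
  waking_wear <- EPOCHS_PER_DAY - n$sleep - n$nonwear
  data.frame(sleep = n$sleep, sb = n$sb, lpa = n$lpa, mvpa = n$mvpa,
             nonwear = n$nonwear, day_type = day_type,
             valid = waking_wear >= rules$min_waking_wear)
}

#' Average valid days into a participant's daily time-use composition
#'
#' Applies the valid-week rule (at least 3 valid weekdays and 1 valid
#' weekend day), averages per-class minutes over valid days only, and
#' closes the four behaviour means to 1440 min (redistributing mean
#' non-wear proportionally).
#'
#' @param day_records data.frame of day rows as returned by
#'   [summarize_day()] (columns sleep, sb, lpa, mvpa, nonwear, day_type,
#'   valid).
#' @param rules See [accel_rules()].
#' @return List: `included` (logical); when included, `composition` (named
#'   minutes summing to 1440), `n_valid_weekday`, `n_valid_weekend`; when
#'   rejected, `reason` (`"valid_week_rule"` or `"zero_behaviour"`).
#' @export
average_valid_days <- function(day_records, rules = accel_rules()) {
  if (nrow(day_records) == 0) stop("need at least one day record")
  v <- day_records[day_records$valid, , drop = FALSE]
  n_wd <- sum(v$day_type == "weekday")
  n_we <- sum(v$day_type == "weekend")
  if (n_wd < rules$min_valid_weekdays || n_we < rules$min_valid_weekend)
    return(list(included = FALSE, reason = "valid_week_rule",
                n_valid_weekday = n_wd, n_valid_weekend = n_we))
  means <- colMeans(v[, tu_parts(), drop = FALSE])
  if (any(means == 0))
    return(list(included = FALSE, reason = "zero_behaviour",
                n_valid_weekday = n_wd, n_valid_weekend = n_we))
  list(included = TRUE,
       composition = closure(means),
       n_valid_weekday = n_wd, n_valid_weekend = n_we)
}

#' Process an epoch table into per-participant compositions
#'
#' Runs the full chain — non-wear detection, classification, valid-day and
#' valid-week rules, averaging — over a long-format epoch table.
#'
#' @param epoch_df data.frame with columns `participant_id`, `day_index`,
#'   `day_type` (weekday/weekend), `epoch_index` (0..1439), `value`
#'   (g-min), `in_sleep_interval` (0/1 or logical).
#' @param rules See [accel_rules()].
#' @return data.frame with one row per participant: `participant_id`,
#'   `sleep_min`, `sb_min`, `lpa_min`, `mvpa_min`, `n_valid_weekday`,
#'   `n_valid_weekend`, `included`, `reason`.
#' @export
process_epochs <- function(epoch_df, rules = accel_rules()) {
  need <- c("participant_id", "day_index", "day_type", "epoch_index",
            "value", "in_sleep_interval")
  miss <- setdiff(need, names(epoch_df))
  if (length(miss)) stop("epoch table missing columns: ",
                         paste(miss, collapse = ", "))
  out <- lapply(split(epoch_df, epoch_df$participant_id), function(pd) {
    days <- lapply(split(pd, pd$day_index), function(dd) {
      dd <- dd[order(dd$epoch_index), ]
      if (!identical(as.integer(dd$epoch_index), 0:(EPOCHS_PER_DAY - 1L)))
        stop("participant ", dd$participant_id[1], " day ", dd$day_index[1],
             ": epoch_index must cover 0..", EPOCHS_PER_DAY - 1L)
      sl_r <- rle(as.logical(dd$in_sleep_interval))
      ends <- cumsum(sl_r$lengths)
      sl <- cbind(start = (ends - sl_r$lengths)[sl_r$values],
                  end = ends[sl_r$values])
      labs <- classify_epochs(dd$value, detect_nonwear(
        dd$value, rules$nonwear_threshold, rules$nonwear_min_run), sl, rules)
      summarize_day(labs, as.character(dd$day_type[1]), rules)
    })
    res <- average_valid_days(do.call(rbind, days), rules)
    comp <- if (res$included) res$composition else
      stats::setNames(rep(NA_real_, 4), tu_parts())
    data.frame(participant_id = pd$participant_id[1],
               sleep_min = comp["sleep"], sb_min = comp["sb"],
               lpa_min = comp["lpa"], mvpa_min = comp["mvpa"],
               n_valid_weekday = res$n_valid_weekday,
               n_valid_weekend = res$n_valid_weekend,
               included = res$included,
               reason = if (res$included) "" else res$reason,
               row.names = NULL)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
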