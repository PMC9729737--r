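## Cognitive outcome construction: orientation (reversal) of raw test
## scores, z-scoring, accuracy-based inclusion criteria and domain
## composite assembly. Global cognition is the raw ACE-III total (0-100);
## the four domain composites are unweighted means of component z-scores
## and are missing unless every component is present and all inclusion
## criteria for that composite are met.

#' Measure definitions for the neuropsychological battery
#'
#' One row per outcome measure: its parent test, the cognitive domain it
#' contributes to (long-term memory, short-term memory, executive function,
#' processing speed), whether lower raw scores mean better performance (and
#' the score is therefore reversed), and the valid score range.
#'
#' @return data.frame with columns `measure`, `test`, `domain`, `reversed`,
#'   `range_min`, `range_max`.
#' @export
cantab_measures <- function() {
  df <- read.table(header = TRUE, stringsAsFactors = FALSE, text = "
measure                      test  domain  reversed range_min range_max
vrm_delayed_recognition      VRM   ltm     FALSE    0         36
vrm_immediate_recognition    VRM   stm     FALSE    0         36
vrm_immediate_free_recall    VRM   stm     FALSE    0         18
pal_total_errors_adjusted    PAL   stm     TRUE     0         70
pal_first_attempt_memory     PAL   stm     FALSE    0         20
mtt_total_incorrect          MTT   exec    TRUE     0         160
mtt_latency_multitask_cost   MTT   exec    TRUE     -1900     1900
mtt_latency_incongruency_cost MTT  exec    TRUE     -1900     1900
ots_problems_first_choice    OTS   exec    FALSE    0         15
ots_median_latency_first     OTS   exec    TRUE     0         Inf
rti_simple_reaction_time     RTI   speed   TRUE     100       5100
rti_choice_reaction_time     RTI   speed   TRUE     100       5100
rti_simple_movement_time     RTI   speed   TRUE     100       5100
rti_choice_movement_time     RTI   speed   TRUE     100       5100
")
  df
}

check_measures <- function(values, definitions) {
  bad <- setdiff(names(values), c("participant_id", definitions$measure))
  if (length(bad)) stop("unknown measure column(s): ", paste(bad, collapse = ", "))
  invisible(values)
}

#' Orient raw scores so that higher always means better
#'
#' Multiplies reversed measures by -1; leaves the rest unchanged. Applying
#' the operation twice restores the input.
#'
#' @param values data.frame of raw measure values (columns named as in
#'   `definitions$measure`; other columns such as `participant_id` pass
#'   through).
#' @param definitions See [cantab_measures()].
#' @return data.frame of oriented values.
#' @export
reverse_scores <- function(values, definitions = cantab_measures()) {
  check_measures(values, definitions)
  rev_cols <- intersect(definitions$measure[definitions$reversed], names(values))
  values[rev_cols] <- lapply(values[rev_cols], function(v) -v)
  values
}

#' Standardise measure columns to sample z-scores
#'
#' `(x - mean)/sd` per column with the n-1 denominator; missing values are
#' propagated and excluded from the mean/sd.
#'
#' @param values data.frame; every column except `cols` passes through.
#' @param cols Columns to standardise (default: all numeric measure
#'   columns other than `participant_id`).
#' @return data.frame with the selected columns z-scored.
#' @export
zscore_columns <- function(values, cols = setdiff(names(values), "participant_id")) {
  for (cl in cols) {
    x <- values[[cl]]
    ok <- !is.na(x)
    if (sum(ok) < 2) stop("measure '", cl, "' needs >= 2 non-missing values")
    s <- stats::sd(x[ok])
    if (s == 0) stop("measure '", cl, "' has zero spread; cannot z-score")
    values[[cl]] <- (x - mean(x[ok])) / s
  }
  values
}

#' Default accuracy-based inclusion rules
#'
#' Participants below 50% accuracy on a test are excluded from the
#' composites that test feeds. The exact rule list is configurable; the
#' default applies the 50% threshold to each accuracy column supplied.
#'
#' @param tests Character vector of test names with accuracy columns.
#' @param definitions See [cantab_measures()].
#' @return data.frame with columns `test`, `threshold`, `composite`.
#' @export
inclusion_rules <- function(tests = c("VRM", "MTT", "RTI"),
                            definitions = cantab_measures()) {
  do.call(rbind, lapply(tests, function(tt) {
    comps <- unique(definitions$domain[definitions$test == tt])
    if (!length(comps)) stop("rule references unknown test: ", tt)
    data.frame(test = tt, threshold = 0.5, composite = comps)
  }))
}

#' Apply inclusion criteria to per-test accuracies
#'
#' @param accuracy data.frame with `participant_id` and one accuracy
#'   column per test, named `acc_<test>` with values in `[0, 1]`.
#' @param rules data.frame of rules (`test`, `threshold`, `composite`),
#'   see [inclusion_rules()]. A participant strictly below a rule's
#'   threshold is masked out of the affected composite(s) only.
#' @param composites Composite names the mask covers.
#' @return Logical matrix participants x composites; TRUE = eligible.
#' @export
apply_inclusion_criteria <- function(accuracy, rules = inclusion_rules(),
                                     composites = c("ltm", "stm", "exec", "speed")) {
  mask <- matrix(TRUE, nrow(accuracy), length(composites),
                 dimnames = list(accuracy$participant_id, composites))
  for (i in seq_len(nrow(rules))) {
    col <- paste0("acc_", rules$test[i])
    if (!col %in% names(accuracy))
      stop("accuracy column '", col, "' not found for rule on test ",
           rules$test[i])
    if (!rules$composite[i] %in% composites)
      stop("rule references unknown composite: ", rules$composite[i])
    fail <- !is.na(accuracy[[col]]) & accuracy[[col]] < rules$threshold[i]
    mask[fail, rules$composite[i]] <- FALSE
  }
  mask
}

#' Assemble domain composites and global cognition
#'
#' Each domain composite is the unweighted arithmetic mean of its
#' component z-scores, and is missing when any component is missing or the
#' participant is masked out of that composite. Global cognition is the
#' raw ACE-III total, passed through unchanged.
#'
#' @param zvalues data.frame of oriented, z-scored measures (plus
#'   `participant_id`).
#' @param ace_total Numeric vector of ACE-III totals (0-100), aligned to
#'   `zvalues` rows.
#' @param definitions See [cantab_measures()].
#' @param mask Eligibility matrix from [apply_inclusion_criteria()]
#'   (optional; all-eligible when NULL).
#' @return data.frame: `participant_id`, `global_cognition`, `ltm`, `stm`,
#'   `exec`, `speed`.
#' @export
build_composites <- function(zvalues, ace_total, definitions = cantab_measures(),
                             mask = NULL) {
  check_measures(zvalues, definitions)
  doms <- c("ltm", "stm", "exec", "speed")
  if (is.null(mask))
    mask <- matrix(TRUE, nrow(zvalues), length(doms),
                   dimnames = list(NULL, doms))
  if (any(!is.na(ace_total) & (ace_total < 0 | ace_total > 100)))
    stop("ACE-III totals must lie in [0, 100]")
  out <- data.frame(participant_id = zvalues$participant_id,
                    global_cognition = ace_total)
  for (d in doms) {
    comp_cols <- definitions$measure[definitions$domain == d]
    missing_cols <- setdiff(comp_cols, names(zvalues))
    if (length(missing_cols))
      stop("missing measure column(s) for composite ", d, ": ",
           paste(missing_cols, collapse = ", "))
    m <- as.matrix(zvalues[comp_cols])
    val <- rowMeans(m)              # NA whenever any component is NA
    val[!mask[, d]] <- NA
    out[[d]] <- val
  }
  out
}

#' Build the five cognitive outcomes from raw scores
#'
#' Convenience chain: orientation, z-scoring, inclusion criteria,
#' composite assembly.
#'
#' @param raw data.frame with `participant_id`, the measure columns of
#'   [cantab_measures()], `ace_total`, and `acc_<test>` accuracy columns
#'   for each test named in `rules`.
#' @param rules See [inclusion_rules()].
#' @param definitions See [cantab_measures()].
#' @return data.frame of composites, see [build_composites()].
#' @export
build_cognitive_outcomes <- function(raw, rules = inclusion_rules(),
                                     definitions = cantab_measures()) {
  meas <- intersect(definitions$measure, names(raw))
  vals <- raw[c("participant_id", meas)]
  vals <- zscore_columns(reverse_scores(vals, definitions), meas)
  mask <- apply_inclusion_criteria(raw, rules)
  build_composites(vals, raw$ace_total, definitions, mask)
}
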