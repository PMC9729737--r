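## Statistical engine: moderator categorisation, the compositional linear
## model with behaviour-context interaction blocks, marginality-respecting
## type II F-tests, the ordered backward-selection procedure,
## Benjamini-Hochberg FDR within each final model, and pivot-coefficient
## extraction.

#' Categorise behaviour-context moderators
#'
#' TV watching is split into empirical tertiles (low / medium / high) at
#' the 1/3 and 2/3 sample quantiles, ties at a cut going to the lower
#' category; recreational PA is none (0 min), upto30 ((0, 30] min) or
#' over30 (> 30 min); the PSQI sleep-quality item is dichotomised as good
#' (rating 0-1) vs bad (2-3).
#'
#' Reference levels carried by the returned factors: TV = low,
#' recreational PA = over30, sleep quality = good.
#'
#' @param tv_minutes Daily TV minutes (>= 0).
#' @param recpa_minutes Daily recreational-PA minutes (>= 0).
#' @param sleep_rating PSQI sleep-quality item, integer 0-3.
#' @return data.frame with factors `tv_tertile`, `recpa_cat`,
#'   `sleep_quality`; missing inputs propagate as NA.
#' @export
assign_moderators <- function(tv_minutes, recpa_minutes, sleep_rating) {
  if (any(tv_minutes < 0, na.rm = TRUE) || any(recpa_minutes < 0, na.rm = TRUE))
    stop("minutes must be >= 0")
  if (any(!sleep_rating %in% c(0:3, NA)))
    stop("sleep rating must be 0, 1, 2 or 3")
  q <- stats::quantile(tv_minutes, c(1, 2) / 3, na.rm = TRUE, names = FALSE)
  tv <- ifelse(tv_minutes <= q[1], "low",
               ifelse(tv_minutes <= q[2], "medium", "high"))
  recpa <- ifelse(recpa_minutes == 0, "none",
                  ifelse(recpa_minutes <= 30, "upto30", "over30"))
  sq <- ifelse(sleep_rating <= 1, "good", "bad")
  data.frame(tv_tertile = factor(tv, levels = c("low", "medium", "high")),
             recpa_cat = factor(recpa, levels = c("over30", "none", "upto30")),
             sleep_quality = factor(sq, levels = c("good", "bad")))
}

#' Prepare a cohort table for analysis
#'
#' Sets reference levels (sex = male, site = Adelaide, smoking = never),
#' derives the moderator factors and computes the default-partition ilr
#' coordinates `z1..z3` from the minute columns.
#'
#' @param data Cohort data.frame with minute columns `sleep`, `sb`, `lpa`,
#'   `mvpa`, covariates, `tv_minutes`, `recpa_minutes`, `sleep_rating`.
#' @return The table augmented with factors and ilr columns.
#' @export
prepare_analysis_data <- function(data) {
  data$sex <- factor(data$sex, levels = c("male", "female"))
  data$site <- factor(data$site, levels = c("Adelaide", "Newcastle"))
  data$smoking <- factor(data$smoking, levels = c("never", "previous", "current"))
  mods <- assign_moderators(data$tv_minutes, data$recpa_minutes,
                            data$sleep_rating)
  data[names(mods)] <- mods
  z <- ilr_transform(as.matrix(data[, tu_parts()]))
  data[colnames(z)] <- as.data.frame(z)
  data
}

#' Pearson correlations with two-sided p-values
#'
#' Pairwise-complete Pearson correlations between all columns, with
#' p-values from the t transform on n-2 degrees of freedom.
#'
#' @param data data.frame of numeric variables.
#' @param min_pairs Minimum complete pairs per cell; cells below it are NA.
#' @return List of matrices `r`, `p`, `n`.
#' @export
pairwise_correlations <- function(data, min_pairs = 3) {
  v <- names(data)
  k <- length(v)
  r <- p <- nm <- matrix(NA_real_, k, k, dimnames = list(v, v))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    ok <- stats::complete.cases(data[[i]], data[[j]])
    nm[i, j] <- sum(ok)
    if (i == j) { r[i, j] <- 1; p[i, j] <- 0; next }
    if (sum(ok) < min_pairs) next
    ri <- stats::cor(data[[i]][ok], data[[j]][ok])
    r[i, j] <- ri
    df <- sum(ok) - 2
    tt <- ri * sqrt(df / (1 - ri^2))
    p[i, j] <- if (abs(ri) >= 1) 0 else 2 * stats::pt(-abs(tt), df)
  }
  list(r = r, p = p, n = nm)
}

#' Specify a compositional regression model
#'
#' A model is a set of term groups: covariates (each its own group),
#' moderator main effects, the 3-coordinate composition block (tested
#' jointly), and composition x moderator interaction blocks. Marginality
#' is enforced at construction: an interaction block requires both the
#' composition block and its moderator's main effect.
#'
#' @param outcome Outcome column name.
#' @param covariates Covariate column names; factors become dummy groups,
#'   numeric columns single-df groups.
#' @param moderators Moderator factor names whose main effects enter.
#' @param composition Include the ilr composition block?
#' @param interactions Moderators whose composition interaction enters.
#' @return Object of class `tu_model_spec`.
#' @export
model_spec <- function(outcome,
                       covariates = c("age", "sex", "site", "smoking", "education"),
                       moderators = c("tv_tertile", "recpa_cat", "sleep_quality"),
                       composition = TRUE,
                       interactions = moderators) {
  if (length(interactions)) {
    if (!composition)
      stop("marginality: interaction blocks require the composition block")
    if (!all(interactions %in% moderators))
      stop("marginality: interaction blocks require their moderator's main effect")
  }
  structure(list(outcome = outcome, covariates = covariates,
                 moderators = moderators, composition = composition,
                 interactions = interactions),
            class = "tu_model_spec")
}

ilr_cols <- c("z1", "z2", "z3")

## Dummy columns for a factor against its first (reference) level.
factor_dummies <- function(f, name, levels) {
  f <- factor(f, levels = levels)
  if (anyNA(f)) stop("value outside the model's levels for '", name, "'")
  m <- sapply(levels[-1], function(l) as.numeric(f == l))
  if (is.null(dim(m))) m <- matrix(m, ncol = length(levels) - 1)
  colnames(m) <- paste0(name, levels[-1])
  m
}

## Build the design matrix and term-group bookkeeping for `spec` on
## (already complete-case) data. `xlevels` freezes factor levels for
## prediction on new data.
design_from_data <- function(data, spec, xlevels = NULL) {
  n <- nrow(data)
  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  groups <- list()
  contains <- list()
  lv <- list()
  add_group <- function(name, cols) {
    start <- ncol(X) + 1
    X <<- cbind(X, cols)
    groups[[name]] <<- start:(start + ncol(cols) - 1)
  }
  add_var <- function(name) {
    v <- data[[name]]
    if (is.null(v)) stop("column '", name, "' not found in data")
    if (is.factor(v) || is.character(v)) {
      ## levels observed in the fitting data; empty levels would alias
      levels <- if (!is.null(xlevels[[name]])) xlevels[[name]]
                else if (is.factor(v)) levels(droplevels(v)) else sort(unique(v))
      lv[[name]] <<- levels
      add_group(name, factor_dummies(v, name, levels))
    } else {
      add_group(name, matrix(as.numeric(v), ncol = 1,
                             dimnames = list(NULL, name)))
    }
  }
  for (v in spec$covariates) add_var(v)
  for (v in spec$moderators) add_var(v)
  if (spec$composition) {
    z <- as.matrix(data[, ilr_cols])
    add_group("composition", z)
    for (m in spec$interactions) {
      d <- factor_dummies(data[[m]], m, lv[[m]])
      cols <- do.call(cbind, lapply(colnames(d), function(dc) {
        ic <- z * d[, dc]
        colnames(ic) <- paste0(ilr_cols, ":", dc)
        ic
      }))
      gname <- paste0("composition:", m)
      add_group(gname, cols)
      contains[[gname]] <- c("composition", m)
    }
  }
  list(X = X, groups = groups, contains = contains, xlevels = lv)
}

model_columns <- function(spec) {
  unique(c(spec$outcome, spec$covariates, spec$moderators,
           if (spec$composition) ilr_cols))
}

rss_rank <- function(X, y, cols) {
  f <- stats::lm.fit(X[, cols, drop = FALSE], y)
  list(rss = sum(f$residuals^2), rank = f$rank)
}

#' Fit the compositional linear model
#'
#' Ordinary least squares on the design implied by a [model_spec()], with
#' listwise deletion of incomplete rows. Errors on a rank-deficient
#' design, naming the aliased columns.
#'
#' @param data Prepared analysis table (see [prepare_analysis_data()]).
#' @param spec A [model_spec()].
#' @return Object of class `tu_fit`: coefficients, fitted values,
#'   residuals, `sigma2`, `df_residual`, coefficient covariance `vcov`,
#'   term `groups`, `n` (complete cases used), `n_dropped`.
#' @export
fit_model <- function(data, spec) {
  keep <- stats::complete.cases(data[, model_columns(spec), drop = FALSE])
  d <- data[keep, , drop = FALSE]
  des <- design_from_data(d, spec)
  X <- des$X
  y <- as.numeric(d[[spec$outcome]])
  q <- qr(X)
  if (q$rank < ncol(X)) {
    aliased <- colnames(X)[q$pivot[(q$rank + 1):ncol(X)]]
    stop("rank-deficient design; aliased column(s): ",
         paste(aliased, collapse = ", "))
  }
  coef <- qr.coef(q, y)
  fitted <- drop(X %*% coef)
  res <- y - fitted
  df_res <- nrow(X) - ncol(X)
  sigma2 <- sum(res^2) / df_res
  xtx_inv <- chol2inv(qr.R(q))
  dimnames(xtx_inv) <- list(colnames(X), colnames(X))
  structure(list(coefficients = coef, fitted = fitted, residuals = res,
                 rss = sum(res^2), sigma2 = sigma2, df_residual = df_res,
                 vcov = sigma2 * xtx_inv, groups = des$groups,
                 contains = des$contains, xlevels = des$xlevels,
                 spec = spec, n = nrow(X), n_dropped = sum(!keep)),
            class = "tu_fit")
}

#' @export
print.tu_fit <- function(x, ...) {
  cat("Compositional linear model for '", x$spec$outcome, "'\n", sep = "")
  cat("  n =", x$n, "complete cases (", x$n_dropped, "dropped )\n")
  cat("  term groups:", paste(names(x$groups), collapse = ", "), "\n")
  cat("  residual df =", x$df_residual,
      " sigma =", sqrt(x$sigma2), "\n")
  invisible(x)
}

#' Predict from a fitted compositional model
#'
#' @param object A `tu_fit`.
#' @param newdata data.frame carrying every model column (ilr coordinates
#'   and covariates at the desired profile).
#' @param interval `"none"` or `"confidence"` (pointwise, delta-method
#'   band from the coefficient covariance).
#' @param level Confidence level.
#' @param ... Unused.
#' @return Numeric vector, or a data.frame `fit`, `lwr`, `upr`.
#' @export
predict.tu_fit <- function(object, newdata, interval = c("none", "confidence"),
                           level = 0.95, ...) {
  interval <- match.arg(interval)
  des <- design_from_data(newdata, object$spec, xlevels = object$xlevels)
  X <- des$X[, names(object$coefficients), drop = FALSE]
  fit <- drop(X %*% object$coefficients)
  if (interval == "none") return(fit)
  se <- sqrt(rowSums((X %*% object$vcov) * X))
  tq <- stats::qt(1 - (1 - level) / 2, object$df_residual)
  data.frame(fit = fit, lwr = fit - tq * se, upr = fit + tq * se)
}

#' Type II F-tests for every term group
#'
#' Each group `g` is tested by comparing the model containing all terms
#' except `g` and except any term containing `g` (marginality) with that
#' model plus `g`: `F = (SS_g / df_g) / MSE(full model)`, with the full
#' model's residual degrees of freedom in the denominator. The
#' composition and interaction blocks are multi-df joint tests.
#'
#' @param data Prepared analysis table.
#' @param spec A [model_spec()].
#' @return data.frame (`term`, `F`, `df1`, `df2`, `p`), one row per term
#'   group, plus attribute `n` (complete cases).
#' @export
type2_anova <- function(data, spec) {
  fit <- fit_model(data, spec)
  keep <- stats::complete.cases(data[, model_columns(spec), drop = FALSE])
  d <- data[keep, , drop = FALSE]
  des <- design_from_data(d, spec)
  X <- des$X
  y <- as.numeric(d[[spec$outcome]])
  out <- lapply(names(des$groups), function(g) {
    holders <- names(des$contains)[vapply(des$contains,
                                          function(p) g %in% p, logical(1))]
    drop_groups <- c(g, holders)
    reduced <- setdiff(seq_len(ncol(X)),
                       unlist(des$groups[drop_groups], use.names = FALSE))
    with_g <- c(reduced, des$groups[[g]])
    r0 <- rss_rank(X, y, reduced)
    r1 <- rss_rank(X, y, with_g)
    df1 <- r1$rank - r0$rank
    Fv <- ((r0$rss - r1$rss) / df1) / fit$sigma2
    data.frame(term = g, F = Fv, df1 = df1, df2 = fit$df_residual,
               p = stats::pf(Fv, df1, fit$df_residual, lower.tail = FALSE))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  attr(out, "n") <- fit$n
  out
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjustment `adj_(k) = min(1, min_{j >= k} p_(j) m / j)` on the
#' ascending sort, mapped back to input order.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Backward selection of the compositional model
#'
#' Starting from the full model, repeatedly removes the interaction block
#' with the largest type II p-value while that p-value is at or above
#' `alpha` (ties broken in the fixed order TV, recreational PA, sleep
#' quality); once no removable interaction remains, the composition block
#' is tested (it can only be removed when no interaction block remains)
#' and removed if non-significant; finally the remaining covariates and
#' free moderator main effects are tested collectively with one joint
#' F-test. By default the collective block is retained regardless of its
#' p-value; `drop_covariates = TRUE` removes it when non-significant.
#'
#' @param data Prepared analysis table.
#' @param spec Initial (full) [model_spec()].
#' @param alpha Significance level for removal decisions.
#' @param drop_covariates Remove the collective covariate block when its
#'   joint p is at or above `alpha`?
#' @return List: `spec` (final model), `trace` (data.frame of steps:
#'   `step`, `action`, `term`, `p`), `covariate_test` (joint F, df, p of
#'   the collective block).
#' @export
backward_select <- function(data, spec, alpha = 0.05, drop_covariates = FALSE) {
  tie_order <- c("composition:tv_tertile", "composition:recpa_cat",
                 "composition:sleep_quality")
  trace <- data.frame(step = integer(0), action = character(0),
                      term = character(0), p = numeric(0))
  step <- 0L
  note <- function(action, term, p) {
    trace <<- rbind(trace, data.frame(step = step, action = action,
                                      term = term, p = p))
  }
  ## (i) interaction blocks, largest p first
  repeat {
    if (!length(spec$interactions)) break
    tt <- type2_anova(data, spec)
    ia <- tt[grepl("^composition:", tt$term), ]
    ia <- ia[order(match(ia$term, tie_order)), ]
    worst <- ia[which.max(ia$p), ]
    step <- step + 1L
    if (worst$p >= alpha) {
      note("remove", worst$term, worst$p)
      spec <- model_spec(spec$outcome, spec$covariates, spec$moderators,
                         composition = TRUE,
                         interactions = setdiff(spec$interactions,
                                                sub("^composition:", "", worst$term)))
    } else {
      note("stop", "interactions", worst$p)
      break
    }
  }
  ## (ii) the composition block, removable only with no interactions left
  if (spec$composition && !length(spec$interactions)) {
    tt <- type2_anova(data, spec)
    pc <- tt$p[tt$term == "composition"]
    step <- step + 1L
    if (pc >= alpha) {
      note("remove", "composition", pc)
      spec <- model_spec(spec$outcome, spec$covariates, spec$moderators,
                         composition = FALSE, interactions = character(0))
    } else note("keep", "composition", pc)
  }
  ## (iii) remaining covariates + free moderator main effects, collectively
  locked <- spec$interactions   # moderators held by retained interactions
  collective <- c(spec$covariates, setdiff(spec$moderators, locked))
  cov_test <- NULL
  if (length(collective)) {
    fit <- fit_model(data, spec)
    keep <- stats::complete.cases(data[, model_columns(spec), drop = FALSE])
    d <- data[keep, , drop = FALSE]
    des <- design_from_data(d, spec)
    y <- as.numeric(d[[spec$outcome]])
    cols_drop <- unlist(des$groups[collective], use.names = FALSE)
    reduced <- setdiff(seq_len(ncol(des$X)), cols_drop)
    r0 <- rss_rank(des$X, y, reduced)
    df1 <- ncol(des$X) - r0$rank
    Fv <- ((r0$rss - fit$rss) / df1) / fit$sigma2
    pv <- stats::pf(Fv, df1, fit$df_residual, lower.tail = FALSE)
    cov_test <- list(F = Fv, df1 = df1, df2 = fit$df_residual, p = pv,
                     terms = collective)
    step <- step + 1L
    if (drop_covariates && pv >= alpha) {
      note("remove", "covariates", pv)
      spec <- model_spec(spec$outcome, covariates = character(0),
                         moderators = intersect(spec$moderators, locked),
                         composition = spec$composition,
                         interactions = spec$interactions)
    } else note("keep", "covariates", pv)
  }
  list(spec = spec, trace = trace, covariate_test = cov_test)
}

#' Behaviour-vs-remaining pivot coefficients
#'
#' Refits the model four times, each under a sequential binary partition
#' placing a different behaviour first, and reports the first-coordinate
#' (pivot) coefficient: the association of that behaviour relative to the
#' remaining three. The four rotated bases span the same space, so fitted
#' values and R-squared are identical across refits (the maximum absolute
#' fitted-value difference is attached as an attribute).
#'
#' @param data Prepared analysis table (must carry the minute columns).
#' @param spec A [model_spec()] containing the composition block.
#' @return Named numeric vector of pivot coefficients (sleep, sb, lpa,
#'   mvpa), with attribute `max_fitted_diff`.
#' @export
extract_pivot_coefficients <- function(data, spec) {
  if (!spec$composition)
    stop("pivot coefficients require the composition block in the model")
  comp <- as.matrix(data[, tu_parts()])
  base_fit <- NULL
  maxdiff <- 0
  betas <- vapply(tu_parts(), function(b) {
    d <- data
    z <- ilr_transform(comp, sbp = sbp_pivot(b))
    d[ilr_cols] <- as.data.frame(z)
    fit <- fit_model(d, spec)
    if (is.null(base_fit)) base_fit <<- fit
    else maxdiff <<- max(maxdiff, max(abs(fit$fitted - base_fit$fitted)))
    unname(fit$coefficients["z1"])
  }, numeric(1))
  attr(betas, "max_fitted_diff") <- maxdiff
  betas
}

#' Run the full per-outcome analysis
#'
#' For each outcome: backward selection from the full model, type II
#' F-tests on the final model, Benjamini-Hochberg adjustment across that
#' model's term p-values (the FDR family is the set of terms within one
#' outcome's final model), and pivot coefficients when the composition
#' block is retained.
#'
#' @param data Prepared analysis table.
#' @param outcomes Outcome column names.
#' @param covariates,moderators Passed to [model_spec()].
#' @param alpha Selection level.
#' @param drop_covariates See [backward_select()].
#' @return List of class `tu_study`, one element per outcome: `term_table`
#'   (with `p_adj`), `trace`, `covariate_test`, `n`, `pivot_betas` (NULL
#'   when composition removed), `spec`.
#' @export
run_study <- function(data, outcomes,
                      covariates = c("age", "sex", "site", "smoking", "education"),
                      moderators = c("tv_tertile", "recpa_cat", "sleep_quality"),
                      alpha = 0.05, drop_covariates = FALSE) {
  res <- lapply(outcomes, function(oc) {
    sel <- backward_select(data, model_spec(oc, covariates, moderators),
                           alpha = alpha, drop_covariates = drop_covariates)
    tt <- type2_anova(data, sel$spec)
    tt$p_adj <- bh_adjust(tt$p)
    pivot <- if (sel$spec$composition)
      extract_pivot_coefficients(data, sel$spec) else NULL
    list(term_table = tt, trace = sel$trace,
         covariate_test = sel$covariate_test, n = attr(tt, "n"),
         pivot_betas = pivot, spec = sel$spec)
  })
  names(res) <- outcomes
  class(res) <- "tu_study"
  res
}

#' Format study results as one wide table
#'
#' One row per term ever retained in any final model; per-outcome columns
#' `F`, `p`, `p_adj`; `"-"` marks terms not in that outcome's final model.
#'
#' @param study A `tu_study` from [run_study()].
#' @param digits Rounding for display.
#' @return data.frame of character cells.
#' @export
format_study_table <- function(study, digits = 2) {
  terms <- unique(unlist(lapply(study, function(s) s$term_table$term)))
  out <- data.frame(term = terms)
  fmt <- function(x) formatC(x, digits = digits, format = "f")
  for (oc in names(study)) {
    tt <- study[[oc]]$term_table
    m <- match(terms, tt$term)
    fcell <- ifelse(is.na(m), "-",
                    paste0(fmt(tt$F[m]), " (", tt$df1[m], ", ", tt$df2[m], ")"))
    out[[paste0(oc, "_F")]] <- fcell
    out[[paste0(oc, "_p")]] <- ifelse(is.na(m), "-", fmt(tt$p[m]))
    out[[paste0(oc, "_p_adj")]] <- ifelse(is.na(m), "-", fmt(tt$p_adj[m]))
  }
  out
}
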