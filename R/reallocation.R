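## One-for-remaining time reallocation: vary one behaviour in fixed-minute
## steps while scaling the remaining three proportionally so the day still
## sums to 1440 min, then predict the outcome along the grid.

#' One-for-remaining reallocation grid
#'
#' For each delta, the focal behaviour becomes `focal + delta` and every
#' remaining part is scaled by `(1440 - focal') / (1440 - focal)`. Deltas
#' that would push any part to zero or beyond (focal' <= 0 or >= 1440) are
#' truncated from the grid, not errors.
#'
#' @param base Strictly positive 4-part composition (closed to 1440).
#' @param focal One of `sleep`, `sb`, `lpa`, `mvpa`.
#' @param max_delta Largest reallocation in minutes (grid spans
#'   `-max_delta..+max_delta`).
#' @param step Grid step in minutes (default 15).
#' @return data.frame of class `realloc_grid`: `delta` plus the four part
#'   columns; attribute `truncated` records dropped deltas.
#' @export
one_for_remaining_grid <- function(base, focal, max_delta = 60, step = 15) {
  focal <- match.arg(focal, tu_parts())
  if (step <= 0) stop("step must be > 0")
  base <- closure(base)
  deltas <- seq(-max_delta, max_delta, by = step)
  f0 <- base[[focal]]
  ok <- (f0 + deltas) > 0 & (f0 + deltas) < tu_total()
  grid <- do.call(rbind, lapply(deltas[ok], function(d) {
    f1 <- f0 + d
    out <- base * (tu_total() - f1) / (tu_total() - f0)
    out[[focal]] <- f1
    out
  }))
  res <- data.frame(delta = deltas[ok], grid)
  attr(res, "focal") <- focal
  attr(res, "truncated") <- deltas[!ok]
  class(res) <- c("realloc_grid", "data.frame")
  res
}

#' Predicted outcome along a reallocation grid
#'
#' ilr-transforms each grid composition, builds the design row at a fixed
#' covariate/moderator profile and predicts from the fitted model, with a
#' pointwise delta-method confidence band from the coefficient covariance.
#'
#' @param fit A `tu_fit` from [fit_model()].
#' @param grid A grid from [one_for_remaining_grid()].
#' @param profile Named list/data.frame giving one value for every
#'   covariate and moderator in the model (moderator levels must exist in
#'   the fitted model).
#' @param level Confidence level of the band.
#' @return data.frame: `delta`, `predicted`, `lwr`, `upr`.
#' @export
predict_response_curve <- function(fit, grid, profile, level = 0.95) {
  comps <- as.matrix(grid[, tu_parts()])
  if (any(comps <= 0)) stop("grid compositions must be strictly positive")
  nd <- as.data.frame(profile)[rep(1, nrow(grid)), , drop = FALSE]
  nd[ilr_cols] <- as.data.frame(ilr_transform(comps))
  pr <- predict(fit, nd, interval = "confidence", level = level)
  data.frame(delta = grid$delta, predicted = pr$fit,
             lwr = pr$lwr, upr = pr$upr)
}

#' Mean covariate / reference-level profile for prediction
#'
#' Numeric covariates at their sample means; factors at their reference
#' level unless overridden.
#'
#' @param data Prepared analysis table.
#' @param spec The fitted model's [model_spec()].
#' @param overrides Named list of profile values to override (e.g. a
#'   moderator level).
#' @return One-row data.frame.
#' @export
reference_profile <- function(data, spec, overrides = list()) {
  vars <- c(spec$covariates, spec$moderators)
  prof <- lapply(vars, function(v) {
    x <- data[[v]]
    if (is.factor(x)) factor(levels(x)[1], levels = levels(x))
    else mean(x, na.rm = TRUE)
  })
  names(prof) <- vars
  for (nm in names(overrides)) prof[[nm]] <- overrides[[nm]]
  as.data.frame(prof)
}
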