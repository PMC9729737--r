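test_that("moderator categorisation follows the stated rules", {
  m <- assign_moderators(tv_minutes = c(10, 20, 30, 40, 50, 60),
                         recpa_minutes = c(0, 10, 30, 30.5, 45, 0),
                         sleep_rating = c(0, 1, 2, 3, 1, 2))
  expect_equal(as.character(m$tv_tertile),
               c("low", "low", "medium", "medium", "high", "high"))
  expect_equal(as.character(m$recpa_cat),
               c("none", "upto30", "upto30", "over30", "over30", "none"))
  expect_equal(as.character(m$sleep_quality),
               c("good", "good", "bad", "bad", "good", "bad"))
  # reference levels fixed for dummy coding
  expect_equal(levels(m$tv_tertile)[1], "low")
  expect_equal(levels(m$recpa_cat)[1], "over30")
  expect_equal(levels(m$sleep_quality)[1], "good")
  expect_error(assign_moderators(10, 10, 5), "0, 1, 2 or 3")
  expect_error(assign_moderators(-1, 0, 1), ">= 0")
})

test_that("pairwise correlations use the t transform on n-2 df", {
  x <- c(1, 2, 3, 4)
  pc <- pairwise_correlations(data.frame(x = x, y = x, yneg = -x,
                                         w = c(1, 3, 2, 4)))
  expect_equal(pc$r["x", "y"], 1)
  expect_equal(pc$r["x", "yneg"], -1)
  expect_equal(pc$r["x", "w"], 0.8)
  ct <- cor.test(x, c(1, 3, 2, 4))
  expect_equal(pc$p["x", "w"], ct$p.value)
  expect_equal(pc$n["x", "w"], 4)
  # insufficient pairs flagged as missing
  short <- data.frame(a = c(1, 2, NA, NA), b = c(NA, 2, 3, 4))
  expect_true(is.na(pairwise_correlations(short)$r["a", "b"]))
})

test_that("the linear model recovers an exact generating design", {
  set.seed(13)
  d <- rand_fixture(150)
  d$y <- 1 + 0.5 * d$z1 - 0.2 * d$z2 + 0.1 * d$z3 + 0.3 * d$age +
    2 * (d$sex == "female") + 0.7 * (d$smoking == "current")
  spec <- model_spec("y", covariates = c("age", "sex", "smoking"),
                     moderators = character(0), interactions = character(0))
  fit <- fit_model(d, spec)
  expect_equal(unname(fit$coefficients[c("z1", "z2", "z3")]),
               c(0.5, -0.2, 0.1), tolerance = 1e-8)
  expect_lt(fit$rss, 1e-16)
  expect_equal(fit$n, 150)

  # complete-case accounting
  d2 <- d
  d2$y[1:7] <- NA
  expect_equal(fit_model(d2, spec)$n, 143)
  expect_equal(fit_model(d2, spec)$n_dropped, 7)

  # raw behaviour minutes alongside the intercept are perfectly collinear
  spec_bad <- model_spec("y", covariates = c("age", tu_parts()),
                         moderators = character(0),
                         interactions = character(0))
  expect_error(fit_model(d, spec_bad), "aliased")
})

test_that("type II F equals the squared t for a single continuous term", {
  set.seed(17)
  d <- rand_fixture(80)
  spec <- model_spec("y", covariates = "age", moderators = character(0),
                     composition = FALSE, interactions = character(0))
  tt <- type2_anova(d, spec)
  lf <- summary(lm(y ~ age, data = d))
  expect_equal(tt$F[tt$term == "age"], lf$coefficients["age", "t value"]^2,
               tolerance = 1e-10)
})

test_that("type II sums of squares match sequential SS on a balanced design", {
  d <- expand.grid(sex = c("male", "female"),
                   site = c("Adelaide", "Newcastle"), rep = 1:10)
  set.seed(19)
  d$y <- rnorm(40) + (d$sex == "female") - 0.5 * (d$site == "Newcastle")
  spec <- model_spec("y", covariates = c("sex", "site"),
                     moderators = character(0), composition = FALSE,
                     interactions = character(0))
  tt <- type2_anova(d, spec)
  seq_tab <- anova(lm(y ~ sex + site, data = d))
  expect_equal(tt$F[tt$term == "sex"], seq_tab["sex", "F value"],
               tolerance = 1e-10)
  expect_equal(tt$F[tt$term == "site"], seq_tab["site", "F value"],
               tolerance = 1e-10)
})

test_that("type II F-tests equal brute-force nested refits and car::Anova", {
  set.seed(23)
  for (i in 1:5) {
    d <- rand_fixture(130)
    spec <- model_spec("y", interactions = sample(
      c("tv_tertile", "recpa_cat", "sleep_quality"), sample(0:3, 1)))
    mine <- type2_anova(d, spec)
    orac <- oracle_type2(d, spec)
    m <- match(mine$term, orac$term)
    expect_false(anyNA(m))
    expect_equal(mine$F, orac$F[m], tolerance = 1e-8)
    expect_equal(mine$df1, orac$df1[m])
    expect_equal(mine$p, orac$p[m], tolerance = 1e-8)
  }

  skip_if_not_installed("car")
  d <- rand_fixture(100)
  spec <- model_spec("y", covariates = c("age", "sex", "smoking"),
                     moderators = character(0), composition = FALSE,
                     interactions = character(0))
  mine <- type2_anova(d, spec)
  ca <- car::Anova(lm(y ~ age + sex + smoking, data = d), type = 2)
  for (g in c("age", "sex", "smoking"))
    expect_equal(mine$F[mine$term == g], ca[g, "F value"], tolerance = 1e-10)
})

test_that("Benjamini-Hochberg adjustment matches the step-up definition", {
  # an eight-term within-model family with known printed adjustments
  p <- c(age = 0.01, sex = 0.01, site = 0.40, smoking = 0.51,
         education = 0.05, sleep_quality = 0.43, tv = 0.38, recpa = 0.05)
  adj <- bh_adjust(p)
  expect_equal(round(unname(adj["site"]), 2), 0.49)
  expect_equal(round(unname(adj["sleep_quality"]), 2), 0.49)
  expect_equal(round(unname(adj["smoking"]), 2), 0.51)
  expect_equal(round(unname(adj["education"]), 2), 0.10)
  expect_equal(round(unname(adj["recpa"]), 2), 0.10)
  expect_true(all(adj >= p))

  expect_equal(bh_adjust(0.32), 0.32)
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  # monotone in the input, never below the raw p, never above 1
  set.seed(29)
  p2 <- runif(20)
  a1 <- bh_adjust(p2)
  expect_true(all(diff(a1[order(p2)]) >= -1e-15))
  expect_true(all(a1 >= p2 & a1 <= 1))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("backward selection obeys the removal order and marginality", {
  set.seed(31)
  n <- 400
  d <- rand_fixture(n)
  # strong interactions on all three blocks: nothing is removed
  d$y <- with(d, z1 + 2 * z1 * (sleep_quality == "bad") +
                2 * z2 * (tv_tertile == "high") +
                2 * z3 * (recpa_cat == "none") + rnorm(n, 0, 0.3))
  sel <- backward_select(d, model_spec("y"))
  expect_length(sel$spec$interactions, 3)
  expect_equal(sel$trace$action[1], "stop")

  # marginality: the composition block is never removed while any
  # interaction block remains, over repeated null fits
  for (i in 1:10) {
    d2 <- rand_fixture(120)
    d2$y <- rnorm(120)
    sel2 <- backward_select(d2, model_spec("y"))
    tr <- sel2$trace
    comp_removed <- which(tr$action == "remove" & tr$term == "composition")
    ia_removed <- which(tr$action == "remove" & grepl("^composition:", tr$term))
    if (length(comp_removed)) {
      expect_length(ia_removed, 3)        # all interactions went first
      expect_true(all(ia_removed < comp_removed))
      expect_false(sel2$spec$composition)
    }
    # the collective covariate block is retained by default
    expect_equal(tr$term[nrow(tr)], "covariates")
    expect_equal(tr$action[nrow(tr)], "keep")
  }

  # strict covariate removal honours the switch
  d3 <- rand_fixture(200)
  d3$y <- rnorm(200)
  sel3 <- backward_select(d3, model_spec("y"), drop_covariates = TRUE)
  if (sel3$covariate_test$p >= 0.05)
    expect_length(sel3$spec$covariates, 0)
})

test_that("pivot coefficients report each behaviour against the rest", {
  set.seed(37)
  d <- rand_fixture(200)
  d$y <- 0.7 * d$z1 + 0.1 * d$age    # z1 = sleep vs remaining
  spec <- model_spec("y", covariates = "age", moderators = character(0),
                     interactions = character(0))
  b <- extract_pivot_coefficients(d, spec)
  expect_equal(unname(b["sleep"]), 0.7, tolerance = 1e-8)
  expect_lt(attr(b, "max_fitted_diff"), 1e-9)
  expect_equal(sum(b), 0, tolerance = 1e-8)   # pivot betas sum to zero

  # the focal pivot is invariant to the ordering of the non-focal parts
  comp <- as.matrix(d[, tu_parts()])
  for (rest in list(c("mvpa", "sleep", "sb", "lpa"),
                    c("mvpa", "lpa", "sb", "sleep"))) {
    dd <- d
    dd[ilr_cols <- c("z1", "z2", "z3")] <-
      as.data.frame(ilr_transform(comp, sbp = rest))
    expect_equal(unname(fit_model(dd, spec)$coefficients["z1"]),
                 unname(b["mvpa"]), tolerance = 1e-10)
  }

  expect_error(extract_pivot_coefficients(
    d, model_spec("y", covariates = "age", moderators = character(0),
                  composition = FALSE, interactions = character(0))),
    "composition block")
})

test_that("run_study assembles final-model tables with within-model FDR", {
  set.seed(41)
  cfg <- cohort_config(n = 800, seed = 41, n_invalid_accel = 0,
                       n_missing_covariate = 0)
  d <- prepare_analysis_data(generate_cohort(cfg))
  study <- run_study(d, c("speed", "exec"))
  # the generator puts a composition effect on processing speed only
  expect_true(study$speed$spec$composition)
  expect_true(all(study$speed$term_table$p_adj >= study$speed$term_table$p))
  expect_true(all(study$exec$term_table$p_adj <= 1))
  # wiring check only: the n = 800 sampling SE of a pivot beta is ~0.18,
  # so require agreement with the generating value within 3 SEs
  expect_lt(abs(study$speed$pivot_betas[["sleep"]] - 0.28), 0.55)
  expect_equal(sum(study$speed$pivot_betas), 0, tolerance = 1e-8)

  tab <- format_study_table(study)
  expect_true("term" %in% names(tab))
  if (!study$exec$spec$composition)
    expect_equal(tab$exec_F[tab$term == "composition"], "-")
})
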