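## Independent oracles used across the suite. These deliberately take a
## different computational route from the package implementation.

## Balance (ilr) coordinates built from a sequential-binary-partition sign
## matrix, with the standard balance normalisation
## sqrt(r q / (r + q)) * (mean log of + parts - mean log of - parts).
oracle_ilr <- function(x, order = tu_parts()) {
  D <- length(order)
  S <- matrix(0, D - 1, D, dimnames = list(NULL, order))
  for (k in seq_len(D - 1)) {
    S[k, k] <- 1
    S[k, (k + 1):D] <- -1
  }
  psi <- t(apply(S, 1, function(s) {
    r <- sum(s > 0); q <- sum(s < 0)
    out <- numeric(D)
    out[s > 0] <- sqrt(q / (r * (r + q)))
    out[s < 0] <- -sqrt(r / (q * (r + q)))
    out
  }))
  drop(psi %*% log(as.numeric(x[order])))
}

## Aitchison distance straight from the pairwise log-ratio definition
## d(x, y) = sqrt( (1/D) * sum_{i<j} (ln(xi/xj) - ln(yi/yj))^2 ).
oracle_aitchison <- function(x, y) {
  D <- length(x)
  s <- 0
  for (i in seq_len(D - 1)) for (j in (i + 1):D)
    s <- s + (log(x[i] / x[j]) - log(y[i] / y[j]))^2
  sqrt(s / D)
}

## Random strictly positive compositions around realistic daily minutes.
rand_comp <- function(n, sdlog = 0.5) {
  m <- exp(matrix(stats::rnorm(n * 4, log(c(500, 650, 180, 90)), sdlog),
                  n, 4, byrow = TRUE))
  colnames(m) <- tu_parts()
  closure(m)
}

## A random regression fixture in the analysis-table layout.
rand_fixture <- function(n = 120) {
  d <- data.frame(
    age = stats::rnorm(n, 65, 3),
    education = stats::rnorm(n, 16, 3),
    sex = sample(c("male", "female"), n, TRUE),
    site = sample(c("Adelaide", "Newcastle"), n, TRUE),
    smoking = sample(c("never", "previous", "current"), n, TRUE),
    sleep_rating = sample(0:3, n, TRUE),
    tv_minutes = stats::rgamma(n, 2, 1 / 60),
    recpa_minutes = ifelse(stats::runif(n) < 0.5, 0, stats::runif(n, 1, 90)))
  d <- cbind(d, as.data.frame(rand_comp(n)))
  d <- prepare_analysis_data(d)
  d$y <- stats::rnorm(n) + 0.3 * d$z1 +
    0.2 * (d$sex == "female") + 0.01 * d$age
  d
}

## Brute-force type II F-tests through R's formula/lm machinery: for each
## term group, explicitly refit the nested models and difference their
## residual sums of squares.
oracle_type2 <- function(data, spec) {
  frag_of <- function(g) {
    if (g == "composition") return(c("z1", "z2", "z3"))
    if (grepl("^composition:", g)) {
      m <- sub("^composition:", "", g)
      return(sprintf("z%d:%s", 1:3, m))
    }
    g
  }
  groups <- c(spec$covariates, spec$moderators,
              if (spec$composition) "composition",
              if (length(spec$interactions))
                paste0("composition:", spec$interactions))
  cols <- unique(c(spec$outcome, spec$covariates, spec$moderators,
                   if (spec$composition) c("z1", "z2", "z3")))
  d <- data[stats::complete.cases(data[, cols, drop = FALSE]), , drop = FALSE]
  form <- function(gs) stats::reformulate(
    if (length(gs)) unlist(lapply(gs, frag_of)) else "1",
    response = spec$outcome)
  full <- stats::lm(form(groups), data = d)
  mse <- stats::deviance(full) / stats::df.residual(full)
  holders_of <- function(g) {
    if (!length(spec$interactions)) return(character(0))
    ia <- paste0("composition:", spec$interactions)
    if (g == "composition") return(ia)
    ia[spec$interactions == g]
  }
  do.call(rbind, lapply(groups, function(g) {
    reduced <- setdiff(groups, c(g, holders_of(g)))
    f0 <- stats::lm(form(reduced), data = d)
    f1 <- stats::lm(form(c(reduced, g)), data = d)
    df1 <- stats::df.residual(f0) - stats::df.residual(f1)
    Fv <- ((stats::deviance(f0) - stats::deviance(f1)) / df1) / mse
    data.frame(term = g, F = Fv, df1 = df1,
               df2 = stats::df.residual(full),
               p = stats::pf(Fv, df1, stats::df.residual(full),
                             lower.tail = FALSE))
  }))
}

## Null cohort p-values for the joint composition F-test: outcomes are
## pure noise, model = all main effects + composition block.
null_composition_pvals <- function(nrep, n, seed) {
  set.seed(seed)
  spec <- model_spec("y", interactions = character(0))
  vapply(seq_len(nrep), function(i) {
    comps <- generate_compositions(n)
    d <- cbind(generate_covariates(n), as.data.frame(comps))
    d$y <- stats::rnorm(n)
    d <- prepare_analysis_data(d)
    tt <- type2_anova(d, spec)
    tt$p[tt$term == "composition"]
  }, numeric(1))
}
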