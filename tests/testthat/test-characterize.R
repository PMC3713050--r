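test_that("group summaries use sample mean and n-1 SD", {
  gs <- group_summary(c(5, 7, 9, 4, 4), c(1, 1, 1, 2, 2))
  expect_equal(gs$mean, c(7, 4))
  expect_equal(gs$sd, c(2, 0))
  expect_equal(gs$n, c(3L, 2L))
  single <- group_summary(c(1, 2), c("a", "b"))
  expect_true(all(is.na(single$sd)))   # singleton groups have undefined SD
  expect_error(group_summary(1:3, 1:2), "align")
})

test_that("raw one-way ANOVA and summary ANOVA are algebraically identical", {
  set.seed(33)
  for (rep in 1:10) {
    k <- sample(2:5, 1)
    ns <- sample(3:12, k, replace = TRUE)
    v <- unlist(lapply(seq_len(k), function(g) rnorm(ns[g], mean = g)))
    lab <- rep(seq_len(k), ns)
    raw <- anova_oneway_raw(v, lab)
    gs <- group_summary(v, lab)
    summ <- anova_from_summaries(gs$n, gs$mean, gs$sd)
    expect_equal(raw$F, summ$F, tolerance = 1e-10)
    expect_equal(raw$p, summ$p, tolerance = 1e-10)
    expect_equal(raw$df_between, summ$df_between)
    expect_equal(raw$df_within, summ$df_within)
  }
})

test_that("ANOVA degenerate and limiting behaviour", {
  expect_equal(anova_from_summaries(c(5, 5), c(3, 3), c(1, 2))$F, 0)
  expect_equal(anova_from_summaries(c(4, 4), c(0, 1), c(0, 0))$F, Inf)
  # F grows without bound as within-group jitter shrinks
  set.seed(34)
  jit <- rnorm(8)
  lastF <- 0
  for (eps in c(1, 0.1, 0.01)) {
    v <- c(rep(0, 4), rep(1, 4)) + eps * jit
    F <- anova_oneway_raw(v, rep(1:2, each = 4))$F
    expect_gt(F, lastF)
    lastF <- F
  }
  expect_error(anova_oneway_raw(1:4, rep(1, 4)), "2 groups")
  expect_error(anova_oneway_raw(1:4, c(1, 1, 1, 2)), "n >= 2")
})

test_that("rough typing with default cutpoints is consistent and monotone", {
  rt <- rough_categorize(c(68.7, 77.9, 55.5, 57.0),
                         c(7.8, 7.6, 2.2, 12.3), c(1, 0, 0, 0))
  expect_equal(rt$age, c("medium", "older", "younger", "younger"))
  expect_equal(rt$nihss, c("medium", "medium", "lower", "higher"))
  expect_equal(rt$dm, c("positive", "negative", "negative", "negative"))
  # a mean exactly on a cutpoint takes the lower category (closed-left)
  edge <- rough_categorize(c(60, 75), c(5, 10), c(0, 0))
  expect_equal(edge$age, c("younger", "medium"))
  expect_equal(edge$nihss, c("lower", "medium"))
  # monotone: raising a mean never lowers its category
  ord_age <- c(younger = 1, medium = 2, older = 3)
  means <- sort(runif(20, 40, 90))
  cats <- ord_age[rough_categorize(means, rep(5, 20), rep(0, 20))$age]
  expect_true(all(diff(cats) >= 0))
  expect_error(rough_categorize(1, 1, 0, age_cutpoints = c(75, 60)),
               "ascending")
})

test_that("combination counting multiplies the level counts", {
  expect_equal(count_combinations(c(3, 3, 2)), 18)
  expect_equal(count_combinations(1), 1)
  expect_equal(count_combinations(c(2, 2, 2, 2)), 16)
})

test_that("follow-up grids summarize per type and day with missing handling", {
  coh <- generate_cohort(cohort_preset("ms", seed = 41))
  lab <- coh$true_type
  fu <- followup_summary(coh, lab)
  expect_equal(nrow(fu), 4 * 2 * 4)   # types x scales x days
  expect_equal(sum(fu$n[fu$scale == "bi" & fu$day == 30]), 602)
  # large-n check against the generator's own follow-up spec (Type 3, day 90):
  # the oracle is the censored-normal expectation of clamp(N(96.1, 9.5), 0, 100),
  # since clamping at BI = 100 pulls the realized mean below the nominal one
  big <- generate_cohort(cohort_preset("ms", seed = 42, n_scale = 5))
  fub <- followup_summary(big, big$true_type)
  cell <- fub[fub$type == 3 & fub$scale == "bi" & fub$day == 90, ]
  mu <- 96.1; s <- 9.5
  a <- (0 - mu) / s; b <- (100 - mu) / s
  oracle <- 100 * (1 - pnorm(b)) + mu * (pnorm(b) - pnorm(a)) -
    s * (dnorm(b) - dnorm(a))
  expect_lt(abs(cell$mean - oracle), 1)
  # constant outcome
  coh2 <- coh
  for (d in c(30, 90, 180, 360)) coh2[[paste0("bi_", d)]] <- 100
  fu2 <- followup_summary(coh2, lab)
  expect_true(all(fu2$mean[fu2$scale == "bi"] == 100))
  expect_true(all(fu2$sd[fu2$scale == "bi"] == 0))
  # missing values excluded cell-wise, singleton cells flagged with NA sd
  coh3 <- coh[1:5, ]
  coh3$bi_30[2:5] <- NA
  fu3 <- followup_summary(coh3, rep(1, 5))
  cell <- fu3[fu3$scale == "bi" & fu3$day == 30, ]
  expect_equal(cell$n, 1L)
  expect_true(is.na(cell$sd))
})

test_that("disability levels and best-prognosis share reproduce hand cases", {
  grid <- expand.grid(type = 1:2, scale = c("bi", "mrs"), day = c(30, 90, 180, 360))
  grid$mean <- ifelse(grid$scale == "bi",
                      ifelse(grid$type == 1, 95, 60), 2)
  dis <- disability_level(grid)
  expect_equal(unname(dis), c("lower", "higher"))
  expect_equal(best_prognosis_share(c(`1` = 85, `2` = 517), dis), 14.1)
  # all-favourable and vacuous-threshold cases
  grid$mean[grid$scale == "bi"] <- 100
  expect_true(all(disability_level(grid) == "lower"))
  expect_true(all(disability_level(grid, bi_threshold = 0) == "lower"))
  expect_warning(share <- best_prognosis_share(c(10, 20), c("higher", "higher")),
                 "no type")
  expect_equal(share, 0)
  # invariant to relabeling of the types
  s1 <- best_prognosis_share(c(a = 85, b = 517), c(a = "lower", b = "higher"))
  s2 <- best_prognosis_share(c(b = 517, a = 85), c(a = "lower", b = "higher"))
  expect_equal(s1, s2)
})

test_that("gap arithmetic rounds the means before subtracting", {
  expect_equal(gap_arithmetic(77.9, 68.7, "integer"), 9)       # 78 - 69
  expect_equal(gap_arithmetic(77.9, 57.0, "integer"), 21)      # 78 - 57
  expect_equal(gap_arithmetic(12.3, 7.6, "one_decimal"), 4.7)
  expect_equal(gap_arithmetic(5.5, 5.5, "integer"), 0)
})
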