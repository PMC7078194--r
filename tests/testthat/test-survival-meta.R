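test_that("median split sends ties to the low group", {
  expect_equal(as.character(median_split(c(1, 2, 3, 4))), c("low", "low", "high", "high"))
  expect_equal(as.character(median_split(c(1, 2, 3))), c("low", "low", "high"))
  expect_error(median_split(c(5, 5, 5)), "constant")
  expect_error(median_split(5))
})

test_that("cox_hr is antisymmetric under label swap and zero for identical groups", {
  d <- tibble::tibble(
    group = factor(c("low", "low", "high", "high"), levels = c("low", "high")),
    time = c(2, 4, 1, 3), event = 1
  )
  a <- cox_hr(d)
  swapped <- dplyr::mutate(d,
    group = factor(ifelse(group == "low", "high", "low"), levels = c("low", "high"))
  )
  b <- cox_hr(swapped)
  expect_equal(a$log_hr, -b$log_hr, tolerance = 1e-8)
  # two groups with identical event-time structure
  sym <- tibble::tibble(
    group = factor(rep(c("low", "high"), each = 3), levels = c("low", "high")),
    time = rep(c(1, 2, 3), 2), event = 1
  )
  expect_equal(cox_hr(sym)$log_hr, 0, tolerance = 1e-8)
})

test_that("cox_hr agrees with the exhaustive partial-likelihood grid search", {
  d <- tibble::tibble(
    group = factor(c("high", "high", "low", "low"), levels = c("low", "high")),
    time = c(1, 3, 2, 4), event = 1
  )
  fit <- cox_hr(d)
  grid <- oracle_cox_grid(as.integer(d$group == "high"), d$time, d$event)
  expect_lt(abs(fit$log_hr - grid), 1.5e-4)
  # random toy datasets, including ties and censoring
  checked <- 0
  for (seed in 1:40) {
    toy <- random_toy_surv(sample(5:10, 1), seed)
    fit <- cox_hr(toy)
    if (!fit$ok) next
    grid <- oracle_cox_grid(as.integer(toy$group == "high"), toy$time, toy$event)
    if (is.na(grid) || abs(grid) > 4.5) next # flat or effectively separated
    expect_lt(abs(fit$log_hr - grid), 1.5e-4)
    checked <- checked + 1
  }
  expect_gt(checked, 15)
})

test_that("degenerate cohorts are flagged instead of estimated", {
  no_events <- tibble::tibble(
    group = factor(c("low", "high"), levels = c("low", "high")),
    time = c(1, 2), event = 0
  )
  expect_false(cox_hr(no_events)$ok)
  # complete separation: all events in one group, far apart
  sep <- tibble::tibble(
    group = factor(rep(c("low", "high"), each = 10), levels = c("low", "high")),
    time = c(rep(100, 10), 1:10), event = c(rep(0, 10), rep(1, 10))
  )
  expect_false(suppressWarnings(cox_hr(sep))$ok)
})

test_that("KM equals the empirical survival without censoring and log-rank checks out", {
  d <- tibble::tibble(
    group = factor(rep(c("low", "high"), each = 4), levels = c("low", "high")),
    time = c(2, 4, 6, 8, 1, 3, 5, 7), event = 1
  )
  km <- km_logrank(d)
  low <- dplyr::filter(km$curves, group == "low")
  expect_equal(low$surv, c(0.75, 0.5, 0.25, 0))
  # hand-tabulated log-rank
  orc <- oracle_logrank(d$group, d$time, d$event)
  expect_equal(km$chisq, orc$chisq, tolerance = 1e-8)
  expect_equal(km$p, orc$p, tolerance = 1e-8)
  # identical groups: chi-square 0, p 1
  same <- tibble::tibble(
    group = factor(rep(c("low", "high"), 3), levels = c("low", "high")),
    time = rep(c(1, 2, 3), each = 2), event = 1
  )
  km2 <- km_logrank(same)
  expect_equal(km2$chisq, 0, tolerance = 1e-10)
  expect_equal(km2$p, 1, tolerance = 1e-8)
  # no events
  expect_warning(km3 <- km_logrank(dplyr::mutate(d, event = 0)), "no events")
  expect_equal(km3$p, 1)
})

test_that("fixed and DL pooling reproduce the hand-derived two-study example", {
  eff <- tibble::tibble(log_hr = c(0, 1), se = c(0.1, 0.1))
  fe <- pool_effects(eff, model = "fixed")
  expect_equal(fe$log_hr, 0.5)
  expect_equal(fe$q, 50)
  expect_equal(fe$tau2, 0.49)
  expect_equal(fe$i2, 98)
  expect_equal(fe$se, sqrt(1 / 200))
  re <- pool_effects(eff, model = "random")
  expect_equal(re$log_hr, 0.5) # symmetric weights
  expect_equal(re$se, sqrt(1 / (2 / (0.01 + 0.49))))
})

test_that("pooling matches metafor on heterogeneous inputs", {
  skip_if_not_installed("metafor")
  set.seed(9)
  eff <- tibble::tibble(
    log_hr = rnorm(8, 0.4, 0.3),
    se = runif(8, 0.1, 0.4)
  )
  re <- pool_effects(eff, model = "random")
  mf <- metafor::rma(yi = eff$log_hr, sei = eff$se, method = "DL")
  expect_equal(re$log_hr, as.numeric(mf$beta), tolerance = 1e-8)
  expect_equal(re$se, mf$se, tolerance = 1e-8)
  expect_equal(re$tau2, mf$tau2, tolerance = 1e-8)
  expect_equal(re$i2, mf$I2, tolerance = 1e-6)
  expect_equal(re$q, mf$QE, tolerance = 1e-8)
  fe <- pool_effects(eff, model = "fixed")
  mf_fe <- metafor::rma(yi = eff$log_hr, sei = eff$se, method = "FE")
  expect_equal(fe$log_hr, as.numeric(mf_fe$beta), tolerance = 1e-8)
  expect_equal(fe$se, mf_fe$se, tolerance = 1e-8)
})

test_that("pooling degenerate and homogeneous cases behave", {
  single <- pool_effects(tibble::tibble(log_hr = 0.7, se = 0.2))
  expect_equal(single$log_hr, 0.7)
  expect_equal(single$i2, 0)
  expect_equal(single$tau2, 0)
  ident <- pool_effects(tibble::tibble(log_hr = rep(0.5, 3), se = rep(0.2, 3)))
  expect_equal(ident$log_hr, 0.5)
  expect_equal(ident$q, 0)
  expect_equal(ident$tau2, 0)
  expect_equal(ident$i2, 0)
  expect_error(pool_effects(tibble::tibble(log_hr = NA_real_, se = NA_real_)), "no finite")
})

test_that("random-effects SE is never below fixed-effects SE and I2 is 0 when Q <= df", {
  for (seed in 1:10) {
    set.seed(seed)
    eff <- tibble::tibble(log_hr = rnorm(6, 0, 0.5), se = runif(6, 0.05, 0.5))
    fe <- pool_effects(eff, "fixed")
    re <- pool_effects(eff, "random")
    expect_gte(re$se, fe$se - 1e-12)
    expect_lte(fe$se, min(eff$se))
    if (fe$q <= fe$df) {
      expect_equal(re$tau2, 0)
      expect_equal(re$i2, 0)
    }
  }
})

test_that("relabeling low and high inverts the pooled hazard ratio", {
  g <- gen_cohorts(c(GENE = 2.5), k_cohorts = 5, n_per_cohort = 120, seed = 21)
  effects <- purrr::map_dfr(g$cohorts$data, function(d) {
    cox_hr(tibble::tibble(
      group = median_split(d$GENE), time = d$time_months, event = d$event
    ))
  })
  flipped <- purrr::map_dfr(g$cohorts$data, function(d) {
    grp <- median_split(d$GENE)
    grp <- factor(ifelse(grp == "low", "high", "low"), levels = c("low", "high"))
    cox_hr(tibble::tibble(group = grp, time = d$time_months, event = d$event))
  })
  a <- pool_effects(effects)
  b <- pool_effects(flipped)
  expect_equal(a$log_hr, -b$log_hr, tolerance = 1e-6)
})

test_that("integrated meta-analysis recovers effect direction and ranking", {
  g <- gen_cohorts(c(PPAT = 5.21, GLS1 = 0.38),
    k_cohorts = 10, n_per_cohort = 300, seed = 31
  )
  res <- integrate_enzymes(g$cohorts, c("PPAT", "GLS1"), min_followup_months = 0)
  ppat <- dplyr::filter(res$integrated, gene == "PPAT")
  gls1 <- dplyr::filter(res$integrated, gene == "GLS1")
  expect_gt(ppat$hr, 1)
  expect_lt(gls1$hr, 1)
  expect_equal(res$integrated$gene[1], "PPAT") # sorted by HR
  expect_equal(ppat$n_patients, 3000)
  # per-organ tables carry both pooling models
  expect_setequal(unique(res$per_organ$model), c("fixed", "random"))
})

test_that("single-cohort integration equals the cohort effect and gaps are reported", {
  g <- gen_cohorts(c(PPAT = 3), k_cohorts = 1, n_per_cohort = 200, seed = 41)
  d <- g$cohorts$data[[1]]
  solo <- cox_hr(tibble::tibble(
    group = median_split(d$PPAT), time = d$time_months, event = d$event
  ))
  res <- integrate_enzymes(g$cohorts, c("PPAT", "MISSING"), min_followup_months = 0)
  got <- dplyr::filter(res$integrated, gene == "PPAT")
  expect_equal(log(got$hr), solo$log_hr, tolerance = 1e-10)
  expect_equal(got$i2, 0)
  expect_true("MISSING" %in% res$skipped$gene)
  expect_false("MISSING" %in% res$integrated$gene)
})

test_that("the follow-up duration filter drops short cohorts", {
  g <- gen_cohorts(c(PPAT = 2), k_cohorts = 3, n_per_cohort = 100, seed = 51)
  # truncate one cohort to under 84 months
  g$cohorts$data[[2]] <- dplyr::mutate(g$cohorts$data[[2]],
    time_months = pmin(time_months, 50)
  )
  res <- integrate_enzymes(g$cohorts, "PPAT", min_followup_months = 84)
  expect_equal(res$dropped_cohorts, "cohort02")
  expect_equal(dplyr::n_distinct(res$per_cohort$cohort_id), 2)
})
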