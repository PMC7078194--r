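#' Median-split group labels
#'
#' Divides subjects at the median expression value: strictly above the median
#' is "high", at or below is "low" (ties-to-low policy).
#'
#' @param expression Numeric vector, length >= 2, not all identical.
#' @return Factor with levels `low`, `high` (low is the reference).
#' @export
median_split <- function(expression) {
  stopifnot(length(expression) >= 2)
  if (length(unique(expression)) == 1) {
    stop("constant expression: degenerate median split", call. = FALSE)
  }
  med <- stats::median(expression)
  factor(ifelse(expression > med, "high", "low"), levels = c("low", "high"))
}

#' Per-cohort hazard ratio for a dichotomized covariate
#'
#' Univariate Cox proportional-hazards fit (Efron tie handling by default) of
#' the high-vs-low group indicator; returns the log hazard ratio and its
#' model-based standard error. Monotone-likelihood (separation) is detected
#' by an absurd coefficient or standard error and flagged non-finite.
#'
#' @param data Data frame with columns `group` (factor, low reference),
#'   `time` (> 0) and `event` (0/1).
#' @param ties Tie-handling method, `"efron"` (default) or `"breslow"`.
#' @return One-row tibble: `log_hr`, `se`, `n`, `n_events`, `ok`.
#' @export
cox_hr <- function(data, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  data <- tibble::as_tibble(data)
  stopifnot(all(c("group", "time", "event") %in% names(data)))
  n_ev <- sum(data$event)
  fail <- function() {
    tibble::tibble(
      log_hr = NA_real_, se = NA_real_,
      n = nrow(data), n_events = n_ev, ok = FALSE
    )
  }
  if (n_ev < 1 || length(unique(data$group)) < 2) {
    return(fail())
  }
  fit <- tryCatch(
    survival::coxph(survival::Surv(time, event) ~ group, data = data, ties = ties),
    error = function(e) NULL, warning = function(w) {
      suppressWarnings(
        survival::coxph(survival::Surv(time, event) ~ group, data = data, ties = ties)
      )
    }
  )
  if (is.null(fit)) {
    return(fail())
  }
  b <- unname(stats::coef(fit))
  se <- sqrt(unname(diag(stats::vcov(fit))))
  if (!is.finite(b) || !is.finite(se) || abs(b) > 15 || se > 100) {
    return(fail())
  }
  tibble::tibble(log_hr = b, se = se, n = nrow(data), n_events = n_ev, ok = TRUE)
}

#' Kaplan-Meier curves and the log-rank test
#'
#' Product-limit survival estimate per group and the standard 1-df log-rank
#' statistic.
#'
#' @inheritParams cox_hr
#' @return List: `curves` (tibble `group`, `time`, `n_risk`, `n_event`,
#'   `surv`), `chisq`, `df`, `p`. With no events, p = 1 with a warning.
#' @export
km_logrank <- function(data) {
  data <- tibble::as_tibble(data)
  sf <- survival::survfit(survival::Surv(time, event) ~ group, data = data)
  strata <- rep(names(sf$strata), sf$strata)
  curves <- tibble::tibble(
    group = sub("^group=", "", strata),
    time = sf$time, n_risk = sf$n.risk, n_event = sf$n.event, surv = sf$surv
  )
  if (sum(data$event) == 0) {
    warning("no events: log-rank undefined, p = 1")
    return(list(curves = curves, chisq = 0, df = 1, p = 1))
  }
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ group, data = data)
  p <- stats::pchisq(sd_$chisq, df = 1, lower.tail = FALSE)
  list(curves = curves, chisq = unname(sd_$chisq), df = 1, p = p)
}

#' Fixed- and random-effects pooling of cohort hazard ratios
#'
#' Inverse-variance fixed-effects pooling, and DerSimonian-Laird
#' random-effects pooling with the moment estimator
#' `tau2 = max(0, (Q - df) / (sum(w) - sum(w^2)/sum(w)))` on fixed-effects
#' weights `w = 1/se^2`. Heterogeneity is summarized by Cochran's Q and
#' `I2 = max(0, (Q - df)/Q) * 100`. The confidence interval and p-value are
#' Wald-type on the log scale.
#'
#' @param effects Data frame with columns `log_hr` and `se` (one row per
#'   cohort; rows with non-finite entries are dropped), optionally `n`.
#' @param model `"random"` (default) or `"fixed"`.
#' @param conf_level Confidence level, default 0.95.
#' @return Object of class `pooled_effect`.
#' @export
pool_effects <- function(effects, model = c("random", "fixed"), conf_level = 0.95) {
  model <- match.arg(model)
  effects <- tibble::as_tibble(effects)
  stopifnot(all(c("log_hr", "se") %in% names(effects)))
  keep <- is.finite(effects$log_hr) & is.finite(effects$se) & effects$se > 0
  effects <- effects[keep, , drop = FALSE]
  k <- nrow(effects)
  if (k == 0) stop("no finite effects to pool", call. = FALSE)
  y <- effects$log_hr
  w <- 1 / effects$se^2
  mu_fe <- sum(w * y) / sum(w)
  Q <- sum(w * (y - mu_fe)^2)
  df <- k - 1
  tau2 <- if (df > 0) max(0, (Q - df) / (sum(w) - sum(w^2) / sum(w))) else 0
  i2 <- if (Q > 0) max(0, (Q - df) / Q) * 100 else 0
  if (model == "random") {
    wr <- 1 / (effects$se^2 + tau2)
    mu <- sum(wr * y) / sum(wr)
    se <- sqrt(1 / sum(wr))
    weights <- wr
  } else {
    mu <- mu_fe
    se <- sqrt(1 / sum(w))
    weights <- w
  }
  zcrit <- stats::qnorm(1 - (1 - conf_level) / 2)
  structure(
    list(
      model = model, k = k, log_hr = mu, se = se,
      ci_low = mu - zcrit * se, ci_high = mu + zcrit * se,
      q = Q, df = df, tau2 = tau2, i2 = i2,
      p = 2 * stats::pnorm(-abs(mu / se)),
      conf_level = conf_level,
      n = if ("n" %in% names(effects)) sum(effects$n) else NA_integer_,
      effects = dplyr::mutate(effects, weight = weights / sum(weights))
    ),
    class = "pooled_effect"
  )
}

#' @export
print.pooled_effect <- function(x, ...) {
  cat(sprintf(
    "%s-effects pooling of %d cohorts\nHR %.3f [%.3f, %.3f], p = %.3g\nQ = %.2f (df %d), tau2 = %.3f, I2 = %.1f%%\n",
    x$model, x$k, exp(x$log_hr), exp(x$ci_low), exp(x$ci_high), x$p,
    x$q, x$df, x$tau2, x$i2
  ))
  invisible(x)
}

#' @export
tidy.pooled_effect <- function(x, exponentiate = FALSE, ...) {
  est <- c(x$log_hr, x$ci_low, x$ci_high)
  if (exponentiate) est <- exp(est)
  tibble::tibble(
    estimate = est[1], conf.low = est[2], conf.high = est[3],
    std.error = x$se, p.value = x$p
  )
}

#' @export
glance.pooled_effect <- function(x, ...) {
  tibble::tibble(
    model = x$model, k = x$k, q = x$q, tau2 = x$tau2, i2 = x$i2,
    p.value = x$p, n = x$n
  )
}

#' Integrated prognostic meta-analysis across cohorts and enzymes
#'
#' For every gene: median-split each cohort, estimate the per-cohort log HR
#' ([cox_hr()]), pool per organ (fixed and random effects) and pool the
#' integrated estimate across all cohorts with the random-effects model.
#' Cohorts where the Cox fit fails (no events, separation, missing gene) are
#' excluded from that gene's pooling and counted in the skip report.
#'
#' @param cohorts Tibble with columns `cohort_id`, `organ` and a list-column
#'   `data` of subject tibbles (`time_months`, `event`, one column per gene);
#'   see [read_cohorts()].
#' @param genes Character vector of gene columns to analyze.
#' @param min_followup_months Minimum maximum-follow-up a cohort must reach to
#'   be included (default 84 months, i.e. > 7 years); set 0 to disable.
#' @return Object of class `meta_result`: list with `integrated` (per-gene
#'   tibble), `per_organ`, `per_cohort` and `skipped`.
#' @export
integrate_enzymes <- function(cohorts, genes, min_followup_months = 84) {
  cohorts <- tibble::as_tibble(cohorts)
  stopifnot(all(c("cohort_id", "organ", "data") %in% names(cohorts)))
  keep <- purrr::map_lgl(cohorts$data, ~ max(.x$time_months) >= min_followup_months)
  dropped <- cohorts$cohort_id[!keep]
  cohorts <- cohorts[keep, , drop = FALSE]
  if (nrow(cohorts) == 0) stop("no cohorts meet the follow-up criterion", call. = FALSE)

  per_cohort <- purrr::map_dfr(genes, function(g) {
    purrr::pmap_dfr(cohorts, function(cohort_id, organ, data, ...) {
      base <- tibble::tibble(gene = g, cohort_id = cohort_id, organ = organ)
      if (!g %in% names(data)) {
        return(dplyr::mutate(base,
          log_hr = NA_real_, se = NA_real_,
          n = nrow(data), n_events = sum(data$event), ok = FALSE,
          reason = "gene missing"
        ))
      }
      grp <- tryCatch(median_split(data[[g]]), error = function(e) NULL)
      if (is.null(grp)) {
        return(dplyr::mutate(base,
          log_hr = NA_real_, se = NA_real_,
          n = nrow(data), n_events = sum(data$event), ok = FALSE,
          reason = "degenerate split"
        ))
      }
      eff <- cox_hr(tibble::tibble(group = grp, time = data$time_months, event = data$event))
      dplyr::mutate(dplyr::bind_cols(base, eff),
        reason = ifelse(eff$ok, NA_character_, "cox fit failed")
      )
    })
  })

  skipped <- dplyr::filter(per_cohort, !.data$ok)
  usable <- dplyr::filter(per_cohort, .data$ok)

  pool_rows <- function(df, model) {
    if (nrow(df) == 0) {
      return(NULL)
    }
    po <- pool_effects(df, model = model)
    tibble::tibble(
      model = model, k = po$k, hr = exp(po$log_hr),
      ci_low = exp(po$ci_low), ci_high = exp(po$ci_high),
      p = po$p, q = po$q, tau2 = po$tau2, i2 = po$i2, n_patients = po$n
    )
  }

  per_organ <- usable |>
    dplyr::group_by(.data$gene, .data$organ) |>
    dplyr::group_modify(~ dplyr::bind_rows(
      pool_rows(.x, "fixed"), pool_rows(.x, "random")
    )) |>
    dplyr::ungroup()

  integrated <- usable |>
    dplyr::group_by(.data$gene) |>
    dplyr::group_modify(~ pool_rows(.x, "random")) |>
    dplyr::ungroup() |>
    dplyr::arrange(dplyr::desc(.data$hr))

  structure(
    list(
      integrated = integrated, per_organ = per_organ,
      per_cohort = per_cohort, skipped = skipped,
      dropped_cohorts = dropped
    ),
    class = "meta_result"
  )
}

#' @export
print.meta_result <- function(x, ...) {
  cat(
    "Integrated meta-analysis:", nrow(x$integrated), "gene(s),",
    length(unique(x$per_cohort$cohort_id)), "cohort(s)\n"
  )
  print(x$integrated)
  invisible(x)
}

#' @export
tidy.meta_result <- function(x, ...) x$integrated

#' @export
glance.meta_result <- function(x, ...) {
  tibble::tibble(
    n_genes = nrow(x$integrated),
    n_cohorts = length(unique(x$per_cohort$cohort_id)),
    n_skipped = nrow(x$skipped)
  )
}

#' Read cohorts from a manifest
#'
#' @param manifest Path to a CSV with columns `cohort_id`, `organ`,
#'   `filename` (paths relative to the manifest's directory), or a data frame
#'   of the same shape with absolute paths.
#' @return Tibble `cohort_id`, `organ`, `data` (list-column of subject
#'   tibbles), ready for [integrate_enzymes()].
#' @export
read_cohorts <- function(manifest) {
  if (is.character(manifest)) {
    dir <- dirname(manifest)
    man <- readr::read_csv(manifest, show_col_types = FALSE)
    man$filename <- file.path(dir, man$filename)
  } else {
    man <- tibble::as_tibble(manifest)
  }
  stopifnot(all(c("cohort_id", "organ", "filename") %in% names(man)))
  missing <- !file.exists(man$filename)
  if (any(missing)) {
    stop("cohort file(s) not found: ", paste(man$filename[missing], collapse = ", "),
      call. = FALSE
    )
  }
  tibble::tibble(
    cohort_id = man$cohort_id, organ = man$organ,
    data = purrr::map(man$filename, ~ readr::read_csv(.x, show_col_types = FALSE))
  )
}
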