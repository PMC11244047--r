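#' Published pre/post outcome summaries for the two intervention groups
#'
#' Means and standard deviations of the four health outcomes -- one-leg
#' stand balance with eyes closed (s), grip strength (kg), SF-12 quality of
#' life score and Beck Depression Inventory score -- before and after the
#' 8-week tai chi program, for the precision-feedback group (n = 21
#' completers) and the standard group (n = 29 completers). These summaries
#' parameterize the synthetic cohort generator; the raw per-subject data
#' were never released.
#'
#' @return A tibble: `measure`, `group`, `n`, `pre_mean`, `pre_sd`,
#'   `post_mean`, `post_sd`.
#' @export
reported_outcomes <- function() {
  tibble::tibble(
    measure = rep(c("balance_s", "grip_kg", "sf12", "bdi"), each = 2),
    group = rep(c("precision", "standard"), times = 4),
    n = rep(c(21L, 29L), times = 4),
    pre_mean = c(8.61, 7.06, 36.17, 33.69, 30.39, 30.07, 19.13, 19.92),
    pre_sd = c(4.21, 3.13, 4.82, 6.88, 1.61, 4.68, 8.03, 7.07),
    post_mean = c(10.72, 7.21, 39.78, 38.98, 31.46, 30.87, 16.06, 17.90),
    post_sd = c(3.50, 2.18, 3.22, 5.15, 2.57, 5.94, 3.44, 5.90)
  )
}

#' Specify a synthetic intervention cohort
#'
#' Each subject's (pre, post) pair for a measure is drawn from a bivariate
#' normal with the group's marginal means and SDs and pre/post correlation
#' `rho`. The correlation is a generator parameter because within-subject
#' correlation was not reported; 0.7 is a typical test-retest correlation
#' for these outcomes over eight weeks.
#'
#' @param params summary table in the format of [reported_outcomes()]
#'   (that table is the default).
#' @param n_precision,n_standard group sizes (defaults 21 and 29).
#' @param rho pre/post correlation, in (-1, 1) (default 0.7).
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(params = reported_outcomes(), n_precision = 21,
                        n_standard = 29, rho = 0.7) {
  stopifnot(all(c("measure", "group", "pre_mean", "pre_sd", "post_mean", "post_sd")
  %in% names(params)))
  if (any(params$pre_sd <= 0) || any(params$post_sd <= 0)) {
    rlang::abort("standard deviations must be positive")
  }
  if (!is.finite(rho) || rho <= -1 || rho >= 1) {
    rlang::abort("rho must lie strictly between -1 and 1")
  }
  if (n_precision < 2 || n_standard < 2) {
    rlang::abort("each group needs at least 2 subjects")
  }
  structure(
    list(
      params = tibble::as_tibble(params),
      n_precision = as.integer(n_precision),
      n_standard = as.integer(n_standard), rho = rho
    ),
    class = "cohort_spec"
  )
}

#' Generate a synthetic intervention cohort
#'
#' @param spec a [cohort_spec()].
#' @param seed integer seed; identical seeds give identical cohorts.
#' @return A tibble of per-subject records: `subject_id`, `group`,
#'   `measure`, `pre`, `post`.
#' @examples
#' cohort <- synth_cohort(cohort_spec(), seed = 1)
#' dplyr::count(cohort, group) # 21 precision, 29 standard per measure
#' @export
synth_cohort <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "cohort_spec"))
  rho <- spec$rho
  groups <- tibble::tibble(
    group = c("precision", "standard"),
    n = c(spec$n_precision, spec$n_standard),
    prefix = c("P", "S")
  )
  withr::with_seed(seed, {
    purrr::pmap_dfr(groups, function(group, n, prefix) {
      ids <- sprintf("%s%02d", prefix, seq_len(n))
      purrr::map_dfr(unique(spec$params$measure), function(ms) {
        row <- spec$params[spec$params$measure == ms & spec$params$group == group, ]
        z1 <- stats::rnorm(n)
        z2 <- stats::rnorm(n)
        tibble::tibble(
          subject_id = ids, group = group, measure = ms,
          pre = row$pre_mean + row$pre_sd * z1,
          post = row$post_mean + row$post_sd * (rho * z1 + sqrt(1 - rho^2) * z2)
        )
      })
    })
  })
}

#' Shapiro-Wilk normality test
#'
#' @param x numeric sample with 3 to 5000 observations.
#' @return A tibble with the `W` statistic (in (0, 1]) and `p_value`.
#' @export
normality_test <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 3 || length(x) > 5000) {
    rlang::abort("Shapiro-Wilk requires between 3 and 5000 observations")
  }
  res <- stats::shapiro.test(x)
  tibble::tibble(W = unname(res$statistic), p_value = res$p.value)
}

#' 2 (group) x 2 (time) mixed-design ANOVA
#'
#' One between-subjects factor (intervention group) and one within-subjects
#' factor (pre/post). Computed via orthonormal between/within subject
#' contrasts: the subject sum contrast `(pre + post) / sqrt(2)` carries the
#' group effect against the subjects-within-group error, and the change
#' contrast `(post - pre) / sqrt(2)` carries the time and group-by-time
#' effects against the time-by-subjects error. Effects use Type III
#' (drop-one, unweighted-means) sums of squares, matching the SPSS
#' convention for the unbalanced 21 vs 29 groups. Partial eta squared is
#' `SS_effect / (SS_effect + SS_error_for_that_effect)`.
#'
#' @param data tibble of subject records with columns `group` (two levels),
#'   `pre`, `post`, and optionally `measure`.
#' @param measure when `data` holds several measures, the one to analyse.
#' @return A `mixed_anova` object; `tidy()` gives one row per effect
#'   (`group`, `time`, `group:time`) with `df_num`, `df_den`, `ss`,
#'   `ss_error`, `statistic` (F), `p_value` and `pes` (partial eta squared).
#' @export
mixed_anova <- function(data, measure = NULL) {
  if (!is.null(measure)) {
    data <- data[data$measure == measure, ]
  } else if ("measure" %in% names(data)) {
    if (length(unique(data$measure)) > 1) {
      rlang::abort("data holds several measures; pick one with `measure`")
    }
    measure <- data$measure[1]
  }
  stopifnot(all(c("group", "pre", "post") %in% names(data)))
  data <- data[stats::complete.cases(data[, c("group", "pre", "post")]), ]
  glev <- sort(unique(data$group))
  if (length(glev) != 2) rlang::abort("exactly two groups required", class = "bafawubu_data_error")
  ng <- table(factor(data$group, levels = glev))
  if (any(ng < 2)) rlang::abort("each group needs at least 2 subjects", class = "bafawubu_data_error")
  N <- nrow(data)
  x <- ifelse(data$group == glev[1], 1, -1)
  X <- cbind(intercept = 1, group = x)
  XtX <- crossprod(X)
  inv <- solve(XtX)

  # orthonormal within-subject contrasts keep all SS on the response scale
  u <- (data$pre + data$post) / sqrt(2)
  cc <- (data$post - data$pre) / sqrt(2)
  fit_part <- function(y) {
    b <- drop(inv %*% crossprod(X, y))
    rss <- sum((y - drop(X %*% b))^2)
    ss <- b^2 / diag(inv) # Type III drop-one SS per coefficient
    list(b = b, rss = rss, ss = ss)
  }
  between <- fit_part(u)
  within <- fit_part(cc)
  df_den <- N - 2
  eff <- tibble::tibble(
    effect = c("group", "time", "group:time"),
    df_num = 1L,
    df_den = df_den,
    ss = unname(c(between$ss["group"], within$ss["intercept"], within$ss["group"])),
    ss_error = c(between$rss, within$rss, within$rss)
  )
  # an effect with literally no variation (e.g. post == pre everywhere)
  # has F = 0 by convention rather than 0/0
  eff$statistic <- ifelse(
    eff$ss == 0, 0,
    (eff$ss / eff$df_num) / (eff$ss_error / eff$df_den)
  )
  eff$p_value <- stats::pf(eff$statistic, eff$df_num, eff$df_den, lower.tail = FALSE)
  eff$pes <- ifelse(eff$ss == 0, 0, eff$ss / (eff$ss + eff$ss_error))
  structure(
    list(
      effects = eff, measure = measure, groups = glev,
      n = as.integer(ng)
    ),
    class = "mixed_anova"
  )
}

#' @export
print.mixed_anova <- function(x, ...) {
  cat(sprintf(
    "<mixed_anova%s: %s (n = %d) vs %s (n = %d)>\n",
    if (is.null(x$measure)) "" else paste0(" [", x$measure, "]"),
    x$groups[1], x$n[1], x$groups[2], x$n[2]
  ))
  print(x$effects)
  invisible(x)
}

#' @rdname mixed_anova
#' @param x a `mixed_anova` object.
#' @param ... unused.
#' @export
tidy.mixed_anova <- function(x, ...) x$effects

#' @rdname mixed_anova
#' @export
glance.mixed_anova <- function(x, ...) {
  e <- x$effects
  tibble::tibble(
    measure = x$measure %||% NA_character_,
    n_total = sum(x$n),
    f_group = e$statistic[1], p_group = e$p_value[1],
    f_time = e$statistic[2], p_time = e$p_value[2],
    f_interaction = e$statistic[3], p_interaction = e$p_value[3],
    pes_interaction = e$pes[3]
  )
}

#' Within-group and between-group contrasts
#'
#' The follow-up tests around the mixed ANOVA: a paired t-test of pre vs
#' post within each group, a Welch two-sample t-test on post scores between
#' groups, and -- because the exact between-group contrast behind a
#' published post-intervention difference can be ambiguous -- a Welch test
#' on change scores (post minus pre) as well. All p-values are two-sided.
#'
#' @param data subject records with `group`, `pre`, `post` (one measure).
#' @param measure optional measure filter as in [mixed_anova()].
#' @return A tibble: `contrast`, `group`, `estimate`, `statistic`, `df`,
#'   `p_value`.
#' @export
outcome_contrasts <- function(data, measure = NULL) {
  if (!is.null(measure)) data <- data[data$measure == measure, ]
  glev <- sort(unique(data$group))
  stopifnot(length(glev) == 2)
  paired <- purrr::map_dfr(glev, function(g) {
    d <- data[data$group == g, ]
    diff <- d$post - d$pre
    if (stats::sd(diff) == 0) {
      # degenerate change scores: zero everywhere -> t = 0, p = 1;
      # a constant nonzero shift -> infinite t, p = 0
      m <- mean(diff)
      return(tibble::tibble(
        contrast = "pre vs post (paired)", group = g,
        estimate = m, statistic = if (m == 0) 0 else sign(m) * Inf,
        df = length(diff) - 1, p_value = if (m == 0) 1 else 0
      ))
    }
    tt <- stats::t.test(d$post, d$pre, paired = TRUE)
    tibble::tibble(
      contrast = "pre vs post (paired)", group = g,
      estimate = unname(tt$estimate), statistic = unname(tt$statistic),
      df = unname(tt$parameter), p_value = tt$p.value
    )
  })
  welch <- function(y, label) {
    tt <- stats::t.test(y[data$group == glev[1]], y[data$group == glev[2]])
    tibble::tibble(
      contrast = label, group = paste(glev, collapse = " vs "),
      estimate = unname(tt$estimate[1] - tt$estimate[2]),
      statistic = unname(tt$statistic), df = unname(tt$parameter),
      p_value = tt$p.value
    )
  }
  dplyr::bind_rows(
    paired,
    welch(data$post, "post between groups (Welch)"),
    welch(data$post - data$pre, "change between groups (Welch)")
  )
}

#' Full intervention analysis across measures
#'
#' Runs [mixed_anova()] and [outcome_contrasts()] for every measure in a
#' cohort and assembles a summary shaped like a published outcomes table:
#' group means +- SD pre and post, within-group paired p-values, and the
#' interaction p-value with its partial eta squared.
#'
#' @param cohort per-subject records as from [synth_cohort()].
#' @return A tibble with one row per measure.
#' @export
intervention_table <- function(cohort) {
  purrr::map_dfr(unique(cohort$measure), function(ms) {
    d <- cohort[cohort$measure == ms, ]
    an <- mixed_anova(d)
    ct <- outcome_contrasts(d)
    fmt <- function(g, col) {
      v <- d[[col]][d$group == g]
      sprintf("%.2f ± %.2f", mean(v), stats::sd(v))
    }
    p_within <- function(g) ct$p_value[ct$contrast == "pre vs post (paired)" & ct$group == g]
    tibble::tibble(
      measure = ms,
      precision_pre = fmt("precision", "pre"),
      precision_post = fmt("precision", "post"),
      precision_p = p_within("precision"),
      standard_pre = fmt("standard", "pre"),
      standard_post = fmt("standard", "post"),
      standard_p = p_within("standard"),
      interaction_p = an$effects$p_value[3],
      interaction_pes = an$effects$pes[3]
    )
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
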