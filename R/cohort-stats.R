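#' Summary statistics for one group
#'
#' Container for a group summarized by its mean, standard deviation and size,
#' as printed in study demographics tables. Used by the summary-statistic
#' t-test and Cohen's d.
#'
#' @param mean Group mean.
#' @param sd Group standard deviation (>= 0).
#' @param n Group size (>= 2).
#' @return A `summary_group` list.
#' @export
summary_group <- function(mean, sd, n) {
  if (!is.finite(sd) || sd < 0) abort("`sd` must be a non-negative number.")
  if (!is.finite(n) || n < 2) abort("`n` must be >= 2.")
  structure(list(mean = mean, sd = sd, n = as.integer(n)), class = "summary_group")
}

#' Pooled-variance Student t-test from group summaries
#'
#' Computes the independent-samples t statistic
#' `t = (m1 - m2) / sqrt(s_p^2 (1/n1 + 1/n2))` with the pooled variance
#' `s_p^2 = ((n1-1) s1^2 + (n2-1) s2^2) / (n1 + n2 - 2)`, its degrees of
#' freedom `n1 + n2 - 2`, and the two-sided p value. Exactly reproducible
#' from printed means and SDs, no raw data needed.
#'
#' @param g1,g2 [summary_group()] objects.
#' @return Tibble with columns `statistic`, `df`, `p_value`.
#' @examples
#' t_from_summary(summary_group(71.4, 10.1, 19), summary_group(78.9, 12.1, 19))
#' @export
t_from_summary <- function(g1, g2) {
  stopifnot(inherits(g1, "summary_group"), inherits(g2, "summary_group"))
  if (g1$sd == 0 && g2$sd == 0) abort("Degenerate input: both group SDs are zero.")
  df <- g1$n + g2$n - 2L
  sp2 <- ((g1$n - 1) * g1$sd^2 + (g2$n - 1) * g2$sd^2) / df
  stat <- (g1$mean - g2$mean) / sqrt(sp2 * (1 / g1$n + 1 / g2$n))
  tibble::tibble(statistic = stat, df = df, p_value = 2 * pt(-abs(stat), df))
}

#' Cohen's d from group summaries
#'
#' Standardized mean difference `|m1 - m2| / sqrt((s1^2 + s2^2) / 2)`, the
#' balanced-design pooled-SD form.
#'
#' @param g1,g2 [summary_group()] objects.
#' @return d, a single non-negative number.
#' @export
cohen_d_from_summary <- function(g1, g2) {
  stopifnot(inherits(g1, "summary_group"), inherits(g2, "summary_group"))
  pooled <- sqrt((g1$sd^2 + g2$sd^2) / 2)
  if (pooled == 0) abort("Degenerate input: zero pooled SD.")
  abs(g1$mean - g2$mean) / pooled
}

#' Demographic summaries for an elite speed-skater cohort and matched controls
#'
#' Published summary statistics (mean, SD, n = 19 per group) for age, body
#' height and body mass of a national-team speed-skating cohort and a
#' physically active non-athlete control group, used in the worked examples
#' and to demonstrate [t_from_summary()] / [cohen_d_from_summary()].
#'
#' @return Tibble with columns `variable`, `group`, `mean`, `sd`, `n`.
#' @export
speed_skater_demographics <- function() {
  tibble::tribble(
    ~variable,    ~group,     ~mean, ~sd,  ~n,
    "age",        "athlete",   18,    3.1, 19L,
    "age",        "control",   19,    2.3, 19L,
    "height",     "athlete",  178.5,  9.0, 19L,
    "height",     "control",  181.5, 11.0, 19L,
    "body_mass",  "athlete",   71.4, 10.1, 19L,
    "body_mass",  "control",   78.9, 12.1, 19L
  )
}

#' Group comparisons from a demographics summary table
#'
#' Runs the pooled-variance t-test and Cohen's d for every variable in a
#' long summary table with exactly two groups per variable.
#'
#' @param summaries Tibble with columns `variable`, `group`, `mean`, `sd`,
#'   `n`, e.g. [speed_skater_demographics()]. The first group in each
#'   variable (table order) is taken as group 1.
#' @return Tibble with one row per variable: `statistic`, `df`, `p_value`,
#'   `cohen_d`, `effect_label`.
#' @examples
#' demographic_tests(speed_skater_demographics())
#' @export
demographic_tests <- function(summaries) {
  summaries |>
    dplyr::group_by(.data$variable) |>
    dplyr::group_modify(function(d, key) {
      if (nrow(d) != 2L) abort("Each variable needs exactly two group rows.")
      g1 <- summary_group(d$mean[1], d$sd[1], d$n[1])
      g2 <- summary_group(d$mean[2], d$sd[2], d$n[2])
      res <- t_from_summary(g1, g2)
      res$cohen_d <- cohen_d_from_summary(g1, g2)
      res$effect_label <- interpret_cohen_d(res$cohen_d)
      res
    }) |>
    dplyr::ungroup()
}

#' Shapiro-Wilk normality check
#'
#' @param values Numeric vector, 3 <= n <= 5000.
#' @param alpha Pass criterion: normality retained when `p > alpha`.
#' @return Tibble with `statistic` (W), `p_value` and logical `pass`.
#' @export
check_normality <- function(values, alpha = 0.05) {
  values <- values[is.finite(values)]
  if (length(values) < 3L || length(values) > 5000L) {
    abort(sprintf("Shapiro-Wilk requires 3 <= n <= 5000 (got %d).", length(values)))
  }
  if (sd(values) == 0) abort("Degenerate input: all values identical.")
  sw <- shapiro.test(values)
  tibble::tibble(statistic = unname(sw$statistic),
                 p_value = sw$p.value,
                 pass = sw$p.value > alpha)
}

#' Levene homogeneity-of-variance check
#'
#' Levene's test with deviations taken about the group means
#' (`center = mean`), the classical form.
#'
#' @param groups List of numeric vectors (>= 2 groups, each n >= 2).
#' @return Tibble with `statistic`, `df1`, `df2`, `p_value`.
#' @export
check_homogeneity <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) {
    abort("`groups` must be a list of at least two numeric vectors.")
  }
  if (any(vapply(groups, length, 1L) < 2L)) abort("Each group needs n >= 2.")
  y <- unlist(groups, use.names = FALSE)
  if (sd(y) == 0) abort("Degenerate input: all values identical.")
  g <- factor(rep(seq_along(groups), vapply(groups, length, 1L)))
  lev <- car::leveneTest(y, g, center = mean)
  tibble::tibble(statistic = lev[1, "F value"],
                 df1 = lev[1, "Df"], df2 = lev[2, "Df"],
                 p_value = lev[1, "Pr(>F)"])
}

# ---- repeated-measures ANOVA ------------------------------------------------

assert_complete_crossing <- function(d) {
  cells <- tidyr::expand_grid(subject_id = unique(d$subject_id),
                              condition = .conditions, limb = .limbs)
  present <- dplyr::distinct(d, .data$subject_id, .data$condition, .data$limb)
  if (nrow(present) != nrow(d)) {
    dup <- d |>
      dplyr::count(.data$subject_id, .data$condition, .data$limb) |>
      dplyr::filter(.data$n > 1L)
    abort(paste0("Duplicate cell(s) in cohort table: ",
                 paste(sprintf("%s/%s/%s", dup$subject_id, dup$condition, dup$limb),
                       collapse = ", ")))
  }
  miss <- dplyr::anti_join(cells, present, by = c("subject_id", "condition", "limb"))
  if (nrow(miss) > 0L) {
    abort(paste0("Incomplete crossing: missing cell(s) ",
                 paste(sprintf("%s/%s/%s", miss$subject_id, miss$condition, miss$limb),
                       collapse = ", ")))
  }
  invisible(d)
}

# Greenhouse-Geisser epsilon for the effect spanned by orthonormal contrast
# rows M over the 6 within-subject cells, from the cell covariance sigma.
gg_epsilon <- function(M, sigma) {
  E <- M %*% sigma %*% t(M)
  k <- nrow(M)
  tr <- sum(diag(E))
  tr^2 / (k * sum(E * t(E)))
}

orthonormal_contrasts <- function(k) {
  C <- stats::contr.helmert(k)
  t(apply(C, 2, function(col) col / sqrt(sum(col^2))))
}

#' Two-within-factor repeated-measures ANOVA on a cohort table
#'
#' Univariate within-subject decomposition for the fully crossed design
#' subject x condition (rest / endurance / sprint) x side (left / right),
#' applied to one dependent variable (`L` or `F`) in one frequency band.
#' For each effect the sum of squares comes from the marginal cell means and
#' the error sum of squares from the effect-by-subject interaction;
#' `F = (SS_effect/df1) / (SS_error/df2)` and partial eta squared is
#' `SS_effect / (SS_effect + SS_error)`.
#'
#' No sphericity correction is applied by default; Greenhouse-Geisser
#' adjusted p values are available via `correction = "greenhouse-geisser"`
#' (dfs in the output stay uncorrected, the correction only rescales the
#' p value's reference distribution).
#'
#' @param table Cohort tibble with columns subject_id, condition, limb,
#'   band, L, F; every subject must have all 6 condition x limb cells for
#'   the chosen band.
#' @param dv `"L"` or `"F"`.
#' @param band Band label to analyse (e.g. `"2_5"`); may be `NULL` if the
#'   table holds a single band.
#' @param correction `"none"` or `"greenhouse-geisser"`.
#' @return A `tremor_rm_anova` object; see [tidy()] and [glance()].
#' @examples
#' tab <- simulate_cohort(cohort_design(seed = 1))
#' fit <- rm_anova(tab, dv = "L", band = "2_5")
#' tidy(fit)
#' @export
rm_anova <- function(table, dv = c("L", "F"), band = NULL,
                     correction = c("none", "greenhouse-geisser")) {
  dv <- match.arg(dv)
  correction <- match.arg(correction)
  d <- tibble::as_tibble(table)
  if (!is.null(band)) d <- dplyr::filter(d, .data$band == !!band)
  if (nrow(d) == 0L) abort("No rows for the requested band.")
  if (length(unique(d$band)) > 1L) {
    abort("Table holds several bands; pass `band` to select one.")
  }
  assert_complete_crossing(d)
  d$y <- d[[dv]]

  a <- length(.conditions); b <- length(.limbs)
  subjects <- sort(unique(d$subject_id))
  n <- length(subjects)
  if (n < 2L) abort("Need at least 2 subjects.")

  # y[i, j, s]: condition i, limb j, subject s
  d <- dplyr::arrange(d,
                      match(.data$subject_id, subjects),
                      match(.data$condition, .conditions),
                      match(.data$limb, .limbs))
  y <- array(d$y, dim = c(b, a, n))  # fastest index = limb
  y <- aperm(y, c(2, 1, 3))          # -> condition x limb x subject

  gm <- mean(y)
  m_i <- apply(y, 1, mean)          # condition means
  m_j <- apply(y, 2, mean)          # limb means
  m_s <- apply(y, 3, mean)          # subject means
  m_ij <- apply(y, c(1, 2), mean)
  m_is <- apply(y, c(1, 3), mean)
  m_js <- apply(y, c(2, 3), mean)

  ss_a <- b * n * sum((m_i - gm)^2)
  ss_b <- a * n * sum((m_j - gm)^2)
  ss_ab <- n * sum((m_ij - outer(m_i, rep(1, b)) - outer(rep(1, a), m_j) + gm)^2)
  ss_as <- b * sum((m_is - outer(m_i, rep(1, n)) - outer(rep(1, a), m_s) + gm)^2)
  ss_bs <- a * sum((m_js - outer(m_j, rep(1, n)) - outer(rep(1, b), m_s) + gm)^2)
  resid <- y
  for (i in seq_len(a)) for (j in seq_len(b)) for (s in seq_len(n)) {
    resid[i, j, s] <- y[i, j, s] - m_ij[i, j] - m_is[i, s] - m_js[j, s] +
      m_i[i] + m_j[j] + m_s[s] - gm
  }
  ss_abs <- sum(resid^2)
  ss_subj <- a * b * sum((m_s - gm)^2)

  eff <- tibble::tibble(
    effect = c("condition", "side", "condition:side"),
    ss_effect = c(ss_a, ss_b, ss_ab),
    ss_error = c(ss_as, ss_bs, ss_abs),
    df1 = c(a - 1L, b - 1L, (a - 1L) * (b - 1L)),
    df2 = c((a - 1L) * (n - 1L), (b - 1L) * (n - 1L), (a - 1L) * (b - 1L) * (n - 1L))
  )
  eff$statistic <- (eff$ss_effect / eff$df1) / (eff$ss_error / eff$df2)
  eff$statistic[eff$ss_effect == 0] <- 0  # 0/0 when the error SS also vanishes
  eff$partial_eta_sq <- ifelse(eff$ss_effect == 0, 0,
                               eff$ss_effect / (eff$ss_effect + eff$ss_error))

  if (correction == "greenhouse-geisser") {
    # cell covariance across subjects, cells ordered condition (slow) x limb
    cellmat <- t(apply(y, 3, function(m) as.vector(t(m))))
    sigma <- stats::cov(cellmat)
    Ca <- orthonormal_contrasts(a); Cb <- orthonormal_contrasts(b)
    ones_a <- matrix(rep(1 / sqrt(a), a), nrow = 1)
    ones_b <- matrix(rep(1 / sqrt(b), b), nrow = 1)
    eps <- c(
      gg_epsilon(kronecker(Ca, ones_b), sigma),
      gg_epsilon(kronecker(ones_a, Cb), sigma),
      gg_epsilon(kronecker(Ca, Cb), sigma)
    )
    eff$gg_epsilon <- eps
    eff$p_value <- pf(eff$statistic, eps * eff$df1, eps * eff$df2, lower.tail = FALSE)
  } else {
    eff$p_value <- pf(eff$statistic, eff$df1, eff$df2, lower.tail = FALSE)
  }
  eff$effect_label <- interpret_eta_squared(eff$partial_eta_sq)

  structure(
    list(
      anova = eff,
      dv = dv,
      band = if (is.null(band)) unique(d$band) else band,
      correction = correction,
      n_subjects = n,
      condition_means = tibble::tibble(condition = .conditions, mean = m_i),
      side_means = tibble::tibble(limb = .limbs, mean = m_j),
      ss_subjects = ss_subj,
      ss_total = ss_subj + sum(eff$ss_effect) + sum(eff$ss_error)
    ),
    class = "tremor_rm_anova"
  )
}

#' @export
print.tremor_rm_anova <- function(x, ...) {
  cat(sprintf("Repeated-measures ANOVA: %s, band %s (n = %d subjects)\n",
              x$dv, x$band, x$n_subjects))
  print(as.data.frame(x$anova), digits = 4, row.names = FALSE)
  invisible(x)
}

#' Tidy a repeated-measures ANOVA fit
#'
#' @param x A `tremor_rm_anova` object.
#' @param ... Ignored.
#' @return Tibble with one row per effect: sums of squares, dfs, F,
#'   p value and partial eta squared.
#' @method tidy tremor_rm_anova
#' @export
tidy.tremor_rm_anova <- function(x, ...) {
  x$anova
}

#' One-row summary of a repeated-measures ANOVA fit
#'
#' @param x A `tremor_rm_anova` object.
#' @param ... Ignored.
#' @return One-row tibble: dv, band, n_subjects, correction, total SS.
#' @method glance tremor_rm_anova
#' @export
glance.tremor_rm_anova <- function(x, ...) {
  tibble::tibble(dv = x$dv, band = x$band, n_subjects = x$n_subjects,
                 correction = x$correction, ss_total = x$ss_total)
}

#' Tukey post hoc contrasts between conditions
#'
#' All pairwise condition contrasts on the condition marginal means, with
#' studentized-range p values using the condition-by-subject error term of
#' the repeated-measures decomposition. Unadjusted p values (paired
#' comparison on the same error term) are reported alongside.
#'
#' @inheritParams rm_anova
#' @return Tibble with columns `contrast`, `estimate`, `p_unadj`, `p_adj`.
#' @export
tukey_posthoc <- function(table, dv = c("L", "F"), band = NULL) {
  dv <- match.arg(dv)
  fit <- rm_anova(table, dv = dv, band = band)
  a <- length(.conditions); b <- length(.limbs); n <- fit$n_subjects
  row <- fit$anova[fit$anova$effect == "condition", ]
  ms_err <- row$ss_error / row$df2
  se_mean <- sqrt(ms_err / (b * n))  # SE of one condition marginal mean
  means <- fit$condition_means$mean
  pairs <- utils::combn(a, 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    diff <- means[j] - means[i]
    q <- abs(diff) / se_mean
    p_unadj <- 2 * pt(-q / sqrt(2), row$df2)
    # ptukey's far tail is less accurate than pt's; the studentized-range p
    # can never fall below the pairwise p, so enforce that floor
    p_adj <- max(ptukey(q, nmeans = a, df = row$df2, lower.tail = FALSE), p_unadj)
    tibble::tibble(
      contrast = sprintf("%s - %s", .conditions[j], .conditions[i]),
      estimate = diff,
      p_unadj = p_unadj,
      p_adj = p_adj
    )
  })
}

#' Interpret partial eta squared
#'
#' Conventional thresholds: >= 0.01 small, >= 0.06 medium, >= 0.14 large.
#'
#' @param x Numeric vector of partial eta squared values in `[0, 1]`.
#' @return Character vector of labels.
#' @export
interpret_eta_squared <- function(x) {
  dplyr::case_when(
    x >= 0.14 ~ "large",
    x >= 0.06 ~ "medium",
    x >= 0.01 ~ "small",
    TRUE ~ "negligible"
  )
}

#' Interpret Cohen's d
#'
#' Conventional thresholds: >= 0.2 small, >= 0.5 medium, >= 0.8 large.
#'
#' @param x Numeric vector of non-negative d values.
#' @return Character vector of labels.
#' @export
interpret_cohen_d <- function(x) {
  dplyr::case_when(
    x >= 0.8 ~ "large",
    x >= 0.5 ~ "medium",
    x >= 0.2 ~ "small",
    TRUE ~ "negligible"
  )
}
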