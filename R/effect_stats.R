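# Effect sizes and group comparisons.
#
# Hedges' g is the standardized mean difference using the pooled SD with
# the small-sample bias correction J = 1 - 3 / (4(n1 + n2 - 2) - 1); the
# correction is always applied (it is negligible at cohort scale but exact
# at small n). Paired designs use the equal-n pooled SD of the two
# condition vectors.

#' Summarise a group from its moments
#'
#' @param n number of observations (>= 2).
#' @param mean group mean (native units).
#' @param sd group standard deviation (>= 0).
#' @param label optional label.
#' @return a `group_summary`.
#' @export
group_summary <- function(n, mean, sd, label = "") {
  if (n < 2) stop("`n` must be >= 2", call. = FALSE)
  if (sd < 0) stop("`sd` must be >= 0", call. = FALSE)
  out <- list(n = n, mean = mean, sd = sd, label = label)
  class(out) <- "group_summary"
  out
}

.hn_as_summary <- function(x, label = "") {
  if (inherits(x, "group_summary")) return(x)
  x <- x[is.finite(x)]
  if (length(x) < 2) stop("need at least 2 finite values", call. = FALSE)
  group_summary(length(x), mean(x), stats::sd(x), label)
}

#' Hedges' g standardized mean difference
#'
#' `g = (mean_a - mean_b) / s_pooled * J` with
#' `s_pooled = sqrt(((n_a - 1) sd_a^2 + (n_b - 1) sd_b^2) / (n_a + n_b - 2))`
#' and `J = 1 - 3 / (4(n_a + n_b - 2) - 1)`. Accepts raw numeric vectors or
#' `group_summary` objects interchangeably; both routes agree exactly. The
#' sign follows `mean_a - mean_b`.
#'
#' @param a,b numeric vectors or `group_summary` objects.
#' @return Hedges' g (dimensionless).
#' @export
hedges_g <- function(a, b) {
  a <- .hn_as_summary(a)
  b <- .hn_as_summary(b)
  df <- a$n + b$n - 2
  sp2 <- ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / df
  if (sp2 == 0) {
    if (a$mean == b$mean) return(0)
    stop("both groups have zero variance but unequal means: ",
         "standardized difference undefined", call. = FALSE)
  }
  j <- 1 - 3 / (4 * df - 1)
  (a$mean - b$mean) / sqrt(sp2) * j
}

#' Proportional (percent) difference between two means
#'
#' `2 (a - b) / (a + b) * 100`: antisymmetric and scale-invariant, so
#' differences of structures of very different sizes can share one axis.
#'
#' @param a,b positive means (same units).
#' @return percent difference.
#' @export
percent_difference <- function(a, b) {
  if (any(a + b <= 0)) stop("`a + b` must be > 0", call. = FALSE)
  2 * (a - b) / (a + b) * 100
}

#' Compare two groups: t-test, Bonferroni threshold, Hedges' g
#'
#' Unpaired comparisons use the pooled-variance Student t-test; paired
#' comparisons test the within-pair differences. Hedges' g for the paired
#' design standardizes by the equal-n pooled SD of the two condition
#' vectors (not the SD of the differences). Significance is declared at
#' `0.05 / family_size`. Group summaries may be supplied instead of raw
#' vectors for unpaired comparisons (and for the paired g, in which case
#' the t-test requires raw data and is reported as `NA`).
#'
#' @param x,y numeric vectors (equal length when paired) or `group_summary`
#'   objects.
#' @param design `"unpaired"` or `"paired"`.
#' @param family_size number of comparisons in the Bonferroni family.
#' @param label optional comparison label.
#' @return an `effect_size_result`: `g`, `t`, `p`, `df`,
#'   `alpha_bonferroni`, `significant`, `design`, group sizes.
#' @export
compare_groups <- function(x, y, design = c("unpaired", "paired"),
                           family_size = 1, label = "") {
  design <- match.arg(design)
  if (family_size < 1) stop("`family_size` must be >= 1", call. = FALSE)
  raw <- is.numeric(x) && is.numeric(y)
  sx <- .hn_as_summary(x)
  sy <- .hn_as_summary(y)
  if (design == "unpaired") {
    g <- hedges_g(sx, sy)
    df <- sx$n + sy$n - 2
    sp2 <- ((sx$n - 1) * sx$sd^2 + (sy$n - 1) * sy$sd^2) / df
    t_stat <- (sx$mean - sy$mean) / sqrt(sp2 * (1 / sx$n + 1 / sy$n))
    p <- 2 * stats::pt(-abs(t_stat), df)
  } else {
    if (raw && length(x) != length(y)) {
      stop("paired design requires equal-length vectors", call. = FALSE)
    }
    # equal-n pooled SD of the two conditions
    sp <- sqrt((sx$sd^2 + sy$sd^2) / 2)
    df <- sx$n + sy$n - 2
    j <- 1 - 3 / (4 * df - 1)
    g <- if (sp == 0) {
      if (sx$mean == sy$mean) 0 else
        stop("zero variance with unequal means", call. = FALSE)
    } else {
      (sx$mean - sy$mean) / sp * j
    }
    if (raw) {
      d <- x - y
      if (stats::sd(d) == 0) {
        t_stat <- if (mean(d) == 0) 0 else Inf
        p <- if (mean(d) == 0) 1 else 0
        df <- length(d) - 1
      } else {
        tt <- stats::t.test(x, y, paired = TRUE)
        t_stat <- unname(tt$statistic)
        p <- tt$p.value
        df <- unname(tt$parameter)
      }
    } else {
      t_stat <- NA_real_
      p <- NA_real_
      df <- NA_real_
    }
  }
  alpha <- 0.05 / family_size
  out <- list(label = label, design = design,
              n1 = sx$n, n2 = sy$n, g = g, t = t_stat, p = p, df = df,
              alpha_bonferroni = alpha,
              significant = !is.na(p) && p < alpha)
  class(out) <- "effect_size_result"
  out
}

#' Bland-Altman agreement summary
#'
#' Mean difference between paired measurements and the 1.96 SD limits of
#' agreement, with the plotting coordinates (pair means vs differences).
#'
#' @param x,y paired finite numeric vectors (n >= 3).
#' @return list with `mean_diff`, `loa_low`, `loa_high`, `sd_diff`,
#'   `means`, `diffs`.
#' @export
bland_altman <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must be paired",
                                   call. = FALSE)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 pairs", call. = FALSE)
  d <- x - y
  m <- mean(d)
  s <- stats::sd(d)
  list(mean_diff = m, sd_diff = s,
       loa_low = m - 1.96 * s, loa_high = m + 1.96 * s,
       means = (x + y) / 2, diffs = d)
}

#' Covariate effects on a deconfounded regional volume
#'
#' Volumes are first corrected for scan date, head size and age (the
#' stated convention for lifestyle-covariate analyses); then: Pearson
#' correlation with BMI, two-group comparisons for hypertension
#' (no-hypertension minus hypertension) and education (higher minus lower),
#' and the three pairwise smoking contrasts (never/previous/current) under
#' a Bonferroni family of 6 together with a one-way ANOVA. Contrasts whose
#' groups have fewer than 2 members are skipped with a message.
#'
#' @inheritParams build_nomogram
#' @param region,hemisphere volume selector, see [cohort_volume()].
#' @return list with `bmi` (r, p, n), `contrasts` (data frame of
#'   comparisons), and `smoking_anova` (F, p, df).
#' @export
covariate_effects <- function(cohort, region = "hippocampus",
                              hemisphere = "average",
                              correction = c("scan_date", "head_scaling",
                                             "age"),
                              mad_cutoff = 5) {
  .hn_assert_cohort(cohort)
  rows <- which(!cohort$excluded_selfreport)
  sub <- cohort[rows, , drop = FALSE]
  v <- cohort_volume(sub, region, hemisphere)
  mask <- suppressWarnings(mad_filter(v, cutoff = mad_cutoff))
  include <- !mask$excluded
  if (length(correction) > 0) {
    model <- fit_confound_model(sub, region, correction,
                                hemisphere = hemisphere, include = include)
    v <- apply_deconfound(v, model, sub)
  }
  v <- v[include]
  sub <- sub[include, , drop = FALSE]

  ok_bmi <- is.finite(sub$bmi) & is.finite(v)
  ct <- stats::cor.test(sub$bmi[ok_bmi], v[ok_bmi])
  bmi <- list(r = unname(ct$estimate), p = ct$p.value, n = sum(ok_bmi))

  contrasts <- list()
  add <- function(lst, label, g1, g2, family) {
    if (sum(!is.na(g1)) < 2 || sum(!is.na(g2)) < 2) {
      message("skipping contrast ", label, ": a level has fewer than 2 ",
              "observations")
      return(lst)
    }
    r <- compare_groups(g1[!is.na(g1)], g2[!is.na(g2)],
                        design = "unpaired", family_size = family,
                        label = label)
    c(lst, list(as.data.frame(unclass(r)[c("label", "design", "n1", "n2",
                                           "g", "t", "p",
                                           "alpha_bonferroni",
                                           "significant")])))
  }
  contrasts <- add(contrasts, "no_hypertension-hypertension",
                   v[!sub$hypertension], v[sub$hypertension], 1)
  contrasts <- add(contrasts, "education_higher-lower",
                   v[sub$education == "higher"],
                   v[sub$education == "lower"], 1)
  sm <- sub$smoking
  contrasts <- add(contrasts, "smoking_never-current",
                   v[sm == "never"], v[sm == "current"], 6)
  contrasts <- add(contrasts, "smoking_previous-current",
                   v[sm == "previous"], v[sm == "current"], 6)
  contrasts <- add(contrasts, "smoking_never-previous",
                   v[sm == "never"], v[sm == "previous"], 6)
  contrasts <- do.call(rbind, contrasts)

  fit <- stats::aov(v ~ factor(sm))
  an <- summary(fit)[[1]]
  smoking_anova <- list(F = an[1, "F value"], p = an[1, "Pr(>F)"],
                        df = unname(an[, "Df"]))

  list(bmi = bmi, contrasts = contrasts, smoking_anova = smoking_anova)
}
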