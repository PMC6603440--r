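# Ratio-to-rest-of-grey-matter trajectories and peak-age inference.
#
# A region's ratio to the rest of grey matter (region / (total GM - region))
# rises while the region declines more slowly than the remaining grey matter
# and falls once its decline accelerates past it; the age of the peak marks
# that transition. Sex differences in peak age are tested by permuting sex
# labels within matched 1-year age bins and recomputing both curves (and
# their peaks) for every permutation.

#' Windowed ratio-to-rest-of-grey-matter curve
#'
#' Each participant's ratio `V / (GM - V)` (bilateral region volume over
#' rest of grey matter) is averaged within sliding age windows and smoothed.
#' Region and total grey matter are deconfounded with the same correction
#' set; rows where total grey matter does not exceed the region volume are
#' excluded with a warning.
#'
#' @inheritParams build_nomogram
#' @return a `ratio_curve`: age grid, smoothed and raw `ratio` curves,
#'   `sem`, `peak_bin` (age interval of the maximizing window, ties broken
#'   towards the youngest window), `peak_age` (its median age), and the
#'   participant-level ages/values used (for bootstrapping).
#' @export
ratio_curve <- function(cohort, region, sex,
                        correction = c("scan_date", "head_scaling"),
                        fraction = 0.10, step = 1L, kernel_sd = 20,
                        mad_cutoff = 5) {
  prep_r <- .hn_prepare_volume(cohort, region, sex, "bilateral",
                               correction, mad_cutoff)
  prep_g <- .hn_prepare_volume(cohort, "total_grey_matter", sex,
                               "average", correction, mad_cutoff)
  v <- prep_r$volume
  g <- prep_g$volume
  keep <- prep_r$include & prep_g$include
  nonpos <- keep & (g <= v)
  if (any(nonpos)) {
    warning(sum(nonpos),
            " row(s) with total grey matter <= region volume excluded",
            call. = FALSE)
    keep <- keep & !nonpos
  }
  ages <- prep_r$data$age[keep]
  ratio <- v[keep] / (g[keep] - v[keep])
  out <- .hn_ratio_curve_core(ages, ratio, fraction, step, kernel_sd)
  out$region <- region
  out$sex <- .hn_match_sex(sex)
  out$correction <- correction
  class(out) <- "ratio_curve"
  out
}

# Curve construction from bare (age, value) pairs; shared with the
# permutation test, which rebuilds curves thousands of times.
.hn_ratio_curve_core <- function(ages, values, fraction, step, kernel_sd) {
  windows <- build_windows(ages, fraction = fraction, step = step)
  raw <- window_statistic(values, windows, "mean")
  sm <- smooth_curve(raw, kernel_sd)
  peak <- .hn_peak_index(sm)
  list(age = windows$median_age, ratio = sm, ratio_raw = raw,
       sem = window_statistic(values, windows, "sem"),
       peak_index = peak,
       peak_bin = c(windows$age_lo[peak], windows$age_hi[peak]),
       peak_age = windows$median_age[peak],
       fraction = fraction, step = step, kernel_sd = kernel_sd,
       ages = ages, values = values, windows = windows)
}

#' Numerical slope of a windowed curve, with bootstrap confidence band
#'
#' Central differences of the smoothed curve against the median-age grid
#' (one-sided at the ends). When `B > 0`, participants are resampled with
#' replacement, the curve is rebuilt, and pointwise percentile intervals of
#' the slope (interpolated back onto the original grid) are returned. The
#' window of most negative slope is the trajectory's inflection.
#'
#' @param curve a `ratio_curve`, or any list with numeric `age` and `ratio`
#'   (or `value`) entries on a non-decreasing age grid.
#' @param B number of bootstrap resamples (0 = no band). Bootstrapping
#'   requires the participant-level data stored in a `ratio_curve`.
#' @param level confidence level for the pointwise band.
#' @param seed optional seed for the resampling.
#' @return list with `age`, `slope`, optional `lower`/`upper`,
#'   `max_slope_bin` (age interval of the most negative slope) and
#'   `max_slope`.
#' @export
numerical_slope <- function(curve, B = 0, level = 0.95, seed = NULL) {
  x <- curve$age
  y <- curve$ratio %||% curve$value
  if (is.null(x) || is.null(y)) {
    stop("`curve` must provide `age` and `ratio` (or `value`)",
         call. = FALSE)
  }
  if (length(x) < 3) stop("need at least 3 grid points", call. = FALSE)
  if (any(diff(x) < 0)) stop("age grid must be non-decreasing", call. = FALSE)
  # collapse duplicated grid ages (tied window medians) before differencing
  if (anyDuplicated(x)) {
    y <- as.numeric(tapply(y, x, mean))
    x <- sort(unique(x))
    if (length(x) < 3) stop("fewer than 3 distinct grid ages", call. = FALSE)
  }
  slope <- .hn_central_diff(x, y)
  out <- list(age = x, slope = slope)
  if (B > 0) {
    if (is.null(curve$ages) || is.null(curve$values)) {
      stop("bootstrap requires participant-level data in the curve object",
           call. = FALSE)
    }
    if (!is.null(seed)) set.seed(seed)
    n <- length(curve$ages)
    boot <- matrix(NA_real_, nrow = B, ncol = length(x))
    for (b in seq_len(B)) {
      idx <- sample.int(n, n, replace = TRUE)
      cb <- .hn_ratio_curve_core(curve$ages[idx], curve$values[idx],
                                 curve$fraction, curve$step,
                                 curve$kernel_sd)
      xb <- cb$age
      yb <- cb$ratio
      if (anyDuplicated(xb)) {
        yb <- as.numeric(tapply(yb, xb, mean))
        xb <- sort(unique(xb))
      }
      sb <- .hn_central_diff(xb, yb)
      boot[b, ] <- stats::approx(xb, sb, xout = x, rule = 2, ties = mean)$y
    }
    alpha <- (1 - level) / 2
    out$lower <- apply(boot, 2, stats::quantile, probs = alpha, names = FALSE)
    out$upper <- apply(boot, 2, stats::quantile, probs = 1 - alpha,
                       names = FALSE)
  }
  i <- which.min(out$slope)
  out$max_slope <- out$slope[i]
  out$max_slope_bin <- c(x[max(1, i - 1)], x[min(length(x), i + 1)])
  out
}

.hn_central_diff <- function(x, y) {
  n <- length(x)
  slope <- numeric(n)
  slope[1] <- (y[2] - y[1]) / (x[2] - x[1])
  slope[n] <- (y[n] - y[n - 1]) / (x[n] - x[n - 1])
  if (n > 2) {
    i <- 2:(n - 1)
    slope[i] <- (y[i + 1] - y[i - 1]) / (x[i + 1] - x[i - 1])
  }
  slope
}

#' Permutation test for sex differences in peak-ratio age
#'
#' The observed statistic is the male minus female peak-ratio age for each
#' region. The null distribution is built by shuffling sex labels within
#' matched 1-year age bins (so the age composition of both groups is
#' preserved exactly), recomputing both smoothed ratio curves and their
#' peaks for every permutation. The two-sided p-value uses the add-one
#' convention `p = (1 + #{|null| >= |observed|}) / (n_perm + 1)` (set
#' `add_one = FALSE` for the raw proportion). Across regions, p-values are
#' adjusted for false discovery rate (Benjamini-Hochberg).
#'
#' @inheritParams ratio_curve
#' @param regions character vector of regions to test.
#' @param n_permutations number of label permutations (must be >= 1).
#' @param bin_width width (years) of the age-matching bins.
#' @param seed seed for the permutation stream.
#' @param add_one use the add-one p-value convention.
#' @return a `peak_permutation_test`: data frame `results` with
#'   `observed_diff_years`, `p`, `p_fdr`, per-region peak ages, plus the
#'   null distributions.
#' @export
permutation_peak_test <- function(cohort, regions = "hippocampus",
                                  n_permutations = 5000,
                                  correction = c("scan_date",
                                                 "head_scaling"),
                                  fraction = 0.10, step = 1L,
                                  kernel_sd = 20, bin_width = 1,
                                  mad_cutoff = 5,
                                  seed = NULL, add_one = TRUE) {
  .hn_assert_cohort(cohort)
  if (length(n_permutations) != 1 || n_permutations < 1) {
    stop("`n_permutations` must be >= 1 (p-value undefined otherwise)",
         call. = FALSE)
  }
  if (!all(cohort$sex %in% c("female", "male")) ||
      length(unique(cohort$sex)) < 2) {
    stop("both sexes must be present", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  res <- vector("list", length(regions))
  nulls <- vector("list", length(regions))
  names(nulls) <- regions
  for (ri in seq_along(regions)) {
    region <- regions[[ri]]
    # Deconfounding is fitted on the pooled cohort so that ratio values are
    # exchangeable across sex under the null.
    rows <- which(!cohort$excluded_selfreport)
    sub <- cohort[rows, , drop = FALSE]
    v <- cohort_volume(sub, region, "bilateral")
    g <- cohort_volume(sub, "total_grey_matter")
    mask_v <- suppressWarnings(mad_filter(v, cutoff = mad_cutoff))
    mask_g <- suppressWarnings(mad_filter(g, cutoff = mad_cutoff))
    include <- !mask_v$excluded & !mask_g$excluded
    if (length(correction) > 0) {
      mod_v <- fit_confound_model(sub, region, correction,
                                  hemisphere = "bilateral",
                                  include = include)
      mod_g <- fit_confound_model(sub, "total_grey_matter", correction,
                                  include = include)
      v <- apply_deconfound(v, mod_v, sub)
      g <- apply_deconfound(g, mod_g, sub)
    }
    keep <- include & (g > v)
    ages <- sub$age[keep]
    ratio <- v[keep] / (g[keep] - v[keep])
    sexes <- sub$sex[keep]

    # global age sort once; subsetting preserves order
    ord <- order(ages)
    ages <- ages[ord]; ratio <- ratio[ord]; sexes <- sexes[ord]
    bins <- floor(ages / bin_width)

    peak_of <- function(is_f) {
      pf <- .hn_fast_peak(ages[is_f], ratio[is_f], fraction, step, kernel_sd)
      pm <- .hn_fast_peak(ages[!is_f], ratio[!is_f], fraction, step,
                          kernel_sd)
      c(female = pf, male = pm)
    }
    obs <- peak_of(sexes == "female")
    observed_diff <- unname(obs["male"] - obs["female"])

    is_f <- sexes == "female"
    bin_ids <- split(seq_along(bins), bins)
    null_diffs <- numeric(n_permutations)
    for (b in seq_len(n_permutations)) {
      perm_f <- is_f
      for (ids in bin_ids) {
        if (length(ids) > 1) perm_f[ids] <- sample(is_f[ids])
      }
      if (!any(perm_f) || all(perm_f)) {
        # cannot happen under within-bin label shuffling unless a sex is
        # globally absent; guarded above
        null_diffs[b] <- NA_real_
        next
      }
      pk <- peak_of(perm_f)
      null_diffs[b] <- unname(pk["male"] - pk["female"])
    }
    null_diffs <- null_diffs[!is.na(null_diffs)]
    hits <- sum(abs(null_diffs) >= abs(observed_diff))
    p <- if (add_one) (1 + hits) / (length(null_diffs) + 1) else
      hits / length(null_diffs)
    res[[ri]] <- data.frame(
      region = region,
      peak_age_female = unname(obs["female"]),
      peak_age_male = unname(obs["male"]),
      observed_diff_years = observed_diff,
      p = p, n_perm = length(null_diffs)
    )
    nulls[[region]] <- null_diffs
  }
  results <- do.call(rbind, res)
  results$p_fdr <- stats::p.adjust(results$p, method = "BH")
  out <- list(results = results, null_diffs = nulls, seed = seed,
              add_one = add_one, fraction = fraction,
              kernel_sd = kernel_sd, bin_width = bin_width)
  class(out) <- "peak_permutation_test"
  out
}

# Index of the curve maximum; numerical near-ties (within a relative
# 1e-9 band) resolve to the youngest window.
.hn_peak_index <- function(sm) {
  mx <- max(sm)
  tol <- 1e-9 * max(abs(mx), 1e-12)
  min(which(sm >= mx - tol))
}

# Fast peak-age of a windowed mean curve for age-sorted inputs.
.hn_fast_peak <- function(ages, values, fraction, step, kernel_sd) {
  n <- length(ages)
  m <- ceiling(fraction * n)
  if (m < 1 || n < m) return(NA_real_)
  s <- seq.int(1L, n - m + 1L, by = as.integer(step))
  cs <- c(0, cumsum(values))
  raw <- (cs[s + m] - cs[s]) / m
  sm <- if (length(raw) >= 2) smooth_curve(raw, kernel_sd) else raw
  peak <- .hn_peak_index(sm)
  lo <- ages[s[peak] + (m - 1L) %/% 2L]
  hi <- ages[s[peak] + m %/% 2L]
  (lo + hi) / 2
}
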