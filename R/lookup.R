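# Percentile lookup against a nomogram: the core of a clinical chart
# reader. Given age and volume, the percentile is read off the quantile
# curves; outside the outermost curves the answer is censored ("<2.5",
# ">97.5") rather than extrapolated into unestimated tails.

#' Look up the percentile of a volume on a nomogram
#'
#' The quantile curves are interpolated linearly between the two age-grid
#' columns flanking the query age (set `age_method = "nearest"` for the
#' nearest-window alternative); the percentile is then obtained by linear
#' interpolation in volume between the flanking quantile levels. Ages
#' outside the smoothed grid clamp to the nearest edge and the result is
#' flagged `extrapolated`. Volumes below the 2.5th or above the 97.5th
#' curve are censored.
#'
#' When the nomogram was built on head-size-corrected volumes, an
#' uncorrected query volume must be corrected first: pass `head_scaling`
#' and `apply_head_correction = TRUE` to apply
#' `volume - b * (head_scaling - reference)` with the nomogram's own fitted
#' head-scaling slope. Requesting head correction against a nomogram that
#' was not head-size corrected is an error, never silent.
#'
#' @param nomogram a `nomogram` (built or read from file).
#' @param age query age(s) in years.
#' @param volume query volume(s), in mm^3 by default.
#' @param unit `"mm3"` or `"cm3"` (cm^3 inputs are converted by 1000).
#' @param head_scaling optional head-scaling factor(s) for correction.
#' @param apply_head_correction apply the head-size correction to `volume`
#'   before lookup.
#' @param age_method `"interpolate"` (default) or `"nearest"`.
#' @return data frame with `age`, `volume` (mm^3, as used), `percentile`
#'   (numeric, `NA` when censored), `label` (e.g. `"37.2"`, `"<2.5"`,
#'   `">97.5"`), `extrapolated`.
#' @export
lookup_percentile <- function(nomogram, age, volume,
                              unit = c("mm3", "cm3"),
                              head_scaling = NULL,
                              apply_head_correction = FALSE,
                              age_method = c("interpolate", "nearest")) {
  stopifnot(inherits(nomogram, "nomogram"))
  unit <- match.arg(unit)
  age_method <- match.arg(age_method)
  if (any(volume <= 0)) stop("`volume` must be > 0", call. = FALSE)
  if (unit == "cm3") volume <- volume * 1000
  head_corrected_nomogram <- "head_scaling" %in% nomogram$correction
  if (apply_head_correction) {
    if (!head_corrected_nomogram) {
      stop("head-size correction requested against a nomogram that was ",
           "not built on head-size-corrected volumes", call. = FALSE)
    }
    if (is.null(head_scaling)) {
      stop("`head_scaling` is required for head-size correction",
           call. = FALSE)
    }
    if (is.null(nomogram$model)) {
      stop("this nomogram carries no fitted head-scaling slope; correct ",
           "the volume externally", call. = FALSE)
    }
    b <- nomogram$model$slopes[["head_scaling"]]
    ref <- nomogram$model$reference[["head_scaling"]]
    volume <- volume - b * (head_scaling - ref)
  }
  k <- max(length(age), length(volume))
  age <- rep_len(age, k)
  volume <- rep_len(volume, k)
  grid <- nomogram$age
  levels <- nomogram$levels
  curves <- nomogram$curves
  out <- data.frame(age = age, volume = volume,
                    percentile = NA_real_, label = NA_character_,
                    extrapolated = FALSE)
  for (i in seq_len(k)) {
    a <- age[i]
    extrap <- a < grid[1] || a > grid[length(grid)]
    a_cl <- min(max(a, grid[1]), grid[length(grid)])
    vals <- if (age_method == "nearest") {
      curves[, which.min(abs(grid - a_cl))]
    } else {
      apply(curves, 1, function(cv) {
        stats::approx(grid, cv, xout = a_cl, rule = 2, ties = mean)$y
      })
    }
    v <- volume[i]
    if (v < vals[1]) {
      out$label[i] <- paste0("<", levels[1])
    } else if (v > vals[length(vals)]) {
      out$label[i] <- paste0(">", levels[length(levels)])
    } else {
      j <- findInterval(v, vals, rightmost.closed = TRUE)
      j <- min(max(j, 1L), length(vals) - 1L)
      span <- vals[j + 1] - vals[j]
      frac <- if (span <= 0) 0 else (v - vals[j]) / span
      p <- levels[j] + frac * (levels[j + 1] - levels[j])
      out$percentile[i] <- p
      out$label[i] <- formatC(p, digits = 1, format = "f")
    }
    out$extrapolated[i] <- extrap
  }
  out
}

#' Audit nomogram calibration with held-out participants
#'
#' Looks up the percentile of every held-out participant's own volume
#' against the nomogram (after applying the nomogram's fitted confound
#' model to their raw volumes) and compares the non-censored percentiles to
#' the uniform distribution they should follow when the nomogram is
#' calibrated: interior values against Uniform(2.5, 97.5) by a
#' Kolmogorov-Smirnov test, with the censored tail counts reported
#' alongside.
#'
#' @param cohort held-out cohort table drawn from the nomogram's
#'   population (same sex as the nomogram is used; self-report exclusions
#'   and per-region outliers are dropped).
#' @param nomogram a `nomogram` with its fitted deconfound model.
#' @param mad_cutoff outlier threshold applied to the held-out volumes.
#' @return list with `percentiles` (numeric, `NA` when censored),
#'   `n`, `n_below`, `n_above`, and `ks` (`statistic`, `p`).
#' @export
self_percentile_audit <- function(cohort, nomogram, mad_cutoff = 5) {
  .hn_assert_cohort(cohort)
  stopifnot(inherits(nomogram, "nomogram"))
  rows <- which(cohort$sex == nomogram$sex & !cohort$excluded_selfreport)
  if (length(rows) == 0) stop("empty held-out set", call. = FALSE)
  sub <- cohort[rows, , drop = FALSE]
  v <- cohort_volume(sub, nomogram$region, nomogram$hemisphere)
  mask <- suppressWarnings(mad_filter(v, cutoff = mad_cutoff))
  sub <- sub[!mask$excluded, , drop = FALSE]
  v <- v[!mask$excluded]
  if (!is.null(nomogram$model)) {
    v <- apply_deconfound(v, nomogram$model, sub)
  }
  res <- lookup_percentile(nomogram, sub$age, v)
  pct <- res$percentile
  lo <- nomogram$levels[1]
  hi <- nomogram$levels[length(nomogram$levels)]
  n_below <- sum(grepl("^<", res$label))
  n_above <- sum(grepl("^>", res$label))
  interior <- pct[!is.na(pct)]
  ks <- suppressWarnings(stats::ks.test(interior, "punif", lo, hi))
  list(percentiles = pct, n = nrow(res), n_below = n_below,
       n_above = n_above,
       ks = list(statistic = unname(ks$statistic), p = ks$p.value))
}
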