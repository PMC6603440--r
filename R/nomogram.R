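# Sliding-window quantile nomograms.
#
# The nomogram is model-free: observations are sorted by age, overlapping
# windows each holding a fixed fraction of participants (default 10%) slide
# one observation at a time, the statistic of interest (mean, SEM, or a set
# of quantiles) is computed inside each window, and the resulting curves are
# smoothed with a Gaussian moving average along the window sequence. The
# x-coordinate of a window is the median age of its members, so age coverage
# contracts near the limits where windows must reach across sparse tails.

#' Build overlapping fixed-quantile-width age windows
#'
#' @param ages numeric vector of ages (years).
#' @param fraction proportion of participants per window, in (0, 1\].
#' @param step number of (age-sorted) observations the window advances
#'   between positions.
#' @return a `sliding_windows` object: the age sort order, window `starts`,
#'   window `size`, and per-window `median_age`, `age_lo`, `age_hi`.
#' @export
build_windows <- function(ages, fraction = 0.10, step = 1L) {
  if (length(fraction) != 1 || is.na(fraction) || fraction <= 0 ||
      fraction > 1) {
    stop("`fraction` must lie in (0, 1]", call. = FALSE)
  }
  n <- length(ages)
  if (n < 10 / fraction) {
    stop("need at least ", ceiling(10 / fraction),
         " observations for fraction = ", fraction, call. = FALSE)
  }
  ord <- order(ages)
  sorted <- ages[ord]
  m <- ceiling(fraction * n)
  starts <- seq.int(1L, n - m + 1L, by = as.integer(step))
  # median of a sorted slice is an order statistic: O(1) per window
  lo_idx <- starts + (m - 1L) %/% 2L
  hi_idx <- starts + m %/% 2L
  median_age <- (sorted[lo_idx] + sorted[hi_idx]) / 2
  out <- list(order = ord, starts = starts, size = m, step = step, n = n,
              fraction = fraction,
              median_age = median_age,
              age_lo = sorted[starts], age_hi = sorted[starts + m - 1L],
              ages_sorted = sorted)
  class(out) <- "sliding_windows"
  out
}

#' Compute a statistic within each sliding window
#'
#' @param values numeric vector aligned with the `ages` used to build
#'   `windows`.
#' @param windows a `sliding_windows` object.
#' @param statistic `"mean"`, `"sem"`, or `"quantile"`.
#' @param level quantile level(s) in percent (required for
#'   `statistic = "quantile"`); quantiles use linear interpolation between
#'   order statistics (type 7).
#' @return for `"mean"`/`"sem"`, a numeric vector (one value per window;
#'   SEM is `NA` for windows of fewer than 2 members); for `"quantile"`, a
#'   matrix with one row per level.
#' @export
window_statistic <- function(values, windows,
                             statistic = c("mean", "sem", "quantile"),
                             level = NULL) {
  stopifnot(inherits(windows, "sliding_windows"))
  statistic <- match.arg(statistic)
  if (length(values) != windows$n) {
    stop("`values` must have one entry per observation used for the windows",
         call. = FALSE)
  }
  v <- values[windows$order]
  m <- windows$size
  s <- windows$starts
  if (statistic == "mean") {
    cs <- c(0, cumsum(v))
    return((cs[s + m] - cs[s]) / m)
  }
  if (statistic == "sem") {
    if (m < 2) {
      warning("windows of fewer than 2 members: SEM undefined",
              call. = FALSE)
      return(rep(NA_real_, length(s)))
    }
    cs <- c(0, cumsum(v))
    cs2 <- c(0, cumsum(v^2))
    mu <- (cs[s + m] - cs[s]) / m
    ss <- (cs2[s + m] - cs2[s]) - m * mu^2
    sd_w <- sqrt(pmax(0, ss) / (m - 1))
    return(sd_w / sqrt(m))
  }
  if (is.null(level)) {
    stop("`level` (percent) is required for statistic = \"quantile\"",
         call. = FALSE)
  }
  probs <- level / 100
  out <- vapply(s, function(si) {
    stats::quantile(v[si:(si + m - 1L)], probs = probs, names = FALSE,
                    type = 7)
  }, numeric(length(probs)))
  if (length(probs) == 1) matrix(out, nrow = 1) else out
}

#' Smooth a curve with a Gaussian moving average
#'
#' Convolution with Gaussian weights of standard deviation `kernel_sd`
#' expressed in grid steps, truncated at 3 SD and renormalised where the
#' support is clipped at the boundaries (no padding). Weights are positive
#' and shared across curves evaluated on the same grid, so pointwise
#' ordering of a family of curves is preserved.
#'
#' @param y numeric vector (a raw curve on an ordered grid).
#' @param kernel_sd kernel SD in grid steps; `0` is the identity.
#' @return smoothed numeric vector of the same length.
#' @export
smooth_curve <- function(y, kernel_sd = 20) {
  if (kernel_sd < 0) stop("`kernel_sd` must be >= 0", call. = FALSE)
  if (kernel_sd == 0) return(y)
  n <- length(y)
  if (n < 2) stop("need at least 2 grid points", call. = FALSE)
  h <- ceiling(3 * kernel_sd)
  num <- numeric(n)
  den <- numeric(n)
  idx <- seq_len(n)
  for (j in -h:h) {
    w <- exp(-0.5 * (j / kernel_sd)^2)
    src <- idx + j
    ok <- src >= 1L & src <= n
    num[ok] <- num[ok] + w * y[src[ok]]
    den[ok] <- den[ok] + w
  }
  num / den
}

#' Build a sex-specific quantile nomogram for one region
#'
#' Full construction: subset to one sex, drop self-report exclusions, flag
#' outliers on the raw volume (MAD distance > `mad_cutoff`), regress out the
#' requested confounds, slide fixed-quantile-width age windows, compute the
#' nine quantile levels plus mean and SEM in each window, and smooth each
#' curve along the window sequence.
#'
#' @inheritParams build_windows
#' @param cohort a cohort table.
#' @param region,hemisphere see [cohort_volume()].
#' @param sex `"female"` or `"male"`.
#' @param correction confound set regressed out; the published tables use
#'   `c("scan_date", "head_scaling")`.
#' @param kernel_sd Gaussian smoothing SD in window steps (default 20).
#' @param levels quantile levels in percent.
#' @param mad_cutoff MAD-distance exclusion threshold.
#' @return a `nomogram` object with the age grid (window median ages),
#'   smoothed and raw quantile `curves` (level x age), `mean`, `sem`,
#'   per-window counts, the fitted deconfound model and grand mean.
#' @export
build_nomogram <- function(cohort, region, sex,
                           hemisphere = "left",
                           correction = c("scan_date", "head_scaling"),
                           fraction = 0.10, step = 1L, kernel_sd = 20,
                           levels = c(2.5, 5, 10, 25, 50, 75, 90, 95, 97.5),
                           mad_cutoff = 5) {
  prep <- .hn_prepare_volume(cohort, region, sex, hemisphere,
                             correction, mad_cutoff)
  keep <- prep$include
  ages <- prep$data$age[keep]
  vols <- prep$volume[keep]
  windows <- build_windows(ages, fraction = fraction, step = step)
  raw <- window_statistic(vols, windows, "quantile", level = levels)
  rownames(raw) <- paste0("q", levels)
  smoothed <- t(apply(raw, 1, smooth_curve, kernel_sd = kernel_sd))
  mean_raw <- window_statistic(vols, windows, "mean")
  sem_raw <- window_statistic(vols, windows, "sem")
  n_window <- rep(windows$size, length(windows$starts))
  out <- list(
    region = region, hemisphere = prep$model$hemisphere %||% hemisphere,
    sex = .hn_match_sex(sex), correction = correction,
    levels = levels, age = windows$median_age,
    curves = smoothed, curves_raw = raw,
    mean = smooth_curve(mean_raw, kernel_sd), mean_raw = mean_raw,
    sem = sem_raw, n_window = n_window,
    fraction = fraction, step = step, kernel_sd = kernel_sd,
    grand_mean = mean(vols), n = length(vols),
    model = prep$model, windows = windows, ages = ages, volumes = vols
  )
  class(out) <- "nomogram"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Age-adjusted percentile table
#'
#' Removes the age trend by taking residuals from the sliding-window mean
#' curve (linearly interpolated at each participant's age) and adding them
#' back onto the grand mean of the volume estimations; the table is then the
#' set of empirical percentiles of these age-adjusted values.
#'
#' @inheritParams build_nomogram
#' @param nomogram optionally, a prebuilt `nomogram` for the same region,
#'   sex and correction set (avoids recomputation).
#' @param use_smoothed interpolate residuals against the smoothed rather
#'   than the raw mean curve.
#' @return list with `table` (named percentile -> volume), the
#'   `adjusted` values, and `flagged` (indices whose age fell outside the
#'   window grid and used the nearest edge value).
#' @export
age_adjusted_percentiles <- function(cohort, region, sex,
                                     hemisphere = "left",
                                     correction = c("scan_date",
                                                    "head_scaling"),
                                     fraction = 0.10, step = 1L,
                                     kernel_sd = 20,
                                     levels = c(2.5, 5, 10, 25, 50, 75, 90,
                                                95, 97.5),
                                     mad_cutoff = 5,
                                     nomogram = NULL,
                                     use_smoothed = FALSE) {
  if (is.null(nomogram)) {
    nomogram <- build_nomogram(cohort, region, sex, hemisphere, correction,
                               fraction, step, kernel_sd, levels, mad_cutoff)
  }
  ages <- nomogram$ages
  vols <- nomogram$volumes
  curve <- if (use_smoothed) nomogram$mean else nomogram$mean_raw
  fit <- stats::approx(nomogram$age, curve, xout = ages, rule = 2,
                       ties = mean)$y
  flagged <- which(ages < min(nomogram$age) | ages > max(nomogram$age))
  adjusted <- (vols - fit) + nomogram$grand_mean
  tab <- stats::quantile(adjusted, probs = nomogram$levels / 100, type = 7)
  names(tab) <- paste0("q", nomogram$levels)
  list(table = tab, adjusted = adjusted, flagged = flagged)
}

#' Mean/SEM curves over fixed-width age bins
#'
#' Non-overlapping half-open bins `[a, a + width)`; each observation falls
#' in exactly one bin. A robustness cross-check for the sliding-window
#' curves.
#'
#' @inheritParams build_nomogram
#' @param bin_width bin width in years (default 5).
#' @return data frame with `bin_start`, `age` (mean age of members), `mean`,
#'   `sem`, `n`; empty bins are omitted with a warning.
#' @export
fixed_bin_curves <- function(cohort, region, sex,
                             hemisphere = "left",
                             correction = c("scan_date", "head_scaling"),
                             bin_width = 5, mad_cutoff = 5) {
  prep <- .hn_prepare_volume(cohort, region, sex, hemisphere,
                             correction, mad_cutoff)
  keep <- prep$include
  ages <- prep$data$age[keep]
  vols <- prep$volume[keep]
  start <- floor(min(ages))
  breaks <- seq(start, max(ages) + bin_width, by = bin_width)
  bin <- findInterval(ages, breaks, rightmost.closed = FALSE)
  all_bins <- seq_len(length(breaks) - 1)
  counts <- tabulate(bin, nbins = length(all_bins))
  if (any(counts == 0)) {
    warning("omitting ", sum(counts == 0), " empty age bin(s)",
            call. = FALSE)
  }
  keep_bins <- which(counts > 0)
  out <- data.frame(
    bin_start = breaks[keep_bins],
    age = vapply(keep_bins, function(b) mean(ages[bin == b]), 0),
    mean = vapply(keep_bins, function(b) mean(vols[bin == b]), 0),
    sem = vapply(keep_bins, function(b) {
      x <- vols[bin == b]
      if (length(x) < 2) NA_real_ else stats::sd(x) / sqrt(length(x))
    }, 0),
    n = counts[keep_bins]
  )
  out
}

#' Write a nomogram to CSV
#'
#' Metadata (region, sex, correction set, window fraction, kernel, n) is
#' stored as leading `#`-prefixed comment lines, followed by a table with
#' columns `age, n, mean, sem, q<level>...` (smoothed quantile curves).
#'
#' @param nomogram a `nomogram`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_nomogram <- function(nomogram, path) {
  stopifnot(inherits(nomogram, "nomogram"))
  meta <- c(
    paste0("# region: ", nomogram$region),
    paste0("# hemisphere: ", nomogram$hemisphere),
    paste0("# sex: ", nomogram$sex),
    paste0("# correction: ", paste(nomogram$correction, collapse = "+")),
    paste0("# fraction: ", nomogram$fraction),
    paste0("# kernel_sd: ", nomogram$kernel_sd),
    paste0("# n: ", nomogram$n),
    paste0("# grand_mean: ", format(nomogram$grand_mean, digits = 15))
  )
  tab <- data.frame(age = nomogram$age, n = nomogram$n_window,
                    mean = nomogram$mean, sem = nomogram$sem)
  qt <- as.data.frame(t(nomogram$curves))
  names(qt) <- rownames(nomogram$curves)
  tab <- cbind(tab, qt)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(meta, con)
  utils::write.csv(tab, con, row.names = FALSE)
  invisible(path)
}

#' Read a nomogram written by [write_nomogram()]
#'
#' The returned object supports [lookup_percentile()] (curves, levels, age
#' grid and metadata are restored; participant-level vectors are not).
#'
#' @param path file path.
#' @return a `nomogram` object.
#' @export
read_nomogram <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ml in meta_lines) {
    kv <- sub("^#\\s*", "", ml)
    key <- sub(":.*$", "", kv)
    val <- trimws(sub("^[^:]*:", "", kv))
    meta[[key]] <- val
  }
  tab <- utils::read.csv(textConnection(lines[!grepl("^#", lines)]))
  qcols <- grep("^q", names(tab), value = TRUE)
  levels <- as.numeric(sub("^q", "", qcols))
  curves <- t(as.matrix(tab[, qcols, drop = FALSE]))
  rownames(curves) <- qcols
  out <- list(
    region = meta$region, hemisphere = meta$hemisphere, sex = meta$sex,
    correction = strsplit(meta$correction %||% "", "\\+")[[1]],
    levels = levels, age = tab$age, curves = curves,
    mean = tab$mean, sem = tab$sem, n_window = tab$n,
    fraction = as.numeric(meta$fraction),
    kernel_sd = as.numeric(meta$kernel_sd),
    grand_mean = as.numeric(meta$grand_mean),
    n = as.numeric(meta$n), model = NULL
  )
  class(out) <- "nomogram"
  out
}
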