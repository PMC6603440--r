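# Joinpoint (piecewise-linear change-point) regression on 1-year binned
# mean trajectories.
#
# Segments are constrained to meet continuously at the joinpoints (hinge
# basis); candidate joinpoints sit on the data grid and are found by
# exhaustive search. The number of joinpoints is selected sequentially
# (k vs k+1) with a Monte Carlo permutation test on the residuals of the
# smaller model, assuming uncorrelated errors, with a Bonferroni adjustment
# over the selection ladder. Grid-search constraints: at least seven data
# points per joinpoint, no joinpoint within two data points of either end,
# and at least two data points between consecutive joinpoints.

#' Bin a cohort into 1-year mean-volume series
#'
#' Mean deconfounded volume per non-overlapping age bin `[a, a + 1)`.
#'
#' @inheritParams build_nomogram
#' @return a `binned_series` data frame: `bin_start`, `bin_mid`,
#'   `mean_volume`, `n`. Empty bins are dropped with a warning.
#' @export
bin_series <- function(cohort, region, sex,
                       hemisphere = "bilateral",
                       correction = c("scan_date", "head_scaling"),
                       mad_cutoff = 5) {
  prep <- .hn_prepare_volume(cohort, region, sex, hemisphere,
                             correction, mad_cutoff)
  keep <- prep$include
  ages <- prep$data$age[keep]
  vols <- prep$volume[keep]
  bin <- floor(ages)
  rng <- seq(min(bin), max(bin))
  counts <- vapply(rng, function(b) sum(bin == b), 0L)
  if (any(counts == 0)) {
    warning("dropping ", sum(counts == 0), " empty 1-year bin(s)",
            call. = FALSE)
  }
  keep_bins <- rng[counts > 0]
  out <- data.frame(
    bin_start = keep_bins,
    bin_mid = keep_bins + 0.5,
    mean_volume = vapply(keep_bins, function(b) mean(vols[bin == b]), 0),
    n = counts[counts > 0]
  )
  class(out) <- c("binned_series", "data.frame")
  out
}

#' Construct a binned series directly
#'
#' @param bin_start integer bin lower edges (years); bins are
#'   `[a, a + 1)`.
#' @param mean_volume mean volume per bin (mm^3).
#' @param n number of observations per bin.
#' @return a `binned_series` data frame.
#' @export
binned_series <- function(bin_start, mean_volume, n = 1L) {
  stopifnot(length(bin_start) == length(mean_volume))
  out <- data.frame(bin_start = bin_start, bin_mid = bin_start + 0.5,
                    mean_volume = mean_volume,
                    n = rep_len(n, length(bin_start)))
  class(out) <- c("binned_series", "data.frame")
  out
}

# Admissible joinpoint index sets for a series of length n: interior
# indices 3..(n-2) with at least two data points between consecutive
# joinpoints (index gap >= 3).
.hn_jp_candidates <- function(n) {
  if (n < 5) return(integer(0))
  3:(n - 2)
}

.hn_jp_combinations <- function(n, k) {
  cand <- .hn_jp_candidates(n)
  if (k == 0) return(matrix(integer(0), nrow = 0, ncol = 0))
  if (length(cand) < k) return(NULL)
  cmb <- utils::combn(cand, k)
  if (k > 1) {
    ok <- apply(cmb, 2, function(ix) all(diff(ix) >= 3))
    cmb <- cmb[, ok, drop = FALSE]
  }
  if (ncol(cmb) == 0) NULL else cmb
}

.hn_jp_design <- function(x, tau) {
  X <- cbind(1, x)
  for (t in tau) X <- cbind(X, pmax(x - t, 0))
  X
}

.hn_jp_rss <- function(X, y, w = NULL) {
  if (!is.null(w)) {
    sw <- sqrt(w)
    fit <- stats::lm.fit(X * sw, y * sw)
  } else {
    fit <- stats::lm.fit(X, y)
  }
  sum(fit$residuals^2)
}

#' Fit a continuous piecewise-linear model with exactly k joinpoints
#'
#' Exhaustive grid search over all admissible joinpoint placements on the
#' bin grid; for each placement an ordinary least-squares fit of the hinge
#' basis `1, x, (x - tau_1)+, ...` is evaluated and the placement with the
#' global minimum residual sum of squares is returned. Deterministic.
#'
#' @param series a `binned_series`.
#' @param k number of joinpoints (0 up to the maximum the series length
#'   allows).
#' @param weighted weight bins by their observation counts.
#' @return a `joinpoint_fit`: joinpoint indices/ages, coefficients, segment
#'   `slopes`, `slope_changes`, `fitted`, `residuals`, `rss`, residual `df`.
#' @export
fit_k_joinpoints <- function(series, k, weighted = FALSE) {
  stopifnot(inherits(series, "binned_series"))
  x <- series$bin_mid
  y <- series$mean_volume
  n <- length(x)
  w <- if (weighted) series$n else NULL
  if (k < 0) stop("`k` must be >= 0", call. = FALSE)
  if (k > 0) {
    cmb <- .hn_jp_combinations(n, k)
    if (is.null(cmb)) {
      stop("k = ", k, " joinpoints infeasible for ", n, " bins: ",
           "joinpoints must lie at least two data points from the ends ",
           "with at least two data points between consecutive joinpoints",
           call. = FALSE)
    }
  }
  best <- NULL
  if (k == 0) {
    X <- .hn_jp_design(x, numeric(0))
    rss <- .hn_jp_rss(X, y, w)
    best <- list(idx = integer(0), rss = rss)
  } else {
    best_rss <- Inf
    for (j in seq_len(ncol(cmb))) {
      tau <- x[cmb[, j]]
      rss <- .hn_jp_rss(.hn_jp_design(x, tau), y, w)
      if (rss < best_rss) {
        best_rss <- rss
        best <- list(idx = cmb[, j], rss = rss)
      }
    }
  }
  tau <- x[best$idx]
  X <- .hn_jp_design(x, tau)
  fit <- if (is.null(w)) stats::lm.fit(X, y) else {
    sw <- sqrt(w)
    f <- stats::lm.fit(X * sw, y * sw)
    f$residuals <- f$residuals / sw
    f$fitted.values <- y - f$residuals
    f
  }
  coefs <- fit$coefficients
  hinge <- if (k > 0) coefs[-(1:2)] else numeric(0)
  out <- list(
    k = k, tau_index = best$idx, tau = tau,
    joinpoint_bins = series$bin_start[best$idx],
    coef = coefs,
    slopes = cumsum(c(coefs[2], hinge)),
    slope_changes = unname(hinge),
    fitted = as.numeric(fit$fitted.values),
    residuals = as.numeric(fit$residuals),
    rss = best$rss,
    df = n - 2 * (k + 1),
    n = n, weighted = weighted
  )
  class(out) <- "joinpoint_fit"
  out
}

# RSS of the best k-joinpoint fit (grid search), for permutation refits.
.hn_best_rss <- function(x, y, k, w = NULL, cmb = NULL) {
  if (k == 0) return(.hn_jp_rss(.hn_jp_design(x, numeric(0)), y, w))
  if (is.null(cmb)) cmb <- .hn_jp_combinations(length(x), k)
  best <- Inf
  for (j in seq_len(ncol(cmb))) {
    rss <- .hn_jp_rss(.hn_jp_design(x, x[cmb[, j]]), y, w)
    if (rss < best) best <- rss
  }
  best
}

# Precomputed orthonormal projectors for every admissible placement of k
# joinpoints: the RSS of each placement for a new response is then
# ||y||^2 - ||Q'y||^2, one small matrix product for the whole grid. Used
# inside the permutation loops, where the design never changes.
.hn_jp_grid <- function(x, k, w = NULL) {
  n <- length(x)
  sw <- if (!is.null(w)) sqrt(w) else NULL
  if (k == 0) {
    cmb <- matrix(integer(0), nrow = 0, ncol = 1)
  } else {
    cmb <- .hn_jp_combinations(n, k)
    if (is.null(cmb)) return(NULL)
  }
  p <- k + 2
  qts <- vector("list", ncol(cmb))
  for (j in seq_len(ncol(cmb))) {
    X <- .hn_jp_design(x, x[cmb[, j]])
    if (!is.null(sw)) X <- X * sw
    qts[[j]] <- t(qr.Q(qr(X)))
  }
  list(cmb = cmb, Qt = do.call(rbind, qts), p = p, sw = sw)
}

.hn_grid_best_rss <- function(grid, y) {
  if (!is.null(grid$sw)) y <- y * grid$sw
  qty <- grid$Qt %*% y
  min(sum(y^2) - colSums(matrix(qty^2, nrow = grid$p)))
}

#' Select the number of joinpoints by Monte Carlo permutation
#'
#' Starting from zero joinpoints, tests k vs k+1 sequentially: the observed
#' statistic is the residual-sum-of-squares ratio `RSS(k) / RSS(k+1)`; its
#' null distribution is obtained by permuting the residuals of the
#' k-joinpoint fit, adding them back onto its fitted values, and refitting
#' both models (full grid search) on each permuted series. The ladder stops
#' when the permutation p-value is not below `alpha / k_max` (Bonferroni
#' over the sequence of tests). The selected model is returned with slope
#' changes, their standard errors (conditional on the joinpoint positions),
#' t statistics on `n - 2(k+1)` degrees of freedom, and confidence
#' intervals for the joinpoint ages.
#'
#' @param series a `binned_series`.
#' @param k_max maximum joinpoints considered (default 4); additionally
#'   capped at one joinpoint per seven data points.
#' @param alpha overall significance level for the selection ladder.
#' @param n_perm Monte Carlo permutations per test (>= 19).
#' @param seed seed for the permutation stream.
#' @param weighted weight bins by observation counts.
#' @param ci_level confidence level for joinpoint age intervals.
#' @return a `joinpoint_model`.
#' @export
select_model <- function(series, k_max = 4, alpha = 0.05, n_perm = 999,
                         seed = NULL, weighted = FALSE, ci_level = 0.95) {
  stopifnot(inherits(series, "binned_series"))
  if (n_perm < 19) {
    stop("`n_perm` must be >= 19 to resolve alpha = 0.05", call. = FALSE)
  }
  x <- series$bin_mid
  y <- series$mean_volume
  n <- length(x)
  w <- if (weighted) series$n else NULL
  k_allow <- min(k_max, floor(n / 7))
  if (!is.null(seed)) set.seed(seed)

  p_perm <- numeric(0)
  k <- 0
  fit_k <- fit_k_joinpoints(series, 0, weighted)
  while (k < k_allow && alpha > 0) {
    grid_k1 <- .hn_jp_grid(x, k + 1, w)
    if (is.null(grid_k1)) break
    rss_k <- fit_k$rss
    if (rss_k <= .Machine$double.eps * sum(y^2)) break  # perfect fit
    grid_k <- .hn_jp_grid(x, k, w)
    rss_k1 <- .hn_grid_best_rss(grid_k1, y)
    t_obs <- rss_k / max(rss_k1, .Machine$double.xmin)
    hits <- 0L
    for (b in seq_len(n_perm)) {
      y_star <- fit_k$fitted + sample(fit_k$residuals)
      r_k <- .hn_grid_best_rss(grid_k, y_star)
      r_k1 <- .hn_grid_best_rss(grid_k1, y_star)
      t_b <- r_k / max(r_k1, .Machine$double.xmin)
      if (t_b >= t_obs) hits <- hits + 1L
    }
    p <- (1 + hits) / (n_perm + 1)
    p_perm <- c(p_perm, p)
    if (p < alpha / max(1, k_allow)) {
      k <- k + 1
      fit_k <- fit_k_joinpoints(series, k, weighted)
    } else {
      break
    }
  }

  fit <- fit_k
  # slope-change inference conditional on the selected joinpoint positions
  se <- t_stat <- p_t <- numeric(0)
  if (fit$k > 0) {
    X <- .hn_jp_design(x, fit$tau)
    df <- fit$df
    s2 <- fit$rss / max(df, 1)
    XtXi <- solve(crossprod(X))
    se_all <- sqrt(s2 * diag(XtXi))
    se <- unname(se_all[-(1:2)])
    t_stat <- fit$slope_changes / se
    p_t <- 2 * stats::pt(-abs(t_stat), df)
  }
  ci <- if (fit$k > 0) joinpoint_ci(series, fit, level = ci_level,
                                    weighted = weighted) else NULL
  out <- list(
    series = series, k = fit$k, fit = fit,
    joinpoint_bins = fit$joinpoint_bins,
    joinpoint_ages = fit$tau,
    ci = ci,
    segment_slopes = unname(fit$slopes),
    slope_changes = fit$slope_changes,
    slope_change_se = se,
    t = t_stat, p_t = p_t, df = fit$df,
    p_perm = p_perm, n_perm = n_perm, alpha = alpha,
    k_max = k_allow, seed = seed
  )
  class(out) <- "joinpoint_model"
  out
}

#' Confidence intervals for joinpoint ages
#'
#' For each joinpoint (others held at their estimates) every admissible
#' candidate position is refitted; a candidate is accepted when its
#' constrained fit is not rejected against the unconstrained optimum by an
#' F-comparison at `1 - level`. The interval spans the accepted bins. For a
#' noise-free series only the true bin is accepted and the interval
#' collapses to it.
#'
#' @param series a `binned_series`.
#' @param fit a `joinpoint_fit` (or `joinpoint_model`) with `k >= 1`.
#' @param level confidence level.
#' @param weighted weight bins by observation counts.
#' @return matrix (k x 2) of lower/upper joinpoint bin starts.
#' @export
joinpoint_ci <- function(series, fit, level = 0.95, weighted = FALSE) {
  if (inherits(fit, "joinpoint_model")) fit <- fit$fit
  stopifnot(inherits(fit, "joinpoint_fit"))
  if (fit$k < 1) stop("model has no joinpoints", call. = FALSE)
  x <- series$bin_mid
  y <- series$mean_volume
  n <- length(x)
  w <- if (weighted) series$n else NULL
  df <- fit$df
  rss_min <- fit$rss
  s2 <- rss_min / max(df, 1)
  fcrit <- stats::qf(level, 1, max(df, 1))
  cand <- .hn_jp_candidates(n)
  out <- matrix(NA_real_, nrow = fit$k, ncol = 2,
                dimnames = list(NULL, c("lower", "upper")))
  for (j in seq_len(fit$k)) {
    others <- fit$tau_index[-j]
    accepted <- integer(0)
    for (c_idx in cand) {
      idx <- sort(c(others, c_idx))
      if (anyDuplicated(idx) || (length(idx) > 1 && any(diff(idx) < 3))) next
      rss_c <- .hn_jp_rss(.hn_jp_design(x, x[idx]), y, w)
      ok <- if (rss_min <= 1e-12 * max(1, sum(y^2) / n)) {
        rss_c <= 1e-12 * max(1, sum(y^2) / n)
      } else {
        (rss_c - rss_min) / s2 <= fcrit
      }
      if (ok) accepted <- c(accepted, c_idx)
    }
    if (length(accepted) == 0) accepted <- fit$tau_index[j]
    if (length(accepted) == length(cand)) {
      warning("joinpoint ", j, ": all candidate bins accepted; ",
              "confidence interval spans the full admissible range",
              call. = FALSE)
    }
    out[j, ] <- c(series$bin_start[min(accepted)],
                  series$bin_start[max(accepted)])
  }
  out
}

#' Tabulate a joinpoint model
#'
#' One row per joinpoint, mirroring the usual report layout: joinpoint bin,
#' CI bounds, slope change, its SE, t statistic and p-value.
#'
#' @param x a `joinpoint_model`.
#' @param ... unused.
#' @return data frame.
#' @export
as.data.frame.joinpoint_model <- function(x, ...) {
  if (x$k == 0) {
    return(data.frame(joinpoint = NA_real_, ci_lower = NA_real_,
                      ci_upper = NA_real_, slope_change = NA_real_,
                      se = NA_real_, t = NA_real_, p = NA_real_,
                      df = x$df))
  }
  data.frame(
    joinpoint = x$joinpoint_bins,
    ci_lower = x$ci[, "lower"],
    ci_upper = x$ci[, "upper"],
    slope_change = x$slope_changes,
    se = x$slope_change_se,
    t = x$t, p = x$p_t, df = x$df
  )
}
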