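# Piecewise-linear joinpoint regression.

make_series <- function(bins = 45:79, f = function(x) 8000 - 6 * (x - 45),
                        noise = 0, n = 300, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  mid <- bins + 0.5
  y <- f(mid) + if (noise > 0) rnorm(length(mid), 0, noise) else 0
  binned_series(bins, y, n)
}

hinge <- function(x, a, b0, s1, dm) b0 + s1 * (x - a) + dm * pmax(x - a, 0)

test_that("exactly linear data fit perfectly with zero joinpoints", {
  s <- make_series()
  fit <- fit_k_joinpoints(s, 0)
  expect_lt(fit$rss, 1e-12)
  expect_equal(unname(fit$slopes), -6, tolerance = 1e-9)
  expect_equal(fit$df, length(s$bin_mid) - 2)
})

test_that("a noise-free two-segment break is recovered exactly", {
  s <- make_series(f = function(x) hinge(x, 64.5, 7500, -6, -32))
  fit <- fit_k_joinpoints(s, 1)
  expect_equal(fit$joinpoint_bins, 64)
  expect_equal(fit$slope_changes, -32, tolerance = 1e-8)
  expect_equal(unname(fit$slopes), c(-6, -38), tolerance = 1e-8)
  expect_lt(fit$rss, 1e-10)
})

test_that("residual sum of squares is non-increasing in k", {
  s <- make_series(noise = 40, seed = 51)
  rss <- vapply(0:3, function(k) fit_k_joinpoints(s, k)$rss, 0)
  expect_true(all(diff(rss) <= 1e-9))
})

test_that("grid search equals a brute-force enumeration oracle", {
  for (sd_seed in 1:2) {
    s <- make_series(bins = 50:71, noise = 60, seed = 60 + sd_seed)
    x <- s$bin_mid
    y <- s$mean_volume
    n <- length(x)
    for (k in 1:2) {
      cand <- 3:(n - 2)
      combs <- utils::combn(cand, k)
      best_rss <- Inf
      best_idx <- NULL
      for (j in seq_len(ncol(combs))) {
        ix <- combs[, j]
        if (k > 1 && any(diff(ix) < 3)) next
        df <- data.frame(y = y, x = x)
        for (t in x[ix]) {
          df[[paste0("h", which(x == t))]] <- pmax(x - t, 0)
        }
        rss <- sum(residuals(lm(y ~ ., data = df))^2)
        if (rss < best_rss) {
          best_rss <- rss
          best_idx <- ix
        }
      }
      fit <- fit_k_joinpoints(s, k)
      expect_equal(fit$tau_index, best_idx)
      expect_equal(fit$rss, best_rss, tolerance = 1e-8)
    }
  }
})

test_that("fitted segments are continuous at the joinpoints", {
  s <- make_series(noise = 50, seed = 53,
                   f = function(x) hinge(x, 60.5, 7800, -4, -25))
  fit <- fit_k_joinpoints(s, 2)
  predict_at <- function(a) {
    X <- cbind(1, a)
    for (t in fit$tau) X <- cbind(X, pmax(a - t, 0))
    drop(X %*% fit$coef)
  }
  for (t in fit$tau) {
    expect_equal(predict_at(t - 1e-9), predict_at(t + 1e-9),
                 tolerance = 1e-9)
  }
})

test_that("infeasible joinpoint counts raise informative errors", {
  s <- make_series(bins = 45:50)
  expect_error(fit_k_joinpoints(s, 2), "infeasible")
  expect_error(select_model(s, n_perm = 5), "n_perm")
  # fewer than 7 bins: no joinpoint is ever tested
  s5 <- make_series(bins = 45:49, noise = 10, seed = 7)
  m <- select_model(s5, n_perm = 50, seed = 1)
  expect_equal(m$k, 0)
})

test_that("model selection finds a strong break and respects alpha = 0", {
  s <- make_series(noise = 8, seed = 55,
                   f = function(x) hinge(x, 64.5, 7500, -6, -32))
  m <- select_model(s, n_perm = 99, seed = 2)
  expect_gte(m$k, 1)
  expect_true(64 %in% m$joinpoint_bins ||
                min(abs(m$joinpoint_bins - 64)) <= 1)
  j <- which.min(abs(m$joinpoint_bins - 64))
  expect_lt(abs(m$slope_changes[j] - (-32)), 5)
  expect_equal(m$df, length(s$bin_mid) - 2 * (m$k + 1))
  # t statistic is slope change over its standard error
  expect_equal(m$t, m$slope_changes / m$slope_change_se)

  m0 <- select_model(s, alpha = 0, n_perm = 99, seed = 2)
  expect_equal(m0$k, 0)

  # reproducibility: same seed, same model and p-values
  m2 <- select_model(s, n_perm = 99, seed = 2)
  expect_equal(m$joinpoint_bins, m2$joinpoint_bins)
  expect_equal(m$p_perm, m2$p_perm)
})

test_that("joinpoint confidence intervals behave", {
  # noise-free: the interval collapses onto the true bin
  s0 <- make_series(f = function(x) hinge(x, 64.5, 7500, -6, -32))
  f0 <- fit_k_joinpoints(s0, 1)
  ci0 <- joinpoint_ci(s0, f0)
  expect_equal(unname(ci0[1, ]), c(64, 64))

  # noisy: the interval always contains the point estimate
  s1 <- make_series(noise = 30, seed = 57,
                    f = function(x) hinge(x, 64.5, 7500, -6, -32))
  m1 <- select_model(s1, n_perm = 99, seed = 3)
  if (m1$k >= 1) {
    expect_true(all(m1$ci[, "lower"] <= m1$joinpoint_bins &
                      m1$joinpoint_bins <= m1$ci[, "upper"]))
  }

  # interval width shrinks as the noise vanishes
  widths <- vapply(c(60, 20, 5), function(sd) {
    s <- make_series(noise = sd, seed = 59,
                     f = function(x) hinge(x, 64.5, 7500, -6, -32))
    f1 <- fit_k_joinpoints(s, 1)
    ci <- joinpoint_ci(s, f1)
    ci[1, "upper"] - ci[1, "lower"]
  }, 0)
  expect_true(all(diff(widths) <= 0))
})

test_that("bin_series averages deconfounded volumes per 1-year bin", {
  spec <- simple_spec(n_female = 3000, seed = 61,
                      hip = list(baseline = 3800, sd = 0, pre = -4,
                                 change = 0, age = 64))
  co <- generate_cohort(spec)
  bs <- bin_series(co, "hippocampus", "female", hemisphere = "average",
                   correction = character(0))
  expect_s3_class(bs, "binned_series")
  expect_equal(sum(bs$n), 3000)
  expect_true(all(diff(bs$bin_start) == 1))
  # noise-free linear volumes: bin means on the generating line at the
  # mean age of the bin members
  f <- function(a) -4 * (a - 64)
  shift <- mean(f(co$age))
  ages <- co$age
  for (i in seq_len(nrow(bs))) {
    members <- ages >= bs$bin_start[i] & ages < bs$bin_start[i] + 1
    expect_equal(bs$mean_volume[i], 3800 + mean(f(ages[members])) - shift,
                 tolerance = 1e-9)
  }
  # duplicating the cohort leaves the series unchanged
  co2 <- rbind(co, co)
  class(co2) <- class(co)
  bs2 <- bin_series(co2, "hippocampus", "female", hemisphere = "average",
                    correction = character(0))
  expect_equal(bs2$mean_volume, bs$mean_volume)
  expect_equal(bs2$n, 2 * bs$n)
})
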