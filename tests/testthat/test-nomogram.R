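# Sliding windows, smoothing, quantile nomograms.

test_that("window construction matches the combinatorial layout", {
  w <- build_windows(1:100, fraction = 0.10, step = 10)
  expect_equal(length(w$starts), 10)
  expect_equal(w$size, 10)
  expect_equal(w$starts, seq(1, 91, by = 10))
  # consecutive windows overlap at step 1
  w1 <- build_windows(1:100, fraction = 0.10, step = 1)
  expect_equal(length(w1$starts), 91)
  expect_true(all(diff(w1$median_age) >= 0))

  wall <- build_windows(rnorm(50, 60, 5), fraction = 1)
  expect_equal(length(wall$starts), 1)
  expect_equal(wall$median_age, median(wall$ages_sorted))

  wconst <- build_windows(rep(60, 40), fraction = 0.25)
  expect_true(all(wconst$median_age == 60))

  expect_error(build_windows(1:100, fraction = 0), "fraction")
  expect_error(build_windows(1:100, fraction = 1.5), "fraction")
  expect_error(build_windows(1:5, fraction = 0.1), "at least")
})

test_that("window statistics behave on constant and linear inputs", {
  w <- build_windows(1:100, fraction = 0.2)
  const <- rep(7.5, 100)
  expect_true(all(window_statistic(const, w, "mean") == 7.5))
  q <- window_statistic(const, w, "quantile", level = c(2.5, 50, 97.5))
  expect_true(all(q == 7.5))
  expect_true(all(window_statistic(const, w, "sem") == 0))

  # symmetric (uniform-grid) windows: mean at median age is exact
  ages <- as.numeric(1:100)
  vol <- 5000 - 3 * ages
  wm <- window_statistic(vol, w, "mean")
  expect_equal(wm, 5000 - 3 * w$median_age, tolerance = 1e-12)
})

test_that("windowed quantiles equal a brute-force sort oracle at small n", {
  for (s in 1:3) {
    set.seed(s)
    n <- sample(40:50, 1)
    ages <- runif(n, 45, 80)
    vals <- rnorm(n, 4000, 300)
    w <- build_windows(ages, fraction = 0.25, step = 2)
    levels <- c(2.5, 25, 50, 75, 97.5)
    got <- window_statistic(vals, w, "quantile", level = levels)
    v_sorted <- vals[w$order]
    for (j in seq_along(w$starts)) {
      idx <- w$starts[j]:(w$starts[j] + w$size - 1)
      expect_equal(got[, j], quantile_type7_oracle(v_sorted[idx],
                                                   levels / 100))
    }
  }
})

test_that("gaussian smoothing matches a direct convolution oracle", {
  y <- rep(0, 201)
  y[101] <- 1
  sm <- smooth_curve(y, kernel_sd = 5)
  h <- ceiling(3 * 5)
  w <- exp(-0.5 * ((-h:h) / 5)^2)
  w <- w / sum(w)
  expect_equal(sm[(101 - h):(101 + h)], rev(w), tolerance = 1e-12)

  expect_equal(smooth_curve(rep(3, 50), 20), rep(3, 50))
  expect_identical(smooth_curve(1:10, 0), 1:10)
  expect_error(smooth_curve(1:10, -1), "kernel_sd")
})

test_that("quantile curves never cross, before or after smoothing", {
  co <- generate_cohort(cohort_spec(n_female = 2000, n_male = 0, seed = 21))
  nom <- build_nomogram(co, "hippocampus", "female", fraction = 0.10,
                        kernel_sd = 20)
  expect_true(all(apply(nom$curves_raw, 2, function(v) all(diff(v) >= 0))))
  expect_true(all(apply(nom$curves, 2, function(v) all(diff(v) >= 0))))
})

test_that("duplicating every observation leaves mean and median curves", {
  set.seed(31)
  ages <- runif(60, 45, 80)
  vals <- rnorm(60, 4000, 300)
  w1 <- build_windows(ages, fraction = 0.2, step = 2)
  w2 <- build_windows(rep(ages, each = 2), fraction = 0.2, step = 4)
  m1 <- window_statistic(vals, w1, "mean")
  m2 <- window_statistic(rep(vals, each = 2), w2, "mean")
  expect_equal(m1, m2, tolerance = 1e-12)
  q1 <- window_statistic(vals, w1, "quantile", level = 50)
  q2 <- window_statistic(rep(vals, each = 2), w2, "quantile", level = 50)
  expect_equal(q1, q2, tolerance = 1e-12)
})

test_that("age-independent cohorts give flat curves at Normal quantiles", {
  spec <- simple_spec(n_female = 20000, seed = 17,
                      hip = list(baseline = 3800, sd = 350, pre = 0,
                                 change = 0, age = 64))
  co <- generate_cohort(spec)
  nom <- build_nomogram(co, "hippocampus", "female", hemisphere = "average",
                        correction = character(0))
  # Monte Carlo tolerance ~4 SE of a 2000-member window quantile; the edge
  # windows (truncated smoothing support) are the noisiest and are skipped
  interior <- 200:(length(nom$age) - 200)
  for (lv in c(5, 50, 95)) {
    truth <- qnorm(lv / 100, 3800, 350)
    curve <- nom$curves[paste0("q", lv), interior]
    expect_lt(max(abs(curve - truth)), 60)
  }
  expect_lt(max(abs(nom$mean[interior] - 3800)), 30)
})

test_that("the nomogram median tracks the generating trajectory", {
  spec <- simple_spec(n_female = 10000, seed = 23,
                      hip = list(baseline = 3765, sd = 367, pre = -3,
                                 change = -16, age = 64.5))
  co <- generate_cohort(spec)
  nom <- build_nomogram(co, "hippocampus", "female", hemisphere = "average",
                        correction = character(0))
  f <- function(a) -3 * (a - 64.5) - 16 * pmax(a - 64.5, 0)
  shift <- mean(f(co$age))  # generator centres the age effect within sex
  truth <- 3765 + f(nom$age) - shift
  sem <- 367 / sqrt(nom$windows$size)
  inside <- abs(nom$mean - truth) <= 3 * sem
  expect_gt(mean(inside), 0.95)
})

test_that("age-adjusted percentiles reduce to the plain percentiles", {
  # volumes exactly on a line in age: adjusted values collapse to the mean
  spec <- simple_spec(n_female = 2000, seed = 25,
                      hip = list(baseline = 3800, sd = 0, pre = -3,
                                 change = 0, age = 64))
  co <- generate_cohort(spec)
  ap <- age_adjusted_percentiles(co, "hippocampus", "female",
                                 hemisphere = "average",
                                 correction = character(0))
  # rows whose age falls outside the window grid are flagged and use the
  # nearest edge value; interior rows collapse onto the grand mean
  inner <- setdiff(seq_along(ap$adjusted), ap$flagged)
  expect_gt(length(ap$flagged), 0)
  expect_lt(max(abs(ap$adjusted[inner] - 3800)), 3)

  # no age effect: adjusted ~ original, table ~ raw empirical percentiles
  spec2 <- simple_spec(n_female = 8000, seed = 26,
                       hip = list(baseline = 3800, sd = 300, pre = 0,
                                  change = 0, age = 64))
  co2 <- generate_cohort(spec2)
  ap2 <- age_adjusted_percentiles(co2, "hippocampus", "female",
                                  hemisphere = "average",
                                  correction = character(0))
  v <- cohort_volume(co2, "hippocampus", "average")
  raw <- quantile(v, probs = c(2.5, 5, 10, 25, 50, 75, 90, 95, 97.5) / 100)
  expect_equal(unname(ap2$table), unname(raw), tolerance = 0.01)
  expect_equal(unname(ap2$table["q50"]),
               unname(quantile(ap2$adjusted, 0.5)))
})

test_that("fixed bins partition the cohort and agree with sliding means", {
  spec <- simple_spec(n_female = 4000, seed = 27,
                      hip = list(baseline = 3800, sd = 0, pre = -4,
                                 change = 0, age = 64))
  co <- generate_cohort(spec)
  fb <- fixed_bin_curves(co, "hippocampus", "female",
                         hemisphere = "average",
                         correction = character(0), bin_width = 5)
  expect_equal(sum(fb$n), 4000)
  # noise-free linear volumes: bin means sit on the generating line
  f <- function(a) -4 * (a - 64)
  shift <- mean(f(co$age))
  expect_equal(fb$mean, 3800 + f(fb$age) - shift, tolerance = 1e-8)

  one <- fixed_bin_curves(co, "hippocampus", "female",
                          hemisphere = "average",
                          correction = character(0), bin_width = 50)
  expect_equal(nrow(one), 1)
  expect_equal(one$mean, mean(cohort_volume(co, "hippocampus", "average")))

  # half-open bins: no observation is double counted
  borders <- toy_cohort(4, age = c(45, 50, 50, 55))
  fb2 <- fixed_bin_curves(borders, "hippocampus", "female",
                          hemisphere = "average",
                          correction = character(0), bin_width = 5)
  expect_equal(fb2$n, c(1, 2, 1))
})

test_that("nomogram CSV round-trips for lookup use", {
  co <- generate_cohort(cohort_spec(n_female = 1500, n_male = 0, seed = 29))
  nom <- build_nomogram(co, "hippocampus", "female")
  path <- withr::local_tempfile(fileext = ".csv")
  write_nomogram(nom, path)
  back <- read_nomogram(path)
  expect_equal(back$curves, nom$curves, tolerance = 1e-6)
  expect_equal(back$age, nom$age, tolerance = 1e-6)
  expect_equal(back$levels, nom$levels)
  expect_equal(back$sex, nom$sex)
  expect_equal(back$correction, nom$correction)
})
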