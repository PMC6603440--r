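# MAD outlier filter and confound regression.

test_that("mad_filter matches hand-computed distances", {
  # median 3, MAD 1; only the value at distance 97 exceeds the cutoff
  m <- mad_filter(c(1, 2, 3, 4, 100))
  expect_equal(m$excluded, c(FALSE, FALSE, FALSE, FALSE, TRUE))
  expect_equal(m$distance, c(2, 1, 0, 1, 97))

  expect_warning(m0 <- mad_filter(c(5, 5, 5, 5)), "MAD is zero")
  expect_false(any(m0$excluded))

  m_inf <- mad_filter(rnorm(100), cutoff = Inf)
  expect_false(any(m_inf$excluded))

  expect_error(mad_filter(numeric(0)))
})

test_that("mad_filter is invariant to affine rescaling", {
  for (s in 1:5) {
    set.seed(s)
    x <- rnorm(200) + c(rep(0, 195), rnorm(5, 0, 50))
    m1 <- mad_filter(x)
    m2 <- mad_filter(3.7 * x - 1200)
    expect_identical(m1$excluded, m2$excluded)
    expect_equal(m1$distance, m2$distance)
  }
})

test_that("confound-independent volumes give zero slopes and identity", {
  spec <- simple_spec(n_female = 200, seed = 8,
                      hip = list(baseline = 3700, sd = 0, pre = 0,
                                 change = 0, age = 64))
  co <- generate_cohort(spec)
  mod <- fit_confound_model(co, "hippocampus",
                            c("scan_date", "head_scaling"))
  expect_equal(unname(mod$slopes), c(0, 0), tolerance = 1e-8)
  v <- cohort_volume(co, "hippocampus")
  expect_equal(apply_deconfound(v, mod, co), v, tolerance = 1e-6)
})

test_that("the generating head-scaling slope is recovered within 2%", {
  spec <- simple_spec(
    n_female = 20000, seed = 13,
    hip = list(baseline = 3765, sd = 100, pre = 0, change = 0, age = 64),
    head_b_hip = c(left = -1340.89, right = -1532.24)
  )
  co <- generate_cohort(spec)
  mod <- fit_confound_model(co, "hippocampus",
                            c("scan_date", "head_scaling"),
                            hemisphere = "left")
  b <- mod$slopes[["head_scaling"]]
  expect_lt(abs(b / -1340.89 - 1), 0.02)
  mod_r <- fit_confound_model(co, "hippocampus",
                              c("scan_date", "head_scaling"),
                              hemisphere = "right")
  expect_lt(abs(mod_r$slopes[["head_scaling"]] / -1532.24 - 1), 0.02)
})

test_that("rank-deficient or constant designs are rejected by name", {
  co <- generate_cohort(simple_spec(n_female = 50, seed = 2))
  co2 <- co
  co2$age <- co2$scan_date  # perfectly collinear pair
  expect_error(
    fit_confound_model(co2, "hippocampus", c("scan_date", "age")),
    "collinear"
  )
  co3 <- co
  co3$scan_date <- 100
  expect_error(fit_confound_model(co3, "hippocampus", "scan_date"),
               "constant")
  expect_error(fit_confound_model(co, "hippocampus", "not_a_confound"),
               "unknown confounds")
})

test_that("the head-size correction formula evaluates as published", {
  mod <- structure(
    list(region = "hippocampus", hemisphere = "left",
         confounds = "head_scaling",
         slopes = c(head_scaling = -1340.89),
         reference = c(head_scaling = 1.29874),
         grand_mean = 3765, n = 1000),
    class = "deconfound_model"
  )
  # correction is the identity at the reference scaling
  at_ref <- apply_deconfound(3600, mod, data.frame(head_scaling = 1.29874))
  expect_equal(at_ref, 3600)
  corrected <- apply_deconfound(3600, mod,
                                data.frame(head_scaling = 1.40))
  expect_equal(corrected, 3600 - (1.40 - 1.29874) * -1340.89,
               tolerance = 1e-12)
  expect_equal(round(corrected, 2), 3735.78)
})

test_that("joint correction equals sequential correction", {
  co <- generate_cohort(cohort_spec(n_female = 2000, n_male = 0, seed = 4))
  v <- cohort_volume(co, "hippocampus")
  mod <- fit_confound_model(co, "hippocampus",
                            c("scan_date", "head_scaling"))
  joint <- apply_deconfound(v, mod, co)
  m1 <- mod; m1$confounds <- "scan_date"
  m2 <- mod; m2$confounds <- "head_scaling"
  seq_corr <- apply_deconfound(apply_deconfound(v, m1, co), m2, co)
  expect_equal(joint, seq_corr, tolerance = 1e-10)
})

test_that("corrected volumes are uncorrelated with each confound", {
  co <- generate_cohort(cohort_spec(n_female = 3000, n_male = 0, seed = 6))
  v <- cohort_volume(co, "hippocampus")
  mod <- fit_confound_model(co, "hippocampus",
                            c("scan_date", "head_scaling", "age"))
  corrected <- apply_deconfound(v, mod, co)
  for (cf in c("scan_date", "head_scaling", "age")) {
    expect_lt(abs(cor(corrected, co[[cf]])), 1e-10)
  }
})

test_that("correction preserves the mean when references are the means", {
  co <- generate_cohort(cohort_spec(n_female = 1500, n_male = 0, seed = 9))
  v <- cohort_volume(co, "hippocampus")
  mod <- fit_confound_model(
    co, "hippocampus", c("scan_date", "head_scaling"),
    reference = c(head_scaling = mean(co$head_scaling))
  )
  corrected <- apply_deconfound(v, mod, co)
  expect_equal(mean(corrected), mean(v), tolerance = 1e-8)
})

test_that("missing confound values flag rows instead of dropping them", {
  co <- generate_cohort(simple_spec(n_female = 20, seed = 3))
  v <- cohort_volume(co, "hippocampus")
  mod <- fit_confound_model(co, "hippocampus", "head_scaling")
  co$head_scaling[5] <- NA
  expect_warning(out <- apply_deconfound(v, mod, co), "flagged")
  expect_true(is.na(out[5]))
  expect_equal(attr(out, "flagged"), 5L)
  expect_equal(length(out), length(v))
})
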