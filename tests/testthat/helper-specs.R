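# Shared fixture builders: cohort specs with nuisance effects switched off
# so individual mechanisms can be isolated.

# Spec whose hippocampus / total grey matter follow the given simple
# parameters with no drift, no covariate effects, no outliers and (by
# default) no head-scaling effect on the hippocampus.
simple_spec <- function(n_female = 1000, n_male = 0, seed = 1,
                        hip = list(baseline = 3765, sd = 300, pre = 0,
                                   change = 0, age = 64),
                        tgm = list(baseline = 594250, sd = 48028, pre = 0,
                                   change = 0, age = 64),
                        head_b_hip = c(left = 0, right = 0),
                        head_b_tgm = 0,
                        asym = 0,
                        outlier_fraction = 0,
                        drift = 0, ...) {
  rp <- default_region_params()
  for (sx in c("female", "male")) {
    rp$hippocampus[[sx]] <- list(
      baseline = hip$baseline, sd = hip$sd, pre_slope = hip$pre,
      slope_change = hip$change, change_age = hip$age,
      asymmetry = asym, head_b = head_b_hip)
    rp$total_grey_matter[[sx]] <- list(
      baseline = tgm$baseline, sd = tgm$sd, pre_slope = tgm$pre,
      slope_change = tgm$change, change_age = tgm$age,
      asymmetry = 0, head_b = c(total = head_b_tgm))
  }
  cohort_spec(n_female = n_female, n_male = n_male, region_params = rp,
              drift_slope = drift, covariate_effects = list(),
              outlier_fraction = outlier_fraction, seed = seed, ...)
}

# Minimal hand-built cohort table with full schema; volume columns default
# to positive constants unless overridden.
toy_cohort <- function(n, age, sex = "female", overrides = list(),
                       seed = 42) {
  set.seed(seed)
  out <- data.frame(
    participant_id = sprintf("T%04d", seq_len(n)),
    age = age, sex = rep_len(sex, n),
    scan_date = stats::runif(n, 0, 1460),
    head_scaling = stats::rnorm(n, 1.29874, 0.1),
    stringsAsFactors = FALSE
  )
  for (col in hippnorm:::.hn_volume_columns()) {
    out[[col]] <- rep(5000, n)
  }
  out$total_grey_matter <- rep(600000, n)
  out$hypertension <- rep(FALSE, n)
  out$smoking <- rep("never", n)
  out$bmi <- rep(27, n)
  out$education <- rep("higher", n)
  out$handedness <- rep("right", n)
  out$excluded_selfreport <- rep(FALSE, n)
  for (nm in names(overrides)) out[[nm]] <- overrides[[nm]]
  class(out) <- c("cohort_table", "data.frame")
  out
}

# Independent type-7 quantile oracle: linear interpolation between order
# statistics, written out from the defining formula.
quantile_type7_oracle <- function(x, p) {
  s <- sort(x)
  n <- length(s)
  vapply(p, function(pp) {
    h <- (n - 1) * pp + 1
    lo <- floor(h)
    hi <- ceiling(h)
    s[lo] + (h - lo) * (s[hi] - s[lo])
  }, 0)
}
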