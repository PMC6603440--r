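# Synthetic cohort generation.
#
# The generator emulates the statistical structure of a large population
# brain-imaging cohort: sex-specific volume distributions, piecewise-linear
# (continuous-hinge) age trajectories, a head-scaling confound, linear
# scanner drift over scan date, lifestyle covariate shifts, and a small
# fraction of gross outliers. It exists so that every downstream stage
# (outlier filtering, deconfounding, nomograms, trajectory inflection,
# joinpoint regression, percentile lookup) can be exercised end to end
# without access-controlled participant data.

#' Default per-region generator parameters
#'
#' Volumes are parameterised per hemisphere for the seven paired regions and
#' as a single total for grey matter. `baseline` is the sex-specific cohort
#' mean volume (mm^3), `sd` the total marginal standard deviation; age
#' effects are a continuous hinge: slope `pre_slope` before `change_age`,
#' `pre_slope + slope_change` after. `asymmetry` is the mean right-minus-left
#' difference; `head_b` the head-scaling regression slope per hemisphere.
#'
#' Hippocampus and total grey matter anchor to published summary statistics
#' (sex means/SDs, head-scaling slopes, hinge ages with slope changes of
#' -32.44 / -26.45 mm^3 per year bilaterally for females/males at ages 64-65
#' and 63-64). The six neighbouring temporal-lobe regions use realistic
#' atlas-ROI scale values with asymmetries signed to match the reported
#' right-larger (superior/inferior temporal, hippocampus) and left-larger
#' (fusiform, parahippocampal, temporal pole) patterns.
#'
#' @return named list: region -> sex -> parameter list.
#' @export
default_region_params <- function() {
  hb_hip <- c(left = -1340.89, right = -1532.24)
  reg <- function(bf, sf, bm, sm, pre_f, ch_f, age_f, pre_m, ch_m, age_m,
                  asym, head_b = NULL) {
    if (is.null(head_b)) {
      head_b <- c(left = -0.45 * (bf + bm) / 2, right = -0.45 * (bf + bm) / 2)
    }
    list(
      female = list(baseline = bf, sd = sf, pre_slope = pre_f,
                    slope_change = ch_f, change_age = age_f,
                    asymmetry = asym, head_b = head_b),
      male = list(baseline = bm, sd = sm, pre_slope = pre_m,
                  slope_change = ch_m, change_age = age_m,
                  asymmetry = asym, head_b = head_b)
    )
  }
  list(
    hippocampus = reg(3765.18, 366.75, 3972.97, 431.03,
                      -3, -16.22, 64.5, -5, -13.225, 63.5,
                      asym = 94, head_b = hb_hip),
    superior_temporal = reg(8800, 1050, 9400, 1100,
                            -20, 0, 60, -20, 0, 60, asym = 880),
    middle_temporal = reg(11800, 1450, 12600, 1550,
                          -30, 0, 60, -30, 0, 60, asym = 0),
    inferior_temporal = reg(10800, 1350, 11500, 1450,
                            -25, 0, 60, -25, 0, 60, asym = 170),
    fusiform = reg(9300, 1150, 10000, 1250,
                   -15, 0, 60, -15, 0, 60, asym = -1530),
    parahippocampal = reg(3900, 480, 4200, 520,
                          -2, -13.49, 66.5, -3, -15.41, 59.5, asym = -235),
    temporal_pole = reg(8300, 980, 8900, 1050,
                        -5, 0, 60, -5, -38.49, 55.5, asym = -40),
    total_grey_matter = list(
      female = list(baseline = 594250, sd = 48028, pre_slope = -1000,
                    slope_change = -1273.98, change_age = 56.5,
                    asymmetry = 0, head_b = c(total = -354545.84)),
      male = list(baseline = 641307, sd = 51379, pre_slope = -1500,
                  slope_change = -754.14, change_age = 62.5,
                  asymmetry = 0, head_b = c(total = -354545.84))
    )
  )
}

#' Specify a synthetic cohort
#'
#' Builds and validates the parameter set consumed by [generate_cohort()].
#' Defaults describe the reference study population: 10,463 females and
#' 9,330 males aged 45-80 with an age density peaking near 64 years (fewer
#' participants at the age limits), head scaling Normal(1.29874, 0.1) with a
#' small sex offset (males have larger heads, hence lower scaling), linear
#' scanner drift over scan date, small lifestyle covariate effects on
#' hippocampal and total grey-matter volume (standardized g / Pearson r
#' scale), and 0.7% gross outliers displaced by 8 SD.
#'
#' @param n_female,n_male numbers of participants per sex.
#' @param age_range numeric length 2, minimum and maximum age in years.
#' @param age_mode mode (years) of the triangular age density.
#' @param region_params per-region parameters, see [default_region_params()].
#' @param head_scaling_mean,head_scaling_sd,head_scaling_sex_offset
#'   head-scaling factor distribution; females get `+offset`, males
#'   `-offset` added to the mean.
#' @param drift_slope scanner drift as a *relative* volume change per
#'   scan-date day (dimensionless per day).
#' @param scan_days length of the scanning period in days.
#' @param covariate_effects named list of per-region standardized effects;
#'   `bmi` entries are Pearson r, others Hedges' g shifts applied to the
#'   flagged group.
#' @param outlier_fraction proportion of rows per volume column displaced;
#'   must lie in \[0, 0.05\].
#' @param outlier_magnitude displacement in multiples of the region SD.
#' @param exclusion_fraction proportion flagged as self-report exclusions.
#' @param asymmetry_sd_frac SD of the within-subject left/right difference,
#'   as a fraction of the region SD.
#' @param seed master seed; all randomness derives from it through
#'   per-column streams, so generation is bit-reproducible.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_female = 10463,
                        n_male = 9330,
                        age_range = c(45, 80),
                        age_mode = 64,
                        region_params = default_region_params(),
                        head_scaling_mean = 1.29874,
                        head_scaling_sd = 0.1,
                        head_scaling_sex_offset = 0.025,
                        drift_slope = -2e-6,
                        scan_days = 1460,
                        covariate_effects = default_covariate_effects(),
                        outlier_fraction = 0.007,
                        outlier_magnitude = 8,
                        exclusion_fraction = 0,
                        asymmetry_sd_frac = 0.5,
                        seed = 1L) {
  spec <- list(
    n_female = n_female, n_male = n_male,
    age_range = age_range, age_mode = age_mode,
    region_params = region_params,
    head_scaling_mean = head_scaling_mean,
    head_scaling_sd = head_scaling_sd,
    head_scaling_sex_offset = head_scaling_sex_offset,
    drift_slope = drift_slope, scan_days = scan_days,
    covariate_effects = covariate_effects,
    outlier_fraction = outlier_fraction,
    outlier_magnitude = outlier_magnitude,
    exclusion_fraction = exclusion_fraction,
    asymmetry_sd_frac = asymmetry_sd_frac,
    seed = seed
  )
  class(spec) <- "cohort_spec"
  validate_cohort_spec(spec)
  spec
}

#' Default covariate effects for the generator
#'
#' Standardized shifts applied to the named regions (negative = lower volume
#' in the flagged/indexed group): hypertension and smoking lower total grey
#' matter and hippocampal volume, lower education lowers hippocampal volume,
#' and BMI has a small negative Pearson correlation with both.
#'
#' @return named list of named numeric vectors.
#' @export
default_covariate_effects <- function() {
  list(
    hypertension = c(total_grey_matter = -0.17, hippocampus = -0.06),
    smoking_previous = c(total_grey_matter = -0.16, hippocampus = -0.10),
    smoking_current = c(total_grey_matter = -0.33, hippocampus = -0.15),
    education_lower = c(total_grey_matter = 0, hippocampus = -0.07),
    bmi = c(total_grey_matter = -0.11, hippocampus = -0.03)
  )
}

#' Validate a cohort specification
#'
#' @param spec a `cohort_spec`.
#' @return `spec`, invisibly; otherwise an error naming the offending field.
#' @export
validate_cohort_spec <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  err <- function(field, msg) {
    stop("invalid cohort spec: field `", field, "` ", msg, call. = FALSE)
  }
  if (length(spec$n_female) != 1 || is.na(spec$n_female) || spec$n_female < 0)
    err("n_female", "must be a non-negative count")
  if (length(spec$n_male) != 1 || is.na(spec$n_male) || spec$n_male < 0)
    err("n_male", "must be a non-negative count")
  if (length(spec$age_range) != 2 || spec$age_range[1] >= spec$age_range[2])
    err("age_range", "must be (min, max) with min < max")
  if (spec$age_mode < spec$age_range[1] || spec$age_mode > spec$age_range[2])
    err("age_mode", "must lie within age_range")
  if (spec$outlier_fraction < 0 || spec$outlier_fraction > 0.05)
    err("outlier_fraction", "must lie in [0, 0.05]")
  if (spec$head_scaling_sd < 0) err("head_scaling_sd", "must be >= 0")
  if (spec$exclusion_fraction < 0 || spec$exclusion_fraction >= 1)
    err("exclusion_fraction", "must lie in [0, 1)")
  for (rn in names(spec$region_params)) {
    for (sx in c("female", "male")) {
      p <- spec$region_params[[rn]][[sx]]
      if (is.null(p)) err("region_params", paste0("missing ", sx, " for ", rn))
      if (is.null(p$sd) || p$sd < 0)
        err("region_params", paste0("sd must be >= 0 for ", rn, " (", sx, ")"))
      if (is.null(p$baseline) || p$baseline <= 0)
        err("region_params", paste0("baseline must be > 0 for ", rn))
    }
  }
  invisible(spec)
}

# Continuous hinge age effect, zero at the change age.
.hn_age_effect <- function(age, p) {
  p$pre_slope * (age - p$change_age) +
    p$slope_change * pmax(age - p$change_age, 0)
}

# Covariate shift for one region and one sex block. `scale_sd` is the
# residual SD after confound correction, because standardized covariate
# effects are reported against confound-corrected volumes.
.hn_covariate_shift <- function(region, spec, covars, scale_sd) {
  eff <- spec$covariate_effects
  shift <- numeric(length(covars$hypertension))
  pick <- function(v) if (region %in% names(v)) v[[region]] else 0
  if (!is.null(eff$hypertension))
    shift <- shift + pick(eff$hypertension) * scale_sd * covars$hypertension
  if (!is.null(eff$smoking_previous))
    shift <- shift + pick(eff$smoking_previous) * scale_sd *
      (covars$smoking == "previous")
  if (!is.null(eff$smoking_current))
    shift <- shift + pick(eff$smoking_current) * scale_sd *
      (covars$smoking == "current")
  if (!is.null(eff$education_lower))
    shift <- shift + pick(eff$education_lower) * scale_sd *
      (covars$education == "lower")
  if (!is.null(eff$bmi)) {
    z <- as.numeric(scale(covars$bmi))
    shift <- shift + pick(eff$bmi) * scale_sd * z
  }
  shift
}

#' Generate a synthetic cohort
#'
#' Draws one participant-level table under the model described in
#' [cohort_spec()]. Each regional volume is
#' `baseline + age effect + head-scaling effect + drift + covariate shifts +
#' noise`, where all systematic effects are mean-centred within sex so that
#' the sex-specific cohort mean equals `baseline` and the marginal SD equals
#' `sd` (the Gaussian noise absorbs the variance not explained by the
#' systematic terms). A fraction of rows per volume column is displaced
#' symmetrically by `outlier_magnitude` SD to emulate segmentation failures.
#'
#' @param spec a `cohort_spec`.
#' @return a `cohort_table` (data frame), one row per participant.
#' @export
#' @examples
#' spec <- cohort_spec(n_female = 200, n_male = 150, seed = 7)
#' cohort <- generate_cohort(spec)
#' mean(cohort_volume(cohort, "hippocampus")[cohort$sex == "female"])
generate_cohort <- function(spec) {
  validate_cohort_spec(spec)
  blocks <- list()
  for (sx in c("female", "male")) {
    n <- if (sx == "female") spec$n_female else spec$n_male
    if (n == 0) next
    blocks[[sx]] <- .hn_generate_sex_block(spec, sx, n)
  }
  if (length(blocks) == 0) {
    cohort <- .hn_empty_cohort()
    class(cohort) <- c("cohort_table", "data.frame")
    return(cohort)
  }
  cohort <- do.call(rbind, blocks)
  rownames(cohort) <- NULL
  cohort$participant_id <- sprintf("P%06d", seq_len(nrow(cohort)))
  cohort <- cohort[, .hn_required_columns()]
  class(cohort) <- c("cohort_table", "data.frame")
  cohort
}

.hn_generate_sex_block <- function(spec, sx, n) {
  base_id <- if (sx == "female") 0L else 1000L
  seed <- spec$seed

  .hn_set_stream(seed, base_id + 1L)
  age <- .hn_rtriangular(n, spec$age_range[1], spec$age_range[2],
                         spec$age_mode)
  .hn_set_stream(seed, base_id + 2L)
  scan_date <- floor(stats::runif(n, 0, spec$scan_days))
  .hn_set_stream(seed, base_id + 3L)
  hs_mu <- spec$head_scaling_mean +
    if (sx == "female") spec$head_scaling_sex_offset else
      -spec$head_scaling_sex_offset
  head_scaling <- stats::rnorm(n, hs_mu, spec$head_scaling_sd)

  .hn_set_stream(seed, base_id + 4L)
  hypertension <- stats::runif(n) < 0.27
  .hn_set_stream(seed, base_id + 5L)
  smoking <- sample(c("never", "previous", "current"), n, replace = TRUE,
                    prob = c(0.60, 0.33, 0.07))
  .hn_set_stream(seed, base_id + 6L)
  bmi <- stats::rnorm(n, 27, 4.5)
  .hn_set_stream(seed, base_id + 7L)
  education <- sample(c("higher", "lower"), n, replace = TRUE,
                      prob = c(0.55, 0.45))
  .hn_set_stream(seed, base_id + 8L)
  handedness <- sample(c("right", "left", "ambidextrous"), n, replace = TRUE,
                       prob = c(0.89, 0.10, 0.01))
  .hn_set_stream(seed, base_id + 9L)
  excluded_selfreport <- stats::runif(n) < spec$exclusion_fraction

  covars <- list(hypertension = hypertension, smoking = smoking,
                 bmi = bmi, education = education)

  out <- data.frame(
    participant_id = rep("", n), age = age, sex = sx,
    scan_date = scan_date, head_scaling = head_scaling,
    stringsAsFactors = FALSE
  )

  ref_hs <- spec$head_scaling_mean
  hs_c <- head_scaling - mean(head_scaling)
  date_c <- scan_date - mean(scan_date)

  rid <- 0L
  for (region in names(spec$region_params)) {
    rid <- rid + 1L
    p <- spec$region_params[[region]][[sx]]
    b_avg <- mean(p$head_b)

    det0 <- .hn_age_effect(age, p) +
      b_avg * (head_scaling - ref_hs) +
      spec$drift_slope * p$baseline * scan_date
    det0 <- det0 - mean(det0)
    # Residual SD after confound/age correction: standardized covariate
    # effects are expressed against it, matching how they are reported.
    resid_sd <- sqrt(max(0, p$sd^2 - mean(det0^2)))
    det <- det0 + .hn_covariate_shift(region, spec, covars, resid_sd)
    det <- det - mean(det)

    # Noise absorbs whatever variance the systematic part does not supply,
    # so the marginal SD of the region matches p$sd.
    v_det <- mean(det^2)
    noise_sd <- sqrt(max(0, p$sd^2 - v_det))
    .hn_set_stream(seed, base_id + 100L + rid)
    avg <- p$baseline + det + stats::rnorm(n, 0, noise_sd)

    if (region == "total_grey_matter") {
      out$total_grey_matter <- avg
    } else {
      asym_sd <- spec$asymmetry_sd_frac * p$sd
      .hn_set_stream(seed, base_id + 200L + rid)
      asym <- p$asymmetry + stats::rnorm(n, 0, asym_sd)
      # hemisphere-specific part of the head-scaling effect
      dev_l <- (p$head_b[["left"]] - b_avg) * hs_c
      dev_r <- (p$head_b[["right"]] - b_avg) * hs_c
      out[[paste0(region, "_left")]] <- avg - asym / 2 + dev_l
      out[[paste0(region, "_right")]] <- avg + asym / 2 + dev_r
    }
  }

  # symmetric outlier injection, independently per volume column
  if (spec$outlier_fraction > 0 && spec$outlier_magnitude > 0) {
    cid <- 0L
    for (col in .hn_volume_columns()) {
      cid <- cid + 1L
      region <- sub("_(left|right)$", "", col)
      p <- spec$region_params[[region]][[sx]]
      k <- round(spec$outlier_fraction * n)
      if (k == 0) next
      .hn_set_stream(seed, base_id + 300L + cid)
      rows <- sample.int(n, k)
      signs <- ifelse(stats::runif(k) < 0.5, -1, 1)
      out[[col]][rows] <- out[[col]][rows] +
        signs * spec$outlier_magnitude * p$sd
    }
  }

  out$hypertension <- hypertension
  out$smoking <- smoking
  out$bmi <- bmi
  out$education <- education
  out$handedness <- handedness
  out$excluded_selfreport <- excluded_selfreport
  out
}

#' Write a cohort table to a CSV file
#'
#' Plain UTF-8 CSV with one header row and empty fields for missing values;
#' round-trips through [read_cohort()].
#'
#' @param cohort a cohort table.
#' @param path file path to write.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  .hn_assert_cohort(cohort)
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE,
                   na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a cohort table from CSV
#'
#' Validates the schema: all mandatory columns must be present and numeric
#' columns must parse; violations raise an error naming the offending
#' columns (and row, for a non-numeric value).
#'
#' @param path file path.
#' @return a `cohort_table`.
#' @export
read_cohort <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  missing_cols <- setdiff(.hn_required_columns(), names(raw))
  if (length(missing_cols) > 0) {
    stop("cohort file is missing mandatory columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  num_cols <- c("age", "scan_date", "head_scaling", .hn_volume_columns(),
                "bmi")
  for (col in num_cols) {
    v <- raw[[col]]
    parsed <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & nzchar(v) & is.na(parsed))
    if (length(bad) > 0) {
      stop("non-numeric value in column `", col, "` at row ", bad[1],
           ": \"", v[bad[1]], "\"", call. = FALSE)
    }
    raw[[col]] <- parsed
  }
  for (col in c("hypertension", "excluded_selfreport")) {
    raw[[col]] <- as.logical(raw[[col]])
  }
  cohort <- raw[, .hn_required_columns()]
  class(cohort) <- c("cohort_table", "data.frame")
  cohort
}
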