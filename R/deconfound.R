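# Outlier exclusion and confound regression.
#
# Volumes are screened per region with a median-absolute-deviation distance
# (robust analogue of a z-score; cut-off 5 by convention) and then corrected
# for nuisance variables by subtracting fitted linear effects: scanner drift
# over scan date, head scaling (volumetric scaling to standard space,
# inversely related to head size), and optionally age. Correction is by
# regression, not by ratio, because regional volumes do not all scale
# proportionately with head size.

#' Flag outliers by MAD-denominated distance from the median
#'
#' Computes `|x - median(x)| / MAD(x)` with the *unscaled* MAD
#' (`median(|x - median(x)|)`, no 1.4826 consistency factor; set
#' `scale_factor = 1.4826` for the Gaussian-consistent convention) and
#' excludes values whose distance exceeds `cutoff`. When the MAD is zero the
#' distance is undefined; nothing is excluded and a warning is emitted.
#'
#' @param values numeric vector with at least one finite value.
#' @param cutoff exclusion threshold on the MAD distance (default 5).
#' @param scale_factor multiplier applied to the raw MAD (default 1).
#' @return an `outlier_mask`: list with `excluded` (logical), `distance`,
#'   `cutoff`.
#' @export
mad_filter <- function(values, cutoff = 5, scale_factor = 1) {
  if (length(values) == 0 || !any(is.finite(values))) {
    stop("`values` must contain at least one finite value", call. = FALSE)
  }
  med <- stats::median(values, na.rm = TRUE)
  mad0 <- stats::median(abs(values - med), na.rm = TRUE) * scale_factor
  if (!is.finite(mad0) || mad0 == 0) {
    warning("MAD is zero; no values excluded", call. = FALSE)
    out <- list(excluded = rep(FALSE, length(values)),
                distance = rep(NA_real_, length(values)),
                cutoff = cutoff)
  } else {
    distance <- abs(values - med) / mad0
    excluded <- !is.na(distance) & distance > cutoff
    out <- list(excluded = excluded, distance = distance, cutoff = cutoff)
  }
  class(out) <- "outlier_mask"
  out
}

#' Fit a linear confound model for one region
#'
#' Ordinary least-squares regression of the (included) volumes on the
#' requested confounds plus an intercept; the fitted slopes are later
#' subtracted by [apply_deconfound()]. The head-scaling reference value
#' defaults to the published constant 1.29874 so that correction is neutral
#' at that scaling; all other confounds default to their sample mean, which
#' makes the correction mean-preserving.
#'
#' @param cohort a cohort table.
#' @param region region name (see [cohort_volume()]).
#' @param confounds character subset of `c("scan_date", "head_scaling",
#'   "age")`.
#' @param hemisphere hemisphere convention passed to [cohort_volume()].
#' @param include optional logical mask of rows to fit on (e.g. the
#'   complement of an outlier mask); defaults to all rows.
#' @param reference optional named numeric vector overriding reference
#'   values per confound.
#' @return a `deconfound_model`: region, confounds, `slopes`, `reference`,
#'   `grand_mean`, `n`.
#' @export
fit_confound_model <- function(cohort, region,
                               confounds = c("scan_date", "head_scaling"),
                               hemisphere = "average",
                               include = NULL,
                               reference = NULL) {
  .hn_assert_cohort(cohort)
  if (length(confounds) == 0) stop("no confounds given", call. = FALSE)
  bad <- setdiff(confounds, c("scan_date", "head_scaling", "age"))
  if (length(bad) > 0) {
    stop("unknown confounds: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  v <- cohort_volume(cohort, region, hemisphere)
  if (is.null(include)) include <- rep(TRUE, length(v))
  include <- include & !is.na(v)
  X <- as.matrix(as.data.frame(cohort)[include, confounds, drop = FALSE])
  y <- v[include]
  if (nrow(X) < length(confounds) + 2) {
    stop("too few included rows to fit ", length(confounds), " confounds",
         call. = FALSE)
  }
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant confound(s): ",
         paste(confounds[sds == 0], collapse = ", "), call. = FALSE)
  }
  D <- cbind(`(intercept)` = 1, X)
  q <- qr(D)
  if (q$rank < ncol(D)) {
    dropped <- colnames(D)[q$pivot[(q$rank + 1):ncol(D)]]
    stop("rank-deficient confound design; collinear term(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  beta <- qr.coef(q, y)
  slopes <- beta[-1]
  names(slopes) <- confounds
  ref <- colMeans(X)
  if ("head_scaling" %in% confounds) {
    ref[["head_scaling"]] <- 1.29874
  }
  if (!is.null(reference)) {
    ref[names(reference)] <- reference
  }
  out <- list(region = region, hemisphere = hemisphere,
              confounds = confounds, slopes = slopes, reference = ref,
              grand_mean = mean(y), n = length(y))
  class(out) <- "deconfound_model"
  out
}

#' Apply a fitted confound model
#'
#' Subtracts the fitted linear confound effects:
#' `corrected = volume - sum_c slope_c * (confound_c - reference_c)`.
#' The correction is linear and order-independent across confounds, and is
#' the identity for a row whose confounds all sit at their reference values
#' (e.g. head scaling exactly 1.29874 in a head-scaling-only model). Rows
#' with a missing confound value yield `NA` and are flagged, never silently
#' dropped.
#'
#' @param volumes numeric vector of uncorrected volumes (mm^3).
#' @param model a `deconfound_model`.
#' @param data data frame holding the model's confound columns, with rows
#'   aligned to `volumes`.
#' @return corrected volumes; rows with missing confounds are `NA` and their
#'   indices are attached as attribute `"flagged"`.
#' @export
apply_deconfound <- function(volumes, model, data) {
  stopifnot(inherits(model, "deconfound_model"))
  missing_cols <- setdiff(model$confounds, names(data))
  if (length(missing_cols) > 0) {
    stop("data lacks confound column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  adj <- numeric(length(volumes))
  for (cf in model$confounds) {
    adj <- adj + model$slopes[[cf]] * (data[[cf]] - model$reference[[cf]])
  }
  corrected <- volumes - adj
  flagged <- which(is.na(adj) & !is.na(volumes))
  if (length(flagged) > 0) {
    warning(length(flagged),
            " row(s) had missing confound values and were flagged",
            call. = FALSE)
    attr(corrected, "flagged") <- flagged
  }
  corrected
}

#' Serialise a deconfound model to a small table
#'
#' One row per confound: region, confound, slope `b`, reference value.
#'
#' @param x a `deconfound_model`.
#' @param ... unused.
#' @return data frame.
#' @export
as.data.frame.deconfound_model <- function(x, ...) {
  data.frame(region = x$region, hemisphere = x$hemisphere,
             confound = x$confounds,
             b = unname(x$slopes[x$confounds]),
             reference = unname(x$reference[x$confounds]),
             row.names = NULL)
}

# Shared preparation step for the curve modules: subset to one sex, drop
# self-report exclusions, flag per-region outliers on the raw volume, fit
# and apply the requested confound correction.
.hn_prepare_volume <- function(cohort, region, sex, hemisphere,
                               correction = c("scan_date", "head_scaling"),
                               mad_cutoff = 5) {
  .hn_assert_cohort(cohort)
  sex <- .hn_match_sex(sex)
  rows <- which(cohort$sex == sex & !cohort$excluded_selfreport)
  sub <- cohort[rows, , drop = FALSE]
  v <- cohort_volume(sub, region, hemisphere)
  mask <- suppressWarnings(mad_filter(v, cutoff = mad_cutoff))
  include <- !mask$excluded
  model <- NULL
  if (length(correction) > 0) {
    model <- fit_confound_model(sub, region, confounds = correction,
                                hemisphere = hemisphere, include = include)
    v <- apply_deconfound(v, model, sub)
  }
  list(rows = rows, data = sub, volume = v, include = include,
       model = model, mask = mask)
}
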