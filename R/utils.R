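# Internal helpers shared across modules.

# Paired grey-matter regions modelled per hemisphere; total grey matter is a
# single column.
.hn_regions <- c(
  "hippocampus", "superior_temporal", "middle_temporal", "inferior_temporal",
  "fusiform", "parahippocampal", "temporal_pole"
)

.hn_volume_columns <- function() {
  c(as.vector(t(outer(.hn_regions, c("_left", "_right"), paste0))),
    "total_grey_matter")
}

.hn_required_columns <- function() {
  c("participant_id", "age", "sex", "scan_date", "head_scaling",
    .hn_volume_columns(),
    "hypertension", "smoking", "bmi", "education", "handedness",
    "excluded_selfreport")
}

# Deterministic per-stream seeding: every random column draws from its own
# stream derived from the master seed, so adding a column never perturbs the
# others. Seeds stay below 2^31 - 1.
.hn_stream_seed <- function(seed, id) {
  s <- (as.numeric(seed) %% 2147483647) * 2654435761 + id * 40503
  as.integer(s %% 2147483629) + 1L
}

.hn_set_stream <- function(seed, id) {
  set.seed(.hn_stream_seed(seed, id))
}

# Triangular density on [lo, hi] with the given mode, sampled by inverse CDF.
.hn_rtriangular <- function(n, lo, hi, mode) {
  u <- stats::runif(n)
  fc <- (mode - lo) / (hi - lo)
  x <- ifelse(
    u < fc,
    lo + sqrt(u * (hi - lo) * (mode - lo)),
    hi - sqrt((1 - u) * (hi - lo) * (hi - mode))
  )
  x
}

.hn_match_sex <- function(sex) {
  match.arg(tolower(sex), c("female", "male"))
}

.hn_empty_cohort <- function() {
  cols <- .hn_required_columns()
  out <- as.data.frame(
    stats::setNames(replicate(length(cols), numeric(0), simplify = FALSE),
                    cols)
  )
  out$participant_id <- character(0)
  out$sex <- character(0)
  out$smoking <- character(0)
  out$education <- character(0)
  out$handedness <- character(0)
  out$hypertension <- logical(0)
  out$excluded_selfreport <- logical(0)
  out
}

.hn_is_cohort <- function(x) {
  is.data.frame(x) && all(.hn_required_columns() %in% names(x))
}

.hn_assert_cohort <- function(x) {
  if (!is.data.frame(x)) stop("`cohort` must be a data frame", call. = FALSE)
  missing_cols <- setdiff(.hn_required_columns(), names(x))
  if (length(missing_cols) > 0) {
    stop("cohort is missing mandatory columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  invisible(x)
}

#' Extract a volume vector from a cohort table
#'
#' Convenience accessor for regional volumes. Paired regions can be returned
#' as the left or right hemisphere, their sum (`"bilateral"`), or their mean
#' (`"average"`, the convention used for summary tables). For
#' `"total_grey_matter"` the hemisphere argument is ignored.
#'
#' @param cohort a cohort table (see [generate_cohort()]).
#' @param region one of `"hippocampus"`, `"superior_temporal"`,
#'   `"middle_temporal"`, `"inferior_temporal"`, `"fusiform"`,
#'   `"parahippocampal"`, `"temporal_pole"`, or `"total_grey_matter"`.
#' @param hemisphere `"average"`, `"left"`, `"right"`, or `"bilateral"`.
#' @return numeric vector of volumes in mm^3, one per row of `cohort`.
#' @export
cohort_volume <- function(cohort, region,
                          hemisphere = c("average", "left", "right",
                                         "bilateral")) {
  .hn_assert_cohort(cohort)
  hemisphere <- match.arg(hemisphere)
  if (region == "total_grey_matter") {
    return(cohort[["total_grey_matter"]])
  }
  if (!region %in% .hn_regions) {
    stop("unknown region: ", region, call. = FALSE)
  }
  l <- cohort[[paste0(region, "_left")]]
  r <- cohort[[paste0(region, "_right")]]
  switch(hemisphere,
         left = l,
         right = r,
         bilateral = l + r,
         average = (l + r) / 2)
}
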