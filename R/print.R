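# Compact print methods.

#' @export
print.cohort_spec <- function(x, ...) {
  cat("Synthetic cohort specification\n")
  cat("  n:", x$n_female, "female /", x$n_male, "male\n")
  cat("  ages:", x$age_range[1], "-", x$age_range[2],
      "(mode", paste0(x$age_mode, ")"), "\n")
  cat("  regions:", paste(names(x$region_params), collapse = ", "), "\n")
  cat("  outliers:", x$outlier_fraction, "at", x$outlier_magnitude,
      "SD; seed", x$seed, "\n")
  invisible(x)
}

#' @export
print.deconfound_model <- function(x, ...) {
  cat("Confound model for", x$region, paste0("(", x$hemisphere, ")"),
      "on", x$n, "rows\n")
  print(as.data.frame(x))
  invisible(x)
}

#' @export
print.nomogram <- function(x, ...) {
  cat("Nomogram:", x$region, paste0("(", x$hemisphere, "),"), x$sex, "\n")
  cat("  correction:", paste(x$correction, collapse = " + "), "\n")
  cat("  windows:", length(x$age), "of", round(x$fraction * 100),
      "% each; kernel SD", x$kernel_sd, "\n")
  cat("  age span:", round(min(x$age), 1), "-", round(max(x$age), 1),
      "years; n =", x$n, "\n")
  invisible(x)
}

#' @export
print.joinpoint_model <- function(x, ...) {
  cat("Joinpoint model:", x$k, "joinpoint(s) selected",
      paste0("(ladder p: ",
             paste(formatC(x$p_perm, digits = 3, format = "g"),
                   collapse = ", "), ")"), "\n")
  if (x$k > 0) print(as.data.frame(x))
  invisible(x)
}

#' @export
print.effect_size_result <- function(x, ...) {
  cat(x$design, "comparison", if (nzchar(x$label)) x$label else "", "\n")
  cat(sprintf("  g = %.3f, t = %.3f, p = %.4g (alpha_bonf = %.4g)\n",
              x$g, x$t, x$p, x$alpha_bonferroni))
  invisible(x)
}

#' @export
print.peak_permutation_test <- function(x, ...) {
  cat("Permutation test for sex difference in peak-ratio age\n")
  print(x$results)
  invisible(x)
}

#' Plot a nomogram
#'
#' Base-graphics chart of the smoothed quantile curves against age, median
#' emphasised.
#'
#' @param x a `nomogram`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.nomogram <- function(x, ...) {
  graphics::matplot(x$age, t(x$curves), type = "l", lty = 1,
                    col = "grey40",
                    xlab = "Age (years)", ylab = "Volume (mm³)",
                    main = paste0(x$region, " (", x$hemisphere, "), ",
                                  x$sex), ...)
  med <- which(x$levels == 50)
  if (length(med) == 1) {
    graphics::lines(x$age, x$curves[med, ], lwd = 2)
  }
  invisible(x)
}
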