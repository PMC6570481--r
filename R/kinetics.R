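#' Fit a phosphorylation rate from an assay time course
#'
#' The rate is the slope of the ordinary-least-squares regression of
#' scintillation counts (CPM) on incubation time, i.e. the initial-rate
#' estimate from a linear time course.
#'
#' @param tc A time-course data frame with columns `time_min` and `cpm`
#'   (as from [simulate_timecourse()] or [read_timecourse_csv()]), or two
#'   numeric vectors via `times`/`counts`.
#' @param times,counts Alternative vector interface.
#' @return Object of class `RateEstimate`: `slope` (CPM/min),
#'   `intercept`, `slope_se`, `r_squared`, `n_points`, `label`.
#' @examples
#' fit_rate(times = c(0, 5, 10, 15, 20), counts = 100 + 10 * c(0, 5, 10, 15, 20))
#' @export
fit_rate <- function(tc = NULL, times = NULL, counts = NULL) {
  if (!is.null(tc)) {
    tc <- as.data.frame(tc)
    times <- tc$time_min
    counts <- tc$cpm
    label <- tc$label[1L] %||% "timecourse"
  } else {
    label <- "timecourse"
  }
  if (length(times) != length(counts) || length(times) < 2L) {
    stop_opls("input", "need matched times and counts of length >= 2")
  }
  if (length(unique(times)) < 2L) {
    stop_opls("degenerate", "all timepoints identical; slope undefined")
  }
  fit <- lm(counts ~ times)
  # noiseless fixtures fit exactly; that is expected, not a problem
  sm <- withCallingHandlers(
    summary(fit),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  structure(
    list(slope = unname(coef(fit)[2L]),
         intercept = unname(coef(fit)[1L]),
         slope_se = unname(sm$coefficients[2L, 2L]),
         r_squared = sm$r.squared,
         n_points = length(times),
         label = label),
    class = "RateEstimate"
  )
}

#' @export
print.RateEstimate <- function(x, ...) {
  cat(sprintf("RateEstimate (%s): slope %.4g CPM/min (SE %.3g), intercept %.4g, r^2 %.4f, n = %d\n",
              x$label, x$slope, x$slope_se, x$intercept, x$r_squared,
              x$n_points))
  invisible(x)
}

slopes_of <- function(group) {
  vapply(group, function(r) {
    if (inherits(r, "RateEstimate")) r$slope else as.numeric(r)
  }, 0)
}

#' Compare phosphorylation rates between substrate groups
#'
#' The unit of replication is the per-replicate fitted slope. Two groups
#' are compared by a two-sample Student's t-test (paired optional); more
#' than two by one-way ANOVA with Tukey HSD post-hoc pairwise
#' comparisons. Effect sizes are reported as slope ratios of group means.
#' Groups with a single replicate, or pairs with zero combined variance,
#' yield descriptive output with a warning instead of a test.
#'
#' @param groups Named list: each element a list of [fit_rate()] results
#'   (or a numeric vector of slopes).
#' @param paired For the two-group case: paired t-test?
#' @return Object of class `RateComparison`: `group_means`, `method`
#'   (`"t.test"`, `"anova"` or `"descriptive"`), `p_value` (overall),
#'   `statistic`, `pairwise` (data frame: pair, difference, ratio,
#'   p_value).
#' @export
compare_rates <- function(groups, paired = FALSE) {
  if (!is.list(groups) || length(groups) < 2L || is.null(names(groups))) {
    stop_opls("input", "groups must be a named list of >= 2 rate sets")
  }
  slopes <- lapply(groups, slopes_of)
  means <- vapply(slopes, mean, 0)
  labels <- names(groups)
  pairs <- utils::combn(labels, 2L)
  ratio <- apply(pairs, 2L, function(p) means[p[1L]] / means[p[2L]])
  diff <- apply(pairs, 2L, function(p) means[p[1L]] - means[p[2L]])
  pairwise <- data.frame(pair = apply(pairs, 2L, paste, collapse = " vs "),
                         difference = diff, ratio = ratio,
                         p_value = NA_real_, stringsAsFactors = FALSE)
  if (any(lengths(slopes) < 2L)) {
    warning("group(s) with a single replicate: descriptive output only",
            call. = FALSE)
    return(structure(list(group_means = means, method = "descriptive",
                          p_value = NA_real_, statistic = NA_real_,
                          pairwise = pairwise),
                     class = "RateComparison"))
  }
  if (length(groups) == 2L) {
    tt <- tryCatch(
      t.test(slopes[[1L]], slopes[[2L]], paired = paired),
      error = function(e) NULL)
    if (is.null(tt)) {
      warning("degenerate within-group variance; t-test unavailable, descriptive output only",
              call. = FALSE)
      return(structure(list(group_means = means, method = "descriptive",
                            p_value = NA_real_, statistic = NA_real_,
                            pairwise = pairwise),
                       class = "RateComparison"))
    }
    pairwise$p_value <- tt$p.value
    return(structure(list(group_means = means, method = "t.test",
                          p_value = tt$p.value,
                          statistic = unname(tt$statistic),
                          pairwise = pairwise),
                     class = "RateComparison"))
  }
  df <- data.frame(
    slope = unlist(slopes, use.names = FALSE),
    group = factor(rep(labels, lengths(slopes)), levels = labels))
  fit <- aov(slope ~ group, data = df)
  an <- summary(fit)[[1L]]
  tk <- TukeyHSD(fit)$group
  # Tukey labels are "b-a"; map back to our pair order
  for (i in seq_len(ncol(pairs))) {
    lab1 <- paste(pairs[2L, i], pairs[1L, i], sep = "-")
    lab2 <- paste(pairs[1L, i], pairs[2L, i], sep = "-")
    row <- if (lab1 %in% rownames(tk)) lab1 else lab2
    pairwise$p_value[i] <- tk[row, "p adj"]
  }
  structure(list(group_means = means, method = "anova",
                 p_value = an[["Pr(>F)"]][1L],
                 statistic = an[["F value"]][1L],
                 pairwise = pairwise),
            class = "RateComparison")
}

#' @export
print.RateComparison <- function(x, ...) {
  cat(sprintf("RateComparison (%s): overall p = %.3g\n", x$method,
              x$p_value))
  cat("  group means:",
      paste(sprintf("%s=%.4g", names(x$group_means), x$group_means),
            collapse = ", "), "\n")
  print(x$pairwise, row.names = FALSE)
  invisible(x)
}
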