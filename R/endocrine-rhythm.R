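# Circadian rhythm disturbance (CRD) classification for cortisol/ACTH
# three-timepoint profiles (08:00, 16:00, 24:00), diurnal slope, and cohort
# incidence summaries.

#' Classify circadian rhythm disturbance from a hormone profile
#'
#' A healthy profile roughly halves across the day; a profile is flagged
#' disturbed when a later draw fails to fall below `threshold` (default 50%)
#' of an earlier draw: c16 >= threshold*c8 ("16v8"), c24 >= threshold*c16
#' ("24v16"), or c24 >= threshold*c8 ("24v8"). Comparisons are inclusive at
#' the boundary. The verdict is scale-invariant in the concentrations.
#'
#' Vectorized over profiles.
#'
#' @param c8,c16,c24 Positive concentrations at 08:00, 16:00, 24:00
#'   (same unit within a profile, e.g. nmol/L for cortisol, pg/mL for ACTH).
#' @param threshold Decline threshold as a proportion (default 0.5).
#' @param rules Subset of c("16v8", "24v16", "24v8") to evaluate.
#' @return data.frame with the three decline ratios, per-rule violation flags
#'   (`viol_*`, NA for rules not evaluated), and `disturbed` (TRUE iff some
#'   evaluated rule is violated).
#' @export
classify_rhythm <- function(c8, c16, c24, threshold = 0.5,
                            rules = c("16v8", "24v16", "24v8")) {
  rules <- match.arg(rules, several.ok = TRUE)
  threshold <- check_scalar(threshold, "threshold", lower = 0)
  vals <- cbind(c8, c16, c24)
  if (anyNA(vals) || any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all three concentrations must be finite and > 0", call. = FALSE)
  }
  out <- data.frame(ratio_16v8 = c16 / c8,
                    ratio_24v16 = c24 / c16,
                    ratio_24v8 = c24 / c8)
  out$viol_16v8 <- if ("16v8" %in% rules) out$ratio_16v8 >= threshold else NA
  out$viol_24v16 <- if ("24v16" %in% rules) out$ratio_24v16 >= threshold else NA
  out$viol_24v8 <- if ("24v8" %in% rules) out$ratio_24v8 >= threshold else NA
  viol <- cbind(out$viol_16v8, out$viol_24v16, out$viol_24v8)
  out$disturbed <- apply(viol, 1L, function(v) any(v, na.rm = TRUE))
  out
}

#' Diurnal hormone slope
#'
#' Rate of decline of the concentration from morning to midnight. The default
#' two-point definition is (c8 - c24) / 16 h (positive = declining); the
#' regression definition fits concentration on clock time over all three
#' draws and negates the slope. The two agree exactly when the three points
#' are collinear in time.
#'
#' @inheritParams classify_rhythm
#' @param method "two_point" or "regression".
#' @return Numeric slope(s), concentration units per hour.
#' @export
diurnal_slope <- function(c8, c16, c24, method = c("two_point", "regression")) {
  method <- match.arg(method)
  vals <- cbind(c8, c16, c24)
  if (anyNA(vals) || any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all three concentrations must be finite and > 0", call. = FALSE)
  }
  if (method == "two_point") {
    (c8 - c24) / 16
  } else {
    tt <- c(8, 16, 24)
    tc <- tt - mean(tt)
    denom <- sum(tc^2)
    -as.numeric(vals %*% tc) / denom
  }
}

#' Cohort incidence of circadian rhythm disturbance
#'
#' Classifies every profile, reports the disturbed fraction per analyte (and
#' per group when a `group` column is present), and tests the 2x2
#' disturbed-by-group table per analyte with Pearson's chi-square
#' (no continuity correction by default).
#'
#' @param profiles data.frame with columns `c8`, `c16`, `c24`, and optionally
#'   `subject_id`, `analyte`, `group`.
#' @inheritParams classify_rhythm
#' @param correct Apply Yates continuity correction (default FALSE).
#' @return List: `incidence` (data.frame: analyte, group, n, n_disturbed,
#'   incidence in percent), `tables` (2x2 per analyte, when groups exist),
#'   `chi_square` (data.frame: analyte, statistic, df, p_value), `verdicts`.
#' @export
cohort_incidence <- function(profiles, threshold = 0.5,
                             rules = c("16v8", "24v16", "24v8"),
                             correct = FALSE) {
  stopifnot(is.data.frame(profiles), all(c("c8", "c16", "c24") %in% names(profiles)))
  if (nrow(profiles) == 0L) stop("empty profile set", call. = FALSE)
  analyte <- if (!is.null(profiles[["analyte"]])) as.character(profiles$analyte)
             else rep("COR", nrow(profiles))
  group <- if (!is.null(profiles[["group"]])) as.character(profiles$group) else NULL
  if (!is.null(group) && any(table(group) < 1L)) stop("empty group", call. = FALSE)
  v <- classify_rhythm(profiles$c8, profiles$c16, profiles$c24,
                       threshold = threshold, rules = rules)
  grp_vec <- if (is.null(group)) rep("all", nrow(profiles)) else group
  inc <- do.call(rbind, lapply(split(seq_len(nrow(profiles)),
                                     list(analyte = analyte, group = grp_vec),
                                     drop = TRUE), function(ix) {
    data.frame(analyte = analyte[ix[1L]], group = grp_vec[ix[1L]],
               n = length(ix), n_disturbed = sum(v$disturbed[ix]),
               incidence = 100 * mean(v$disturbed[ix]),
               stringsAsFactors = FALSE)
  }))
  rownames(inc) <- NULL
  inc <- inc[order(inc$analyte, inc$group), ]
  tables <- NULL
  chi <- NULL
  if (!is.null(group) && length(unique(group)) == 2L) {
    tables <- list()
    chi <- list()
    for (an in unique(analyte)) {
      ix <- analyte == an
      tab <- table(disturbed = factor(v$disturbed[ix], levels = c(TRUE, FALSE)),
                   group = group[ix])
      tables[[an]] <- tab
      if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
        # a zero margin carries no association: statistic 0 by convention
        chi[[an]] <- data.frame(analyte = an, statistic = 0, df = 1,
                                p_value = 1, stringsAsFactors = FALSE)
      } else {
        ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
        chi[[an]] <- data.frame(analyte = an, statistic = unname(ct$statistic),
                                df = unname(ct$parameter), p_value = ct$p.value,
                                stringsAsFactors = FALSE)
      }
    }
    chi <- do.call(rbind, chi)
    rownames(chi) <- NULL
  }
  list(incidence = inc, tables = tables, chi_square = chi, verdicts = v)
}

#' Two-sample Welch t-test utility
#'
#' Thin wrapper over [stats::t.test()] for the group-comparison harness
#' (e.g. morning cortisol or diurnal slope between subtype groups).
#'
#' @param x,y Numeric samples.
#' @return data.frame with `t`, `df`, `p_value`, `mean_x`, `mean_y`.
#' @export
welch_t <- function(x, y) {
  tt <- stats::t.test(x, y)
  data.frame(t = unname(tt$statistic), df = unname(tt$parameter),
             p_value = tt$p.value,
             mean_x = unname(tt$estimate[1L]), mean_y = unname(tt$estimate[2L]))
}
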