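# Domain-coalescence time courses, the domain-number-ratio statistic,
# initial-count categories and the group-comparison tests used for
# condition contrasts (bare vs NPF-coated vs actin-covered GUVs).

#' Build a domain-count trajectory
#'
#' Assembles per-frame Ld-domain counts into a time course and computes
#' the domain number ratio N_t / N_0 at t = 10 and 60 min, each taken
#' from the nearest frame within +/- 2 min.  A ratio of 1 means full
#' stabilization; the minimum indicates complete coalescence.  Ratios
#' above 1 (counting noise; the model forbids domain fission) are
#' clipped to 1 with a warning.
#'
#' @param domain_sets List of `domain_set` objects (one per frame), or a
#'   numeric vector of per-frame counts.
#' @param times_min Frame times in minutes (t = 0 at the demixing /
#'   first-acquisition frame).
#' @param condition One of `"bare"`, `"spvca"`, `"actin"`.
#' @param t_tol_min Nearest-frame tolerance (default 2 min).
#' @return Object of class `domain_trajectory` with `counts`, `N0`,
#'   `N10`, `N60`, `ratio_10`, `ratio_60`, `initial_group` and flags.
#' @export
build_trajectory <- function(domain_sets, times_min,
                             condition = c("bare", "spvca", "actin"),
                             t_tol_min = 2) {
  condition <- match.arg(condition)
  counts <- if (is.numeric(domain_sets)) as.numeric(domain_sets) else
    vapply(domain_sets, function(d) as.numeric(d$n_d), 1.0)
  if (length(counts) < 2L) stop_validation("need >= 2 frames")
  if (length(counts) != length(times_min)) {
    stop_validation("counts and times must have equal length")
  }
  o <- order(times_min)
  times_min <- times_min[o]
  counts <- counts[o]
  if (any(counts < 0)) stop_validation("counts must be >= 0")

  nearest <- function(target) {
    i <- which.min(abs(times_min - target))
    if (abs(times_min[i] - target) <= t_tol_min) counts[i] else NA_real_
  }
  n0 <- nearest(0)
  if (is.na(n0)) stop_validation("no frame within tolerance of t = 0")
  n10 <- nearest(10)
  n60 <- nearest(60)
  flagged <- n0 == 0
  ratio <- function(nt) {
    if (is.na(nt) || n0 == 0) return(NA_real_)
    r <- nt / n0
    if (r > 1) {
      warning("domain count increased; ratio clipped to 1", call. = FALSE)
      r <- 1
    }
    r
  }
  structure(
    list(times_min = times_min, counts = counts,
         N0 = n0, N10 = n10, N60 = n60,
         ratio_10 = ratio(n10), ratio_60 = ratio(n60),
         condition = condition,
         initial_group = if (n0 >= 32 && n0 <= 36) "32-36"
                         else if (n0 >= 8 && n0 <= 12) "8-12" else "other",
         flagged = flagged,
         missing_60 = is.na(n60)),
    class = "domain_trajectory"
  )
}

#' Categorize trajectories by initial domain number
#'
#' Three categories of phase-separated GUVs based on the initial Ld
#' domain count n_d: (a) n_d = 2, (b) 2 < n_d <= 10 (upper bound
#' inclusive), (c) n_d > 10.  Trajectories with N0 < 2 (already fully
#' coalesced at t = 0) are grouped with category (a).
#'
#' @param trajectories List of `domain_trajectory` objects.
#' @return Named list of trajectory lists (`"nd_eq_2"`, `"nd_3_10"`,
#'   `"nd_gt_10"`), with an `nd_category` factor attached as attribute.
#' @export
categorize_by_nd <- function(trajectories) {
  n0 <- vapply(trajectories, function(t) t$N0, 1.0)
  cat <- ifelse(n0 <= 2, "nd_eq_2", ifelse(n0 <= 10, "nd_3_10", "nd_gt_10"))
  out <- list(
    nd_eq_2 = trajectories[cat == "nd_eq_2"],
    nd_3_10 = trajectories[cat == "nd_3_10"],
    nd_gt_10 = trajectories[cat == "nd_gt_10"]
  )
  attr(out, "nd_category") <- factor(cat,
    levels = c("nd_eq_2", "nd_3_10", "nd_gt_10"))
  out
}

#' Significance tier for a p-value
#'
#' Standard tiers: n.s. p > 0.05; * p <= 0.05; ** p <= 0.01;
#' *** p <= 0.001.
#'
#' @param p p-value in `[0, 1]`.
#' @return One of `"n.s."`, `"*"`, `"**"`, `"***"`.
#' @export
significance_tier <- function(p) {
  stopifnot(p >= 0, p <= 1)
  if (p <= 0.001) "***" else if (p <= 0.01) "**" else if (p <= 0.05) "*"
  else "n.s."
}

#' Two-group comparison with the design-appropriate test
#'
#' Independent samples without a normality assumption are compared with
#' a two-sided Mann-Whitney U test (exact for n <= 8 per group without
#' ties, normal approximation with tie correction otherwise); paired
#' samples with a Wilcoxon signed-rank test; independent samples under
#' normality with Welch's t-test.
#'
#' @param x,y Numeric vectors (>= 3 values each).
#' @param design `"independent"` or `"paired"`.
#' @param normality_assumed Use Welch's t-test for independent designs?
#' @param labels Optional length-2 group labels.
#' @return Object of class `group_comparison` with `test`, `statistic`,
#'   `p_value`, `tier`.
#' @export
compare_groups <- function(x, y, design = c("independent", "paired"),
                           normality_assumed = FALSE,
                           labels = c("group1", "group2")) {
  design <- match.arg(design)
  if (length(x) < 3L || length(y) < 3L) {
    stop_validation("need >= 3 values per group")
  }
  if (design == "paired" && length(x) != length(y)) {
    stop_validation("paired design requires equal group lengths")
  }
  if (design == "paired") {
    ht <- suppressWarnings(stats::wilcox.test(x, y, paired = TRUE))
    test <- "wilcoxon_signed_rank"
  } else if (normality_assumed) {
    ht <- stats::t.test(x, y, var.equal = FALSE)
    test <- "welch_t"
  } else {
    exact <- length(x) <= 8 && length(y) <= 8 &&
      !anyDuplicated(c(x, y))
    ht <- suppressWarnings(
      stats::wilcox.test(x, y, exact = exact, correct = !exact))
    test <- "mann_whitney_u"
  }
  structure(
    list(labels = labels, test = test,
         statistic = unname(ht$statistic),
         p_value = ht$p.value,
         tier = significance_tier(ht$p.value),
         values = list(x = x, y = y)),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s vs %s: %s, statistic = %.4g, p = %.4g (%s)\n",
              x$labels[1], x$labels[2], x$test, x$statistic, x$p_value,
              x$tier))
  invisible(x)
}

#' Trajectories as a summary table
#'
#' @param trajectories List of `domain_trajectory` objects.
#' @return data.frame with one row per trajectory.
#' @export
trajectory_table <- function(trajectories) {
  do.call(rbind, lapply(seq_along(trajectories), function(i) {
    t <- trajectories[[i]]
    data.frame(id = i, condition = t$condition, N0 = t$N0, N10 = t$N10,
               N60 = t$N60, ratio_10 = t$ratio_10, ratio_60 = t$ratio_60,
               initial_group = t$initial_group, flagged = t$flagged,
               stringsAsFactors = FALSE)
  }))
}
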