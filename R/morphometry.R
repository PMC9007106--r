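# Histology-derived statistics: fiber cross-sectional area (CSA)
# distributions, 3-SD size classification against a control group,
# labeled-cell count ratios, and the group comparisons used throughout
# (t-test; one-way ANOVA with Dunnett's or Tukey's post hoc).

#' Summary statistics for a fiber-area sample
#'
#' @param areas Numeric vector of cross-sectional areas (um^2, positive).
#' @param bin_width Histogram bin width in um^2 (default 200).
#' @return List with `n`, `mean`, `sd` (n-1 denominator), `sem`
#'   (`sd / sqrt(n)`), and `histogram` (data frame `bin_start`,
#'   `bin_end`, `count`, `fraction`; fractions sum to 1). With a single
#'   observation `sd`/`sem` are `NA` with a warning.
#' @examples
#' csa_stats(c(1, 2, 3), bin_width = 1)
#' @export
csa_stats <- function(areas, bin_width = 200) {
  areas <- as.numeric(areas)
  stopifnot(length(areas) >= 1, bin_width > 0)
  if (anyNA(areas) || any(areas <= 0)) stop("areas must be positive")
  n <- length(areas)
  if (n < 2) {
    warning("n < 2: dispersion (sd, sem) undefined, returned as NA")
    s <- NA_real_
  } else {
    s <- stats::sd(areas)
  }
  breaks <- seq(0, bin_width * ceiling(max(areas) / bin_width), by = bin_width)
  if (length(breaks) < 2) breaks <- c(0, bin_width)
  counts <- graphics::hist(areas, breaks = breaks, plot = FALSE,
                           right = FALSE)$counts
  list(n = n, mean = mean(areas), sd = s,
       sem = if (is.na(s)) NA_real_ else s / sqrt(n),
       histogram = data.frame(bin_start = breaks[-length(breaks)],
                              bin_end = breaks[-1], count = counts,
                              fraction = counts / n))
}

#' Classify fiber sizes against control thresholds
#'
#' Thresholds are set at the control group's mean minus and plus
#' `k` standard deviations (lower threshold clamped at 0); the test
#' sample is partitioned into fibers strictly below the lower threshold
#' (`small`), within `[lower, upper]` (`within`; boundary values count as
#' within), and strictly above the upper threshold (`large`).
#'
#' @param test Numeric vector of test-group areas (um^2).
#' @param control Numeric vector of control-group areas (n >= 2).
#' @param k Standard-deviation multiplier (default 3).
#' @return List with `lower`, `upper` (um^2) and `fractions` (named
#'   `small`, `within`, `large`; sums to 1).
#' @examples
#' classify_sizes(c(600, 1000, 1500), rnorm(100, 1000, 100))
#' @export
classify_sizes <- function(test, control, k = 3) {
  test <- as.numeric(test); control <- as.numeric(control)
  stopifnot(length(test) >= 1, k > 0)
  if (length(control) < 2) stop("control needs n >= 2 to estimate SD")
  if (any(test <= 0) || any(control <= 0)) stop("areas must be positive")
  m <- mean(control); s <- stats::sd(control)
  lower <- max(0, m - k * s); upper <- m + k * s
  fr <- c(small = mean(test < lower),
          within = mean(test >= lower & test <= upper),
          large = mean(test > upper))
  list(lower = lower, upper = upper, fractions = fr)
}

#' Labeled-cell count ratio
#'
#' Covers the study's count readouts: immunolabeled cells per 100 fibers
#' (`scale = 100`), myonuclei per fiber (`scale = 1`), and co-label
#' proportions such as H3K27me3+Pax7+ / total Pax7+ (`scale = 1`).
#'
#' @param numerator,denominator Non-negative integer counts
#'   (`denominator > 0`).
#' @param scale 1 or 100.
#' @return List with `numerator`, `denominator`, `scale`, `value`.
#' @examples
#' count_ratio(12, 400, scale = 100)  # 3 cells per 100 fibers
#' @export
count_ratio <- function(numerator, denominator, scale = 1) {
  stopifnot(length(numerator) == 1, length(denominator) == 1,
            scale %in% c(1, 100))
  if (anyNA(c(numerator, denominator)) || numerator < 0 ||
      numerator != floor(numerator) || denominator != floor(denominator)) {
    stop("counts must be non-negative integers")
  }
  if (denominator <= 0) stop("denominator must be positive")
  list(numerator = numerator, denominator = denominator, scale = scale,
       value = scale * numerator / denominator)
}

#' Compare measurement groups
#'
#' Plumbing around the standard tests used for these assays: two-group
#' designs use Student's t-test (or the Mann-Whitney / Wilcoxon rank-sum
#' test); designs with more than two groups fit a one-way ANOVA followed
#' by Dunnett's many-to-one comparisons against the first factor level
#' (via \pkg{multcomp}) or Tukey's all-pairs post hoc. Significance is
#' flagged at p < .05.
#'
#' @param values Numeric vector of measurements.
#' @param group Group label per value (first unique label is the control
#'   / reference for Dunnett).
#' @param design `"two_group"`, `"one_way_dunnett"`, or
#'   `"one_way_tukey"`.
#' @param two_group_test `"t"` (Student's, equal variances) or
#'   `"wilcoxon"` for the two-group design.
#' @return Data frame with one row per comparison: `comparison`,
#'   `estimate` (difference in means / location), `p_value`,
#'   `significant`. For the one-way designs the ANOVA F-test p-value is
#'   attached as attribute `"anova_p"`.
#' @examples
#' group_compare(c(rnorm(8), rnorm(8, 3)), rep(c("a", "b"), each = 8))
#' @export
group_compare <- function(values, group,
                          design = c("two_group", "one_way_dunnett",
                                     "one_way_tukey"),
                          two_group_test = c("t", "wilcoxon")) {
  design <- match.arg(design)
  two_group_test <- match.arg(two_group_test)
  stopifnot(length(values) == length(group))
  group <- factor(group, levels = unique(as.character(group)))
  if (any(table(group) < 2)) stop("every group needs n >= 2")
  ng <- nlevels(group)
  if (ng < 2) stop("need at least two groups")
  if (design == "two_group") {
    if (ng != 2) stop("two_group design requires exactly 2 groups")
    a <- values[group == levels(group)[1]]
    b <- values[group == levels(group)[2]]
    if (two_group_test == "t") {
      tt <- stats::t.test(b, a, var.equal = TRUE)
      est <- mean(b) - mean(a); p <- tt$p.value
    } else {
      wt <- stats::wilcox.test(b, a, exact = FALSE)
      est <- stats::median(b) - stats::median(a); p <- wt$p.value
    }
    out <- data.frame(comparison = paste(levels(group)[2], "-", levels(group)[1]),
                      estimate = est, p_value = p, significant = p < 0.05,
                      stringsAsFactors = FALSE)
    return(out)
  }
  if (ng < 3) {
    stop("one-way designs need more than 2 groups; use design = 'two_group'")
  }
  dat <- data.frame(y = values, g = group)
  fit <- stats::aov(y ~ g, data = dat)
  anova_p <- summary(fit)[[1]][["Pr(>F)"]][1]
  if (design == "one_way_dunnett") {
    gl <- summary(multcomp::glht(fit, linfct = multcomp::mcp(g = "Dunnett")))
    out <- data.frame(comparison = names(gl$test$coefficients),
                      estimate = as.numeric(gl$test$coefficients),
                      p_value = as.numeric(gl$test$pvalues),
                      stringsAsFactors = FALSE)
  } else {
    tk <- stats::TukeyHSD(fit)$g
    out <- data.frame(comparison = rownames(tk), estimate = tk[, "diff"],
                      p_value = tk[, "p adj"], stringsAsFactors = FALSE)
  }
  out$significant <- out$p_value < 0.05
  rownames(out) <- NULL
  attr(out, "anova_p") <- anova_p
  out
}
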