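# Longitudinal change and the statistical toolkit of socket-preservation
# studies: per-position change tables, descriptive aggregation, one-way
# ANOVA + Tukey HSD, Shrout-Fleiss ICC forms, Bland-Altman limits of
# agreement, and a priori t-test sample size.

#' Per-position width change between timepoints
#'
#' Pairs the baseline (`t0`, post-extraction) and follow-up (`t1`,
#' pre-implantation) measurement tables by position label and computes
#' `loss_mm = width_t0 - width_t1`: positive values are resorption, negative
#' values apparent gain. Positions unmeasurable at either timepoint are kept
#' as explicit gaps (`NA`), never dropped.
#'
#' @param t0,t1 measurement data frames from [measure_grid()].
#' @return A data frame: `offset_mm`, `depth_level`, `width_t0_mm`,
#'   `width_t1_mm`, `loss_mm`, `flags`.
#' @export
width_change <- function(t0, t1) {
  key <- function(d) paste(d$offset_mm, d$depth_level)
  if (nrow(t0) != nrow(t1) || !setequal(key(t0), key(t1)))
    stop("timepoints have mismatching measurement positions", call. = FALSE)
  t1 <- t1[match(key(t0), key(t1)), ]
  data.frame(offset_mm = t0$offset_mm, depth_level = t0$depth_level,
             width_t0_mm = t0$width_mm, width_t1_mm = t1$width_mm,
             loss_mm = t0$width_mm - t1$width_mm,
             flags = trimws(paste(t0$flags, t1$flags), whitespace = "[ ;]"),
             stringsAsFactors = FALSE)
}

#' Aggregate change records across subjects per position
#'
#' @param records row-bound [width_change()] tables across subjects (an
#'   optional `scan_pair_id` column identifies subjects).
#' @param value column to aggregate; default `"loss_mm"`.
#' @return A data frame per `(offset_mm, depth_level)` cell: `n` (number of
#'   non-missing records), `mean`, `sd` (denominator `n - 1`; `NA` when
#'   `n < 2`). Cells with no measurable record report `n = 0` and no value.
#' @export
summarize_positions <- function(records, value = "loss_mm") {
  stopifnot(value %in% names(records))
  cells <- unique(records[, c("offset_mm", "depth_level")])
  cells <- cells[order(cells$depth_level, cells$offset_mm), ]
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    v <- records[[value]][records$offset_mm == cells$offset_mm[i] &
                          records$depth_level == cells$depth_level[i]]
    v <- v[!is.na(v)]
    data.frame(offset_mm = cells$offset_mm[i],
               depth_level = cells$depth_level[i],
               n = length(v),
               mean = if (length(v)) mean(v) else NA_real_,
               sd = if (length(v) >= 2) stats::sd(v) else NA_real_)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' One-way ANOVA with Tukey HSD post-hoc comparisons
#'
#' The between-position comparison of the protocol: one-way ANOVA across
#' groups (e.g. depth levels within a horizontal position) followed by
#' Tukey's multiple-comparison test at the given confidence level.
#'
#' @param values numeric observations.
#' @param groups grouping factor (>= 2 groups, >= 2 observations each).
#' @param conf_level confidence level for the Tukey intervals; default 0.95.
#' @return A list: `anova` (`df_between`, `df_within`, `F`, `p`) and
#'   `tukey` (one row per pair: `comparison`, `diff`, `lwr`, `upr`,
#'   `p_adj`).
#' @export
anova_tukey <- function(values, groups, conf_level = 0.95) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L)
    stop("ANOVA needs at least two groups", call. = FALSE)
  if (any(table(groups) < 2L))
    stop("every group needs at least two observations", call. = FALSE)
  fit <- stats::aov(values ~ groups)
  tab <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit, conf.level = conf_level)$groups
  list(anova = data.frame(df_between = tab$Df[1], df_within = tab$Df[2],
                          F = tab$`F value`[1], p = tab$`Pr(>F)`[1]),
       tukey = data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                          lwr = tk[, "lwr"], upr = tk[, "upr"],
                          p_adj = tk[, "p adj"], row.names = NULL))
}

# Shrout-Fleiss ICC forms from the two-way (target x rater) ANOVA mean
# squares of a balanced n x k matrix.
icc_from_matrix <- function(m) {
  n <- nrow(m); k <- ncol(m)
  if (n < 2L || k < 2L)
    stop("ICC needs >= 2 targets and >= 2 raters/measurements", call. = FALSE)
  grand <- mean(m)
  row_m <- rowMeans(m); col_m <- colMeans(m)
  ss_row <- k * sum((row_m - grand)^2)
  ss_col <- n * sum((col_m - grand)^2)
  ss_tot <- sum((m - grand)^2)
  ss_err <- ss_tot - ss_row - ss_col
  msr <- ss_row / (n - 1)
  msc <- ss_col / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  p_of <- function(f, df1, df2)
    if (is.nan(f)) NA_real_ else stats::pf(f, df1, df2, lower.tail = FALSE)
  # degenerate mse = 0 with perfect agreement -> ICC 1 by continuity
  safe <- function(num, den) if (den == 0) ifelse(num == 0, 1, NaN) else num / den
  list(
    icc_single_random = safe(msr - mse, msr + (k - 1) * mse + k * (msc - mse) / n),
    icc_single_fixed = safe(msr - mse, msr + (k - 1) * mse),
    icc_average_random = safe(msr - mse, msr + (msc - mse) / n),
    icc_average_fixed = safe(msr - mse, msr),
    msr = msr, msc = msc, mse = mse,
    p = p_of(if (mse == 0) Inf else msr / mse, n - 1, (n - 1) * (k - 1)))
}

#' Intraclass correlation coefficients for a rater study
#'
#' Inter-rater reliability as the Shrout-Fleiss forms computed from two-way
#' ANOVA mean squares: ICC(2,1) (two-way random, absolute agreement;
#' "single random"), ICC(3,1) (two-way mixed, consistency; "single fixed"),
#' and their average-measures counterparts ICC(2,k)/ICC(3,k). Intra-rater
#' reliability is the two-way (target x repeat) consistency ICC within each
#' rater's repeats.
#'
#' @param ratings either a numeric matrix `targets x raters`, or a 3D array
#'   `subjects x raters x repeats` (balanced). For the 3D form the
#'   inter-rater ICC treats each subject-repeat combination as a target,
#'   pairing raters within rounds (configurable via `repeats_as`).
#' @param repeats_as for 3D input: `"targets"` (default; each repeat round
#'   is a target) or `"mean"` (average repeats per rater first).
#' @return A list with the four inter-rater forms (`estimate` + shared
#'   `p`), the ANOVA mean squares, and `intra_rater`: per-rater ICC(3,1)
#'   across repeats with p-values (3D input only).
#' @export
icc <- function(ratings, repeats_as = c("targets", "mean")) {
  repeats_as <- match.arg(repeats_as)
  intra <- NULL
  if (is.array(ratings) && length(dim(ratings)) == 3L) {
    d <- dim(ratings)
    if (d[2] < 2L) stop("inter-rater ICC needs >= 2 raters", call. = FALSE)
    m <- if (repeats_as == "targets") {
      matrix(aperm(ratings, c(1, 3, 2)), nrow = d[1] * d[3], ncol = d[2])
    } else {
      apply(ratings, c(1, 2), mean)
    }
    if (d[3] >= 2L) {
      intra <- lapply(seq_len(d[2]), function(r) {
        res <- icc_from_matrix(ratings[, r, ])
        list(estimate = res$icc_single_fixed, p = res$p)
      })
      names(intra) <- paste0("rater", seq_len(d[2]))
    }
  } else {
    m <- as.matrix(ratings)
  }
  res <- icc_from_matrix(m)
  res$intra_rater <- intra
  res
}

#' Bland-Altman agreement analysis
#'
#' Differences `rater1 - rater2` against pair means; limits of agreement
#' are `mean difference +/- 1.96 * SD` of the differences. Points strictly
#' outside the limits are outliers; points within `epsilon` of a limit are
#' flagged separately as boundary cases.
#'
#' @param rater1,rater2 equal-length paired measurements.
#' @param epsilon half-width of the boundary band around each limit.
#' @return A list: `mean_diff`, `sd_diff`, `upper_loa`, `lower_loa`,
#'   `outliers` (indices), `boundary` (indices), and `data`
#'   (`mean`, `diff`) for plotting.
#' @export
bland_altman <- function(rater1, rater2, epsilon = 1e-8) {
  if (length(rater1) != length(rater2))
    stop("rater vectors must be paired (equal length)", call. = FALSE)
  diffs <- rater1 - rater2
  means <- (rater1 + rater2) / 2
  md <- mean(diffs)
  sdd <- if (length(diffs) >= 2) stats::sd(diffs) else 0
  upper <- md + 1.96 * sdd
  lower <- md - 1.96 * sdd
  outside <- which(diffs > upper + epsilon | diffs < lower - epsilon)
  boundary <- which(abs(diffs - upper) <= epsilon | abs(diffs - lower) <= epsilon)
  list(mean_diff = md, sd_diff = sdd, upper_loa = upper, lower_loa = lower,
       outliers = outside, boundary = setdiff(boundary, outside),
       data = data.frame(mean = means, diff = diffs))
}

#' A priori sample size for a two-sample t-test
#'
#' Smallest integer group size `n` such that the two-sample t-test at the
#' given effect size reaches the requested power: the power is evaluated
#' from the noncentral t distribution with noncentrality
#' `d * sqrt(n / 2)` and `2n - 2` degrees of freedom.
#'
#' @param d Cohen's effect size (> 0).
#' @param alpha significance level; default 0.05.
#' @param power requested power (1 - beta); default 0.80.
#' @param tails 1 or 2; default 2.
#' @param n_max search cap.
#' @return A list: `n_per_group`, `achieved_power`, and the inputs.
#' @examples
#' sample_size_ttest(d = 1.019, alpha = 0.05, power = 0.80)$n_per_group  # 17
#' @export
sample_size_ttest <- function(d, alpha = 0.05, power = 0.80, tails = 2,
                              n_max = 1e6) {
  if (!is.finite(d) || d <= 0) stop("effect size d must be > 0", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)", call. = FALSE)
  if (power <= 0 || power >= 1) stop("power must lie in (0, 1)", call. = FALSE)
  if (!tails %in% c(1, 2)) stop("tails must be 1 or 2", call. = FALSE)
  power_at <- function(n) {
    df <- 2 * n - 2
    ncp <- d * sqrt(n / 2)
    tcrit <- stats::qt(1 - alpha / tails, df)
    p <- stats::pt(tcrit, df, ncp = ncp, lower.tail = FALSE)
    if (tails == 2) p <- p + stats::pt(-tcrit, df, ncp = ncp)
    p
  }
  for (n in 2:n_max) {
    pw <- power_at(n)
    if (pw >= power)
      return(list(n_per_group = as.integer(n), achieved_power = pw,
                  d = d, alpha = alpha, power = power, tails = tails))
  }
  stop("no n within search cap reaches the requested power", call. = FALSE)
}
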