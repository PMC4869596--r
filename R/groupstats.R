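# Group-level statistics: ROI degree aggregation, condition contrasts,
# Welch / paired t-tests, mixed-design ANOVA, and the multi-density
# significance convention.

#' Mean node degree over a region of interest
#'
#' @param degree named degree vector from [node_degree()]
#' @param roi character vector of channel labels (nonempty, all present)
#' @return scalar mean degree
#' @export
roi_mean_degree <- function(degree, roi) {
  if (!length(roi)) stop("empty ROI")
  miss <- setdiff(roi, names(degree))
  if (length(miss)) stop("unknown ROI channel(s): ", paste(miss, collapse = ", "))
  mean(degree[roi])
}

#' Relative change between two condition values
#'
#' Default is the symmetric percent difference
#' `100 * (a - b) / ((a + b) / 2)`, which is antisymmetric in its
#' arguments and bounded in (-200, 200) for positive inputs; the
#' conventional asymmetric form `100 * (a - b) / b` is available via
#' `method = "baseline"`. The convention is recorded in the result's
#' `method` attribute because published values depend on it.
#'
#' @param a,b scalar values (e.g. Go and NoGo ROI degree)
#' @param method "symmetric" (default) or "baseline"
#' @return percentage, with attribute `method`
#' @export
relative_change <- function(a, b, method = c("symmetric", "baseline")) {
  method <- match.arg(method)
  denom <- if (method == "symmetric") (a + b) / 2 else b
  if (denom == 0) stop("zero denominator in relative change")
  structure(100 * (a - b) / denom, method = method)
}

stat_row <- function(effect, statistic, df, p, family) {
  data.table::data.table(effect = effect, statistic = statistic, df = df,
                         p = p, family = family)
}

#' Welch two-sample t-test (unequal variances)
#'
#' Two-tailed, with the Welch-Satterthwaite (fractional) degrees of
#' freedom.
#'
#' @param x,y numeric samples, each of length >= 2
#' @return data.table: effect, statistic, df, p, family
#' @export
welch_t <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) stop("need n >= 2 per sample")
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    stop("zero variance in both samples")
  }
  tt <- stats::t.test(x, y, var.equal = FALSE)
  stat_row("x - y", unname(tt$statistic), unname(tt$parameter), tt$p.value,
           "welch_t")
}

#' Paired-samples t-test
#'
#' One-sample t on the paired differences, two-tailed.
#'
#' @param x,y numeric samples of equal length >= 2
#' @return data.table: effect, statistic, df, p, family
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y)) stop("paired samples must have equal length")
  if (length(x) < 2) stop("need n >= 2 pairs")
  if (stats::var(x - y) == 0) stop("zero-variance differences")
  tt <- stats::t.test(x, y, paired = TRUE)
  stat_row("x - y (paired)", unname(tt$statistic), unname(tt$parameter),
           tt$p.value, "paired_t")
}

#' Two-way mixed-design ANOVA (one within, one between factor)
#'
#' Classical sums-of-squares decomposition for a design with a
#' within-subject factor (e.g. Task: Baseline/Go/NoGo, every subject
#' observed at every level) and a between-subject factor (e.g. Age group).
#' The between effect is tested against subject-within-group error; the
#' within effect and the interaction against the task-by-subject residual.
#' No sphericity correction is applied (plain F).
#'
#' @param data data.frame/data.table with one row per observation
#' @param dv name of the response column
#' @param within name of the within-subject factor column
#' @param between name of the between-subject factor column
#' @param subject name of the subject identifier column
#' @return data.table with one row per effect (within, between,
#'   interaction): effect, statistic (F), df (string "df1,df2"), p, family
#' @export
mixed_anova <- function(data, dv = "value", within = "task",
                        between = "group", subject = "subject") {
  dt <- data.table::as.data.table(data)
  y <- dt[[dv]]
  task <- as.factor(dt[[within]])
  grp <- as.factor(dt[[between]])
  subj <- as.factor(dt[[subject]])
  tl <- nlevels(task)
  G <- nlevels(grp)
  # balance check: every subject must have every within level exactly once
  tab <- table(subj, task)
  if (any(tab != 1)) stop("design not balanced: every subject needs every ",
                          "within-factor level exactly once")
  subj_grp <- tapply(as.character(grp), subj, function(g) g[1])
  n_g <- table(factor(subj_grp, levels = levels(grp)))
  N <- sum(n_g)
  grand <- mean(y)
  m_subj <- tapply(y, subj, mean)
  m_grp <- tapply(y, grp, mean)
  m_task <- tapply(y, task, mean)
  m_cell <- tapply(y, list(grp, task), mean)
  ss_total <- sum((y - grand)^2)
  ss_bsubj <- tl * sum((m_subj - grand)^2)
  ss_group <- tl * sum(n_g * (m_grp - grand)^2)
  ss_serr <- ss_bsubj - ss_group
  ss_task <- N * sum((m_task - grand)^2)
  ss_cells <- sum(outer(as.numeric(n_g), rep(1, tl)) * (m_cell - grand)^2)
  ss_inter <- ss_cells - ss_group - ss_task
  ss_werr <- ss_total - ss_bsubj - ss_task - ss_inter
  df_group <- G - 1; df_serr <- N - G
  df_task <- tl - 1; df_inter <- (G - 1) * (tl - 1)
  df_werr <- (N - G) * (tl - 1)
  fstat <- function(ss_num, df_num, ss_den, df_den) {
    if (ss_num <= 1e-300) return(0)      # no effect at all, even if MSE = 0
    (ss_num / df_num) / (ss_den / df_den)
  }
  Fg <- fstat(ss_group, df_group, ss_serr, df_serr)
  Ft <- fstat(ss_task, df_task, ss_werr, df_werr)
  Fi <- fstat(ss_inter, df_inter, ss_werr, df_werr)
  rbind(
    stat_row(within, Ft, sprintf("%d,%d", df_task, df_werr),
             stats::pf(Ft, df_task, df_werr, lower.tail = FALSE), "mixed_anova"),
    stat_row(between, Fg, sprintf("%d,%d", df_group, df_serr),
             stats::pf(Fg, df_group, df_serr, lower.tail = FALSE), "mixed_anova"),
    stat_row(paste0(within, ":", between), Fi, sprintf("%d,%d", df_inter, df_werr),
             stats::pf(Fi, df_inter, df_werr, lower.tail = FALSE), "mixed_anova")
  )
}

#' Multi-density significance rule
#'
#' Because graphs across the density sweep are far from independent, no
#' multiple-comparison correction is applied; instead an effect is treated
#' as significant only when `p < alpha` at a minimum number of density
#' levels (default 3 of the 7-level sweep).
#'
#' @param p_values numeric vector of per-density-level p-values
#' @param alpha significance level (default 0.05)
#' @param min_levels minimum number of levels below alpha (default 3)
#' @return logical flag
#' @export
multi_density_rule <- function(p_values, alpha = 0.05, min_levels = 3) {
  if (!length(p_values)) stop("empty p-value list")
  sum(p_values < alpha) >= min_levels
}

#' Per-channel paired-t topography of node degree
#'
#' For each channel, a paired t-test of node degree between two conditions
#' across subjects (at a single density level, conventionally K = 120).
#' Channels with zero-variance differences yield NA statistics rather than
#' an error.
#'
#' @param degree_table data.table with columns subject, condition, channel,
#'   degree (one row per subject x condition x channel)
#' @param conditions `c(a, b)`: the contrast is a minus b
#' @return data.table: channel, t, df, p (NA for degenerate channels)
#' @export
degree_tmap <- function(degree_table, conditions) {
  dt <- data.table::as.data.table(degree_table)
  a <- dt[dt$condition == conditions[1], ]
  b <- dt[dt$condition == conditions[2], ]
  m <- merge(a, b, by = c("subject", "channel"), suffixes = c("_a", "_b"))
  out <- m[, {
    d <- degree_a - degree_b
    if (length(d) < 2 || stats::var(d) == 0) {
      list(t = NA_real_, df = NA_real_, p = NA_real_)
    } else {
      tt <- stats::t.test(d)
      list(t = unname(tt$statistic), df = unname(tt$parameter),
           p = tt$p.value)
    }
  }, by = "channel"]
  out
}
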