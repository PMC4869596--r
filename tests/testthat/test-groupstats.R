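test_that("ROI degree aggregation and relative change behave", {
  deg <- stats::setNames(c(4, 6, 8, 2), c("Fz", "Cz", "Pz", "Oz"))
  expect_equal(roi_mean_degree(deg, c("Fz", "Cz")), 5)
  expect_equal(roi_mean_degree(deg, names(deg)), mean(deg))
  expect_equal(roi_mean_degree(stats::setNames(rep(3, 4), names(deg)), "Pz"), 3)
  expect_error(roi_mean_degree(deg, "Qz"), "unknown")
  expect_error(roi_mean_degree(deg, character()), "empty")

  expect_equal(as.numeric(relative_change(5, 5)), 0)
  expect_equal(as.numeric(relative_change(3, 1)), 100)      # symmetric form
  expect_equal(as.numeric(relative_change(1, 3)), -100)     # antisymmetry
  expect_equal(as.numeric(relative_change(3, 1, "baseline")), 200)
  expect_error(relative_change(1, 0, "baseline"), "denominator")
})

test_that("welch_t matches direct formula evaluation", {
  x <- c(1, 2, 3, 4); y <- c(2, 4, 6, 8)
  res <- welch_t(x, y)
  # independent hand computation
  se2 <- var(x) / 4 + var(y) / 4
  t_hand <- (mean(x) - mean(y)) / sqrt(se2)
  df_hand <- se2^2 / ((var(x) / 4)^2 / 3 + (var(y) / 4)^2 / 3)
  expect_equal(res$statistic, t_hand, tolerance = 1e-12)
  expect_equal(res$df, df_hand, tolerance = 1e-10)
  expect_equal(res$p, 2 * pt(-abs(t_hand), df_hand), tolerance = 1e-12)
  # identical samples (with internal variance): t = 0, p = 1
  z <- c(1, 2, 3)
  res0 <- welch_t(z, z)
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p, 1)
  expect_error(welch_t(c(1, 1), c(2, 2)), "zero variance")
  # equal variances and sizes: Welch df equals Student df (n1 + n2 - 2)
  a <- c(1, 2, 3, 4, 5); b <- a + 2
  expect_equal(welch_t(a, b)$df, 8)
})

test_that("paired_t matches direct formula evaluation", {
  x <- c(3.1, 2.8, 3.6, 3.0, 3.3)
  y <- c(2.9, 2.6, 3.5, 2.7, 3.2)
  res <- paired_t(x, y)
  d <- x - y
  t_hand <- mean(d) / (sd(d) / sqrt(5))
  expect_equal(res$statistic, t_hand, tolerance = 1e-12)
  expect_equal(res$df, 4)
  expect_equal(res$p, 2 * pt(-abs(t_hand), 4), tolerance = 1e-12)
  expect_error(paired_t(x, x), "zero-variance")
  # y = x + c with noise: t sign is -sign(c)
  set.seed(1)
  xx <- rnorm(20); yy <- xx + 1 + rnorm(20, 0, 0.1)
  expect_lt(paired_t(xx, yy)$statistic, 0)
})

make_mixed_data <- function(n_per_group, effect_task = 0, effect_group = 0,
                            effect_inter = 0, seed = 1) {
  set.seed(seed)
  grid <- expand.grid(subject = seq_len(2 * n_per_group),
                      task = c("Baseline", "Go", "NoGo"))
  grid$group <- ifelse(grid$subject <= n_per_group, "younger", "older")
  subj_eff <- rnorm(2 * n_per_group, 0, 0.5)
  grid$value <- rnorm(nrow(grid)) + subj_eff[grid$subject] +
    effect_task * (grid$task == "NoGo") +
    effect_group * (grid$group == "older") +
    effect_inter * (grid$task == "NoGo") * (grid$group == "older")
  grid$subject <- paste0("S", grid$subject)
  grid
}

test_that("mixed_anova matches the aov Error-stratum oracle", {
  for (case in list(c(4, 4), c(5, 3))) {
    d <- make_mixed_data(4, 0.8, 0.5, 0.4, seed = 7)
    if (case[2] == 3) {                      # unbalanced groups
      d <- d[d$subject != "S8", ]
    }
    res <- mixed_anova(d)
    fit <- stats::aov(value ~ group * task + Error(subject),
                      data = transform(d, subject = factor(subject),
                                       group = factor(group),
                                       task = factor(task)))
    s <- summary(fit)
    f_between <- s[["Error: subject"]][[1]]["group", "F value"]
    f_task <- s[["Error: Within"]][[1]]["task", "F value"]
    f_inter <- s[["Error: Within"]][[1]]["group:task", "F value"]
    expect_equal(res$statistic[res$effect == "group"], f_between,
                 tolerance = 1e-8)
    expect_equal(res$statistic[res$effect == "task"], f_task,
                 tolerance = 1e-8)
    expect_equal(res$statistic[res$effect == "task:group"], f_inter,
                 tolerance = 1e-8)
  }
})

test_that("mixed_anova degenerate and structured cases", {
  d <- make_mixed_data(4, seed = 3)
  d$value <- 1                                     # all equal: F = 0
  res <- mixed_anova(d)
  expect_equal(res$statistic, rep(0, 3))
  # pure group offset with subject noise but structurally no task effect:
  # Age F > 0, Task F = 0 exactly
  set.seed(5)
  d2 <- make_mixed_data(6, seed = 5)
  subj_eff <- stats::setNames(rnorm(12, 0, 0.5), paste0("S", 1:12))
  d2$value <- subj_eff[d2$subject] + 5 * (d2$group == "older")
  res2 <- mixed_anova(d2)
  expect_gt(res2$statistic[res2$effect == "group"], 5)
  expect_lt(res2$p[res2$effect == "group"], 0.05)
  expect_equal(res2$statistic[res2$effect == "task"], 0)
  # missing cell: error
  d3 <- make_mixed_data(4, seed = 6)
  expect_error(mixed_anova(d3[-1, ]), "balanced")
})

test_that("multi-density rule counts levels and is monotone", {
  expect_true(multi_density_rule(c(0.01, 0.02, 0.04, 0.9, 0.9, 0.9, 0.9)))
  expect_false(multi_density_rule(c(0.01, 0.02, 0.9, 0.9, 0.9, 0.9, 0.9)))
  expect_true(multi_density_rule(rep(0.001, 7)))
  expect_error(multi_density_rule(numeric()), "empty")
  # monotone: lowering any p never flips significant -> not significant
  set.seed(8)
  for (i in 1:20) {
    p <- runif(7)
    before <- multi_density_rule(p)
    j <- sample(7, 1)
    p2 <- p; p2[j] <- p[j] * runif(1)
    if (before) expect_true(multi_density_rule(p2))
  }
})

test_that("degree_tmap runs per channel and flags degenerate ones", {
  set.seed(12)
  tab <- data.table::CJ(subject = paste0("S", 1:6),
                        condition = c("Go", "NoGo"),
                        channel = c("Fz", "Cz", "Pz"))
  tab$degree <- rnorm(nrow(tab), 10)
  tab$degree[tab$channel == "Fz" & tab$condition == "NoGo"] <-
    tab$degree[tab$channel == "Fz" & tab$condition == "NoGo"] + 5
  tm <- degree_tmap(tab, c("NoGo", "Go"))
  expect_identical(nrow(tm), 3L)
  expect_gt(tm$t[tm$channel == "Fz"], 2)
  # identical conditions: degenerate channels yield NA, not an error
  tab2 <- tab
  tab2$degree[tab2$condition == "NoGo"] <- tab2$degree[tab2$condition == "Go"]
  tm2 <- degree_tmap(tab2, c("NoGo", "Go"))
  expect_true(all(is.na(tm2$t)))
})
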