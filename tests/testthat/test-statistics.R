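test_that("one-way ANOVA: identical groups, hand example, degenerate input", {
  expect_equal(one_way_anova(list(a = c(1, 2, 3), b = c(1, 2, 3)))$statistic, 0)
  expect_equal(one_way_anova(list(a = c(1, 2, 3), b = c(1, 2, 3)))$p_value, 1)
  ## hand-computed 3-group example: means 2, 3, 7; SSB = 42, SSW = 6,
  ## F = (42/2) / (6/6) = 21
  g <- list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(6, 7, 8))
  an <- one_way_anova(g)
  expect_equal(an$statistic, 21, tolerance = 1e-10)
  expect_equal(unname(an$df), c(2, 6))
  expect_equal(an$p_value, stats::pf(21, 2, 6, lower.tail = FALSE))
  ## identical constant groups: F undefined
  expect_error(one_way_anova(list(a = c(2, 2), b = c(2, 2))), "undefined")
  expect_error(one_way_anova(list(a = 1:3)), ">= 2 groups")
  expect_error(one_way_anova(list(a = 1:3, b = 2)), ">= 2 values")
})

test_that("ANOVA on two groups satisfies F = t^2", {
  set.seed(61)
  for (k in 1:10) {
    a <- stats::rnorm(sample(4:9, 1)); b <- stats::rnorm(sample(4:9, 1), 0.5)
    an <- one_way_anova(list(a = a, b = b))
    tt <- unpaired_t_test(a, b)
    expect_equal(an$statistic, tt$statistic^2, tolerance = 1e-12)
    expect_equal(an$p_value, tt$p_value, tolerance = 1e-12)
  }
})

test_that("all tests agree with the reference implementations to 1e-8", {
  set.seed(62)
  for (k in 1:20) {
    ng <- sample(3:5, 1)
    g <- lapply(seq_len(ng), function(i)
      stats::rnorm(sample(4:10, 1), mean = stats::runif(1, -1, 1)))
    names(g) <- paste0("g", seq_len(ng))
    df <- data.frame(y = unlist(g),
                     grp = factor(rep(names(g), lengths(g))))
    ## ANOVA vs aov
    an <- one_way_anova(g)
    ref <- summary(stats::aov(y ~ grp, df))[[1]]
    expect_equal(an$statistic, ref$`F value`[1], tolerance = 1e-8)
    expect_equal(an$p_value, ref$`Pr(>F)`[1], tolerance = 1e-8)
    ## Tukey HSD vs TukeyHSD
    tk <- tukey_pairwise(g)
    ref_tk <- stats::TukeyHSD(stats::aov(y ~ grp, df))$grp
    expect_equal(sort(tk$pairwise$p_adjusted), sort(unname(ref_tk[, "p adj"])),
                 tolerance = 1e-8)
    expect_equal(sort(tk$pairwise$mean_difference),
                 sort(unname(ref_tk[, "diff"])), tolerance = 1e-8)
    ## t-tests vs t.test, both variants
    tt <- unpaired_t_test(g[[1]], g[[2]])
    ref_t <- stats::t.test(g[[1]], g[[2]], var.equal = TRUE)
    expect_equal(tt$statistic, unname(ref_t$statistic), tolerance = 1e-8)
    expect_equal(tt$p_value, ref_t$p.value, tolerance = 1e-8)
    tw <- unpaired_t_test(g[[1]], g[[2]], welch = TRUE)
    ref_w <- stats::t.test(g[[1]], g[[2]])
    expect_equal(tw$statistic, unname(ref_w$statistic), tolerance = 1e-8)
    expect_equal(tw$df, unname(ref_w$parameter), tolerance = 1e-8)
    expect_equal(tw$p_value, ref_w$p.value, tolerance = 1e-8)
    ## regression vs lm
    x <- stats::rnorm(12); y <- 2 * x + stats::rnorm(12)
    fit <- simple_linear_regression(x, y)
    ref_lm <- stats::lm(y ~ x)
    expect_equal(fit$slope, unname(stats::coef(ref_lm)[2]), tolerance = 1e-8)
    expect_equal(fit$intercept, unname(stats::coef(ref_lm)[1]),
                 tolerance = 1e-8)
    expect_equal(fit$r_squared, summary(ref_lm)$r.squared, tolerance = 1e-8)
    expect_equal(fit$p_value, summary(ref_lm)$coefficients[2, 4],
                 tolerance = 1e-8)
  }
})

test_that("Tukey HSD behaves at the edges and under a planted shift", {
  ## identical groups: adjusted p ~ 1
  tk <- tukey_pairwise(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_gt(min(tk$pairwise$p_adjusted), 0.999)
  ## adjusted p >= unadjusted pairwise p for every pair
  set.seed(63)
  g <- lapply(1:4, function(i) stats::rnorm(6, mean = i / 4))
  names(g) <- letters[1:4]
  tk2 <- tukey_pairwise(g)
  pairs <- utils::combn(names(g), 2)
  for (j in seq_len(ncol(pairs))) {
    praw <- unpaired_t_test(g[[pairs[1, j]]], g[[pairs[2, j]]])$p_value
    lab <- grepl(pairs[1, j], tk2$pairwise$pair) &
           grepl(pairs[2, j], tk2$pairwise$pair)
    expect_gte(tk2$pairwise$p_adjusted[lab] + 1e-12, praw)
  }
  ## one shifted group dominates the rejections
  set.seed(64)
  hits <- integer(4)
  for (s in 1:30) {
    g <- c(lapply(1:3, function(i) stats::rnorm(8)),
           list(stats::rnorm(8, mean = 2.5)))
    names(g) <- letters[1:4]
    tk3 <- tukey_pairwise(g)
    rej <- tk3$pairwise$pair[tk3$pairwise$p_adjusted < 0.05]
    hits <- hits + vapply(letters[1:4], function(l)
      sum(grepl(l, rej)), integer(1))
  }
  expect_equal(unname(which.max(hits)), 4L)
})

test_that("null ANOVA p-values are uniform under permutation", {
  set.seed(65)
  y <- stats::rnorm(18)
  p <- replicate(500, {
    grp <- sample(rep(1:3, each = 6))
    one_way_anova(split(y, grp))$p_value
  })
  ks <- stats::ks.test(p, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("t-test symmetry and regression exact cases", {
  set.seed(66)
  a <- stats::rnorm(6); b <- stats::rnorm(7, 0.4)
  t1 <- unpaired_t_test(a, b); t2 <- unpaired_t_test(b, a)
  expect_equal(t1$statistic, -t2$statistic)
  expect_equal(t1$p_value, t2$p_value)
  expect_equal(unpaired_t_test(a, a)$statistic, 0)
  expect_equal(unpaired_t_test(a, a)$p_value, 1)
  ## exact line
  x <- 1:10
  fit <- simple_linear_regression(x, 2 * x + 1)
  expect_equal(fit$slope, 2)
  expect_equal(fit$intercept, 1)
  expect_equal(fit$r_squared, 1)
  ## constant response
  fit0 <- simple_linear_regression(x, rep(3, 10))
  expect_equal(fit0$slope, 0)
  expect_equal(fit0$r_squared, 0)
  expect_error(simple_linear_regression(rep(1, 5), stats::rnorm(5)),
               "degenerate")
  ## noisy planted slope within 3 SE
  set.seed(67)
  xx <- seq(1, 133, 0.5)
  yy <- 0.001 * xx + stats::rnorm(length(xx), sd = 0.02)
  fit2 <- simple_linear_regression(xx, yy)
  expect_lt(abs(fit2$slope - 0.001), 3 * fit2$slope_se)
})
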