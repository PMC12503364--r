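## Statistics layer, implemented from the standard formulas: one-way
## ANOVA with Tukey HSD multiple comparisons, unpaired t-test (pooled
## by default, Welch optional), and simple linear regression. R's
## aov/TukeyHSD/t.test/lm serve as independent cross-checks in the test
## suite, never as the implementation.

as_grouped <- function(groups) {
  if (is.data.frame(groups)) groups <- split(groups[[2]], groups[[1]])
  if (!is.list(groups) || length(groups) < 2L)
    stop("need a named list of >= 2 groups")
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("group", seq_along(groups))
  lapply(groups, as.numeric)
}

#' One-way ANOVA
#'
#' Standard between/within decomposition: `F = MS_between / MS_within`
#' with `df = (k - 1, N - k)`; the p-value comes from the F
#' distribution.
#'
#' @param groups named list of numeric vectors (>= 2 groups, each with
#'   >= 2 values), or a two-column data.frame (group, value).
#' @return list of class `hg_test` with `method`, `statistic` (F),
#'   `df` (c(between, within)), `p_value`, and the sums of squares.
#' @export
one_way_anova <- function(groups) {
  g <- as_grouped(groups)
  if (any(lengths(g) < 2L)) stop("every group needs >= 2 values for ANOVA")
  k <- length(g)
  N <- sum(lengths(g))
  grand <- mean(unlist(g))
  ss_between <- sum(lengths(g) * (vapply(g, mean, numeric(1)) - grand)^2)
  ss_within <- sum(vapply(g, function(v) sum((v - mean(v))^2), numeric(1)))
  df1 <- k - 1L; df2 <- N - k
  if (ss_within == 0 && ss_between == 0)
    stop("zero variance within and between groups: F is undefined")
  ms_b <- ss_between / df1
  ms_w <- ss_within / df2
  if (ms_w == 0) stop("zero within-group variance: F is undefined")
  F <- ms_b / ms_w
  structure(list(method = "one-way ANOVA",
                 statistic = F, df = c(between = df1, within = df2),
                 p_value = stats::pf(F, df1, df2, lower.tail = FALSE),
                 ss_between = ss_between, ss_within = ss_within,
                 ms_within = ms_w, group_means = vapply(g, mean, numeric(1)),
                 group_n = lengths(g)),
            class = "hg_test")
}

#' Tukey HSD pairwise comparisons
#'
#' All pairwise mean differences after a one-way ANOVA, with adjusted
#' p-values from the studentized range distribution
#' (`q = |diff| / sqrt(MS_within/2 * (1/n_i + 1/n_j))`, the
#' Tukey-Kramer form for unequal group sizes).
#'
#' @inheritParams one_way_anova
#' @return list of class `hg_test` carrying the ANOVA fields plus
#'   `pairwise`: data.frame of pair, mean difference, q statistic and
#'   adjusted p.
#' @export
tukey_pairwise <- function(groups) {
  g <- as_grouped(groups)
  an <- one_way_anova(g)
  k <- length(g)
  df2 <- unname(an$df["within"])
  labs <- names(g)
  rows <- list()
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    diff <- mean(g[[j]]) - mean(g[[i]])
    se <- sqrt(an$ms_within / 2 * (1 / length(g[[i]]) + 1 / length(g[[j]])))
    q <- abs(diff) / se
    p <- stats::ptukey(q, nmeans = k, df = df2, lower.tail = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      pair = paste(labs[j], "-", labs[i]), mean_difference = diff,
      q = q, p_adjusted = p, stringsAsFactors = FALSE)
  }
  an$pairwise <- do.call(rbind, rows)
  an$method <- "one-way ANOVA with Tukey HSD multiple comparisons"
  an
}

#' Unpaired two-sample t-test
#'
#' Student's pooled-variance test by default (the common unpaired
#' default); Welch's unequal-variance form by flag. Two-sided p.
#'
#' @param a,b numeric samples (each >= 2 values).
#' @param welch use the Welch-Satterthwaite form.
#' @return list of class `hg_test` with `statistic` (t), `df`,
#'   `p_value`, `mean_difference`.
#' @export
unpaired_t_test <- function(a, b, welch = FALSE) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L) stop("each sample needs >= 2 values")
  na <- length(a); nb <- length(b)
  va <- stats::var(a); vb <- stats::var(b)
  diff <- mean(a) - mean(b)
  if (welch) {
    se2 <- va / na + vb / nb
    if (se2 == 0) stop("zero variance in both samples: t is undefined")
    t <- diff / sqrt(se2)
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
    method <- "Welch unpaired t-test"
  } else {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    if (sp2 == 0 && diff == 0) stop("zero variance and equal means: t is undefined")
    t <- diff / sqrt(sp2 * (1 / na + 1 / nb))
    df <- na + nb - 2
    method <- "Student unpaired t-test (pooled variance)"
  }
  structure(list(method = method, statistic = t, df = df,
                 p_value = 2 * stats::pt(abs(t), df, lower.tail = FALSE),
                 mean_difference = diff),
            class = "hg_test")
}

#' Simple linear regression (ordinary least squares)
#'
#' Closed-form OLS of y on x: slope, intercept and the coefficient of
#' determination, plus the slope's standard error and two-sided p.
#'
#' @param x,y numeric vectors (>= 3 points; x not all equal).
#' @return list of class `hg_test` with `slope`, `intercept`,
#'   `r_squared`, `slope_se`, `statistic` (t for slope), `df`,
#'   `p_value`.
#' @export
simple_linear_regression <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  if (n < 3L || length(y) != n) stop("need >= 3 paired points")
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0) stop("degenerate x: all values equal")
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  resid <- y - intercept - slope * x
  ss_res <- sum(resid^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 0 else 1 - ss_res / ss_tot
  df <- n - 2L
  se <- sqrt(ss_res / df / sxx)
  t <- if (se == 0) 0 else slope / se
  structure(list(method = "simple linear regression",
                 slope = slope, intercept = intercept, r_squared = r2,
                 slope_se = se, statistic = t, df = df,
                 p_value = if (se == 0) NA_real_
                           else 2 * stats::pt(abs(t), df, lower.tail = FALSE)),
            class = "hg_test")
}

#' @export
print.hg_test <- function(x, ...) {
  cat(x$method, "\n")
  if (!is.null(x$slope))
    cat(sprintf("  slope %.6g, intercept %.6g, r^2 %.4f\n",
                x$slope, x$intercept, x$r_squared))
  if (!is.null(x$statistic))
    cat(sprintf("  statistic %.4f, df %s, p = %.4g\n", x$statistic,
                paste(round(x$df, 2), collapse = "/"), x$p_value))
  if (!is.null(x$pairwise)) {
    cat("  pairwise (Tukey HSD):\n")
    print(x$pairwise, row.names = FALSE)
  }
  invisible(x)
}
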