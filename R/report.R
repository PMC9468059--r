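# Thin statistical reporting layer: the test battery applied to pipeline
# outputs (two-way ANOVA, ANCOVA with age, Pearson correlation, Tukey
# post-hoc) plus simple figure-style plots.  Standard linear-model
# formulas; Type-II sums of squares for unbalanced designs.

type2_term_f <- function(y, full_terms, drop_term, data) {
  f_full <- stats::as.formula(paste("y ~", paste(full_terms, collapse = "+")))
  rest <- setdiff(full_terms, drop_term)
  f_red <- stats::as.formula(
    if (length(rest)) paste("y ~", paste(rest, collapse = "+")) else "y ~ 1")
  data$y <- y
  m_full <- lm(f_full, data = data)
  m_red <- lm(f_red, data = data)
  rss_full <- sum(stats::residuals(m_full)^2)
  rss_red <- sum(stats::residuals(m_red)^2)
  df1 <- m_red$df.residual - m_full$df.residual
  df2 <- m_full$df.residual
  ss <- rss_red - rss_full
  eps <- 1e-12 * max(1, sum(y^2))
  if (ss <= eps && rss_full <= eps) {        # constant response
    f <- 0; p <- 1
  } else if (rss_full <= eps) {              # perfect fit, nonzero effect
    f <- Inf; p <- 0
  } else {
    f <- (ss / df1) / (rss_full / df2)
    p <- pf(f, df1, df2, lower.tail = FALSE)
  }
  data.frame(term = drop_term, F = f, df1 = df1, df2 = df2, p = p,
             stringsAsFactors = FALSE)
}

#' Two-way ANOVA (main effects, Type-II SS)
#'
#' Main-effect F, degrees of freedom and p for each factor, from standard
#' linear-model formulas; Type-II sums of squares so unbalanced designs are
#' handled consistently (each main effect adjusted for the other).  A
#' constant response reports F = 0, p = 1.
#'
#' @param values numeric response (e.g. AT8+ volume per case x subregion).
#' @param factor_stage,factor_region the two factors (coerced to factor).
#' @return data frame of class `stat_report`: one row per main effect.
#' @export
two_way_anova <- function(values, factor_stage, factor_region) {
  a <- factor(factor_stage)
  b <- factor(factor_region)
  if (nlevels(a) < 2 || nlevels(b) < 2)
    stop("each factor needs at least 2 levels")
  if (length(values) != length(a) || length(values) != length(b))
    stop("lengths differ")
  dat <- data.frame(stage = a, region = b)
  out <- rbind(type2_term_f(values, c("stage", "region"), "stage", dat),
               type2_term_f(values, c("stage", "region"), "region", dat))
  out$n <- length(values)
  class(out) <- c("stat_report", "data.frame")
  out
}

#' ANCOVA: stage factor with age covariate
#'
#' One linear model `value ~ stage + age`; Type-II F and p for the factor
#' and for the covariate.
#'
#' @param values numeric response.
#' @param stage grouping factor (e.g. Braak group).
#' @param age numeric covariate.
#' @return data frame of class `stat_report`.
#' @export
ancova_age <- function(values, stage, age) {
  s <- factor(stage)
  if (nlevels(s) < 2) stop("stage needs at least 2 levels")
  if (!is.numeric(age)) stop("age must be numeric")
  if (var(age) == 0) stop("age covariate has zero variance (collinear design)")
  dat <- data.frame(stage = s, age = age)
  out <- rbind(type2_term_f(values, c("stage", "age"), "stage", dat),
               type2_term_f(values, c("stage", "age"), "age", dat))
  out$n <- length(values)
  class(out) <- c("stat_report", "data.frame")
  out
}

#' Pearson product-moment correlation with t-based p value
#'
#' @param x,y numeric vectors (n >= 3).
#' @return list with `r`, `p_value`, `n`; `r` is NA (flagged via attribute
#'   `undefined`) when either variable has zero variance.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("lengths differ")
  if (length(x) < 3) stop("need at least 3 pairs")
  if (var(x) == 0 || var(y) == 0) {
    warning("zero variance: correlation undefined")
    out <- list(r = NA_real_, p_value = NA_real_, n = length(x))
    attr(out, "undefined") <- TRUE
    return(out)
  }
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' One-way ANOVA with Tukey HSD post-hoc comparisons
#'
#' @param values numeric response.
#' @param group grouping factor.
#' @return list with the one-way ANOVA `stat_report` and the Tukey table.
#' @export
tukey_posthoc <- function(values, group) {
  g <- factor(group)
  if (nlevels(g) < 2) stop("need at least 2 groups")
  fit <- aov(values ~ g)
  an <- summary(fit)[[1]]
  rep_ <- data.frame(term = "group", F = an$`F value`[1], df1 = an$Df[1],
                     df2 = an$Df[2], p = an$`Pr(>F)`[1], n = length(values))
  class(rep_) <- c("stat_report", "data.frame")
  list(anova = rep_, tukey = stats::TukeyHSD(fit)$g)
}

# ---- figure-style plots ----------------------------------------------------

#' Bar plot of group means with SEM error bars
#'
#' @param summary_tbl output of [group_summary()].
#' @param main,ylab plot annotation.
#' @export
plot_burden_bars <- function(summary_tbl, main = "", ylab = "value") {
  m <- summary_tbl$mean
  s <- summary_tbl$sem
  lab <- do.call(paste, c(summary_tbl[setdiff(names(summary_tbl),
                                              c("n", "mean", "sem"))],
                          sep = "\n"))
  up <- ifelse(is.na(s), m, m + s)
  bp <- graphics::barplot(m, names.arg = lab, main = main, ylab = ylab,
                          ylim = c(0, max(up) * 1.15))
  ok <- !is.na(s)
  if (any(ok))
    graphics::arrows(bp[ok], m[ok] - s[ok], bp[ok], m[ok] + s[ok],
                     angle = 90, code = 3, length = 0.04)
  invisible(bp)
}

#' Shell-profile curve (process volume fraction per concentric shell)
#'
#' @param profile a [shell_profile()] result.
#' @param main plot title.
#' @export
plot_shell_profile <- function(profile, main = "AT8+ process zoning") {
  mid <- (profile$r_lo_um + profile$r_hi_um) / 2
  graphics::plot(mid, profile$fraction, type = "b", pch = 16,
                 xlab = "distance from cell bodies (um)",
                 ylab = "process volume fraction", main = main)
  invisible(NULL)
}

#' Dot plot of NNI values with the CSR reference line at 1
#'
#' @param nni_values numeric NNI per case.
#' @param groups grouping labels.
#' @param main plot title.
#' @export
plot_nni_dots <- function(nni_values, groups, main = "Nearest neighbour index") {
  g <- factor(groups)
  x <- jitter(as.integer(g), amount = 0.08)
  graphics::plot(x, nni_values, xaxt = "n", xlab = "", ylab = "NNI",
                 main = main, pch = 16,
                 ylim = range(c(nni_values, 1)) + c(-0.05, 0.05))
  graphics::axis(1, at = seq_len(nlevels(g)), labels = levels(g))
  graphics::abline(h = 1, lty = 2)
  invisible(NULL)
}
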