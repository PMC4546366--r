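# Statistical battery for cohort tables of global/regional indices.
#
# The design has three groups (sham, MI, MI+Val) followed over baseline,
# 24 h, 1 week and 4 weeks. At 24 h (pre-treatment) a one-way ANOVA with two
# orthogonal Helmert-type contrasts checks that surgery worked (sham vs the
# average of the infarcted groups) and that randomization was unbiased (MI
# vs MI+Val). Post-treatment, treatment contrasts compare MI against each
# other group. Time constancy in shams uses a repeated-measures ANOVA with
# Holm-adjusted pairwise tests. Regional maps are compared cell by cell with
# unpaired t-tests; power for a two-group comparison uses the noncentral-t
# with the pooled SD convention; mortality uses Kaplan-Meier and log-rank.

#' One-way ANOVA with the planned Helmert-type contrasts
#'
#' Contrast (a): `sham` against the average of the two infarcted groups;
#' contrast (b): `MI` against `MI+Val`. The two contrasts are orthogonal.
#'
#' @param values numeric response.
#' @param groups group labels; must contain exactly the three levels.
#' @param levels group level names in the order (infarcted, infarcted
#'   treated, control).
#' @return data frame with one row per contrast: `contrast`, `estimate`
#'   (difference on the contrast), `t`, `df`, `p`; attribute `overall`
#'   carries the omnibus F and p. With zero residual variance the p-values
#'   are `NaN` and attribute `degenerate` is set.
#' @export
helmert_anova <- function(values, groups,
                          levels = c("MI", "MI+Val", "sham")) {
  g <- factor(groups, levels = levels)
  if (anyNA(g)) stop("groups contains labels outside: ",
                     paste(levels, collapse = ", "))
  if (nlevels(g) != 3L || any(table(g) < 2L))
    stop("need 3 groups with n >= 2 each")
  est <- c(mean(values[g == levels[3]]) -
             mean(c(mean(values[g == levels[1]]),
                    mean(values[g == levels[2]]))),
           mean(values[g == levels[1]]) - mean(values[g == levels[2]]))
  if (sum((values - stats::ave(values, g))^2) == 0) {
    # zero within-group variance everywhere: p undefined
    out <- data.frame(contrast = c("sham_vs_infarcted", "MI_vs_MIVal"),
                      estimate = est, t = NaN, df = length(values) - 3L,
                      p = NaN)
    attr(out, "overall") <- c(F = NaN, p = NaN)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  # columns: (b) MI vs MI+Val, (a) sham vs mean(MI, MI+Val)
  cmat <- cbind(b_MI_vs_MIVal = c(-1, 1, 0) / 2,
                a_sham_vs_infarcted = c(-1, -1, 2) / 3)
  fit <- stats::lm(values ~ g, contrasts = list(g = cmat))
  sm <- stats::summary.lm(fit)$coefficients
  an <- stats::anova(fit)
  out <- data.frame(
    contrast = c("sham_vs_infarcted", "MI_vs_MIVal"),
    estimate = est,
    t = c(sm["ga_sham_vs_infarcted", "t value"],
          -sm["gb_MI_vs_MIVal", "t value"]),
    df = fit$df.residual,
    p = c(sm["ga_sham_vs_infarcted", "Pr(>|t|)"],
          sm["gb_MI_vs_MIVal", "Pr(>|t|)"]))
  attr(out, "overall") <- c(F = an$`F value`[1], p = an$`Pr(>F)`[1])
  attr(out, "degenerate") <- !is.finite(an$`F value`[1])
  out
}

#' One-way ANOVA with treatment contrasts against a reference group
#'
#' @param values numeric response.
#' @param groups group labels.
#' @param reference reference level (default `"MI"`).
#' @return data frame with one row per non-reference group: `comparison`,
#'   `estimate` (group minus reference), `t`, `df`, `p`.
#' @export
treatment_anova <- function(values, groups, reference = "MI") {
  g <- factor(groups)
  if (!reference %in% levels(g)) stop("reference group absent: ", reference)
  g <- stats::relevel(g, ref = reference)
  if (any(table(g) < 2L)) stop("each group needs n >= 2")
  fit <- stats::lm(values ~ g)
  sm <- stats::summary.lm(fit)$coefficients
  rows <- rownames(sm)[-1]
  data.frame(comparison = paste(sub("^g", "", rows), "vs", reference),
             estimate = sm[rows, "Estimate"],
             t = sm[rows, "t value"], df = fit$df.residual,
             p = sm[rows, "Pr(>|t|)"], row.names = NULL)
}

#' Repeated-measures ANOVA with Holm-adjusted pairwise comparisons
#'
#' One-way repeated-measures ANOVA with subject as block (error stratum),
#' followed by paired t-tests between timepoints adjusted by Holm's
#' step-down. The subject x timepoint grid must be complete.
#'
#' @param values numeric response.
#' @param subject subject identifiers.
#' @param timepoint within-subject condition labels.
#' @return list with `overall_F`, `overall_p`, `df`, and `pairwise` (matrix
#'   of Holm-adjusted p-values from [stats::pairwise.t.test()]).
#' @export
rm_anova_holm <- function(values, subject, timepoint) {
  subject <- factor(subject); timepoint <- factor(timepoint)
  tab <- table(subject, timepoint)
  if (any(tab != 1L))
    stop("incomplete subject x timepoint grid (no imputation performed)")
  df <- data.frame(values, subject, timepoint)
  df <- df[order(df$timepoint, df$subject), ]
  fit <- stats::aov(values ~ timepoint + Error(subject), data = df)
  sm <- summary(fit)[["Error: Within"]][[1]]
  rn <- trimws(rownames(sm))
  pw <- stats::pairwise.t.test(df$values, df$timepoint, paired = TRUE,
                               p.adjust.method = "holm")
  list(overall_F = sm[rn == "timepoint", "F value"],
       overall_p = sm[rn == "timepoint", "Pr(>F)"],
       df = c(sm[rn == "timepoint", "Df"], sm[rn == "Residuals", "Df"]),
       pairwise = pw$p.value)
}

#' Cell-by-cell unpaired t-tests between two groups of RFAC maps
#'
#' Each (slice, sector) cell of the resampled grid is compared across
#' subjects with a two-sample t-test (pooled variance by default, matching
#' the plain unpaired t-test; Welch optional). Raw p-values by default, to
#' match raw-p display marks on the bull's-eye; Benjamini-Hochberg optional.
#'
#' @param maps_a,maps_b lists of resampled `rfac_map` objects, one per
#'   subject, all on the same grid.
#' @param var_equal pooled-variance t-test if `TRUE` (default), Welch
#'   otherwise.
#' @param adjust `"none"` (default) or any [stats::p.adjust()] method.
#' @return list of slice x sector matrices: `p`, `t`, `mean_a`, `mean_b`;
#'   cells with fewer than 2 values in either group are `NA`.
#' @export
sectorwise_tests <- function(maps_a, maps_b, var_equal = TRUE,
                             adjust = "none") {
  arr_a <- simplify2array(lapply(maps_a, function(m) m$rfac_pct))
  arr_b <- simplify2array(lapply(maps_b, function(m) m$rfac_pct))
  d <- dim(arr_a)[1:2]
  labels <- maps_a[[1]]$sector_labels
  p <- tstat <- ma <- mb <- matrix(NA_real_, d[1], d[2],
                                   dimnames = list(NULL, labels))
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    xa <- arr_a[i, j, ]; xb <- arr_b[i, j, ]
    xa <- xa[!is.na(xa)]; xb <- xb[!is.na(xb)]
    ma[i, j] <- if (length(xa)) mean(xa) else NA_real_
    mb[i, j] <- if (length(xb)) mean(xb) else NA_real_
    if (length(xa) >= 2L && length(xb) >= 2L &&
        (stats::sd(c(xa - mean(xa), xb - mean(xb))) > 0)) {
      tt <- stats::t.test(xa, xb, var.equal = var_equal)
      p[i, j] <- tt$p.value
      tstat[i, j] <- unname(tt$statistic)
    }
  }
  if (adjust != "none") {
    adj <- stats::p.adjust(as.vector(p), method = adjust)
    p <- matrix(adj, d[1], d[2], dimnames = dimnames(p))
  }
  list(p = p, t = tstat, mean_a = ma, mean_b = mb,
       test = if (var_equal) "pooled two-sample t" else "Welch t",
       adjust = adjust)
}

#' Power of the two-sample t-test (noncentral-t, pooled-SD convention)
#'
#' Pooled SD `sqrt((sd1^2 + sd2^2) / 2)`, noncentrality
#' `delta / (sd_pooled * sqrt(2 / n))`, `2n - 2` degrees of freedom.
#'
#' @param n per-group sample size.
#' @param delta true difference to detect (index units).
#' @param sd1,sd2 group standard deviations.
#' @param alpha significance level.
#' @param sides 1 or 2 (default 2).
#' @return power in `[0, 1]`.
#' @examples
#' two_sample_power(n = 12, delta = 14, sd1 = 10.4, sd2 = 17.3)
#' @export
two_sample_power <- function(n, delta, sd1, sd2 = sd1, alpha = 0.05,
                             sides = 2) {
  stopifnot(n >= 2, sd1 >= 0, sd2 >= 0, alpha > 0, alpha < 1,
            sides %in% c(1, 2))
  sp <- sqrt((sd1^2 + sd2^2) / 2)
  ncp <- delta / (sp * sqrt(2 / n))
  df <- 2 * n - 2
  if (sides == 2) {
    tc <- stats::qt(1 - alpha / 2, df)
    stats::pt(-tc, df, ncp) + stats::pt(tc, df, ncp, lower.tail = FALSE)
  } else {
    tc <- stats::qt(1 - alpha, df)
    stats::pt(tc, df, ncp, lower.tail = FALSE)
  }
}

#' Kaplan-Meier curves and log-rank comparison of group mortality
#'
#' @param times follow-up times (>= 0).
#' @param events event indicator (1 = death, 0 = censored).
#' @param groups group labels (>= 2 groups).
#' @return list with `fit` ([survival::survfit()] object), `chisq`, `df`,
#'   `p`; with no events anywhere the log-rank is undefined and `p` is `NA`
#'   with `degenerate = TRUE`.
#' @export
km_logrank <- function(times, events, groups) {
  g <- factor(groups)
  if (nlevels(g) < 2L) stop("log-rank needs at least two groups")
  stopifnot(all(times >= 0), all(events %in% c(0, 1)))
  srv <- survival::Surv(times, events)
  fit <- survival::survfit(srv ~ g)
  if (sum(events) == 0) {
    return(list(fit = fit, chisq = NA_real_, df = nlevels(g) - 1L,
                p = NA_real_, degenerate = TRUE))
  }
  sd <- survival::survdiff(srv ~ g)
  df <- length(sd$n) - 1L
  list(fit = fit, chisq = sd$chisq, df = df,
       p = stats::pchisq(sd$chisq, df, lower.tail = FALSE),
       degenerate = FALSE)
}
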