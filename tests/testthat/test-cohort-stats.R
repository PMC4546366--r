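# Independent hand/textbook oracles for the contrast ANOVAs, Holm step-down,
# the log-rank table, and the power routine.

test_that("Helmert contrasts match a hand-computed decomposition on toy data", {
  # 3 groups x 4 observations
  y <- c(10, 12, 11, 13,  4, 6, 5, 7,  8, 9, 7, 8)
  g <- rep(c("sham", "MI", "MI+Val"), each = 4)
  res <- helmert_anova(y, g)

  # oracle: contrast t-tests from first principles
  ms <- tapply(y, g, mean)
  n <- 4
  sse <- sum((y - ave(y, g))^2)
  mse <- sse / (12 - 3)
  # (a) sham vs mean(MI, MI+Val): weights (1, -1/2, -1/2)
  est_a <- ms["sham"] - (ms["MI"] + ms["MI+Val"]) / 2
  se_a <- sqrt(mse * (1 + 0.25 + 0.25) / n)
  t_a <- est_a / se_a
  # (b) MI vs MI+Val
  est_b <- ms["MI"] - ms["MI+Val"]
  se_b <- sqrt(mse * 2 / n)
  t_b <- est_b / se_b
  p_a <- 2 * pt(-abs(t_a), 9); p_b <- 2 * pt(-abs(t_b), 9)

  expect_equal(res$estimate, unname(c(est_a, est_b)), tolerance = 1e-12)
  expect_equal(res$t, unname(c(t_a, t_b)), tolerance = 1e-10)
  expect_equal(res$p, unname(c(p_a, p_b)), tolerance = 1e-10)
})

test_that("identical groups give F = 0 and p = 1; degenerate data flagged", {
  y <- rep(c(1, 2, 3), 3)
  g <- rep(c("sham", "MI", "MI+Val"), each = 3)
  res <- helmert_anova(y, g)
  expect_equal(res$p, c(1, 1))
  expect_equal(unname(attr(res, "overall")["F"]), 0)

  # sham split from both MI groups, MI == MI+Val up to jitter
  set.seed(7)
  y2 <- c(10, 10, 10, 0, 0, 0, 0, 0, 0) + rnorm(9, 0, 1e-3)
  res2 <- helmert_anova(y2, g)
  expect_lt(res2$p[res2$contrast == "sham_vs_infarcted"], 1e-6)
  expect_gt(res2$p[res2$contrast == "MI_vs_MIVal"], 0.05)

  y3 <- rep(5, 9)
  res3 <- helmert_anova(y3, g)
  expect_true(attr(res3, "degenerate"))
})

test_that("treatment contrasts equal the explicit normal-equations fit", {
  set.seed(3)
  y <- rnorm(12, rep(c(5, 9, 6), each = 4))
  g <- rep(c("MI", "MI+Val", "sham"), each = 4)
  res <- treatment_anova(y, g, reference = "MI")
  # oracle: X beta = y with dummy coding, solved by normal equations
  X <- cbind(1, g == "MI+Val", g == "sham")
  beta <- solve(t(X) %*% X, t(X) %*% y)
  resid <- y - X %*% beta
  s2 <- sum(resid^2) / (12 - 3)
  se <- sqrt(diag(solve(t(X) %*% X)) * s2)
  tstat <- beta / se
  expect_equal(res$estimate, beta[2:3], tolerance = 1e-10)
  expect_equal(res$t, tstat[2:3], tolerance = 1e-10)
  expect_equal(res$p, 2 * pt(-abs(tstat[2:3]), 9), tolerance = 1e-10)

  # all-equal groups -> p = 1 in both comparisons
  res0 <- treatment_anova(rep(c(1, 2), 6), rep(c("MI", "MI+Val", "sham"),
                                               each = 4))
  expect_equal(res0$p, c(1, 1), tolerance = 1e-10)

  # large shift of MI -> both comparisons significant
  y2 <- c(rnorm(4, 50, 0.1), rnorm(4, 5, 0.1), rnorm(4, 5, 0.1))
  res2 <- treatment_anova(y2, g, reference = "MI")
  expect_true(all(res2$p < 1e-6))
})

test_that("repeated-measures ANOVA detects constancy and Holm matches step-down", {
  set.seed(11)
  subj <- rep(sprintf("s%d", 1:6), times = 4)
  tp <- rep(c("baseline", "24h", "1w", "4w"), each = 6)
  # time-constant data with subject effects
  y <- rep(rnorm(6, 10, 2), times = 4) + rnorm(24, 0, 1e-6)
  res <- rm_anova_holm(y, subj, tp)
  expect_gt(res$overall_p, 0.2)

  # Holm step-down on raw pairwise p-values, checked by direct definition
  raw <- c(0.01, 0.02, 0.04)
  holm_hand <- c(0.03, 0.04, 0.04)   # cummax(pmin((m - i + 1) * p_(i), 1))
  expect_equal(p.adjust(raw, "holm"), holm_hand)
  y2 <- rep(rnorm(6, 10, 2), times = 4) +
    rep(c(0, 3, 0, 0), each = 6) + rnorm(24, 0, 0.5)
  res2 <- rm_anova_holm(y2, subj, tp)
  pw <- res2$pairwise
  raw2 <- stats::pairwise.t.test(y2, factor(tp), paired = TRUE,
                                 p.adjust.method = "none")$p.value
  pv <- raw2[!is.na(raw2)]
  ord <- order(pv)
  adj <- pmin(cummax((length(pv) - seq_along(pv) + 1) * pv[ord]), 1)
  expect_equal(sort(pw[!is.na(pw)]), sort(adj))
  # Holm never below raw and monotone
  expect_true(all(pw[!is.na(pw)] >= raw2[!is.na(raw2)] - 1e-12))

  # incomplete grid is rejected
  expect_error(rm_anova_holm(y[-1], subj[-1], tp[-1]), "incomplete")
})

test_that("two-timepoint repeated-measures reduces to the paired t-test", {
  set.seed(5)
  subj <- rep(sprintf("s%d", 1:8), times = 2)
  tp <- rep(c("a", "b"), each = 8)
  y <- rnorm(16, rep(c(5, 6), each = 8))
  res <- rm_anova_holm(y, subj, tp)
  tt <- t.test(y[tp == "a"], y[tp == "b"], paired = TRUE)
  expect_equal(res$overall_p, tt$p.value, tolerance = 1e-10)
  expect_equal(res$overall_F, unname(tt$statistic)^2, tolerance = 1e-10)
})

test_that("sector-wise t maps match the hand formula and flag signal cells", {
  set.seed(21)
  mk_maps <- function(n, shift_cell = NULL) {
    lapply(seq_len(n), function(i) {
      v <- matrix(rnorm(60, 50, 5), 10, 6, dimnames = list(NULL, SECTORS6))
      if (!is.null(shift_cell)) v[shift_cell[1], shift_cell[2]] <-
          v[shift_cell[1], shift_cell[2]] + 50
      rfackit:::new_rfac_map(v, seq(0, 1, length.out = 10), TRUE, 1, 2,
                             SECTORS6)
    })
  }
  a <- mk_maps(6); b <- mk_maps(6, shift_cell = c(4, 2))
  res <- sectorwise_tests(a, b)
  expect_lt(res$p[4, 2], 0.01)
  expect_gt(min(res$p[-(which(row(res$p) == 4 & col(res$p) == 2))]), 0.001)

  # hand-computed pooled t for one cell
  xa <- sapply(a, function(m) m$rfac_pct[3, 5])
  xb <- sapply(b, function(m) m$rfac_pct[3, 5])
  sp2 <- (5 * var(xa) + 5 * var(xb)) / 10
  t_hand <- (mean(xa) - mean(xb)) / sqrt(sp2 * (2 / 6))
  expect_equal(unname(res$t[3, 5]), t_hand, tolerance = 1e-10)
  expect_equal(unname(res$p[3, 5]), 2 * pt(-abs(t_hand), 10),
               tolerance = 1e-10)

  # identical groups -> p = 1 everywhere
  res_id <- sectorwise_tests(a, a)
  expect_true(all(abs(res_id$p - 1) < 1e-12))
})

test_that("power equals alpha at zero effect, grows with n and delta, matches MC", {
  expect_equal(two_sample_power(12, 0, 10, 10, alpha = 0.05), 0.05,
               tolerance = 1e-10)
  p_n <- sapply(c(6, 12, 24, 48), two_sample_power, delta = 10,
                sd1 = 10.4, sd2 = 17.3)
  expect_true(all(diff(p_n) > 0))
  p_d <- sapply(c(5, 10, 15, 20), function(d)
    two_sample_power(12, d, 10.4, 17.3))
  expect_true(all(diff(p_d) > 0))

  # Monte-Carlo oracle at the study's spec (the authority for this routine)
  set.seed(99)
  B <- 2e5; n <- 12
  xa <- matrix(rnorm(B * n, 14, 10.4), n)
  xb <- matrix(rnorm(B * n, 0, 17.3), n)
  va <- colSums((xa - rep(colMeans(xa), each = n))^2) / (n - 1)
  vb <- colSums((xb - rep(colMeans(xb), each = n))^2) / (n - 1)
  sp2 <- (va + vb) / 2
  tstat <- (colMeans(xa) - colMeans(xb)) / sqrt(sp2 * 2 / n)
  mc <- mean(abs(tstat) > qt(0.975, 2 * n - 2))
  expect_equal(two_sample_power(12, 14, 10.4, 17.3), mc, tolerance = 0.01)
})

test_that("log-rank matches a hand-computed observed-expected table", {
  # textbook 2-group toy data, no ties across groups at event times
  t1 <- c(3, 5, 7, 9, 11); e1 <- c(1, 1, 0, 1, 0)
  t2 <- c(2, 4, 6, 8, 10); e2 <- c(1, 1, 1, 0, 1)
  res <- km_logrank(c(t1, t2), c(e1, e2), rep(c("a", "b"), each = 5))

  # oracle: O-E and hypergeometric variance at each event time
  times <- sort(unique(c(t1[e1 == 1], t2[e2 == 1])))
  o1 <- e1s <- v <- 0
  for (tt in times) {
    n1 <- sum(t1 >= tt); n2 <- sum(t2 >= tt); nn <- n1 + n2
    d <- sum(t1 == tt & e1 == 1) + sum(t2 == tt & e2 == 1)
    o1 <- o1 + sum(t1 == tt & e1 == 1)
    e1s <- e1s + d * n1 / nn
    if (nn > 1) v <- v + d * (n1 / nn) * (n2 / nn) * (nn - d) / (nn - 1)
  }
  chisq_hand <- (o1 - e1s)^2 / v
  expect_equal(res$chisq, chisq_hand, tolerance = 1e-10)
  expect_equal(res$p, pchisq(chisq_hand, 1, lower.tail = FALSE),
               tolerance = 1e-10)

  # identical groups -> chi-square 0, p = 1
  res0 <- km_logrank(rep(t1, 2), rep(e1, 2), rep(c("a", "b"), each = 5))
  expect_equal(res0$chisq, 0, tolerance = 1e-10)
  expect_equal(res0$p, 1, tolerance = 1e-10)

  # no events -> flagged, survival stays at 1
  resn <- km_logrank(rep(10, 8), rep(0, 8), rep(c("a", "b"), each = 4))
  expect_true(resn$degenerate)
  expect_true(all(resn$fit$surv == 1))
  expect_error(km_logrank(t1, e1, rep("a", 5)), "two groups")
})
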