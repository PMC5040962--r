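test_that("welch_anova: degenerate, classic-F identity, formula oracle", {
  same <- list(a = c(1, 1, 1), b = c(1, 1, 1))
  r <- welch_anova(same)
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 1)

  # equal n and equal variances: the Welch statistic equals the classic
  # one-way F divided by its small-sample denominator correction
  # B = 1 + 2(k-2)/(k^2-1) * sum((1 - w/W)^2 / (n - 1)); the plain equality
  # holds only as n -> infinity (see decisions ledger: the correction never
  # vanishes at finite n)
  set.seed(1)
  k <- 3; nn <- 10
  g <- lapply(1:k, function(i) i + scale(rnorm(nn))[, 1])  # var exactly 1
  w <- welch_anova(g)
  classic <- oneway.test(y ~ grp, data.frame(
    y = unlist(g), grp = rep(letters[1:k], each = nn)), var.equal = TRUE)
  B <- 1 + 2 * (k - 2) / (k^2 - 1) * (k - 1)^2 / (k * (nn - 1))
  expect_equal(w$statistic * B, unname(classic$statistic), tolerance = 1e-10)
  # asymptotically the correction vanishes
  gL <- lapply(1:k, function(i) i + scale(rnorm(4000))[, 1])
  cL <- oneway.test(y ~ grp, data.frame(
    y = unlist(gL), grp = rep(letters[1:k], each = 4000)), var.equal = TRUE)
  expect_equal(welch_anova(gL)$statistic, unname(cL$statistic),
               tolerance = 1e-3)

  # seeded normals vs independent formula evaluation and oneway.test
  set.seed(42)
  g2 <- list(a = rnorm(5, 0, 1), b = rnorm(7, 0.5, 2), c = rnorm(9, 1, 3))
  w2 <- welch_anova(g2)
  orc <- welch_oracle(g2)
  expect_equal(w2$statistic, orc$f, tolerance = 1e-10)
  expect_equal(w2$df2, orc$df2, tolerance = 1e-10)
  expect_equal(w2$p, orc$p, tolerance = 1e-10)
  ow <- oneway.test(y ~ grp, data.frame(
    y = unlist(g2), grp = rep(letters[1:3], times = c(5, 7, 9))),
    var.equal = FALSE)
  expect_equal(w2$statistic, unname(ow$statistic), tolerance = 1e-10)
  expect_equal(w2$p, unname(ow$p.value), tolerance = 1e-10)

  expect_error(welch_anova(list(a = c(1, 1), b = c(2, 2))), "zero")
})

test_that("games_howell: identical groups, Welch-t mapping, symmetry, family bound", {
  set.seed(3)
  x <- rnorm(12)
  gh0 <- games_howell(list(a = x, b = x))
  expect_gt(gh0$p, 0.999)
  expect_true(gh0$lo <= 0 && gh0$hi >= 0)

  # exactly two groups: p is the studentized-range transform of Welch's t
  g <- list(a = rnorm(8, 0, 1), b = rnorm(11, 1, 2))
  gh <- games_howell(g)
  tt <- t.test(g$a, g$b)
  expect_equal(abs(gh$t), unname(abs(tt$statistic)), tolerance = 1e-10)
  expect_equal(gh$df, unname(tt$parameter), tolerance = 1e-10)
  expect_equal(gh$p,
               ptukey(abs(gh$t) * sqrt(2), 2, gh$df, lower.tail = FALSE),
               tolerance = 1e-12)

  # relabelling symmetry
  g3 <- list(a = rnorm(6), b = rnorm(9, 0.5), c = rnorm(7, 1))
  gh3 <- games_howell(g3)
  gh3r <- games_howell(rev(g3))
  key <- function(d) {
    k <- apply(cbind(d$group1, d$group2), 1, function(r)
      paste(sort(r), collapse = "-"))
    d$p[order(k)]
  }
  expect_equal(key(gh3), key(gh3r), tolerance = 1e-12)

  # each Games-Howell p >= the unadjusted Welch-t p for that pair
  for (i in seq_len(nrow(gh3))) {
    pa <- g3[[gh3$group1[i]]]; pb <- g3[[gh3$group2[i]]]
    expect_gte(gh3$p[i], t.test(pa, pb)$p.value - 1e-12)
  }
})

test_that("cohens_d: zero, unit, sign and errors", {
  expect_equal(cohens_d(c(1, 2, 3), c(1, 2, 3)), 0)
  # means one pooled SD apart
  x <- c(-1, 0, 1); y <- x + sd(x)
  expect_equal(abs(cohens_d(y, x)), 1)
  expect_gt(cohens_d(c(5, 6, 7), c(1, 2, 3)), 0)
  expect_error(cohens_d(c(1, 1), c(1, 1)), "pooled")
})

test_that("levene_test: identical groups, type-I calibration, power", {
  r <- levene_test(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_equal(r$p, 1)
  # type-I error under equal variances: 500 seeded replicates
  set.seed(99)
  rej <- 0L
  for (i in 1:500) {
    gg <- list(rnorm(20), rnorm(20), rnorm(20))
    if (levene_test(gg)$p < 0.05) rej <- rej + 1L
  }
  expect_lt(abs(rej / 500 - 0.05), 0.02)
  # power for a scale shift at n = 100
  set.seed(7)
  p <- levene_test(list(rnorm(100, 0, 1), rnorm(100, 0, 3)))$p
  expect_lt(p, 0.01)
})

test_that("spearman and partial spearman: identities and residual-rank oracle", {
  x <- c(3, 1, 4, 1.5, 9, 2.6, 5)
  expect_equal(spearman_cor(x, x)$statistic, 1)
  expect_equal(spearman_cor(x, -x)$statistic, -1)
  expect_error(spearman_cor(x, rep(1, 7)), "constant")

  set.seed(12)
  y <- x + rnorm(7, 0, 0.1)
  expect_equal(partial_spearman(x, y)$statistic,
               spearman_cor(x, y)$statistic)

  # trivariate: y = x + noise, z = x; controlling z collapses r(x, y)
  set.seed(5)
  n <- 60
  xx <- rnorm(n); zz <- xx + rnorm(n, 0, 0.05); yy <- xx + rnorm(n, 0, 0.5)
  simple <- spearman_cor(xx, yy)$statistic
  part <- partial_spearman(xx, yy, zz)$statistic
  expect_lt(abs(part), abs(simple) / 2)
  # residual-rank oracle: correlate residuals of rank regressions
  rx <- rank(xx); ry <- rank(yy); rz <- rank(zz)
  ex <- residuals(lm(rx ~ rz)); ey <- residuals(lm(ry ~ rz))
  expect_equal(part, unname(cor(ex, ey)), tolerance = 1e-8)

  # exact collinearity in the controls is reported, not silently wrong
  expect_error(partial_spearman(xx, yy, xx), "singular")

  # rank statistics are invariant to strictly monotone transforms
  set.seed(8)
  a <- rlnorm(20); b <- rlnorm(20)
  expect_equal(spearman_cor(a, b)$statistic,
               spearman_cor(log(a), sqrt(b))$statistic)
})

test_that("moods_median: degenerate, hand-computed chi-square, rank invariance", {
  set.seed(4)
  x <- rnorm(10)
  r0 <- moods_median(x, x)
  expect_equal(r0$statistic, 0)

  # table (9,1 / 1,9): chi2 = N(ad-bc)^2 / (r1 r2 c1 c2) = 12.8
  x1 <- c(1:9 + 100, 1)        # 9 above, 1 below the grand median
  y1 <- c(1:9, 101)
  r1 <- moods_median(x1, y1)
  expect_equal(r1$statistic, 12.8)
  expect_lt(r1$p, 0.001)

  # invariance under strictly monotone transform
  a <- rlnorm(15, 1); b <- rlnorm(12, 2)
  expect_equal(moods_median(a, b)$statistic,
               moods_median(log(a), log(b))$statistic)
  expect_error(moods_median(c(1, 1), c(1, 1)), "equal")
})

test_that("wilcoxon_median_ci: achieved levels, exact method, Walsh endpoints", {
  set.seed(10)
  for (cse in list(c(21, 94.8), c(12, 94.5), c(9, 95.6))) {
    x <- rnorm(cse[1])
    ci <- wilcoxon_median_ci(x)
    expect_equal(round(100 * ci$level, 1), cse[2])
    expect_lte(ci$lo, ci$median)
    expect_gte(ci$hi, ci$median)
  }
  # exact method: achieved level comes from the exact null distribution and
  # endpoints are Walsh averages
  x <- rnorm(15)
  ce <- wilcoxon_median_ci(x, method = "exact")
  ws <- outer(sort(x), sort(x), "+") / 2
  walsh <- sort(ws[lower.tri(ws, diag = TRUE)])
  k <- which(walsh == ce$lo)[1]
  expect_equal(ce$level, 1 - 2 * psignrank(k - 1, 15))
  expect_equal(ce$hi, walsh[length(walsh) + 1 - k])
  expect_error(wilcoxon_median_ci(c(1, 2, 3)), "n >= 4")
})

test_that("linear_trend: exact recovery and normal-equations oracle", {
  x <- 1:10
  expect_equal(linear_trend(x, 2 * x + 3), list(slope = 2, intercept = 3))
  expect_equal(linear_trend(x, rep(5, 10))$slope, 0)
  set.seed(6)
  y <- 1.5 * x + rnorm(10)
  tr <- linear_trend(x, y)
  cf <- unname(coef(lm(y ~ x)))
  expect_equal(tr$intercept, cf[1], tolerance = 1e-12)
  expect_equal(tr$slope, cf[2], tolerance = 1e-12)
})

test_that("empirical_variogram: constant field, white noise, range recovery", {
  set.seed(14)
  coords <- cbind(runif(300, 0, 100), runif(300, 0, 100))
  vg0 <- empirical_variogram(rep(3, 300), coords)
  expect_true(all(vg0$gamma == 0))

  wn <- rnorm(300, 0, 2)
  vgw <- empirical_variogram(wn, coords)
  # flat at the sample variance within Monte-Carlo error
  expect_lt(max(abs(vgw$gamma - var(wn))) / var(wn), 0.35)

  # parameter recovery: exponential-covariance Gaussian field
  set.seed(15)
  n <- 2000; true_range <- 15
  cds <- cbind(runif(n, 0, 100), runif(n, 0, 100))
  S <- exp(-as.matrix(dist(cds)) / true_range)
  vals <- drop(t(chol(S + diag(1e-8, n))) %*% rnorm(n))
  fit <- fit_exponential_variogram(
    empirical_variogram(vals, cds, lag_bins = 15))
  expect_lt(abs(fit$range - true_range) / true_range, 0.25)
  expect_error(empirical_variogram(c(1, 2), rbind(c(0, 0), c(0, 0))),
               "degenerate")
})
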