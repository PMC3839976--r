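test_that("the proportional chance criterion follows its definition", {
  expect_equal(cpro(24, 24), 0.5)
  expect_equal(cpro(48, 0), 1)
  expect_equal(cpro(30, 18), 0.53125)
  # minimized at balance, monotone in imbalance
  vals <- vapply(0:24, function(k) cpro(24 - k, 24 + k), numeric(1))
  expect_equal(vals[1], min(vals))
  expect_true(all(diff(vals) > 0))
  expect_error(cpro(-1, 5), "non-negative")
  expect_error(cpro(0, 0), "positive")
})

test_that("the improvement z-statistic and p-value behave as defined", {
  expect_equal(improvement_z(24, 48, 0.5)$z, 0)
  z <- improvement_z(36, 48, 0.5)
  expect_equal(z$z, 12 / sqrt(12))
  expect_equal(round(z$z, 4), 3.4641)
  expect_equal(z$p, 2 * pnorm(-z$z))
  # below-chance: negative z, small p
  zlow <- improvement_z(10, 48, 0.5)
  expect_lt(zlow$z, 0)
  expect_lt(zlow$p, 0.001)
  # legacy density convention
  expect_equal(improvement_z(36, 48, 0.5, compat_pdf = TRUE)$p,
               dnorm(sqrt(12)))
  expect_error(improvement_z(10, 48, 1), "strictly between")
  # agreement with the exact binomial oracle (mid-p) at N = 48
  pb <- 2 * (pbinom(36, 48, 0.5, lower.tail = FALSE) +
               0.5 * dbinom(36, 48, 0.5))
  expect_lt(max(z$p / pb, pb / z$p), 1.3)
  # z agrees with the binomial-equivalent z across N in [20, 100]
  for (N in seq(20, 100, 8)) {
    nc <- round(N / 2 + 3.4641 * sqrt(N / 4))
    zz <- improvement_z(nc, N, 0.5)$z
    pb <- 2 * pbinom(nc - 1, N, 0.5, lower.tail = FALSE)
    zb <- qnorm(1 - pb / 2)
    expect_lt(max(zz / zb, zb / zz), 1.3)
  }
})

test_that("the improvement-over-chance effect size hits its identities", {
  expect_equal(iocc(0.5, 0.5), 0)
  expect_equal(iocc(1, 0.5), 1)
  expect_equal(iocc(0.75, 0.5), 0.5)
  expect_equal(iocc(0.25, 0.5), -0.5)
  expect_error(iocc(0.5, 1), "undefined")
  st <- chance_stats(30, 20, 28)
  expect_equal(st$cpro, cpro(20, 28))
  expect_equal(sign(st$iocc), sign(st$z))
})

test_that("Benjamini-Hochberg equals the brute-force step-up everywhere", {
  expect_true(all(fdr_bh(rep(0.001, 10))$rejected))
  expect_true(all(fdr_bh(c(0.01, 0.02, 0.03, 0.04, 0.05))$rejected))
  expect_false(any(fdr_bh(c(0.04, 0.2, 0.5))$rejected))
  expect_error(fdr_bh(numeric(0)), "empty")
  # exhaustive comparison on all non-empty subsets of 10 p-values
  brute <- function(p, q = 0.05) {
    m <- length(p); o <- order(p)
    thr <- 0
    for (i in seq_len(m)) if (p[o[i]] <= q * i / m) thr <- p[o[i]]
    p <= thr & thr > 0
  }
  base <- c(0.001, 0.004, 0.01, 0.02, 0.049, 0.05, 0.12, 0.2, 0.6, 0.94)
  for (mask in 1:1023) {
    p <- base[bitwAnd(mask, 2^(0:9)) > 0]
    got <- fdr_bh(p)
    want <- brute(p)
    expect_identical(got$rejected, want)
    expect_equal(got$threshold, if (any(want)) max(p[want]) else 0)
  }
})

test_that("above-chance counting requires small p and positive effect", {
  res <- data.frame(
    subject = c("a", "b", "c", "d"), group = "g",
    feature = "f", classifier = "svm_linear",
    p = c(0.001, 0.001, 0.2, 0.001), iocc = c(0.8, -0.7, 0.1, 0.9),
    failed = c(FALSE, FALSE, FALSE, TRUE))
  unc <- count_above_chance(res)
  expect_equal(nrow(unc), 3)                 # failed excluded
  expect_equal(sum(unc$above_chance), 1)     # below-chance not counted
  cor <- count_above_chance(res, corrected = TRUE)
  expect_equal(sum(cor$above_chance), 1)
  # perfect accuracy counts in both modes
  res2 <- data.frame(subject = "s", group = "g", feature = "f",
                     classifier = "c", p = 1e-10, iocc = 1, failed = FALSE)
  expect_true(count_above_chance(res2)$above_chance)
  expect_true(count_above_chance(res2, corrected = TRUE)$above_chance)
})

test_that("the signed-rank test is exact for small n and tie-aware", {
  expect_equal(wilcoxon_signed_rank(c(5, 5, 5), c(5, 5, 5))$p, 1)
  expect_equal(wilcoxon_signed_rank(c(1, 2, 3))$p, 0.25)
  # n = 12 brute force over all 4096 sign assignments
  set.seed(9)
  x <- rnorm(12); y <- rnorm(12)
  d <- x - y; r <- rank(abs(d)); V <- sum(r[d > 0])
  allV <- vapply(0:4095, function(b)
    sum(r[bitwAnd(b, 2^(0:11)) > 0]), numeric(1))
  want <- min(1, 2 * min(mean(allV <= V), mean(allV >= V)))
  got <- wilcoxon_signed_rank(x, y)
  expect_equal(got$p, want)
  expect_equal(got$p, wilcox.test(x, y, paired = TRUE, exact = TRUE)$p.value)
  # mid-ranked ties still give a valid exact distribution
  tied <- wilcoxon_signed_rank(c(1, 1, 2, -1, -1, 3), mu = 0)
  expect_true(tied$p > 0 && tied$p <= 1)
  expect_equal(tied$method, "exact")
  # large n falls back to the corrected normal approximation
  set.seed(10)
  xl <- rnorm(40) + 0.5
  big <- wilcoxon_signed_rank(xl)
  ref <- wilcox.test(xl, exact = FALSE, correct = TRUE)$p.value
  expect_equal(big$p, ref, tolerance = 1e-10)
})

test_that("group summaries report mean, SD, range and counts", {
  res <- data.frame(
    subject = c("s1", "s2", "s3"), group = "healthy",
    feature = "fft", classifier = "svm_linear",
    N = 48, n_correct = c(19, 29, 2), accuracy = c(0.4, 0.6, 0.99),
    cpro = 0.5, z = 1, p = c(0.3, 0.2, 1e-8), iocc = c(-0.2, 0.2, 0.98),
    failed = c(FALSE, FALSE, TRUE), reason = NA)
  s <- summarize_group(res)
  expect_equal(s$mean_accuracy, 0.5)
  expect_equal(s$range_accuracy, 0.2)
  expect_equal(s$n_subjects, 2)
  expect_equal(attr(s, "n_failed"), 1)
  # single subject: SD and range are zero
  s1 <- summarize_group(res[2, ])
  expect_equal(s1$sd_accuracy, 0)
  expect_equal(s1$range_accuracy, 0)
  expect_error(summarize_group(res[res$failed, ]), "no non-failed")
})

test_that("comparison tables detect planted structure and size families", {
  # 20 features x 2 classifiers x 3 groups with a dominant feature
  set.seed(11)
  feats <- sprintf("f%02d", 1:20)
  grid <- expand.grid(subject = sprintf("s%02d", 1:8), feature = feats,
                      classifier = c("svm_linear", "knn_k1"),
                      group = c("g1", "g2", "g3"),
                      stringsAsFactors = FALSE)
  grid$N <- 48
  dominant <- grid$feature == "f01" & grid$classifier == "svm_linear"
  grid$accuracy <- ifelse(dominant, 0.95, 0.5 + rnorm(nrow(grid), 0, 0.02))
  grid$n_correct <- round(grid$accuracy * 48)
  grid$cpro <- 0.5
  st <- improvement_z(grid$n_correct, 48, 0.5)
  grid$z <- st$z; grid$p <- st$p
  grid$iocc <- iocc(grid$accuracy, 0.5)
  grid$failed <- FALSE; grid$reason <- NA
  s <- summarize_group(grid)
  cmp <- compare_features_and_classifiers(s, best_classifier = "svm_linear")
  fam <- attr(cmp, "family_sizes")
  expect_equal(unname(fam["metrics"]), 180L)  # 20 features x 3 metrics x 3 groups
  expect_equal(unname(fam["counts"]), 120L)   # 20 x 2 corrections x 3 groups
  fc <- cmp$features_counts
  expect_true(all(fc$significant_fdr[fc$feature == "f01" &
                                       fc$correction == "uncorrected"]))
  # identical classifier count profiles compare as non-significant
  grid2 <- grid; grid2$accuracy <- 0.5; grid2$n_correct <- 24
  grid2$p <- 1; grid2$iocc <- 0
  cmp2 <- compare_features_and_classifiers(summarize_group(grid2))
  expect_true(all(cmp2$classifiers$p == 1))
  expect_error(compare_features_and_classifiers(s[s$feature == "f01", ]),
               "at least 2")
})

test_that("normality checks flag non-normal samples and degeneracy", {
  set.seed(12)
  norm_ok <- vapply(1:20, function(i)
    normality_check(rnorm(500))$lilliefors_p > 0.05, logical(1))
  expect_gte(sum(norm_ok), 17)
  unif_bad <- vapply(1:20, function(i)
    normality_check(runif(500))$lilliefors_p < 0.05, logical(1))
  expect_gte(sum(unif_bad), 17)
  chi_bad <- vapply(1:20, function(i)
    normality_check(rexp(500))$chisq_p < 0.05, logical(1))
  expect_gte(sum(chi_bad), 17)
  expect_true(normality_check(rep(3, 50))$degenerate)
  expect_error(normality_check(1:5), "at least 8")
})
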