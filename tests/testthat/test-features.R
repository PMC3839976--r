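test_that("the dimension table holds for the 21-channel montage", {
  d <- feature_dimensions(21)
  expect_length(d, 20)
  expect_identical(sort(names(d)), sort(feature_names()))
  expect_equal(unname(d[c("hjorth_activity", "fft", "coherence",
                          "granger_gw", "granger_pp", "pdc", "dtf")]),
               c(21L, 252L, 2520L, 5040L, 252L, 5040L, 5040L))
  expect_equal(unname(d[c("wackermann_sigma", "wackermann_phi",
                          "wackermann_omega")]), c(1L, 1L, 1L))
})

test_that("extracted matrices match the dimension table", {
  set.seed(1)
  labs <- micf_analysis_channels()
  eps <- lapply(1:2, function(i) {
    m <- matrix(rnorm(21 * 1000), 21, dimnames = list(labs, NULL))
    m
  })
  tr <- mk_trials(eps, c("imagery", "rest"), labels = labs)
  for (fn in c("hjorth_activity", "brainrate", "wackermann_omega",
               "fft", "coherence", "shannon_spacing", "correntropy")) {
    fm <- extract_feature_matrix(tr, fn)
    expect_equal(ncol(fm$values), unname(feature_dimensions(21)[fn]),
                 info = fn)
    expect_equal(nrow(fm$values), 2)
  }
  # directed measures on a channel subset follow the same K(K-1) rule
  tr4 <- mk_trials(lapply(eps, function(e) e[1:4, ]),
                   c("imagery", "rest"), labels = labs[1:4])
  for (fn in c("pdc", "dtf", "granger_gw", "granger_pp")) {
    fm <- extract_feature_matrix(tr4, fn, opts = list(max_order = 3))
    expect_equal(ncol(fm$values), unname(feature_dimensions(4)[fn]),
                 info = fn)
  }
  expect_error(extract_feature_matrix(tr, "not_a_feature"),
               "registry error")
})

test_that("Hjorth parameters match their defining ratios", {
  x <- sin(2 * pi * 10 * (0:999) / 250)
  h <- hjorth(matrix(x, 1))
  v0 <- var(x); d1 <- diff(x); d2 <- diff(d1)
  mob <- sqrt(var(d1) / v0)
  expect_equal(unname(h[, 1]),
               c(v0, mob, sqrt(var(d2) / var(d1)) / mob))
  # white-noise activity concentrates near its variance
  set.seed(2)
  act <- hjorth(matrix(rnorm(1000), 1))["activity", 1]
  expect_true(act > 0.85 && act < 1.15)
  # constant channel: activity 0, the rest undefined
  hc <- hjorth(matrix(5, 1, 100))
  expect_equal(unname(hc[, 1]), c(0, NA, NA))
  # amplitude covariance: activity ~ a^2, mobility invariant
  set.seed(3); y <- rnorm(500)
  h1 <- hjorth(matrix(y, 1)); h2 <- hjorth(matrix(3 * y, 1))
  expect_equal(h2["activity", 1], 9 * h1["activity", 1])
  expect_equal(h2["mobility", 1], h1["mobility", 1])
})

test_that("brainrate recovers narrowband frequencies and band midpoints", {
  t <- (0:999) / 250
  br <- brainrate(matrix(sin(2 * pi * 10.5 * t), 1), 250)
  expect_lt(abs(br - 10.5), 0.3)
  # equal power in all five bands averages the midpoints: 12.1 Hz
  mids <- c(2.5, 6, 10.5, 16.5, 25)
  x <- rowSums(vapply(mids, function(f) sin(2 * pi * f * t +
                                              f), numeric(1000)))
  expect_lt(abs(brainrate(matrix(x, 1), 250) - 12.1), 0.3)
  expect_true(is.na(brainrate(matrix(1, 1, 1000), 250)))
})

test_that("Wackermann descriptors hit their analytic limits", {
  # rank-one topography: omega = 1
  same <- matrix(rep(rnorm(1000), each = 5), 5)
  w <- wackermann(same, 250)
  expect_lt(abs(w["omega"] - 1), 1e-6)
  # 21 independent channels: omega near the channel count
  set.seed(4)
  w2 <- wackermann(matrix(rnorm(21 * 4000), 21), 250)
  expect_true(w2["omega"] >= 18 && w2["omega"] <= 21)
  # pure f-Hz oscillation: global frequency near f
  s <- matrix(rep(sin(2 * pi * 10 * (0:999) / 250), each = 2), 2)
  expect_lt(abs(wackermann(s, 250)["phi"] - 10), 0.2)
  # zero epoch
  w0 <- wackermann(matrix(0, 3, 100), 250)
  expect_equal(unname(w0["sigma"]), 0)
  expect_true(all(is.na(w0[c("phi", "omega")])))
})

test_that("rescaled-range Hurst exponent separates noise classes", {
  set.seed(5)
  white <- mean(replicate(30, hurst_rs(matrix(rnorm(1000), 1))))
  expect_true(white > 0.45 && white < 0.60)
  brown <- mean(replicate(10, hurst_rs(matrix(cumsum(rnorm(1000)), 1))))
  expect_gt(brown, 0.8)
  expect_true(is.na(hurst_rs(matrix(2, 1, 1000))))
})

test_that("binned FFT places a 10 Hz sine in the 10.76 Hz bin", {
  x <- matrix(sin(2 * pi * 10 * (0:999) / 250), 1)
  bp <- fft_binned_power(x, 250)
  expect_equal(which.max(bp[1, ]), 5)   # center 10.76, edges 9.54-11.98
  expect_true(all(fft_binned_power(matrix(0, 1, 1000), 250) == 0))
})

test_that("coherence is 1 for duplicated channels and matches a Welch oracle", {
  set.seed(6)
  x <- rnorm(1000)
  dup <- rbind(x, x)
  expect_true(all(coherence_binned(dup, 250) >= 0.999))
  # independent pair: package values equal an independently coded Welch
  # estimate, and the mean reflects the known estimator bias
  y <- rnorm(1000)
  cb <- coherence_binned(rbind(x, y), 250)
  or <- oracle_msc(x, y, 250)
  binning <- frequency_binning()
  ob <- vapply(seq_len(12), function(b)
    mean(or$msc[or$freq >= binning$lower[b] & or$freq < binning$upper[b]]),
    numeric(1))
  expect_equal(unname(cb[1, ]), ob, tolerance = 1e-10)
  bias <- mean(replicate(40, mean(coherence_binned(
    rbind(rnorm(1000), rnorm(1000)), 250))))
  expect_lt(abs(bias - 1 / 8), 0.05)    # approx 1/segments
  expect_true(all(cb >= 0 & cb <= 1))
})

test_that("MVAR fitting recovers order and coefficients of a known VAR(2)", {
  set.seed(7)
  A <- list(matrix(c(0.5, 0.4, 0, 0.6), 2, byrow = TRUE),
            matrix(c(-0.3, 0, 0, -0.2), 2, byrow = TRUE))
  hits <- coef_ok <- 0
  for (i in 1:12) {
    x <- sim_var(A, 5000)
    m <- fit_mvar(x, 20)
    hits <- hits + (m$order == 2)
    if (m$order == 2)
      coef_ok <- coef_ok + all(abs(m$A[1, , ] - A[[1]]) < 0.05,
                               abs(m$A[2, , ] - A[[2]]) < 0.05)
  }
  expect_gte(hits, 11)
  expect_gte(coef_ok, 11)
  # white noise: near-zero coefficients, order never above the cap
  m0 <- fit_mvar(matrix(rnorm(4000), 2), 20)
  expect_lt(max(abs(m0$A)), 0.1)
  expect_lte(m0$order, 20)
})

test_that("PDC is column-normalized and directional; DTF row-normalized", {
  set.seed(8)
  A <- list(matrix(c(0.6, 0, 0.8, 0.3), 2, byrow = TRUE),
            matrix(c(-0.5, 0, 0, 0), 2, byrow = TRUE))
  x <- sim_var(A, 4000)
  m <- fit_mvar(x, 20)
  # exact column normalization of |PDC|^2 at a raw frequency
  Af <- micf:::mvar_afreq(m, 10, 250)
  P <- sweep(Mod(Af), 2, sqrt(colSums(Mod(Af)^2)), `/`)
  expect_equal(colSums(P^2), c(1, 1), tolerance = 1e-12)
  pd <- directed_spectral(m, method = "pdc", rate = 250)
  expect_gte(max(pd["ch1->ch2", ]), 3 * max(pd["ch2->ch1", ]))
  dt <- directed_spectral(m, method = "dtf", rate = 250)
  expect_gt(max(dt["ch1->ch2", ]), max(dt["ch2->ch1", ]))
  expect_true(all(pd >= 0 & pd <= 1) && all(dt >= 0 & dt <= 1))
  # uncoupled channels stay low
  xu <- rbind(sim_var(list(matrix(c(0.5, 0, 0, 0), 2)), 3000)[1, ],
              sim_var(list(matrix(c(0.5, 0, 0, 0), 2)), 3000)[1, ])
  pu <- directed_spectral(fit_mvar(xu, 20), method = "pdc", rate = 250)
  expect_lt(mean(pu), 0.15)
})

test_that("spectral Granger causality is directional and non-negative", {
  set.seed(9)
  A <- list(matrix(c(0.6, 0, 0.8, 0.3), 2, byrow = TRUE),
            matrix(c(-0.5, 0, 0, 0), 2, byrow = TRUE))
  x <- sim_var(A, 4000)
  g <- granger_spectral(x, 250)
  expect_gt(max(g$gw["ch1->ch2", ]), max(g$gw["ch2->ch1", ]))
  expect_true(all(g$gw >= 0))
  expect_equal(dim(g$pp), c(2, 12))
  xu <- rbind(sim_var(list(matrix(c(0.5, 0, 0, 0), 2)), 3000)[1, ],
              sim_var(list(matrix(c(0.5, 0, 0, 0), 2)), 3000)[1, ])
  gu <- granger_spectral(xu, 250)
  expect_lt(mean(gu$gw), 0.05)
})

test_that("approximate entropy equals a direct double-loop oracle", {
  apen_oracle <- function(x, m, r) {
    n <- length(x)
    phi <- function(mm) {
      nt <- n - mm + 1
      tpl <- sapply(seq_len(nt), function(i) x[i:(i + mm - 1)])
      cnt <- vapply(seq_len(nt), function(i)
        sum(vapply(seq_len(nt), function(j)
          max(abs(tpl[, i] - tpl[, j])) <= r, logical(1))), numeric(1))
      mean(log(cnt / nt))
    }
    phi(m) - phi(m + 1)
  }
  set.seed(10)
  x <- rnorm(60)
  r <- 0.2 * sd(x)
  expect_equal(approximate_entropy(matrix(x, 1), 2, 0.2)[[1]],
               apen_oracle(x, 2, r), tolerance = 1e-10)
  # white noise is less regular than a sine of equal variance
  t <- (0:499) / 250
  s <- sin(2 * pi * 10 * t) * sqrt(2)
  set.seed(11); w <- rnorm(500)
  expect_gt(approximate_entropy(matrix(w, 1))[[1]],
            approximate_entropy(matrix(s, 1))[[1]])
  expect_equal(approximate_entropy(matrix(1, 1, 100))[[1]], 0)
})

test_that("spacing entropies match closed forms", {
  set.seed(12)
  sh_u <- median(replicate(40,
    spacing_entropy(matrix(runif(1000), 1), "shannon")[[1]]))
  expect_lt(abs(sh_u), 0.1)                       # ln(1) = 0
  sh_g <- median(replicate(40,
    spacing_entropy(matrix(rnorm(1000), 1), "shannon")[[1]]))
  expect_lt(abs(sh_g - 0.5 * log(2 * pi * exp(1))), 0.1)
  re_g <- median(replicate(40,
    spacing_entropy(matrix(rnorm(1000), 1), "renyi", alpha = 2)[[1]]))
  expect_lt(abs(re_g - log(2 * sqrt(pi))), 0.1)   # -log int f^2
  # shift invariance of spacings
  x <- matrix(rnorm(500), 1)
  expect_equal(spacing_entropy(x, "shannon")[[1]],
               spacing_entropy(x + 100, "shannon")[[1]], tolerance = 1e-12)
})

test_that("kNN Tsallis entropy matches the Gaussian closed form", {
  set.seed(13)
  q <- 1.5
  target <- (1 - (2 * pi)^((1 - q) / 2) / sqrt(q)) / (q - 1)
  est <- median(replicate(40,
    knn_entropy_tsallis(matrix(rnorm(1000), 1), q = q, k = 4)[[1]]))
  expect_lt(abs(est - target) / target, 0.1)
  # q -> 1 approaches the spacing Shannon estimate
  x <- matrix(rnorm(1000), 1)
  expect_lt(abs(knn_entropy_tsallis(x, q = 1.01, k = 4)[[1]] -
                  spacing_entropy(x, "shannon")[[1]]), 0.15)
  # permutation invariance
  y <- rnorm(300)
  expect_equal(knn_entropy_tsallis(matrix(y, 1), 1.5, 4)[[1]],
               knn_entropy_tsallis(matrix(sample(y), 1), 1.5, 4)[[1]])
})

test_that("kNN Bhattacharyya distance matches the Gaussian closed form", {
  set.seed(14)
  same <- median(replicate(30, {
    x <- rnorm(1000); bhattacharyya_knn(x[1:500], x[501:1000])
  }))
  expect_lt(abs(same), 0.1)
  sep <- median(replicate(30,
    bhattacharyya_knn(rnorm(500), rnorm(500) + 2)))
  expect_lt(abs(sep - 0.5) / 0.5, 0.2)            # (mu1-mu2)^2/8 = 0.5
  a <- rnorm(300); b <- rnorm(300) + 1
  expect_equal(bhattacharyya_knn(a, b), bhattacharyya_knn(b, a),
               tolerance = 1e-12)
})

test_that("correntropy matches its Gaussian expectation and invariances", {
  expect_equal(correntropy_kde(matrix(7, 1, 200))[[1]], 1)   # kernel max
  set.seed(15)
  x <- rnorm(50000)
  # lag-1 differences of iid N(0,1) are N(0,2): E k(d) = w/sqrt(w^2+2)
  expect_lt(abs(correntropy_kde(matrix(x, 1), kernel_width = 1)[[1]] -
                  1 / sqrt(3)) * sqrt(3), 0.05)
  y <- matrix(rnorm(500), 1)
  expect_equal(correntropy_kde(y, 0.5)[[1]],
               correntropy_kde(y + 42, 0.5)[[1]], tolerance = 1e-12)
})

test_that("global scaling leaves scale-invariant features unchanged", {
  set.seed(16)
  ep <- matrix(rnorm(4 * 1000), 4,
               dimnames = list(paste0("ch", 1:4), NULL))
  eps <- list(ep, 5 * ep)
  expect_equal(coherence_binned(eps[[1]], 250),
               coherence_binned(eps[[2]], 250), tolerance = 1e-9)
  expect_equal(hurst_rs(eps[[1]]), hurst_rs(eps[[2]]), tolerance = 1e-9)
  m1 <- fit_mvar(eps[[1]], 5); m2 <- fit_mvar(eps[[2]], 5)
  expect_equal(directed_spectral(m1, method = "pdc", rate = 250),
               directed_spectral(m2, method = "pdc", rate = 250),
               tolerance = 1e-8)
  w1 <- wackermann(eps[[1]], 250); w2 <- wackermann(eps[[2]], 250)
  expect_equal(w1["omega"], w2["omega"], tolerance = 1e-9)
})

test_that("degenerate inputs are flagged, mirroring the constant-brainrate case", {
  eps <- lapply(1:4, function(i) matrix(1, 3, 1000))
  tr <- mk_trials(eps, rep(c("imagery", "rest"), 2))
  fm <- extract_feature_matrix(tr, "brainrate")
  expect_true(fm$degenerate)
  expect_true(loocv(fm, classifier_spec("knn", 1))$failed)
})
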