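test_that("TRV implements the printed formula and its symmetries", {
  expect_equal(trv(5, 5), 0)
  expect_equal(trv(1, 3), 100)
  # ACC mean V_T pair: direct formula evaluation
  expect_equal(trv(6.28, 6.85), abs(6.85 - 6.28) / ((6.28 + 6.85) / 2) * 100)
  expect_equal(round(trv(6.28, 6.85), 2), 8.68)
  set.seed(2)
  x <- runif(50, 1, 10); y <- runif(50, 1, 10); a <- runif(50, 0.1, 7)
  expect_equal(trv(x, y), trv(y, x))
  expect_equal(trv(a * x, a * y), trv(x, y), tolerance = 1e-12)
  expect_error(trv(-2, 1), "positive")
})

test_that("one-way ICC matches a from-scratch ANOVA oracle", {
  # identical sessions: perfect reliability
  m <- cbind(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(icc_oneway(m), 1)
  # direct formula: msb = 3, msw = 1 -> (3-1)/(3+1)
  # construct data with exact mean squares via the decomposition
  oracle_icc <- function(m) {
    n <- nrow(m); k <- ncol(m)
    gm <- mean(m)
    ssb <- 0; ssw <- 0
    for (i in seq_len(n)) {
      mi <- mean(m[i, ])
      ssb <- ssb + k * (mi - gm)^2
      for (j in seq_len(k)) ssw <- ssw + (m[i, j] - mi)^2
    }
    msb <- ssb / (n - 1); msw <- ssw / (n * (k - 1))
    (msb - msw) / (msb + (k - 1) * msw)
  }
  set.seed(7)
  for (rep in 1:200) {
    m <- matrix(rnorm(16, 10, 3), 8, 2)
    expect_equal(icc_oneway(m), oracle_icc(m), tolerance = 1e-10)
  }
  # and against stats::aov mean squares
  m <- matrix(rnorm(16, 5, 2), 8, 2)
  d <- data.frame(y = as.vector(m), subj = factor(rep(1:8, 2)))
  ms <- summary(stats::aov(y ~ subj, d))[[1]]$`Mean Sq`
  expect_equal(icc_oneway(m), (ms[1] - ms[2]) / (ms[1] + ms[2]),
               tolerance = 1e-10)
  expect_error(icc_oneway(m[1:2, ]), "3 subjects")
})

test_that("ICC limits: perfect agreement and reshuffled independence", {
  set.seed(12)
  base <- rnorm(40, 10, 3)
  expect_equal(icc_oneway(cbind(base, base)), 1)
  # mean ICC over independent reshuffles is ~0 (the one-way estimator has
  # a small negative O(1/n) finite-sample bias, hence many subjects here)
  vals <- replicate(400, {
    icc_oneway(cbind(sample(base), sample(base)))
  })
  expect_lt(abs(mean(vals)), 0.05)
  # location and scale invariance
  m <- matrix(rnorm(20, 8, 2), 10, 2)
  expect_equal(icc_oneway(m + 5), icc_oneway(m), tolerance = 1e-12)
  expect_equal(icc_oneway(m * 3), icc_oneway(m), tolerance = 1e-12)
})

test_that("reliability table summarizes per-region TRV/ICC and is order-invariant", {
  set.seed(3)
  d <- expand.grid(metric = c("A", "B"), subject = sprintf("S%d", 1:8))
  d$test <- runif(16, 4, 8)
  d$retest <- d$test * exp(rnorm(16, 0, 0.1))
  tab <- reliability_table(d)
  expect_equal(nrow(tab), 2)
  expect_true(all(tab$trv_mean >= 0))
  expect_true(all(tab$icc >= -1 & tab$icc <= 1))
  # permutation of subjects leaves the table unchanged
  perm <- d[sample(nrow(d)), ]
  expect_equal(reliability_table(perm), tab)
  # pairwise exclusion of incomplete subjects
  d2 <- d; d2$retest[d2$subject == "S1" & d2$metric == "A"] <- NA
  tab2 <- reliability_table(d2)
  expect_equal(tab2$n_subjects[tab2$metric == "A"], 7)
  expect_equal(tab2$n_subjects[tab2$metric == "B"], 8)
})

test_that("variance components are recovered through the ICC pipeline", {
  # subjects ~ N(mu, sb2), sessions ~ N(subject, sw2); true one-way ICC
  # = (sb2 - ... ) expectation ~ sb2/(sb2+sw2) = 0.8 here
  sb2 <- 1.0; sw2 <- 0.25
  true_icc <- sb2 / (sb2 + sw2)
  set.seed(31)
  est <- replicate(400, {
    mu <- rnorm(8, 10, sqrt(sb2))
    icc_oneway(cbind(rnorm(8, mu, sqrt(sw2)), rnorm(8, mu, sqrt(sw2))))
  })
  expect_lt(abs(mean(est) - true_icc), 0.05)
})

test_that("published per-region table reproduces the abstract summary", {
  path <- system.file("extdata", "fih_vt_reliability_2tcm.csv",
                      package = "petquant")
  tab <- read.csv(path, comment.char = "#")
  s <- summarize_reliability(data.frame(trv_mean = tab$trv_mean,
                                        icc = tab$icc))
  expect_equal(round(s$icc, 3), 0.496)
  expect_equal(round(s$trv_mean, 1), 16.5)
  expect_equal(round(c(s$icc_min, s$icc_max), 3), c(0.291, 0.644))
})
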