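test_that("percent injected dose is the direct formula", {
  expect_equal(percent_id(1000, 100, 1e6), 10)
  expect_equal(percent_id(1000, 200, 1e6), 20)  # linear in volume
  expect_error(percent_id(1000, 100, 0), "> 0")
})

test_that("urine voids accumulate onto the bladder curve", {
  bl <- organ_retention("urinary_bladder", c(0.5, 1.5, 3, 5), c(1, 1, 1, 1))
  expect_equal(bladder_with_urine(bl, NULL)$pid, bl$pid)
  one <- bladder_with_urine(bl, data.frame(t = 1, pid = 5))
  expect_equal(one$pid, c(1, 6, 6, 6))
  multi <- bladder_with_urine(bl, data.frame(t = c(1, 2.5), pid = c(5, 3)))
  expect_equal(multi$pid, c(1, 6, 9, 9))
  expect_error(bladder_with_urine(bl, data.frame(t = 1, pid = -2)), ">= 0")
})

test_that("retention fitting recovers sums of exponentials", {
  t <- c(0.15, 0.45, 0.75, 1.725, 2.175, 3.725, 4.175, 5.8)
  # plateau: a single term with lambda 0
  flat <- fit_retention(organ_retention("o", t, rep(10, 8)))
  expect_equal(sum(flat$a * exp(-flat$lambda * 10)), 10, tolerance = 1e-6)
  # biexponential recovery
  y <- 20 * exp(-0.5 * t) + 5 * exp(-0.05 * t)
  fit <- fit_retention(organ_retention("o", t, y), n_exp = 2)
  ord <- order(fit$lambda, decreasing = TRUE)
  expect_lt(abs(fit$a[ord[1]] - 20) / 20, 0.02)
  expect_lt(abs(fit$lambda[ord[1]] - 0.5) / 0.5, 0.02)
  expect_lt(abs(fit$a[ord[2]] - 5) / 5, 0.02)
  expect_lt(abs(fit$lambda[ord[2]] - 0.05) / 0.05, 0.02)
  # under-determined request
  expect_error(fit_retention(organ_retention("o", t[1:2], y[1:2]),
                             n_exp = 3), "determine")
})

test_that("residence time matches the physical-decay closed forms", {
  # whole body, no excretion: tau = T1/2 / ln 2 in hours
  target <- (109.77 / 60) / log(2)
  expect_equal(residence_time(list(a = 100, lambda = 0)), target,
               tolerance = 1e-10)
  expect_equal(residence_time(list(a = 10, lambda = 0)), target / 10,
               tolerance = 1e-10)
  # closed form vs numerical quadrature for a biexponential
  fit <- list(a = c(20, 5), lambda = c(0.5, 0.05))
  lam_p <- log(2) / (109.77 / 60)
  quad <- stats::integrate(function(tt) {
    (20 * exp(-0.5 * tt) + 5 * exp(-0.05 * tt)) * exp(-lam_p * tt) / 100
  }, 0, Inf, rel.tol = 1e-10)$value
  expect_equal(residence_time(fit), quad, tolerance = 1e-6)
  expect_error(residence_time(list(a = 1, lambda = -10)), "non-integrable")
})

test_that("absorbed doses are the S-matrix product with remainder routing", {
  s <- matrix(c(2, 0, 1, 3), 2, 2,
              dimnames = list(c("liver", "kidneys"), c("liver", "kidneys")))
  taus <- c(liver = 0.5, kidneys = 0.5)
  expect_equal(absorbed_doses(taus, s),
               c(liver = 2 * 0.5 + 1 * 0.5, kidneys = 0 * 0.5 + 3 * 0.5))
  expect_equal(unname(absorbed_doses(c(liver = 0, kidneys = 0), s)), c(0, 0))
  # identity S-matrix returns the residence times
  sm <- read_smatrix(system.file("extdata", "toy_smatrix.csv",
                                 package = "petquant"))
  ident <- diag(ncol(sm))
  dimnames(ident) <- list(colnames(sm), colnames(sm))
  taus2 <- stats::setNames(runif(ncol(sm), 0, 0.3), colnames(sm))
  expect_equal(absorbed_doses(taus2, ident), taus2[colnames(sm)])
  # unmatched organs fall into the remainder column
  taus3 <- c(liver = 0.1, thyroid = 0.2)
  d3 <- absorbed_doses(taus3, sm)
  d3b <- absorbed_doses(c(liver = 0.1, remainder = 0.2), sm)
  expect_equal(d3, d3b)
  expect_error(absorbed_doses(c(thyroid = 0.1), s), "missing")
})

test_that("effective dose weighting: uniform field, oracle, monotonicity", {
  scheme <- tissue_weights()
  dd <- read.csv(system.file("extdata", "fih_organ_doses.csv",
                             package = "petquant"), comment.char = "#")
  organs <- setdiff(dd$organ, c("effective_dose", "total_body"))
  uni <- stats::setNames(rep(7.5, length(organs)), organs)
  expect_equal(effective_dose(uni, scheme)$effective_dose, 7.5)
  # monotone non-decreasing in every organ dose
  base <- effective_dose(uni, scheme)$effective_dose
  for (org in c("liver", "pancreas", "testes", "uli_wall", "muscle")) {
    up <- uni; up[org] <- up[org] + 5
    expect_gte(effective_dose(up, scheme)$effective_dose, base)
  }
  expect_error(effective_dose(uni[setdiff(organs, "liver")], scheme),
               "liver")
  # brute-force dot product oracle on the named organs with a scheme
  # without surrogate/remainder indirection
  flat <- list(name = "flat", sex = "male",
               weights = as.list(stats::setNames(rep(1 / 4, 4),
                                                 c("liver", "lungs",
                                                   "kidneys", "spleen"))),
               surrogates = NULL, composites = NULL,
               remainder = list(weight = 0, organs = list("brain"),
                                masses = list(brain = 1400)))
  d <- c(liver = 10, lungs = 20, kidneys = 30, spleen = 40, brain = 1)
  expect_equal(effective_dose(d, flat)$effective_dose,
               sum(d[1:4] * 0.25))
})

test_that("published organ doses reproduce the published effective dose", {
  dd <- read.csv(system.file("extdata", "fih_organ_doses.csv",
                             package = "petquant"), comment.char = "#")
  doses <- stats::setNames(dd$mean, dd$organ)
  published <- doses[["effective_dose"]]
  doses <- doses[setdiff(names(doses), c("effective_dose", "total_body"))]
  ed <- effective_dose(doses)
  # the pancreas is the hottest remainder organ and triggers the ICRP-60
  # splitting rule
  expect_equal(ed$split_organ, "pancreas")
  expect_lt(abs(ed$effective_dose - published) / published, 0.05)
})
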