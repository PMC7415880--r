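test_that("EM recovers a well-separated mixture and is monotone", {
  set.seed(21)
  v <- c(rnorm(1000, 0, 1), rnorm(1000, 10, 1))
  g <- fit_protein_gmm(v, preprocessing = "raw")
  expect_lt(abs(sort(g$means)[1] - 0), 0.2)
  expect_lt(abs(sort(g$means)[2] - 10), 0.2)
  expect_lt(max(abs(g$weights - 0.5)), 0.05)
  expect_equal(g$on_component, which.max(g$means))
  # per-iteration mean log-likelihood never decreases
  expect_true(all(diff(g$log_lik) >= -1e-8))
})

test_that("clearly separated point masses force the on component", {
  set.seed(22)
  v <- c(rep(0, 500), rep(5, 500)) + rnorm(1000, 0, 1e-3)
  g <- fit_protein_gmm(v, preprocessing = "raw")
  expect_lt(abs(g$means[g$on_component] - 5), 0.1)
})

test_that("degenerate and undersized inputs error", {
  expect_error(fit_protein_gmm(rep(3, 100), preprocessing = "raw"),
               "identical")
  expect_error(fit_protein_gmm(c(1, 2, 3)), "at least 10")
})

test_that("probabilize matches brute-force Bayes and its limits", {
  set.seed(23)
  v <- c(rnorm(500, 1, 1), rnorm(500, 6, 1.5))
  g <- fit_protein_gmm(v, preprocessing = "raw")
  x <- runif(100, -2, 9)
  p <- probabilize(g, x)
  # direct oracle: weight * density products, normalized
  d1 <- g$weights[1] * dnorm(x, g$means[1], sqrt(g$variances[1]))
  d2 <- g$weights[2] * dnorm(x, g$means[2], sqrt(g$variances[2]))
  post_on <- (if (g$on_component == 1) d1 else d2) / (d1 + d2)
  expect_equal(p, post_on, tolerance = 1e-10)
  expect_true(all(p >= 0 & p <= 1))

  # symmetric midpoint -> 0.5 for an equal-weight equal-variance fit
  gsym <- g
  gsym$weights <- c(0.5, 0.5)
  gsym$variances <- c(1, 1)
  gsym$means <- c(0, 4)
  gsym$on_component <- 2L
  expect_equal(probabilize(gsym, 2), 0.5, tolerance = 1e-12)
  # limit: far into the on component
  expect_gt(probabilize(gsym, 100), 1 - 1e-10)

  expect_error(probabilize(list(), 1), "fitted")
})

test_that("binarize thresholds correctly and validates input", {
  expect_identical(binarize(c(0.1, 0.5, 0.9), 0.5), c(0L, 1L, 1L))
  expect_identical(binarize(c(0.1, 0.2), 0.5), c(0L, 0L))
  expect_error(binarize(c(0.5), 1.5), "\\(0, 1\\)")
  expect_error(binarize(c(-0.1, 0.5)), "\\[0, 1\\]")
})

test_that("mixture gating recovers the composition a naive split distorts", {
  # one rare high population (15%): a quantile split is pinned near
  # 50/50 regardless of the truth, while the mixture gate recovers the
  # generating composition
  set.seed(24)
  raw <- c(rnbinom(1700, size = 8, mu = 8), rnbinom(300, size = 8, mu = 120))
  g <- fit_protein_gmm(raw)   # log_normalized default
  b <- binarize(probabilize(g, raw), 0.5)
  frac_gate <- mean(b)
  frac_median <- mean(raw > median(raw))
  true_frac <- 300 / 2000
  expect_lt(abs(frac_gate - true_frac), 0.05)
  expect_lt(abs(frac_gate - true_frac), abs(frac_median - true_frac))
})

test_that("fit + probabilize assigns generating components correctly", {
  # means >= 6 SD apart: at least 95% of points recover their component
  set.seed(25)
  comp <- rbinom(2000, 1, 0.4)
  v <- rnorm(2000, mean = ifelse(comp == 1, 8, 0), sd = 1)
  g <- fit_protein_gmm(v, preprocessing = "raw")
  assigned <- probabilize(g, v) >= 0.5
  expect_gte(mean(assigned == (comp == 1)), 0.95)
})

test_that("protein table gating round-trips through JSON", {
  sim <- tiny_sim()
  plab <- probabilize_proteins(sim$proteins)
  expect_true(all(plab$prob >= 0 & plab$prob <= 1))
  expect_identical(plab$binary, binarize(plab$prob, 0.5))

  path <- withr::local_tempfile(fileext = ".json")
  write_protein_gmms(plab, path)
  back <- read_protein_gmms(path)
  expect_equal(names(back), sim$proteins$protein_ids)
  for (p in names(back)) {
    expect_equal(back[[p]]$means, plab$gmms[[p]]$means, tolerance = 1e-12)
    expect_equal(back[[p]]$weights, plab$gmms[[p]]$weights,
                 tolerance = 1e-12)
    expect_identical(back[[p]]$on_component, plab$gmms[[p]]$on_component)
    # restored gate reproduces the probabilities
    expect_equal(probabilize(back[[p]], sim$proteins$values[, p]),
                 plab$prob[, p], tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
})
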