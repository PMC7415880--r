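test_that("encode is deterministic with valid posteriors", {
  m <- tiny_model()
  sim <- tiny_sim()
  X <- sim$counts$values[1:10, ]
  lc <- encode(m, rbind(X, X[1, , drop = FALSE]))
  expect_true(all(lc$stddev > 0))
  # two identical cells -> identical posteriors
  expect_equal(lc$mean[11, ], lc$mean[1, ])
  expect_equal(lc$stddev[11, ], lc$stddev[1, ])
  # deterministic across calls
  expect_identical(encode(m, X)$mean, encode(m, X)$mean)
  expect_error(encode(m, X[, 1:5]), "expects")
})

test_that("untrained models produce finite outputs on random input", {
  net <- network_config(n_hidden_layers = 2, n_hidden_units = 8,
                        n_latent = 3)
  m <- scvae_model(12, n_proteins = 2, network = net, seed = 9)
  set.seed(91)
  X <- matrix(rpois(100 * 12, 4), 100, 12)
  lc <- encode(m, X)
  expect_true(all(is.finite(lc$mean)) && all(is.finite(lc$stddev)))
  dec <- decode(m, lc$mean)
  expect_true(all(is.finite(dec$gene$mean)) && all(dec$gene$mean > 0))
  expect_true(all(dec$gene$dropout_prob >= 0 & dec$gene$dropout_prob <= 1))
  expect_true(all(dec$label$prob > 0 & dec$label$prob < 1))
  # z = 0 decodes to valid parameters too
  d0 <- decode(m, matrix(0, 1, 3))
  expect_true(all(is.finite(d0$gene$mean)))
  expect_error(decode(m, matrix(0, 1, 5)), "n_latent")
  # sampling from the decoded ZINB yields non-negative integers
  z <- zinb_params(nb_params(d0$gene$mean[1, 1], d0$gene$dispersion[1]),
                   d0$gene$dropout_prob[1, 1])
  draws <- sample_zinb(z, 100, seed = 1)
  expect_true(all(draws >= 0) && all(draws == floor(draws)))
})

test_that("ELBO terms behave: KL nonneg, zero at the prior, MC consistent", {
  m <- tiny_model()
  sim <- tiny_sim()
  X <- sim$counts$values[1:40, ]
  e <- elbo_unsupervised(m, X, n_samples = 1)
  expect_gte(e$kl, 0)
  expect_equal(e$elbo, e$recon - e$kl)

  # encoder forced to the prior -> KL exactly 0
  m0 <- m
  m0$params$W_mu[] <- 0; m0$params$b_mu[] <- 0
  m0$params$W_lv[] <- 0; m0$params$b_lv[] <- 0
  expect_equal(elbo_unsupervised(m0, X)$kl, 0)

  # S = 1 vs S = 100 agree within 3 MC standard errors
  set.seed(92)
  draws <- replicate(30, elbo_unsupervised(m, X, n_samples = 1)$elbo)
  se <- sd(draws) / sqrt(30)
  set.seed(93)
  big <- elbo_unsupervised(m, X, n_samples = 100)$elbo
  expect_lt(abs(mean(draws) - big), 3 * se)
})

test_that("total_loss collapses to the unsupervised objective", {
  m <- tiny_model()
  sim <- tiny_sim()
  X <- sim$counts$values[1:30, ]
  lab <- probabilize_proteins(sim$proteins)$prob[1:30, ]
  L <- m$network$n_latent
  set.seed(94)
  eps <- matrix(rnorm(30 * L), 30, L)

  # gamma = 0 equals the negative ELBO on identical z samples
  tl <- total_loss(m, X, lab, rep(TRUE, 30), gamma = 0, eps = eps)
  el <- elbo_unsupervised(m, X, eps = eps)
  expect_equal(tl$total, -el$elbo, tolerance = 1e-10)

  # all-false mask likewise
  expect_warning(
    tl2 <- total_loss(m, X, lab, rep(FALSE, 30), gamma = 5, eps = eps),
    "ignoring")
  expect_equal(tl2$total, -el$elbo, tolerance = 1e-10)
})

test_that("total_loss is affine in gamma and matches manual assembly", {
  m <- tiny_model()
  sim <- tiny_sim()
  X <- sim$counts$values[1:3, , drop = FALSE]
  lab <- probabilize_proteins(sim$proteins)$prob[1:3, , drop = FALSE]
  mask <- c(TRUE, FALSE, TRUE)
  L <- m$network$n_latent
  set.seed(95)
  eps <- matrix(rnorm(3 * L), 3, L)

  gammas <- c(0, 1, 7, 20)
  totals <- vapply(gammas, function(g)
    total_loss(m, X, lab, mask, gamma = g, eps = eps)$total, numeric(1))
  slope <- (totals[2] - totals[1]) / (gammas[2] - gammas[1])
  expect_equal(totals, totals[1] + slope * gammas, tolerance = 1e-8)

  # manual assembly on the 3-cell batch from package primitives
  lc_fwd <- scsemivae:::.forward(m, X, eps)
  recon <- vapply(1:3, function(i) {
    -sum(zinb_log_prob(X[i, ], zinb_params(
      nb_params(lc_fwd$mu_x[i, ], lc_fwd$theta), lc_fwd$pi_x[i, ])))
  }, numeric(1))
  kl <- vapply(1:3, function(i)
    gaussian_kl_to_standard(gaussian_params(lc_fwd$mu_z[i, ],
                                            exp(0.5 * lc_fwd$lv[i, ]))),
    numeric(1))
  p <- lc_fwd$p_y
  sup <- vapply(1:3, function(i)
    -sum(lab[i, ] * log(p[i, ]) + (1 - lab[i, ]) * log(1 - p[i, ])),
    numeric(1))
  manual <- mean(recon + kl) + 20 * mean(sup[mask])
  expect_equal(total_loss(m, X, lab, mask, gamma = 20, eps = eps)$total,
               manual, tolerance = 1e-6)
})

test_that("training descends, is seed-deterministic, and gamma=0 matches no-label", {
  sim <- tiny_sim()
  plab <- probabilize_proteins(sim$proteins)
  net <- network_config(n_hidden_layers = 1, n_hidden_units = 12,
                        n_latent = 3)
  tc <- training_config(gamma = 20, max_epochs = 15, batch_size = 64,
                        patience = Inf, seed = 77)
  m1 <- fit_scvae(scvae_model(20, 3, net, seed = 77), sim$counts,
                  labels = plab, training = tc)
  expect_true(m1$fitted)
  expect_lt(m1$history$total[nrow(m1$history)], m1$history$total[1])
  expect_true(all(is.finite(m1$history$total)))

  # same seeds -> bitwise-identical history
  m2 <- fit_scvae(scvae_model(20, 3, net, seed = 77), sim$counts,
                  labels = plab, training = tc)
  expect_identical(m1$history, m2$history)

  # gamma = 0 with labels vs no-head no-label run: identical loss curves
  tc0 <- training_config(gamma = 0, max_epochs = 8, batch_size = 64,
                         patience = Inf, seed = 78)
  ma <- fit_scvae(scvae_model(20, 0, net, seed = 78), sim$counts,
                  training = tc0)
  mb <- fit_scvae(scvae_model(20, 3, net, seed = 78), sim$counts,
                  labels = plab, training = tc0)
  expect_equal(ma$history$total, mb$history$total, tolerance = 1e-8)
})

test_that("label_fraction masks the supervised loss as configured", {
  sim <- tiny_sim()
  plab <- probabilize_proteins(sim$proteins)
  net <- network_config(n_hidden_layers = 1, n_hidden_units = 8,
                        n_latent = 3)
  m <- fit_scvae(scvae_model(20, 3, net, seed = 5), sim$counts,
                 labels = plab,
                 training = training_config(gamma = 20, max_epochs = 3,
                                            label_fraction = 0,
                                            batch_size = 64, seed = 5))
  expect_equal(m$history$supervised_nll, rep(0, nrow(m$history)))
})

test_that("impute returns non-negative denoised expression tracking markers", {
  m <- tiny_model()
  sim <- tiny_sim()
  den <- impute(m, sim$counts)
  expect_true(all(den >= 0))
  expect_identical(dim(den), dim(sim$counts$values))
  # nb_mean >= expected value since (1 - pi) <= 1
  expect_true(all(impute(m, sim$counts, type = "nb_mean") >= den - 1e-12))
  # marker-gene column correlates positively with its protein signal
  clr <- clr_normalize(sim$proteins)
  rho <- cor(den[, sim$pairs$gene[1]], clr$values[, sim$pairs$protein[1]],
             method = "spearman")
  expect_gt(rho, 0)
  expect_error(impute(scvae_model(20, 0), sim$counts), "not fitted")
})

test_that("predict_protein needs no protein input and is deterministic", {
  m <- tiny_model()
  sim <- tiny_sim()
  pred <- predict_protein(m, sim$counts)
  expect_true(all(pred > 0 & pred < 1))   # bernoulli head
  expect_identical(colnames(pred), sim$proteins$protein_ids)
  # identical input cells -> identical predictions
  X <- sim$counts$values[c(1, 1), , drop = FALSE]
  rownames(X) <- c("a", "b")
  p2 <- predict_protein(m, X)
  expect_equal(unname(p2[1, ]), unname(p2[2, ]))
  # trained protein ranks concordant with the ground-truth protein
  rho <- cor(pred[, 1], sim$proteins$values[, 1], method = "spearman")
  expect_gt(rho, 0.5)
  # capability error without a head
  m0 <- fit_scvae(scvae_model(20, 0, network_config(1, 8, 3), seed = 1),
                  sim$counts,
                  training = training_config(gamma = 0, max_epochs = 2,
                                             batch_size = 64, seed = 1))
  expect_error(predict_protein(m0, sim$counts), "without a label head")
})

test_that("inference entry points never accept label arguments", {
  # evaluation-path purity: imputation, encoding and protein prediction
  # must be computable from counts alone
  for (f in list(impute, encode, predict_protein)) {
    args <- names(formals(f))
    expect_false(any(grepl("label|protein_table|targets", args)))
    expect_true("counts" %in% args)
  }
})

test_that("importance-weighted likelihood collapses at S=1 and grows with S", {
  m <- tiny_model()
  sim <- tiny_sim()
  X <- sim$counts$values[1:20, ]

  # S = 1 equals a single-sample ELBO draw (same noise)
  set.seed(96)
  m1 <- marginal_log_likelihood(m, X, 1, seed = 111)
  set.seed(111)
  L <- m$network$n_latent
  eps <- matrix(rnorm(20 * L), 20, L)
  fwd <- scsemivae:::.forward(m, X, eps)
  ll <- rowSums(scsemivae:::.zinb_terms(X, fwd$mu_x, fwd$theta, fwd$pi_x,
                                        want_grad = FALSE)$ll)
  lp <- rowSums(dnorm(fwd$z, log = TRUE))
  lq <- rowSums(dnorm(fwd$z, fwd$mu_z, fwd$sd_z, log = TRUE))
  expect_equal(m1, ll + lp - lq, tolerance = 1e-10)

  expect_true(all(is.finite(marginal_log_likelihood(m, X, 8, seed = 2))))
})

test_that("model checkpoints round-trip through JSON", {
  m <- tiny_model()
  sim <- tiny_sim()
  f <- withr::local_tempfile(fileext = ".json")
  write_scvae(m, f)
  back <- read_scvae(f)
  expect_equal(back$params, m$params, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_identical(back$n_genes, m$n_genes)
  expect_true(back$fitted)
  expect_equal(impute(back, sim$counts), impute(m, sim$counts),
               tolerance = 1e-10)
})
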