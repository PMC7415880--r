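test_that("marker correlation matches textbook formulas and edge cases", {
  set.seed(71)
  g <- rnorm(10)
  p <- 0.8 * g + rnorm(10, sd = 0.3)
  imp <- matrix(g, 10, 1, dimnames = list(paste0("c", 1:10), "gene1"))
  pt <- protein_table(matrix(p, 10, 1,
                             dimnames = list(paste0("c", 1:10), "prot1")),
                      scale = "clr")
  pairs <- marker_pairs("gene1", "prot1")
  mc <- marker_correlation(imp, pt, pairs)
  direct <- mean(c(cor(g, p), cor(g, p, method = "spearman")))
  expect_equal(mc$score, direct, tolerance = 1e-10)

  # identical columns -> pair score 1
  pt1 <- protein_table(imp, scale = "clr")
  colnames(pt1$values) <- "prot1"
  pt1$protein_ids <- "prot1"
  expect_equal(marker_correlation(imp, pt1, pairs)$score, 1)

  # exact linear anti-relation: pearson -1 and spearman -1 -> score -1
  ptr <- protein_table(matrix(-g, 10, 1,
                              dimnames = list(paste0("c", 1:10), "prot1")),
                       scale = "clr")
  expect_equal(marker_correlation(imp, ptr, pairs)$score, -1)

  # zero-variance column -> 0 with a warning
  imp0 <- imp; imp0[, 1] <- 5
  expect_warning(mc0 <- marker_correlation(imp0, pt, pairs),
                 "zero-variance")
  expect_equal(mc0$score, 0)

  expect_error(marker_correlation(imp[1:2, , drop = FALSE], pt, pairs),
               "at least 3")
  expect_error(marker_correlation(imp, pt, marker_pairs("nope", "prot1")),
               "unknown pair")
})

test_that("latent classifier achieves perfect, chance, and seeded F1", {
  set.seed(72)
  n <- 500
  Z <- matrix(rnorm(n * 3), n, 3,
              dimnames = list(sprintf("c%03d", 1:n), NULL))
  split <- split_train_test(rownames(Z), 0.8, seed = 1)

  # separable: label determined by thresholding one coordinate
  y_sep <- setNames(factor(ifelse(Z[, 1] > 0, "hi", "lo")), rownames(Z))
  expect_equal(latent_classifier_f1(Z, y_sep, split, "train"), 1,
               tolerance = 0.01)

  # shuffled labels: near chance for balanced binary targets
  y_rand <- setNames(factor(sample(c("a", "b"), n, TRUE)), rownames(Z))
  f1 <- latent_classifier_f1(Z, y_rand, split, "test")
  expect_lt(abs(f1 - 0.5), 0.15)

  # deterministic given seed
  expect_identical(latent_classifier_f1(Z, y_sep, split, "test", seed = 3),
                   latent_classifier_f1(Z, y_sep, split, "test", seed = 3))

  # multi-label binary matrix averages per-column F1
  tm <- cbind(as.integer(Z[, 1] > 0), as.integer(Z[, 2] > 0))
  rownames(tm) <- rownames(Z)
  f1m <- latent_classifier_f1(Z, tm, split, "train")
  expect_gt(f1m, 0.9)
})

test_that("UCA matches brute-force search and dominates the trivial baseline", {
  # 3-cluster / 3-label toy confusion: verify against exhaustive search
  cl <- c(1, 1, 1, 2, 2, 3, 3, 3, 3)
  lb <- c("a", "a", "b", "b", "b", "c", "c", "a", "c")
  tab <- table(cl, lb)
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  best <- max(vapply(perms, function(p)
    sum(tab[cbind(1:3, p)]), numeric(1))) / length(cl)
  expect_equal(unsupervised_clustering_accuracy(cl, lb), best)

  # the optimal assignment dominates any fixed one-to-one relabeling
  set.seed(73)
  for (i in 1:10) {
    cl <- sample(1:4, 60, TRUE)
    lb <- sample(letters[1:4], 60, TRUE)
    uca <- unsupervised_clustering_accuracy(cl, lb)
    fixed <- mean(letters[cl] == lb)   # identity assignment
    expect_gte(uca, fixed - 1e-12)
    # and a clustering identical to the labels is recognized as such
    expect_equal(unsupervised_clustering_accuracy(lb, lb), 1)
  }
})

test_that("NMI behaves at its extremes", {
  a <- rep(1:3, each = 10)
  expect_equal(normalized_mutual_information(a, a), 1)
  # relabeled partition still 1
  expect_equal(normalized_mutual_information(a, c("x", "y", "z")[a]), 1)
  set.seed(74)
  b <- sample(1:3, 30, TRUE)
  expect_lt(normalized_mutual_information(a, b), 0.5)
})

test_that("clustering_score is perfect on separated clusters and invariant to relabeling", {
  set.seed(75)
  centers <- matrix(c(0, 0, 10, 0, 0, 10), 3, 2, byrow = TRUE)
  lab <- rep(1:3, each = 40)
  Z <- centers[lab, ] + matrix(rnorm(240, sd = 0.2), 120, 2)
  cs <- clustering_score(Z, lab, seed = 1)
  expect_equal(cs$ari, 1)
  expect_equal(cs$nmi, 1)
  expect_equal(cs$uca, 1)
  expect_gt(cs$asw, 0.8)
  expect_true(cs$pooled >= 0 && cs$pooled <= 1)

  # label-permutation invariance
  relab <- c("typeC", "typeA", "typeB")[lab]
  cs2 <- clustering_score(Z, relab, seed = 1)
  expect_equal(cs2[c("ari", "nmi", "uca")], cs[c("ari", "nmi", "uca")])

  expect_error(clustering_score(Z, lab, k = 500), "exceeds")
  expect_error(clustering_score(Z, rep(1, 120)), "at least 2")
})

test_that("assemble_report covers both splits and degrades gracefully", {
  m <- tiny_model()
  sim <- tiny_sim()
  split <- split_train_test(sim$counts$cell_ids, 0.8, seed = 2)

  full <- assemble_report(m, sim$counts, split = split,
                          proteins = sim$proteins, labels = sim$labels,
                          pairs = sim$pairs, n_importance_samples = 4)
  expect_s3_class(full, "eval_report")
  expect_setequal(unique(full$metrics$split), c("train", "test"))
  expect_true(all(is.finite(full$metrics$value)))
  expect_true("marker_correlation" %in% full$metrics$metric)
  expect_true("protein_prediction_correlation" %in% full$metrics$metric)

  # no proteins -> marker/prediction metrics absent, clustering present
  bare <- assemble_report(m, sim$counts, split = split,
                          labels = sim$labels, n_importance_samples = 4)
  expect_false("marker_correlation" %in% bare$metrics$metric)
  expect_true("pooled_clustering" %in% bare$metrics$metric)
  expect_true("marginal_log_likelihood" %in% bare$metrics$metric)

  # report round-trips through disk
  f <- withr::local_tempfile(fileext = ".tsv")
  write_eval_report(full, f)
  back <- read.delim(f)
  expect_equal(nrow(back), nrow(full$metrics))
  expect_equal(back$value, full$metrics$value, tolerance = 1e-12)

  expect_equal(report_metric(full, "pooled_clustering", "test"),
               full$metrics$value[full$metrics$metric == "pooled_clustering" &
                                  full$metrics$split == "test"])
})

test_that("trained latent beats a random untrained latent on clustering", {
  sim <- tiny_sim()
  m <- tiny_model()
  trained <- clustering_score(encode(m, sim$counts), sim$labels,
                              seed = 1)$pooled
  pooled_rand <- vapply(1:5, function(s) {
    mr <- scvae_model(20, 0, network_config(1, 16, 4), seed = 100 + s)
    clustering_score(encode(mr, sim$counts), sim$labels, seed = 1)$pooled
  }, numeric(1))
  expect_gt(trained, median(pooled_rand))
})
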