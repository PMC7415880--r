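# Metric battery: marker gene/protein correlation on the denoised
# output space, secondary-classifier F1 and pooled clustering quality
# (ARI, NMI, silhouette, unsupervised clustering accuracy) on the
# latent space, protein-prediction correlation, and report assembly.

.safe_cor <- function(x, y, method) {
  if (sd(x) == 0 || sd(y) == 0) {
    .warnf("zero-variance vector in correlation; recording 0")
    return(0)
  }
  cor(x, y, method = method)
}

#' Marker gene/protein correlation score
#'
#' For each designated pair, the Pearson and Spearman correlations
#' between the denoised expression of the marker gene and the measured
#' level of its protein are computed across cells; the score is the
#' mean over both statistics and all pairs.  Zero-variance vectors
#' yield a per-pair correlation of 0 (with a warning) so averages stay
#' finite.
#'
#' @param imputed cells x genes numeric matrix with gene colnames and
#'   cell rownames (e.g. from [impute()]).
#' @param proteins a [protein_table()] (CLR or raw; correlations are
#'   scale-aware through Spearman and location-invariant Pearson).
#' @param pairs a [marker_pairs()].
#' @return A list with `score` (scalar mean) and `per_pair` (data.frame
#'   with `gene`, `protein`, `pearson`, `spearman`).
#' @export
marker_correlation <- function(imputed, proteins, pairs) {
  stopifnot(inherits(proteins, "protein_table"),
            inherits(pairs, "marker_pairs"))
  imputed <- as.matrix(imputed)
  shared <- intersect(rownames(imputed), proteins$cell_ids)
  if (length(shared) < 3)
    .stopf("need at least 3 shared cells (got %d)", length(shared))
  missing_g <- setdiff(pairs$gene, colnames(imputed))
  missing_p <- setdiff(pairs$protein, proteins$protein_ids)
  if (length(missing_g) || length(missing_p))
    .stopf("unknown pair members: %s",
           paste(c(missing_g, missing_p), collapse = ", "))
  per <- lapply(seq_len(nrow(pairs)), function(i) {
    g <- imputed[shared, pairs$gene[i]]
    p <- proteins$values[shared, pairs$protein[i]]
    data.frame(gene = pairs$gene[i], protein = pairs$protein[i],
               pearson = .safe_cor(g, p, "pearson"),
               spearman = .safe_cor(g, p, "spearman"))
  })
  per <- do.call(rbind, per)
  list(score = mean(c(per$pearson, per$spearman)), per_pair = per)
}

#' Macro-averaged F1 of a secondary classifier on the latent space
#'
#' Trains a multinomial logistic regression (with a small L2 weight
#' decay, fixed settings) on the train-split latent means and scores
#' macro F1 on the requested split.  Binary multi-label targets (one
#' column per protein) are scored per column and averaged.
#'
#' @param latent a `latent_code` from [encode()], or a numeric matrix
#'   of latent means with cell rownames.
#' @param targets a named factor/character vector (categorical), or a
#'   cells x proteins binary matrix with rownames (multi-label).
#' @param split list with `train` and `test` cell-id vectors.
#' @param eval_split which split to score: `"test"` (default) or
#'   `"train"`.
#' @param seed seed for the (otherwise deterministic) optimizer start.
#' @return Macro-averaged F1 in `[0, 1]`.
#' @export
latent_classifier_f1 <- function(latent, targets, split,
                                 eval_split = c("test", "train"),
                                 seed = 1L) {
  eval_split <- match.arg(eval_split)
  Z <- if (inherits(latent, "latent_code")) {
    m <- latent$mean; rownames(m) <- latent$cell_ids; m
  } else as.matrix(latent)
  if (is.null(rownames(Z))) .stopf("latent matrix needs cell rownames")

  if (is.matrix(targets) || is.data.frame(targets)) {
    tm <- as.matrix(targets)
    f1s <- vapply(seq_len(ncol(tm)), function(j)
      latent_classifier_f1(Z, setNames(factor(tm[, j]), rownames(tm)),
                           split, eval_split, seed),
      numeric(1))
    return(mean(f1s))
  }

  targets <- setNames(factor(targets), names(targets))
  tr <- intersect(split$train, intersect(rownames(Z), names(targets)))
  te <- intersect(split[[eval_split]],
                  intersect(rownames(Z), names(targets)))
  ytr <- droplevels(targets[tr])
  if (nlevels(ytr) < 2) return(1 * (length(unique(targets[te])) == 1))
  absent <- setdiff(unique(as.character(targets[te])), levels(ytr))
  if (length(absent))
    .warnf("classes absent from the training split are excluded: %s",
           paste(absent, collapse = ", "))

  set.seed(seed)
  df_tr <- data.frame(y = ytr, Z[tr, , drop = FALSE])
  fit <- nnet::multinom(y ~ ., data = df_tr, decay = 1e-3,
                        maxit = 200, trace = FALSE)
  pred <- predict(fit, newdata = data.frame(Z[te, , drop = FALSE]))
  truth <- factor(as.character(targets[te]), levels = levels(ytr))
  keep <- !is.na(truth)
  .macro_f1(truth[keep], factor(pred[keep], levels = levels(ytr)))
}

# macro F1 over the classes present in the truth vector
.macro_f1 <- function(truth, pred) {
  lev <- levels(droplevels(truth))
  f1 <- vapply(lev, function(cl) {
    tp <- sum(truth == cl & pred == cl)
    fp <- sum(truth != cl & pred == cl)
    fn <- sum(truth == cl & pred != cl)
    if (tp == 0) return(0)
    p <- tp / (tp + fp); r <- tp / (tp + fn)
    2 * p * r / (p + r)
  }, numeric(1))
  mean(f1)
}

#' Unsupervised clustering accuracy
#'
#' Classification accuracy under the best one-to-one assignment of
#' clusters to labels, found by exhaustive search over assignments
#' (feasible for the small numbers of clusters used here; at most 9).
#'
#' @param clusters,labels equal-length vectors (any label coding).
#' @return Accuracy in `[0, 1]`.
#' @export
unsupervised_clustering_accuracy <- function(clusters, labels) {
  cl <- as.integer(factor(clusters))
  lb <- as.integer(factor(labels))
  tab <- table(cl, lb)
  k <- max(nrow(tab), ncol(tab))
  if (k > 9)
    .stopf("exhaustive assignment search supports at most 9 clusters")
  # pad to square so every cluster maps to a distinct label slot
  m <- matrix(0, k, k)
  m[seq_len(nrow(tab)), seq_len(ncol(tab))] <- tab
  perms <- .permutations(k)
  best <- 0
  for (i in seq_len(nrow(perms)))
    best <- max(best, sum(m[cbind(seq_len(k), perms[i, ])]))
  best / length(cl)
}

.permutations <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- .permutations(k - 1L)
  out <- matrix(0L, 0, k)
  for (pos in seq_len(k)) {
    block <- cbind(sub[, seq_len(pos - 1), drop = FALSE], k,
                   sub[, seq(pos, k - 1)[seq_len(k - pos)], drop = FALSE])
    out <- rbind(out, block)
  }
  out
}

#' Normalized mutual information between two partitions
#'
#' `I(U; V) / sqrt(H(U) H(V))`; 1 for identical partitions (up to
#' relabeling), 0 for independent ones.
#'
#' @param a,b equal-length label vectors.
#' @return NMI in `[0, 1]`.
#' @export
normalized_mutual_information <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  pij <- tab / n
  pi <- rowSums(pij); pj <- colSums(pij)
  nz <- pij > 0
  mi <- sum(pij[nz] * log(pij[nz] / outer(pi, pj)[nz]))
  hu <- -sum(pi[pi > 0] * log(pi[pi > 0]))
  hv <- -sum(pj[pj > 0] * log(pj[pj > 0]))
  if (hu == 0 || hv == 0) return(as.numeric(hu == hv))
  max(0, min(1, mi / sqrt(hu * hv)))
}

#' Pooled clustering quality of a latent space
#'
#' Clusters the latent means with k-means (10 seeded restarts) and
#' scores the partition against true labels with ARI and NMI, the
#' latent geometry with the mean silhouette width rescaled to `[0, 1]`
#' via `(ASW + 1) / 2`, and the optimal cluster-to-label assignment
#' accuracy (UCA).  The pooled score is the unweighted mean of the
#' four.
#'
#' @param latent a `latent_code` or numeric matrix of latent means.
#' @param labels true categorical labels, aligned with the latent rows
#'   (by name when both carry names).
#' @param k number of clusters (defaults to the number of label
#'   classes; must be >= 2 and <= the number of cells).
#' @param seed seed for the k-means restarts.
#' @return A list with `pooled`, `ari`, `nmi`, `asw` (raw silhouette in
#'   `[-1, 1]`), `uca`.
#' @export
clustering_score <- function(latent, labels, k = NULL, seed = 1L) {
  Z <- if (inherits(latent, "latent_code")) {
    m <- latent$mean; rownames(m) <- latent$cell_ids; m
  } else as.matrix(latent)
  if (!is.null(names(labels)) && !is.null(rownames(Z))) {
    shared <- intersect(rownames(Z), names(labels))
    Z <- Z[shared, , drop = FALSE]
    labels <- labels[shared]
  }
  labels <- factor(labels)
  if (is.null(k)) k <- nlevels(labels)
  if (k < 2) .stopf("k must be at least 2")
  if (k > nrow(Z)) .stopf("k (%d) exceeds number of cells (%d)", k, nrow(Z))
  set.seed(seed)
  km <- kmeans(Z, centers = k, nstart = 10, iter.max = 50)
  cl <- km$cluster
  ari <- mclust::adjustedRandIndex(cl, labels)
  nmi <- normalized_mutual_information(cl, labels)
  sil <- cluster::silhouette(cl, dist(Z))
  asw <- if (is.matrix(sil)) mean(sil[, "sil_width"]) else 0
  uca <- unsupervised_clustering_accuracy(cl, labels)
  pooled <- mean(c(ari, nmi, (asw + 1) / 2, uca))
  list(pooled = pooled, ari = ari, nmi = nmi, asw = asw, uca = uca)
}

#' Assemble a full evaluation report for a fitted model
#'
#' Computes, on the train and test splits: marker gene/protein
#' correlation of the denoised output, latent-space classifier F1 and
#' pooled clustering score, protein-prediction correlation (predicted
#' vs measured protein, mean over proteins of Pearson and Spearman),
#' and the mean importance-weighted marginal log-likelihood.  Metrics
#' whose inputs are absent are skipped.
#'
#' @param model a fitted `scvae_model`.
#' @param counts the full [count_matrix()].
#' @param split list with `train`/`test` cell ids (default: a seeded
#'   90/10 split).
#' @param proteins optional [protein_table()] for marker/prediction
#'   metrics (raw tables are CLR-normalized for correlation scoring).
#' @param labels optional named factor of true cell types.
#' @param pairs optional [marker_pairs()].
#' @param n_importance_samples importance samples for the marginal
#'   log-likelihood (default 16).
#' @param seed seed for classifier/clustering randomness.
#' @return An object of class `eval_report`: `metrics` (data.frame with
#'   columns `split`, `metric`, `value`) and `meta`.
#' @export
assemble_report <- function(model, counts, split = NULL, proteins = NULL,
                            labels = NULL, pairs = NULL,
                            n_importance_samples = 16L, seed = 1L) {
  stopifnot(inherits(model, "scvae_model"), inherits(counts, "count_matrix"))
  if (!model$fitted) .stopf("model is not fitted")
  if (is.null(split))
    split <- split_train_test(counts$cell_ids, 0.9, seed = seed)

  if (!is.null(proteins) && proteins$scale == "raw")
    proteins <- clr_normalize(proteins)

  imput <- impute(model, counts)
  latent <- encode(model, counts)
  Z <- latent$mean; rownames(Z) <- latent$cell_ids

  rows <- list()
  add <- function(split_name, metric, value)
    rows[[length(rows) + 1]] <<- data.frame(split = split_name,
                                            metric = metric, value = value)
  for (sp in c("train", "test")) {
    ids <- split[[sp]]
    idx <- match(ids, counts$cell_ids)
    sub_counts <- subset_cells(counts, cells = idx)

    if (!is.null(proteins) && !is.null(pairs)) {
      mc <- marker_correlation(imput[ids, , drop = FALSE], proteins, pairs)
      add(sp, "marker_correlation", mc$score)
    }
    if (!is.null(proteins) && model$n_proteins > 0) {
      pred <- predict_protein(model, sub_counts)
      shared_p <- intersect(colnames(pred), proteins$protein_ids)
      shared_c <- intersect(ids, proteins$cell_ids)
      if (length(shared_p) && length(shared_c) >= 3) {
        cors <- vapply(shared_p, function(p)
          mean(c(.safe_cor(pred[shared_c, p],
                           proteins$values[shared_c, p], "pearson"),
                 .safe_cor(pred[shared_c, p],
                           proteins$values[shared_c, p], "spearman"))),
          numeric(1))
        add(sp, "protein_prediction_correlation", mean(cors))
      }
    }
    if (!is.null(labels)) {
      cs <- clustering_score(Z[ids, , drop = FALSE], labels[ids],
                             seed = seed)
      add(sp, "pooled_clustering", cs$pooled)
      add(sp, "ari", cs$ari); add(sp, "nmi", cs$nmi)
      add(sp, "asw", cs$asw); add(sp, "uca", cs$uca)
      f1 <- latent_classifier_f1(Z, labels, split, eval_split = sp,
                                 seed = seed)
      add(sp, "classifier_f1", f1)
    }
    mll <- marginal_log_likelihood(model, sub_counts,
                                   n_importance_samples,
                                   seed = .derive_seed(seed, 97L))
    add(sp, "marginal_log_likelihood", mean(mll))
  }
  metrics <- do.call(rbind, rows)
  structure(list(metrics = metrics,
                 meta = list(seed = seed,
                             n_cells = nrow(counts$values),
                             n_train = length(split$train),
                             n_test = length(split$test),
                             gamma = if (!is.null(model$training))
                               model$training$gamma else NA_real_)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report>\n")
  print(x$metrics, row.names = FALSE)
  invisible(x)
}

#' Fetch one metric from a report
#'
#' @param report an `eval_report`.
#' @param metric metric name as in `report$metrics$metric`.
#' @param split `"train"` or `"test"`.
#' @return The metric value (scalar).
#' @export
report_metric <- function(report, metric, split = "test") {
  m <- report$metrics
  v <- m$value[m$metric == metric & m$split == split]
  if (length(v) != 1)
    .stopf("metric '%s' (%s split) not present in report", metric, split)
  v
}

#' Write an evaluation report
#'
#' The metric table goes to a TSV and the metadata to a JSON summary
#' next to it.
#'
#' @param report an `eval_report`.
#' @param path TSV output path; the JSON lands at the same path with a
#'   `.json` extension.
#' @export
write_eval_report <- function(report, path) {
  write.table(report$metrics, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(report$meta, sub("\\.[^.]*$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
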