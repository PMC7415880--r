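# Imputation-robustness protocol: binomially downsample a fixed
# fraction of count-matrix entries, train on the corrupted data, and
# score the imputed output against the original (uncorrupted) data.

#' Corruption specification
#'
#' @param fraction fraction of matrix entries to corrupt, in (0, 1];
#'   default 0.25 (a quarter of all entries, the benchmark convention).
#' @param keep_prob binomial success probability of the downsampling
#'   draw `Binomial(n, keep_prob)` applied to a selected entry with
#'   original value `n`; default 0.2.
#' @param seed integer seed.
#' @return A list of class `corruption_spec`.
#' @export
corruption_spec <- function(fraction = 0.25, keep_prob = 0.2, seed = 1L) {
  if (fraction <= 0 || fraction > 1)
    .stopf("fraction must lie in (0, 1]")
  if (keep_prob <= 0 || keep_prob >= 1)
    .stopf("keep_prob must lie strictly in (0, 1)")
  structure(list(fraction = fraction, keep_prob = keep_prob,
                 seed = as.integer(seed)),
            class = "corruption_spec")
}

#' Binomially corrupt a count matrix
#'
#' Selects exactly `round(fraction * n_entries)` entries uniformly
#' without replacement (zeros included, so the selected share is exact)
#' and replaces each selected entry `n` with a `Binomial(n, keep_prob)`
#' draw.  Corruption never increases an entry.
#'
#' @param counts a [count_matrix()].
#' @param spec a [corruption_spec()].
#' @return A list with `corrupted` (a [count_matrix()]) and `mask`
#'   (logical matrix marking selected entries).
#' @export
corrupt_counts <- function(counts, spec = corruption_spec()) {
  stopifnot(inherits(counts, "count_matrix"),
            inherits(spec, "corruption_spec"))
  v <- counts$values
  n_entries <- length(v)
  k <- round(spec$fraction * n_entries)
  set.seed(spec$seed)
  sel <- sample.int(n_entries, k)
  out <- v
  out[sel] <- rbinom(k, size = v[sel], prob = spec$keep_prob)
  mask <- matrix(FALSE, nrow(v), ncol(v), dimnames = dimnames(v))
  mask[sel] <- TRUE
  list(corrupted = count_matrix(out, cell_ids = counts$cell_ids,
                                gene_ids = counts$gene_ids),
       mask = mask)
}

#' Run the corruption benchmark over model configurations
#'
#' Corrupts the training portion of the data, trains each configuration
#' on the corrupted counts, and evaluates the imputed output and latent
#' space against the ORIGINAL (uncorrupted) counts, proteins and
#' labels.
#'
#' @param counts a [count_matrix()] (the clean data).
#' @param configs named list of configurations; each element is a list
#'   with components `network` ([network_config()]) and `training`
#'   ([training_config()]).
#' @param proteins optional raw [protein_table()] used both for
#'   supervision (probabilized) and for marker-correlation scoring.
#' @param labels optional named factor of true cell types.
#' @param pairs optional [marker_pairs()].
#' @param spec a [corruption_spec()].
#' @param train_fraction train/test split fraction (default 0.9).
#' @param seed seed for the split.
#' @return A data.frame of class `benchmark_report`: one row per
#'   configuration x split x metric.
#' @export
run_corruption_benchmark <- function(counts, configs, proteins = NULL,
                                     labels = NULL, pairs = NULL,
                                     spec = corruption_spec(),
                                     train_fraction = 0.9, seed = 1L) {
  stopifnot(inherits(counts, "count_matrix"), length(configs) >= 1)
  if (is.null(names(configs)))
    names(configs) <- paste0("config", seq_along(configs))

  split <- split_train_test(counts$cell_ids, train_fraction, seed = seed)
  train_counts <- subset_cells(counts, cells = split$train)
  corrupted <- corrupt_counts(train_counts, spec)$corrupted

  plab <- if (!is.null(proteins)) probabilize_proteins(proteins) else NULL

  rows <- list()
  for (nm in names(configs)) {
    cfg <- configs[[nm]]
    n_prot <- if (!is.null(plab) && cfg$training$gamma > 0)
      ncol(plab$prob) else 0L
    model <- scvae_model(ncol(counts$values), n_proteins = n_prot,
                         network = cfg$network,
                         seed = cfg$training$seed)
    lab_in <- if (n_prot > 0) plab else NULL
    model <- tryCatch(
      fit_scvae(model, corrupted, labels = lab_in,
                training = cfg$training),
      error = function(e) .stopf("configuration '%s' failed: %s",
                                 nm, conditionMessage(e)))
    rep <- assemble_report(model, counts, split = split,
                           proteins = proteins, labels = labels,
                           pairs = pairs)
    df <- rep$metrics
    df$config <- nm
    rows[[nm]] <- df
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("benchmark_report", "data.frame")
  out
}
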