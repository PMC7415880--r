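# Probabilistic protein gating: a two-component Gaussian mixture is
# fitted per protein; the posterior responsibility of the high-abundance
# ("on") component converts raw ADT measurements into probabilistic
# labels, which may be thresholded into binary presence/absence calls.
# The EM fit is deliberately hand-rolled: deterministic quantile-based
# initialization and a variance floor make the gate reproducible, which
# off-the-shelf mixture fitters with random restarts do not guarantee.

#' Fit a two-component Gaussian mixture to one protein
#'
#' Runs EM on the (optionally log-transformed) measurements of a single
#' protein.  Initialization is deterministic: component means start at
#' the 25th and 75th percentiles, both variances at the pooled variance,
#' weights at 1/2.  A variance floor of `1e-6 * var(values)` guards
#' against singular components.  The component with the larger mean is
#' designated the "on" (activated) component; ties break by weight.
#'
#' @param values numeric vector of measurements for one protein
#'   (at least 10 finite values).
#' @param preprocessing `"log_normalized"` (default) applies
#'   `log1p` before fitting, the convention for raw ADT counts;
#'   `"raw"` fits the values as given.
#' @param tol EM stops when the mean log-likelihood improves by less
#'   than this (default `1e-8`).
#' @param max_iter maximum EM iterations (default 500).
#' @param seed unused by the deterministic initialization; accepted so
#'   callers can treat all fitters uniformly.
#' @return An object of class `protein_gmm`: fields `weights`, `means`,
#'   `variances` (each length 2), `on_component`, `preprocessing`,
#'   `log_lik` (per-iteration mean log-likelihood trace), `protein_id`.
#' @examples
#' set.seed(1)
#' v <- c(rnorm(300, 0), rnorm(300, 6))
#' g <- fit_protein_gmm(v, preprocessing = "raw")
#' g$means
#' @export
fit_protein_gmm <- function(values, preprocessing = c("log_normalized", "raw"),
                            tol = 1e-8, max_iter = 500, seed = NULL) {
  preprocessing <- match.arg(preprocessing)
  protein_id <- attr(values, "protein_id")
  values <- values[is.finite(values)]
  if (length(values) < 10)
    .stopf("need at least 10 finite values to fit a protein mixture (got %d)",
           length(values))
  x <- if (preprocessing == "log_normalized") log1p(values) else values
  if (diff(range(x)) == 0)
    .stopf("all values identical after preprocessing; mixture is degenerate")

  n <- length(x)
  v_floor <- max(1e-6 * var(x), .Machine$double.xmin)
  mu <- unname(quantile(x, c(0.25, 0.75), names = FALSE))
  if (mu[1] == mu[2]) mu <- mu + c(-0.5, 0.5) * sd(x)
  sg2 <- rep(max(var(x), v_floor), 2)
  w <- c(0.5, 0.5)

  ll_trace <- numeric(0)
  prev_ll <- -Inf
  for (it in seq_len(max_iter)) {
    # E step: log responsibilities
    lw <- matrix(0, n, 2)
    for (k in 1:2)
      lw[, k] <- log(w[k]) + dnorm(x, mu[k], sqrt(sg2[k]), log = TRUE)
    norm <- .row_logsumexp(lw)
    r <- exp(lw - norm)
    ll <- mean(norm)
    ll_trace <- c(ll_trace, ll)
    # M step
    nk <- colSums(r)
    nk <- pmax(nk, 1e-12)
    w <- nk / n
    mu <- colSums(r * x) / nk
    for (k in 1:2)
      sg2[k] <- max(sum(r[, k] * (x - mu[k])^2) / nk[k], v_floor)
    if (is.finite(prev_ll) && ll - prev_ll < tol) break
    prev_ll <- ll
  }

  on <- if (mu[1] == mu[2]) which.max(w) else which.max(mu)
  structure(list(protein_id = protein_id,
                 preprocessing = preprocessing,
                 weights = w, means = mu, variances = sg2,
                 on_component = on, log_lik = ll_trace, n = n),
            class = "protein_gmm")
}

#' @export
print.protein_gmm <- function(x, ...) {
  cat(sprintf(paste0("<protein_gmm%s> %s scale; weights (%.3f, %.3f); ",
                     "means (%.3f, %.3f); on = component %d\n"),
              if (is.null(x$protein_id)) "" else paste0(" ", x$protein_id),
              x$preprocessing, x$weights[1], x$weights[2],
              x$means[1], x$means[2], x$on_component))
  invisible(x)
}

#' Posterior probability of protein activation
#'
#' Bayes-rule responsibility of the "on" component for each value,
#' computed under the same preprocessing used for the fit.
#'
#' @param gmm a fitted [fit_protein_gmm()] object.
#' @param values numeric vector on the original measurement scale.
#' @return Probabilities in `[0, 1]`, one per value.
#' @export
probabilize <- function(gmm, values) {
  if (!inherits(gmm, "protein_gmm"))
    .stopf("probabilize() needs a fitted protein_gmm")
  x <- if (gmm$preprocessing == "log_normalized") log1p(values) else values
  lw <- vapply(1:2, function(k)
    log(gmm$weights[k]) + dnorm(x, gmm$means[k], sqrt(gmm$variances[k]),
                                log = TRUE),
    numeric(length(x)))
  lw <- matrix(lw, ncol = 2)
  exp(lw[, gmm$on_component] - .row_logsumexp(lw))
}

#' Threshold probabilistic labels into binary calls
#'
#' @param probs numeric vector or matrix of probabilities in `[0, 1]`.
#' @param threshold scalar in `(0, 1)`; default 0.5.
#' @return Binary (0/1) object of the same shape.
#' @export
binarize <- function(probs, threshold = 0.5) {
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold <= 0 || threshold >= 1)
    .stopf("threshold must be a single number in (0, 1)")
  if (any(probs < 0 | probs > 1, na.rm = TRUE))
    .stopf("probs must lie in [0, 1]")
  out <- (probs >= threshold) + 0L
  out
}

#' Fit per-protein mixtures and probabilize a whole ADT table
#'
#' Convenience wrapper: fits one two-component mixture per protein
#' column of a raw [protein_table()] and returns probabilistic and
#' binary label matrices alongside the fitted mixtures.
#'
#' @param proteins a raw-scale [protein_table()].
#' @inheritParams fit_protein_gmm
#' @param threshold binarization threshold, default 0.5.
#' @return A list of class `probabilized_labels`: `prob` and `binary`
#'   (cells x proteins matrices), `gmms` (named list of `protein_gmm`),
#'   `cells`, `proteins`.
#' @export
probabilize_proteins <- function(proteins,
                                 preprocessing = c("log_normalized", "raw"),
                                 threshold = 0.5, tol = 1e-8,
                                 max_iter = 500) {
  stopifnot(inherits(proteins, "protein_table"))
  preprocessing <- match.arg(preprocessing)
  v <- proteins$values
  gmms <- lapply(seq_len(ncol(v)), function(p) {
    col <- v[, p]
    attr(col, "protein_id") <- proteins$protein_ids[p]
    fit_protein_gmm(col, preprocessing = preprocessing,
                    tol = tol, max_iter = max_iter)
  })
  names(gmms) <- proteins$protein_ids
  prob <- vapply(seq_len(ncol(v)),
                 function(p) probabilize(gmms[[p]], v[, p]),
                 numeric(nrow(v)))
  prob <- matrix(prob, ncol = ncol(v),
                 dimnames = list(proteins$cell_ids, proteins$protein_ids))
  structure(list(prob = prob, binary = binarize(prob, threshold),
                 gmms = gmms, cells = proteins$cell_ids,
                 proteins = proteins$protein_ids, threshold = threshold),
            class = "probabilized_labels")
}

#' Serialize fitted protein mixtures to JSON
#'
#' Writes all five parameter groups (weights, means, variances, on
#' component, preprocessing) per protein to a human-readable JSON file;
#' [read_protein_gmms()] restores them.
#'
#' @param gmms a named list of `protein_gmm` objects (or a
#'   `probabilized_labels` object, whose `$gmms` is used).
#' @param path output file path.
#' @export
write_protein_gmms <- function(gmms, path) {
  if (inherits(gmms, "probabilized_labels")) gmms <- gmms$gmms
  payload <- lapply(gmms, function(g)
    list(protein_id = g$protein_id, preprocessing = g$preprocessing,
         weights = g$weights, means = g$means, variances = g$variances,
         on_component = g$on_component))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_protein_gmms
#' @return `read_protein_gmms()` returns the named list of
#'   `protein_gmm` objects.
#' @export
read_protein_gmms <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE,
                                 simplifyDataFrame = FALSE)
  gmms <- lapply(payload, function(g)
    structure(list(protein_id = g$protein_id,
                   preprocessing = g$preprocessing,
                   weights = as.numeric(g$weights),
                   means = as.numeric(g$means),
                   variances = as.numeric(g$variances),
                   on_component = as.integer(g$on_component),
                   log_lik = numeric(0), n = NA_integer_),
              class = "protein_gmm"))
  names(gmms) <- vapply(gmms, function(g)
    if (is.null(g$protein_id)) "" else g$protein_id, character(1))
  gmms
}
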