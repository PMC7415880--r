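# The semisupervised single-cell variational autoencoder.
#
# An encoder network maps library-size-normalized, log1p-transformed
# counts to a diagonal Gaussian posterior q(z|x) over a low-dimensional
# latent code with a standard-normal prior.  A shared decoder trunk maps
# sampled codes back up, and two linear heads read the trunk out:
#
#   * a gene head emitting zero-inflated negative binomial parameters on
#     the raw count scale (log-mean and dropout-logit projections, with
#     a free per-gene inverse dispersion shared across cells), and
#   * an optional label head for surface-protein supervision, either a
#     Bernoulli probability per protein (for probabilized GMM labels) or
#     an NB mean with per-protein dispersion (for raw ADT counts).
#
# Training minimizes  -ELBO(x) + gamma * L_y  where the supervised term
# L_y is the label negative log-likelihood averaged over the labeled
# cells only, so the meaning of gamma does not drift with the labeled
# fraction.  gamma = 0, or an absent label head, recovers the purely
# unsupervised model.  Gradients are computed analytically (closed-form
# derivatives of the ZINB/NB/Bernoulli losses chained through the dense
# stacks) and optimized with ADAM.

#' Network architecture configuration
#'
#' Defaults reproduce the tuned design: 2 hidden layers of 128 units and
#' a 32-dimensional latent space.
#'
#' @param n_hidden_layers hidden layers in encoder and decoder (>= 1).
#' @param n_hidden_units units per hidden layer.
#' @param n_latent latent dimensionality.
#' @param activation `"relu"` (default) or `"tanh"`.
#' @param label_likelihood `"bernoulli"` for probabilized labels in
#'   `[0, 1]` (default) or `"nb"` for raw label counts.
#' @return A list of class `network_config`.  The gene likelihood is
#'   always zero-inflated negative binomial.
#' @export
network_config <- function(n_hidden_layers = 2L, n_hidden_units = 128L,
                           n_latent = 32L, activation = c("relu", "tanh"),
                           label_likelihood = c("bernoulli", "nb")) {
  activation <- match.arg(activation)
  label_likelihood <- match.arg(label_likelihood)
  stopifnot(n_hidden_layers >= 1, n_hidden_units >= 1, n_latent >= 1)
  structure(list(n_hidden_layers = as.integer(n_hidden_layers),
                 n_hidden_units = as.integer(n_hidden_units),
                 n_latent = as.integer(n_latent),
                 activation = activation,
                 gene_likelihood = "zinb",
                 label_likelihood = label_likelihood),
            class = "network_config")
}

#' Training configuration
#'
#' @param gamma non-negative weight of the supervised (label) loss.
#'   The default 20 is the smallest weight at which supervision gives a
#'   clear advantage over the unsupervised model.
#' @param learning_rate ADAM learning rate.
#' @param batch_size minibatch size.
#' @param max_epochs upper bound on training epochs.
#' @param patience early-stopping patience (epochs without validation
#'   improvement); `Inf` disables early stopping.
#' @param label_fraction fraction of cells whose labels are visible to
#'   the supervised head (a seeded random subset); in `[0, 1]`.
#' @param validation_fraction fraction of training cells held out for
#'   the early-stopping criterion.
#' @param n_mc_samples Monte-Carlo samples of z per ELBO evaluation.
#' @param max_grad_norm global gradient-norm clip.
#' @param seed integer seed controlling label masking, initialization
#'   order, shuffling and reparameterization noise.
#' @param verbose print per-epoch losses.
#' @return A list of class `training_config`.
#' @export
training_config <- function(gamma = 20, learning_rate = 1e-3,
                            batch_size = 128L, max_epochs = 200L,
                            patience = 20L, label_fraction = 1,
                            validation_fraction = 0.1,
                            n_mc_samples = 1L, max_grad_norm = 100,
                            seed = 1L, verbose = FALSE) {
  if (gamma < 0) .stopf("gamma must be non-negative")
  if (label_fraction < 0 || label_fraction > 1)
    .stopf("label_fraction must lie in [0, 1]")
  structure(list(gamma = gamma, learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs), patience = patience,
                 label_fraction = label_fraction,
                 validation_fraction = validation_fraction,
                 n_mc_samples = as.integer(n_mc_samples),
                 max_grad_norm = max_grad_norm,
                 seed = as.integer(seed), verbose = verbose),
            class = "training_config")
}

# ---------------------------------------------------------------------
# model state

.init_params <- function(n_genes, n_proteins, net) {
  H <- net$n_hidden_units; L <- net$n_latent; K <- net$n_hidden_layers
  p <- list()
  d_in <- n_genes
  for (l in seq_len(K)) {
    p[[paste0("enc_W", l)]] <- .glorot(d_in, H)
    p[[paste0("enc_b", l)]] <- numeric(H)
    d_in <- H
  }
  p$W_mu <- .glorot(H, L); p$b_mu <- numeric(L)
  p$W_lv <- .glorot(H, L); p$b_lv <- numeric(L)
  d_in <- L
  for (l in seq_len(K)) {
    p[[paste0("dec_W", l)]] <- .glorot(d_in, H)
    p[[paste0("dec_b", l)]] <- numeric(H)
    d_in <- H
  }
  p$W_gene_mu <- .glorot(H, n_genes); p$b_gene_mu <- numeric(n_genes)
  p$W_gene_pi <- .glorot(H, n_genes); p$b_gene_pi <- numeric(n_genes)
  p$log_theta <- numeric(n_genes)
  if (n_proteins > 0) {
    p$W_label <- .glorot(H, n_proteins)
    p$b_label <- numeric(n_proteins)
    if (net$label_likelihood == "nb")
      p$log_theta_label <- numeric(n_proteins)
  }
  p
}

#' Construct an untrained model state
#'
#' @param n_genes number of genes (input/output dimension).
#' @param n_proteins number of proteins served by the supervised head;
#'   0 builds a purely unsupervised model with no head.
#' @param network a [network_config()].
#' @param seed seed for weight initialization.
#' @return An object of class `scvae_model`.
#' @export
scvae_model <- function(n_genes, n_proteins = 0L,
                        network = network_config(), seed = 1L) {
  stopifnot(inherits(network, "network_config"), n_genes >= 1,
            n_proteins >= 0)
  set.seed(.derive_seed(seed, 11L))
  structure(list(network = network,
                 n_genes = as.integer(n_genes),
                 n_proteins = as.integer(n_proteins),
                 params = .init_params(n_genes, n_proteins, network),
                 size_factor_ref = 1e4,
                 fitted = FALSE,
                 history = NULL,
                 gene_ids = NULL, protein_ids = NULL,
                 init_seed = as.integer(seed)),
            class = "scvae_model")
}

#' @export
print.scvae_model <- function(x, ...) {
  cat(sprintf(paste0("<scvae_model> %d genes, %d proteins (%s head); ",
                     "%dx%d hidden, %d latent; %s\n"),
              x$n_genes, x$n_proteins,
              if (x$n_proteins > 0) x$network$label_likelihood else "no",
              x$network$n_hidden_layers, x$network$n_hidden_units,
              x$network$n_latent,
              if (x$fitted) sprintf("fitted (%d epochs)", nrow(x$history))
              else "untrained"))
  invisible(x)
}

.as_count_values <- function(counts) {
  if (inherits(counts, "count_matrix")) counts$values
  else as.matrix(counts)
}

# library-size scaling to a common reference followed by log1p:
# the encoder sees relative expression, the decoder emits raw counts
.encoder_input <- function(model, X) {
  sf <- rowSums(X)
  log1p(X / pmax(sf, 1) * model$size_factor_ref)
}

.enc_layers <- function(model) {
  K <- model$network$n_hidden_layers
  list(W = lapply(seq_len(K), function(l) model$params[[paste0("enc_W", l)]]),
       b = lapply(seq_len(K), function(l) model$params[[paste0("enc_b", l)]]))
}

.dec_layers <- function(model) {
  K <- model$network$n_hidden_layers
  list(W = lapply(seq_len(K), function(l) model$params[[paste0("dec_W", l)]]),
       b = lapply(seq_len(K), function(l) model$params[[paste0("dec_b", l)]]))
}

.LV_CLAMP <- 10    # log-variance clamp
.ETA_CLAMP <- 13   # log-mean / logit clamp for decoder heads

# Full forward pass.  X: raw counts (B x G).  eps: B x L standard-normal
# draws (NULL -> posterior mean, i.e. eps = 0).
.forward <- function(model, X, eps = NULL) {
  p <- model$params
  act <- model$network$activation
  e_in <- .encoder_input(model, X)
  enc <- .enc_layers(model)
  fe <- .dense_forward(e_in, enc$W, enc$b, act)
  mu_z <- sweep(fe$out %*% p$W_mu, 2, p$b_mu, "+")
  lv <- .clamp(sweep(fe$out %*% p$W_lv, 2, p$b_lv, "+"),
               -.LV_CLAMP, .LV_CLAMP)
  sd_z <- exp(0.5 * lv)
  if (is.null(eps)) eps <- matrix(0, nrow(mu_z), ncol(mu_z))
  z <- mu_z + sd_z * eps

  dec <- .dec_layers(model)
  fd <- .dense_forward(z, dec$W, dec$b, act)
  a_mu <- .clamp(sweep(fd$out %*% p$W_gene_mu, 2, p$b_gene_mu, "+"),
                 -.ETA_CLAMP, .ETA_CLAMP)
  s_pi <- .clamp(sweep(fd$out %*% p$W_gene_pi, 2, p$b_gene_pi, "+"),
                 -.ETA_CLAMP, .ETA_CLAMP)
  theta <- exp(.clamp(p$log_theta, -8, 8))

  out <- list(e_in = e_in, fe = fe, mu_z = mu_z, lv = lv, sd_z = sd_z,
              eps = eps, z = z, fd = fd,
              a_mu = a_mu, mu_x = exp(a_mu),
              s_pi = s_pi, pi_x = .sigmoid(s_pi), theta = theta)
  if (model$n_proteins > 0) {
    eta_y <- .clamp(sweep(fd$out %*% p$W_label, 2, p$b_label, "+"),
                    -.ETA_CLAMP, .ETA_CLAMP)
    out$eta_y <- eta_y
    if (model$network$label_likelihood == "bernoulli") {
      out$p_y <- .sigmoid(eta_y)
    } else {
      out$mu_y <- exp(eta_y)
      out$theta_y <- exp(.clamp(p$log_theta_label, -8, 8))
    }
  }
  out
}

# ZINB log-likelihood matrix plus derivatives of the NEGATIVE
# log-likelihood w.r.t. the log-mean preactivation, the dropout logit,
# and log(theta).  All inputs are B x G matrices except theta (length G).
.zinb_terms <- function(x, mu, theta_vec, pi, want_grad = TRUE) {
  B <- nrow(x); G <- ncol(x)
  theta <- matrix(theta_vec, B, G, byrow = TRUE)
  tm <- theta + mu
  log_ratio <- log(theta) - log(tm)
  xpos <- x > 0
  nbll <- lgamma(x + theta) - lgamma(theta) - lgamma(x + 1) +
    theta * log_ratio + ifelse(xpos, x * (log(mu) - log(tm)), 0)
  p0 <- exp(theta * log_ratio)
  A <- pi + (1 - pi) * p0
  ll <- ifelse(xpos, log1p(-pi) + nbll, log(A))
  out <- list(ll = ll)
  if (want_grad) {
    out$g_a <- ifelse(xpos,
                      mu * (x + theta) / tm - x,
                      (1 - pi) * p0 * theta * mu / (tm * A))
    out$g_s <- ifelse(xpos,
                      pi,
                      -pi * (1 - pi) * (1 - p0) / A)
    g_theta <- ifelse(xpos,
                      -(digamma(x + theta) - digamma(theta) + log_ratio +
                          (mu - x) / tm),
                      -(1 - pi) * p0 * (log_ratio + mu / tm) / A)
    out$g_lt <- g_theta * theta    # chain through theta = exp(log_theta)
  }
  out
}

# NB log-likelihood + gradients for the label head (no zero inflation)
.nb_terms <- function(x, mu, theta_vec, want_grad = TRUE) {
  B <- nrow(x); G <- ncol(x)
  theta <- matrix(theta_vec, B, G, byrow = TRUE)
  tm <- theta + mu
  log_ratio <- log(theta) - log(tm)
  ll <- lgamma(x + theta) - lgamma(theta) - lgamma(x + 1) +
    theta * log_ratio + ifelse(x > 0, x * (log(mu) - log(tm)), 0)
  out <- list(ll = ll)
  if (want_grad) {
    out$g_a <- mu * (x + theta) / tm - x
    out$g_lt <- -(digamma(x + theta) - digamma(theta) + log_ratio +
                    (mu - x) / tm) * theta
  }
  out
}

.kl_per_cell <- function(mu_z, lv) {
  rowSums(0.5 * (mu_z^2 + exp(lv) - 1 - lv))
}

# label negative log-likelihood per cell (B vector) + gradient w.r.t.
# the head preactivation
.label_terms <- function(model, fwd, labels, want_grad = TRUE) {
  if (model$network$label_likelihood == "bernoulli") {
    if (any(labels < 0 | labels > 1))
      .stopf("bernoulli label head expects targets in [0, 1]")
    eta <- fwd$eta_y
    # -log lik = softplus(eta) - t * eta  (stable cross-entropy)
    nll <- rowSums(.softplus(eta) - labels * eta)
    g_eta <- if (want_grad) fwd$p_y - labels else NULL
  } else {
    terms <- .nb_terms(labels, fwd$mu_y, fwd$theta_y, want_grad)
    nll <- -rowSums(terms$ll)
    g_eta <- if (want_grad) terms$g_a else NULL
    if (want_grad) attr(g_eta, "g_lt") <- terms$g_lt
  }
  list(nll = nll, g_eta = g_eta)
}

# ---------------------------------------------------------------------
# objectives

#' Unsupervised evidence lower bound
#'
#' `ELBO = E_q[log p(x|z)] - KL(q(z|x) || N(0, I))`, estimated with
#' `n_samples` Monte-Carlo draws of z through the reparameterization
#' trick.
#'
#' @param model an `scvae_model`.
#' @param counts a [count_matrix()] or numeric matrix (cells x genes).
#' @param n_samples Monte-Carlo samples (default 1).
#' @param eps optional fixed noise: a `B x n_latent` matrix (or a list
#'   of them, one per sample) to evaluate the bound on given draws.
#' @return A list with per-batch means `elbo`, `recon`
#'   (`E_q[log p(x|z)]`) and `kl`.
#' @export
elbo_unsupervised <- function(model, counts, n_samples = 1L, eps = NULL) {
  X <- .as_count_values(counts)
  if (ncol(X) != model$n_genes)
    .stopf("counts have %d genes but the model expects %d",
           ncol(X), model$n_genes)
  if (nrow(X) == 0) .stopf("empty batch")
  L <- model$network$n_latent
  if (is.matrix(eps)) eps <- list(eps)
  recon <- 0; kl <- NA_real_
  for (s in seq_len(n_samples)) {
    e <- if (is.null(eps)) matrix(rnorm(nrow(X) * L), nrow(X), L)
         else eps[[s]]
    fwd <- .forward(model, X, e)
    terms <- .zinb_terms(X, fwd$mu_x, fwd$theta, fwd$pi_x,
                         want_grad = FALSE)
    recon <- recon + mean(rowSums(terms$ll)) / n_samples
    kl <- mean(.kl_per_cell(fwd$mu_z, fwd$lv))  # same for every sample
  }
  list(elbo = recon - kl, recon = recon, kl = kl)
}

#' Semisupervised training objective
#'
#' `-ELBO + gamma * L_y` where `L_y` is the label negative
#' log-likelihood averaged over the masked (labeled) cells only; cells
#' outside the mask contribute only the unsupervised part.  With
#' `gamma = 0` or an all-false mask this equals the negative ELBO.
#'
#' @param model an `scvae_model`.
#' @param counts counts batch (cells x genes).
#' @param labels cells x proteins target matrix (may be `NULL` when the
#'   mask is all false).
#' @param label_mask logical vector marking which cells carry labels.
#' @param gamma supervised weight (>= 0).
#' @param eps optional fixed reparameterization noise (see
#'   [elbo_unsupervised()]).
#' @return A list with `total`, `recon_nll`, `kl`, `supervised_nll`
#'   (the per-labeled-cell mean; 0 when no cell is masked).
#' @export
total_loss <- function(model, counts, labels = NULL, label_mask = NULL,
                       gamma = 0, eps = NULL) {
  X <- .as_count_values(counts)
  B <- nrow(X)
  if (is.null(label_mask)) label_mask <- rep(FALSE, B)
  if (!is.null(labels) && !any(label_mask) && gamma > 0)
    .warnf("labels supplied but label_mask is all false; ignoring labels")
  L <- model$network$n_latent
  if (is.null(eps)) eps <- matrix(rnorm(B * L), B, L)
  fwd <- .forward(model, X, eps)
  terms <- .zinb_terms(X, fwd$mu_x, fwd$theta, fwd$pi_x, want_grad = FALSE)
  recon_nll <- mean(-rowSums(terms$ll))
  kl <- mean(.kl_per_cell(fwd$mu_z, fwd$lv))
  sup <- 0
  if (any(label_mask) && model$n_proteins > 0 && !is.null(labels)) {
    lt <- .label_terms(model, fwd, as.matrix(labels), want_grad = FALSE)
    sup <- mean(lt$nll[label_mask])
  }
  list(total = recon_nll + kl + gamma * sup,
       recon_nll = recon_nll, kl = kl, supervised_nll = sup)
}

# ---------------------------------------------------------------------
# analytic gradient of the training objective for one minibatch

.batch_grad <- function(model, X, eps, labels, label_mask, gamma) {
  p <- model$params
  act <- model$network$activation
  B <- nrow(X)
  fwd <- .forward(model, X, eps)

  zt <- .zinb_terms(X, fwd$mu_x, fwd$theta, fwd$pi_x)
  recon_nll <- mean(-rowSums(zt$ll))
  kl <- mean(.kl_per_cell(fwd$mu_z, fwd$lv))

  w <- 1 / B
  g <- list()
  d_amu <- zt$g_a * w
  d_spi <- zt$g_s * w
  g$W_gene_mu <- crossprod(fwd$fd$out, d_amu)
  g$b_gene_mu <- colSums(d_amu)
  g$W_gene_pi <- crossprod(fwd$fd$out, d_spi)
  g$b_gene_pi <- colSums(d_spi)
  g$log_theta <- colSums(zt$g_lt) * w

  delta_trunk <- d_amu %*% t(p$W_gene_mu) + d_spi %*% t(p$W_gene_pi)

  sup_nll <- 0
  has_labels <- gamma > 0 && model$n_proteins > 0 && !is.null(labels) &&
    any(label_mask)
  if (has_labels) {
    lt <- .label_terms(model, fwd, labels)
    n_lab <- sum(label_mask)
    sup_nll <- mean(lt$nll[label_mask])
    wy <- (gamma / n_lab) * label_mask   # zero rows for unlabeled cells
    d_eta <- lt$g_eta * wy
    g$W_label <- crossprod(fwd$fd$out, d_eta)
    g$b_label <- colSums(d_eta)
    if (model$network$label_likelihood == "nb")
      g$log_theta_label <- colSums(attr(lt$g_eta, "g_lt") * wy)
    delta_trunk <- delta_trunk + d_eta %*% t(p$W_label)
  }

  dec <- .dec_layers(model)
  bd <- .dense_backward(fwd$z, fwd$fd, dec$W, delta_trunk, act)
  K <- model$network$n_hidden_layers
  for (l in seq_len(K)) {
    g[[paste0("dec_W", l)]] <- bd$gW[[l]]
    g[[paste0("dec_b", l)]] <- bd$gb[[l]]
  }

  d_z <- bd$d_input
  d_mu_z <- d_z + fwd$mu_z * w
  d_lv <- d_z * 0.5 * (fwd$z - fwd$mu_z) +
    0.5 * (exp(fwd$lv) - 1) * w
  g$W_mu <- crossprod(fwd$fe$out, d_mu_z)
  g$b_mu <- colSums(d_mu_z)
  g$W_lv <- crossprod(fwd$fe$out, d_lv)
  g$b_lv <- colSums(d_lv)

  delta_h <- d_mu_z %*% t(p$W_mu) + d_lv %*% t(p$W_lv)
  enc <- .enc_layers(model)
  be <- .dense_backward(fwd$e_in, fwd$fe, enc$W, delta_h, act)
  for (l in seq_len(K)) {
    g[[paste0("enc_W", l)]] <- be$gW[[l]]
    g[[paste0("enc_b", l)]] <- be$gb[[l]]
  }

  list(grads = g,
       loss = list(total = recon_nll + kl + gamma * sup_nll,
                   recon_nll = recon_nll, kl = kl,
                   supervised_nll = sup_nll))
}

# ---------------------------------------------------------------------
# training

.align_labels <- function(labels, cell_ids, n_proteins, likelihood) {
  if (is.null(labels)) return(NULL)
  if (inherits(labels, "probabilized_labels")) {
    m <- labels$prob
  } else if (inherits(labels, "protein_table")) {
    m <- labels$values
  } else {
    m <- as.matrix(labels)
  }
  if (!is.null(rownames(m))) {
    keep <- intersect(cell_ids, rownames(m))
    full <- matrix(NA_real_, length(cell_ids), ncol(m),
                   dimnames = list(cell_ids, colnames(m)))
    full[keep, ] <- m[keep, , drop = FALSE]
    m <- full
  } else if (nrow(m) != length(cell_ids)) {
    .stopf("unnamed label matrix must have one row per cell")
  }
  if (ncol(m) != n_proteins)
    .stopf("label matrix has %d proteins but the model expects %d",
           ncol(m), n_proteins)
  if (likelihood == "nb") {
    ok <- is.finite(m)
    if (any(m[ok] < 0) || any(m[ok] != floor(m[ok])))
      .stopf("NB label head expects non-negative integer targets")
  }
  m
}

#' Fit the model
#'
#' Minibatch ADAM training of the semisupervised objective.  When
#' `labels` are supplied, a seeded `label_fraction`-sized subset of the
#' labeled cells is made visible to the supervised head; all other cells
#' contribute only the unsupervised ELBO.  A held-out validation slice
#' of the cells drives early stopping.  Labels are used only through the
#' training objective, never at inference time.
#'
#' @param model an `scvae_model` from [scvae_model()].
#' @param counts a [count_matrix()] (cells x genes) of raw counts.
#' @param labels optional supervision targets: a `probabilized_labels`
#'   object, a [protein_table()] (for the NB head), or a numeric matrix
#'   with cell rownames.  Rows are matched to `counts` by cell id; cells
#'   without a label row are treated as unlabeled.
#' @param training a [training_config()].
#' @return The fitted `scvae_model`, with `$history` holding a
#'   data.frame of per-epoch loss components (`epoch`, `recon_nll`,
#'   `kl`, `supervised_nll`, `total`, `val_total`).
#' @export
fit_scvae <- function(model, counts, labels = NULL,
                      training = training_config()) {
  stopifnot(inherits(model, "scvae_model"),
            inherits(training, "training_config"))
  X <- .as_count_values(counts)
  if (ncol(X) != model$n_genes)
    .stopf("counts have %d genes but the model expects %d",
           ncol(X), model$n_genes)
  cell_ids <- if (inherits(counts, "count_matrix")) counts$cell_ids
              else rownames(X)
  if (is.null(cell_ids)) cell_ids <- paste0("cell", seq_len(nrow(X)))
  n <- nrow(X)

  model$size_factor_ref <- stats::median(rowSums(X))
  if (model$size_factor_ref <= 0) model$size_factor_ref <- 1
  if (inherits(counts, "count_matrix")) model$gene_ids <- counts$gene_ids

  lab <- .align_labels(labels, cell_ids, model$n_proteins,
                       model$network$label_likelihood)
  if (!is.null(lab) && model$n_proteins == 0)
    .stopf("model was built without a label head; rebuild with n_proteins > 0")
  if (!is.null(lab)) model$protein_ids <- colnames(lab)

  # label visibility mask: labeled rows, thinned to label_fraction
  has_lab <- if (is.null(lab)) rep(FALSE, n) else rowSums(is.na(lab)) == 0
  set.seed(.derive_seed(training$seed, 23L))
  if (any(has_lab) && training$label_fraction < 1) {
    idx <- which(has_lab)
    keep <- sample(idx, floor(training$label_fraction * length(idx)))
    has_lab[] <- FALSE
    has_lab[keep] <- TRUE
  }
  if (training$label_fraction == 0) has_lab[] <- FALSE
  if (!any(has_lab)) lab <- NULL           # fully unlabeled run
  if (!is.null(lab)) lab[!has_lab, ] <- 0  # masked rows never touched

  # validation slice for early stopping
  set.seed(.derive_seed(training$seed, 31L))
  n_val <- floor(training$validation_fraction * n)
  val_idx <- if (n_val >= 5) sample.int(n, n_val) else integer(0)
  tr_idx <- setdiff(seq_len(n), val_idx)

  L <- model$network$n_latent
  opt <- .adam_init(model$params)
  hist <- vector("list", training$max_epochs)
  best_val <- Inf; best_params <- NULL; stall <- 0L

  set.seed(.derive_seed(training$seed, 47L))
  for (epoch in seq_len(training$max_epochs)) {
    ord <- tr_idx[sample.int(length(tr_idx))]
    batches <- split(ord, ceiling(seq_along(ord) / training$batch_size))
    ep <- c(total = 0, recon_nll = 0, kl = 0, supervised_nll = 0)
    nb <- 0
    for (b in batches) {
      Xb <- X[b, , drop = FALSE]
      labb <- if (is.null(lab)) NULL else lab[b, , drop = FALSE]
      acc <- NULL
      for (s in seq_len(training$n_mc_samples)) {
        epsb <- matrix(rnorm(length(b) * L), length(b), L)
        res <- .batch_grad(model, Xb, epsb, labb, has_lab[b],
                           training$gamma)
        if (is.null(acc)) acc <- res
        else {
          acc$grads <- Map(`+`, acc$grads, res$grads)
          acc$loss <- Map(`+`, acc$loss, res$loss)
        }
      }
      if (training$n_mc_samples > 1L) {
        acc$grads <- lapply(acc$grads, `/`, training$n_mc_samples)
        acc$loss <- lapply(acc$loss, `/`, training$n_mc_samples)
      }
      if (!is.finite(acc$loss$total))
        .stopf(paste0("non-finite loss at epoch %d (recon=%.3g kl=%.3g ",
                      "supervised=%.3g); try a lower learning rate"),
               epoch, acc$loss$recon_nll, acc$loss$kl,
               acc$loss$supervised_nll)
      acc$grads <- .clip_global_norm(acc$grads, training$max_grad_norm)
      step <- .adam_step(model$params, acc$grads, opt,
                         training$learning_rate)
      model$params <- step$params
      opt <- step$state
      ep <- ep + unlist(acc$loss)[names(ep)]
      nb <- nb + 1
    }
    ep <- ep / nb

    val_total <- NA_real_
    if (length(val_idx) > 0) {
      epsv <- matrix(rnorm(length(val_idx) * L), length(val_idx), L)
      vl <- total_loss(model, X[val_idx, , drop = FALSE],
                       labels = if (is.null(lab)) NULL
                                else lab[val_idx, , drop = FALSE],
                       label_mask = has_lab[val_idx],
                       gamma = training$gamma, eps = epsv)
      val_total <- vl$total
    }
    hist[[epoch]] <- data.frame(epoch = epoch, recon_nll = ep["recon_nll"],
                                kl = ep["kl"],
                                supervised_nll = ep["supervised_nll"],
                                total = ep["total"], val_total = val_total,
                                row.names = NULL)
    if (training$verbose)
      message(sprintf("epoch %3d  total %.3f  recon %.3f  kl %.3f  sup %.3f  val %.3f",
                      epoch, ep["total"], ep["recon_nll"], ep["kl"],
                      ep["supervised_nll"], val_total))

    monitor <- if (is.na(val_total)) ep["total"] else val_total
    if (monitor < best_val - 1e-6) {
      best_val <- monitor; best_params <- model$params; stall <- 0L
    } else {
      stall <- stall + 1L
      if (is.finite(training$patience) && stall >= training$patience) break
    }
  }
  if (!is.null(best_params)) model$params <- best_params
  model$history <- do.call(rbind, hist[!vapply(hist, is.null, logical(1))])
  model$fitted <- TRUE
  model$training <- training
  model
}

# ---------------------------------------------------------------------
# inference (labels are never consumed here)

#' Encode cells into the latent posterior
#'
#' Deterministic: returns the mean and standard deviation of `q(z|x)`
#' per cell; no sampling, no label input.
#'
#' @param model an `scvae_model`.
#' @param counts counts (cells x genes), same gene set as training.
#' @return A list of class `latent_code` with matrices `mean` and
#'   `stddev` (cells x n_latent) and `cell_ids`.
#' @export
encode <- function(model, counts) {
  X <- .as_count_values(counts)
  if (ncol(X) != model$n_genes)
    .stopf("counts have %d genes but the model expects %d",
           ncol(X), model$n_genes)
  fwd <- .forward(model, X, eps = NULL)
  structure(list(mean = fwd$mu_z, stddev = exp(0.5 * fwd$lv),
                 cell_ids = if (inherits(counts, "count_matrix"))
                   counts$cell_ids else rownames(X)),
            class = "latent_code")
}

#' Decode latent codes into distribution parameters
#'
#' Runs the shared decoder trunk and both linear heads.
#'
#' @param model an `scvae_model`.
#' @param z numeric matrix (cells x n_latent).
#' @return A list with `gene` (fields `mean`, `dispersion`,
#'   `dropout_prob`) and, if the model has a label head, `label`
#'   (`prob` for a Bernoulli head, `mean`/`dispersion` for NB).
#' @export
decode <- function(model, z) {
  z <- as.matrix(z)
  if (ncol(z) != model$network$n_latent)
    .stopf("z has dimension %d but n_latent is %d",
           ncol(z), model$network$n_latent)
  p <- model$params
  act <- model$network$activation
  dec <- .dec_layers(model)
  fd <- .dense_forward(z, dec$W, dec$b, act)
  a_mu <- .clamp(sweep(fd$out %*% p$W_gene_mu, 2, p$b_gene_mu, "+"),
                 -.ETA_CLAMP, .ETA_CLAMP)
  s_pi <- .clamp(sweep(fd$out %*% p$W_gene_pi, 2, p$b_gene_pi, "+"),
                 -.ETA_CLAMP, .ETA_CLAMP)
  out <- list(gene = list(mean = exp(a_mu),
                          dispersion = exp(.clamp(p$log_theta, -8, 8)),
                          dropout_prob = .sigmoid(s_pi)))
  if (model$n_proteins > 0) {
    eta <- .clamp(sweep(fd$out %*% p$W_label, 2, p$b_label, "+"),
                  -.ETA_CLAMP, .ETA_CLAMP)
    out$label <- if (model$network$label_likelihood == "bernoulli")
      list(prob = .sigmoid(eta))
    else
      list(mean = exp(eta),
           dispersion = exp(.clamp(p$log_theta_label, -8, 8)))
  }
  out
}

#' Denoised (imputed) gene expression
#'
#' Decodes the posterior mean of each cell and returns the expected
#' value of the zero-inflated negative binomial: `(1 - pi) * mu`
#' (default), or the NB mean `mu` alone with `type = "nb_mean"`.
#'
#' @param model a fitted `scvae_model`.
#' @param counts counts (cells x genes).
#' @param type `"expected"` (default) or `"nb_mean"`.
#' @return Non-negative numeric matrix, cells x genes.
#' @export
impute <- function(model, counts, type = c("expected", "nb_mean")) {
  type <- match.arg(type)
  if (!model$fitted) .stopf("model is not fitted; call fit_scvae() first")
  X <- .as_count_values(counts)
  z <- encode(model, counts)$mean
  dec <- decode(model, z)
  out <- if (type == "expected")
    (1 - dec$gene$dropout_prob) * dec$gene$mean
  else dec$gene$mean
  dimnames(out) <- dimnames(X)
  out
}

#' Predict surface-protein response from expression alone
#'
#' Decodes the label head at each cell's posterior mean.  No protein
#' measurements are consumed: prediction needs only the count matrix.
#'
#' @param model a fitted `scvae_model` trained with a label head.
#' @param counts counts (cells x genes).
#' @return Cells x proteins matrix: Bernoulli probabilities in `(0, 1)`
#'   or NB means, depending on the head.
#' @export
predict_protein <- function(model, counts) {
  if (!model$fitted) .stopf("model is not fitted; call fit_scvae() first")
  if (model$n_proteins == 0)
    .stopf("model was trained without a label head; cannot predict proteins")
  z <- encode(model, counts)$mean
  dec <- decode(model, z)
  out <- if (model$network$label_likelihood == "bernoulli")
    dec$label$prob else dec$label$mean
  rn <- if (inherits(counts, "count_matrix")) counts$cell_ids
        else rownames(.as_count_values(counts))
  dimnames(out) <- list(rn, model$protein_ids)
  out
}

#' Importance-weighted marginal log-likelihood
#'
#' Per-cell estimate `log (1/S) sum_s p(x|z_s) p(z_s) / q(z_s|x)` with
#' `z_s ~ q(z|x)`.  At `S = 1` this is a single-sample ELBO draw; the
#' expectation is non-decreasing in `S`.
#'
#' @param model a fitted (or initialized) `scvae_model`.
#' @param counts counts (cells x genes).
#' @param n_importance_samples number of importance samples `S` (>= 1).
#' @param seed optional seed for the draws.
#' @return Numeric vector: one estimate (nats) per cell.
#' @export
marginal_log_likelihood <- function(model, counts,
                                    n_importance_samples = 64L,
                                    seed = NULL) {
  S <- as.integer(n_importance_samples)
  if (S < 1) .stopf("n_importance_samples must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  X <- .as_count_values(counts)
  B <- nrow(X); L <- model$network$n_latent
  logw <- matrix(NA_real_, B, S)
  for (s in seq_len(S)) {
    eps <- matrix(rnorm(B * L), B, L)
    fwd <- .forward(model, X, eps)
    ll_x <- rowSums(.zinb_terms(X, fwd$mu_x, fwd$theta, fwd$pi_x,
                                want_grad = FALSE)$ll)
    lp_z <- rowSums(dnorm(fwd$z, log = TRUE))
    lq_z <- rowSums(dnorm(fwd$z, fwd$mu_z, fwd$sd_z, log = TRUE))
    logw[, s] <- ll_x + lp_z - lq_z
  }
  out <- apply(logw, 1, .logsumexp) - log(S)
  names(out) <- rownames(X)
  out
}

# ---------------------------------------------------------------------
# checkpointing

#' Save / load a model checkpoint
#'
#' A single JSON archive holding the architecture configuration and all
#' parameter arrays (with shapes), plus the training history.
#'
#' @param model an `scvae_model`.
#' @param path file path (conventionally `.json`).
#' @export
write_scvae <- function(model, path) {
  stopifnot(inherits(model, "scvae_model"))
  params <- lapply(model$params, function(p)
    list(dim = if (is.matrix(p)) dim(p) else length(p),
         data = as.numeric(p)))
  payload <- list(network = unclass(model$network),
                  n_genes = model$n_genes, n_proteins = model$n_proteins,
                  size_factor_ref = model$size_factor_ref,
                  fitted = model$fitted,
                  gene_ids = model$gene_ids,
                  protein_ids = model$protein_ids,
                  params = params,
                  history = model$history)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_scvae
#' @return `read_scvae()` returns the restored `scvae_model`.
#' @export
read_scvae <- function(path) {
  pl <- jsonlite::read_json(path, simplifyVector = TRUE,
                            simplifyDataFrame = TRUE)
  net <- do.call(network_config,
                 pl$network[c("n_hidden_layers", "n_hidden_units",
                              "n_latent", "activation",
                              "label_likelihood")])
  params <- lapply(pl$params, function(p) {
    d <- p$dim
    if (length(d) == 2) matrix(p$data, d[1], d[2]) else as.numeric(p$data)
  })
  structure(list(network = net,
                 n_genes = as.integer(pl$n_genes),
                 n_proteins = as.integer(pl$n_proteins),
                 params = params,
                 size_factor_ref = pl$size_factor_ref,
                 fitted = isTRUE(pl$fitted),
                 history = if (is.data.frame(pl$history)) pl$history
                           else NULL,
                 gene_ids = pl$gene_ids, protein_ids = pl$protein_ids,
                 init_seed = NA_integer_),
            class = "scvae_model")
}
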