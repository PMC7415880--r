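# Count and latent distributions used by the model.
#
# The negative binomial is parameterized by its mean mu and inverse
# dispersion theta, with variance mu + mu^2 / theta.  The classic
# (r, p) parameterization maps onto this as r = theta and
# p = theta / (theta + mu).

#' Negative binomial parameters (mean / inverse-dispersion)
#'
#' @param mean positive mean `mu`, per gene per cell (vectorized).
#' @param dispersion positive inverse dispersion `theta`; the variance is
#'   `mu + mu^2 / theta`, so larger `theta` means closer to Poisson.
#' @return A list of class `nb_params`.
#' @export
nb_params <- function(mean, dispersion) {
  if (any(!is.finite(mean)) || any(mean <= 0))
    .stopf("NB mean must be positive and finite")
  if (any(!is.finite(dispersion)) || any(dispersion <= 0))
    .stopf("NB dispersion must be positive and finite")
  structure(list(mean = mean, dispersion = dispersion), class = "nb_params")
}

#' Zero-inflated negative binomial parameters
#'
#' @param nb an [nb_params()] object.
#' @param dropout_prob zero-inflation rate `pi` in `[0, 1]`: the
#'   probability that an observation is a structural (dropout) zero.
#' @return A list of class `zinb_params`.
#' @export
zinb_params <- function(nb, dropout_prob) {
  stopifnot(inherits(nb, "nb_params"))
  if (any(!is.finite(dropout_prob)) || any(dropout_prob < 0) ||
      any(dropout_prob > 1))
    .stopf("dropout_prob must lie in [0, 1]")
  structure(list(nb = nb, dropout_prob = dropout_prob),
            class = "zinb_params")
}

#' Diagonal Gaussian parameters
#'
#' @param mean real vector (latent dimension).
#' @param stddev positive real vector, same length.
#' @return A list of class `gaussian_params`.
#' @export
gaussian_params <- function(mean, stddev) {
  if (length(mean) != length(stddev))
    .stopf("mean and stddev must have equal length")
  if (any(!is.finite(stddev)) || any(stddev <= 0))
    .stopf("stddev must be positive and finite")
  structure(list(mean = mean, stddev = stddev), class = "gaussian_params")
}

#' Negative binomial log probability mass
#'
#' Computes `lgamma(x + theta) - lgamma(theta) - lgamma(x + 1) +
#' theta * log(theta / (theta + mu)) + x * log(mu / (theta + mu))`.
#'
#' @param x non-negative integer counts (vectorized).
#' @param params an [nb_params()] object; `mean` and `dispersion` recycle
#'   against `x`.
#' @return Log density, same length as the broadcast inputs.
#' @export
nb_log_prob <- function(x, params) {
  stopifnot(inherits(params, "nb_params"))
  .assert_count_vector(x)
  mu <- params$mean
  theta <- params$dispersion
  # x * log(mu) is defined as 0 at x = 0 even when mu underflows to 0
  xterm <- ifelse(x == 0, 0, x * (log(mu) - log(theta + mu)))
  lgamma(x + theta) - lgamma(theta) - lgamma(x + 1) +
    theta * (log(theta) - log(theta + mu)) + xterm
}

#' Zero-inflated negative binomial log probability mass
#'
#' For `x = 0` the mass is `pi + (1 - pi) * NB(0)`, combined in log space
#' with log-sum-exp; for `x > 0` it is `log(1 - pi) + nb_log_prob(x)`.
#'
#' @param x non-negative integer counts.
#' @param params a [zinb_params()] object.
#' @return Log density values.
#' @export
zinb_log_prob <- function(x, params) {
  stopifnot(inherits(params, "zinb_params"))
  .assert_count_vector(x)
  pi <- params$dropout_prob
  nb_ll <- nb_log_prob(x, params$nb)
  n <- max(length(x), length(pi), length(nb_ll))
  x <- rep_len(x, n); pi <- rep_len(pi, n); nb_ll <- rep_len(nb_ll, n)
  out <- numeric(n)
  zero <- x == 0
  # x > 0: only the NB component can generate it
  out[!zero] <- log1p(-pi[!zero]) + nb_ll[!zero]
  if (any(zero)) {
    lp <- ifelse(pi[zero] > 0, log(pi[zero]), -Inf)
    lq <- ifelse(pi[zero] < 1, log1p(-pi[zero]) + nb_ll[zero], -Inf)
    m <- pmax(lp, lq)
    out[zero] <- m + log(exp(lp - m) + exp(lq - m))
    out[zero][pi[zero] == 1] <- 0   # pure dropout: P(0) = 1
  }
  out
}

#' KL divergence of a diagonal Gaussian from the standard normal
#'
#' `KL(N(mu, diag(sigma^2)) || N(0, I)) =
#'  sum_d 0.5 * (mu_d^2 + sigma_d^2 - 1 - log sigma_d^2)`, in nats.
#' Non-negative, zero iff `mu = 0, sigma = 1`.
#'
#' @param q a [gaussian_params()] object.
#' @return A single non-negative number.
#' @export
gaussian_kl_to_standard <- function(q) {
  stopifnot(inherits(q, "gaussian_params"))
  s2 <- q$stddev^2
  sum(0.5 * (q$mean^2 + s2 - 1 - log(s2)))
}

#' Sample from a zero-inflated negative binomial
#'
#' Draws NB counts and independently zeroes each with probability
#' `dropout_prob`.
#'
#' @param params a [zinb_params()] object (scalar parameters).
#' @param n number of draws.
#' @param seed integer seed; required for reproducibility.
#' @return Integer vector of length `n`.
#' @export
sample_zinb <- function(params, n, seed) {
  stopifnot(inherits(params, "zinb_params"), n >= 1)
  set.seed(seed)
  base <- rnbinom(n, size = params$nb$dispersion, mu = params$nb$mean)
  keep <- rbinom(n, 1L, 1 - params$dropout_prob)
  as.integer(base * keep)
}
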