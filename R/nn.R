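# Minimal dense-network machinery: Glorot initialization, forward and
# backward passes for fully connected stacks, and an ADAM optimizer.
# All state is plain R matrices so models serialize to JSON cleanly.

.glorot <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(runif(n_in * n_out, -lim, lim), n_in, n_out)
}

.act <- function(x, kind) {
  switch(kind,
         relu = pmax(x, 0),
         tanh = tanh(x),
         .stopf("unknown activation '%s'", kind))
}

# derivative of the activation given preactivation and activation value
.act_grad <- function(pre, post, kind) {
  switch(kind,
         relu = (pre > 0) + 0,
         tanh = 1 - post^2,
         .stopf("unknown activation '%s'", kind))
}

# Forward through a stack of dense layers; returns activations and
# preactivations for use in the backward pass.
.dense_forward <- function(x, Ws, bs, kind) {
  L <- length(Ws)
  pre <- vector("list", L)
  post <- vector("list", L)
  h <- x
  for (l in seq_len(L)) {
    pre[[l]] <- sweep(h %*% Ws[[l]], 2, bs[[l]], "+")
    post[[l]] <- .act(pre[[l]], kind)
    h <- post[[l]]
  }
  list(out = h, pre = pre, post = post)
}

# Backward through the stack. delta is dLoss/d(output activations).
# Returns gradients for each W and b plus dLoss/d(input).
.dense_backward <- function(x, fwd, Ws, delta, kind) {
  L <- length(Ws)
  gW <- vector("list", L)
  gb <- vector("list", L)
  for (l in rev(seq_len(L))) {
    d_pre <- delta * .act_grad(fwd$pre[[l]], fwd$post[[l]], kind)
    input <- if (l == 1) x else fwd$post[[l - 1]]
    gW[[l]] <- crossprod(input, d_pre)
    gb[[l]] <- colSums(d_pre)
    delta <- d_pre %*% t(Ws[[l]])
  }
  list(gW = gW, gb = gb, d_input = delta)
}

# ADAM state for a named list of parameter arrays
.adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

.adam_step <- function(params, grads, state, lr, beta1 = 0.9,
                       beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# rescale gradients so their global L2 norm is at most max_norm
.clip_global_norm <- function(grads, max_norm) {
  total <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
  if (is.finite(total) && total > max_norm)
    grads <- lapply(grads, function(g) g * (max_norm / total))
  grads
}
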