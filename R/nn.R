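# Minimal dense-network engine: He-initialised fully connected layers,
# manual backpropagation, Adam. All training in this package runs through
# these primitives; sizes are small enough that base BLAS matmuls dominate.

act_forward <- function(a, act) {
  switch(act,
    linear  = a,
    relu    = pmax(a, 0),
    sigmoid = 1 / (1 + exp(-a)),
    stop("unknown activation: ", act)
  )
}

# derivative expressed through pre-activation `a` and post-activation `h`
act_backward <- function(d, a, h, act) {
  switch(act,
    linear  = d,
    relu    = d * (a > 0),
    sigmoid = d * h * (1 - h),
    stop("unknown activation: ", act)
  )
}

# widths: c(input, hidden..., output); acts: one per weight layer.
# Draws from the current RNG stream; callers seed it.
mlp_init <- function(widths, acts) {
  stopifnot(length(acts) == length(widths) - 1L, all(widths >= 1L))
  L <- length(acts)
  W <- vector("list", L)
  b <- vector("list", L)
  for (l in seq_len(L)) {
    fan_in <- widths[l]
    W[[l]] <- matrix(stats::rnorm(fan_in * widths[l + 1L], sd = sqrt(2 / fan_in)),
                     fan_in, widths[l + 1L])
    b[[l]] <- numeric(widths[l + 1L])
  }
  structure(list(W = W, b = b, acts = acts, widths = widths), class = "survaug_mlp")
}

mlp_forward <- function(net, X, keep_cache = FALSE) {
  h <- X
  L <- length(net$W)
  pre <- if (keep_cache) vector("list", L) else NULL
  post <- if (keep_cache) vector("list", L + 1L) else NULL
  if (keep_cache) post[[1L]] <- X
  for (l in seq_len(L)) {
    a <- h %*% net$W[[l]]
    a <- sweep(a, 2L, net$b[[l]], "+")
    h <- act_forward(a, net$acts[l])
    if (keep_cache) {
      pre[[l]] <- a
      post[[l + 1L]] <- h
    }
  }
  if (keep_cache) list(out = h, pre = pre, post = post) else h
}

# dout: gradient of the loss w.r.t. the network output.
# Returns per-layer weight/bias gradients and the gradient w.r.t. the input.
mlp_backward <- function(net, cache, dout) {
  L <- length(net$W)
  gW <- vector("list", L)
  gb <- vector("list", L)
  d <- dout
  for (l in rev(seq_len(L))) {
    d <- act_backward(d, cache$pre[[l]], cache$post[[l + 1L]], net$acts[l])
    gW[[l]] <- crossprod(cache$post[[l]], d)
    gb[[l]] <- colSums(d)
    d <- tcrossprod(d, net$W[[l]])
  }
  list(W = gW, b = gb, dinput = d)
}

adam_init <- function(net) {
  zeros <- function(p) if (is.matrix(p)) matrix(0, nrow(p), ncol(p)) else numeric(length(p))
  list(
    mW = lapply(net$W, zeros), vW = lapply(net$W, zeros),
    mb = lapply(net$b, zeros), vb = lapply(net$b, zeros),
    t = 0L
  )
}

adam_step <- function(net, state, grads, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (l in seq_along(net$W)) {
    state$mW[[l]] <- beta1 * state$mW[[l]] + (1 - beta1) * grads$W[[l]]
    state$vW[[l]] <- beta2 * state$vW[[l]] + (1 - beta2) * grads$W[[l]]^2
    net$W[[l]] <- net$W[[l]] - lr * (state$mW[[l]] / bc1) / (sqrt(state$vW[[l]] / bc2) + eps)
    state$mb[[l]] <- beta1 * state$mb[[l]] + (1 - beta1) * grads$b[[l]]
    state$vb[[l]] <- beta2 * state$vb[[l]] + (1 - beta2) * grads$b[[l]]^2
    net$b[[l]] <- net$b[[l]] - lr * (state$mb[[l]] / bc1) / (sqrt(state$vb[[l]] / bc2) + eps)
  }
  list(net = net, state = state)
}

# add gradients accumulated from two loss terms on the same network
grads_add <- function(g1, g2, weight2 = 1) {
  list(
    W = Map(function(a, b) a + weight2 * b, g1$W, g2$W),
    b = Map(function(a, b) a + weight2 * b, g1$b, g2$b)
  )
}

grads_zero <- function(net) {
  list(
    W = lapply(net$W, function(p) matrix(0, nrow(p), ncol(p))),
    b = lapply(net$b, function(p) numeric(length(p)))
  )
}
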