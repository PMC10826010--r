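# Minimal dense-network engine used by the adversarial backends.
#
# Everything is plain matrix algebra on (n x d) batches with manual
# backpropagation and Adam updates. Critics use leaky-relu hidden layers and
# a linear scalar output; for such piecewise-linear networks the gradient of
# the WGAN gradient-penalty term with respect to the weights has a closed
# form (activation masks are locally constant, exactly as reverse-mode
# autodiff treats them), implemented in nn_gp_grads(). All gradients are
# verified against central finite differences in the test suite.

nn_act <- function(z, act, alpha = 0.2) {
  switch(act,
    linear = z,
    relu = pmax(z, 0),
    lrelu = ifelse(z > 0, z, alpha * z),
    tanh = tanh(z),
    sigmoid = 1 / (1 + exp(-pmin(pmax(z, -30), 30)))
  )
}

nn_act_grad <- function(z, h, act, alpha = 0.2) {
  switch(act,
    linear = matrix(1, nrow(z), ncol(z)),
    relu = (z > 0) * 1,
    lrelu = ifelse(z > 0, 1, alpha),
    tanh = 1 - h^2,
    sigmoid = h * (1 - h)
  )
}

# He-style initialisation; sizes = c(d_in, hidden..., d_out)
nn_new <- function(sizes, hidden_act = "relu", out_act = "linear") {
  L <- length(sizes) - 1L
  W <- vector("list", L); b <- vector("list", L)
  for (k in seq_len(L)) {
    W[[k]] <- matrix(stats::rnorm(sizes[k] * sizes[k + 1], 0,
                                  sqrt(2 / sizes[k])),
                     sizes[k], sizes[k + 1])
    b[[k]] <- rep(0, sizes[k + 1])
  }
  list(W = W, b = b, sizes = sizes, hidden_act = hidden_act,
       out_act = out_act)
}

nn_forward <- function(net, X, keep_cache = TRUE) {
  L <- length(net$W)
  Z <- vector("list", L); H <- vector("list", L + 1L)
  H[[1]] <- X
  for (k in seq_len(L)) {
    Z[[k]] <- sweep(H[[k]] %*% net$W[[k]], 2, net$b[[k]], "+")
    act <- if (k < L) net$hidden_act else net$out_act
    H[[k + 1]] <- nn_act(Z[[k]], act)
  }
  if (keep_cache) list(out = H[[L + 1]], Z = Z, H = H) else H[[L + 1]]
}

# dOut: gradient of the loss wrt the activated output (n x d_out)
nn_backward <- function(net, cache, dOut) {
  L <- length(net$W)
  gW <- vector("list", L); gb <- vector("list", L)
  delta <- dOut
  for (k in rev(seq_len(L))) {
    act <- if (k < L) net$hidden_act else net$out_act
    delta <- delta * nn_act_grad(cache$Z[[k]], cache$H[[k + 1]], act)
    gW[[k]] <- crossprod(cache$H[[k]], delta)
    gb[[k]] <- colSums(delta)
    if (k > 1) delta <- delta %*% t(net$W[[k]])
  }
  list(gW = gW, gb = gb, dX = delta %*% t(net$W[[1]]))
}

# Per-sample gradient of a scalar-output network wrt its input (n x d_in);
# also returns the per-layer deltas and masks needed by nn_gp_grads().
nn_input_grad <- function(net, X) {
  L <- length(net$W)
  fwd <- nn_forward(net, X)
  n <- nrow(X)
  masks <- vector("list", L - 1L)
  for (k in seq_len(L - 1L)) {
    masks[[k]] <- nn_act_grad(fwd$Z[[k]], fwd$H[[k + 1]], net$hidden_act)
  }
  deltas <- vector("list", L)
  deltas[[L]] <- matrix(1, n, 1)  # linear scalar output
  for (k in rev(seq_len(L - 1L))) {
    deltas[[k]] <- (deltas[[k + 1]] %*% t(net$W[[k + 1]])) * masks[[k]]
  }
  list(G = deltas[[1]] %*% t(net$W[[1]]), deltas = deltas, masks = masks,
       out = fwd$out)
}

# Gradient-penalty term mean_i (||grad_x D(x_i)|| - 1)^2 and its weight
# gradients (bias gradients vanish for piecewise-linear hidden units).
nn_gp_grads <- function(net, X) {
  L <- length(net$W)
  ig <- nn_input_grad(net, X)
  G <- ig$G
  n <- nrow(X)
  norms <- sqrt(rowSums(G^2))
  loss <- mean((norms - 1)^2)
  coef <- 2 * (norms - 1) / (n * pmax(norms, 1e-12))
  A <- G * coef  # dLoss/dG
  gW <- vector("list", L); gb <- vector("list", L)
  for (k in seq_len(L)) {
    gW[[k]] <- crossprod(A, ig$deltas[[k]])
    gb[[k]] <- rep(0, length(net$b[[k]]))
    if (k < L) A <- (A %*% net$W[[k]]) * ig$masks[[k]]
  }
  list(loss = loss, gW = gW, gb = gb)
}

nn_zero_like <- function(net) {
  list(gW = lapply(net$W, function(w) w * 0),
       gb = lapply(net$b, function(b) b * 0))
}

nn_add_grads <- function(a, b, scale = 1) {
  list(gW = Map(function(x, y) x + scale * y, a$gW, b$gW),
       gb = Map(function(x, y) x + scale * y, a$gb, b$gb))
}

# Adam (beta1 = 0.5, beta2 = 0.9 -- the usual WGAN-GP schedule)
adam_new <- function(net) {
  list(mW = lapply(net$W, function(w) w * 0),
       vW = lapply(net$W, function(w) w * 0),
       mb = lapply(net$b, function(b) b * 0),
       vb = lapply(net$b, function(b) b * 0),
       t = 0)
}

adam_step <- function(net, opt, grads, lr, beta1 = 0.5, beta2 = 0.9,
                      eps = 1e-8) {
  opt$t <- opt$t + 1
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (k in seq_along(net$W)) {
    opt$mW[[k]] <- beta1 * opt$mW[[k]] + (1 - beta1) * grads$gW[[k]]
    opt$vW[[k]] <- beta2 * opt$vW[[k]] + (1 - beta2) * grads$gW[[k]]^2
    net$W[[k]] <- net$W[[k]] -
      lr * (opt$mW[[k]] / bc1) / (sqrt(opt$vW[[k]] / bc2) + eps)
  }
  for (k in seq_along(net$b)) {
    opt$mb[[k]] <- beta1 * opt$mb[[k]] + (1 - beta1) * grads$gb[[k]]
    opt$vb[[k]] <- beta2 * opt$vb[[k]] + (1 - beta2) * grads$gb[[k]]^2
    net$b[[k]] <- net$b[[k]] -
      lr * (opt$mb[[k]] / bc1) / (sqrt(opt$vb[[k]] / bc2) + eps)
  }
  list(net = net, opt = opt)
}

# Batch Pearson correlation matrix (population moments) with a validity mask
# for (near-)constant columns.
batch_pearson <- function(X, eps = 1e-8) {
  n <- nrow(X)
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  s <- sqrt(colMeans(Xc^2))
  ok <- s > eps
  Z <- Xc
  Z[, ok] <- sweep(Xc[, ok, drop = FALSE], 2, s[ok], "/")
  R <- crossprod(Z) / n
  R[!ok, ] <- NA; R[, !ok] <- NA
  diag(R)[ok] <- 1
  list(R = R, Z = Z, s = s, ok = ok)
}

# Value and gradient (wrt the synthetic batch Xf) of the correlation
# alignment penalty lambda * sum_{i>j} |r_hat_ij - r_ij|. Pairs undefined on
# either side (constant columns) are excluded.
align_penalty_grad <- function(Xf, R_real, lambda) {
  p <- ncol(Xf)
  n <- nrow(Xf)
  bp <- batch_pearson(Xf)
  D <- bp$R - R_real
  valid <- !is.na(D)
  diag(valid) <- FALSE
  lt <- lower.tri(D)
  val <- lambda * sum(abs(D[lt & valid]))
  if (lambda == 0) {
    return(list(value = 0, grad = matrix(0, n, p)))
  }
  S <- sign(D)
  S[!valid] <- 0
  cvec <- rowSums(S * ifelse(is.na(bp$R), 0, bp$R))
  grad <- (bp$Z %*% S - sweep(bp$Z, 2, cvec, "*"))
  grad <- sweep(grad, 2, n * pmax(bp$s, 1e-12), "/")
  grad[, !bp$ok] <- 0
  list(value = val, grad = lambda * grad)
}
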