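# Minimal dense feed-forward network engine used by the autoencoder and the
# predictor: full-batch gradient descent with momentum, an exponential
# learning-rate decay schedule, optional inverted dropout on hidden layers,
# an l2 weight penalty, and relative-improvement early stopping. All
# randomness (initialization, dropout masks) is driven by an explicit seed.

mlp_act <- function(z, kind) {
  switch(kind,
         linear = z,
         relu = pmax(z, 0),
         elu = { neg <- z < 0; z[neg] <- expm1(z[neg]); z },
         sigmoid = 1 / (1 + exp(-z)),
         stop("unknown activation: ", kind))
}

# derivative of the activation, written in terms of pre-activation z and
# activation value a (cheaper for sigmoid/elu)
mlp_act_grad <- function(z, a, kind) {
  switch(kind,
         linear = 1,
         relu = (z > 0) * 1,
         elu = { g <- a + 1; g[z > 0] <- 1; g },
         sigmoid = a * (1 - a),
         stop("unknown activation: ", kind))
}

# sizes: widths including input and output; activations: one per layer
mlp_new <- function(sizes, activations, seed) {
  stopifnot(length(activations) == length(sizes) - 1)
  set.seed(seed)
  W <- vector("list", length(sizes) - 1)
  b <- vector("list", length(sizes) - 1)
  for (l in seq_along(W)) {
    s <- sqrt(6 / (sizes[l] + sizes[l + 1]))  # Glorot uniform
    W[[l]] <- matrix(stats::runif(sizes[l] * sizes[l + 1], -s, s), sizes[l], sizes[l + 1])
    b[[l]] <- rep(0, sizes[l + 1])
  }
  list(sizes = sizes, act = activations, W = W, b = b)
}

mlp_forward <- function(net, X, dropout = 0, training = FALSE) {
  L <- length(net$W)
  A <- vector("list", L + 1)
  Z <- vector("list", L)
  M <- vector("list", L)
  A[[1]] <- X
  for (l in seq_len(L)) {
    Z[[l]] <- sweep(A[[l]] %*% net$W[[l]], 2, net$b[[l]], `+`)
    a <- mlp_act(Z[[l]], net$act[l])
    if (training && dropout > 0 && l < L) {  # hidden layers only
      M[[l]] <- matrix((stats::runif(length(a)) >= dropout) / (1 - dropout), nrow(a), ncol(a))
      a <- a * M[[l]]
    }
    A[[l + 1]] <- a
  }
  list(A = A, Z = Z, M = M)
}

mlp_predict <- function(net, X) {
  mlp_forward(net, X)$A[[length(net$W) + 1]]
}

# Full-batch training against mean squared error, using adaptive
# moment-estimated gradient descent (Adam) under an exponential
# learning-rate decay schedule: the step size decays by `decay` once per
# `decay_every` epochs. Training stops early when the relative loss
# improvement over `patience` consecutive epochs falls below `tol`.
# Returns the trained net plus the loss trace.
mlp_train <- function(net, X, Y, epochs, learning_rate, decay = 1, decay_every = 1000,
                      l2 = 0, dropout = 0, beta1 = 0.9, beta2 = 0.999,
                      tol = 1e-6, patience = 100, seed = 1) {
  stopifnot(nrow(X) == nrow(Y))
  set.seed(seed)
  L <- length(net$W)
  mW <- lapply(net$W, function(w) w * 0); vW <- mW
  mb <- lapply(net$b, function(b) b * 0); vb <- mb
  eps <- 1e-8
  n_elem <- nrow(Y) * ncol(Y)
  loss_trace <- numeric(0)
  ref_loss <- Inf
  for (epoch in seq_len(epochs)) {
    lr <- learning_rate * decay^((epoch - 1) %/% decay_every)
    bc1 <- 1 - beta1^epoch
    bc2 <- 1 - beta2^epoch
    fw <- mlp_forward(net, X, dropout = dropout, training = TRUE)
    err <- fw$A[[L + 1]] - Y
    mse <- mean(err^2)
    if (!is.finite(mse) || mse > 1e100)
      stop("divergence: training loss became non-finite at epoch ", epoch,
           "; lower the learning rate")
    loss_trace[epoch] <- mse
    if (epoch %% patience == 0) {
      if ((ref_loss - mse) < tol * max(ref_loss, 1e-12)) break
      ref_loss <- mse
    }
    delta <- 2 * err / n_elem
    for (l in rev(seq_len(L))) {
      dZ <- delta * mlp_act_grad(fw$Z[[l]], mlp_act(fw$Z[[l]], net$act[l]), net$act[l])
      if (!is.null(fw$M[[l]])) dZ <- dZ * fw$M[[l]]
      gW <- crossprod(fw$A[[l]], dZ)
      gb <- colSums(dZ)
      if (l > 1) delta <- dZ %*% t(net$W[[l]])
      mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW
      vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW^2
      mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb
      vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb^2
      # l2 acts as decoupled weight decay, scaled by the current step size
      net$W[[l]] <- net$W[[l]] * (1 - lr * l2) -
        lr * (mW[[l]] / bc1) / (sqrt(vW[[l]] / bc2) + eps)
      net$b[[l]] <- net$b[[l]] - lr * (mb[[l]] / bc1) / (sqrt(vb[[l]] / bc2) + eps)
    }
  }
  final <- mean((mlp_predict(net, X) - Y)^2)
  list(net = net, mse = final, epochs = length(loss_trace), loss_trace = loss_trace)
}

# R^2 of predictions against observations, per the standard definition
# (residual sum of squares over corrected total of the evaluation set).
r_squared <- function(observed, predicted) {
  ss_tot <- sum(sweep(as.matrix(observed), 2, colMeans(as.matrix(observed)), `-`)^2)
  ss_res <- sum((as.matrix(observed) - as.matrix(predicted))^2)
  if (ss_tot <= 0) return(NA_real_)
  1 - ss_res / ss_tot
}
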